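# Diagnosis-code -> rhythm-class mapping, seeded from the PhysioNet/CinC
# 2020 SNOMED CT conventions. Two whitespace-separated columns:
#   <code> <class label>
# Class labels must come from the nine-entry vocabulary
# (AF IAVB LBBB RBBB PAC PVC SB STach SNR). Codes absent from this file are
# ignored when labelling a record. Edit a copy and pass its path to
# load_record()/read_dx_mapping() to override.
164889003	AF
270492004	IAVB
164909002	LBBB
59118001	RBBB
713427006	RBBB
284470004	PAC
63593006	PAC
427172004	PVC
17338001	PVC
426177001	SB
427084000	STach
426783006	SNR
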