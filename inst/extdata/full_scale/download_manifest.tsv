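# Source databases for full-scale training (PhysioNet Challenge 2020
# training tranches; WFDB headers + MAT signals, 12-lead, 500 Hz).
# Columns: database <tab> url <tab> n_records <tab> mains_hz
# After download + extraction, point run_pipeline(data_dir = ...) at a
# directory containing the .hea/.mat pairs converted to the packaged
# format-16 dialect (or adapt load_record to the MAT container).
CPSC2018	https://physionet.org/static/published-projects/challenge-2020/1.0.2/training/cpsc_2018/	5806	50
CPSC2018-Extra	https://physionet.org/static/published-projects/challenge-2020/1.0.2/training/cpsc_2018_extra/	920	50
Georgia	https://physionet.org/static/published-projects/challenge-2020/1.0.2/training/georgia/	6705	60
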