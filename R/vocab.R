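#' Rhythm class vocabulary
#'
#' The nine rhythm classes the classifier predicts, in the fixed order that
#' defines the multi-hot label index: atrial fibrillation (AF), first-degree
#' atrioventricular block (IAVB), left and right bundle branch block
#' (LBBB, RBBB), premature atrial and ventricular contractions (PAC, PVC),
#' sinus bradycardia (SB), sinus tachycardia (STach) and normal sinus rhythm
#' (SNR).
#'
#' @return Character vector of length 9 (the canonical label order).
#' @export
#' @examples
#' class_vocabulary()
class_vocabulary <- function() {
  c("AF", "IAVB", "LBBB", "RBBB", "PAC", "PVC", "SB", "STach", "SNR")
}

#' Diagnosis-code to class mapping
#'
#' Reads a two-column mapping file (diagnosis code, class label; `#` starts a
#' comment) and returns it as a named character vector. The packaged default
#' is seeded from the PhysioNet/CinC 2020 SNOMED CT conventions and is data,
#' not code: users may edit a copy and pass its path.
#'
#' @param path Mapping file; defaults to the table shipped with the package.
#' @return Named character vector: names are diagnosis codes, values are
#'   class labels from [class_vocabulary()].
#' @export
read_dx_mapping <- function(path = system.file("extdata", "dx_mapping.tsv",
                                               package = "ecmam")) {
  if (!file.exists(path)) stopf("mapping file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("code", "label"),
                           colClasses = "character")
  bad <- setdiff(unique(tab$label), class_vocabulary())
  if (length(bad))
    stopf("mapping file contains labels outside the vocabulary: %s",
          paste(bad, collapse = ", "))
  stats::setNames(tab$label, tab$code)
}

#' Map diagnosis codes to a multi-hot label vector
#'
#' @param codes Character vector of diagnosis codes (e.g. from a `Dx:` header
#'   comment).
#' @param mapping Named vector from [read_dx_mapping()].
#' @return Named integer 0/1 vector of length 9 in vocabulary order. Codes
#'   that map to none of the nine classes are ignored; if no code maps, the
#'   vector is all zero (the caller decides whether to keep the record).
#' @export
codes_to_labels <- function(codes, mapping = read_dx_mapping()) {
  lab <- stats::setNames(integer(9L), class_vocabulary())
  hit <- mapping[intersect(as.character(codes), names(mapping))]
  lab[unique(unname(hit))] <- 1L
  lab
}

standard_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}
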