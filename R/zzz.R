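#' @keywords internal
#' @useDynLib hlatyper, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
"_PACKAGE"

utils::globalVariables(c(
  "read", "read_id", "allele", "offset", "strand", "mismatches",
  "fragment", "fragment_id", "strand1", "strand2", "offset1", "offset2",
  "mismatches1", "mismatches2", "w", "lg", "locus", ".", "n"
))
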