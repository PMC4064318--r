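## Locus-level HLA expression: fragments are proportionally split over the
## determined two-digit groups they map to, then normalized to RPKM.

#' Proportional assignment of ambiguous fragments
#'
#' Each fragment contributes `1/k` to each of the `k` determined groups it
#' maps to (a fragment mapping to determined groups at two loci gives each
#' 0.5); fragments mapping to no determined group contribute nothing.
#'
#' @param read_to_groups list mapping fragment id to a character vector of
#'   determined groups it hits.
#' @param group_locus named character vector mapping group to locus.
#' @return named numeric vector of fractional counts per locus.
#' @export
proportional_assignment <- function(read_to_groups, group_locus) {
  out <- stats::setNames(numeric(length(unique(group_locus))),
                         unique(group_locus))
  for (groups in read_to_groups) {
    groups <- unique(groups[groups %in% names(group_locus)])
    k <- length(groups)
    if (k == 0L) next
    for (g in groups) {
      l <- group_locus[[g]]
      out[[l]] <- out[[l]] + 1 / k
    }
  }
  out
}

#' Reads-per-kilobase-per-million normalization
#'
#' @param fractional_count fragments (possibly fractional) assigned to the
#'   locus.
#' @param length_nt sub-transcript length in nucleotides.
#' @param total_reads total mapped reads of the library.
#' @return RPKM value.
#' @examples
#' rpkm(100, 694, 1e6) # ~144.09
#' @export
rpkm <- function(fractional_count, length_nt, total_reads) {
  if (any(length_nt <= 0)) stop("length_nt must be positive")
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  fractional_count / (length_nt / 1000) / (total_reads / 1e6)
}

#' Locus-level expression profile of a typed sample
#'
#' All mapped fragments are proportionally assigned over the groups called
#' by the typer, then each locus's fractional count is RPKM-normalized. The
#' normalization length is the mean sub-transcript length over the alleles
#' of that locus's called groups (`lengths = "reference"`) or the canonical
#' constants 694/694/694/400/421/421 nt (`lengths = "canonical"`) for a
#' paper-shaped reference.
#'
#' The per-million denominator defaults to the number of input fragments of
#' the sample; supply `total_reads` to normalize against an externally
#' computed library-wide mapped-read total instead.
#'
#' @param type an `hla_type` (from [type_sample()]).
#' @param db the `hla_refdb` the sample was typed against.
#' @param total_reads denominator override (default: input fragments).
#' @param lengths `"reference"` or `"canonical"`.
#' @return an `hla_expression`: data.frame with columns `sample_id`,
#'   `locus`, `fractional_count`, `length_nt`, `total_reads`, `rpkm`, plus
#'   attribute `class_totals` (summed RPKM for class I and II).
#' @export
expression_profile <- function(type, db, total_reads = NULL,
                               lengths = c("reference", "canonical")) {
  stopifnot(inherits(type, "hla_type"), inherits(db, "hla_refdb"))
  lengths <- match.arg(lengths)
  total <- if (is.null(total_reads)) type$n_fragments else total_reads
  determined <- determined_groups(type)
  loci <- names(type$calls)

  fh <- type$frag_hits
  frac <- stats::setNames(numeric(length(loci)), loci)
  if (nrow(fh) > 0L && length(determined) > 0L) {
    lg <- paste(db$locus, db$group, sep = "|")[fh$allele]
    keep <- lg %in% paste(names(determined), determined, sep = "|")
    sub <- unique(data.table::data.table(fragment = fh$fragment[keep],
                                         lg = lg[keep]))
    if (nrow(sub)) {
      sub[, w := 1 / .N, by = fragment]
      sub[, locus := sub("\\|.*$", "", lg)]
      agg <- sub[, .(n = sum(w)), by = locus]
      frac[agg$locus] <- agg$n
    }
  }
  len <- vapply(loci, function(l) {
    if (lengths == "canonical") {
      return(as.numeric(CANONICAL_SUBTRANSCRIPT_NT[[l]]))
    }
    gr <- determined[names(determined) == l]
    idx <- which(db$locus == l & db$group %in% gr)
    if (length(idx) == 0L) idx <- which(db$locus == l)
    mean(db$length_nt[idx])
  }, 1.0)
  out <- data.frame(
    sample_id = type$sample_id, locus = loci,
    fractional_count = unname(frac), length_nt = unname(len),
    total_reads = total,
    rpkm = rpkm(unname(frac), unname(len), total),
    stringsAsFactors = FALSE)
  cls <- ifelse(out$locus %in% HLA_CLASS1_LOCI, "I", "II")
  attr(out, "class_totals") <- c(
    I = sum(out$rpkm[cls == "I"]), II = sum(out$rpkm[cls == "II"]))
  class(out) <- c("hla_expression", "data.frame")
  out
}

## determined (called) groups per locus: first winner always, second winner
## when the locus is heterozygous
determined_groups <- function(type) {
  out <- character()
  for (cl in type$calls) {
    if (cl$no_call) next
    out <- c(out, stats::setNames(cl$call1$group, cl$locus))
    if (identical(cl$zygosity$status, "heterozygous") &&
        !is.null(cl$call2)) {
      out <- c(out, stats::setNames(cl$call2$group, cl$locus))
    }
  }
  out
}

#' @export
print.hla_expression <- function(x, ...) {
  cat("HLA expression profile,", x$sample_id[1], "\n")
  print.data.frame(cbind(x[, c("locus", "fractional_count", "length_nt")],
                         rpkm = signif(x$rpkm, 4)), row.names = FALSE)
  ct <- attr(x, "class_totals")
  cat(sprintf("class I total: %.4g RPKM, class II total: %.4g RPKM\n",
              ct[["I"]], ct[["II"]]))
  invisible(x)
}

#' Write the expression report TSV
#'
#' Per-locus rows followed by the class I / class II summary row pair.
#'
#' @param profile an `hla_expression`.
#' @param path output path.
#' @export
write_expression_report <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# hlatyper expression report (RPKM)", con)
  utils::write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ct <- attr(profile, "class_totals")
  writeLines(c(sprintf("# class_I_total_rpkm\t%.6g", ct[["I"]]),
               sprintf("# class_II_total_rpkm\t%.6g", ct[["II"]])), con)
  invisible(path)
}
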