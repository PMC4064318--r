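## Two-iteration two-digit HLA calling: per-locus winning group by maximal
## allele read count, an outlier p-value for each call, removal of
## first-winner reads before the second pass, and a median-threshold
## zygosity decision.

#' Winning two-digit group of a count distribution
#'
#' The called group is the one containing the allele with the globally
#' maximal read count. Ties across groups break lexicographically by group
#' name.
#'
#' @param counts an `hla_counts` object ([count_reads()]).
#' @return list with `group`, `read_count` (the maximal allele count) and
#'   `no_call` (`TRUE` when all counts are zero).
#' @export
top_group <- function(counts) {
  g <- group_values(counts)
  a <- max(g)
  if (a == 0L) {
    return(list(group = NA_character_, read_count = 0L, no_call = TRUE))
  }
  winners <- sort(names(g)[g == a])
  list(group = winners[[1L]], read_count = as.integer(a), no_call = FALSE)
}

#' Read-count outlier p-value of a called group
#'
#' The top count `a` is tested against the background of per-group counts:
#' `tail_prob` is the upper-tail probability of `a` under a normal
#' distribution with the sample mean and sample (n-1) standard deviation of
#' the background, and the p-value is the chance that at least one of the
#' `x` background draws exceeds `a`, i.e. `1 - (1 - tail_prob)^x`.
#'
#' In the first iteration the top count is removed from the background
#' (`mode = "exclude_top"`); in the second it is kept
#' (`mode = "include_top"`), which inflates the background mean and sd and
#' makes the test stricter.
#'
#' A zero-sd background degenerates to the normal limit: `tail_prob` 0 when
#' `a` is above the (constant) background, 0.5 at equality, 1 below.
#'
#' @param counts numeric vector of background read counts (per group).
#' @param a the top count being tested.
#' @param mode `"exclude_top"` or `"include_top"`.
#' @param printed_form if `TRUE`, return as `p_value` the complementary
#'   zero-successes binomial form `(1 - tail_prob)^x` instead (compatibility
#'   with the typeset formula; small values then mean uncertain calls).
#' @return list with `tail_prob`, `p_value` and `x` (background size used).
#' @export
outlier_pvalue <- function(counts, a,
                           mode = c("exclude_top", "include_top"),
                           printed_form = FALSE) {
  mode <- match.arg(mode)
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("empty count vector")
  if (mode == "exclude_top") {
    hit <- match(a, counts)
    if (!is.na(hit)) counts <- counts[-hit]
  }
  x <- length(counts)
  if (x == 0L) {
    return(list(tail_prob = NA_real_, p_value = 1, x = 0L))
  }
  m <- mean(counts)
  s <- if (x > 1L) stats::sd(counts) else 0
  tail_prob <- if (is.na(s) || s == 0) {
    if (a > m) 0 else if (a == m) 0.5 else 1
  } else {
    stats::pnorm(a, mean = m, sd = s, lower.tail = FALSE)
  }
  p <- -expm1(x * log1p(-tail_prob)) # 1 - (1 - tail)^x, precision-safe
  if (printed_form) p <- exp(x * log1p(-tail_prob))
  list(tail_prob = tail_prob, p_value = p, x = x)
}

#' Remove fragments associated with the winning group
#'
#' Every fragment with at least one hit on any allele of the winning group
#' at the given locus is removed; hits at other loci are untouched (each
#' locus's second iteration sees the full read set minus only its own first
#' winner's reads).
#'
#' @param frag_hits fragment-level hits ([fragment_hits()]).
#' @param db an `hla_refdb`.
#' @param winning_group group label (e.g. `"A*01"`).
#' @param locus locus name.
#' @return reduced fragment-hit `data.table`.
#' @export
remove_group_reads <- function(frag_hits, db, winning_group, locus) {
  locus <- normalize_locus(locus)
  win_idx <- which(db$locus == locus & db$group == winning_group)
  drop <- unique(frag_hits[allele %in% win_idx, fragment])
  frag_hits[!fragment %in% drop]
}

#' Zygosity decision for one locus
#'
#' The decision threshold is the median per-allele read count of the first
#' iteration (class I), halved for class II where pervasive ambiguous
#' mapping inflates the median. A second-iteration winner above the
#' threshold means heterozygous; below it, homozygous, with a certainty
#' p-value from the outlier test of the threshold itself against the
#' second-iteration group counts augmented by the threshold (the farther
#' the residual counts sit below the threshold, the smaller the p-value).
#' At equality, or when the homozygosity p-value does not pass `p_cutoff`,
#' the locus is reported ambiguous ("likely homozygous or single allele
#' expressed").
#'
#' @param counts1 iteration-1 `hla_counts` for the locus.
#' @param groupvals2 named vector of iteration-2 per-group counts.
#' @param call2_count read count of the iteration-2 winner (0 if none).
#' @param hla_class `"I"` or `"II"`.
#' @param p_cutoff call cutoff (default 0.1).
#' @return list with `status` (`"heterozygous"`, `"homozygous"` or
#'   `"ambiguous"`), `threshold` and `p_value` (homozygosity certainty; `NA`
#'   for heterozygous loci).
#' @export
zygosity <- function(counts1, groupvals2, call2_count, hla_class,
                     p_cutoff = 0.1) {
  med <- stats::median(as.numeric(counts1))
  thr <- if (hla_class == "II") med / 2 else med
  if (call2_count > thr) {
    return(list(status = "heterozygous", threshold = thr, p_value = NA_real_))
  }
  p_hom <- outlier_pvalue(c(as.numeric(groupvals2), thr), thr,
                          mode = "include_top")$p_value
  status <- if (call2_count == thr || p_hom >= p_cutoff) {
    "ambiguous"
  } else {
    "homozygous"
  }
  list(status = status, threshold = thr, p_value = p_hom)
}

#' Call one locus
#'
#' Runs the full two-iteration procedure at one locus: count, pick the
#' winning group, score it (background excludes the top count), remove the
#' winner's fragments, recount, pick and score the second winner (background
#' includes the top count), then decide zygosity.
#'
#' @param frag_hits fragment-level hits over the full read set.
#' @param db an `hla_refdb`.
#' @param locus locus name.
#' @param p_cutoff call cutoff (default 0.1).
#' @return an `hla_locus_call`: list with `locus`, `hla_class`, `call1`,
#'   `call2` (each: `group`, `read_count`, `tail_prob`, `p_value`),
#'   `zygosity` and `no_call`.
#' @export
call_locus <- function(frag_hits, db, locus, p_cutoff = 0.1) {
  locus <- normalize_locus(locus)
  hla_class <- if (locus %in% HLA_CLASS1_LOCI) "I" else "II"
  counts1 <- count_reads(frag_hits, db, locus, iteration = 1L)
  t1 <- top_group(counts1)
  out <- list(locus = locus, hla_class = hla_class, no_call = t1$no_call)
  class(out) <- "hla_locus_call"
  if (t1$no_call) {
    out$call1 <- list(group = NA_character_, read_count = 0L,
                      tail_prob = NA_real_, p_value = 1)
    out$call2 <- NULL
    out$zygosity <- list(status = "no_call", threshold = NA_real_,
                         p_value = NA_real_)
    return(out)
  }
  g1 <- group_values(counts1)
  p1 <- outlier_pvalue(g1, t1$read_count, mode = "exclude_top")
  out$call1 <- list(group = t1$group, read_count = t1$read_count,
                    tail_prob = p1$tail_prob, p_value = p1$p_value)

  reduced <- remove_group_reads(frag_hits, db, t1$group, locus)
  counts2 <- count_reads(reduced, db, locus, iteration = 2L)
  g2 <- group_values(counts2)
  t2 <- top_group(counts2)
  if (t2$no_call) {
    out$call2 <- NULL
    c2_count <- 0L
  } else {
    p2 <- outlier_pvalue(g2, t2$read_count, mode = "include_top")
    out$call2 <- list(group = t2$group, read_count = t2$read_count,
                      tail_prob = p2$tail_prob, p_value = p2$p_value)
    c2_count <- t2$read_count
  }
  out$zygosity <- zygosity(counts1, g2, c2_count, hla_class, p_cutoff)
  out
}

#' Type a sample from RNA-Seq reads
#'
#' Aligns all reads against the whole reference once, then calls every
#' locus independently (cross-locus ambiguous fragments count toward every
#' locus's background; first-winner removal is scoped per locus). Output is
#' deterministic for identical inputs.
#'
#' @param reads1 read sequences (named character vector or `DNAStringSet`),
#'   or a FASTQ path.
#' @param reads2 second mates (same forms), or `NULL` for single-end data.
#' @param db an `hla_refdb`.
#' @param cfg an [aligner_config()].
#' @param p_cutoff call cutoff (default 0.1).
#' @param sample_id sample label used in reports.
#' @param class_selection `"I"`, `"II"` or `"both"`.
#' @return an `hla_type`: list with `sample_id`, `calls` (one
#'   `hla_locus_call` per locus), `n_fragments`, `frag_hits`, `config`.
#' @export
type_sample <- function(reads1, reads2 = NULL, db, cfg = aligner_config(),
                        p_cutoff = 0.1, sample_id = "sample",
                        class_selection = c("both", "I", "II")) {
  class_selection <- match.arg(class_selection)
  if (is.character(reads1) && length(reads1) == 1L && file.exists(reads1)) {
    reads1 <- read_fastq(reads1)
  }
  if (is.character(reads2) && length(reads2) == 1L && file.exists(reads2)) {
    reads2 <- read_fastq(reads2)
  }
  if (!is.null(reads2) && length(reads1) != length(reads2)) {
    stop("mate files have unequal read counts (", length(reads1), " vs ",
         length(reads2), ")")
  }
  loci <- unique(db$locus)
  if (class_selection == "I") loci <- intersect(loci, HLA_CLASS1_LOCI)
  if (class_selection == "II") loci <- intersect(loci, HLA_CLASS2_LOCI)
  if (length(loci) == 0L) stop("no loci of the requested class in reference")
  fh <- fragment_hits(reads1, reads2, db, cfg)
  calls <- lapply(loci, function(l) call_locus(fh, db, l, p_cutoff))
  names(calls) <- loci
  structure(list(sample_id = sample_id, calls = calls,
                 n_fragments = length(reads1), frag_hits = fh,
                 config = c(unclass(cfg), list(p_cutoff = p_cutoff))),
            class = "hla_type")
}

#' Genotype table of a typed sample
#'
#' One row per locus mirroring the standard report layout: first and second
#' allele group with their p-values, zygosity status and homozygosity
#' p-value. Homozygous loci repeat the first group annotated `"homoz"`;
#' ambiguous loci are annotated `"likely homozygous or single allele
#' expressed"`.
#'
#' @param type an `hla_type`.
#' @return data.frame with columns `sample_id`, `locus`, `allele1`, `p1`,
#'   `allele2`, `p2`, `zygosity_status`, `zygosity_p`.
#' @export
genotype_table <- function(type) {
  stopifnot(inherits(type, "hla_type"))
  rows <- lapply(type$calls, function(cl) {
    zy <- cl$zygosity
    het <- identical(zy$status, "heterozygous")
    allele2 <- if (cl$no_call) {
      NA_character_
    } else if (het && !is.null(cl$call2)) {
      cl$call2$group
    } else {
      paste0(cl$call1$group, "'homoz'")
    }
    p2 <- if (het && !is.null(cl$call2)) cl$call2$p_value else zy$p_value
    data.frame(
      sample_id = type$sample_id, locus = cl$locus,
      allele1 = if (cl$no_call) NA_character_ else cl$call1$group,
      p1 = cl$call1$p_value,
      allele2 = allele2, p2 = p2,
      zygosity_status = zy$status, zygosity_p = zy$p_value,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.hla_type <- function(x, ...) {
  cat("HLA type for sample", x$sample_id, "\n")
  tab <- genotype_table(x)
  tab$p1 <- signif(tab$p1, 3)
  tab$p2 <- signif(tab$p2, 3)
  tab$zygosity_p <- signif(tab$zygosity_p, 3)
  print(tab[, c("locus", "allele1", "p1", "allele2", "p2",
                "zygosity_status")], row.names = FALSE)
  invisible(x)
}

#' Write the genotype report TSV
#'
#' Plain TSV with `#`-prefixed metadata lines followed by a single header.
#'
#' @param type an `hla_type`.
#' @param path output path.
#' @export
write_genotype_report <- function(type, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- type$config
  writeLines(c(
    paste0("# hlatyper genotype report"),
    sprintf("# sample=%s fragments=%d v=%d policy=%s paired=%s p_cutoff=%g",
            type$sample_id, type$n_fragments, cfg$v, cfg$report_policy,
            cfg$paired, cfg$p_cutoff)), con)
  utils::write.table(genotype_table(type), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
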