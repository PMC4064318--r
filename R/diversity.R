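## Allele-diversity analytics: per-position Shannon variability over an
## alignment, intra-/inter-group Hamming distance summaries, and the
## unique f-mer (tag) analysis relating read length and mismatch tolerance
## to allele distinguishability.

#' Per-position Shannon variability of aligned sequences
#'
#' For each column the variability is the Shannon entropy (binary log) of
#' the observed A/C/G/T frequencies, equivalently 2 minus the information
#' content: 0 when a single base is observed, 2 when all four are equally
#' frequent. Gap and `N` characters are excluded from the frequencies; a
#' column with no A/C/G/T at all scores 0.
#'
#' @param aligned_sequences character vector of equal-length sequences
#'   (an alignment).
#' @return numeric vector of per-column variabilities in `[0, 2]`.
#' @export
column_variability <- function(aligned_sequences) {
  if (length(aligned_sequences) < 2L) stop("need at least 2 sequences")
  n <- nchar(aligned_sequences)
  if (length(unique(n)) != 1L) stop("sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aligned_sequences), ""))
  apply(mat, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0L) return(0)
    f <- table(col) / length(col)
    -sum(f * log2(f))
  })
}

#' Hamming distance of two equal-length sequences
#'
#' @param seq_a,seq_b DNA strings of equal length.
#' @return integer count of differing positions.
#' @export
hamming <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences have unequal length (", nchar(seq_a), " vs ",
         nchar(seq_b), ")")
  }
  a <- strsplit(seq_a, "")[[1L]]
  b <- strsplit(seq_b, "")[[1L]]
  sum(a != b)
}

#' Intra- and inter-group mean Hamming distances
#'
#' Distances are computed over all sequence pairs and summarized per group
#' (mean over unordered within-group pairs; `NA` for single-member groups,
#' reported as absent rather than zero) and per group pair (mean over
#' cross-group pairs). Sequences of unequal length are right-trimmed to the
#' common minimum with a warning.
#'
#' @param seqs character vector of sequences, or an `hla_refdb` (whose
#'   exon 2(+3) region is used when exon annotations are available,
#'   otherwise the sub-transcripts).
#' @param groups character vector of group labels parallel to `seqs`
#'   (ignored when `seqs` is an `hla_refdb`).
#' @return list with `intra` (named numeric per group) and `inter`
#'   (symmetric group-by-group matrix, diagonal = intra).
#' @export
group_distance_summary <- function(seqs, groups = NULL) {
  if (inherits(seqs, "hla_refdb")) {
    db <- seqs
    groups <- db$group
    seqs <- vapply(seq_along(db$name), function(i) {
      ex <- db$exons[[i]]
      if (is.null(ex)) {
        db$seq[[i]]
      } else if (db$hla_class[[i]] == "I") {
        paste0(ex[["2"]], ex[["3"]])
      } else {
        ex[["2"]]
      }
    }, "")
  }
  stopifnot(length(seqs) == length(groups), length(seqs) >= 2L)
  n <- nchar(seqs)
  if (length(unique(n)) != 1L) {
    warning("unequal sequence lengths; right-trimming to ", min(n), " nt")
    seqs <- substr(seqs, 1L, min(n))
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  m <- length(seqs)
  d <- matrix(0L, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
    }
  }
  gs <- sort(unique(groups))
  inter <- matrix(NA_real_, length(gs), length(gs),
                  dimnames = list(gs, gs))
  for (a in seq_along(gs)) {
    for (b in a:length(gs)) {
      ia <- which(groups == gs[a])
      ib <- which(groups == gs[b])
      vals <- if (a == b) {
        if (length(ia) < 2L) NA_real_ else d[ia, ia][upper.tri(d[ia, ia])]
      } else {
        d[ia, ib, drop = FALSE]
      }
      inter[a, b] <- inter[b, a] <- mean(vals)
    }
  }
  list(intra = stats::setNames(diag(inter), gs), inter = inter)
}

#' Fraction of alleles carrying a unique tag f-mer
#'
#' An allele has a unique tag when at least one of its length-`f`
#' substrings occurs, within at most `v` mismatches and on either strand,
#' in no other allele of the scope. Longer tags and stricter mismatch
#' tolerance increase distinguishability; the fraction is non-increasing in
#' `v` and non-decreasing in `f`.
#'
#' @param db an `hla_refdb`.
#' @param scope `"all"`, a locus name, or `"I"`/`"II"` for a class.
#' @param f tag length (must not exceed the shortest sequence in scope;
#'   sequences shorter than `f` contribute no f-mers, with a warning).
#' @param v mismatch tolerance (0-2).
#' @return fraction of alleles in scope with at least one unique tag.
#' @export
unique_fmer_fraction <- function(db, scope = "all", f, v = 0L) {
  stopifnot(inherits(db, "hla_refdb"), f >= 1L, v >= 0L)
  idx <- switch(scope,
                all = seq_along(db$name),
                I = which(db$hla_class == "I"),
                II = which(db$hla_class == "II"),
                which(db$locus == normalize_locus(scope)))
  if (length(idx) < 2L) stop("scope must contain at least 2 alleles")
  seqs <- db$seq[idx]
  if (any(nchar(seqs) < f)) {
    warning("sequence(s) shorter than f contribute no f-mers")
  }
  has_unique <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    L <- nchar(s)
    if (L < f) return(FALSE)
    fmers <- substring(s, 1:(L - f + 1L), f:L)
    hits <- data.table::as.data.table(
      .align_reads_cpp(unique(fmers), seqs[-i], as.integer(v)))
    foreign <- unique(hits$read)
    length(foreign) < length(unique(fmers))
  }, TRUE)
  mean(has_unique)
}

#' Unique-tag fraction grid over f and v
#'
#' @inheritParams unique_fmer_fraction
#' @param f_values,v_values vectors of tag lengths and mismatch tolerances.
#' @return data.frame with columns `f`, `v`, `fraction`.
#' @export
unique_fmer_grid <- function(db, scope = "all", f_values, v_values = 0:2) {
  grid <- expand.grid(f = f_values, v = v_values)
  grid$fraction <- mapply(function(f, v) {
    unique_fmer_fraction(db, scope, f, v)
  }, grid$f, grid$v)
  grid
}
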