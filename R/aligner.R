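## Ungapped end-to-end read alignment against the reference sub-transcripts.
## The contract is a fixed mismatch budget v (Hamming placement, both
## strands, all offsets); report-all or unique-only policies; paired-end
## pairing with no insert-size constraint.

#' Aligner configuration
#'
#' Defaults reproduce the settings the method was tuned on: one allowed
#' mismatch and report-all (unique-only mapping loses most informative reads
#' across near-identical alleles and degrades typing badly).
#'
#' @param v mismatch budget, a non-negative integer (0-2 are the supported
#'   regimes).
#' @param report_policy `"all"` (default) or `"unique"`. Under `"unique"` a
#'   read (or fragment, in paired mode) is kept only if all of its hits fall
#'   on a single allele.
#' @param paired logical; paired-end input.
#' @return an `aligner_config` list.
#' @export
aligner_config <- function(v = 1L, report_policy = c("all", "unique"),
                           paired = TRUE) {
  v <- as.integer(v)
  stopifnot(length(v) == 1L, v >= 0L)
  structure(list(v = v, report_policy = match.arg(report_policy),
                 paired = isTRUE(paired)),
            class = "aligner_config")
}

validate_reads <- function(reads) {
  if (length(reads) == 0L) return(character())
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  up <- toupper(reads)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad)) {
    stop("read(s) contain non-ACGTN characters: ",
         paste(utils::head(names(reads)[bad], 5L), collapse = ", "))
  }
  names(up) <- names(reads)
  up
}

#' Align reads against a reference database
#'
#' Every full-length ungapped placement of each read (or of its reverse
#' complement, reported as strand `-`) with at most `cfg$v` mismatches is
#' returned. `N` in read or reference never matches. Internally a
#' pigeonhole seed index accelerates the scan; the hit set is identical to
#' exhaustive enumeration over all alleles, offsets and strands.
#'
#' @param reads character vector (or `DNAStringSet`) of read sequences;
#'   names are read ids.
#' @param db an `hla_refdb`.
#' @param cfg an [aligner_config()].
#' @return a `data.table` with columns `read_id`, `read` (index), `allele`
#'   (index into `db`), `offset` (0-based), `strand`, `mismatches`. Under
#'   `report_policy = "unique"`, reads whose hits span more than one allele
#'   are dropped entirely.
#' @export
align_reads <- function(reads, db, cfg = aligner_config()) {
  stopifnot(inherits(db, "hla_refdb"))
  nms <- names(reads)
  reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- nms
  reads <- validate_reads(reads)
  if (length(reads) == 0L) return(empty_hits())
  hits <- data.table::as.data.table(
    .align_reads_cpp(unname(reads), db$seq, cfg$v))
  hits[, read_id := names(reads)[read]]
  data.table::setcolorder(hits, c("read_id", "read", "allele", "offset",
                                  "strand", "mismatches"))
  if (cfg$report_policy == "unique") {
    hits <- hits[, if (data.table::uniqueN(allele) == 1L) .SD, by = read]
    data.table::setcolorder(hits, c("read_id", "read", "allele", "offset",
                                    "strand", "mismatches"))
  }
  data.table::setorder(hits, read, allele, offset, strand)
  hits[]
}

empty_hits <- function() {
  data.table::data.table(read_id = character(), read = integer(),
                         allele = integer(), offset = integer(),
                         strand = character(), mismatches = integer())
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one sequence.
#'
#' @param read_sequence a single DNA string.
#' @inheritParams align_reads
#' @return a `data.table` of hits (see [align_reads()]).
#' @export
align_read <- function(read_sequence, db, cfg = aligner_config()) {
  stopifnot(length(read_sequence) == 1L)
  align_reads(stats::setNames(as.character(read_sequence), "read1"), db, cfg)
}

#' Align mate pairs against a reference database
#'
#' A fragment hits an allele when both mates place on that allele (each
#' within the mismatch budget) on opposite strands; no insert-size or
#' ordering constraint is imposed. Under `report_policy = "unique"` a
#' fragment is kept only if all of its pair hits fall on one allele.
#'
#' @param reads1,reads2 mate sequences, equal length vectors; names of
#'   `reads1` are the fragment ids.
#' @inheritParams align_reads
#' @param detail if `TRUE`, return one row per concrete mate placement
#'   combination (columns `offset1`, `strand1`, `mismatches1`, `offset2`,
#'   `strand2`, `mismatches2`); otherwise one row per (fragment, allele).
#' @return a `data.table` with columns `fragment_id`, `fragment`, `allele`
#'   (plus placement columns when `detail = TRUE`).
#' @export
align_pairs <- function(reads1, reads2, db, cfg = aligner_config(),
                        detail = FALSE) {
  if (length(reads1) != length(reads2)) {
    stop("mate files have unequal read counts (", length(reads1), " vs ",
         length(reads2), ")")
  }
  sub <- aligner_config(v = cfg$v, report_policy = "all")
  h1 <- align_reads(reads1, db, sub)
  h2 <- align_reads(reads2, db, sub)
  if (detail) {
    pairs <- merge(
      h1[, .(read, allele, offset1 = offset, strand1 = strand,
             mismatches1 = mismatches)],
      h2[, .(read, allele, offset2 = offset, strand2 = strand,
             mismatches2 = mismatches)],
      by = c("read", "allele"), allow.cartesian = TRUE)
    pairs <- pairs[strand1 != strand2]
  } else {
    u1 <- unique(h1[, .(read, allele, strand)])
    u2 <- unique(h2[, .(read, allele, strand)])
    pairs <- merge(u1, u2, by = c("read", "allele"),
                   allow.cartesian = TRUE, suffixes = c("1", "2"))
    pairs <- unique(pairs[strand1 != strand2, .(read, allele)])
  }
  ids <- if (is.null(names(reads1))) {
    paste0("frag", seq_along(reads1))
  } else {
    names(reads1)
  }
  pairs[, fragment_id := ids[read]]
  data.table::setnames(pairs, "read", "fragment")
  if (cfg$report_policy == "unique") {
    pairs <- pairs[, if (data.table::uniqueN(allele) == 1L) .SD,
                   by = fragment]
  }
  front <- c("fragment_id", "fragment", "allele")
  data.table::setcolorder(pairs, c(front, setdiff(names(pairs), front)))
  data.table::setorderv(pairs, c("fragment", "allele"))
  pairs[]
}

#' Collapse alignments to fragment-level hits
#'
#' Unifies single- and paired-end alignment into the counting unit of the
#' typing algorithm: one row per (fragment, allele), a fragment being a
#' mate pair (paired mode) or a single read.
#'
#' @inheritParams align_pairs
#' @param reads2 second mates, or `NULL` for single-end input.
#' @return `data.table` with columns `fragment_id`, `fragment`, `allele`.
#' @export
fragment_hits <- function(reads1, reads2 = NULL, db,
                          cfg = aligner_config()) {
  if (!is.null(reads2)) {
    align_pairs(reads1, reads2, db, cfg)[, .(fragment_id, fragment, allele)]
  } else {
    h <- align_reads(reads1, db, cfg)
    unique(h[, .(fragment_id = read_id, fragment = read, allele)])
  }
}

#' Per-allele read counts at one locus
#'
#' Counts, for every allele of the locus, the number of distinct fragments
#' with at least one hit on that allele. One fragment may increment many
#' alleles: ambiguous mappings are intentional background for the outlier
#' statistics.
#'
#' @param frag_hits fragment-level hits from [fragment_hits()].
#' @param db an `hla_refdb`.
#' @param locus locus name.
#' @param iteration 1 or 2 (bookkeeping only).
#' @return an `hla_counts` object: named integer vector of counts (one per
#'   allele of the locus) with attributes `locus`, `iteration` and `group`
#'   (allele-to-group map).
#' @export
count_reads <- function(frag_hits, db, locus, iteration = 1L) {
  locus <- normalize_locus(locus)
  idx <- which(db$locus == locus)
  if (length(idx) == 0L) stop("locus not in reference: ", locus)
  sub <- frag_hits[allele %in% idx]
  counts <- integer(length(idx))
  names(counts) <- db$name[idx]
  if (nrow(sub)) {
    tab <- sub[, .(n = data.table::uniqueN(fragment)), by = allele]
    counts[match(db$name[tab$allele], names(counts))] <- tab$n
  }
  structure(counts, locus = locus, iteration = as.integer(iteration),
            group = stats::setNames(db$group[idx], db$name[idx]),
            class = "hla_counts")
}

#' @export
print.hla_counts <- function(x, ...) {
  cat(sprintf("read counts, locus %s (iteration %d): %d alleles, %d groups\n",
              attr(x, "locus"), attr(x, "iteration"), length(x),
              length(unique(attr(x, "group")))))
  g <- group_values(x)
  print(sort(g, decreasing = TRUE))
  invisible(x)
}

## per-group value = maximal allele count within the group
group_values <- function(counts) {
  g <- attr(counts, "group")
  vapply(split(as.integer(counts), g), max, 1L)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (optionally gzip-compressed).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ
#'
#' Placeholder constant qualities ("I") are emitted; the typing algorithm
#' does not use base qualities.
#'
#' @param reads named character vector of read sequences.
#' @param path output path; `.gz` suffix compresses.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    paste(rep("I", n), collapse = "")
  }, ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
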