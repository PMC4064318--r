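# Independent brute-force oracles used to validate the production code
# paths. These deliberately share no code with the package internals.

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# exhaustive enumeration of all ungapped placements of one read over all
# references, offsets and strands with <= v mismatches
oracle_align_read <- function(read, refs, v) {
  out <- list()
  for (st in c("+", "-")) {
    q <- if (st == "+") read else oracle_revcomp(read)
    qc <- strsplit(q, "")[[1L]]
    L <- length(qc)
    for (r in seq_along(refs)) {
      rc <- strsplit(refs[[r]], "")[[1L]]
      M <- length(rc)
      if (L > M) next
      for (off in 0:(M - L)) {
        seg <- rc[(off + 1L):(off + L)]
        mm <- sum(seg != qc | qc == "N" | seg == "N")
        if (mm <= v) {
          out[[length(out) + 1L]] <- data.frame(
            allele = r, offset = off, strand = st, mismatches = mm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(allele = integer(), offset = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

oracle_align_many <- function(reads, refs, v) {
  out <- lapply(seq_along(reads), function(i) {
    h <- oracle_align_read(reads[[i]], refs, v)
    if (nrow(h)) cbind(read = i, h) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(read = integer(), allele = integer(),
                      offset = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  }
  out
}

# an allele has a unique tag f-mer iff >= 1 of its f-mers occurs (within
# <= v mismatches, either strand) in no other sequence
oracle_unique_fmer_fraction <- function(seqs, f, v) {
  mean(vapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[[i]])
    if (L < f) return(FALSE)
    fmers <- unique(substring(seqs[[i]], 1:(L - f + 1L), f:L))
    any(vapply(fmers, function(q) {
      !any(vapply(seq_along(seqs)[-i], function(j) {
        nrow(oracle_align_read(q, seqs[j], v)) > 0L
      }, TRUE))
    }, TRUE))
  }, TRUE))
}

sort_hits <- function(h) {
  h <- as.data.frame(h)[, c("read", "allele", "offset", "strand",
                            "mismatches")]
  h <- h[do.call(order, h), , drop = FALSE]
  rownames(h) <- NULL
  h
}
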