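# Shared fixture builders; everything is generated in code, seeded.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reference database straight from sequences (no exon annotation)
toy_refdb <- function(seqs) {
  nm <- parse_allele_name(names(seqs))
  db <- list(name = names(seqs), locus = nm$locus, group = nm$group,
             hla_class = nm$hla_class, seq = toupper(unname(seqs)),
             length_nt = nchar(seqs),
             short_flank = rep(FALSE, length(seqs)),
             exons = rep(list(NULL), length(seqs)))
  class(db) <- "hla_refdb"
  db
}

# hla_counts object from a named count vector and allele -> group map
toy_counts <- function(counts, groups, locus = "A", iteration = 1L) {
  structure(as.integer(counts),
            names = names(counts), locus = locus,
            iteration = as.integer(iteration),
            group = groups, class = "hla_counts")
}

# small simulated world reused by several tests
small_sim <- function(seed = 11L, groups = 4L, alleles = 3L) {
  make_allele_db(sim_db_config(groups_per_locus = groups,
                               alleles_per_group = alleles, seed = seed))
}

# FASTA text for a toy class I allele set with exon annotations
toy_class1_fasta <- function() {
  set.seed(402)
  e1 <- rand_seq(73)
  e2 <- rand_seq(270)
  e3 <- rand_seq(276)
  e4 <- rand_seq(150)
  seqs <- c("A*01:01" = paste0(e1, e2, e3, e4),
            "A*02:01" = paste0(e1, e2, e3, e4),
            "B*07:02" = paste0(e1, e2, e3, e4))
  exons <- do.call(rbind, lapply(names(seqs), function(nm) {
    data.frame(name = nm, exon_index = 1:4,
               start = cumsum(c(1, 73, 270, 276)),
               end = cumsum(c(73, 270, 276, 150)))
  }))
  fasta <- paste(vapply(names(seqs), function(nm) {
    paste0(">", nm, "\n", seqs[[nm]])
  }, ""), collapse = "\n")
  list(fasta = fasta, exons = exons, seqs = seqs)
}
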