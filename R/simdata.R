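## Seeded simulator of HLA-like allele databases and diploid RNA-Seq read
## sets with known truth. The generator emulates the structure the typing
## algorithm exploits: two-digit groups with high intra-group similarity,
## moderate inter-group divergence, strong cross-locus conservation,
## diploid genotypes with homozygous and heterozygous loci, locus-specific
## expression, and short paired/single reads with substitution errors.

SIM_BASES <- c("A", "C", "G", "T")

#' Allele-database simulation configuration
#'
#' Divergence parameters are per-lineage substitution rates relative to the
#' immediate common ancestor: each locus ancestor is the class root mutated
#' at `cross_locus_divergence`, each group founder is the locus ancestor
#' mutated at `inter_group_divergence`, and each allele is its founder
#' mutated at `intra_group_divergence`. Expected pairwise Hamming fractions
#' are the corresponding path sums (so two alleles of different groups
#' differ by roughly twice the inter-group rate).
#'
#' Default exon lengths give paper-shaped sub-transcripts: class I exons
#' (73, 270, 276, 75) concatenate to 694 nt; class II exon 2 is 250 nt for
#' DQA1 and 271 nt for DQB1/DRB1, flanked by 75 nt each side, giving
#' 400/421/421 nt.
#'
#' @param loci named character vector: locus name -> class (`"I"`/`"II"`).
#' @param groups_per_locus,alleles_per_group integers (>= 1).
#' @param exon_lengths_class1 four class I exon lengths.
#' @param exon_lengths_class2 named list/vector: per class II locus, three
#'   exon lengths; unlisted loci fall back to `c(150, 270, 150)`.
#' @param intra_group_divergence,inter_group_divergence,cross_locus_divergence
#'   per-lineage substitution fractions; must satisfy
#'   `0 <= intra < inter <= cross <= 1`.
#' @param seed integer RNG seed.
#' @return a `sim_db_config` list.
#' @export
sim_db_config <- function(loci = c(A = "I", B = "I", C = "I",
                                   DQA1 = "II", DQB1 = "II", DRB1 = "II"),
                          groups_per_locus = 8L, alleles_per_group = 5L,
                          exon_lengths_class1 = c(73L, 270L, 276L, 75L),
                          exon_lengths_class2 = list(
                            DQA1 = c(75L, 250L, 75L),
                            DQB1 = c(75L, 271L, 75L),
                            DRB1 = c(75L, 271L, 75L)),
                          intra_group_divergence = 0.005,
                          inter_group_divergence = 0.03,
                          cross_locus_divergence = 0.08,
                          seed = 1L) {
  stopifnot(groups_per_locus >= 1L, alleles_per_group >= 1L,
            length(exon_lengths_class1) == 4L)
  if (!(0 <= intra_group_divergence &&
        intra_group_divergence < inter_group_divergence &&
        inter_group_divergence <= cross_locus_divergence &&
        cross_locus_divergence <= 1)) {
    stop("divergence ordering violated: need 0 <= intra < inter <= cross <= 1")
  }
  structure(list(
    loci = loci, groups_per_locus = as.integer(groups_per_locus),
    alleles_per_group = as.integer(alleles_per_group),
    exon_lengths_class1 = as.integer(exon_lengths_class1),
    exon_lengths_class2 = exon_lengths_class2,
    intra = intra_group_divergence, inter = inter_group_divergence,
    cross = cross_locus_divergence, seed = as.integer(seed)),
    class = "sim_db_config")
}

mutate_chars <- function(x, rate) {
  n <- stats::rbinom(1L, length(x), rate)
  if (n == 0L) return(x)
  pos <- sample.int(length(x), n)
  x[pos] <- vapply(x[pos], function(b) {
    sample(setdiff(SIM_BASES, b), 1L)
  }, "")
  x
}

locus_exon_lengths <- function(cfg, locus) {
  if (cfg$loci[[locus]] == "I") {
    cfg$exon_lengths_class1
  } else if (locus %in% names(cfg$exon_lengths_class2)) {
    as.integer(cfg$exon_lengths_class2[[locus]])
  } else {
    c(75L, 270L, 75L)
  }
}

#' Simulate an HLA-like allele database
#'
#' Deterministic under the config seed: identical configs yield
#' byte-identical sequences. Exon annotations are emitted so the reference
#' module can rebuild the sub-transcripts from the FASTA + exon table
#' exactly as for real input.
#'
#' @param cfg a [sim_db_config()].
#' @return a `sim_db` list: `db` (an `hla_refdb` of sub-transcripts),
#'   `fasta` (named character, full allele sequences), `exon_table`
#'   (data.frame `name`, `exon_index`, `start`, `end`), `ancestry`
#'   (data.frame `name`, `locus`, `group`) and `config`.
#' @export
make_allele_db <- function(cfg) {
  stopifnot(inherits(cfg, "sim_db_config"))
  set.seed(cfg$seed)
  max_len <- max(vapply(names(cfg$loci), function(l) {
    sum(locus_exon_lengths(cfg, l))
  }, 1L))
  roots <- list(
    I = sample(SIM_BASES, max_len, replace = TRUE),
    II = sample(SIM_BASES, max_len, replace = TRUE))
  records <- list()
  fasta <- character()
  exon_rows <- list()
  ancestry <- list()
  for (locus in names(cfg$loci)) {
    cls <- cfg$loci[[locus]]
    ex_len <- locus_exon_lengths(cfg, locus)
    total <- sum(ex_len)
    ancestor <- mutate_chars(roots[[cls]][seq_len(total)], cfg$cross)
    starts <- cumsum(c(1L, ex_len[-length(ex_len)]))
    ends <- cumsum(ex_len)
    for (g in seq_len(cfg$groups_per_locus)) {
      founder <- mutate_chars(ancestor, cfg$inter)
      group <- sprintf("%s*%02d", locus, g)
      for (a in seq_len(cfg$alleles_per_group)) {
        al <- mutate_chars(founder, cfg$intra)
        nm <- sprintf("%s:%02d", group, a)
        seqstr <- paste(al, collapse = "")
        fasta[[nm]] <- seqstr
        exon_rows[[nm]] <- data.frame(
          name = nm, exon_index = seq_along(ex_len),
          start = starts, end = ends, stringsAsFactors = FALSE)
        exons <- as.list(substring(seqstr, starts, ends))
        names(exons) <- as.character(seq_along(ex_len))
        records[[nm]] <- list(name = parse_allele_name(nm), exons = exons,
                              sequence = seqstr)
        ancestry[[nm]] <- data.frame(name = nm, locus = locus,
                                     group = group, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    db = build_reference_db(unname(records)),
    fasta = fasta,
    exon_table = do.call(rbind, c(unname(exon_rows),
                                  list(make.row.names = FALSE))),
    ancestry = do.call(rbind, c(unname(ancestry),
                                list(make.row.names = FALSE))),
    config = cfg), class = "sim_db")
}

#' Read-simulation configuration
#'
#' Defaults mirror the study conditions the method was developed for:
#' 37-nt paired-end reads with 1% per-base substitution error and at least
#' 2,000 fragments per locus.
#'
#' @param read_length read length in nt (30-100 is the sensible range).
#' @param paired logical; emit mate pairs from opposite fragment ends.
#' @param fragment_mean,fragment_sd normal fragment-length model (nt),
#'   truncated to `[read_length, sub-transcript length]`.
#' @param error_rate per-base substitution probability, in `[0, 0.1]`.
#' @param fragments_per_locus baseline fragments per locus.
#' @param expression_weights named per-locus multipliers of
#'   `fragments_per_locus` (relative expression levels); default 1.
#' @return a `sim_read_config` list.
#' @export
sim_read_config <- function(read_length = 37L, paired = TRUE,
                            fragment_mean = 120, fragment_sd = 20,
                            error_rate = 0.01, fragments_per_locus = 2000L,
                            expression_weights = NULL) {
  stopifnot(read_length >= 1L, error_rate >= 0, error_rate <= 0.1,
            fragment_mean >= read_length, fragments_per_locus >= 1L)
  structure(list(read_length = as.integer(read_length),
                 paired = isTRUE(paired), fragment_mean = fragment_mean,
                 fragment_sd = fragment_sd, error_rate = error_rate,
                 fragments_per_locus = as.integer(fragments_per_locus),
                 expression_weights = expression_weights),
            class = "sim_read_config")
}

#' Draw a diploid genotype
#'
#' Per locus, with probability `hom_prob` the locus is homozygous (one
#' group, one allele on both copies); otherwise two distinct groups are
#' drawn with one allele each.
#'
#' @param sim a `sim_db` ([make_allele_db()]).
#' @param hom_prob homozygosity probability per locus.
#' @param seed integer RNG seed.
#' @return data.frame with columns `locus`, `zygosity`, `group1`,
#'   `allele1`, `group2`, `allele2`.
#' @export
sim_genotype <- function(sim, hom_prob = 0.25, seed = 1L) {
  stopifnot(inherits(sim, "sim_db"))
  set.seed(seed)
  db <- sim$db
  rows <- lapply(unique(db$locus), function(locus) {
    groups <- unique(db$group[db$locus == locus])
    pick_allele <- function(g) {
      sample(db$name[db$group == g], 1L)
    }
    if (stats::runif(1L) < hom_prob) {
      g <- sample(groups, 1L)
      a <- pick_allele(g)
      data.frame(locus = locus, zygosity = "homozygous", group1 = g,
                 allele1 = a, group2 = g, allele2 = a,
                 stringsAsFactors = FALSE)
    } else {
      gs <- sample(groups, 2L)
      data.frame(locus = locus, zygosity = "heterozygous", group1 = gs[1L],
                 allele1 = pick_allele(gs[1L]), group2 = gs[2L],
                 allele2 = pick_allele(gs[2L]), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

apply_errors <- function(reads, rate) {
  if (rate == 0 || length(reads) == 0L) return(reads)
  chars <- strsplit(reads, "")
  lens <- lengths(chars)
  flat <- unlist(chars)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    flat[hit] <- vapply(flat[hit], function(b) {
      sample(setdiff(SIM_BASES, b), 1L)
    }, "")
  }
  idx <- factor(rep(seq_along(lens), lens), levels = seq_along(lens))
  out <- vapply(split(flat, idx), paste, "", collapse = "")
  names(out) <- names(reads)
  unname(out)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate an RNA-Seq read set from a genotype
#'
#' Fragments are drawn uniformly along the sub-transcript of the expressed
#' allele (haplotypes 50/50), with normal fragment lengths truncated to the
#' feasible range; paired mode emits the two fragment ends on opposite
#' strands; substitution errors are applied per base. Deterministic under
#' the seed.
#'
#' @param sim a `sim_db`.
#' @param genotype data.frame from [sim_genotype()].
#' @param cfg a [sim_read_config()].
#' @param seed integer RNG seed.
#' @return list with `reads1`, `reads2` (named character; `reads2` `NULL`
#'   in single-end mode) and `truth` (data.frame: `fragment_id`, `locus`,
#'   `group`, `allele`, `hap`, `start`, `frag_len`).
#' @export
simulate_reads <- function(sim, genotype, cfg = sim_read_config(),
                           seed = 1L) {
  stopifnot(inherits(sim, "sim_db"), inherits(cfg, "sim_read_config"))
  set.seed(seed)
  db <- sim$db
  rl <- cfg$read_length
  reads1 <- character()
  reads2 <- character()
  truth <- list()
  for (i in seq_len(nrow(genotype))) {
    locus <- genotype$locus[i]
    w <- 1
    if (!is.null(cfg$expression_weights) &&
        locus %in% names(cfg$expression_weights)) {
      w <- cfg$expression_weights[[locus]]
    }
    n <- as.integer(round(cfg$fragments_per_locus * w))
    if (n == 0L) next
    hap <- sample.int(2L, n, replace = TRUE)
    alleles <- c(genotype$allele1[i], genotype$allele2[i])[hap]
    seqs <- db$seq[match(alleles, db$name)]
    lens <- nchar(seqs)
    if (any(lens < rl)) stop("read_length exceeds sub-transcript length")
    fl <- pmin(pmax(as.integer(round(stats::rnorm(n, cfg$fragment_mean,
                                                  cfg$fragment_sd))),
                    rl), lens)
    start <- 1L + floor(stats::runif(n) * (lens - fl + 1L))
    m1 <- substring(seqs, start, start + rl - 1L)
    ids <- sprintf("%s_f%06d", locus, seq_len(n))
    names(m1) <- ids
    reads1 <- c(reads1, m1)
    if (cfg$paired) {
      m2 <- revcomp_chr(substring(seqs, start + fl - rl, start + fl - 1L))
      names(m2) <- ids
      reads2 <- c(reads2, m2)
    }
    truth[[locus]] <- data.frame(
      fragment_id = ids, locus = locus,
      group = c(genotype$group1[i], genotype$group2[i])[hap],
      allele = alleles, hap = hap, start = start, frag_len = fl,
      stringsAsFactors = FALSE)
  }
  reads1 <- apply_errors(reads1, cfg$error_rate) |>
    stats::setNames(names(reads1))
  if (cfg$paired) {
    reads2 <- apply_errors(reads2, cfg$error_rate) |>
      stats::setNames(names(reads2))
  }
  list(reads1 = reads1, reads2 = if (cfg$paired) reads2 else NULL,
       truth = do.call(rbind, c(unname(truth), list(make.row.names = FALSE))))
}

#' Simulate a cohort of diploid individuals
#'
#' Per-individual seeds are drawn once from the cohort seed, so the cohort
#' is fully reproducible and individuals are independent.
#'
#' @param sim a `sim_db`.
#' @param n_individuals cohort size.
#' @param cfg a [sim_read_config()].
#' @param hom_prob per-locus homozygosity probability.
#' @param seed cohort RNG seed.
#' @return list of individuals, each a list with `sample_id`, `genotype`,
#'   `reads1`, `reads2`, `truth`.
#' @export
simulate_cohort <- function(sim, n_individuals, cfg = sim_read_config(),
                            hom_prob = 0.25, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(2^30, 2L * n_individuals)
  lapply(seq_len(n_individuals), function(i) {
    genotype <- sim_genotype(sim, hom_prob, seed = seeds[2L * i - 1L])
    reads <- simulate_reads(sim, genotype, cfg, seed = seeds[2L * i])
    c(list(sample_id = sprintf("sim%02d", i), genotype = genotype), reads)
  })
}

#' Write a simulated database to disk
#'
#' Emits the full-length allele FASTA, the exon table TSV, the
#' sub-transcript reference FASTA and the manifest TSV.
#'
#' @param sim a `sim_db`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim_db <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alleles = file.path(dir, "alleles.fa"),
             exons = file.path(dir, "exons.tsv"),
             reference = file.path(dir, "reference.fa"),
             manifest = file.path(dir, "manifest.tsv"))
  x <- Biostrings::DNAStringSet(unname(sim$fasta))
  names(x) <- names(sim$fasta)
  Biostrings::writeXStringSet(x, paths[["alleles"]])
  utils::write.table(sim$exon_table, paths[["exons"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_reference(sim$db, paths[["reference"]])
  write_manifest(sim$db, paths[["manifest"]])
  invisible(paths)
}
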