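test_that("exact substrings align at their source placements", {
  set.seed(21)
  db <- toy_refdb(c("A*01:01" = rand_seq(200), "A*02:01" = rand_seq(200),
                    "B*07:01" = rand_seq(200)))
  read <- substr(db$seq[2], 51, 87) # 37-mer of allele 2
  hits <- align_read(read, db, aligner_config(v = 0))
  expect_true(nrow(hits) >= 1L)
  expect_true(any(hits$allele == 2L & hits$offset == 50L &
                    hits$strand == "+" & hits$mismatches == 0L))
  # every reported hit is a true 0-mismatch placement
  expect_true(all(hits$mismatches == 0L))
})

test_that("a substitution consumes the mismatch budget", {
  set.seed(22)
  db <- toy_refdb(c("A*01:01" = rand_seq(200)))
  read <- substr(db$seq[1], 11, 47)
  sub <- read
  orig <- substr(sub, 10, 10)
  substr(sub, 10, 10) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  expect_equal(nrow(align_read(sub, db, aligner_config(v = 0))), 0L)
  h1 <- align_read(sub, db, aligner_config(v = 1))
  expect_true(all(h1$mismatches == 1L))
  expect_true(any(h1$offset == 10L))
})

test_that("hit sets equal exhaustive brute-force enumeration", {
  set.seed(23)
  db <- toy_refdb(c("A*01:01" = rand_seq(200), "A*01:02" = rand_seq(200),
                    "A*02:01" = rand_seq(200)))
  reads <- character(60)
  for (i in seq_len(60)) {
    if (i %% 3 == 0) {
      reads[i] <- rand_seq(30)
    } else {
      src <- sample(3, 1)
      off <- sample(170, 1)
      r <- substr(db$seq[src], off, off + 29)
      nmut <- sample(0:2, 1)
      if (nmut) {
        pos <- sample(30, nmut)
        ch <- strsplit(r, "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, "")
        r <- paste(ch, collapse = "")
      }
      reads[i] <- if (runif(1) < 0.5) r else oracle_revcomp(r)
    }
  }
  names(reads) <- paste0("r", seq_along(reads))
  for (v in 0:2) {
    got <- align_reads(reads, db, aligner_config(v = v))
    want <- oracle_align_many(reads, db$seq, v)
    expect_identical(sort_hits(got), sort_hits(want),
                     label = paste("hit set at v =", v))
  }
})

test_that("strand symmetry: reverse-complemented reads flip strands only", {
  set.seed(24)
  db <- toy_refdb(c("A*01:01" = rand_seq(150), "B*05:01" = rand_seq(150)))
  for (i in 1:10) {
    r <- if (i <= 5) substr(db$seq[1 + i %% 2], i * 7, i * 7 + 32) else
      rand_seq(33)
    h_f <- align_read(r, db, aligner_config(v = 1))
    h_r <- align_read(oracle_revcomp(r), db, aligner_config(v = 1))
    flip <- data.frame(allele = h_r$allele, offset = h_r$offset,
                       strand = chartr("+-", "-+", h_r$strand),
                       mismatches = h_r$mismatches,
                       stringsAsFactors = FALSE)
    orig <- as.data.frame(h_f[, c("allele", "offset", "strand",
                                  "mismatches")])
    expect_equal(orig[do.call(order, orig), ],
                 flip[do.call(order, flip), ], ignore_attr = TRUE)
  }
})

test_that("hit sets grow monotonically with the mismatch budget", {
  set.seed(25)
  db <- toy_refdb(c("A*01:01" = rand_seq(200), "A*02:01" = rand_seq(200)))
  reads <- setNames(replicate(20, rand_seq(25)), paste0("r", 1:20))
  key <- function(h) paste(h$read, h$allele, h$offset, h$strand)
  h0 <- align_reads(reads, db, aligner_config(v = 0))
  h1 <- align_reads(reads, db, aligner_config(v = 1))
  h2 <- align_reads(reads, db, aligner_config(v = 2))
  expect_true(all(key(h0) %in% key(h1)))
  expect_true(all(key(h1) %in% key(h2)))
})

test_that("unique policy keeps only single-allele reads", {
  set.seed(26)
  shared <- rand_seq(60)
  db <- toy_refdb(c("A*01:01" = paste0(shared, rand_seq(80)),
                    "A*02:01" = paste0(shared, rand_seq(80))))
  amb <- substr(shared, 5, 40)           # present in both alleles
  uniq <- substr(db$seq[1], 90, 125)     # private to allele 1
  reads <- c(amb = amb, uniq = uniq)
  all_h <- align_reads(reads, db, aligner_config(v = 0, report_policy = "all"))
  unq_h <- align_reads(reads, db,
                       aligner_config(v = 0, report_policy = "unique"))
  expect_setequal(unique(unq_h$read_id), "uniq")
  # unique output is a subset of report-all output
  key <- function(h) paste(h$read_id, h$allele, h$offset, h$strand)
  expect_true(all(key(unq_h) %in% key(all_h)))
})

test_that("paired alignment requires both mates on one allele, opposite strands", {
  set.seed(27)
  db <- toy_refdb(c("A*01:01" = rand_seq(300), "B*09:01" = rand_seq(300)))
  frag <- substr(db$seq[1], 101, 220)
  m1 <- substr(frag, 1, 37)
  m2 <- oracle_revcomp(substr(frag, 84, 120))
  ph <- align_pairs(c(f1 = m1), c(f1 = m2), db, aligner_config(v = 0))
  expect_true(nrow(ph) >= 1L)
  expect_true(all(ph$allele == 1L))
  # discordant pair: mate2 from the other locus
  m2b <- oracle_revcomp(substr(db$seq[2], 51, 87))
  ph2 <- align_pairs(c(f1 = m1), c(f1 = m2b), db, aligner_config(v = 0))
  expect_equal(nrow(ph2), 0L)
})

test_that("pair hits equal the brute-force composition of mate hit sets", {
  set.seed(28)
  db <- toy_refdb(c("A*01:01" = rand_seq(250), "A*02:01" = rand_seq(250),
                    "B*03:01" = rand_seq(250)))
  n <- 30
  m1 <- character(n); m2 <- character(n)
  for (i in seq_len(n)) {
    src <- sample(3, 1)
    st <- sample(140, 1)
    frag <- substr(db$seq[src], st, st + 99)
    m1[i] <- substr(frag, 1, 30)
    m2[i] <- oracle_revcomp(substr(frag, 71, 100))
    if (i %% 5 == 0) m2[i] <- rand_seq(30) # some discordant pairs
  }
  names(m1) <- names(m2) <- paste0("f", seq_len(n))
  got <- align_pairs(m1, m2, db, aligner_config(v = 1))
  # oracle: allele shared by both mates with opposite strands
  want <- list()
  for (i in seq_len(n)) {
    h1 <- oracle_align_read(m1[i], db$seq, 1)
    h2 <- oracle_align_read(m2[i], db$seq, 1)
    for (al in intersect(h1$allele, h2$allele)) {
      s1 <- unique(h1$strand[h1$allele == al])
      s2 <- unique(h2$strand[h2$allele == al])
      if (any(outer(s1, s2, "!="))) {
        want[[length(want) + 1L]] <- data.frame(fragment = i, allele = al)
      }
    }
  }
  want <- do.call(rbind, want)
  got_keys <- sort(paste(got$fragment, got$allele))
  want_keys <- sort(paste(want$fragment, want$allele))
  expect_identical(got_keys, want_keys)
})

test_that("read counts tally distinct fragments per allele", {
  db <- toy_refdb(c("A*01:01" = strrep("A", 50), "A*02:01" = strrep("C", 50),
                    "B*01:01" = strrep("G", 50)))
  fh <- data.table::data.table(fragment_id = c("r1", "r1", "r2"),
                               fragment = c(1L, 1L, 2L),
                               allele = c(1L, 2L, 1L))
  counts <- count_reads(fh, db, "A")
  expect_equal(unname(counts[1:2]), c(2L, 1L))
  # empty hits give an all-zero distribution, not an error
  empty <- count_reads(fh[0], db, "A")
  expect_true(all(empty == 0L))
  # locus scoping: allele of locus B invisible from locus A counts
  expect_length(count_reads(fh, db, "B"), 1L)
})

test_that("non-ACGTN characters are rejected naming the read", {
  db <- toy_refdb(c("A*01:01" = rand_seq(60)))
  expect_error(align_reads(c(badread = "ACGTX"), db), "badread")
})
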