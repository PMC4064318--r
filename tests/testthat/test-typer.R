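groups3 <- c("A*01:01" = "A*01", "A*01:02" = "A*01", "A*02:01" = "A*02")

test_that("the winning group holds the globally maximal allele count", {
  counts <- toy_counts(c("A*01:01" = 10, "A*02:01" = 7, "A*01:02" = 3),
                       groups = c("A*01:01" = "A*01", "A*02:01" = "A*02",
                                  "A*01:02" = "A*01"))
  t <- top_group(counts)
  expect_equal(t$group, "A*01")
  expect_equal(t$read_count, 10L)
  expect_false(t$no_call)
})

test_that("cross-group count ties break lexicographically; zeros give no-call", {
  counts <- toy_counts(c("A*02:01" = 10, "A*01:01" = 10, "A*01:02" = 1),
                       groups = c("A*02:01" = "A*02", "A*01:01" = "A*01",
                                  "A*01:02" = "A*01"))
  expect_equal(top_group(counts)$group, "A*01")
  zero <- toy_counts(c("A*01:01" = 0, "A*02:01" = 0),
                     groups = c("A*01:01" = "A*01", "A*02:01" = "A*02"))
  expect_true(top_group(zero)$no_call)
})

test_that("outlier p-value matches its normal-tail/binomial definition", {
  # a = 20 against background {2,4,6,8}: mean 5, sample sd ~2.582
  res <- outlier_pvalue(c(2, 4, 6, 8), 20, mode = "exclude_top")
  expect_equal(res$x, 4L)
  s <- sd(c(2, 4, 6, 8))
  expect_equal(s, 2.581989, tolerance = 1e-6)
  # independent numerical oracle for the upper normal tail
  tail_oracle <- stats::integrate(function(t) dnorm(t, 5, s), 20, Inf,
                                  rel.tol = 1e-13, abs.tol = 1e-16)$value
  expect_equal(res$tail_prob, tail_oracle, tolerance = 1e-12)
  # p = P(at least one of x background draws >= a), exact binomial sum
  p_oracle <- sum(vapply(1:4, function(k) {
    choose(4, k) * res$tail_prob^k * (1 - res$tail_prob)^(4 - k)
  }, 1.0))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-15)
})

test_that("exclude_top removes one instance of the top count", {
  res <- outlier_pvalue(c(5, 5, 100), 100, mode = "exclude_top")
  expect_equal(res$x, 2L)            # background reduced to {5, 5}
  expect_equal(res$tail_prob, 0)     # sd 0, a above the constant background
  expect_equal(res$p_value, 0)
  inc <- outlier_pvalue(c(5, 5, 100), 100, mode = "include_top")
  expect_equal(inc$x, 3L)
  expect_gt(inc$p_value, res$p_value)
})

test_that("degenerate zero-sd background follows the normal limit", {
  expect_equal(outlier_pvalue(c(5, 5, 5), 9, "include_top")$tail_prob, 0)
  expect_equal(outlier_pvalue(c(5, 5, 5), 5, "include_top")$tail_prob, 0.5)
  expect_equal(outlier_pvalue(c(9, 9), 5, "include_top")$tail_prob, 1)
  # limit cases: tail 0 -> p 0; tail 1 -> p 1 (exactly)
  expect_identical(outlier_pvalue(c(5, 5, 5), 9, "include_top")$p_value, 0)
  expect_identical(outlier_pvalue(c(9, 9), 5, "include_top")$p_value, 1)
})

test_that("printed compatibility form is the exact complement", {
  res <- outlier_pvalue(c(3, 8, 14, 30), 30, "include_top")
  cmp <- outlier_pvalue(c(3, 8, 14, 30), 30, "include_top",
                        printed_form = TRUE)
  expect_equal(res$p_value + cmp$p_value, 1, tolerance = 1e-12)
})

test_that("p-value decreases in a and include_top is stricter", {
  set.seed(31)
  for (rep in 1:20) {
    bg <- sort(rpois(6, 40))
    a_vals <- max(bg) + c(0, 10, 40, 120)
    ps <- vapply(a_vals, function(a) {
      outlier_pvalue(c(bg, a), a, "include_top")$p_value
    }, 1.0)
    expect_true(all(diff(ps) <= 1e-12))  # non-increasing in a
    a <- max(bg) + 25
    p_inc <- outlier_pvalue(c(bg, a), a, "include_top")$p_value
    p_exc <- outlier_pvalue(c(bg, a), a, "exclude_top")$p_value
    expect_gte(p_inc, p_exc - 1e-12)     # the "stricter calculation"
  }
})

test_that("winner-associated fragments are removed, others retained", {
  db <- toy_refdb(c("A*01:01" = strrep("A", 40), "A*01:02" = strrep("C", 40),
                    "A*02:01" = strrep("G", 40)))
  fh <- data.table::data.table(
    fragment_id = c("r1", "r2", "r3", "r3"),
    fragment = c(1L, 2L, 3L, 3L),
    allele = c(1L, 3L, 1L, 3L)) # r1 on A*01 only; r2 on A*02; r3 on both
  red <- remove_group_reads(fh, db, "A*01", "A")
  expect_setequal(unique(red$fragment), 2L)
  counts <- count_reads(red, db, "A", iteration = 2L)
  expect_equal(as.integer(counts), c(0L, 0L, 1L))
})

test_that("zygosity compares the second winner to the iteration-1 median", {
  c1 <- toy_counts(setNames(c(10, 30, 50, 70, 90), paste0("A*0", 1:5, ":01")),
                   groups = setNames(paste0("A*0", 1:5),
                                     paste0("A*0", 1:5, ":01")))
  # median 50; confident residual background for the homozygous branch
  g2 <- c("A*01" = 2, "A*02" = 3, "A*03" = 1, "A*04" = 0, "A*05" = 2,
          "A*06" = 1, "A*07" = 2, "A*08" = 3)
  expect_equal(zygosity(c1, g2, 60, "I")$status, "heterozygous")
  hom <- zygosity(c1, g2, 10, "I")
  expect_equal(hom$status, "homozygous")
  expect_lt(hom$p_value, 0.1)
  expect_equal(hom$threshold, 50)
  # class II threshold is half the median
  expect_equal(zygosity(c1, g2, 30, "II")$status, "heterozygous")
  expect_equal(zygosity(c1, g2, 30, "II")$threshold, 25)
  # second winner near the threshold: uncertain, reported ambiguous
  g2_noisy <- c("A*01" = 45, "A*02" = 48, "A*03" = 40, "A*04" = 42,
                "A*05" = 44)
  expect_equal(zygosity(c1, g2_noisy, 48, "I")$status, "ambiguous")
})

test_that("calls are invariant under rescaling of all counts", {
  c1 <- toy_counts(setNames(c(12, 34, 50, 72, 90), paste0("A*0", 1:5, ":01")),
                   groups = setNames(paste0("A*0", 1:5),
                                     paste0("A*0", 1:5, ":01")))
  g2 <- c("A*01" = 2, "A*02" = 3, "A*03" = 1, "A*04" = 0, "A*05" = 2)
  for (k in c(2, 10)) {
    ck <- toy_counts(unclass(c1) * k, groups = attr(c1, "group"))
    expect_equal(top_group(ck)$group, top_group(c1)$group)
    expect_equal(zygosity(ck, g2 * k, 10 * k, "I")$status,
                 zygosity(c1, g2, 10, "I")$status)
    expect_equal(zygosity(ck, g2 * k, 60 * k, "I")$status,
                 zygosity(c1, g2, 60, "I")$status)
  }
})

test_that("simulated heterozygous and homozygous loci are called end-to-end", {
  sim <- small_sim(seed = 33, groups = 6L, alleles = 3L)
  gt <- data.frame(
    locus = c("A", "B"), zygosity = c("heterozygous", "homozygous"),
    group1 = c("A*02", "B*03"), allele1 = c("A*02:01", "B*03:02"),
    group2 = c("A*05", "B*03"), allele2 = c("A*05:03", "B*03:02"),
    stringsAsFactors = FALSE)
  rd <- simulate_reads(sim, gt, sim_read_config(fragments_per_locus = 1200L),
                       seed = 34)
  ty <- type_sample(rd$reads1, rd$reads2, sim$db, sample_id = "t")
  a <- ty$calls[["A"]]
  expect_setequal(c(a$call1$group, a$call2$group), c("A*02", "A*05"))
  expect_equal(a$zygosity$status, "heterozygous")
  b <- ty$calls[["B"]]
  expect_equal(b$call1$group, "B*03")
  expect_equal(b$zygosity$status, "homozygous")
  tab <- genotype_table(ty)
  expect_match(tab$allele2[tab$locus == "B"], "homoz")
})

test_that("typing is deterministic and empty input gives no-calls", {
  sim <- small_sim(seed = 35)
  gt <- sim_genotype(sim, hom_prob = 0, seed = 36)
  rd <- simulate_reads(sim, gt, sim_read_config(fragments_per_locus = 300L),
                       seed = 37)
  t1 <- type_sample(rd$reads1, rd$reads2, sim$db, sample_id = "x")
  t2 <- type_sample(rd$reads1, rd$reads2, sim$db, sample_id = "x")
  expect_identical(genotype_table(t1), genotype_table(t2))
  t0 <- type_sample(character(0), NULL, sim$db, sample_id = "empty")
  expect_true(all(vapply(t0$calls, function(cl) cl$no_call, TRUE)))
  expect_true(all(genotype_table(t0)$p1 == 1))
  expect_error(type_sample(rd$reads1, rd$reads2[-1], sim$db), "unequal")
})
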