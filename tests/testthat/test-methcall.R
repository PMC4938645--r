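test_that("fragment methylation pools reads across covered CpGs", {
  fr <- make_fragment(100, 160, c(105, 120))
  ct <- make_counts(c(105, 120), meth = c(8, 2), total = c(10, 10))
  res <- fragment_methylation(fr, ct)
  expect_equal(res$methylation, 0.5)
  expect_equal(res$n_cpg_covered, 2L)
  expect_equal(res$total_reads, 20L)

  # all CpGs uncovered -> missing
  none <- fragment_methylation(fr, make_counts(integer(0), integer(0), integer(0)))
  expect_true(is.na(none$methylation))

  # counts at non-fragment coordinates are ignored
  extra <- rbind(ct, make_counts(999, 5, 5))
  expect_equal(fragment_methylation(fr, extra)$methylation, 0.5)
})

test_that("fragment methylation equals the brute-force pooled ratio", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    pos <- sort(sample(100:400, n))
    tot <- sample(0:40, n, replace = TRUE)
    met <- vapply(tot, function(t) if (t > 0) sample(0:t, 1) else 0L, integer(1))
    fr <- make_fragment(90, 410, pos)
    res <- fragment_methylation(fr, make_counts(pos, met, tot))
    if (sum(tot) == 0) {
      expect_true(is.na(res$methylation))
    } else {
      expect_equal(res$methylation, sum(met) / sum(tot))
    }
  }
})

test_that("coverage filter requires min_cpgs sites at min_depth reads", {
  fr <- make_fragment(100, 160, c(105, 120))
  expect_true(coverage_filter(fr, make_counts(c(105, 120), c(0, 0), c(10, 10))))
  expect_false(coverage_filter(fr, make_counts(c(105, 120), c(0, 0), c(10, 9))))
  expect_false(coverage_filter(fr, make_counts(integer(0), integer(0), integer(0))))
})

test_that("methylation and filter are invariant to splitting a CpG's reads", {
  fr <- make_fragment(100, 160, c(105, 120))
  whole <- make_counts(c(105, 120), c(6, 3), c(12, 11))
  split2 <- make_counts(c(105, 105, 120), c(2, 4, 3), c(5, 7, 11))
  expect_equal(fragment_methylation(fr, whole)$methylation,
               fragment_methylation(fr, split2)$methylation)
  expect_equal(coverage_filter(fr, whole), coverage_filter(fr, split2))
  m1 <- fragment_meth_matrix(fr, list(s1 = whole))
  m2 <- fragment_meth_matrix(fr, list(s1 = split2))
  expect_equal(m1$meth, m2$meth)
  expect_equal(m1$pass, m2$pass)
})

test_that("matrix builder agrees with the per-fragment operations", {
  set.seed(31)
  frs <- make_fragments(c(100, 300, 600), c(180, 420, 700),
                        list(c(105, 150), c(310, 340, 400), 650))
  samples <- lapply(1:4, function(s) {
    pos <- c(105, 150, 310, 340, 400, 650)
    keep <- runif(6) < 0.8
    tot <- sample(0:30, 6, replace = TRUE) * keep
    met <- vapply(tot, function(t) if (t > 0) sample(0:t, 1) else 0L, integer(1))
    make_counts(pos[tot > 0], met[tot > 0], tot[tot > 0])
  })
  names(samples) <- paste0("s", 1:4)
  fmm <- fragment_meth_matrix(frs, samples)
  for (i in 1:3) {
    for (s in names(samples)) {
      ref <- fragment_methylation(frs[i], samples[[s]])
      expect_equal(unname(fmm$meth[i, s]), ref$methylation)
      expect_equal(unname(fmm$pass[i, s]),
                   coverage_filter(frs[i], samples[[s]]))
    }
  }
})

test_that("tightening the coverage filter never enlarges the pass set", {
  set.seed(41)
  frs <- make_fragments(c(100, 300), c(200, 400),
                        list(c(110, 150, 190), c(320, 380)))
  samples <- lapply(1:6, function(s) {
    pos <- c(110, 150, 190, 320, 380)
    tot <- sample(0:25, 5, replace = TRUE)
    make_counts(pos, rbinom(5, tot, 0.5), tot)
  })
  names(samples) <- paste0("s", 1:6)
  loose <- fragment_meth_matrix(frs, samples, min_cpgs = 1, min_depth = 5)
  for (md in c(10, 20)) {
    for (mc in 1:3) {
      tight <- fragment_meth_matrix(frs, samples, min_cpgs = mc, min_depth = md)
      expect_true(all(loose$pass | !tight$pass))
    }
  }
})

test_that("comparison set enforces the per-group sample rule symmetrically", {
  frs <- make_fragments(seq(100, 100 + 99 * 50, by = 50),
                        seq(140, 140 + 99 * 50, by = 50))
  n_frag <- 100
  set.seed(5)
  pass <- matrix(runif(n_frag * 22) < 0.7, n_frag, 22,
                 dimnames = list(frs$fragment_id, paste0("s", 1:22)))
  fmm <- structure(
    list(meth = matrix(runif(n_frag * 22), n_frag, 22,
                       dimnames = dimnames(pass)),
         pass = pass, fragment_ids = frs$fragment_id,
         n_cpg = setNames(frs$n_cpg, frs$fragment_id),
         fragments = frs, min_cpgs = 2L, min_depth = 10L),
    class = "fragment_meth_matrix"
  )
  design <- setNames(rep(c("a", "b"), each = 11), paste0("s", 1:22))
  cs <- build_comparison_set(fmm, design, min_per_group = 6)
  na <- rowSums(pass[, 1:11]); nb <- rowSums(pass[, 12:22])
  expect_setequal(cs$fragment_ids, frs$fragment_id[na >= 6 & nb >= 6])
  # symmetric in group labels
  design_sw <- setNames(rep(c("b", "a"), each = 11), paste0("s", 1:22))
  cs_sw <- build_comparison_set(fmm, design_sw, min_per_group = 6)
  expect_setequal(cs$fragment_ids, cs_sw$fragment_ids)
  # 11 + 5 passing excluded; min_per_group = 1 retains everything covered
  pass[1, ] <- c(rep(TRUE, 11), rep(TRUE, 5), rep(FALSE, 6))
  fmm$pass <- pass
  cs2 <- build_comparison_set(fmm, design, min_per_group = 6)
  expect_false(frs$fragment_id[1] %in% cs2$fragment_ids)
  cs3 <- build_comparison_set(fmm, design, min_per_group = 1)
  expect_setequal(cs3$fragment_ids,
                  frs$fragment_id[rowSums(pass[, 1:11]) >= 1 &
                                    rowSums(pass[, 12:22]) >= 1])
  expect_error(build_comparison_set(fmm, design, min_per_group = 12),
               "fewer than")
})

test_that("methylation level categories use inclusive printed bounds", {
  expect_equal(classify_methylation_level(c(0.30, 0.70, 0.31, 0.69, 0, 1)),
               c("low", "high", "intermediate", "intermediate", "low", "high"))
  expect_error(classify_methylation_level(1.2), "0, 1")
  expect_error(classify_methylation_level(-0.1), "0, 1")
})

test_that("global weighted mean weights fragments by CpG count", {
  expect_equal(global_weighted_mean(c(0.2, 0.8), c(2, 6)), 0.65)
  set.seed(13)
  m <- runif(100)
  expect_equal(global_weighted_mean(m, rep(3, 100)), mean(m))
  w <- sample(1:20, 100, replace = TRUE)
  expect_equal(global_weighted_mean(m, w), sum(m * w) / sum(w))
  expect_error(global_weighted_mean(numeric(0), numeric(0)), "no fragments")
})

test_that("relative reduction reproduces the printed percent scale", {
  expect_equal(signif(relative_reduction(0.475, 0.371), 2), 22)
  expect_equal(relative_reduction(0.5, 0.5), 0)
  expect_equal(relative_reduction(0.3, 0), 100)
  expect_error(relative_reduction(0, 0.1), "reference")
})

test_that("bismark coverage files round-trip in both dialects", {
  ct <- make_counts(c(11, 25, 300), c(3, 0, 12), c(10, 5, 12))
  p <- tempfile(fileext = ".cov")
  write_bismark_cov(ct, p)
  back <- read_bismark_cov(p)
  expect_equal(back, ct)
  # zero-based dialect shifts the start column
  zb <- read.table(p, sep = "\t")
  zb$V2 <- zb$V2 - 1L
  p0 <- tempfile(fileext = ".cov")
  write.table(zb, p0, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_equal(read_bismark_cov(p0, zero_based = TRUE)$pos, ct$pos)
})
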