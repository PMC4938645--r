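# Brute-force oracles and fixture builders shared across tests.
# Oracles are written independently of the implementation paths they
# check: plain string scans, loops and closed forms.

# Brute-force MspI digestion of a single sequence string: scan for CCGG,
# cut after the first C, drop the chromosome-terminal pieces.
bf_digest <- function(seq) {
  hits <- gregexpr("CCGG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1 || length(hits) < 2) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  cuts <- as.integer(hits)  # 0-based cut coordinate equals 1-based motif start
  data.frame(start = cuts[-length(cuts)] + 1L, end = cuts[-1L])
}

# Random DNA string with plenty of CCGG sites.
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Count table from parallel vectors (single chromosome "chr1").
make_counts <- function(pos, meth, total, chrom = "chr1") {
  data.frame(
    chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
    count_meth = as.integer(meth),
    count_unmeth = as.integer(total - meth),
    count_total = as.integer(total),
    stringsAsFactors = FALSE
  )
}

# A one-fragment GRanges with explicit CpG positions.
make_fragment <- function(start, end, cpg_pos, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start, end = end)
  )
  gr$fragment_id <- sprintf("%s:%d-%d", chrom, start - 1L, end)
  gr$cpg_pos <- IRanges::IntegerList(list(as.integer(cpg_pos)))
  gr$n_cpg <- length(cpg_pos)
  gr$passes_size_selection <- TRUE
  gr
}

# Fragment GRanges from parallel vectors, one CpG list per fragment.
make_fragments <- function(starts, ends, cpg_list = NULL, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts, end = ends)
  )
  gr$fragment_id <- sprintf("%s:%d-%d", chrom, starts - 1L, ends)
  if (is.null(cpg_list)) {
    cpg_list <- lapply(seq_along(starts), function(i) starts[i])
  }
  gr$cpg_pos <- IRanges::IntegerList(lapply(cpg_list, as.integer))
  gr$n_cpg <- lengths(cpg_list)
  gr$passes_size_selection <- TRUE
  gr
}

# Hand Yates chi-square from the textbook formula (no flooring subtleties
# hidden: computed cell by cell in a loop).
bf_yates <- function(tab) {
  n <- sum(tab)
  chi2 <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      d <- abs(tab[i, j] - e) - 0.5
      if (d < 0) d <- 0
      chi2 <- chi2 + d^2 / e
    }
  }
  chi2
}

# Truth values from a shared-mixture two-group model with planted shifts
# of a fixed size; used by the calibration and recovery simulations.
planted_truth <- function(n, mixture, n_planted, shift, hypo_frac = 0.9,
                          seed = 1) {
  set.seed(seed)
  comp <- sample(nrow(mixture), n, TRUE, prob = mixture$weight)
  m1 <- plogis(rnorm(n, mixture$logit_mean[comp], mixture$logit_sd[comp]))
  m2 <- m1
  planted <- sort(sample.int(n, n_planted))
  hypo <- runif(n_planted) < hypo_frac
  can_lo <- m1[planted] - shift >= 0
  go_hypo <- (hypo & can_lo) | (!hypo & m1[planted] + shift > 1)
  m2[planted] <- ifelse(go_hypo, m1[planted] - shift, m1[planted] + shift)
  list(true_meth = cbind(group1 = m1, group2 = m2),
       planted = planted,
       direction = ifelse(go_hypo, "hypo", "hyper"))
}
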