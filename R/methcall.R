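# Pool duplicate records at the same coordinate so that splitting one
# CpG's reads across rows cannot change methylation or filter results.
.aggregate_counts <- function(counts) {
  key <- paste0(counts$chrom, ":", counts$pos)
  if (!anyDuplicated(key)) {
    return(counts)
  }
  met <- rowsum(counts$count_meth, key, reorder = FALSE)
  tot <- rowsum(counts$count_total, key, reorder = FALSE)
  first <- !duplicated(key)
  data.frame(
    chrom = counts$chrom[first], pos = counts$pos[first],
    count_meth = as.integer(met), count_unmeth = as.integer(tot - met),
    count_total = as.integer(tot),
    stringsAsFactors = FALSE
  )
}

#' Per-fragment methylation for one sample
#'
#' Fragment methylation pools reads across all covered CpGs of the
#' fragment: sum of methylated counts divided by sum of total counts.
#' Pooling is read-weighted (a deeply covered CpG contributes more),
#' matching the fragment-as-unit philosophy.  Count rows at coordinates
#' that are not CpGs of the fragment are ignored.
#'
#' @param fragment A length-one `GRanges` from [mspi_digest()] (carrying
#'   the `cpg_pos` metadata column).
#' @param counts A per-sample count table from [read_bismark_cov()].
#' @return A list with `methylation` (in \[0,1\], `NA` when no fragment
#'   CpG is covered), `n_cpg_covered`, and `total_reads`.
#' @export
fragment_methylation <- function(fragment, counts) {
  stopifnot(length(fragment) == 1L)
  chrom <- as.character(GenomicRanges::seqnames(fragment))
  pos <- fragment$cpg_pos[[1L]]
  idx <- which(counts$chrom == chrom & counts$pos %in% pos)
  tot <- sum(counts$count_total[idx])
  met <- sum(counts$count_meth[idx])
  list(
    methylation = if (tot > 0) met / tot else NA_real_,
    n_cpg_covered = sum(counts$count_total[idx] > 0),
    total_reads = tot
  )
}

#' Per-sample fragment coverage filter
#'
#' A fragment passes for a sample when at least `min_cpgs` of its CpG
#' sites are each covered by `min_depth` or more reads (the "F2 t10"
#' inclusion criterion with defaults 2 and 10).
#'
#' @inheritParams fragment_methylation
#' @param min_cpgs Minimum number of qualifying CpG sites.
#' @param min_depth Minimum reads per qualifying CpG.
#' @return Logical pass flag.
#' @export
coverage_filter <- function(fragment, counts, min_cpgs = 2L, min_depth = 10L) {
  stopifnot(length(fragment) == 1L)
  counts <- .aggregate_counts(counts)
  chrom <- as.character(GenomicRanges::seqnames(fragment))
  pos <- fragment$cpg_pos[[1L]]
  idx <- which(counts$chrom == chrom & counts$pos %in% pos)
  sum(counts$count_total[idx] >= min_depth) >= min_cpgs
}

#' Fragment-by-sample methylation matrix
#'
#' Computes pooled fragment methylation and the coverage-filter flag for
#' every fragment and sample in one pass.
#'
#' @param fragments `GRanges` of (size-selected) fragments.
#' @param counts_list Named list of per-sample count tables (names are
#'   sample ids), each as returned by [read_bismark_cov()].
#' @inheritParams coverage_filter
#' @return An object of class `"fragment_meth_matrix"`: a list with
#'   matrices `meth` (methylation, `NA` where no read covers the
#'   fragment), `pass` (coverage-filter flags), `n_cpg_covered`,
#'   `total_reads`, all fragments x samples, plus `fragment_ids`,
#'   `n_cpg` (CpG sites per fragment) and the `fragments` GRanges.
#' @export
fragment_meth_matrix <- function(fragments, counts_list,
                                 min_cpgs = 2L, min_depth = 10L) {
  if (is.null(names(counts_list)) || anyDuplicated(names(counts_list))) {
    stop("`counts_list` must be a named list with unique sample ids")
  }
  n_frag <- length(fragments)
  ids <- fragments$fragment_id
  cpg <- fragments$cpg_pos
  frag_idx <- rep(seq_len(n_frag), lengths(cpg))
  key <- paste0(
    rep(as.character(GenomicRanges::seqnames(fragments)), lengths(cpg)),
    ":", unlist(cpg)
  )
  samples <- names(counts_list)
  meth <- pass <- ncov <- reads <- matrix(
    NA_real_, n_frag, length(samples), dimnames = list(ids, samples)
  )
  # rowsum() drops empty groups; pad with an explicit zero per fragment
  rowsum_full <- function(x) {
    as.numeric(rowsum(c(x, rep(0, n_frag)), c(frag_idx, seq_len(n_frag))))
  }
  for (s in samples) {
    ct <- .aggregate_counts(counts_list[[s]])
    m <- match(key, paste0(ct$chrom, ":", ct$pos))
    tot <- ct$count_total[m]
    met <- ct$count_meth[m]
    tot[is.na(tot)] <- 0
    met[is.na(met)] <- 0
    sum_tot <- rowsum_full(tot)
    sum_met <- rowsum_full(met)
    reads[, s] <- sum_tot
    ncov[, s] <- rowsum_full(as.numeric(tot > 0))
    pass[, s] <- rowsum_full(as.numeric(tot >= min_depth)) >= min_cpgs
    meth[, s] <- ifelse(sum_tot > 0, sum_met / sum_tot, NA_real_)
  }
  structure(
    list(
      meth = meth, pass = pass == 1, n_cpg_covered = ncov,
      total_reads = reads, fragment_ids = ids,
      n_cpg = setNames(fragments$n_cpg, ids), fragments = fragments,
      min_cpgs = min_cpgs, min_depth = min_depth
    ),
    class = "fragment_meth_matrix"
  )
}

#' @export
print.fragment_meth_matrix <- function(x, ...) {
  cat("fragment_meth_matrix:", nrow(x$meth), "fragments x",
      ncol(x$meth), "samples\n")
  cat("  coverage filter: >=", x$min_cpgs, "CpGs at >=", x$min_depth,
      "reads; pass rate", round(mean(x$pass), 3), "\n")
  invisible(x)
}

.check_design <- function(design) {
  if (is.data.frame(design)) {
    design <- setNames(as.character(design$group), design$sample)
  }
  if (is.null(names(design))) {
    stop("`design` must map sample ids to group labels")
  }
  groups <- unique(design)
  if (length(groups) != 2L) {
    stop("exactly two groups are required, got: ",
         paste(groups, collapse = ", "))
  }
  design
}

#' Build the two-group comparison fragment set
#'
#' Comparison fragments are those passing the per-sample coverage filter
#' in at least `min_per_group` individuals of each of the two groups.
#'
#' @param fmm A [fragment_meth_matrix()] object.
#' @param design Named character vector (or data.frame with columns
#'   `sample`, `group`) mapping sample ids to exactly two group labels.
#' @param min_per_group Minimum passing samples required in each group.
#' @return An object of class `"comparison_set"`: list with
#'   `fragment_ids` of retained fragments, `contributing` (logical
#'   fragments x samples matrix of which samples contribute, i.e. pass),
#'   `design`, and `groups`.
#' @export
build_comparison_set <- function(fmm, design, min_per_group = 6L) {
  design <- .check_design(design)
  if (!all(names(design) %in% colnames(fmm$pass))) {
    stop("design contains samples absent from the matrix")
  }
  groups <- unique(design)
  for (g in groups) {
    if (sum(design == g) < min_per_group) {
      stop("group '", g, "' has fewer than min_per_group = ",
           min_per_group, " samples")
    }
  }
  pass <- fmm$pass[, names(design), drop = FALSE]
  n1 <- rowSums(pass[, design == groups[1], drop = FALSE], na.rm = TRUE)
  n2 <- rowSums(pass[, design == groups[2], drop = FALSE], na.rm = TRUE)
  keep <- n1 >= min_per_group & n2 >= min_per_group
  structure(
    list(
      fragment_ids = fmm$fragment_ids[keep],
      contributing = pass[keep, , drop = FALSE],
      design = design, groups = groups,
      min_per_group = min_per_group
    ),
    class = "comparison_set"
  )
}

#' @export
print.comparison_set <- function(x, ...) {
  cat("comparison_set:", length(x$fragment_ids), "fragments;",
      "groups:", paste(x$groups, collapse = " vs "),
      "(>=", x$min_per_group, "samples each)\n")
  invisible(x)
}

#' Per-group mean fragment methylation
#'
#' Group means over the contributing (filter-passing) samples of each
#' comparison fragment; non-passing samples are treated as missing.
#'
#' @param fmm A [fragment_meth_matrix()] object.
#' @param cs A [build_comparison_set()] object.
#' @return Numeric matrix, comparison fragments x 2 groups.
#' @export
group_means <- function(fmm, cs) {
  meth <- fmm$meth[cs$fragment_ids, names(cs$design), drop = FALSE]
  meth[!cs$contributing] <- NA_real_
  vapply(cs$groups, function(g) {
    rowMeans(meth[, cs$design == g, drop = FALSE], na.rm = TRUE)
  }, numeric(length(cs$fragment_ids)))
}

#' Classify a methylation level as low / intermediate / high
#'
#' Bounds are inclusive: low for m <= 0.30, high for m >= 0.70.
#'
#' @param m Methylation values in \[0,1\] (vectorised).
#' @return Character vector in `c("low", "intermediate", "high")`.
#' @export
classify_methylation_level <- function(m) {
  if (any(is.na(m)) || any(m < 0 | m > 1)) {
    stop("methylation values must lie in [0, 1]")
  }
  ifelse(m <= 0.30, "low", ifelse(m >= 0.70, "high", "intermediate"))
}

#' CpG-count-weighted global mean methylation
#'
#' The global summary of a group's methylome: the mean of per-fragment
#' group means weighted by the number of CpG sites in each fragment.
#'
#' @param m Per-fragment mean methylation values.
#' @param n_cpg CpG-site count per fragment (the weights).
#' @return Weighted mean in \[0,1\].
#' @export
global_weighted_mean <- function(m, n_cpg) {
  if (length(m) == 0L) {
    stop("no fragments supplied")
  }
  if (length(n_cpg) != length(m)) {
    stop("`m` and `n_cpg` must have the same length")
  }
  keep <- !is.na(m)
  sum(m[keep] * n_cpg[keep]) / sum(n_cpg[keep])
}

#' Relative reduction between two methylation summaries
#'
#' @param reference Reference-group summary (> 0).
#' @param test Test-group summary.
#' @return Percent reduction, `100 * (reference - test) / reference`.
#' @export
relative_reduction <- function(reference, test) {
  if (reference == 0) {
    stop("`reference` must be > 0")
  }
  100 * (reference - test) / reference
}
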