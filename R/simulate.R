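#' Configuration for the synthetic two-group methylome generator
#'
#' Bundles and validates every tunable of the simulator.  The defaults
#' emulate the statistical structure of a two-tissue RRBS comparison:
#' eleven samples per group; a bimodal (low/high) logit-Gaussian
#' fragment-methylation mixture for the first group and a trimodal
#' (low/intermediate/high) mixture for the second; negative-binomial
#' read depth around 30x; and a small fraction of fragments with a
#' planted group shift of at least 0.25.
#'
#' @param genome_length Chromosome length in bp.
#' @param n_chromosomes Number of chromosomes.
#' @param ccgg_rate Expected CCGG (MspI) sites per kb.
#' @param cpg_rate Expected additional CpG dinucleotides per kb.
#' @param n_samples_per_group Samples per group.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth mean
#'   and size (dispersion) per CpG.
#' @param group_mixtures Named list of two data.frames (one per group),
#'   each with columns `weight`, `logit_mean`, `logit_sd`; weights must
#'   sum to 1.
#' @param dmf_fraction Fraction of fragments receiving a planted group
#'   shift.
#' @param dmf_min_shift Minimum absolute methylation shift of a planted
#'   DMF, in (0, 1).
#' @param hypo_fraction Fraction of planted DMFs shifted downwards in
#'   the second (test) group.
#' @param jitter_concentration Beta concentration of the per-CpG jitter
#'   around the fragment-level methylation (larger = tighter).
#' @param repeat_classes data.frame with columns `class`, `family`,
#'   `fraction` (target genome fraction per repeat family).
#' @param gene_density Genes per Mb.
#' @param seed Integer RNG seed; each simulation stage derives its own
#'   substream from it, so e.g. adding samples does not perturb genome
#'   synthesis.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(genome_length = 1e6,
                              n_chromosomes = 2L,
                              ccgg_rate = 4,
                              cpg_rate = 15,
                              n_samples_per_group = 11L,
                              depth_mean = 30,
                              depth_dispersion = 8,
                              group_mixtures = default_group_mixtures(),
                              dmf_fraction = 0.03,
                              dmf_min_shift = 0.25,
                              hypo_fraction = 0.9,
                              jitter_concentration = 50,
                              repeat_classes = default_repeat_classes(),
                              gene_density = 10,
                              seed = 1L) {
  stopifnot(
    genome_length > 0, n_chromosomes >= 1,
    ccgg_rate >= 0, cpg_rate >= 0,
    n_samples_per_group >= 2,
    depth_mean > 0, depth_dispersion > 0,
    dmf_fraction >= 0, dmf_fraction <= 1,
    dmf_min_shift > 0, dmf_min_shift < 1,
    hypo_fraction >= 0, hypo_fraction <= 1,
    jitter_concentration > 0,
    gene_density >= 0
  )
  if (length(group_mixtures) != 2L) {
    stop("`group_mixtures` must list exactly two groups")
  }
  if (is.null(names(group_mixtures))) {
    names(group_mixtures) <- c("group1", "group2")
  }
  for (g in names(group_mixtures)) {
    mx <- group_mixtures[[g]]
    stopifnot(all(c("weight", "logit_mean", "logit_sd") %in% colnames(mx)))
    if (abs(sum(mx$weight) - 1) > 1e-9) {
      stop("mixture weights for group '", g, "' must sum to 1")
    }
    if (any(mx$weight <= 0) || any(mx$logit_sd <= 0)) {
      stop("mixture weights and sds must be positive for group '", g, "'")
    }
  }
  stopifnot(all(c("class", "family", "fraction") %in% colnames(repeat_classes)))
  if (any(repeat_classes$fraction <= 0) || sum(repeat_classes$fraction) >= 1) {
    stop("repeat fractions must be positive and sum to < 1")
  }
  structure(
    list(
      genome_length = genome_length, n_chromosomes = as.integer(n_chromosomes),
      ccgg_rate = ccgg_rate, cpg_rate = cpg_rate,
      n_samples_per_group = as.integer(n_samples_per_group),
      depth_mean = depth_mean, depth_dispersion = depth_dispersion,
      group_mixtures = group_mixtures,
      dmf_fraction = dmf_fraction, dmf_min_shift = dmf_min_shift,
      hypo_fraction = hypo_fraction,
      jitter_concentration = jitter_concentration,
      repeat_classes = repeat_classes, gene_density = gene_density,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Default two-group mixture parameters
#'
#' Group 1 ("neutrophil"-like): a bimodal mixture with low and high
#' methylation components.  Group 2 ("placenta"-like): a trimodal
#' mixture with low, intermediate and high components with weights
#' 21.5% / 63.8% / 14.7% and log-odds means -3.34 / 0.10 / 2.45
#' (methylation 0.034 / 0.525 / 0.920).  Component sd 0.8 throughout.
#'
#' @return Named list of two mixture data.frames.
#' @export
default_group_mixtures <- function() {
  list(
    neutrophil = data.frame(
      weight = c(0.45, 0.55),
      logit_mean = c(-3.34, 2.45),
      logit_sd = c(0.8, 0.8)
    ),
    placenta = data.frame(
      weight = c(0.215, 0.638, 0.147),
      logit_mean = c(-3.34, 0.10, 2.45),
      logit_sd = c(0.8, 0.8, 0.8)
    )
  )
}

#' Default repeat-family composition
#'
#' Human-genome-like target fractions for the repeat classes analysed:
#' SINE (Alu, MIR), LINE (L1, L2), LTR (ERV1, ERVK, ERVL, ERVL-MaLR),
#' Satellite, Low_complexity, Simple_repeat.
#'
#' @return data.frame with columns `class`, `family`, `fraction`.
#' @export
default_repeat_classes <- function() {
  data.frame(
    class = c("SINE", "SINE", "LINE", "LINE", "LTR", "LTR", "LTR", "LTR",
              "Satellite", "Low_complexity", "Simple_repeat"),
    family = c("Alu", "MIR", "L1", "L2", "ERV1", "ERVK", "ERVL",
               "ERVL-MaLR", "Satellite", "Low_complexity", "Simple_repeat"),
    fraction = c(0.10, 0.025, 0.17, 0.03, 0.03, 0.01, 0.02, 0.04,
                 0.02, 0.01, 0.02),
    stringsAsFactors = FALSE
  )
}

.stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

# CG-free random background sequence of given length
.background_seq <- function(len) {
  if (len <= 0L) return(character(0))
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (len >= 2L) {
    bad <- which(s[-len] == "C" & s[-1L] == "G")
    if (length(bad)) s[bad + 1L] <- "A"
  }
  s
}

#' Simulate a miniature genome with repeat and gene tracks
#'
#' Each chromosome is a CG-free random background into which exact
#' `CCGG` motifs (Poisson at `ccgg_rate` per kb) and extra `CG`
#' dinucleotides (Poisson at `cpg_rate` per kb) are placed with A/T
#' flanks, so the motif counts are exactly the Poisson draws and a rate
#' of zero yields a genome with no occurrence at all.  Repeat intervals
#' are placed per family until the target genome fraction is reached;
#' genes (bodies of 5-30 kb with 2-8 exons, random strand) are placed at
#' `gene_density` per Mb.
#'
#' @param config A [simulation_config()].
#' @return List of class `"simulated_genome"` with elements `genome`
#'   (`DNAStringSet`), `repeats` (`GRanges` with `class`, `family`,
#'   `name`), `genes` (`GRanges` with `type` in gene/exon, `gene_id`,
#'   strand), and `seqlengths`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- as.integer(config$genome_length)
  set.seed(.stage_seed(config$seed, 11L))
  chroms <- setNames(
    vector("list", config$n_chromosomes),
    paste0("chr", seq_len(config$n_chromosomes))
  )
  for (i in seq_len(config$n_chromosomes)) {
    n_ccgg <- rpois(1L, config$ccgg_rate * L / 1000)
    n_cpg <- rpois(1L, config$cpg_rate * L / 1000)
    # motifs carry A/T flanks so insertion cannot create extra sites
    tokens <- c(rep("ACCGGT", n_ccgg), rep("ACGT", n_cpg))
    if (length(tokens)) tokens <- sample(tokens)
    token_bp <- sum(nchar(tokens))
    bg_bp <- L - token_bp
    if (bg_bp < 0L) {
      stop("genome_length ", L, " too short for requested ccgg_rate/",
           "cpg_rate (needs >= ", token_bp, " bp)")
    }
    n_gaps <- length(tokens) + 1L
    gaps <- as.integer(rmultinom(1L, bg_bp, rep(1, n_gaps)))
    pieces <- character(2L * length(tokens) + 1L)
    pieces[seq(1L, length(pieces), by = 2L)] <-
      vapply(gaps, function(g) paste(.background_seq(g), collapse = ""),
             character(1))
    if (length(tokens)) {
      pieces[seq(2L, length(pieces) - 1L, by = 2L)] <- tokens
    }
    chroms[[i]] <- paste(pieces, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  seqlengths <- setNames(Biostrings::width(genome), names(genome))

  set.seed(.stage_seed(config$seed, 23L))
  repeats <- .simulate_repeats(config, seqlengths)
  set.seed(.stage_seed(config$seed, 37L))
  genes <- .simulate_genes(config, seqlengths)
  structure(
    list(genome = genome, repeats = repeats, genes = genes,
         seqlengths = seqlengths),
    class = "simulated_genome"
  )
}

.simulate_repeats <- function(config, seqlengths) {
  rows <- list()
  for (j in seq_len(nrow(config$repeat_classes))) {
    rc <- config$repeat_classes[j, ]
    for (chrom in names(seqlengths)) {
      L <- seqlengths[[chrom]]
      target <- rc$fraction * L
      placed <- 0
      starts <- integer(0)
      widths <- integer(0)
      while (placed < target) {
        w <- as.integer(round(runif(1L, 150, 600)))
        if (w >= L) w <- as.integer(L %/% 2)
        s <- as.integer(sample.int(L - w, 1L))
        starts <- c(starts, s)
        widths <- c(widths, w)
        placed <- placed + w
      }
      if (length(starts) == 0L) {
        stop("chromosome too short to place repeat family ", rc$family)
      }
      rows[[length(rows) + 1L]] <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = starts, width = widths),
        class = rc$class, family = rc$family
      )
    }
  }
  out <- sort(suppressWarnings(do.call(c, rows)), ignore.strand = TRUE)
  out$name <- paste0(out$class, "/", out$family)
  out
}

.simulate_genes <- function(config, seqlengths) {
  rows <- list()
  gid <- 0L
  for (chrom in names(seqlengths)) {
    L <- seqlengths[[chrom]]
    n_genes <- max(1L, as.integer(round(config$gene_density * L / 1e6)))
    for (g in seq_len(n_genes)) {
      gid <- gid + 1L
      len <- as.integer(round(runif(1L, 5000, min(30000, L - 1))))
      if (len >= L) {
        stop("chromosome too short to place a gene")
      }
      s <- as.integer(sample.int(L - len, 1L))
      e <- s + len - 1L
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(2:8, 1L)
      ex_w <- as.integer(round(runif(n_ex, 100, 400)))
      # first exon anchored at the TSS end of the gene body
      gap_total <- len - sum(ex_w)
      if (gap_total < n_ex - 1L) {
        n_ex <- 2L
        ex_w <- c(150L, 150L)
        gap_total <- len - 300L
      }
      gaps <- as.integer(rmultinom(1L, gap_total - (n_ex - 1L),
                                   rep(1, n_ex - 1L))) + 1L
      ex_start <- s + cumsum(c(0L, head(ex_w, -1L) + gaps))
      id <- sprintf("gene_%04d", gid)
      rows[[length(rows) + 1L]] <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(
          start = c(s, ex_start),
          end = c(e, ex_start + ex_w - 1L)
        ),
        strand = strand,
        type = c("gene", rep("exon", n_ex)),
        gene_id = id
      )
    }
  }
  sort(suppressWarnings(do.call(c, rows)), ignore.strand = TRUE)
}

# Mixture quantile function via grid inversion of the CDF
.mixture_quantile <- function(u, mx) {
  lo <- min(mx$logit_mean - 6 * mx$logit_sd)
  hi <- max(mx$logit_mean + 6 * mx$logit_sd)
  grid <- seq(lo, hi, length.out = 4001L)
  cdf <- rowSums(vapply(seq_len(nrow(mx)), function(j) {
    mx$weight[j] * pnorm(grid, mx$logit_mean[j], mx$logit_sd[j])
  }, numeric(length(grid))))
  approx(cdf, grid, xout = u, rule = 2, ties = "ordered")$y
}

# Most likely mixture component of each logit value
.mixture_component <- function(x, mx) {
  dens <- vapply(seq_len(nrow(mx)), function(j) {
    mx$weight[j] * dnorm(x, mx$logit_mean[j], mx$logit_sd[j])
  }, numeric(length(x)))
  max.col(dens)
}

#' Simulate per-sample bisulfite count tables with a planted truth set
#'
#' Fragments are derived from the genome by MspI digestion and 40-220 bp
#' size selection.  Each fragment receives one latent quantile shared by
#' the two groups and mapped through each group's logit-Gaussian mixture
#' quantile function, so each group's marginal fragment-methylation
#' distribution follows its own mixture while unplanted fragments stay
#' maximally coupled across groups (identical when both groups share a
#' mixture).  A `dmf_fraction` of fragments is planted as true DMFs: the
#' second group's value is set a shift of at least `dmf_min_shift` below
#' (probability `hypo_fraction`) or above the first group's value,
#' clipped to \[0,1\] with the direction flipped if clipping would
#' violate the minimum shift.
#'
#' Reads are then sampled per sample and per CpG: total reads are
#' negative binomial (`depth_mean`, `depth_dispersion`); the CpG's
#' methylation is a Beta draw around the fragment's true value
#' (concentration `jitter_concentration`; degenerate at 0 and 1); and
#' methylated reads are binomial.  Only covered CpGs (depth > 0) appear
#' in the count tables, mirroring real coverage files.
#'
#' @param sim_genome A [simulate_genome()] result (or a list with
#'   elements `genome` and `seqlengths`).
#' @param config The [simulation_config()].
#' @return List of class `"simulated_methylomes"` with `fragments`
#'   (size-selected `GRanges`), `counts` (named list of per-sample
#'   count tables in [read_bismark_cov()] layout), `truth` (data.frame:
#'   fragment_id, true per-group methylation, mixture component per
#'   group, is_planted_dmf, direction), and `design` (named character
#'   vector sample -> group).
#' @export
simulate_methylomes <- function(sim_genome, config) {
  stopifnot(inherits(config, "simulation_config"))
  fragments <- size_select(mspi_digest(sim_genome$genome))
  if (length(fragments) == 0L) {
    stop("digestion produced no size-selected fragments; ",
         "increase genome_length or ccgg_rate")
  }
  groups <- names(config$group_mixtures)
  n_frag <- length(fragments)

  set.seed(.stage_seed(config$seed, 101L))
  u <- runif(n_frag)
  logit1 <- .mixture_quantile(u, config$group_mixtures[[1L]])
  logit2 <- .mixture_quantile(u, config$group_mixtures[[2L]])
  m1 <- plogis(logit1)
  m2 <- plogis(logit2)
  comp1 <- .mixture_component(logit1, config$group_mixtures[[1L]])
  comp2 <- .mixture_component(logit2, config$group_mixtures[[2L]])

  set.seed(.stage_seed(config$seed, 102L))
  n_dmf <- round(config$dmf_fraction * n_frag)
  planted <- rep(FALSE, n_frag)
  direction <- rep("none", n_frag)
  if (n_dmf > 0L) {
    idx <- sample.int(n_frag, n_dmf)
    planted[idx] <- TRUE
    shift <- config$dmf_min_shift + runif(n_dmf, 0, 0.15)
    shift <- pmin(shift, 0.49)
    want_hypo <- runif(n_dmf) < config$hypo_fraction
    # anchor the planted difference to the first group's value; flip the
    # direction when clipping at the [0,1] boundary would shrink it
    lo_ok <- m1[idx] - shift >= 0
    hi_ok <- m1[idx] + shift <= 1
    go_hypo <- (want_hypo & lo_ok) | (!want_hypo & !hi_ok)
    m2[idx] <- ifelse(go_hypo, m1[idx] - shift, m1[idx] + shift)
    direction[idx] <- ifelse(go_hypo, "hypo", "hyper")
  }
  truth <- data.frame(
    fragment_id = fragments$fragment_id,
    stringsAsFactors = FALSE
  )
  truth[[paste0("true_", groups[1])]] <- m1
  truth[[paste0("true_", groups[2])]] <- m2
  truth[[paste0("component_", groups[1])]] <- comp1
  truth[[paste0("component_", groups[2])]] <- comp2
  truth$is_planted_dmf <- planted
  truth$direction <- direction

  design <- setNames(
    rep(groups, each = config$n_samples_per_group),
    paste0(rep(groups, each = config$n_samples_per_group), "_s",
           sprintf("%02d", rep(seq_len(config$n_samples_per_group), 2L)))
  )
  chrom_per_cpg <- rep(as.character(GenomicRanges::seqnames(fragments)),
                       lengths(fragments$cpg_pos))
  pos_per_cpg <- unlist(fragments$cpg_pos)
  frag_per_cpg <- rep(seq_len(n_frag), lengths(fragments$cpg_pos))
  truth_mat <- cbind(m1, m2)
  counts <- setNames(vector("list", length(design)), names(design))
  for (s_i in seq_along(design)) {
    set.seed(.stage_seed(config$seed, 1000L + s_i))
    g_i <- match(design[[s_i]], groups)
    m_frag <- truth_mat[frag_per_cpg, g_i]
    counts[[s_i]] <- .sample_cpg_counts(
      m_frag, config,
      chrom = chrom_per_cpg, pos = pos_per_cpg
    )
  }
  structure(
    list(fragments = fragments, counts = counts, truth = truth,
         design = design, config = config),
    class = "simulated_methylomes"
  )
}

# Sample one sample's reads for a vector of CpGs with fragment-level
# true methylation m (already expanded per CpG).
.sample_cpg_counts <- function(m, config, chrom, pos) {
  n <- length(m)
  depth <- rnbinom(n, mu = config$depth_mean, size = config$depth_dispersion)
  m_cpg <- m
  interior <- m > 0 & m < 1
  if (any(interior)) {
    c0 <- config$jitter_concentration
    m_cpg[interior] <- rbeta(sum(interior),
                             m[interior] * c0, (1 - m[interior]) * c0)
  }
  meth <- rbinom(n, depth, m_cpg)
  keep <- depth > 0
  data.frame(
    chrom = chrom[keep], pos = pos[keep],
    count_meth = meth[keep],
    count_unmeth = depth[keep] - meth[keep],
    count_total = depth[keep],
    stringsAsFactors = FALSE
  )
}

#' Simulate a fragment methylation matrix directly
#'
#' A fast path for statistical experiments (null calibration, power)
#' that skips genome synthesis: abstract fragments with given true
#' per-group methylation and CpG counts are pushed through the same
#' per-CpG read sampler as [simulate_methylomes()], and the pooled
#' fragment methylation and coverage-filter flags are returned as a
#' [fragment_meth_matrix()]-compatible object.
#'
#' @param true_meth Numeric matrix, fragments x 2 groups, of true
#'   fragment methylation (column names become group labels).
#' @param n_cpg Integer vector of CpG sites per fragment.
#' @param config A [simulation_config()] providing depth, jitter and
#'   sample-size parameters.
#' @param min_cpgs,min_depth Coverage-filter parameters.
#' @return List with `fmm` (class `"fragment_meth_matrix"`) and
#'   `design`.
#' @export
simulate_fragment_matrix <- function(true_meth, n_cpg, config,
                                     min_cpgs = 2L, min_depth = 10L) {
  stopifnot(ncol(true_meth) == 2L, nrow(true_meth) == length(n_cpg))
  groups <- colnames(true_meth)
  if (is.null(groups)) groups <- c("group1", "group2")
  n_frag <- nrow(true_meth)
  ids <- sprintf("frag_%06d", seq_len(n_frag))
  design <- setNames(
    rep(groups, each = config$n_samples_per_group),
    paste0(rep(groups, each = config$n_samples_per_group), "_s",
           sprintf("%02d", rep(seq_len(config$n_samples_per_group), 2L)))
  )
  frag_per_cpg <- rep(seq_len(n_frag), n_cpg)
  meth <- pass <- ncov <- reads <- matrix(
    NA_real_, n_frag, length(design),
    dimnames = list(ids, names(design))
  )
  for (s_i in seq_along(design)) {
    set.seed(.stage_seed(config$seed, 5000L + s_i))
    g_i <- match(design[[s_i]], groups)
    m <- true_meth[frag_per_cpg, g_i]
    n <- length(m)
    depth <- rnbinom(n, mu = config$depth_mean,
                     size = config$depth_dispersion)
    m_cpg <- m
    interior <- m > 0 & m < 1
    if (any(interior)) {
      c0 <- config$jitter_concentration
      m_cpg[interior] <- rbeta(sum(interior),
                               m[interior] * c0, (1 - m[interior]) * c0)
    }
    met <- rbinom(n, depth, m_cpg)
    rs <- function(x) {
      as.numeric(rowsum(c(x, rep(0, n_frag)),
                        c(frag_per_cpg, seq_len(n_frag))))
    }
    sum_tot <- rs(depth)
    sum_met <- rs(met)
    reads[, s_i] <- sum_tot
    ncov[, s_i] <- rs(as.numeric(depth > 0))
    pass[, s_i] <- rs(as.numeric(depth >= min_depth)) >= min_cpgs
    meth[, s_i] <- ifelse(sum_tot > 0, sum_met / sum_tot, NA_real_)
  }
  fmm <- structure(
    list(meth = meth, pass = pass == 1, n_cpg_covered = ncov,
         total_reads = reads, fragment_ids = ids,
         n_cpg = setNames(n_cpg, ids), fragments = NULL,
         min_cpgs = min_cpgs, min_depth = min_depth),
    class = "fragment_meth_matrix"
  )
  list(fmm = fmm, design = design)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the genome FASTA, repeat and gene BED tracks, per-sample
#' bismark-coverage-style count files, the fragment BED and the truth
#' table into a directory.  Output is byte-identical across runs with
#' the same config seed.
#'
#' @param sim_genome A [simulate_genome()] result.
#' @param sim_meth A [simulate_methylomes()] result (optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim_genome, sim_meth = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim_genome$genome,
                              file.path(dir, "genome.fa"))
  write_track_bed(sim_genome$repeats, file.path(dir, "repeats.bed"))
  genes <- sim_genome$genes
  genes$name <- paste0(genes$gene_id, ":", genes$type)
  write_track_bed(genes, file.path(dir, "genes.bed"))
  if (!is.null(sim_meth)) {
    write_fragments_bed(sim_meth$fragments, file.path(dir, "fragments.bed"))
    for (s in names(sim_meth$counts)) {
      write_bismark_cov(sim_meth$counts[[s]],
                        file.path(dir, paste0(s, ".cov")))
    }
    write.table(sim_meth$truth, file.path(dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(
      data.frame(sample = names(sim_meth$design),
                 group = unname(sim_meth$design)),
      file.path(dir, "design.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(dir)
}
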