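#' 1-Mb DMF density tiles and density correlations
#'
#' The genome is divided into non-overlapping tiles of `window` bp
#' starting at coordinate 0.  Each comparison fragment and DMF is
#' assigned to the tile containing its midpoint.  A tile's density
#' score is the number of DMFs divided by the number of comparison
#' fragments; tiles with fewer than `min_fragments` comparison
#' fragments are flagged `excluded` and omitted from the correlations.
#' Hypo- and hypermethylated DMFs get separate scores.  When gene and
#' genome tracks are supplied, each tile also carries its TSS count and
#' its genomic CpG (CG dinucleotide) count, and Pearson correlations of
#' density score against both are reported for each direction.
#'
#' @param fragments `GRanges` of comparison fragments.
#' @param dmf_table The `table` element of a [call_dmfs()] result (or
#'   any data.frame with `fragment_id`, `is_dmf`, `direction`).
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param genes Optional gene track (`GRanges`, `type == "gene"` rows
#'   define TSS) for gene-density correlations.
#' @param genome Optional `DNAStringSet` for CpG-density correlations.
#' @param window Tile width in bp (> 0).
#' @param min_fragments Minimum comparison fragments per retained tile.
#' @return List with `tiles` (data.frame: chrom, start, end,
#'   n_comparison, n_dmf, n_hypo, n_hyper, density_score, density_hypo,
#'   density_hyper, gene_count, cpg_count, excluded) and `correlations`
#'   (data.frame: direction, covariate, pearson_r, n_tiles).
#' @export
density_tiles <- function(fragments, dmf_table, seqlengths,
                          genes = NULL, genome = NULL,
                          window = 1e6, min_fragments = 3L) {
  if (window <= 0) {
    stop("`window` must be > 0")
  }
  tiles <- GenomicRanges::tileGenome(
    seqlengths, tilewidth = window, cut.last.tile.in.chrom = TRUE
  )
  mid <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(fragments),
    ranges = IRanges::IRanges(
      start = (GenomicRanges::start(fragments) +
                 GenomicRanges::end(fragments)) %/% 2L,
      width = 1L
    )
  )
  tile_of <- rep(NA_integer_, length(fragments))
  hit <- GenomicRanges::findOverlaps(mid, tiles, ignore.strand = TRUE)
  tile_of[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  tl <- factor(tile_of, levels = seq_along(tiles))
  n_comparison <- as.integer(table(tl))
  d <- dmf_table[match(fragments$fragment_id, dmf_table$fragment_id), ]
  is_dmf <- !is.na(d$is_dmf) & d$is_dmf
  n_dmf <- as.integer(table(tl[is_dmf]))
  n_hypo <- as.integer(table(tl[is_dmf & d$direction == "hypo"]))
  n_hyper <- as.integer(table(tl[is_dmf & d$direction == "hyper"]))
  excluded <- n_comparison < min_fragments
  score <- function(num) ifelse(excluded, NA_real_, num / n_comparison)
  gene_count <- cpg_count <- rep(NA_integer_, length(tiles))
  if (!is.null(genes)) {
    gr <- genes[genes$type == "gene"]
    plus <- as.character(GenomicRanges::strand(gr)) == "+"
    tss <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(gr),
      ranges = IRanges::IRanges(
        start = ifelse(plus, GenomicRanges::start(gr),
                       GenomicRanges::end(gr)),
        width = 1L
      )
    )
    gene_count <- GenomicRanges::countOverlaps(tiles, tss,
                                               ignore.strand = TRUE)
  }
  if (!is.null(genome)) {
    genome <- .as_genome(genome)
    cg <- Biostrings::vmatchPattern("CG", genome, fixed = TRUE)
    cg_gr <- GenomicRanges::GRanges(
      seqnames = rep(names(genome), lengths(IRanges::start(cg))),
      ranges = IRanges::IRanges(start = unlist(IRanges::start(cg)),
                                width = 1L)
    )
    cpg_count <- GenomicRanges::countOverlaps(tiles, cg_gr,
                                              ignore.strand = TRUE)
  }
  tab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tiles)),
    start = GenomicRanges::start(tiles) - 1L,
    end = GenomicRanges::end(tiles),
    n_comparison = n_comparison, n_dmf = n_dmf,
    n_hypo = n_hypo, n_hyper = n_hyper,
    density_score = score(n_dmf),
    density_hypo = score(n_hypo),
    density_hyper = score(n_hyper),
    gene_count = gene_count, cpg_count = cpg_count,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
  cors <- list()
  keep <- !excluded
  for (dir in c("hypo", "hyper")) {
    dens <- tab[[paste0("density_", dir)]]
    for (cov in c("gene_count", "cpg_count")) {
      v <- tab[[cov]]
      ok <- keep & !is.na(v) & !is.na(dens)
      if (sum(ok) >= 3 && sd(dens[ok]) > 0 && sd(v[ok]) > 0) {
        cors[[length(cors) + 1L]] <- data.frame(
          direction = dir, covariate = cov,
          pearson_r = cor(dens[ok], v[ok]),
          n_tiles = sum(ok), stringsAsFactors = FALSE
        )
      }
    }
  }
  list(
    tiles = tab,
    correlations = if (length(cors)) do.call(rbind, cors) else
      data.frame(direction = character(0), covariate = character(0),
                 pearson_r = numeric(0), n_tiles = integer(0))
  )
}

#' Upper-tail hypergeometric overlap test
#'
#' Tests whether a drawn fragment set (e.g. hypomethylated DMFs) is
#' enriched for a success category (e.g. fragments inside partially
#' methylated domains) relative to the population: `P[X >= k]` with
#' population size `N`, `K` successes, `n` draws and `k` observed
#' successes among the draws.
#'
#' @param population Character ids of the full fragment population.
#' @param successes Ids of success fragments (subset of population).
#' @param draws Ids of drawn fragments (subset of population).
#' @return List with `p_value`, `k`, `n`, `K`, `N`,
#'   `prop_draws` (= k/n) and `prop_rest` (= (K-k)/(N-n)).
#' @export
hypergeometric_overlap <- function(population, successes, draws) {
  population <- unique(population)
  N <- length(population)
  if (N == 0L) {
    stop("population is empty")
  }
  successes <- unique(successes)
  draws <- unique(draws)
  if (!all(successes %in% population) || !all(draws %in% population)) {
    stop("`successes` and `draws` must be subsets of `population`")
  }
  K <- length(successes)
  n <- length(draws)
  k <- length(intersect(draws, successes))
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(
    p_value = p, k = k, n = n, K = K, N = N,
    prop_draws = if (n > 0) k / n else NA_real_,
    prop_rest = if (N > n) (K - k) / (N - n) else NA_real_
  )
}

#' 2x2 chi-square test with Yates continuity correction
#'
#' `chi2 = sum((max(|O - E| - 0.5, 0))^2 / E)` over the four cells, with
#' expected counts from the margins; the continuity term is floored so
#' a deviation below 0.5 contributes nothing.  The p-value is the upper
#' tail of chi-square with 1 df.
#'
#' @param table 2x2 numeric matrix of non-negative counts with positive
#'   margins.
#' @return List with `chi2` and `p_value`.
#' @export
chi2_yates <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0)) {
    stop("`table` must be a 2x2 matrix of non-negative counts")
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("both margins must be positive")
  }
  expected <- outer(rs, cs) / sum(table)
  chi2 <- sum(pmax(abs(table - expected) - 0.5, 0)^2 / expected)
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Regulatory-feature enrichment of DMFs
#'
#' For each feature track, builds the 2x2 table of strong overlap
#' (>= `min_fraction` of the fragment length, default 50%) against set
#' membership (DMF vs non-DMF), tests it with [chi2_yates()], and
#' reports the direction (enriched when the DMF overlap proportion
#' exceeds the non-DMF proportion) and the fold ratio of the two
#' proportions.  Run it separately for hypo- and hypermethylated DMF
#' sets against the non-DMFs.
#'
#' @param dmf_fragments,non_dmf_fragments Disjoint `GRanges` sets.
#' @param feature_tracks Named list of `GRanges` feature tracks.
#' @param min_fraction Strong-overlap threshold (fraction of fragment).
#' @return data.frame with one row per feature: `feature`,
#'   `dmf_overlap`, `dmf_total`, `non_overlap`, `non_total`, `chi2`,
#'   `p_value`, `direction`, `fold`.
#' @export
feature_enrichment <- function(dmf_fragments, non_dmf_fragments,
                               feature_tracks, min_fraction = 0.5) {
  if (length(dmf_fragments) == 0L) {
    stop("DMF set is empty")
  }
  if (length(intersect(dmf_fragments$fragment_id,
                       non_dmf_fragments$fragment_id)) > 0L) {
    stop("DMF and non-DMF sets must be disjoint")
  }
  if (is.null(names(feature_tracks))) {
    stop("`feature_tracks` must be a named list")
  }
  strong <- function(frags, track) {
    hits <- overlap_labels(frags, track, min_fraction = min_fraction)
    frags$fragment_id %in% hits$fragment_id
  }
  rows <- lapply(names(feature_tracks), function(nm) {
    a <- sum(strong(dmf_fragments, feature_tracks[[nm]]))
    b <- sum(strong(non_dmf_fragments, feature_tracks[[nm]]))
    tab <- matrix(
      c(a, length(dmf_fragments) - a, b, length(non_dmf_fragments) - b),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("dmf", "non_dmf"), c("overlap", "no_overlap"))
    )
    ct <- chi2_yates(tab)
    p_dmf <- a / length(dmf_fragments)
    p_non <- b / length(non_dmf_fragments)
    data.frame(
      feature = nm,
      dmf_overlap = a, dmf_total = length(dmf_fragments),
      non_overlap = b, non_total = length(non_dmf_fragments),
      chi2 = ct$chi2, p_value = ct$p_value,
      direction = if (p_dmf > p_non) "enriched" else "depleted",
      fold = p_dmf / p_non,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
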