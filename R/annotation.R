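#' Overlap fragments with a labelled annotation track
#'
#' Reports, for each fragment, the track labels it overlaps together
#' with the overlap fraction (overlap bp / fragment length).  With
#' `min_fraction = 0` any 1-bp overlap qualifies (the rule used for
#' repeat and gene-model tracks); with `min_fraction > 0` an overlap
#' qualifies when the fraction is greater than or equal to the
#' threshold (the "strong overlap" rule used for regulatory-feature
#' enrichment, default 0.5 there).
#'
#' @param fragments `GRanges` of fragments.
#' @param track `GRanges` with a `name` (or `class`) metadata column.
#' @param min_fraction Minimum overlap fraction in \[0,1\].
#' @return data.frame with columns `fragment_id`, `label`,
#'   `overlap_bp`, `fraction`; one row per qualifying fragment-interval
#'   pair.
#' @export
overlap_labels <- function(fragments, track, min_fraction = 0) {
  if (min_fraction < 0 || min_fraction > 1) {
    stop("`min_fraction` must lie in [0, 1]")
  }
  if (any(GenomicRanges::width(track) < 1L)) {
    stop("track contains malformed (empty) intervals")
  }
  hits <- GenomicRanges::findOverlaps(fragments, track, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(
    GenomicRanges::ranges(fragments)[qi],
    GenomicRanges::ranges(track)[si]
  )
  ov_bp <- IRanges::width(ov)
  frac <- ov_bp / GenomicRanges::width(fragments)[qi]
  keep <- if (min_fraction > 0) frac >= min_fraction else ov_bp >= 1L
  label <- if (!is.null(track$name)) track$name else
    if (!is.null(track$class)) track$class else rep(".", length(track))
  data.frame(
    fragment_id = fragments$fragment_id[qi][keep],
    label = label[si][keep],
    overlap_bp = ov_bp[keep],
    fraction = frac[keep],
    stringsAsFactors = FALSE
  )
}

#' Assign each fragment to a primary genomic element
#'
#' The primary element is assigned by precedence
#' promoter > exon > intron > intergenic.  Promoters are the
#' strand-oriented window `promoter_window` (default -5 kb to +1 kb)
#' around the TSS.  Intergenic requires no gene-body overlap and a
#' distance greater than `intergenic_distance` (default 5 kb) from every
#' TSS; the rare fragment that is none of promoter/exon/intron yet lies
#' within 5 kb of a TSS is labelled `tss_proximal`.  Fixed-width TSS
#' windows (+/- 200 bp, 500 bp, 1 kb) are reported as additional flags.
#'
#' @param fragments `GRanges` of fragments.
#' @param genes `GRanges` gene track with metadata columns `type`
#'   (`"gene"` rows define gene bodies and the TSS; `"exon"` rows define
#'   exons) and `gene_id`; strand must be `+` or `-` for gene rows.
#' @param promoter_window Numeric length-2: offsets (upstream, downstream)
#'   of the TSS in gene orientation.
#' @param intergenic_distance Minimum TSS distance for intergenic (bp).
#' @return data.frame with `fragment_id`, `element` (promoter / exon /
#'   intron / intergenic / tss_proximal), and logical `tss_200`,
#'   `tss_500`, `tss_1k` flags.
#' @export
assign_element <- function(fragments, genes,
                           promoter_window = c(-5000, 1000),
                           intergenic_distance = 5000) {
  gene_rows <- genes[genes$type == "gene"]
  exon_rows <- genes[genes$type == "exon"]
  strand <- as.character(GenomicRanges::strand(gene_rows))
  if (any(!strand %in% c("+", "-"))) {
    stop("every gene must have strand '+' or '-'")
  }
  plus <- strand == "+"
  tss <- ifelse(plus, GenomicRanges::start(gene_rows),
                GenomicRanges::end(gene_rows))
  promoters <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gene_rows),
    ranges = IRanges::IRanges(
      start = pmax(1L, ifelse(plus, tss + promoter_window[1],
                              tss - promoter_window[2])),
      end = ifelse(plus, tss + promoter_window[2],
                   tss - promoter_window[1])
    )
  )
  tss_gr <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gene_rows),
    ranges = IRanges::IRanges(start = tss, width = 1L)
  )
  ov <- function(subject) {
    IRanges::overlapsAny(fragments, subject, ignore.strand = TRUE)
  }
  in_promoter <- ov(promoters)
  in_exon <- ov(exon_rows)
  in_gene <- ov(gene_rows)
  dist_tss <- rep(Inf, length(fragments))
  near <- GenomicRanges::distanceToNearest(fragments, tss_gr,
                                           ignore.strand = TRUE)
  dist_tss[S4Vectors::queryHits(near)] <- S4Vectors::mcols(near)$distance
  element <- ifelse(
    in_promoter, "promoter",
    ifelse(in_exon, "exon",
           ifelse(in_gene, "intron",
                  ifelse(dist_tss > intergenic_distance,
                         "intergenic", "tss_proximal")))
  )
  win <- function(w) {
    ov(GenomicRanges::resize(tss_gr, width = 2L * w + 1L, fix = "center"))
  }
  data.frame(
    fragment_id = fragments$fragment_id,
    element = element,
    tss_200 = win(200L), tss_500 = win(500L), tss_1k = win(1000L),
    stringsAsFactors = FALSE
  )
}

.RETRO_CLASSES <- c("SINE", "LINE", "LTR")
.KNOWN_REPEAT_CLASSES <- c(.RETRO_CLASSES, "Satellite", "Low_complexity",
                           "Simple_repeat")

#' Classify fragments by repeat overlap
#'
#' A fragment carries every repeat class it overlaps by at least 1 bp.
#' It is a retroelement fragment when any overlapping class is SINE,
#' LINE or LTR; fragments overlapping only Satellite, Low_complexity or
#' Simple_repeat are repeat-containing but non-retroelement.  Unknown
#' class labels raise a warning and count as non-retroelement.
#'
#' @param fragments `GRanges` of fragments.
#' @param repeats `GRanges` repeat track with `class` and `family`
#'   metadata columns (see [read_track_bed()] with `repeat_names=TRUE`).
#' @return data.frame with `fragment_id`, `repeat_classes` (comma-joined
#'   class names, `""` when none), `repeat_families` (comma-joined
#'   `class/family`), `is_retroelement`.
#' @export
classify_repeat <- function(fragments, repeats) {
  unknown <- setdiff(unique(repeats$class), .KNOWN_REPEAT_CLASSES)
  if (length(unknown) > 0) {
    warning("unknown repeat classes treated as non-retroelement: ",
            paste(unknown, collapse = ", "))
  }
  hits <- GenomicRanges::findOverlaps(fragments, repeats,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  cls <- repeats$class[S4Vectors::subjectHits(hits)]
  fam <- paste0(cls, "/", repeats$family[S4Vectors::subjectHits(hits)])
  join <- function(v, i) {
    vapply(
      split(v, factor(i, levels = seq_along(fragments))),
      function(x) paste(sort(unique(x)), collapse = ","),
      character(1)
    )
  }
  classes <- join(cls, qi)
  families <- join(fam, qi)
  retro <- vapply(
    split(cls %in% .RETRO_CLASSES, factor(qi, levels = seq_along(fragments))),
    any, logical(1)
  )
  data.frame(
    fragment_id = fragments$fragment_id,
    repeat_classes = unname(classes),
    repeat_families = unname(families),
    is_retroelement = unname(retro),
    stringsAsFactors = FALSE
  )
}

#' Per-class methylation summaries for two groups
#'
#' For each annotation class and each group: the number of fragments,
#' median and quartiles of the per-fragment group-mean methylation, the
#' proportions in the low (<= 0.30), intermediate, and high (>= 0.70)
#' categories, and the between-group median difference.  A fragment
#' contributes to every class it is a member of.
#'
#' @param gm Group-mean matrix from [group_means()] (fragments x 2
#'   groups, rownames are fragment ids).
#' @param membership data.frame with columns `fragment_id` and `class`
#'   (one row per fragment-class membership).
#' @return data.frame with one row per class x group.
#' @export
class_summary <- function(gm, membership) {
  if (is.null(rownames(gm))) {
    stop("`gm` must have fragment ids as rownames")
  }
  membership <- membership[membership$fragment_id %in% rownames(gm), ,
                           drop = FALSE]
  classes <- unique(membership$class)
  groups <- colnames(gm)
  rows <- list()
  for (cl in classes) {
    ids <- membership$fragment_id[membership$class == cl]
    sub <- gm[ids, , drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("class '", cl, "' has no fragments with defined methylation; omitted")
      next
    }
    med_diff <- median(sub[, 2]) - median(sub[, 1])
    for (g in groups) {
      v <- sub[, g]
      lev <- classify_methylation_level(v)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, group = g, n = length(v),
        median = median(v),
        q1 = as.numeric(quantile(v, 0.25)),
        q3 = as.numeric(quantile(v, 0.75)),
        prop_low = mean(lev == "low"),
        prop_intermediate = mean(lev == "intermediate"),
        prop_high = mean(lev == "high"),
        median_diff = med_diff,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' High-methylation retention by repeat class
#'
#' Restricts to fragments highly methylated in the reference group
#' (methylation > `high_ref`) and reports, per repeat class and for the
#' non-retroelement remainder, the fraction that retains high
#' methylation in the test group (> `high_test`), along with each
#' class's share among the retained fragments.
#'
#' @param gm Group-mean matrix from [group_means()].
#' @param repeat_assign Output of [classify_repeat()]; families listed
#'   in its `repeat_families` column define the classes summarised.
#' @param reference_group,test_group Column names of `gm`.
#' @param high_ref Reference-group threshold (exclusive, default 0.7).
#' @param high_test Test-group retention threshold (exclusive, 0.8).
#' @return data.frame with `class`, `n_selected`, `n_retained`,
#'   `retention_fraction`, `share_of_retained`.  When no fragment
#'   exceeds `high_ref` an empty data.frame is returned with a message.
#' @export
retention_table <- function(gm, repeat_assign, reference_group, test_group,
                            high_ref = 0.7, high_test = 0.8) {
  for (thr in c(high_ref, high_test)) {
    if (thr <= 0 || thr >= 1) {
      stop("thresholds must lie in (0, 1)")
    }
  }
  ref <- gm[, reference_group]
  tst <- gm[, test_group]
  sel <- !is.na(ref) & !is.na(tst) & ref > high_ref
  if (!any(sel)) {
    message("no fragment exceeds ", high_ref, " in the reference group")
    return(data.frame(
      class = character(0), n_selected = integer(0),
      n_retained = integer(0), retention_fraction = numeric(0),
      share_of_retained = numeric(0)
    ))
  }
  ids <- rownames(gm)[sel]
  retained_all <- sum(tst[sel] > high_test)
  ra <- repeat_assign[match(ids, repeat_assign$fragment_id), ]
  fam_lists <- strsplit(ra$repeat_families, ",", fixed = TRUE)
  classes <- sort(unique(unlist(fam_lists)))
  classes <- classes[classes != ""]
  rows <- lapply(classes, function(cl) {
    in_cl <- vapply(fam_lists, function(f) cl %in% f, logical(1))
    n_sel <- sum(in_cl)
    n_ret <- sum(tst[sel][in_cl] > high_test)
    data.frame(
      class = cl, n_selected = n_sel, n_retained = n_ret,
      retention_fraction = n_ret / n_sel,
      share_of_retained = if (retained_all > 0) n_ret / retained_all else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  non_retro <- !ra$is_retroelement
  rows[[length(rows) + 1L]] <- data.frame(
    class = "non_retroelement",
    n_selected = sum(non_retro),
    n_retained = sum(tst[sel][non_retro] > high_test),
    retention_fraction = if (any(non_retro)) {
      sum(tst[sel][non_retro] > high_test) / sum(non_retro)
    } else NA_real_,
    share_of_retained = if (retained_all > 0) {
      sum(tst[sel][non_retro] > high_test) / retained_all
    } else NA_real_,
    stringsAsFactors = FALSE
  )
  do.call(rbind, rows)
}
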