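#' In-silico MspI digestion of a genome
#'
#' MspI cuts the palindromic site CCGG between the first and second base
#' (C^CGG).  Fragments are the intervals between consecutive cuts; the
#' leading and trailing piece of each chromosome lacks an MspI end (no
#' adaptor could ligate there in an RRBS library) and is excluded.  Each
#' retained fragment therefore starts with `CGG` and the base preceding
#' its start is `C`.
#'
#' CpG sites are enumerated on the forward strand: the coordinate of the
#' `C` of every `CG` dinucleotide whose `C` lies inside the fragment.
#' Both bisulfite strands of a CpG map to this single site.  Ambiguity
#' codes (e.g. `N`) never match `CCGG` or `CG`.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome sequences.  Case is folded to upper.
#'
#' @return A [GenomicRanges::GRanges] of internal MspI fragments, ordered
#'   by chromosome and position, with metadata columns:
#'   \describe{
#'     \item{fragment_id}{stable id `"chrom:start-end"` in 0-based
#'       half-open coordinates (BED convention);}
#'     \item{cpg_pos}{an [IRanges::IntegerList] of 1-based C positions of
#'       CpG dinucleotides within the fragment;}
#'     \item{n_cpg}{number of CpG sites;}
#'     \item{passes_size_selection}{`TRUE` when the fragment length is
#'       within the default 40-220 bp RRBS size-selection window.}
#'   }
#'   A chromosome without at least two CCGG sites contributes no
#'   fragments; an empty genome yields an empty `GRanges`.
#'
#' @seealso [size_select()], [enumerate_cpgs()]
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AACCGGTTCCGGAA"))
#' mspi_digest(g)
#' @export
mspi_digest <- function(genome) {
  genome <- .as_genome(genome)
  if (length(genome) == 0L) {
    return(.empty_fragments())
  }
  site_hits <- Biostrings::vmatchPattern("CCGG", genome, fixed = TRUE)
  cg_hits <- Biostrings::vmatchPattern("CG", genome, fixed = TRUE)

  pieces <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    # cut falls after the first C: a motif at 1-based position p yields a
    # fragment boundary at 0-based coordinate p
    cuts <- IRanges::start(site_hits[[i]])
    if (length(cuts) < 2L) next
    start1 <- cuts[-length(cuts)] + 1L
    end1 <- cuts[-1L]
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start1, end = end1)
    )
    cg_start <- IRanges::start(cg_hits[[i]])
    idx <- findInterval(cg_start - 1L, start1 - 1L)  # fragment whose start precedes C
    keep <- idx >= 1L & cg_start <= end1[pmax(idx, 1L)]
    cpg <- S4Vectors::split(
      cg_start[keep],
      factor(idx[keep], levels = seq_along(start1))
    )
    gr$cpg_pos <- IRanges::IntegerList(unname(cpg))
    pieces[[i]] <- gr
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    return(.empty_fragments())
  }
  out <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlevels(out) <- names(genome)
  GenomeInfoDb::seqlengths(out) <- Biostrings::width(genome)
  out$fragment_id <- fragment_ids(out)
  out$n_cpg <- lengths(out$cpg_pos)
  w <- GenomicRanges::width(out)
  out$passes_size_selection <- w >= 40L & w <= 220L
  S4Vectors::mcols(out) <- S4Vectors::mcols(out)[, c(
    "fragment_id", "cpg_pos", "n_cpg", "passes_size_selection"
  )]
  out
}

.as_genome <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- paste0("chr", seq_along(genome))
    }
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("`genome` must be a DNAStringSet or named character vector")
  }
  if (length(genome) > 0L && is.null(names(genome))) {
    stop("genome sequences must be named")
  }
  genome
}

.empty_fragments <- function() {
  gr <- GenomicRanges::GRanges()
  gr$fragment_id <- character(0)
  gr$cpg_pos <- IRanges::IntegerList()
  gr$n_cpg <- integer(0)
  gr$passes_size_selection <- logical(0)
  gr
}

#' Stable fragment identifiers in BED convention
#'
#' @param fragments A `GRanges` of fragments.
#' @return Character vector `"chrom:start-end"` with 0-based half-open
#'   coordinates.
#' @export
fragment_ids <- function(fragments) {
  sprintf(
    "%s:%d-%d",
    as.character(GenomicRanges::seqnames(fragments)),
    GenomicRanges::start(fragments) - 1L,
    GenomicRanges::end(fragments)
  )
}

#' Size-select digestion fragments
#'
#' RRBS libraries retain 40-220 bp (pre-adaptor) MspI fragments; bounds
#' are inclusive and measured on the genomic fragment length.
#'
#' @param fragments `GRanges` from [mspi_digest()].
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The subset of `fragments` with `min_len <= length <= max_len`.
#' @export
size_select <- function(fragments, min_len = 40L, max_len = 220L) {
  if (min_len > max_len) {
    stop("`min_len` must not exceed `max_len`")
  }
  w <- GenomicRanges::width(fragments)
  fragments[w >= min_len & w <= max_len]
}

#' Enumerate CpG sites within an interval
#'
#' Returns the 1-based forward-strand coordinates of the `C` of every
#' `CG` dinucleotide whose `C` lies within the interval (the `G` may be
#' the first base beyond its end).
#'
#' @param fragment A length-one `GRanges`.
#' @param genome A `DNAStringSet` containing the fragment's chromosome.
#' @return Integer vector of C positions (possibly empty).
#' @export
enumerate_cpgs <- function(fragment, genome) {
  genome <- .as_genome(genome)
  stopifnot(length(fragment) == 1L)
  chrom <- as.character(GenomicRanges::seqnames(fragment))
  if (!chrom %in% names(genome)) {
    stop("chromosome ", chrom, " not present in genome")
  }
  s <- GenomicRanges::start(fragment)
  e <- GenomicRanges::end(fragment)
  hits <- Biostrings::matchPattern("CG", genome[[chrom]], fixed = TRUE)
  pos <- IRanges::start(hits)
  pos[pos >= s & pos <= e]
}
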