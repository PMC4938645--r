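track <- function(starts, ends, name, strand = "*", chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                               strand = strand)
  gr$name <- name
  gr
}

test_that("overlap labelling honours the strong-overlap threshold", {
  # fragment [100,200) vs feature [150,400): exactly 50% of the fragment
  fr <- make_fragments(101, 200)
  tk <- track(151, 400, "feat")
  hit <- overlap_labels(fr, tk, min_fraction = 0.5)
  expect_equal(nrow(hit), 1L)  # >= reading: exactly 50% qualifies
  expect_equal(hit$fraction, 0.5)
  expect_equal(nrow(overlap_labels(fr, tk, min_fraction = 0.51)), 0L)
  # 1-bp boundary overlap qualifies at min_fraction = 0
  tk2 <- track(200, 300, "edge")
  expect_equal(nrow(overlap_labels(fr, tk2, min_fraction = 0)), 1L)
  expect_equal(nrow(overlap_labels(fr, track(201, 300, "out"))), 0L)
  expect_error(overlap_labels(fr, tk, min_fraction = 2), "min_fraction")
})

test_that("overlap labelling equals a brute-force interval scan", {
  set.seed(101)
  frs <- make_fragments(starts <- sort(sample.int(50000, 200)),
                        starts + sample(40:220, 200, replace = TRUE))
  t_start <- sort(sample.int(50000, 80))
  tk <- track(t_start, t_start + sample(100:2000, 80, replace = TRUE),
              paste0("f", 1:80))
  for (mf in c(0, 0.5)) {
    got <- overlap_labels(frs, tk, min_fraction = mf)
    exp_rows <- 0L
    for (i in seq_along(frs)) {
      fs <- GenomicRanges::start(frs)[i]; fe <- GenomicRanges::end(frs)[i]
      for (j in seq_along(tk)) {
        ov <- min(fe, GenomicRanges::end(tk)[j]) -
          max(fs, GenomicRanges::start(tk)[j]) + 1
        if (ov < 1) next
        frac <- ov / (fe - fs + 1)
        if ((mf == 0 && ov >= 1) || (mf > 0 && frac >= mf)) {
          exp_rows <- exp_rows + 1L
          row <- got[got$fragment_id == frs$fragment_id[i] &
                       got$label == tk$name[j], ]
          expect_equal(nrow(row), 1L)
          expect_equal(row$overlap_bp, ov)
        }
      }
    }
    expect_equal(nrow(got), exp_rows)
  }
})

test_that("overlap results do not depend on track interval order", {
  set.seed(102)
  frs <- make_fragments(c(500, 3000), c(700, 3100))
  tk <- track(c(100, 600, 3050), c(550, 800, 3300), c("a", "b", "c"))
  g1 <- overlap_labels(frs, tk)
  g2 <- overlap_labels(frs, tk[c(3, 1, 2)])
  key <- function(d) d[order(d$fragment_id, d$label), c("fragment_id", "label", "overlap_bp")]
  expect_equal(key(g1), key(g2), ignore_attr = TRUE)
})

gene_track <- function() {
  # plus-strand gene on chr1 at [20000, 32000], exons at its start and end;
  # minus-strand gene at [60000, 71000] (TSS at 71000)
  gr <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(
      start = c(20000, 20000, 31500, 60000, 70500, 60000),
      end = c(32000, 20400, 32000, 71000, 71000, 60350)
    ),
    strand = c("+", "+", "+", "-", "-", "-"),
    type = c("gene", "exon", "exon", "gene", "exon", "exon"),
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g2")
  )
  gr
}

test_that("element assignment follows promoter > exon > intron > intergenic", {
  genes <- gene_track()
  frs <- make_fragments(
    c(17000, 25000, 20100, 100000, 31400, 74000, 33500),
    c(17100, 25100, 20200, 100150, 31600, 74100, 33600)
  )
  asg <- assign_element(frs, genes)
  # 3 kb upstream of the plus-strand TSS -> promoter
  expect_equal(asg$element[1], "promoter")
  # inside the gene body, no exon -> intron
  expect_equal(asg$element[2], "intron")
  # inside the first exon (also inside the promoter window) -> promoter wins
  expect_equal(asg$element[3], "promoter")
  # far from everything -> intergenic
  expect_equal(asg$element[4], "intergenic")
  # exon overlap outside any promoter window -> exon
  expect_equal(asg$element[5], "exon")
  # 3 kb upstream of the minus-strand TSS (i.e. higher coordinates) -> promoter
  expect_equal(asg$element[6], "promoter")
  # past the plus-strand gene end, within 5 kb of no TSS -> intergenic
  expect_equal(asg$element[7], "intergenic")
  expect_error(assign_element(frs, {
    g <- gene_track(); GenomicRanges::strand(g) <- "*"; g
  }), "strand")
})

test_that("fragments overlapping an exon and a neighbour's promoter are promoter", {
  genes <- gene_track()
  # second gene whose promoter window covers the first gene's 3' exon
  extra <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(33000, 40000), strand = "+",
    type = "gene", gene_id = "g3"
  )
  frs <- make_fragments(31600, 31700)  # inside g1's 3' exon, 1.4 kb before g3 TSS
  asg <- assign_element(frs, c(genes, extra))
  expect_equal(asg$element, "promoter")
})

test_that("TSS windows are reported as flags", {
  genes <- gene_track()
  frs <- make_fragments(c(20050, 19400, 18990), c(20060, 19450, 19010))
  asg <- assign_element(frs, genes)
  expect_equal(asg$tss_200, c(TRUE, FALSE, FALSE))
  expect_equal(asg$tss_500, c(TRUE, FALSE, FALSE))
  expect_equal(asg$tss_1k, c(TRUE, TRUE, TRUE))
})

repeat_track <- function() {
  gr <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(1000, 5000, 9000, 12000),
                     end = c(1300, 5300, 9350, 12400))
  )
  gr$class <- c("SINE", "Satellite", "LINE", "Simple_repeat")
  gr$family <- c("Alu", "Satellite", "L1", "Simple_repeat")
  gr
}

test_that("repeat classification applies the retroelement union rule", {
  rp <- repeat_track()
  frs <- make_fragments(c(1300, 5100, 9300, 50000),
                        c(1400, 5200, 12050, 50100))
  ra <- classify_repeat(frs, rp)
  # 1-bp Alu overlap -> retroelement
  expect_true(ra$is_retroelement[1])
  expect_equal(ra$repeat_classes[1], "SINE")
  # satellite only -> repeat fragment but not retroelement
  expect_false(ra$is_retroelement[2])
  # LINE + Simple_repeat -> retroelement, both classes recorded
  expect_true(ra$is_retroelement[3])
  expect_equal(ra$repeat_classes[3], "LINE,Simple_repeat")
  expect_equal(ra$repeat_families[3], "LINE/L1,Simple_repeat/Simple_repeat")
  # no overlap
  expect_false(ra$is_retroelement[4])
  expect_equal(ra$repeat_classes[4], "")
})

test_that("unknown repeat classes warn and count as non-retroelement", {
  rp <- repeat_track()
  rp$class[1] <- "Mystery"
  frs <- make_fragments(1300, 1400)
  expect_warning(ra <- classify_repeat(frs, rp), "Mystery")
  expect_false(ra$is_retroelement[1])
})

test_that("class summaries match direct per-class computation", {
  gm <- cbind(nt = c(0.1, 0.5, 0.9, 0.8, 0.2),
              pl = c(0.05, 0.3, 0.7, 0.5, 0.25))
  rownames(gm) <- paste0("f", 1:5)
  memb <- data.frame(fragment_id = c("f1", "f2", "f3", "f4", "f5", "f1"),
                     class = c("A", "A", "A", "B", "B", "B"))
  cs <- class_summary(gm, memb)
  a_nt <- cs[cs$class == "A" & cs$group == "nt", ]
  expect_equal(a_nt$median, 0.5)
  expect_equal(a_nt$n, 3L)
  expect_equal(a_nt$prop_low, 1 / 3)
  expect_equal(a_nt$prop_high, 1 / 3)
  b_pl <- cs[cs$class == "B" & cs$group == "pl", ]
  expect_equal(b_pl$median, median(c(0.5, 0.25, 0.05)))
  expect_equal(unique(cs$median_diff[cs$class == "A"]),
               median(c(0.05, 0.3, 0.7)) - 0.5)
  # random oracle
  set.seed(111)
  gm2 <- cbind(g1 = runif(500), g2 = runif(500))
  rownames(gm2) <- paste0("r", 1:500)
  memb2 <- data.frame(
    fragment_id = rownames(gm2)[sample(500, 800, replace = TRUE)],
    class = sample(c("x", "y", "z"), 800, replace = TRUE)
  )
  memb2 <- unique(memb2)
  cs2 <- class_summary(gm2, memb2)
  for (cl in c("x", "y", "z")) {
    ids <- memb2$fragment_id[memb2$class == cl]
    expect_equal(cs2$median[cs2$class == cl & cs2$group == "g1"],
                 median(gm2[ids, "g1"]))
  }
})

test_that("retention table reports high-methylation retention by class", {
  gm <- cbind(nt = c(0.9, 0.8, 0.95, 0.5, 0.75),
              pl = c(0.85, 0.3, 0.9, 0.9, 1.0))
  rownames(gm) <- paste0("f", 1:5)
  ra <- data.frame(
    fragment_id = rownames(gm),
    repeat_classes = c("SINE", "SINE", "", "SINE", ""),
    repeat_families = c("SINE/Alu", "SINE/Alu", "", "SINE/Alu", ""),
    is_retroelement = c(TRUE, TRUE, FALSE, TRUE, FALSE)
  )
  rt <- retention_table(gm, ra, "nt", "pl")
  # f4 fails the reference filter; f1, f2, f3, f5 selected
  alu <- rt[rt$class == "SINE/Alu", ]
  expect_equal(alu$n_selected, 2L)
  expect_equal(alu$retention_fraction, 0.5)  # f1 retains, f2 does not
  nr <- rt[rt$class == "non_retroelement", ]
  expect_equal(nr$n_selected, 2L)
  expect_equal(nr$retention_fraction, 1.0)
  expect_equal(sum(rt$n_retained[rt$class != "non_retroelement"]) +
                 nr$n_retained, 3L)
  # all test values high -> retention 1 everywhere
  gm_hi <- gm; gm_hi[, "pl"] <- 1.0
  rt_hi <- retention_table(gm_hi, ra, "nt", "pl")
  expect_true(all(rt_hi$retention_fraction == 1))
  # nothing selected -> empty table with a notice
  gm_lo <- gm; gm_lo[, "nt"] <- 0.1
  expect_message(rt_lo <- retention_table(gm_lo, ra, "nt", "pl"),
                 "no fragment")
  expect_equal(nrow(rt_lo), 0L)
  expect_error(retention_table(gm, ra, "nt", "pl", high_ref = 1.5),
               "thresholds")
})
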