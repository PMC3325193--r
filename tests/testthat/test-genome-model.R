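# Genome container, partition accounting, gene orders, rotation symmetry.

test_that("AT content matches a direct letter-count oracle and handles N", {
  g <- annotated_genome("t", "ATAT", is_circular = FALSE)
  expect_equal(at_content(g), 100)
  set.seed(11)
  s <- rand_seq(10000)
  g <- annotated_genome("t", s, is_circular = FALSE)
  cnt <- table(strsplit(s, "")[[1]])
  expect_equal(at_content(g),
               100 * (cnt[["A"]] + cnt[["T"]]) / sum(cnt))
  gn <- annotated_genome("t", paste0(s, strrep("N", 500)), is_circular = FALSE)
  expect_equal(at_content(gn), at_content(g))   # N excluded from denominator
  expect_error(at_content(annotated_genome("t", "NNNN", is_circular = FALSE)),
               "undefined")
})

test_that("a genome that is one intron-less gene is 100% exon", {
  f <- gene_feature("cox1", "protein", "+", list(c(0, 300)))
  g <- annotated_genome("t", rand_seq(300, seed = 1), FALSE, list(f))
  p <- partition(g)
  expect_equal(p$exon_pct, 100)
  expect_equal(p$spacer_pct, 0)
  expect_equal(p$exon_bp + p$intron_bp + p$spacer_bp, p$genome_bp)
})

test_that("partition classifies every position once, with priority rules", {
  set.seed(21)
  r <- generate_genome(small_config(), seed = 21)
  p <- partition(r$genome)
  expect_identical(p$exon_bp + p$intron_bp + p$spacer_bp, p$genome_bp)
  expect_equal(p$gene_pct, p$exon_pct + p$intron_pct)
  expect_equal(p$gene_pct + p$spacer_pct, 100)
  # pseudogene-flagged features count as spacer
  f1 <- gene_feature("nad1", "protein", "+", list(c(0, 120)))
  f2 <- gene_feature("nad2", "protein", "+", list(c(200, 320)),
                     is_pseudo = TRUE)
  g <- annotated_genome("t", rand_seq(500, seed = 3), FALSE, list(f1, f2))
  expect_equal(partition(g)$exon_bp, 120)
  # overlapping exon annotations are counted once, with a warning
  f3 <- gene_feature("nad3", "protein", "-", list(c(60, 180)))
  g2 <- annotated_genome("t", rand_seq(500, seed = 3), FALSE, list(f1, f3))
  expect_warning(p2 <- partition(g2), "counted once")
  expect_equal(p2$exon_bp, 180)
})

test_that("partition, AT content and cyclic gene order are rotation-invariant", {
  r <- generate_genome(small_config(), seed = 5)
  g <- r$genome
  for (off in c(1L, 17L, g$length_bp %/% 2L)) {
    gr <- rotate_genome(g, off)
    expect_equal(at_content(gr), at_content(g))
    p <- partition(g); pr <- partition(gr)
    expect_identical(pr$exon_bp, p$exon_bp)
    expect_identical(pr$intron_bp, p$intron_bp)
    o <- gene_order(g)$tab; or <- gene_order(gr)$tab
    sig <- function(t) paste0(t$strand, t$gene, ".", t$copy)
    a <- sig(o); b <- sig(or)
    i <- which(b == a[1L])[1L]
    b_rot <- b[((seq_along(b) - 1L + i - 1L) %% length(b)) + 1L]
    expect_identical(a, b_rot)
  }
})

test_that("gene order is signed, sorted by leftmost exon start", {
  fs <- list(gene_feature("a", "protein", "+", list(c(10, 50))),
             gene_feature("b", "protein", "-", list(c(100, 140))),
             gene_feature("c", "tRNA", "+", list(c(200, 270))))
  g <- annotated_genome("t", rand_seq(400, seed = 8), TRUE, fs)
  o <- gene_order(g)
  expect_identical(paste0(o$tab$strand, o$tab$gene), c("+a", "-b", "+c"))
  o2 <- gene_order(g, include_trna = FALSE)
  expect_identical(o2$tab$gene, c("a", "b"))
})

test_that("intron nomenclature is host + insertion position + group", {
  it <- intron_record("nad1", 728, "g2", "cis", c(1000, 2500))
  expect_identical(intron_name(it), "nad1i728g2")
})

test_that("spacer intervals complement the functional features", {
  r <- generate_genome(small_config(), seed = 9)
  g <- r$genome
  sp <- spacer_intervals(g)
  total_sp <- sum(vapply(sp, function(iv) iv[2] - iv[1], numeric(1)))
  p <- partition(g)
  expect_identical(as.integer(total_sp), as.integer(p$spacer_bp))
  # no spacer overlaps any functional feature interval
  for (f in g$features) {
    if (f$is_pseudo) next
    for (iv in c(f$exons, lapply(f$introns, `[[`, "interval")))
      for (s in sp)
        expect_equal(iv_overlap_bp_test(iv, s, g$length_bp), 0)
  }
})
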