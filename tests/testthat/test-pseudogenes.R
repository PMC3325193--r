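# Spacer scanning, fragment recovery, origin classification, retroposition
# signatures.

test_that("spacers free of homology give no fragments", {
  cfg <- small_config(
    pseudo = list(n = 0, len_range = c(60, 300),
                  identity_range = c(85, 100), retro_frac = 0.7),
    repeats = list(min_len = 100, lengths = integer(0),
                   orientations = character(0), n_copies = integer(0),
                   intron_origin = logical(0), near_exact_edits = integer(0)))
  r <- generate_genome(cfg, seed = 61)
  fr <- scan_spacers(r$genome)
  expect_identical(nrow(fr), 0L)
})

test_that("planted fragments >=80 bp at >=90% identity are recovered at
           >=95% sensitivity with zero false parents", {
  # repeats without intron origin, so every spacer homology is a fragment
  recovered <- 0L; eligible <- 0L; false_parent <- 0L
  for (seed in c(62, 63)) {
    cfg <- small_config(
      pseudo = list(n = 20, len_range = c(60, 400),
                    identity_range = c(85, 100), retro_frac = 0.7))
    r <- generate_genome(cfg, seed = seed)
    fr <- scan_spacers(r$genome)
    pt <- r$manifest$pseudogene_table
    for (i in seq_len(nrow(pt))) {
      hit <- fr[fr$start < pt$end[i] & fr$end > pt$start[i], , drop = FALSE]
      strong <- pt$length_bp[i] >= 80 && pt$identity_pct[i] >= 90
      if (strong) eligible <- eligible + 1L
      if (nrow(hit)) {
        if (!any(hit$parent == pt$parent[i])) false_parent <- false_parent + 1L
        else if (strong) recovered <- recovered + 1L
      }
    }
  }
  expect_gte(eligible, 10L)
  expect_identical(false_parent, 0L)
  expect_gte(recovered / eligible, 0.95)
})

test_that("fragment flags reproduce the planted retro/unspliced mix and the
           reported total conserves the per-fragment sum", {
  cfg <- small_config(
    pseudo = list(n = 20, len_range = c(80, 300),
                  identity_range = c(92, 100), retro_frac = 0.7))
  r <- generate_genome(cfg, seed = 64)
  fr <- scan_spacers(r$genome)
  pt <- r$manifest$pseudogene_table
  for (i in seq_len(nrow(pt))) {
    hit <- fr[fr$start < pt$end[i] & fr$end > pt$start[i] &
                fr$parent == pt$parent[i], , drop = FALSE]
    expect_identical(nrow(hit), 1L, label = paste("fragment", i))
    expect_identical(retro_signature(hit[1, ]), pt$signature[i],
                     label = paste("signature of fragment", i))
  }
  s <- pseudogene_summary(fr, r$genome$length_bp)
  expect_identical(s$total_bp, sum(fr$length_bp))
  expect_equal(s$fraction_pct, 100 * sum(fr$length_bp) / r$genome$length_bp)
  expect_identical(s$n_fragments, nrow(fr))
  # no reported fragment overlaps a functional feature interval
  for (i in seq_len(nrow(fr))) {
    iv <- c(fr$start[i], fr$end[i])
    for (f in r$genome$features)
      for (ex in c(f$exons, lapply(f$introns, `[[`, "interval")))
        expect_equal(iv_overlap_bp_test(iv, ex, r$genome$length_bp), 0)
  }
})

test_that("retroposition signatures follow from construction", {
  # fragment = 40 bp of exon1 3' + 40 bp of exon2 5' -> retroposed_spliced
  frag1 <- list(contains_intron = FALSE, spans_exon_junction = TRUE)
  expect_identical(retro_signature(frag1), "retroposed_spliced")
  frag2 <- list(contains_intron = TRUE, spans_exon_junction = FALSE)
  expect_identical(retro_signature(frag2), "unspliced_copy")
  frag3 <- list(contains_intron = FALSE, spans_exon_junction = FALSE)
  expect_identical(retro_signature(frag3), "single_exon_uninformative")
})

test_that("origin classification is self at distance 0 for an identical
           fragment and foreign-like for ortholog-derived fragments", {
  set.seed(65)
  self_copy <- rand_seq(600)
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), round(rate * length(ch)))
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  panel <- c(sp1 = mutate(self_copy, 0.25), sp2 = mutate(self_copy, 0.30))
  oc <- classify_origin(substr(self_copy, 100, 400), self_copy, panel)
  expect_identical(oc$call, "self")
  expect_identical(oc$self_distance, 0)
  # fragment derived from an ortholog, further mutated by 10%
  correct <- 0L
  for (trial in 1:10) {
    frag <- mutate(substr(panel[["sp1"]], 50, 450), 0.10)
    oc2 <- classify_origin(frag, self_copy, panel)
    # exhaustive check: the p-distance ordering determines the call
    d_self <- oc2$self_distance
    d_orth <- oc2$best_ortholog_distance
    if (d_orth <= d_self - 0.02) {
      expect_identical(oc2$call, "foreign-like")
      correct <- correct + 1L
    }
  }
  expect_gte(correct, 9L)   # 10% extra divergence still well below ~25%
  # too-short overlap is ambiguous with a reason
  oc3 <- classify_origin(substr(self_copy, 1, 30), self_copy, panel)
  expect_identical(oc3$call, "ambiguous")
  expect_match(oc3$reason, "overlap")
  expect_error(classify_origin("ACGT", self_copy, character(0)), "empty")
})

test_that("queries shorter than min_len are skipped with a warning", {
  f1 <- gene_feature("trnA", "tRNA", "+", list(c(10, 40)))
  f2 <- gene_feature("cob", "protein", "+", list(c(100, 700)))
  g <- annotated_genome("t", rand_seq(2000, seed = 66), TRUE, list(f1, f2))
  expect_warning(fr <- scan_spacers(g, min_len = 50), "skipped")
  expect_identical(nrow(fr), 0L)
})
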