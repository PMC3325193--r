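# Generator contracts: determinism, emptiness, feasibility checks, and
# manifest--genome consistency.

test_that("the same seed reproduces the genome byte-for-byte", {
  r1 <- generate_genome(small_config(), seed = 4)
  r2 <- generate_genome(small_config(), seed = 4)
  expect_identical(r1$genome$sequence, r2$genome$sequence)
  expect_identical(r1$manifest$pseudogene_table, r2$manifest$pseudogene_table)
  expect_identical(r1$manifest$microsat_table, r2$manifest$microsat_table)
  r3 <- generate_genome(small_config(), seed = 5)
  expect_false(identical(r1$genome$sequence, r3$genome$sequence))
})

test_that("a config with nothing planted yields genomes whose scans are empty", {
  cfg <- small_config(
    pseudo = list(n = 0, len_range = c(60, 300),
                  identity_range = c(85, 100), retro_frac = 0.7),
    repeats = list(min_len = 100, lengths = integer(0),
                   orientations = character(0), n_copies = integer(0),
                   intron_origin = logical(0), near_exact_edits = integer(0)),
    microsat = c(di = 0, tri = 0, tetra = 0, penta = 0, hexa = 0),
    duplicate_rrna_cluster = FALSE, n_trna_duplicates = 0)
  r <- generate_genome(cfg, seed = 2)
  expect_identical(nrow(find_microsatellites(r$genome)), 0L)
  expect_length(find_exact_repeats(r$genome, 100), 0L)
  expect_identical(nrow(scan_spacers(r$genome)), 0L)
})

test_that("infeasible configs fail before emission", {
  cfg <- small_config(genome_size = 20000)   # features alone exceed this
  expect_error(generate_genome(cfg, seed = 1), "infeasible")
})

test_that("planted elements are where the manifest says they are", {
  r <- generate_genome(small_config(), seed = 12)
  g <- r$genome; m <- r$manifest
  seqchr <- g$sequence
  # microsatellite runs read back as unit^count
  for (i in seq_len(nrow(m$microsat_table))) {
    row <- m$microsat_table[i, ]
    expect_identical(substr(seqchr, row$start + 1L, row$start + row$len),
                     strrep(row$unit, row$count))
  }
  # exact repeat copies are identical (up to orientation)
  cp <- m$repeat_copies
  for (cl in unique(cp$class)) {
    cc <- cp[cp$class == cl, ]
    edits <- m$repeat_table$edits[m$repeat_table$class == cl]
    if (edits > 0) next
    s1 <- substr(seqchr, cc$start[1] + 1L, cc$end[1])
    for (k in 2:nrow(cc)) {
      sk <- substr(seqchr, cc$start[k] + 1L, cc$end[k])
      if (cc$orientation[k] != cc$orientation[1]) {
        sk <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(sk)))
      }
      expect_identical(sk, s1)
    }
  }
  # pseudogene fragments sit in spacers: no overlap with functional features
  for (i in seq_len(nrow(m$pseudogene_table))) {
    iv <- c(m$pseudogene_table$start[i], m$pseudogene_table$end[i])
    for (f in g$features) {
      for (ex in c(f$exons, lapply(f$introns, `[[`, "interval")))
        expect_equal(iv_overlap_bp_test(iv, ex, g$length_bp), 0)
    }
  }
  # gene features spell out their designed structure: CDS of the editing
  # gene translates to a protein at the planted distance from the reference
  ed <- m$editing_table
  f <- Filter(function(x) x$name == ed$gene, g$features)[[1]]
  cds <- spliced_seq(g, f)
  expect_identical(nchar(cds) %% 3L, 0L)
  expect_identical(nrow(ed$sites), ed$n_c2u + ed$n_u2c)
})

test_that("event application logs what it does and n = 0 is the identity", {
  r <- generate_genome(small_config(), seed = 3)
  o <- gene_order(r$genome)
  same <- apply_events(o, 0)
  expect_identical(same$order$tab, o$tab)
  expect_identical(nrow(same$rearrangement_log), 0L)
  one <- apply_events(o, 1, mix = c(inversion = 1, translocation = 0,
                                    duplication = 0, deletion = 0), seed = 9)
  expect_identical(one$rearrangement_log$type, "inversion")
  # exactly one reversed co-oriented block: the multisets of signed labels
  # differ only by the flipped block
  expect_identical(nrow(one$order$tab), nrow(o$tab))
  est <- rearrangement_distance(o, one$order)
  expect_identical(est$event_count, 1L)
  expect_error(apply_events(gene_order_obj("x", "a", "+"), 1,
                            mix = c(inversion = 0, translocation = 0,
                                    duplication = 0, deletion = 1)),
               "empty")
})

test_that("estimates on k applied inversions never exceed k", {
  # duplicate-free order: with duplicated genes the exemplar reduction is
  # a heuristic and the strict bound does not hold in general
  cfg <- small_config(duplicate_rrna_cluster = FALSE, n_trna_duplicates = 0)
  r <- generate_genome(cfg, seed = 6)
  o <- gene_order(r$genome)
  inv_only <- c(inversion = 1, translocation = 0, duplication = 0,
                deletion = 0)
  hit <- 0L; trials <- 25L
  for (t in seq_len(trials)) {
    k <- sample(1:6, 1)
    ev <- apply_events(o, k, mix = inv_only, seed = 1000 + t)
    est <- rearrangement_distance(o, ev$order)
    expect_lte(est$event_count, k)
    if (est$event_count == k) hit <- hit + 1L
  }
  expect_gt(hit, 0L)   # equality occurs in a sizeable share of trials
  # mixed events: a block translocation is two elementary DCJ operations,
  # so the general bound is 2k
  for (t in 1:10) {
    k <- sample(1:5, 1)
    ev <- apply_events(o, k, seed = 2000 + t)
    expect_lte(rearrangement_distance(o, ev$order)$event_count, 2L * k)
  }
})
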