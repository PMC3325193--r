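# Repeat and microsatellite detection: oracle equivalence, maximality,
# symmetry, near-exact fusion, origin annotation.

plant_in <- function(s, sub, at) {
  paste0(substr(s, 1, at), sub, substr(s, at + nchar(sub) + 1, nchar(s)))
}

test_that("random sequences carry no >=100 bp repeat and no threshold run", {
  set.seed(301)
  s <- rand_seq(5000)
  expect_identical(nrow(find_exact_repeat_pairs(s, 100)), 0L)
})

test_that("a planted 257 bp direct repeat is found at exact coordinates", {
  set.seed(302)
  core <- rand_seq(257)
  s <- rand_seq(4000)
  s <- plant_in(s, core, 500)
  s <- plant_in(s, core, 2600)
  pr <- find_exact_repeat_pairs(s, 100)
  expect_identical(nrow(pr), 1L)
  expect_identical(pr$orientation, "direct")
  # maximal match contains the planted copy; chance flank matches may add
  # a base or two but never more
  expect_lte(pr$a_start, 500); expect_gte(pr$a_end, 500 + 257)
  expect_lt(pr$length, 257 + 10)
  cls <- find_exact_repeats(annotated_genome("t", s, FALSE), 100)
  expect_length(cls, 1L)
  expect_identical(nrow(cls[[1]]$copies), 2L)
})

test_that("engine equals the quadratic all-pairs oracle on seeded sequences", {
  set.seed(303)
  canon <- function(df) {
    df <- df[order(df$orientation, df$a_start, df$b_start, df$length), ,
             drop = FALSE]
    rownames(df) <- NULL
    df
  }
  for (trial in 1:30) {
    n <- sample(300:1500, 1)
    s <- rand_seq(n)
    min_len <- sample(c(40L, 60L, 80L), 1)
    for (p in seq_len(sample(0:3, 1))) {
      core_len <- sample(min_len:(min_len + 150), 1)
      at1 <- sample(0:(n - core_len - 1), 1)
      core <- substr(s, at1 + 1, at1 + core_len)
      if (runif(1) < 0.5)
        core <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(core)))
      at2 <- sample(0:(n - core_len - 1), 1)
      s <- plant_in(s, core, at2)
    }
    got <- find_exact_repeat_pairs(annotated_genome("t", s, FALSE), min_len)
    want <- oracle_repeat_pairs(s, min_len)
    expect_identical(canon(got), canon(want),
                     label = sprintf("trial %d (n=%d, min_len=%d)",
                                     trial, n, min_len))
  }
})

test_that("inverted-repeat detection is reverse-complement symmetric and
           circular detection is rotation-invariant", {
  r <- generate_genome(small_config(), seed = 44)
  g <- r$genome
  tab <- function(cls) {
    t <- repeat_class_table(cls)
    t[order(-t$length_bp), c("length_bp", "n_copies", "orientation")]
  }
  cls <- find_exact_repeats(g, 100)
  grc <- annotated_genome("rc", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g$sequence))), TRUE)
  cls_rc <- find_exact_repeats(grc, 100)
  expect_equal(tab(cls), tab(cls_rc), ignore_attr = TRUE)
  grot <- rotate_genome(g, 12345L)
  cls_rot <- find_exact_repeats(grot, 100)
  expect_equal(tab(cls), tab(cls_rot), ignore_attr = TRUE)
})

test_that("exact copies stay exact and a RepH-like pair is fused with its
           edit count", {
  r <- generate_genome(small_config(), seed = 45)
  g <- r$genome
  cls <- find_exact_repeats(g, 100)
  ext <- extend_near_exact(cls, g)
  expect_true(all(vapply(ext, function(cl) cl$edits_between_copies, integer(1))
                  == 0L))
  # construct two long copies differing by one indel and one substitution
  set.seed(46)
  core <- rand_seq(2000)
  copy2 <- core
  substr(copy2, 700, 700) <- if (substr(copy2, 700, 700) == "A") "C" else "A"
  copy2 <- paste0(substr(copy2, 1, 1400), substr(copy2, 1402, 2000)) # 1bp del
  s <- rand_seq(9000)
  s <- plant_in(s, core, 1000)
  s <- plant_in(s, copy2, 5000)
  gg <- annotated_genome("t", s, FALSE)
  cls2 <- find_exact_repeats(gg, 100)
  expect_gte(length(cls2), 2L)              # edit-split exact cores
  fused <- extend_near_exact(cls2, gg)
  expect_identical(length(fused), 1L)
  expect_identical(fused[[1]]$edits_between_copies, 2L)
  expect_gte(fused[[1]]$length_bp, 1990L)
})

test_that("microsatellite scanner matches its definition and the
           sliding-window oracle", {
  ms <- find_microsatellites("GGACACACACACACTT")
  expect_identical(nrow(ms), 1L)
  expect_identical(ms$unit_size, 2L)
  expect_identical(ms$count, 6L)
  expect_identical(ms$canonical_unit, "AC")
  # below threshold: di x5 is not reported
  expect_identical(nrow(find_microsatellites("GGACACACACACTT")), 0L)
  # maximality: reported run cannot be extended either side
  set.seed(310)
  for (trial in 1:20) {
    s <- rand_seq(800)
    unit <- c("AC", "AAT", "ACGT", "AATC")[sample(4, 1)]
    cnt <- if (nchar(unit) == 2) sample(6:9, 1) else sample(4:7, 1)
    s <- plant_in(s, strrep(unit, cnt), 300)
    got <- find_microsatellites(s)
    want <- oracle_msats(s)
    expect_identical(got[, c("start", "len", "unit_size", "count")],
                     want[order(want$start), , drop = FALSE],
                     label = paste("trial", trial))
  }
})

test_that("compound and self-periodic units are reported at the shortest
           unit and homopolymers are not microsatellites", {
  expect_identical(nrow(find_microsatellites(
    paste0("GG", strrep("A", 30), "TT"))), 0L)
  ms <- find_microsatellites(paste0("GT", strrep("AC", 12), "TT"))
  expect_identical(ms$unit_size, 2L)         # not reported again as ACAC
  expect_identical(nrow(ms), 1L)
})

test_that("origin annotation names the intron a repeat was carved from", {
  cfg <- small_config(
    repeats = list(min_len = 100, lengths = c(150, 400),
                   orientations = c("direct", "inverted"),
                   n_copies = c(2L, 2L), intron_origin = c(FALSE, TRUE),
                   near_exact_edits = c(0L, 0L)))
  r <- generate_genome(cfg, seed = 47)
  g <- r$genome
  cls <- find_exact_repeats(g, 100)
  cls <- lapply(cls, annotate_origin, genome = g)
  tab <- repeat_class_table(cls)
  want_origin <- r$manifest$repeat_table$origin[
    r$manifest$repeat_table$class == "plantB"]
  expect_true(want_origin %in% tab$origin)
  # the fresh-sequence class with both copies in spacers has no origin
  plain <- tab[tab$length_bp < 200 & tab$length_bp >= 150, ]
  expect_true(all(plain$origin == "-"))
})
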