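# Codon reconstitution and comparative editing prediction.

codons <- function(...) paste(c(...), collapse = "")

test_that("a clean ATG...TAA CDS needs no reconstitution", {
  cds <- codons("ATG", "GCT", "CAT", "TGG", "TAA")
  expect_identical(nrow(reconstitute(cds, "cox2")), 0L)
})

test_that("constructed ACG | internal TAA | CAA-end CDS yields exactly the
           three event kinds, matching a rule-enumeration oracle", {
  pad <- replicate(10, sample(setdiff(names(Biostrings::GENETIC_CODE),
                                      c("TAA", "TAG", "TGA")), 1))
  cds <- codons("ACG", pad[1:5], "TAA", pad[6:10], "CAA")
  ev <- reconstitute(cds, "nad5")
  expect_setequal(ev$kind, c("start_created", "internal_stop_removed",
                             "stop_created"))
  expect_identical(nrow(ev), 3L)
  expect_identical(ev$direction[ev$kind == "start_created"], "C>U")
  expect_identical(ev$direction[ev$kind == "internal_stop_removed"], "U>C")
  expect_identical(ev$direction[ev$kind == "stop_created"], "C>U")
  # independent oracle: enumerate codons and apply the three rules directly
  set.seed(51)
  for (trial in 1:20) {
    n <- sample(5:30, 1)
    cs <- sample(names(Biostrings::GENETIC_CODE), n, replace = TRUE)
    cs[1] <- sample(c("ATG", "ACG", "GTG", "CTG"), 1)
    cds <- paste(cs, collapse = "")
    want <- sum(cs[1] == "ACG",
                cs[2:(n - 1)] %in% c("TAA", "TAG"),
                cs[n] %in% c("CAA", "CGA"))
    got <- suppressWarnings(reconstitute(cds, "x"))
    expect_identical(nrow(got), as.integer(want), label = paste("trial", trial))
  }
})

test_that("internal TGA is flagged unresolvable, GTG start is tolerated
           only for listed genes", {
  cds <- codons("ATG", "GCT", "TGA", "CAT", "TAA")
  expect_warning(ev <- reconstitute(cds, "nad3"), "TGA")
  expect_identical(nrow(ev), 0L)
  gtg <- codons("GTG", "GCT", "CAT", "TAA")
  expect_silent(reconstitute(gtg, "rpl16"))
  expect_warning(reconstitute(gtg, "nad3"), "unusual")
})

test_that("CCA aligned to Leu needs one C-to-U edit", {
  # CCA (Pro) -> CTA (Leu) by a single C>U at codon position 2
  cds <- codons("ATG", "CCA", "TAA")
  p <- predict_edits(cds, "ML", gene = "t")
  expect_identical(p$c_to_u, 1L)
  expect_identical(p$u_to_c, 0L)
  expect_identical(p$total, 1L)
})

test_that("the identity reference predicts zero edits for any valid CDS", {
  set.seed(52)
  for (trial in 1:10) {
    n <- sample(20:120, 1)
    cds <- paste0("ATG", paste(sample(
      setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA")),
      n, replace = TRUE), collapse = ""), "TAA")
    ref <- sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAString(cds))))
    p <- predict_edits(cds, ref)
    expect_identical(c(p$c_to_u, p$u_to_c), c(0L, 0L))
  }
})

test_that("planted 12 C>U and 5 U>C edits are recovered exactly", {
  r <- generate_genome(small_config(), seed = 53)
  ed <- r$manifest$editing_table
  f <- Filter(function(x) x$name == ed$gene, r$genome$features)[[1]]
  p <- predict_edits(spliced_seq(r$genome, f), ed$ref_protein,
                     gene = ed$gene, reference_name = "truth")
  expect_identical(p$c_to_u, ed$n_c2u)
  expect_identical(p$u_to_c, ed$n_u2c)
  expect_identical(p$total, ed$n_c2u + ed$n_u2c)
})

test_that("per-codon minimal-edit search matches the exhaustive oracle", {
  set.seed(54)
  all_codons <- names(Biostrings::GENETIC_CODE)
  aas <- unique(unname(Biostrings::GENETIC_CODE))
  for (trial in 1:200) {
    cod <- sample(all_codons, 1)
    aa <- sample(setdiff(aas, "*"), 1)
    got <- chondromics:::min_cu_edits(cod, aa)
    want <- oracle_codon_edits(cod, aa)
    expect_identical(got, want, label = paste(cod, "->", aa))
  }
})

test_that("aggregation sums per reference and is permutation-invariant", {
  expect_identical(nrow(aggregate_edits(list())), 0L)
  set.seed(55)
  df <- data.frame(
    gene = paste0("g", 1:40),
    reference_name = sample(c("M", "I", "S"), 40, replace = TRUE),
    c_to_u = sample(0:25, 40, replace = TRUE),
    u_to_c = sample(0:25, 40, replace = TRUE))
  agg <- aggregate_edits(df)
  for (r in agg$reference_name) {
    expect_identical(agg$c_to_u[agg$reference_name == r],
                     sum(df$c_to_u[df$reference_name == r]))
    expect_identical(agg$total[agg$reference_name == r],
                     sum(df$c_to_u[df$reference_name == r]) +
                       sum(df$u_to_c[df$reference_name == r]))
  }
  perm <- df[sample(nrow(df)), ]
  agg2 <- aggregate_edits(perm)
  expect_equal(agg[order(agg$reference_name), ],
               agg2[order(agg2$reference_name), ], ignore_attr = TRUE)
})
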