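# GenBank flat-file I/O: fixture round-trips, strandedness, wrap-around
# locations, pseudo flags, malformed input.

two_gene_genome <- function() {
  it <- intron_record("nad5", 90, "g2", "cis", c(140, 400))
  fs <- list(
    gene_feature("nad5", "protein", "+", list(c(50, 140), c(400, 520)),
                 introns = list(it)),
    gene_feature("trnYgua", "tRNA", "-", list(c(700, 775))),
    gene_feature("ccmFC", "protein", "+", list(c(800, 950)),
                 is_pseudo = TRUE))
  annotated_genome("fixture1", rand_seq(1200, seed = 42), TRUE, fs)
}

test_that("a two-gene fixture round-trips with exact coordinates", {
  g <- two_gene_genome()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$length_bp, g$length_bp)
  expect_true(g2$is_circular)
  expect_identical(length(g2$features), length(g$features))
  byname <- function(gg, n) Filter(function(f) f$name == n, gg$features)[[1]]
  for (nm in c("nad5", "trnYgua", "ccmFC")) {
    a <- byname(g, nm); b <- byname(g2, nm)
    expect_identical(b$strand, a$strand)
    expect_identical(b$category, a$category)
    expect_identical(b$is_pseudo, a$is_pseudo)
    expect_equal(b$exons, a$exons)
  }
  b <- byname(g2, "nad5")
  expect_length(b$introns, 1L)
  expect_identical(intron_name(b$introns[[1]]), "nad5i90g2")
  expect_equal(b$introns[[1]]$interval, c(140, 400))
})

test_that("generator-emitted GenBank reproduces the truth manifest", {
  r <- generate_genome(small_config(), seed = 33)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(r$genome, path)
  g2 <- read_genbank(path)
  expect_identical(g2$sequence, r$genome$sequence)
  key <- function(g) {
    rows <- lapply(g$features, function(f) {
      paste(f$name, f$category, f$strand, f$copy_index,
            paste(vapply(f$exons, paste, character(1), collapse = "-"),
                  collapse = ";"),
            paste(vapply(f$introns, intron_name, character(1)),
                  collapse = ";"))
    })
    sort(unlist(rows))
  }
  expect_identical(key(g2), key(r$genome))
})

test_that("minus-strand and origin-wrapping locations are handled", {
  fs <- list(
    gene_feature("atp9", "protein", "-", list(c(900, 1040), c(700, 820)),
                 introns = list(intron_record("atp9", 140, "g2", "cis",
                                              c(820, 900)))),
    # feature spanning the origin of the circle
    gene_feature("rrn5", "rRNA", "+", list(c(1150, 1310))))
  g <- annotated_genome("wrap", rand_seq(1200, seed = 77), TRUE, fs)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  txt <- readLines(path)
  expect_true(any(grepl("join\\(1151\\.\\.1200,1\\.\\.110\\)", txt)))
  g2 <- read_genbank(path)
  f <- Filter(function(x) x$name == "rrn5", g2$features)[[1]]
  expect_equal(f$exons[[1]], c(1150, 1310))    # folded back into one wrap
  fm <- Filter(function(x) x$name == "atp9", g2$features)[[1]]
  expect_identical(fm$strand, "-")
  expect_equal(fm$exons, list(c(900, 1040), c(700, 820)))  # transcription order
})

test_that("linear records are accepted and malformed ones are named", {
  f <- gene_feature("cob", "protein", "+", list(c(10, 100)))
  g <- annotated_genome("lin", rand_seq(200, seed = 5), FALSE, list(f))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_false(g2$is_circular)
  bad <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       x 10 bp DNA linear",
               "FEATURES             Location/Qualifiers",
               "     CDS             banana..7",
               '                     /gene="z"',
               "ORIGIN", "        1 acgtacgtac", "//"), bad)
  expect_error(read_genbank(bad), "CDS")
  nofeat <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       y 10 bp DNA linear", "ORIGIN",
               "        1 acgtacgtac", "//"), nofeat)
  expect_silent(gy <- read_genbank(nofeat))
  expect_identical(gy$length_bp, 10L)
})

test_that("GFF3 + FASTA round-trips non-wrapping annotations", {
  g <- two_gene_genome()
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_gff3(g, gff)
  write_fasta(g, fa)
  g2 <- read_gff3_genome(gff, fa)
  expect_identical(g2$sequence, g$sequence)
  byname <- function(gg, n) Filter(function(f) f$name == n, gg$features)[[1]]
  for (nm in c("nad5", "trnYgua", "ccmFC")) {
    a <- byname(g, nm); b <- byname(g2, nm)
    expect_identical(b$strand, a$strand)
    expect_identical(b$is_pseudo, a$is_pseudo)
    expect_equal(b$exons, a$exons)
  }
  expect_identical(intron_name(byname(g2, "nad5")$introns[[1]]), "nad5i90g2")
})

test_that("FASTA writer/reader round-trips the sequence", {
  g <- two_gene_genome()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g, path)
  g2 <- read_fasta_genome(path)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$identifier, g$identifier)
})
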