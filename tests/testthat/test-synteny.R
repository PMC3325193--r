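# Gene-order comparison: adjacencies, conserved clusters, rearrangement
# distance with its BFS oracle over elementary DCJ operations.

test_that("identical circular orders share all n adjacencies", {
  a <- parse_gene_order("A", "+g1 +g2 -g3 +g4 +g5")
  b <- parse_gene_order("B", "+g1 +g2 -g3 +g4 +g5")
  adj <- shared_adjacencies(a, b)
  expect_identical(nrow(adj), 5L)
  expect_true(all(adj$status == "conserved"))
})

test_that("a flipped block shows up as reversed adjacency", {
  a <- parse_gene_order("A", "+a +b +c +d")
  b <- parse_gene_order("B", "+a +b -c -d")
  adj <- shared_adjacencies(a, b)
  key <- function(g1, g2) adj$status[adj$gene1 == g1 & adj$gene2 == g2]
  expect_identical(key("a", "b"), "conserved")
  expect_identical(key("c", "d"), "reversed")
  expect_error(shared_adjacencies(parse_gene_order("A", "+x +y"),
                                  parse_gene_order("B", "+p +q")),
               "shared")
})

test_that("adjacency sets after known inversions match prediction", {
  a <- parse_gene_order("A", paste0("+g", 1:12, collapse = " "))
  ev <- apply_events(a, 3, mix = c(inversion = 1, translocation = 0,
                                   duplication = 0, deletion = 0), seed = 71)
  adj <- shared_adjacencies(a, ev$order)
  # every adjacency not cut by one of the <= 6 breakpoints is conserved
  expect_gte(sum(adj$status == "conserved"), 12L - 6L)
})

test_that("all orders identical -> one cluster covering the genome;
           a planted block survives scrambling", {
  ords <- lapply(c("A", "B", "C"), function(id)
    parse_gene_order(id, "+g1 +g2 -g3 +g4 +g5 -g6"))
  cl <- conserved_clusters(ords)
  expect_identical(length(cl), 1L)
  expect_identical(length(cl[[1]]$member_genes), 6L)

  # ten-gene block kept intact in four otherwise scrambled genomes
  block <- paste0("+b", 1:10)
  others <- paste0("+o", 1:15)
  set.seed(72)
  mk <- function(id) {
    rest <- sample(others)
    sgn <- sample(c("+", "-"), 15, replace = TRUE)
    rest <- paste0(sgn, substring(rest, 2))
    at <- sample(0:15, 1)
    parse_gene_order(id, paste(c(rest[seq_len(at)], block,
                                 rest[-seq_len(at)][seq_len(15 - at)]),
                               collapse = " "))
  }
  ords2 <- lapply(c("A", "B", "C", "D"), mk)
  cl2 <- conserved_clusters(ords2, min_genomes = 4)
  hit <- Filter(function(c_) all(block %in% c_$member_genes) ||
                  all(paste0("-", substring(rev(block), 2)) %in%
                        c_$member_genes), cl2)
  expect_gte(length(hit), 1L)
  expect_lte(length(hit[[1]]$member_genes), 12L)
})

test_that("plain order files round-trip, numbering duplicate labels", {
  o <- gene_order_obj("x", c("nad5", "cob", "nad5", "atp9"),
                      c("+", "-", "+", "+"), c(1L, 1L, 2L, 1L))
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_order(o, path)
  o2 <- read_gene_order(path, "x")
  expect_identical(o2$tab, o$tab)
})

test_that("distance axioms hold: d(A,A) = 0, symmetry, single inversion = 1", {
  a <- parse_gene_order("A", "+a +b +c +d +e")
  expect_identical(rearrangement_distance(a, a)$event_count, 0L)
  b <- parse_gene_order("B", "+a -c -b +d +e")
  expect_identical(rearrangement_distance(a, b)$event_count, 1L)
  expect_identical(rearrangement_distance(b, a)$event_count, 1L)
  # circular symmetry: rotation and whole-order reflection cost nothing
  rot <- parse_gene_order("C", "+c +d +e +a +b")
  expect_identical(rearrangement_distance(a, rot)$event_count, 0L)
  refl <- parse_gene_order("D", "-e -d -c -b -a")
  expect_identical(rearrangement_distance(a, refl)$event_count, 0L)
})

test_that("private genes and copy-number differences are charged as
           indel/duplication events", {
  a <- parse_gene_order("A", "+a +b +c +d +e")
  b <- parse_gene_order("B", "+a +b +c")
  est <- rearrangement_distance(a, b)
  expect_identical(unname(est$breakdown["deletion"]), 1L)  # one private run
  d <- gene_order_obj("D", c("a", "b", "c", "a"), c("+", "+", "+", "+"),
                      c(1L, 1L, 1L, 2L))
  est2 <- rearrangement_distance(b, d)
  expect_identical(unname(est2$breakdown["duplication"]), 1L)
  expect_error(rearrangement_distance(parse_gene_order("X", "+u +v"),
                                      parse_gene_order("Y", "+w +z")),
               "disjoint")
})

test_that("the estimate equals BFS over elementary DCJ operations on all
           signed circular orders of up to 5 genes", {
  for (n in 3:5) {
    genes <- paste0("g", seq_len(n))
    id_order <- gene_order_obj("ID", genes, rep("+", n))
    dist_env <- bfs_dcj_all(order_matching(paste0("+", genes)))
    perms <- combinat_perms(genes[-1L])
    checked <- 0L
    for (p in perms) {
      ordered <- c(genes[1L], p)
      for (smask in 0:(2^n - 1L)) {
        sgn <- ifelse(bitwAnd(smask, 2^(seq_len(n) - 1L)) > 0, "-", "+")
        o <- gene_order_obj("B", ordered, sgn)
        want <- dist_env[[canon_state(order_matching(
          paste0(sgn, ordered)))]]
        got <- rearrangement_distance(id_order, o)$event_count
        expect_identical(got, want,
                         label = paste(paste0(sgn, ordered), collapse = " "))
        checked <- checked + 1L
      }
    }
    expect_identical(checked, as.integer(factorial(n - 1) * 2^n))
  }
})
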