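# Independent oracles used across the suite.  Each one is a deliberately
# naive implementation (quadratic scans, exhaustive enumeration, BFS) kept
# free of any code shared with the package's own engines.

## quadratic all-pairs maximal repeat oracle (linear sequences) --------------

oracle_repeat_pairs <- function(s, min_len) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  rc <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))), "")[[1]]
  out <- list()
  add <- function(a0, b0, len, orient) {
    ivA <- c(a0, a0 + len); ivB <- c(b0, b0 + len)
    if (ivB[1L] < ivA[1L]) { tmp <- ivA; ivA <- ivB; ivB <- tmp }
    if (identical(ivA, ivB)) return()
    if (ivA[2L] > ivB[1L]) return()            # overlapping/tandem
    out[[length(out) + 1L]] <<- data.frame(
      a_start = ivA[1L], a_end = ivA[2L], b_start = ivB[1L], b_end = ivB[2L],
      length = len, orientation = orient, stringsAsFactors = FALSE)
  }
  runs_on <- function(x, y) {
    m <- x == y
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], r$lengths[r$values])
  }
  for (d in seq_len(n - 1L)) {                  # direct, diagonal offset d
    ru <- runs_on(chars[seq_len(n - d)], chars[seq_len(n - d) + d])
    if (nrow(ru)) for (k in seq_len(nrow(ru)))
      if (ru[k, 2L] >= min_len)
        add(ru[k, 1L] - 1L, ru[k, 1L] - 1L + d, ru[k, 2L], "direct")
  }
  for (d in -(n - 1L):(n - 1L)) {               # inverted: s[i] vs rc[i-d]
    i1 <- max(1L, 1L + d); i2 <- min(n, n + d)
    if (i2 - i1 + 1L < min_len) next
    idx <- i1:i2
    ru <- runs_on(chars[idx], rc[idx - d])
    if (nrow(ru)) for (k in seq_len(nrow(ru))) {
      if (ru[k, 2L] < min_len) next
      i0 <- idx[ru[k, 1L]] - 1L                 # 0-based start in s
      j0 <- i0 - d                              # 0-based start in rc
      len <- ru[k, 2L]
      add(i0, n - j0 - len, len, "inverted")
    }
  }
  if (!length(out))
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      length = integer(0), orientation = character(0)))
  res <- unique(do.call(rbind, out))
  res[order(res$orientation, res$a_start, res$b_start), , drop = FALSE]
}

## sliding-window microsatellite oracle --------------------------------------

oracle_msats <- function(s, thresholds = c(`2` = 6L, `3` = 4L, `4` = 4L,
                                           `5` = 4L, `6` = 4L)) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  hits <- list()
  for (u in 2:6) {
    thr <- thresholds[[as.character(u)]]
    i <- 1L
    while (i + u * thr - 1L <= n) {
      # extend a candidate run starting at i
      len <- u
      while (i + len <= n && chars[i + len] == chars[i + len - u]) len <- len + 1L
      if (len %/% u >= thr) {
        unit <- paste(chars[i:(i + u - 1L)], collapse = "")
        primitive <- TRUE
        for (dd in seq_len(u - 1L))
          if (u %% dd == 0L &&
              unit == strrep(substr(unit, 1L, dd), u / dd)) primitive <- FALSE
        left_ext <- i > 1L && chars[i - 1L] == chars[i - 1L + u]
        if (primitive && !left_ext)
          hits[[length(hits) + 1L]] <- data.frame(
            start = i - 1L, len = len, unit_size = u, count = len %/% u,
            stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), len = integer(0),
                      unit_size = integer(0), count = integer(0)))
  unique(do.call(rbind, hits))
}

## exhaustive minimal C<->U codon-repair oracle -------------------------------

oracle_codon_edits <- function(codon, target_aa) {
  code <- Biostrings::GENETIC_CODE
  bases <- strsplit(codon, "")[[1]]
  results <- list()
  for (b1 in if (bases[1] %in% c("C", "T")) c(FALSE, TRUE) else FALSE)
    for (b2 in if (bases[2] %in% c("C", "T")) c(FALSE, TRUE) else FALSE)
      for (b3 in if (bases[3] %in% c("C", "T")) c(FALSE, TRUE) else FALSE) {
        nb <- bases
        fl <- c(b1, b2, b3)
        for (p in which(fl)) nb[p] <- if (nb[p] == "C") "T" else "C"
        if (identical(unname(code[paste(nb, collapse = "")]), target_aa)) {
          c2u <- sum(bases[fl] == "C"); u2c <- sum(bases[fl] == "T")
          results[[length(results) + 1L]] <- c(c2u, u2c)
        }
      }
  if (!length(results)) return(NULL)
  ns <- vapply(results, sum, numeric(1))
  cand <- results[ns == min(ns)]
  c2us <- vapply(cand, `[`, numeric(1), 1L)
  cand[[which.max(c2us)]]
}

## BFS over elementary DCJ operations on adjacency-set states -----------------

order_matching <- function(signed) {
  # signed: character vector like c("+a","-b"); returns canonical adjacency
  # strings of the circular chromosome
  gene <- sub("^[+-]", "", signed)
  sgn <- substr(signed, 1, 1)
  n <- length(signed)
  left <- ifelse(sgn == "+", paste0(gene, ".t"), paste0(gene, ".h"))
  right <- ifelse(sgn == "+", paste0(gene, ".h"), paste0(gene, ".t"))
  nxt <- c(2:n, 1L)
  vapply(seq_len(n), function(i)
    paste(sort(c(right[i], left[nxt[i]])), collapse = "|"), character(1))
}

canon_state <- function(adjs) paste(sort(adjs), collapse = ";")

dcj_neighbors <- function(adjs) {
  n <- length(adjs)
  ends <- strsplit(adjs, "|", fixed = TRUE)
  out <- character(0)
  if (n < 2L) return(out)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    p <- ends[[i]][1L]; q <- ends[[i]][2L]
    r <- ends[[j]][1L]; s <- ends[[j]][2L]
    rest <- adjs[-c(i, j)]
    n1 <- c(rest, paste(sort(c(p, r)), collapse = "|"),
            paste(sort(c(q, s)), collapse = "|"))
    n2 <- c(rest, paste(sort(c(p, s)), collapse = "|"),
            paste(sort(c(q, r)), collapse = "|"))
    out <- c(out, canon_state(n1), canon_state(n2))
  }
  unique(out)
}

# distances from `start_adjs` to every reachable adjacency-set state
bfs_dcj_all <- function(start_adjs) {
  dist <- new.env(hash = TRUE)
  s0 <- canon_state(start_adjs)
  assign(s0, 0L, envir = dist)
  frontier <- list(start_adjs)
  d <- 0L
  while (length(frontier)) {
    nxt <- list()
    d <- d + 1L
    for (st in frontier) {
      for (nb in dcj_neighbors(st)) {
        if (is.null(dist[[nb]])) {
          assign(nb, d, envir = dist)
          nxt[[length(nxt) + 1L]] <- strsplit(nb, ";", fixed = TRUE)[[1]]
        }
      }
    }
    frontier <- nxt
  }
  dist
}

## misc ----------------------------------------------------------------------

# all permutations of a character vector (tiny n only)
combinat_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in combinat_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

# plain circular-interval overlap, independent of the package's helpers
iv_overlap_bp_test <- function(a, b, L) {
  unwrap <- function(iv) {
    if (iv[2] <= L) list(iv) else list(c(iv[1], L), c(0, iv[2] - L))
  }
  tot <- 0
  for (x in unwrap(a)) for (y in unwrap(b))
    tot <- tot + max(0, min(x[2], y[2]) - max(x[1], y[1]))
  tot
}

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small, fast generator settings used throughout the suite
small_config <- function(...) {
  defaults <- list(
    genome_size = 45000, n_protein = 8, n_rrna = 3, n_trna = 4,
    intron_total = 6, n_trna_duplicates = 1,
    pseudo = list(n = 10, len_range = c(60, 300),
                  identity_range = c(85, 100), retro_frac = 0.7),
    repeats = list(min_len = 100, lengths = c(150, 257),
                   orientations = c("inverted", "direct"),
                   n_copies = c(2L, 2L), intron_origin = c(FALSE, FALSE),
                   near_exact_edits = c(0L, 0L)),
    microsat = c(di = 2, tri = 3, tetra = 1, penta = 0, hexa = 0),
    editing = list(n_c2u = 12, n_u2c = 5),
    reconstitution = list(start_acg = 2, stop_removed = 1, stop_created = 2))
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}
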