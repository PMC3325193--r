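# Maximal direct/inverted repeat detection, near-exact extension and fusion,
# microsatellite scanning, and repeat origin annotation.
#
# The exact engine is seed-and-extend: identical k-mers (k <= 32) anchor
# candidate pairs, which are extended to maximal exact matches with modular
# (circular) coordinate arithmetic.  Any maximal repeat >= min_len contains
# an exact k-mer, so the engine is complete; the quadratic all-pairs oracle
# in the test suite checks exactly that.

MSAT_THRESHOLDS <- c(`2` = 6L, `3` = 4L, `4` = 4L, `5` = 4L, `6` = 4L)

## microsatellites -----------------------------------------------------------

#' @keywords internal
msat_scan_linear <- function(s, thresholds = MSAT_THRESHOLDS) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  out <- list()
  for (u in 2:6) {
    thr <- thresholds[[as.character(u)]]
    if (n < u * thr) next
    m <- chars[seq_len(n - u)] == chars[seq_len(n - u) + u]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & (r$lengths + u) >= u * thr)
    for (h in hit) {
      i <- starts[h]                     # 1-based in m
      t_len <- r$lengths[h] + u          # maximal period-u run length
      unit <- paste(chars[i:(i + u - 1L)], collapse = "")
      if (is_self_periodic(unit)) next   # reported at the shorter unit
      cnt <- t_len %/% u
      if (cnt < thr) next
      out[[length(out) + 1L]] <- data.frame(
        start = i - 1L, len = t_len, unit_size = u, unit = unit,
        canonical_unit = canonical_rotation(unit), count = cnt,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), len = integer(0),
                      unit_size = integer(0), unit = character(0),
                      canonical_unit = character(0), count = integer(0)))
  do.call(rbind, out)
}

#' Find perfect microsatellite runs
#'
#' Maximal mismatch-free tandem runs of a 2--6 bp unit, accepting
#' di-nucleotide repeats of six or more units and tri- through
#' hexa-nucleotide repeats of four or more.  Runs whose unit is a power of
#' a shorter unit are reported at the shortest unit; homopolymer runs are
#' not reported.  On circular genomes runs may span the origin.
#'
#' @param genome an [annotated_genome()] (or a plain DNA string).
#' @param thresholds named integer vector of minimal unit counts, names
#'   `"2"` to `"6"`.
#' @return data.frame with columns `start` (0-based), `len`, `unit_size`,
#'   `unit` (as found), `canonical_unit` (lexicographically minimal
#'   rotation), `count` (complete units in the run).
#' @export
find_microsatellites <- function(genome, thresholds = MSAT_THRESHOLDS) {
  if (is.character(genome))
    genome <- annotated_genome("seq", genome, is_circular = FALSE)
  s <- genome$sequence
  L <- genome$length_bp
  if (!genome$is_circular) return(msat_scan_linear(s, thresholds))
  runs <- msat_scan_linear(paste0(s, s), thresholds)
  runs <- runs[runs$start < L, , drop = FALSE]
  runs$len <- pmin(runs$len, L)
  if (nrow(runs) > 1L) {
    # drop runs circularly contained in another run
    keep <- rep(TRUE, nrow(runs))
    for (i in seq_len(nrow(runs))) for (j in seq_len(nrow(runs))) {
      if (i == j || !keep[i]) next
      di <- (runs$start[i] - runs$start[j]) %% L
      if (di + runs$len[i] <= runs$len[j] &&
          (runs$len[i] < runs$len[j] || i > j))
        keep[i] <- FALSE
    }
    runs <- runs[keep, , drop = FALSE]
  }
  rownames(runs) <- NULL
  runs
}

## exact repeats -------------------------------------------------------------

#' Maximal exact repeated pairs on a genome
#'
#' Low-level engine behind [find_exact_repeats()]: every maximal exact
#' match of length >= `min_len`, forward--forward (`direct`) and
#' forward--reverse-complement (`inverted`).  Self-overlapping (tandem)
#' hits are excluded.
#'
#' @param genome an [annotated_genome()] or DNA string.
#' @param min_len minimal repeat length in bp.
#' @return data.frame with 0-based half-open copy intervals `a_start`,
#'   `a_end`, `b_start`, `b_end`, `length` and `orientation`.
#' @export
find_exact_repeat_pairs <- function(genome, min_len = 100L) {
  if (is.character(genome))
    genome <- annotated_genome("seq", genome, is_circular = FALSE)
  s <- genome$sequence
  L <- genome$length_bp
  circ <- genome$is_circular
  k <- as.integer(min(min_len, 32L))
  chars <- strsplit(s, "")[[1]]
  rc <- revcomp(s)
  rchars <- strsplit(rc, "")[[1]]

  kmers_of <- function(str, n) {
    text <- if (circ) paste0(str, substr(str, 1L, k - 1L)) else str
    npos <- if (circ) n else n - k + 1L
    if (npos < 1L) return(data.table::data.table(kmer = character(0),
                                                 pos = integer(0)))
    data.table::data.table(kmer = substring(text, seq_len(npos),
                                            seq_len(npos) + k - 1L),
                           pos = seq_len(npos) - 1L)
  }
  at <- function(v, i) v[(i %% L) + 1L]   # 0-based circular accessor
  at_lin <- function(v, i) if (i < 0L || i >= L) NA_character_ else v[i + 1L]
  get1 <- if (circ) at else at_lin

  extend <- function(i, j, other) {
    # maximal exact match seeded at (i, j): s[i..] vs other[j..], both 0-based
    l <- 0L
    while (l < L) {
      ci <- get1(chars, i - l - 1L); cj <- get1(other, j - l - 1L)
      if (is.na(ci) || is.na(cj) || ci != cj) break
      l <- l + 1L
    }
    r <- k
    while (l + r < L) {
      ci <- get1(chars, i + r); cj <- get1(other, j + r)
      if (is.na(ci) || is.na(cj) || ci != cj) break
      r <- r + 1L
    }
    c(i - l, j - l, l + r)               # starts and total length
  }

  collect <- function(pairs_dt, other, inverted) {
    if (!nrow(pairs_dt)) return(NULL)
    seen <- new.env(hash = TRUE)
    rows <- list()
    for (row in seq_len(nrow(pairs_dt))) {
      i <- pairs_dt$i[row]; j <- pairs_dt$j[row]
      m <- extend(i, j, other)
      len <- m[3L]
      if (len < min_len || len > L) next
      a <- m[1L] %% L
      bo <- m[2L]                        # start in `other` coordinates
      if (!circ) { a <- m[1L]; }
      if (!inverted) {
        b <- if (circ) bo %% L else bo
        ivA <- c(a, a + len); ivB <- c(b, b + len)
      } else {
        # other = reverse complement; map back to genome coordinates
        b <- if (circ) (L - bo - len) %% L else L - bo - len
        ivA <- c(a, a + len); ivB <- c(b, b + len)
      }
      # canonical ordering of the two copies
      if (ivB[1L] < ivA[1L] || (ivB[1L] == ivA[1L] && ivB[2L] < ivA[2L])) {
        tmp <- ivA; ivA <- ivB; ivB <- tmp
      }
      if (identical(ivA, ivB)) next                      # self match
      if (iv_overlaps(ivA, ivB, L)) next                 # tandem/self-overlap
      key <- paste(ivA[1L], ivA[2L], ivB[1L], ivB[2L], inverted)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        a_start = ivA[1L], a_end = ivA[2L],
        b_start = ivB[1L], b_end = ivB[2L], length = len,
        orientation = if (inverted) "inverted" else "direct",
        stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }

  # one seed per diagonal run: consecutive seeds of one maximal match share
  # a diagonal, so extending every one of them would be quadratic work
  thin_seeds <- function(ii, jj) {
    if (!length(ii)) return(data.table::data.table(i = integer(0),
                                                   j = integer(0)))
    dt <- data.table::data.table(i = ii, j = jj, diag = jj - ii)
    data.table::setorder(dt, diag, i)
    keep <- c(TRUE, !(dt$diag[-1L] == dt$diag[-nrow(dt)] &
                        dt$i[-1L] == dt$i[-nrow(dt)] + 1L))
    dt[keep, list(i = i, j = j)]
  }

  dtd <- kmers_of(s, L)
  jd <- dtd[dtd, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  jd <- jd[jd$pos < jd$i.pos, ]
  direct <- collect(thin_seeds(jd$pos, jd$i.pos), chars, inverted = FALSE)

  dtr <- kmers_of(rc, L)
  ji <- dtd[dtr, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  inv <- collect(thin_seeds(ji$pos, ji$i.pos), rchars, inverted = TRUE)

  out <- rbind(direct, inv)
  if (is.null(out))
    out <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      length = integer(0), orientation = character(0))
  # a pair can be rediscovered with swapped roles via the inverted join
  out <- unique(out)
  rownames(out) <- NULL
  out[order(-out$length, out$a_start), , drop = FALSE]
}

#' Find classes of maximal exact repeats
#'
#' Maximal exact repeated pairs >= `min_len` (see
#' [find_exact_repeat_pairs()]) are merged into classes of copies: pairs
#' sharing a copy interval belong to one class.
#'
#' @param genome an [annotated_genome()] or DNA string.
#' @param min_len minimal repeat length (default 100 bp, the conventional
#'   organelle repeat-survey cutoff).
#' @return list of `repeat_class` objects, each with `name`, `copies`
#'   (data.frame `start`, `end`, `orientation`), `length_bp`,
#'   `orientation` (`direct`/`inverted`/`mixed`), `edits_between_copies`
#'   and `origin_annotation`.
#' @export
find_exact_repeats <- function(genome, min_len = 100L) {
  if (is.character(genome))
    genome <- annotated_genome("seq", genome, is_circular = FALSE)
  pairs <- find_exact_repeat_pairs(genome, min_len)
  if (!nrow(pairs)) return(list())
  ivkey <- function(s, e) paste(s, e, sep = ":")
  keys <- unique(c(ivkey(pairs$a_start, pairs$a_end),
                   ivkey(pairs$b_start, pairs$b_end)))
  idx <- stats::setNames(seq_along(keys), keys)
  kiv <- do.call(rbind, lapply(strsplit(keys, ":"), as.integer))
  uf <- uf_new(length(keys))
  for (r in seq_len(nrow(pairs)))
    uf <- uf_union(uf, idx[[ivkey(pairs$a_start[r], pairs$a_end[r])]],
                   idx[[ivkey(pairs$b_start[r], pairs$b_end[r])]])
  # the "same" copy can surface with slightly different maximal extents in
  # different pairs (chance flank matches); treat heavily overlapping
  # intervals as one copy
  L0 <- genome$length_bp
  if (length(keys) > 1L) for (i in 1:(length(keys) - 1L))
    for (j in (i + 1L):length(keys)) {
      ov <- iv_overlap_bp(kiv[i, ], kiv[j, ], max(L0, kiv[i, 2L], kiv[j, 2L]))
      w <- min(kiv[i, 2L] - kiv[i, 1L], kiv[j, 2L] - kiv[j, 1L])
      if (ov >= 0.8 * w) uf <- uf_union(uf, i, j)
    }
  roots <- vapply(seq_along(keys), function(i) uf_find(uf, i), integer(1))
  classes <- list()
  for (root in unique(roots)) {
    members <- keys[roots == root]
    ivs <- do.call(rbind, lapply(strsplit(members, ":"), as.integer))
    # collapse near-duplicate extents of the same copy: keep the widest of
    # each overlap cluster
    if (length(members) > 1L) {
      ufm <- uf_new(length(members))
      for (i in 1:(length(members) - 1L)) for (j in (i + 1L):length(members)) {
        ov <- iv_overlap_bp(ivs[i, ], ivs[j, ],
                            max(L0, ivs[i, 2L], ivs[j, 2L]))
        w <- min(ivs[i, 2L] - ivs[i, 1L], ivs[j, 2L] - ivs[j, 1L])
        if (ov >= 0.8 * w) ufm <- uf_union(ufm, i, j)
      }
      rm_roots <- vapply(seq_along(members), function(i) uf_find(ufm, i),
                         integer(1))
      keep <- vapply(unique(rm_roots), function(rt) {
        grp <- which(rm_roots == rt)
        grp[which.max(ivs[grp, 2L] - ivs[grp, 1L])]
      }, integer(1))
      members <- members[keep]
      ivs <- ivs[keep, , drop = FALSE]
    }
    # orientation propagation: first copy "+", flip across inverted pairs
    ori <- stats::setNames(rep(NA_character_, length(members)), members)
    ori[members[1L]] <- "+"
    key_rep <- function(s, e) {
      k <- ivkey(s, e)
      if (k %in% members) return(k)
      for (i in seq_along(members)) {
        ov <- iv_overlap_bp(c(s, e), ivs[i, ], max(L0, e, ivs[i, 2L]))
        if (ov >= 0.8 * min(e - s, ivs[i, 2L] - ivs[i, 1L]))
          return(members[i])
      }
      NA_character_
    }
    changed <- TRUE
    while (changed && anyNA(ori)) {
      changed <- FALSE
      for (r in seq_len(nrow(pairs))) {
        ka <- key_rep(pairs$a_start[r], pairs$a_end[r])
        kb <- key_rep(pairs$b_start[r], pairs$b_end[r])
        if (is.na(ka) || is.na(kb) || !(ka %in% members)) next
        flip <- pairs$orientation[r] == "inverted"
        for (kk in list(c(ka, kb), c(kb, ka))) {
          if (!is.na(ori[kk[1L]]) && is.na(ori[kk[2L]])) {
            ori[kk[2L]] <- if (flip) setdiff(c("+", "-"), ori[kk[1L]])
                           else ori[kk[1L]]
            changed <- TRUE
          }
        }
      }
    }
    ori[is.na(ori)] <- "+"
    o <- order(ivs[, 1L])
    copies <- data.frame(start = ivs[o, 1L], end = ivs[o, 2L],
                         orientation = unname(ori[members[o]]),
                         stringsAsFactors = FALSE)
    orientation <- if (length(unique(copies$orientation)) == 1L) "direct"
      else if (nrow(copies) == 2L) "inverted" else {
        inv_n <- sum(copies$orientation == "-")
        if (inv_n == 0L) "direct" else if (inv_n == nrow(copies)) "direct"
        else if (nrow(copies) == 2L) "inverted" else "mixed"
      }
    if (nrow(copies) == 2L && length(unique(copies$orientation)) == 2L)
      orientation <- "inverted"
    classes[[length(classes) + 1L]] <- structure(
      list(name = NA_character_, copies = copies,
           length_bp = max(copies$end - copies$start),
           orientation = orientation, edits_between_copies = 0L,
           origin_annotation = "-"),
      class = "repeat_class")
  }
  # sort by first coordinate, then name RepA, RepB, ...
  firsts <- vapply(classes, function(cl) cl$copies$start[1L], numeric(1))
  classes <- classes[order(firsts)]
  for (i in seq_along(classes))
    classes[[i]]$name <- paste0("Rep", LETTERS[((i - 1L) %% 26L) + 1L],
                                if (i > 26L) i else "")
  classes
}

#' @export
print.repeat_class <- function(x, ...) {
  cat(sprintf("<repeat_class> %s: %d bp, %s, %d copies, %d edits, origin %s\n",
              x$name, x$length_bp, x$orientation, nrow(x$copies),
              x$edits_between_copies, x$origin_annotation))
  invisible(x)
}

#' Summarise repeat classes as a data.frame
#' @param classes list of `repeat_class` objects.
#' @export
repeat_class_table <- function(classes) {
  if (!length(classes))
    return(data.frame(name = character(0), length_bp = integer(0),
                      n_copies = integer(0), orientation = character(0),
                      edits = integer(0), origin = character(0)))
  do.call(rbind, lapply(classes, function(cl)
    data.frame(name = cl$name, length_bp = cl$length_bp,
               n_copies = nrow(cl$copies), orientation = cl$orientation,
               edits = cl$edits_between_copies,
               origin = cl$origin_annotation, stringsAsFactors = FALSE)))
}

## near-exact extension ------------------------------------------------------

#' @keywords internal
oriented_copy_seq <- function(genome, copy) {
  s <- iv_seq(genome$sequence, c(copy$start, copy$end), genome$length_bp)
  if (copy$orientation == "-") s <- revcomp(s)
  s
}

#' @keywords internal
count_alignment_edits <- function(aln) {
  # substitutions + indel events (a multi-bp gap counts once)
  nsub <- Biostrings::nmismatch(aln)
  ip <- Biostrings::indel(Biostrings::pattern(aln))
  is <- Biostrings::indel(Biostrings::subject(aln))
  nind <- length(ip[[1]]) + length(is[[1]])
  nsub + nind
}

#' Extend and fuse exact repeat classes allowing a low edit rate
#'
#' Exact repeat cores whose copies continue to agree under at most
#' `max_edit_rate` edits (substitutions and indel events) are fused when
#' their copies lie within `max_gap` bp of each other, and each two-copy
#' class is then extended outwards while the cumulative edit rate stays
#' below the threshold.  Mirrors the situation of a long duplication whose
#' two copies differ by a handful of mutations.
#'
#' @param classes list of `repeat_class` objects (from
#'   [find_exact_repeats()]).
#' @param genome the [annotated_genome()] they came from.
#' @param max_edit_rate maximal edits per aligned column (default 0.01).
#' @param max_gap maximal distance between exact cores to attempt fusion.
#' @param min_extension minimal flank extension worth keeping (bp).
#' @return list of `repeat_class` objects with `edits_between_copies` set.
#' @export
extend_near_exact <- function(classes, genome, max_edit_rate = 0.01,
                              max_gap = 50L, min_extension = 20L) {
  two <- which(vapply(classes, function(cl) nrow(cl$copies) == 2L, logical(1)))
  if (length(two) >= 2L) {
    uf <- uf_new(length(classes))
    near <- function(x, y) {
      gap <- function(a, b) {
        g1 <- max(x$copies$start[a], y$copies$start[b]) -
          min(x$copies$end[a], y$copies$end[b])
        g1
      }
      same_ori <- identical(sort(x$copies$orientation),
                            sort(y$copies$orientation))
      same_ori && gap(1L, 1L) <= max_gap && gap(2L, 2L) <= max_gap
    }
    for (i in two) for (j in two) if (i < j && near(classes[[i]], classes[[j]]))
      uf <- uf_union(uf, i, j)
    roots <- vapply(seq_along(classes), function(i) uf_find(uf, i), integer(1))
    fused <- list()
    for (root in unique(roots)) {
      grp <- which(roots == root)
      if (length(grp) == 1L) { fused <- c(fused, classes[grp]); next }
      g1s <- min(vapply(grp, function(i) classes[[i]]$copies$start[1L], numeric(1)))
      g1e <- max(vapply(grp, function(i) classes[[i]]$copies$end[1L], numeric(1)))
      g2s <- min(vapply(grp, function(i) classes[[i]]$copies$start[2L], numeric(1)))
      g2e <- max(vapply(grp, function(i) classes[[i]]$copies$end[2L], numeric(1)))
      ori <- classes[[grp[1L]]]$copies$orientation
      span1 <- list(start = g1s, end = g1e, orientation = ori[1L])
      span2 <- list(start = g2s, end = g2e, orientation = ori[2L])
      s1 <- oriented_copy_seq(genome, span1)
      s2 <- oriented_copy_seq(genome, span2)
      sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
      aln <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                           substitutionMatrix = sm,
                                           gapOpening = 5, gapExtension = 2)
      edits <- count_alignment_edits(aln)
      alen <- Biostrings::nchar(aln)
      if (edits / alen <= max_edit_rate) {
        cl <- classes[[grp[1L]]]
        cl$copies <- data.frame(start = c(g1s, g2s), end = c(g1e, g2e),
                                orientation = ori, stringsAsFactors = FALSE)
        cl$length_bp <- max(g1e - g1s, g2e - g2s)
        cl$edits_between_copies <- edits
        cl$orientation <- if (length(unique(ori)) == 1L) "direct" else "inverted"
        fused <- c(fused, list(cl))
      } else fused <- c(fused, classes[grp])
    }
    classes <- fused
  }
  # outward flank extension for two-copy classes
  L <- genome$length_bp
  chars <- strsplit(genome$sequence, "")[[1]]
  at <- function(i) if (genome$is_circular) chars[(i %% L) + 1L]
    else if (i < 0L || i >= L) NA_character_ else chars[i + 1L]
  for (ci in seq_along(classes)) {
    cl <- classes[[ci]]
    if (nrow(cl$copies) != 2L) next
    inv <- length(unique(cl$copies$orientation)) == 2L
    # the extension itself must stay near-exact: its own mismatch count is
    # budgeted (one free edit to cross), never amortised against the core
    budget <- function(ext, edits) edits <= max_edit_rate * ext + 1
    for (side in c("right", "left")) {
      edits0 <- cl$edits_between_copies
      t <- 0L; extra_edits <- 0L; best <- 0L; best_edits <- 0L
      repeat {
        # next base beyond each copy on this side (inverted: opposite ends)
        p1 <- if (side == "right") cl$copies$end[1L] + t
              else cl$copies$start[1L] - 1L - t
        p2 <- if (!inv) {
          if (side == "right") cl$copies$end[2L] + t
          else cl$copies$start[2L] - 1L - t
        } else {
          if (side == "right") cl$copies$start[2L] - 1L - t
          else cl$copies$end[2L] + t
        }
        c1 <- at(p1); c2 <- at(p2)
        if (!inv) { cmp <- !is.na(c1) && !is.na(c2) && c1 == c2 }
        else {
          cmp <- !is.na(c1) && !is.na(c2) &&
            c1 == chartr("ACGT", "TGCA", c2)
        }
        if (is.na(c1) || is.na(c2)) break
        if (!cmp) extra_edits <- extra_edits + 1L
        if (!budget(t + 1L, extra_edits)) break
        t <- t + 1L
        if (cmp) { best <- t; best_edits <- extra_edits }
        if (t > L) break
      }
      if (best >= min_extension) {
        if (side == "right") {
          cl$copies$end[1L] <- cl$copies$end[1L] + best
          if (!inv) cl$copies$end[2L] <- cl$copies$end[2L] + best
          else cl$copies$start[2L] <- cl$copies$start[2L] - best
        } else {
          cl$copies$start[1L] <- cl$copies$start[1L] - best
          if (!inv) cl$copies$start[2L] <- cl$copies$start[2L] - best
          else cl$copies$end[2L] <- cl$copies$end[2L] + best
        }
        cl$edits_between_copies <- edits0 + best_edits
        cl$length_bp <- max(cl$copies$end - cl$copies$start)
      }
    }
    classes[[ci]] <- cl
  }
  # fusion may have consumed classes; re-letter in coordinate order
  firsts <- vapply(classes, function(cl) cl$copies$start[1L], numeric(1))
  classes <- classes[order(firsts)]
  for (i in seq_along(classes))
    classes[[i]]$name <- paste0("Rep", LETTERS[((i - 1L) %% 26L) + 1L],
                                if (i > 26L) i else "")
  classes
}

## origin annotation ---------------------------------------------------------

#' Annotate the genomic origin of a repeat class
#'
#' Sets `origin_annotation` to the gene(s) or intron(s) whose intervals the
#' repeat copies cover: a feature qualifies when the overlap reaches 80%
#' of the shorter of the feature and the repeat.  Introns (by canonical
#' name) are preferred over their host genes; multiple qualifying features
#' are comma-joined; `"-"` if none.
#'
#' @param rc a `repeat_class`.
#' @param genome the [annotated_genome()].
#' @return the `repeat_class` with `origin_annotation` filled in.
#' @export
annotate_origin <- function(rc, genome) {
  L <- genome$length_bp
  q_introns <- character(0); q_genes <- character(0)
  for (f in genome$features) {
    sp <- feature_span(f, L)
    glen <- sp[2L] - sp[1L]
    for (r in seq_len(nrow(rc$copies))) {
      civ <- c(rc$copies$start[r], rc$copies$end[r])
      ov <- iv_overlap_bp(sp, civ, L)
      if (ov >= 0.8 * min(glen, rc$length_bp)) q_genes <- c(q_genes, f$name)
      for (it in f$introns) {
        ilen <- iv_width(it$interval)
        ovi <- iv_overlap_bp(it$interval, civ, L)
        if (ovi >= 0.8 * min(ilen, rc$length_bp))
          q_introns <- c(q_introns, intron_name(it))
      }
    }
  }
  q_introns <- unique(q_introns); q_genes <- unique(q_genes)
  rc$origin_annotation <- if (length(q_introns))
    paste(q_introns, collapse = ", ")
  else if (length(q_genes)) paste(q_genes, collapse = ", ")
  else "-"
  rc
}
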