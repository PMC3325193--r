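# Planting helpers for the synthetic genome generator: editing sites,
# pseudogene fragments, repeat classes, microsatellites, and the final
# scrub pass that removes tandem runs arising by accident at assembly
# junctions.

#' @keywords internal
plant_editing_sites <- function(cds, n_c2u, n_u2c) {
  # The clean CDS plays the functional (edited) transcript; the genomic
  # CDS gets the pre-edit base at each planted site.  C>U: genomic C,
  # transcript U (DNA T).  U>C: genomic T, transcript C.
  ref_protein <- sub("\\*$", "", translate_cds(cds))
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  nc <- length(codons)
  avail <- sample(2:(nc - 1L))
  sites <- list()
  genomic <- codons
  try_plant <- function(ci, direction) {
    cod <- codons[ci]
    bases <- strsplit(cod, "")[[1]]
    aa <- unname(GENETIC_CODE1[cod])
    pos_ok <- sample(1:3)
    for (p in pos_ok) {
      if (direction == "C>U" && bases[p] != "T") next
      if (direction == "U>C" && bases[p] != "C") next
      nb <- bases
      nb[p] <- if (direction == "C>U") "C" else "T"
      gcod <- paste(nb, collapse = "")
      gaa <- unname(GENETIC_CODE1[gcod])
      if (is.na(gaa) || gaa == "*" || gaa == aa) next
      # the minimal-edit search must recover the planted direction: for a
      # planted U>C there must be no competing single C>U solution
      e <- min_cu_edits(gcod, aa)
      want <- if (direction == "C>U") c(1L, 0L) else c(0L, 1L)
      if (!identical(e, want)) next
      return(list(gcod = gcod, pos = p))
    }
    NULL
  }
  planted <- 0L
  need <- c(rep("C>U", n_c2u), rep("U>C", n_u2c))
  for (direction in need) {
    done <- FALSE
    while (length(avail) && !done) {
      ci <- avail[1L]; avail <- avail[-1L]
      hit <- try_plant(ci, direction)
      if (!is.null(hit)) {
        genomic[ci] <- hit$gcod
        sites[[length(sites) + 1L]] <- data.frame(
          codon_index = ci, pos_in_codon = hit$pos,
          cds_pos = 3L * (ci - 1L) + hit$pos, direction = direction,
          stringsAsFactors = FALSE)
        done <- TRUE
      }
    }
    if (!done) stop("could not plant the requested editing sites: CDS too short")
  }
  list(cds = paste(genomic, collapse = ""),
       ref_protein = ref_protein,
       sites = do.call(rbind, sites))
}

#' @keywords internal
decay_seq <- function(s, target_identity, cap_run = 90L) {
  n <- nchar(s)
  n_sub <- round(n * (1 - target_identity / 100))
  pos <- if (n_sub > 0) sort(sample.int(n, n_sub)) else integer(0)
  repeat {
    gaps <- diff(c(0L, pos, n + 1L)) - 1L
    bad <- which(gaps > cap_run)
    if (!length(bad)) break
    b <- bad[1L]
    lo <- if (b == 1L) 0L else pos[b - 1L]
    hi <- if (b > length(pos)) n + 1L else pos[b]
    pos <- sort(c(pos, lo + (hi - lo) %/% 2L))
  }
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  list(seq = paste(ch, collapse = ""),
       identity = 100 * (n - length(pos)) / n)
}

#' @keywords internal
element_exon_layout <- function(e) {
  # spliced sequence, junction positions and intron offsets of an element
  segs <- e$segments
  spl <- character(0); cursor <- 0L
  junctions <- integer(0); introns <- list()
  spl_len <- 0L
  for (r in seq_len(nrow(segs))) {
    len <- segs$len[r]
    if (segs$type[r] == "exon") {
      spl <- c(spl, substr(e$seq, cursor + 1L, cursor + len))
      spl_len <- spl_len + len
      if (r < nrow(segs)) junctions <- c(junctions, spl_len)
    } else introns[[length(introns) + 1L]] <- c(cursor, cursor + len)
    cursor <- cursor + len
  }
  list(spliced = paste(spl, collapse = ""),
       junctions = junctions[seq_len(max(0L, length(introns)))],
       introns = introns)
}

#' @keywords internal
plant_pseudogenes <- function(cfg, placed, alloc_slot, put) {
  p <- cfg$pseudo
  empty <- data.frame(parent = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length_bp = integer(0), identity_pct = numeric(0),
                      contains_intron = logical(0),
                      spans_exon_junction = logical(0),
                      signature = character(0))
  if (is.null(p) || p$n == 0L) return(list(tab = empty))
  cap <- cfg$repeats$min_len - 10L
  cands <- Filter(function(e) !is.null(e$strand) && e$category == "protein" &&
                    e$copy == 1L && any(e$segments$type == "intron"), placed)
  if (!length(cands)) stop("infeasible config: pseudogene fragments requested
 but no intron-containing protein gene exists")
  rows <- list()
  for (i in seq_len(p$n)) {
    retro <- stats::runif(1) < p$retro_frac
    len <- sample(seq(p$len_range[1L], p$len_range[2L]), 1L)
    ident <- stats::runif(1, p$identity_range[1L], p$identity_range[2L])
    frag <- NULL
    for (attempt in 1:50) {
      e <- cands[[sample.int(length(cands), 1L)]]
      lay <- element_exon_layout(e)
      if (retro) {
        if (!length(lay$junctions)) next
        j <- lay$junctions[sample.int(length(lay$junctions), 1L)]
        a_max <- min(len - 25L, j)
        b_max <- min(len - 25L, nchar(lay$spliced) - j)
        if (a_max < 25L || b_max < 25L) next
        a <- sample(25L:a_max, 1L)
        b <- len - a
        if (b < 25L || b > b_max) next
        frag <- substr(lay$spliced, j - a + 1L, j + b)
      } else {
        it <- lay$introns[[sample.int(length(lay$introns), 1L)]]
        a_max <- min(len - 30L, it[1L])
        if (a_max < 20L) next
        a <- sample(20L:a_max, 1L)
        cc <- min(len - a, it[2L] - it[1L])
        if (cc < 30L) next
        frag <- substr(e$seq, it[1L] - a + 1L, it[1L] + cc)
      }
      if (!is.null(frag)) break
    }
    if (is.null(frag)) stop("could not construct a pseudogene fragment; ",
                            "loosen the length range or add introns")
    dec <- decay_seq(frag, ident, cap_run = cap)
    strand <- sample(c("+", "-"), 1L)
    ins <- if (strand == "+") dec$seq else revcomp(dec$seq)
    slot <- alloc_slot(nchar(ins))
    start <- put(slot, ins)
    rows[[length(rows) + 1L]] <- data.frame(
      parent = sub("#\\d+$", "", e$name), start = start,
      end = start + nchar(ins), strand = strand, length_bp = nchar(ins),
      identity_pct = dec$identity,
      contains_intron = !retro, spans_exon_junction = retro,
      signature = if (retro) "retroposed_spliced" else "unspliced_copy",
      stringsAsFactors = FALSE)
  }
  list(tab = do.call(rbind, rows))
}

#' @keywords internal
apply_copy_edits <- function(s, n_edits, spacing = 130L) {
  if (n_edits == 0L) return(s)
  n <- nchar(s)
  n_edits <- min(n_edits, max(0L, n %/% spacing - 1L))
  if (n_edits == 0L) return(s)
  pos <- round(seq(spacing, n - spacing, length.out = n_edits))
  ch <- strsplit(s, "")[[1]]
  types <- rep(c("sub", "del", "ins"), length.out = n_edits)
  # apply right-to-left so positions stay valid
  for (k in rev(seq_len(n_edits))) {
    p <- pos[k]
    if (types[k] == "sub") {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    } else if (types[k] == "del") {
      ch <- ch[-p]
    } else {
      ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), after = p)
    }
  }
  paste(ch, collapse = "")
}

#' @keywords internal
plant_repeats <- function(cfg, placed, alloc_slot, put) {
  rp <- cfg$repeats
  classes <- list(); copies <- list()
  empty_cl <- data.frame(class = character(0), length_bp = integer(0),
                         n_copies = integer(0), orientation = character(0),
                         edits = integer(0), origin = character(0))
  empty_cp <- data.frame(class = character(0), copy = integer(0),
                         start = integer(0), end = integer(0),
                         orientation = character(0))
  if (is.null(rp$lengths) || !length(rp$lengths))
    return(list(classes = empty_cl, copies = empty_cp))
  need_idx <- cumsum(rp$intron_origin)     # index into the repeat_source attr
  for (i in seq_along(rp$lengths)) {
    len <- rp$lengths[i]
    ori <- rp$orientations[i]
    ncp <- rp$n_copies[i]
    edits <- rp$near_exact_edits[i]
    name <- paste0("plant", LETTERS[i])
    origin <- "-"
    cps <- list()
    if (rp$intron_origin[i]) {
      e <- Filter(function(x) !is.null(x$repeat_source) &&
                    need_idx[i] %in% x$repeat_source, placed)[[1]]
      segs <- e$segments
      ioffs <- cumsum(c(0, segs$len))
      irow <- which(segs$type == "intron")
      irow <- irow[which.max(segs$len[irow])]
      ioff <- ioffs[irow]
      src_off <- ioff + 20L
      sub <- substr(e$seq, src_off + 1L, src_off + len)
      elen <- nchar(e$seq)
      if (e$strand == "+") {
        g0 <- e$start + src_off
        rep_fwd <- sub
      } else {
        g0 <- e$start + elen - (src_off + len)
        rep_fwd <- revcomp(sub)
      }
      cps[[1L]] <- data.frame(class = name, copy = 1L, start = g0,
                              end = g0 + len, orientation = "+",
                              stringsAsFactors = FALSE)
      # origin: canonical name of that intron
      k_int <- sum(segs$type[seq_len(irow)] == "intron")
      cds_before <- sum(segs$len[seq_len(irow - 1L)][
        segs$type[seq_len(irow - 1L)] == "exon"])
      origin <- paste0(sub("#\\d+$", "", e$name), "i", cds_before, "g2")
      first_placed <- 1L
    } else {
      rep_fwd <- random_clean_dna(len, cfg$at)
      slot <- alloc_slot(len)
      g0 <- put(slot, rep_fwd)
      cps[[1L]] <- data.frame(class = name, copy = 1L, start = g0,
                              end = g0 + len, orientation = "+",
                              stringsAsFactors = FALSE)
      first_placed <- 1L
    }
    for (cpy in 2:ncp) {
      s <- if (ori == "inverted") revcomp(rep_fwd) else rep_fwd
      if (edits > 0L) s <- apply_copy_edits(s, edits)
      slot <- alloc_slot(nchar(s))
      g0 <- put(slot, s)
      cps[[cpy]] <- data.frame(class = name, copy = cpy, start = g0,
                               end = g0 + nchar(s),
                               orientation = if (ori == "inverted") "-" else "+",
                               stringsAsFactors = FALSE)
    }
    classes[[i]] <- data.frame(class = name, length_bp = len, n_copies = ncp,
                               orientation = ori, edits = edits,
                               origin = origin, stringsAsFactors = FALSE)
    copies <- c(copies, cps)
  }
  list(classes = do.call(rbind, classes), copies = do.call(rbind, copies))
}

#' @keywords internal
plant_microsats <- function(cfg, alloc_slot, put) {
  ms <- cfg$microsat
  sizes <- c(di = 2L, tri = 3L, tetra = 4L, penta = 5L, hexa = 6L)
  rows <- list()
  for (kind in names(ms)) {
    u <- sizes[[kind]]
    kcount <- ms[[kind]]
    if (kcount == 0L) next
    for (j in seq_len(kcount)) {
      repeat {
        unit <- paste(sample(c("A", "C", "G", "T"), u, replace = TRUE),
                      collapse = "")
        if (!is_self_periodic(unit)) break
      }
      cnt <- if (u == 2L) sample(6:11, 1L) else sample(4:8, 1L)
      run <- strrep(unit, cnt)
      lg <- sample(setdiff(c("A", "C", "G", "T"),
                           substr(unit, u, u)), 1L)
      rg <- sample(setdiff(c("A", "C", "G", "T"),
                           substr(unit, 1L, 1L)), 1L)
      ins <- paste0(lg, run, rg)
      slot <- alloc_slot(nchar(ins))
      g0 <- put(slot, ins)
      rows[[length(rows) + 1L]] <- data.frame(
        unit = unit, canonical_unit = canonical_rotation(unit),
        unit_size = u, count = cnt, start = g0 + 1L, len = u * cnt,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit = character(0), canonical_unit = character(0),
               unit_size = integer(0), count = integer(0),
               start = integer(0), len = integer(0))
  list(tab = tab)
}

#' @keywords internal
scrub_boundary_msats <- function(genome, ms_tab, protect = NULL,
                                 protect2 = NULL) {
  L <- genome$length_bp
  prot <- list()
  add_prot <- function(df, s = "start", e = "end") {
    if (!is.null(df) && nrow(df))
      for (r in seq_len(nrow(df)))
        prot[[length(prot) + 1L]] <<- c(df[[s]][r], df[[e]][r])
  }
  add_prot(protect); add_prot(protect2)
  if (!is.null(ms_tab) && nrow(ms_tab))
    for (r in seq_len(nrow(ms_tab)))
      prot[[length(prot) + 1L]] <- c(ms_tab$start[r],
                                     ms_tab$start[r] + ms_tab$len[r])
  in_prot <- function(p) {
    for (iv in prot) if (p >= iv[1L] && p < iv[2L]) return(TRUE)
    FALSE
  }
  is_planted <- function(st, ln) {
    if (is.null(ms_tab) || !nrow(ms_tab)) return(FALSE)
    any(ms_tab$start == st & ms_tab$len == ln)
  }
  seqc <- strsplit(genome$sequence, "")[[1]]
  for (round in 1:6) {
    g <- annotated_genome(genome$identifier, paste(seqc, collapse = ""),
                          genome$is_circular, genome$features)
    det <- find_microsatellites(g)
    rogue <- det[!mapply(is_planted, det$start, det$len), , drop = FALSE]
    if (!nrow(rogue)) return(g)
    for (r in seq_len(nrow(rogue))) {
      cands <- (rogue$start[r] +
                  round(rogue$len[r] * c(0.5, 0.33, 0.66))) %% L
      p <- NULL
      for (cp in cands) if (!in_prot(cp)) { p <- cp; break }
      if (is.null(p)) next
      u <- rogue$unit_size[r]
      cur <- seqc[p + 1L]
      prev <- seqc[((p - u) %% L) + 1L]
      repl <- scrub_base_choice(genome, p, setdiff(c("A", "C", "G", "T"),
                                                   c(cur, prev)))
      if (!is.null(repl)) seqc[p + 1L] <- repl
    }
  }
  annotated_genome(genome$identifier, paste(seqc, collapse = ""),
                   genome$is_circular, genome$features)
}

#' @keywords internal
scrub_base_choice <- function(genome, p, candidates) {
  # avoid creating an in-frame stop when the position sits in a protein exon
  if (!length(candidates)) return(NULL)
  for (f in genome$features) {
    if (f$category != "protein" || f$is_pseudo) next
    cds_off <- 0L
    for (iv in f$exons) {
      w <- iv_width(iv)
      inside <- p >= iv[1L] && p < iv[2L]
      if (inside) {
        tpos <- if (f$strand == "+") cds_off + (p - iv[1L])
                else cds_off + (iv[2L] - 1L - p)
        ci <- tpos %/% 3L             # 0-based codon index
        cstart <- ci * 3L
        cds <- spliced_seq(genome, f)
        if (cstart + 3L > nchar(cds)) return(candidates[1L])
        codon <- substr(cds, cstart + 1L, cstart + 3L)
        within <- tpos - cstart
        for (b in candidates) {
          bb <- if (f$strand == "+") b else chartr("ACGT", "TGCA", b)
          nc <- codon
          substr(nc, within + 1L, within + 1L) <- bb
          if (!identical(unname(GENETIC_CODE1[nc]), "*")) return(b)
        }
        return(NULL)
      }
      cds_off <- cds_off + w
    }
  }
  candidates[1L]
}
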