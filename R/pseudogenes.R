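# Pseudogene-fragment archaeology in intergenic spacers: BLAST-like
# seeded local alignment of functional gene (and intron) sequences against
# spacers, origin classification by nearest-neighbour p-distance, and
# retroposition signatures.

#' Build the query set for a spacer scan
#'
#' For every functional (non-pseudogene) gene of the genome, copy 1 only:
#' the spliced (exon-joined) form, and additionally the unspliced genomic
#' form for intron-containing genes.  Junction and intron coordinates are
#' carried along so hits can be flagged.
#'
#' @param genome an [annotated_genome()].
#' @param include_trna include tRNA genes (their fragments are reported but
#'   conventionally excluded from origin analysis)?
#' @return list of query records (`gene`, `form`, `seq`, `junctions`,
#'   `intron_spans`, `category`).
#' @export
build_queries <- function(genome, include_trna = TRUE) {
  out <- list()
  for (f in genome$features) {
    if (f$is_pseudo || f$copy_index != 1L) next
    if (!include_trna && f$category == "tRNA") next
    exl <- vapply(f$exons, iv_width, numeric(1))
    junctions <- if (length(exl) > 1L) cumsum(exl)[-length(exl)] else numeric(0)
    out[[length(out) + 1L]] <- list(
      gene = f$name, form = "spliced", seq = spliced_seq(genome, f),
      junctions = junctions, intron_spans = list(), category = f$category)
    if (length(f$introns)) {
      # intron spans in unspliced (transcription-orientation) coordinates
      segs <- numeric(0); spans <- list(); cursor <- 0
      for (i in seq_along(f$exons)) {
        cursor <- cursor + exl[i]
        if (i <= length(f$introns)) {
          il <- iv_width(f$introns[[i]]$interval)
          spans[[length(spans) + 1L]] <- c(cursor, cursor + il)
          cursor <- cursor + il
        }
      }
      out[[length(out) + 1L]] <- list(
        gene = f$name, form = "unspliced", seq = unspliced_seq(genome, f),
        junctions = numeric(0), intron_spans = spans, category = f$category)
    }
  }
  out
}

#' @keywords internal
seed_hits <- function(qseq, tseq, k = 11L) {
  nq <- nchar(qseq) - k + 1L
  nt <- nchar(tseq) - k + 1L
  if (nq < 1L || nt < 1L)
    return(data.frame(q = integer(0), t = integer(0)))
  qk <- data.table::data.table(
    kmer = substring(qseq, seq_len(nq), seq_len(nq) + k - 1L),
    q = seq_len(nq) - 1L)
  tk <- data.table::data.table(
    kmer = substring(tseq, seq_len(nt), seq_len(nt) + k - 1L),
    t = seq_len(nt) - 1L)
  j <- qk[tk, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  data.frame(q = j$q, t = j$t)
}

#' @keywords internal
seed_windows <- function(hits, k = 11L, band = 40L, max_sep = 250L) {
  if (!nrow(hits)) return(data.frame(tmin = integer(0), tmax = integer(0)))
  hits$diag <- hits$t - hits$q
  hits <- hits[order(hits$diag, hits$t), ]
  grp <- cumsum(c(1L, diff(hits$diag) > band))
  out <- list()
  for (g in split(hits, grp)) {
    sub <- cumsum(c(1L, diff(g$t) > max_sep))
    for (gg in split(g, sub))
      out[[length(out) + 1L]] <- data.frame(tmin = min(gg$t),
                                            tmax = max(gg$t) + k)
  }
  win <- do.call(rbind, out)
  # merge overlapping windows
  win <- win[order(win$tmin), , drop = FALSE]
  merged <- list(win[1L, ])
  if (nrow(win) > 1L) for (r in 2:nrow(win)) {
    last <- merged[[length(merged)]]
    if (win$tmin[r] <= last$tmax) {
      merged[[length(merged)]]$tmax <- max(last$tmax, win$tmax[r])
    } else merged[[length(merged) + 1L]] <- win[r, ]
  }
  do.call(rbind, merged)
}

#' Scan intergenic spacers for pseudogene fragments
#'
#' Seeded local alignment (match +1, mismatch -1, gap open -2, gap extend
#' -1) of every query against both strands of every spacer; hits of at
#' least `min_len` aligned target bp and `min_identity` percent identity
#' are reported.  Overlapping hits from the same parent gene are merged;
#' each fragment carries its identity, strand, and whether it retains
#' intron sequence or crosses an exon--exon junction.
#'
#' @param genome an [annotated_genome()].
#' @param queries query set from [build_queries()] (built automatically
#'   when `NULL`).
#' @param min_len minimal fragment length in bp (default 50).
#' @param min_identity minimal percent identity (default 70).
#' @param min_score minimal raw alignment score (matches minus penalties).
#'   Length and identity floors alone still admit the occasional chance
#'   local alignment between unrelated sequences (a 50 bp hit at barely
#'   70% identity arises by chance in hundreds of kb); the score floor
#'   plays the role of BLAST's expectation cutoff and is far below the
#'   score of any genuine fragment at the identity floor and ~100 bp.
#' @param word_size exact seed length for the scan.
#' @return data.frame of fragments: `parent`, `category`, `start`, `end`
#'   (0-based half-open genomic), `strand`, `length_bp`, `identity_pct`,
#'   `contains_intron`, `spans_exon_junction`.
#' @export
scan_spacers <- function(genome, queries = NULL, min_len = 50L,
                         min_identity = 70, min_score = 30,
                         word_size = 11L) {
  if (is.null(queries)) queries <- build_queries(genome)
  short <- vapply(queries, function(q) nchar(q$seq) < min_len, logical(1))
  if (any(short)) {
    warning(sprintf("%d quer%s shorter than min_len skipped", sum(short),
                    if (sum(short) == 1L) "y" else "ies"))
    queries <- queries[!short]
  }
  spacers <- spacer_intervals(genome)
  empty <- data.frame(parent = character(0), category = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length_bp = integer(0),
                      identity_pct = numeric(0), contains_intron = logical(0),
                      spans_exon_junction = logical(0))
  if (!length(spacers) || !length(queries)) return(empty)

  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  hits <- list()
  for (sp in spacers) {
    tfwd <- iv_seq(genome$sequence, sp, genome$length_bp)
    tl <- nchar(tfwd)
    for (q in queries) {
      for (strand in c("+", "-")) {
        tseq <- if (strand == "+") tfwd else revcomp(tfwd)
        sh <- seed_hits(q$seq, tseq, k = word_size)
        if (!nrow(sh)) next
        wins <- seed_windows(sh, k = word_size)
        for (w in seq_len(nrow(wins))) {
          pad <- min_len + 60L
          ws <- max(0L, wins$tmin[w] - pad)
          we <- min(tl, wins$tmax[w] + pad)
          aln <- Biostrings::pairwiseAlignment(
            q$seq, substr(tseq, ws + 1L, we), type = "local",
            substitutionMatrix = sm, gapOpening = 2, gapExtension = 1)
          alen <- Biostrings::nchar(aln)
          if (alen == 0) next
          ident <- 100 * Biostrings::nmatch(aln) / alen
          tr <- Biostrings::subject(aln)
          t0 <- ws + Biostrings::start(tr) - 1L        # 0-based in tseq
          t1 <- ws + Biostrings::end(tr)
          if (t1 - t0 < min_len || ident < min_identity ||
              Biostrings::score(aln) < min_score) next
          # map back to genome coordinates
          if (strand == "+") { g0 <- sp[1L] + t0; g1 <- sp[1L] + t1 }
          else { g0 <- sp[1L] + (tl - t1); g1 <- sp[1L] + (tl - t0) }
          qr <- c(Biostrings::start(Biostrings::pattern(aln)) - 1L,
                  Biostrings::end(Biostrings::pattern(aln)))
          spans <- any(q$junctions > qr[1L] + 10 & q$junctions < qr[2L] - 10)
          containsi <- FALSE
          for (isp in q$intron_spans)
            if (min(isp[2L], qr[2L]) - max(isp[1L], qr[1L]) >= 20)
              containsi <- TRUE
          hits[[length(hits) + 1L]] <- data.frame(
            parent = q$gene, category = q$category, form = q$form,
            start = g0 %% genome$length_bp, end = g0 %% genome$length_bp + (g1 - g0),
            strand = strand, length_bp = g1 - g0, identity_pct = ident,
            contains_intron = containsi, spans_exon_junction = spans,
            score = Biostrings::score(aln), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  merge_fragment_hits(h, genome$length_bp)
}

#' @keywords internal
merge_fragment_hits <- function(h, L) {
  out <- list()
  for (parent in unique(h$parent)) {
    hp <- h[h$parent == parent, , drop = FALSE]
    uf <- uf_new(nrow(hp))
    if (nrow(hp) > 1L)
      for (i in 1:(nrow(hp) - 1L)) for (j in (i + 1L):nrow(hp))
        if (iv_overlaps(c(hp$start[i], hp$end[i]),
                        c(hp$start[j], hp$end[j]), L))
          uf <- uf_union(uf, i, j)
    roots <- vapply(seq_len(nrow(hp)), function(i) uf_find(uf, i), integer(1))
    for (root in unique(roots)) {
      grp <- hp[roots == root, , drop = FALSE]
      best <- grp[which.max(grp$score), , drop = FALSE]
      best$contains_intron <- any(grp$contains_intron)
      best$spans_exon_junction <- any(grp$spans_exon_junction)
      # fragment interval: the union of the merged hits
      best$start <- min(grp$start)
      best$end <- max(grp$end)
      best$length_bp <- best$end - best$start
      out[[length(out) + 1L]] <- best
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res[, setdiff(names(res), c("score", "form"))]
}

## origin classification -----------------------------------------------------

#' @keywords internal
pdist_local <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  best <- NULL
  for (bb in c(b, revcomp(b))) {
    aln <- Biostrings::pairwiseAlignment(a, bb, type = "local",
                                         substitutionMatrix = sm,
                                         gapOpening = 2, gapExtension = 1)
    if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best))
      best <- aln
  }
  pa <- strsplit(as.character(Biostrings::alignedPattern(best)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(best)), "")[[1]]
  keep <- pa != "-" & sb != "-"
  cols <- sum(keep)
  mism <- sum(pa[keep] != sb[keep])
  list(dist = if (cols) mism / cols else NA_real_, overlap = cols)
}

#' Classify the origin of a pseudogene fragment
#'
#' Uncorrected p-distances on locally aligned columns (both orientations
#' tried) between the fragment and (i) the functional copy in the same
#' genome, (ii) each member of an ortholog panel.  The call is `self` when
#' the self distance beats the best ortholog distance by at least `margin`
#' substitutions/site, `foreign-like` in the opposite case, `ambiguous`
#' when the margin is not met or fewer than `min_overlap` columns align.
#'
#' @param fragment_seq DNA sequence of the fragment.
#' @param self_seq functional copy from the same genome.
#' @param ortholog_panel named character vector of ortholog sequences.
#' @param margin required distance margin (default 0.02 subst/site).
#' @param min_overlap minimal aligned columns (default 50).
#' @return list: `call`, `self_distance`, `best_ortholog`,
#'   `best_ortholog_distance`, `reason`.
#' @export
classify_origin <- function(fragment_seq, self_seq, ortholog_panel,
                            margin = 0.02, min_overlap = 50L) {
  if (!length(ortholog_panel)) stop("ortholog panel is empty")
  self <- pdist_local(fragment_seq, self_seq)
  # an ortholog alignment below the overlap floor carries no signal: a
  # short chance alignment can have a deceptively low p-distance
  od <- vapply(ortholog_panel, function(o) {
    p <- pdist_local(fragment_seq, o)
    if (p$overlap < min_overlap) NA_real_ else p$dist
  }, numeric(1))
  ok <- !is.na(od)
  if (self$overlap < min_overlap || is.na(self$dist) || !any(ok))
    return(list(call = "ambiguous", self_distance = self$dist,
                best_ortholog = NA_character_,
                best_ortholog_distance = NA_real_,
                reason = "insufficient aligned overlap"))
  bo <- which.min(od)
  call <- if (self$dist <= od[bo] - margin) "self"
    else if (od[bo] <= self$dist - margin) "foreign-like"
    else "ambiguous"
  list(call = call, self_distance = self$dist,
       best_ortholog = names(ortholog_panel)[bo],
       best_ortholog_distance = unname(od[bo]),
       reason = if (call == "ambiguous") "margin not met" else "")
}

#' Retroposition signature of a pseudogene fragment
#'
#' `retroposed_spliced` when the fragment crosses an exon--exon junction
#' without retaining intron sequence (the footprint of a reverse-
#' transcribed, spliced mRNA), `unspliced_copy` when intron sequence is
#' retained, `single_exon_uninformative` otherwise.
#'
#' @param fragment one row of the [scan_spacers()] result (or any list
#'   with `contains_intron` and `spans_exon_junction`).
#' @return character scalar signature.
#' @export
retro_signature <- function(fragment) {
  if (isTRUE(fragment$contains_intron)) "unspliced_copy"
  else if (isTRUE(fragment$spans_exon_junction)) "retroposed_spliced"
  else "single_exon_uninformative"
}

#' Summarise a fragment table
#'
#' @param fragments result of [scan_spacers()].
#' @param genome_bp genome length, for the genome-fraction figure.
#' @return list: `n_fragments`, `total_bp`, `fraction_pct`, `n_parents`,
#'   `per_parent` table.
#' @export
pseudogene_summary <- function(fragments, genome_bp) {
  total <- sum(fragments$length_bp)
  list(n_fragments = nrow(fragments), total_bp = total,
       fraction_pct = genome_fraction_pct(total, genome_bp),
       n_parents = length(unique(fragments$parent)),
       per_parent = if (nrow(fragments))
         as.data.frame(table(parent = fragments$parent),
                       stringsAsFactors = FALSE)
       else data.frame(parent = character(0), Freq = integer(0)))
}

#' Percentage of a genome occupied by a sequence total
#' @param part_bp numerator in bp.
#' @param genome_bp genome size in bp.
#' @return percentage.
#' @export
genome_fraction_pct <- function(part_bp, genome_bp) 100 * part_bp / genome_bp
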