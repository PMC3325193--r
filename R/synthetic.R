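# Synthetic circular chondrome generator with a ground-truth manifest.
#
# Every structure the pipeline detects is planted by construction: strand-
# assigned multi-exon genes with cis-spliced group II introns, a duplicated
# rRNA gene cluster, intergenic spacers seeded with retroposed (intron-less)
# and unspliced pseudogene fragments, exact and near-exact direct/inverted
# repeats, perfect microsatellite runs, planted C<->U editing sites, and
# codon states that force start/stop reconstitution events.  The manifest
# records exact coordinates, so downstream scans can be checked against
# ground truth instead of against each other.

MT_PROTEIN_GENES <- c(
  "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6", "nad9",
  "sdh3", "sdh4", "cob", "cox1", "cox2", "cox3",
  "atp1", "atp4", "atp6", "atp8", "atp9", "ccmFC", "tatC",
  "rpl2", "rpl5", "rpl6", "rpl10", "rpl16",
  "rps1", "rps2", "rps3", "rps4", "rps7", "rps10", "rps11", "rps12",
  "rps13", "rps14", "rps19")
MT_RRNA_GENES <- c("rrn5", "rrn18", "rrn26")
MT_TRNA_GENES <- c(
  "trnAugc", "trnCgca", "trnDguc", "trnEuuc", "trnFgaa", "trnGgcc",
  "trnHgug", "trnIcau", "trnKuuu", "trnLuaa", "trnLcaa", "trnMcau",
  "trnMfcau", "trnNguu", "trnPugg", "trnQuug", "trnRacg", "trnRucu",
  "trnSgcu", "trnSuga", "trnTugu", "trnVuac", "trnWcca", "trnYgua",
  "trnLuag", "trnGucc")

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

#' Generator settings for a synthetic chondrome
#'
#' Defaults mirror the scale of a large, archaic vascular-plant chondrome:
#' about 413 kb, AT fraction 0.558, 66 unique genes (37 protein, 3 rRNA,
#' 26 tRNA) plus a duplicated rRNA cluster and duplicated tRNA copies, 32
#' cis-spliced group II introns, 69 pseudogene fragments in spacers, 9
#' repeat classes (one large inverted repeat arising from the duplicated
#' rRNA cluster, one near-exact class), 15 microsatellites (4 di, 9 tri,
#' 2 tetra), 12 C-to-U plus 5 U-to-C planted editing sites in one gene,
#' and 19 codon-reconstitution states (6 ACG starts, 4 internal stops,
#' 9 editing-created stops).
#'
#' @param genome_size target genome length in bp (50--500 kb sensible).
#' @param at AT fraction of background sequence.
#' @param n_protein,n_rrna,n_trna unique gene counts by category.
#' @param intron_total number of group II introns distributed over
#'   multi-exon protein genes.
#' @param duplicate_rrna_cluster duplicate the rRNA gene cluster (the
#'   duplication is recorded as a repeat class in the manifest)?
#' @param inverted_rrna_cluster place the duplicate in inverted orientation?
#' @param n_trna_duplicates extra identical tRNA gene copies.
#' @param pseudo list: `n`, `len_range`, `identity_range`, `retro_frac`.
#' @param repeats list: `min_len` plus per-class `lengths`, `orientations`,
#'   `n_copies`, `intron_origin` (copy 1 carved from a real intron) and
#'   `near_exact_edits` (0 = exact class).
#' @param microsat named counts of planted runs per unit size.
#' @param editing list: `n_c2u`, `n_u2c` sites planted in one gene.
#' @param reconstitution list: `start_acg`, `stop_removed`, `stop_created`
#'   counts of genes given the corresponding codon states.
#' @return a `synth_config` list.
#' @export
synth_config <- function(genome_size = 413530, at = 0.558,
                         n_protein = 37, n_rrna = 3, n_trna = 26,
                         intron_total = 32,
                         duplicate_rrna_cluster = TRUE,
                         inverted_rrna_cluster = TRUE,
                         n_trna_duplicates = 11,
                         pseudo = list(n = 69, len_range = c(60, 400),
                                       identity_range = c(85, 100),
                                       retro_frac = 0.7),
                         repeats = list(
                           min_len = 100,
                           lengths = c(124, 1241, 681, 362, 143, 168, 100, 764),
                           orientations = c("direct", "inverted", "direct",
                                            "inverted", "direct", "direct",
                                            "inverted", "direct"),
                           n_copies = c(2, 2, 2, 2, 2, 3, 2, 2),
                           intron_origin = c(FALSE, TRUE, TRUE, FALSE, FALSE,
                                             FALSE, FALSE, TRUE),
                           near_exact_edits = c(0, 0, 0, 0, 0, 0, 0, 3)),
                         microsat = c(di = 4, tri = 9, tetra = 2,
                                      penta = 0, hexa = 0),
                         editing = list(n_c2u = 12, n_u2c = 5),
                         reconstitution = list(start_acg = 6, stop_removed = 4,
                                               stop_created = 9)) {
  cfg <- list(genome_size = genome_size, at = at, n_protein = n_protein,
              n_rrna = n_rrna, n_trna = n_trna, intron_total = intron_total,
              duplicate_rrna_cluster = duplicate_rrna_cluster,
              inverted_rrna_cluster = inverted_rrna_cluster,
              n_trna_duplicates = n_trna_duplicates,
              pseudo = pseudo, repeats = repeats, microsat = microsat,
              editing = editing, reconstitution = reconstitution)
  class(cfg) <- "synth_config"
  cfg
}

## clean random sequence (no accidental threshold microsatellite runs) -------

#' @keywords internal
random_clean_dna <- function(n, at) {
  s <- random_dna(n, at)
  for (i in 1:20) {
    hits <- msat_scan_linear(s)
    if (!nrow(hits)) return(s)
    for (k in seq_len(nrow(hits))) {
      mid <- hits$start[k] + hits$len[k] %/% 2L
      u <- hits$unit_size[k]
      cur <- substr(s, mid + 1L, mid + 1L)
      prev <- substr(s, mid + 1L - u, mid + 1L - u)
      repl <- setdiff(c("A", "C", "G", "T"), c(cur, prev))[1]
      substr(s, mid + 1L, mid + 1L) <- repl
    }
  }
  s
}

#' @keywords internal
random_cds <- function(n_codons) {
  cds <- paste0("ATG",
                paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                      collapse = ""),
                "TAA")
  # break accidental tandem runs by re-drawing a codon inside each run
  for (i in 1:20) {
    hits <- msat_scan_linear(cds)
    if (!nrow(hits)) break
    for (k in seq_len(nrow(hits))) {
      ci <- (hits$start[k] + hits$len[k] %/% 2L) %/% 3L    # 0-based codon
      ci <- min(max(ci, 1L), n_codons - 2L)
      old <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
      repl <- sample(setdiff(SENSE_CODONS, old), 1L)
      substr(cds, 3L * ci + 1L, 3L * ci + 3L) <- repl
    }
  }
  cds
}

## main generator ------------------------------------------------------------

#' Generate a synthetic annotated circular genome with ground truth
#'
#' @param config a [synth_config()].
#' @param seed integer seed; the same seed reproduces the genome
#'   byte-for-byte.
#' @param out_dir optional directory: writes `genome.gb`, `genome.fasta`
#'   and `manifest.json` there.
#' @return list with elements `genome` (an [annotated_genome()]) and
#'   `manifest` (a `truth_manifest` list of data frames; see Details).
#' @details The manifest holds `gene_table`, `pseudogene_table`,
#'   `repeat_table` (+ `repeat_copies`), `microsat_table`, `editing_table`
#'   (+ planted site coordinates), `reconstitution_table` and an (initially
#'   empty) `rearrangement_log`.  All coordinates are 0-based half-open.
#' @export
generate_genome <- function(config = synth_config(), seed = 1L,
                            out_dir = NULL) {
  set.seed(seed)
  cfg <- config

  ## -- gene roster ----------------------------------------------------------
  prot <- MT_PROTEIN_GENES[seq_len(min(cfg$n_protein, length(MT_PROTEIN_GENES)))]
  rrna <- MT_RRNA_GENES[seq_len(min(cfg$n_rrna, length(MT_RRNA_GENES)))]
  trna <- MT_TRNA_GENES[seq_len(min(cfg$n_trna, length(MT_TRNA_GENES)))]

  genes <- list()
  for (g in prot) {
    n_codons <- 3L * sample(34:170, 1)  # CDS 306..1530 bp, multiple of 9 not needed
    genes[[g]] <- list(name = g, category = "protein",
                       cds = random_cds(n_codons))
  }
  for (g in rrna) {
    len <- switch(g, rrn5 = 119, rrn18 = 1598, rrn26 = 2812,
                  sample(900:2500, 1))
    genes[[g]] <- list(name = g, category = "rRNA",
                       cds = random_clean_dna(len, cfg$at))
  }
  for (g in trna) {
    genes[[g]] <- list(name = g, category = "tRNA",
                       cds = random_clean_dna(sample(72:85, 1), cfg$at))
  }

  ## -- reconstitution codon states -----------------------------------------
  rec <- cfg$reconstitution
  rec_tab <- data.frame(gene = character(0), kind = character(0))
  elig <- prot
  pick <- function(n) sample(elig, min(n, length(elig)))
  g_start <- pick(rec$start_acg)
  g_rm <- pick(rec$stop_removed)
  g_cr <- pick(rec$stop_created)
  for (g in g_start) {
    genes[[g]]$cds <- paste0("ACG", substr(genes[[g]]$cds, 4, nchar(genes[[g]]$cds)))
    rec_tab <- rbind(rec_tab, data.frame(gene = g, kind = "start_created"))
  }
  for (g in g_rm) {
    cds <- genes[[g]]$cds
    nc <- nchar(cds) / 3L
    j <- sample(3:(nc - 2L), 1)           # internal codon index
    substr(cds, 3L * (j - 1L) + 1L, 3L * j) <- sample(c("TAA", "TAG"), 1)
    genes[[g]]$cds <- cds
    rec_tab <- rbind(rec_tab, data.frame(gene = g, kind = "internal_stop_removed"))
  }
  for (g in g_cr) {
    cds <- genes[[g]]$cds
    substr(cds, nchar(cds) - 2L, nchar(cds)) <- sample(c("CAA", "CGA"), 1)
    genes[[g]]$cds <- cds
    rec_tab <- rbind(rec_tab, data.frame(gene = g, kind = "stop_created"))
  }

  ## -- planted editing sites ------------------------------------------------
  ed <- cfg$editing
  ed_gene <- NULL; ed_sites <- NULL; ed_ref <- NULL
  if ((ed$n_c2u + ed$n_u2c) > 0) {
    cand <- setdiff(prot, unique(rec_tab$gene))
    lens <- vapply(cand, function(g) nchar(genes[[g]]$cds), numeric(1))
    cand <- cand[lens >= 3 * (ed$n_c2u + ed$n_u2c) + 90]
    ed_gene <- cand[1]
    planted <- plant_editing_sites(genes[[ed_gene]]$cds, ed$n_c2u, ed$n_u2c)
    genes[[ed_gene]]$cds <- planted$cds
    ed_sites <- planted$sites
    ed_ref <- planted$ref_protein
  }

  ## -- introns --------------------------------------------------------------
  # intron-origin repeat classes need introns long enough to carve from
  rp <- cfg$repeats
  n_classes <- length(rp$lengths)
  need_long <- rp$lengths[rp$intron_origin]
  host_pool <- setdiff(prot, ed_gene)
  lens <- vapply(host_pool, function(g) nchar(genes[[g]]$cds), numeric(1))
  host_pool <- host_pool[lens >= 240]
  n_hosts <- max(1L, min(length(host_pool), ceiling(cfg$intron_total / 2)))
  hosts <- sample(host_pool, n_hosts)
  alloc <- rep(0L, n_hosts)
  for (i in seq_len(cfg$intron_total))
    alloc[(i - 1L) %% n_hosts + 1L] <- alloc[(i - 1L) %% n_hosts + 1L] + 1L
  alloc <- pmin(alloc, 3L)
  intron_seqs <- list()   # named by canonical intron name
  for (h in seq_along(hosts)) {
    g <- hosts[h]
    k <- alloc[h]
    if (k == 0L) next
    cds_len <- nchar(genes[[g]]$cds)
    pos <- sort(sample(seq(45L, cds_len - 45L, by = 3L), k))
    while (k > 1L && min(diff(pos)) < 60L)
      pos <- sort(sample(seq(45L, cds_len - 45L, by = 3L), k))
    ilens <- sample(400:1500, k, replace = TRUE)
    genes[[g]]$intron_pos <- pos
    genes[[g]]$intron_len <- ilens
    genes[[g]]$intron_seq <- lapply(ilens, random_clean_dna, at = cfg$at)
  }
  # guarantee material for intron-origin repeat classes
  if (length(need_long)) {
    withi <- hosts[alloc > 0L]
    picks <- sample(withi, length(need_long))
    for (i in seq_along(need_long)) {
      g <- picks[i]
      j <- which.max(genes[[g]]$intron_len)
      L_need <- need_long[i] + 80L
      if (genes[[g]]$intron_len[j] < L_need) {
        genes[[g]]$intron_len[j] <- L_need
        genes[[g]]$intron_seq[[j]] <- random_clean_dna(L_need, cfg$at)
      }
      attr(genes[[g]], "repeat_source") <-
        c(attr(genes[[g]], "repeat_source"), i)
    }
  }

  ## -- build genomic element sequences -------------------------------------
  # each element: name, category, strand, segments (exon/intron walk in
  # transcription order), total length
  elements <- list()
  for (g in names(genes)) {
    gn <- genes[[g]]
    if (is.null(gn$intron_pos)) {
      segs <- data.frame(type = "exon", len = nchar(gn$cds))
      gseq <- gn$cds
    } else {
      pos <- gn$intron_pos
      cds <- gn$cds
      bnd <- c(0L, pos, nchar(cds))
      ex <- substring(cds, head(bnd, -1) + 1L, bnd[-1])
      segs <- data.frame(type = character(0), len = numeric(0))
      gseq <- ""
      for (i in seq_along(ex)) {
        segs <- rbind(segs, data.frame(type = "exon", len = nchar(ex[i])))
        gseq <- paste0(gseq, ex[i])
        if (i <= length(pos)) {
          segs <- rbind(segs, data.frame(type = "intron", len = gn$intron_len[i]))
          gseq <- paste0(gseq, gn$intron_seq[[i]])
        }
      }
    }
    elements[[g]] <- list(name = g, category = gn$category,
                          strand = sample(c("+", "-"), 1),
                          segments = segs, seq = gseq, copy = 1L,
                          intron_pos = gn$intron_pos,
                          repeat_source = attr(gn, "repeat_source"))
  }

  ## -- rRNA cluster block (and optional duplicate) -------------------------
  cluster_names <- intersect(rrna, names(elements))
  cluster_block <- NULL
  if (cfg$duplicate_rrna_cluster && length(cluster_names) >= 2) {
    bl <- build_block(elements[cluster_names], cfg$at)
    cluster_block <- bl
    elements <- elements[setdiff(names(elements), cluster_names)]
  }

  ## tRNA duplicates: identical copies appended as separate elements
  dup_trna <- character(0)
  if (cfg$n_trna_duplicates > 0 && length(trna)) {
    dup_trna <- sample(trna, min(cfg$n_trna_duplicates, length(trna)),
                       replace = FALSE)
    for (g in dup_trna) {
      nm <- paste0(g, "#2")
      el <- elements[[g]]
      el$copy <- 2L
      el$strand <- sample(c("+", "-"), 1)
      elements[[nm]] <- el
    }
  }

  ## -- layout ---------------------------------------------------------------
  order_names <- sample(names(elements))
  placed <- elements[order_names]
  block_elems <- list()
  if (!is.null(cluster_block)) {
    # primary cluster + duplicate are placed as two opaque blocks
    placed <- append(placed, list(`__cluster1__` = list(
      name = "__cluster1__", category = "block", seq = cluster_block$seq)),
      after = sample(0:length(placed), 1))
    placed <- append(placed, list(`__cluster2__` = list(
      name = "__cluster2__", category = "block",
      seq = if (cfg$inverted_rrna_cluster) revcomp(cluster_block$seq)
            else cluster_block$seq)),
      after = sample(0:length(placed), 1))
  }
  elem_bp <- sum(vapply(placed, function(e) nchar(e$seq), numeric(1)))
  n_sp <- length(placed)
  spacer_total <- cfg$genome_size - elem_bp
  planted_bp <- est_planted_bp(cfg)
  if (spacer_total < planted_bp + 60L * n_sp)
    stop(sprintf(paste0("infeasible config: %d bp of features + %d bp of ",
                        "planted spacer content exceed genome size %d"),
                 elem_bp, planted_bp, cfg$genome_size))
  w <- stats::rgamma(n_sp, shape = 2)
  sp_len <- 60L + floor((spacer_total - 60L * n_sp) * w / sum(w))
  sp_len[1L] <- sp_len[1L] + (spacer_total - sum(sp_len))

  ## coordinates: spacer_i then element_i, i = 1..n_sp
  features <- list()
  gene_rows <- list()
  spacers <- list()    # per spacer: start, len, free gaps
  pos <- 0L
  for (i in seq_along(placed)) {
    spacers[[i]] <- list(start = pos, len = sp_len[i], occ = list())
    pos <- pos + sp_len[i]
    e <- placed[[i]]
    elen <- nchar(e$seq)
    if (e$category == "block") {
      inv <- identical(e$name, "__cluster2__") && cfg$inverted_rrna_cluster
      bf <- block_features(cluster_block, pos, elen, inverted = inv,
                           copy = if (e$name == "__cluster1__") 1L else 2L)
      features <- c(features, bf)
      placed[[i]]$start <- pos
    } else {
      f <- element_feature(e, pos)
      features <- c(features, list(f))
      placed[[i]]$start <- pos
    }
    pos <- pos + elen
  }
  stopifnot(pos == cfg$genome_size)

  ## -- spacer content -------------------------------------------------------
  spacer_seq <- lapply(spacers, function(s) random_clean_dna(s$len, cfg$at))

  alloc_slot <- function(len) {
    # returns c(spacer_index, offset) honouring 15 bp buffers
    ok <- sample(seq_along(spacers))
    for (i in ok) {
      gaps <- free_gaps(spacers[[i]], len + 30L)
      if (nrow(gaps)) {
        g <- gaps[sample(nrow(gaps), 1L), ]
        off <- g$start + 15L +
          sample.int(max(1L, g$len - len - 30L), 1L) - 1L
        spacers[[i]]$occ <<- c(spacers[[i]]$occ, list(c(off, off + len)))
        return(c(i, off))
      }
    }
    stop("infeasible config: no spacer slot for a planted element of ",
         len, " bp")
  }
  put <- function(slot, s) {
    i <- slot[1L]; off <- slot[2L]
    substr(spacer_seq[[i]], off + 1L, off + nchar(s)) <<- s
    spacers[[i]]$start + off
  }

  ## pseudogene fragments
  ps <- plant_pseudogenes(cfg, placed, alloc_slot, put)

  ## repeat classes
  rep_out <- plant_repeats(cfg, placed, alloc_slot, put)
  if (!is.null(cluster_block)) {
    blen <- nchar(cluster_block$seq)
    c1 <- placed[["__cluster1__"]]$start
    c2 <- placed[["__cluster2__"]]$start
    ori <- if (cfg$inverted_rrna_cluster) "inverted" else "direct"
    rep_out$classes <- rbind(rep_out$classes, data.frame(
      class = "rrn_cluster", length_bp = blen, n_copies = 2L,
      orientation = ori, edits = 0L,
      origin = paste(names(cluster_block$offsets), collapse = ", "),
      stringsAsFactors = FALSE))
    rep_out$copies <- rbind(rep_out$copies, data.frame(
      class = "rrn_cluster", copy = 1:2, start = c(c1, c2),
      end = c(c1 + blen, c2 + blen),
      orientation = c("+", if (ori == "inverted") "-" else "+"),
      stringsAsFactors = FALSE))
  }

  ## microsatellites
  ms_out <- plant_microsats(cfg, alloc_slot, put)

  ## -- assemble -------------------------------------------------------------
  chunks <- character(2L * n_sp)
  for (i in seq_along(placed)) {
    chunks[2L * i - 1L] <- spacer_seq[[i]]
    e <- placed[[i]]
    # gene sequences are built in transcription orientation; minus-strand
    # genes enter the genome as their reverse complement
    chunks[2L * i] <- if (e$category != "block" && e$strand == "-")
      revcomp(e$seq) else e$seq
  }
  sequence <- paste(chunks, collapse = "")
  stopifnot(nchar(sequence) == cfg$genome_size)

  genome <- annotated_genome(sprintf("synth_%d", seed), sequence,
                             is_circular = TRUE, features = features)

  ## scrub microsatellite runs that arose across chunk boundaries
  genome <- scrub_boundary_msats(genome, ms_out$tab, protect = ps$tab,
                                 protect2 = rep_out$copies)

  gene_tab <- do.call(rbind, lapply(genome$features, function(f) {
    sp <- feature_span(f, genome$length_bp)
    data.frame(gene = f$name, category = f$category, strand = f$strand,
               copy = f$copy_index, start = sp[1L], end = sp[2L],
               n_introns = length(f$introns), is_pseudo = f$is_pseudo)
  }))

  manifest <- structure(list(
    seed = seed, genome_size = cfg$genome_size,
    gene_table = gene_tab,
    pseudogene_table = ps$tab,
    repeat_table = rep_out$classes,
    repeat_copies = rep_out$copies,
    microsat_table = ms_out$tab,
    editing_table = if (is.null(ed_gene)) NULL else
      list(gene = ed_gene, ref_protein = ed_ref, sites = ed_sites,
           n_c2u = sum(ed_sites$direction == "C>U"),
           n_u2c = sum(ed_sites$direction == "U>C")),
    reconstitution_table = rec_tab,
    rearrangement_log = data.frame()), class = "truth_manifest")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genbank(genome, file.path(out_dir, "genome.gb"))
    write_fasta(genome, file.path(out_dir, "genome.fasta"))
    jsonlite::write_json(manifest_json(manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(genome = genome, manifest = manifest)
}

#' @keywords internal
manifest_json <- function(m) {
  lapply(unclass(m), function(x) if (is.data.frame(x) || is.list(x)) x else x)
}

#' @keywords internal
est_planted_bp <- function(cfg) {
  p <- cfg$pseudo$n * mean(cfg$pseudo$len_range)
  r <- sum(cfg$repeats$lengths * cfg$repeats$n_copies)
  m <- sum(cfg$microsat * c(di = 2, tri = 3, tetra = 4, penta = 5,
                            hexa = 6)[names(cfg$microsat)] * 8)
  ceiling(p + r + m + 40 * (cfg$pseudo$n + sum(cfg$repeats$n_copies) +
                              sum(cfg$microsat)))
}

#' @keywords internal
free_gaps <- function(sp, need) {
  occ <- sp$occ
  if (!length(occ)) {
    if (sp$len >= need) return(data.frame(start = 0L, len = sp$len))
    return(data.frame(start = integer(0), len = integer(0)))
  }
  occ <- do.call(rbind, occ)
  occ <- occ[order(occ[, 1L]), , drop = FALSE]
  starts <- c(0L, occ[, 2L])
  ends <- c(occ[, 1L], sp$len)
  gl <- ends - starts
  keep <- gl >= need
  data.frame(start = starts[keep], len = gl[keep])
}

## element -> feature --------------------------------------------------------

#' @keywords internal
element_feature <- function(e, pos) {
  segs <- e$segments
  elen <- nchar(e$seq)
  # walk transcription-order segments; map to genomic coordinates
  exons <- list(); introns <- list()
  cursor <- 0
  exon_cds_end <- 0
  k_intron <- 0L
  for (r in seq_len(nrow(segs))) {
    len <- segs$len[r]
    if (e$strand == "+") iv <- c(pos + cursor, pos + cursor + len)
    else iv <- c(pos + elen - cursor - len, pos + elen - cursor)
    if (segs$type[r] == "exon") {
      exons <- c(exons, list(iv))
      exon_cds_end <- exon_cds_end + len
    } else {
      k_intron <- k_intron + 1L
      introns <- c(introns, list(intron_record(
        e$name, insertion_pos = exon_cds_end, group = "g2",
        splicing = "cis", interval = iv)))
    }
    cursor <- cursor + len
  }
  gene_feature(e$name, e$category, e$strand, exons, introns,
               copy_index = e$copy)
}

#' @keywords internal
build_block <- function(els, at) {
  # concatenate elements with small internal spacers; remember offsets
  seqs <- character(0); offs <- list(); pos <- 0L
  for (nm in names(els)) {
    gap <- random_clean_dna(sample(60:180, 1), at)
    seqs <- c(seqs, gap)
    pos <- pos + nchar(gap)
    offs[[nm]] <- c(pos, pos + nchar(els[[nm]]$seq))
    seqs <- c(seqs, els[[nm]]$seq)
    pos <- pos + nchar(els[[nm]]$seq)
  }
  list(seq = paste(seqs, collapse = ""), offsets = offs, elements = els)
}

#' @keywords internal
block_features <- function(block, pos, blen, inverted, copy) {
  out <- list()
  for (nm in names(block$offsets)) {
    off <- block$offsets[[nm]]
    e <- block$elements[[nm]]
    e$copy <- copy
    if (!inverted) {
      f <- element_feature(e, pos + off[1L])
    } else {
      e$strand <- if (e$strand == "+") "-" else "+"
      f <- element_feature(e, pos + blen - off[2L])
    }
    out <- c(out, list(f))
  }
  out
}
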