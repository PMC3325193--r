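# Annotated circular genome model: containers, partition accounting,
# signed gene orders, intron nomenclature.
#
# All coordinates are 0-based half-open internally; reports and GenBank I/O
# use the 1-based inclusive convention.  An interval c(start, end) with
# end > length_bp wraps around the origin of a circular molecule.

#' Construct an annotated (possibly circular) genome
#'
#' The central container of the package: a DNA sequence plus strand-aware
#' multi-exon gene features, the shape a plant mitochondrial (chondrome)
#' annotation takes.
#'
#' @param identifier character scalar naming the genome.
#' @param sequence DNA string over A/C/G/T/N (case-insensitive).
#' @param is_circular logical; wrap-around feature coordinates are only
#'   accepted on circular molecules.
#' @param features list of [gene_feature()] objects.
#' @return An object of class `annotated_genome` with elements `identifier`,
#'   `sequence`, `length_bp`, `is_circular`, `features`.
#' @export
annotated_genome <- function(identifier, sequence, is_circular = TRUE,
                             features = list()) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside A/C/G/T/N")
  L <- nchar(sequence)
  if (L < 1L) stop("empty sequence")
  g <- structure(
    list(identifier = identifier, sequence = sequence, length_bp = L,
         is_circular = isTRUE(is_circular), features = features),
    class = "annotated_genome")
  validate_genome(g)
  g
}

#' @keywords internal
validate_genome <- function(g) {
  L <- g$length_bp
  stopifnot(L == nchar(g$sequence))
  for (f in g$features) {
    for (iv in f$exons) {
      if (iv[1L] < 0 || iv[1L] >= L || iv[2L] <= iv[1L] || iv[2L] > iv[1L] + L)
        stop(sprintf("feature '%s': exon interval [%d,%d) out of range",
                     f$name, iv[1L], iv[2L]))
      if (iv[2L] > L && !g$is_circular)
        stop(sprintf("feature '%s': wrap-around interval on a linear molecule",
                     f$name))
    }
  }
  invisible(g)
}

#' Construct a gene feature
#'
#' @param name gene symbol (e.g. `"nad5"`, `"rrn26"`, `"trnYgua"`).
#' @param category one of `"protein"`, `"rRNA"`, `"tRNA"`.
#' @param strand `"+"` or `"-"`.
#' @param exons list of 0-based half-open intervals, ordered along the
#'   transcription direction (for `"-"` strand genes the first exon is the
#'   rightmost on the genome).
#' @param introns list of [intron_record()] objects; for a cis-spliced gene
#'   there is one intron between each pair of consecutive exons.
#' @param is_pseudo logical pseudogene flag.
#' @param copy_index integer >= 1 distinguishing duplicated copies.
#' @export
gene_feature <- function(name, category = c("protein", "rRNA", "tRNA"),
                         strand = c("+", "-"), exons, introns = list(),
                         is_pseudo = FALSE, copy_index = 1L) {
  category <- match.arg(category)
  strand <- match.arg(strand)
  exons <- lapply(exons, as.numeric)
  structure(list(name = name, category = category, strand = strand,
                 exons = exons, introns = introns,
                 is_pseudo = isTRUE(is_pseudo),
                 copy_index = as.integer(copy_index)),
            class = "gene_feature")
}

#' Construct an intron record
#'
#' Plant mitochondrial group II introns are named by host gene, 1-based
#' insertion position in a reference ortholog coding sequence, and intron
#' group, e.g. `nad1i728g2`.
#'
#' @param host_gene gene symbol of the host.
#' @param insertion_pos 1-based nucleotide position in the reference CDS
#'   5' of the insertion point.
#' @param group `"g1"` or `"g2"`.
#' @param splicing `"cis"` or `"trans"`.
#' @param interval genomic half-open interval of the intron.
#' @export
intron_record <- function(host_gene, insertion_pos, group = c("g2", "g1"),
                          splicing = c("cis", "trans"), interval) {
  group <- match.arg(group)
  splicing <- match.arg(splicing)
  structure(list(host_gene = host_gene,
                 insertion_pos = as.integer(insertion_pos),
                 group = group, splicing = splicing,
                 interval = as.numeric(interval)),
            class = "intron_record")
}

#' Canonical intron name (geneiNNNgK convention)
#' @param intron an [intron_record()].
#' @return character scalar such as `"nad1i728g2"`.
#' @export
intron_name <- function(intron) {
  paste0(intron$host_gene, "i", intron$insertion_pos, intron$group)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %s, %d features\n",
              x$identifier, format(x$length_bp, big.mark = ","),
              if (x$is_circular) "circular" else "linear",
              length(x$features)))
  invisible(x)
}

## sequence extraction -------------------------------------------------------

#' Genomic span of a feature (leftmost exon start to rightmost exon end)
#' @keywords internal
feature_span <- function(f, L) {
  s <- vapply(f$exons, `[`, numeric(1), 1L)
  e <- vapply(f$exons, `[`, numeric(1), 2L)
  # exons are stored in transcription order; on the genome the span runs
  # from the minimal start to the maximal end (wrap handled by end > L)
  c(min(s), max(e))
}

#' Spliced (exon-joined) sequence of a gene, in transcription orientation
#' @param genome an [annotated_genome()].
#' @param f a [gene_feature()] of `genome`.
#' @export
spliced_seq <- function(genome, f) {
  parts <- vapply(f$exons, function(iv)
    iv_seq(genome$sequence, iv, genome$length_bp), character(1))
  if (f$strand == "-") parts <- vapply(parts, revcomp, character(1))
  paste(parts, collapse = "")
}

#' Unspliced (genomic) sequence of a gene span, in transcription orientation
#' @inheritParams spliced_seq
#' @export
unspliced_seq <- function(genome, f) {
  s <- iv_seq(genome$sequence, feature_span(f, genome$length_bp),
              genome$length_bp)
  if (f$strand == "-") s <- revcomp(s)
  s
}

## partition accounting ------------------------------------------------------

#' AT content of a genome
#'
#' @param genome an [annotated_genome()].
#' @return percentage 100 * (A + T) / (A + C + G + T); `N` is excluded from
#'   the denominator.
#' @export
at_content <- function(genome) {
  f <- table(strsplit(genome$sequence, "")[[1]])
  n <- function(b) if (b %in% names(f)) as.numeric(f[[b]]) else 0
  denom <- n("A") + n("C") + n("G") + n("T")
  if (denom == 0) stop("AT content undefined: no unambiguous bases")
  100 * (n("A") + n("T")) / denom
}

#' Partition a genome into exon, intron and spacer fractions
#'
#' Classifies every position exactly once with priority exon > intron >
#' spacer.  Pseudogene-flagged features count as spacer; duplicated gene
#' copies count toward the exon/intron totals.
#'
#' @param genome an [annotated_genome()].
#' @return An object of class `partition_stats`: `genome_bp`, `at_percent`,
#'   `exon_bp`, `intron_bp`, `spacer_bp` and the corresponding percentages
#'   (`gene_pct = exon_pct + intron_pct`).
#' @export
partition <- function(genome) {
  L <- genome$length_bp
  exon_mask <- logical(L)
  intron_mask <- logical(L)
  raw_exon_bp <- 0
  for (f in genome$features) {
    if (f$is_pseudo) next
    for (iv in f$exons) {
      exon_mask <- iv_mark(exon_mask, iv, L)
      raw_exon_bp <- raw_exon_bp + iv_width(iv)
    }
    for (intr in f$introns)
      intron_mask <- iv_mark(intron_mask, intr$interval, L)
  }
  if (raw_exon_bp > sum(exon_mask))
    warning("overlapping exon annotations counted once")
  intron_mask <- intron_mask & !exon_mask
  exon_bp <- sum(exon_mask)
  intron_bp <- sum(intron_mask)
  spacer_bp <- L - exon_bp - intron_bp
  pct <- function(x) 100 * x / L
  structure(list(genome_bp = L, at_percent = at_content(genome),
                 exon_bp = exon_bp, intron_bp = intron_bp,
                 spacer_bp = spacer_bp,
                 exon_pct = pct(exon_bp), intron_pct = pct(intron_bp),
                 gene_pct = pct(exon_bp + intron_bp),
                 spacer_pct = pct(spacer_bp)),
            class = "partition_stats")
}

#' @export
print.partition_stats <- function(x, digits = 1, ...) {
  cat(sprintf(
    "genome %s bp | AT %.1f%% | genes %.*f%% (exons %.*f%%, introns %.*f%%) | spacers %.*f%%\n",
    format(x$genome_bp, big.mark = ","), x$at_percent,
    digits, x$gene_pct, digits, x$exon_pct, digits, x$intron_pct,
    digits, x$spacer_pct))
  invisible(x)
}

#' Intergenic spacer intervals of a genome
#'
#' The complement of all functional (non-pseudogene) feature spans, exons
#' and introns included.  Pseudogene-annotated features fall in spacers.
#'
#' @param genome an [annotated_genome()].
#' @return list of 0-based half-open intervals (the interval spanning the
#'   origin of a circular genome may wrap).
#' @export
spacer_intervals <- function(genome) {
  ivs <- list()
  for (f in genome$features) {
    if (f$is_pseudo) next
    ivs <- c(ivs, f$exons, lapply(f$introns, `[[`, "interval"))
  }
  iv_complement(ivs, genome$length_bp, genome$is_circular)
}

## gene order ----------------------------------------------------------------

#' Signed (cyclic) gene order of a genome
#'
#' Features are ordered by leftmost exon start; the sign records the strand.
#' Duplicated genes keep their `copy_index`.
#'
#' @param genome an [annotated_genome()].
#' @param include_trna keep tRNA genes in the order?
#' @param include_pseudo keep pseudogene features? Default drops them.
#' @return An object of class `gene_order`; see [gene_order_obj()].
#' @export
gene_order <- function(genome, include_trna = TRUE, include_pseudo = FALSE) {
  keep <- vapply(genome$features, function(f) {
    (include_trna || f$category != "tRNA") &&
      (include_pseudo || !f$is_pseudo)
  }, logical(1))
  fs <- genome$features[keep]
  if (!length(fs))
    return(gene_order_obj(genome$identifier, character(0), character(0),
                          integer(0)))
  starts <- vapply(fs, function(f) feature_span(f, genome$length_bp)[1L],
                   numeric(1))
  o <- order(starts)
  gene_order_obj(genome$identifier,
                 vapply(fs, `[[`, character(1), "name")[o],
                 vapply(fs, `[[`, character(1), "strand")[o],
                 vapply(fs, `[[`, integer(1), "copy_index")[o])
}

#' Construct a signed circular gene order
#'
#' @param genome_id identifier.
#' @param gene character vector of gene symbols, in cyclic order.
#' @param strand character vector of `"+"`/`"-"`.
#' @param copy integer vector of copy indices (default all 1).
#' @return object of class `gene_order` wrapping a data.frame with columns
#'   `gene`, `strand`, `copy`.
#' @export
gene_order_obj <- function(genome_id, gene, strand, copy = rep(1L, length(gene))) {
  stopifnot(length(gene) == length(strand), length(gene) == length(copy),
            all(strand %in% c("+", "-")))
  structure(list(genome_id = genome_id,
                 tab = data.frame(gene = as.character(gene),
                                  strand = as.character(strand),
                                  copy = as.integer(copy),
                                  stringsAsFactors = FALSE)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s (circular, %d elements)\n %s\n",
              x$genome_id, nrow(x$tab),
              paste0(x$tab$strand, x$tab$gene, collapse = " ")))
  invisible(x)
}

#' Parse a signed gene order from compact text
#'
#' @param genome_id identifier.
#' @param txt character vector of signed labels, e.g. `c("+nad5","-cob")`,
#'   or a single whitespace-separated string.
#' @export
parse_gene_order <- function(genome_id, txt) {
  if (length(txt) == 1L) txt <- strsplit(trimws(txt), "\\s+")[[1]]
  sgn <- ifelse(substr(txt, 1, 1) == "-", "-", "+")
  lab <- sub("^[+-]", "", txt)
  copy <- stats::ave(seq_along(lab), lab, FUN = seq_along)
  gene_order_obj(genome_id, lab, sgn, as.integer(copy))
}

## rotation ------------------------------------------------------------------

#' Rotate the sequence origin of a circular genome
#'
#' Shifts all coordinates so that position `offset` (0-based) becomes the
#' new origin; the cyclic structure is unchanged.
#'
#' @param genome a circular [annotated_genome()].
#' @param offset integer in `[0, length_bp)`.
#' @export
rotate_genome <- function(genome, offset) {
  stopifnot(genome$is_circular)
  L <- genome$length_bp
  offset <- offset %% L
  if (offset == 0) return(genome)
  seq2 <- paste0(substr(genome$sequence, offset + 1L, L),
                 substr(genome$sequence, 1L, offset))
  shift_iv <- function(iv) {
    s <- (iv[1L] - offset) %% L
    c(s, s + iv_width(iv))
  }
  feats <- lapply(genome$features, function(f) {
    f$exons <- lapply(f$exons, shift_iv)
    f$introns <- lapply(f$introns, function(it) {
      it$interval <- shift_iv(it$interval); it
    })
    f
  })
  annotated_genome(genome$identifier, seq2, TRUE, feats)
}
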