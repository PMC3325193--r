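# Internal helpers shared across modules: sequence utilities and circular
# interval arithmetic.  Intervals are 0-based half-open `c(start, end)` with
# 0 <= start < L and start < end <= start + L; end > L encodes wrap-around
# on a circular molecule.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# data.table subsetting semantics inside this package
.datatable.aware <- TRUE

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @keywords internal
random_dna <- function(n, at = 0.5) {
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## interval helpers ----------------------------------------------------------

iv_width <- function(iv) iv[2L] - iv[1L]

#' Split a possibly wrapping interval into linear pieces
#' @keywords internal
iv_pieces <- function(iv, L) {
  stopifnot(iv[1L] >= 0, iv[1L] < L, iv[2L] > iv[1L], iv[2L] <= iv[1L] + L)
  if (iv[2L] <= L) list(iv) else list(c(iv[1L], L), c(0, iv[2L] - L))
}

#' Extract the genomic subsequence of an interval (plus strand)
#' @keywords internal
iv_seq <- function(sequence, iv, L = nchar(sequence)) {
  paste(vapply(iv_pieces(iv, L),
               function(p) substr(sequence, p[1L] + 1L, p[2L]),
               character(1)), collapse = "")
}

#' Mark interval positions in a logical mask of length L
#' @keywords internal
iv_mark <- function(mask, iv, L) {
  for (p in iv_pieces(iv, L)) mask[seq.int(p[1L] + 1L, p[2L])] <- TRUE
  mask
}

#' Do two circular intervals overlap?
#' @keywords internal
iv_overlaps <- function(a, b, L) {
  pa <- iv_pieces(a, L); pb <- iv_pieces(b, L)
  for (x in pa) for (y in pb) if (x[1L] < y[2L] && y[1L] < x[2L]) return(TRUE)
  FALSE
}

#' Overlap width of two circular intervals
#' @keywords internal
iv_overlap_bp <- function(a, b, L) {
  tot <- 0L
  for (x in iv_pieces(a, L)) for (y in iv_pieces(b, L))
    tot <- tot + max(0L, min(x[2L], y[2L]) - max(x[1L], y[1L]))
  tot
}

#' Complement of a set of intervals on a (possibly circular) sequence
#'
#' @param ivs list of intervals.
#' @return list of non-wrapping intervals covering every unmarked position.
#' @keywords internal
iv_complement <- function(ivs, L, circular = TRUE) {
  mask <- logical(L)
  for (iv in ivs) mask <- iv_mark(mask, iv, L)
  free <- which(!mask)
  if (!length(free)) return(list())
  r <- rle(diff(free))
  ends <- cumsum(c(1L, r$lengths))  # not used; build runs directly
  runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
  out <- lapply(runs, function(p) c(p[1L] - 1L, p[length(p)]))
  names(out) <- NULL
  # merge a run touching the origin with a run touching the end (circular)
  if (circular && length(out) > 1L) {
    first <- out[[1L]]; last <- out[[length(out)]]
    if (first[1L] == 0L && last[2L] == L) {
      out[[length(out)]] <- c(last[1L], L + first[2L])
      out <- out[-1L]
    }
  }
  out
}

## codon helpers -------------------------------------------------------------

GENETIC_CODE1 <- Biostrings::GENETIC_CODE

#' Translate a DNA coding sequence codon-wise (standard code; "*" for stop)
#' @keywords internal
translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- GENETIC_CODE1[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Canonical (lexicographically minimal) rotation of a repeat unit
#' @keywords internal
canonical_rotation <- function(unit) {
  n <- nchar(unit)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(unit, i, n), substr(unit, 1, i - 1L)), character(1))
  min(rots)
}

#' Is a tandem unit a power of a shorter unit?
#' @keywords internal
is_self_periodic <- function(unit) {
  n <- nchar(unit)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L &&
        unit == paste(rep(substr(unit, 1, d), n / d), collapse = ""))
      return(TRUE)
  }
  FALSE
}

#' Simple union-find used to merge repeat pairs into classes
#' @keywords internal
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) { while (uf[i] != i) i <- uf[i]; i }
uf_union <- function(uf, i, j) {
  ri <- uf_find(uf, i); rj <- uf_find(uf, j)
  if (ri != rj) uf[ri] <- rj
  uf
}
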