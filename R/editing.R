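# RNA-editing inference.
#
# Two complementary routes, as used for plant chondromes without cDNA
# evidence: (i) codon reconstitution -- obligatory edits implied by the
# genomic sequence alone (ACG starts, internal genomic stops, missing
# stops recoverable as CAA/CGA); (ii) comparative prediction against an
# unedited reference protein, assigning to each discrepant codon the
# minimal set of C<->U changes that restores the reference residue.

#' Infer obligatory editing events by codon reconstitution
#'
#' One `start_created` event iff the first codon is ACG (edited ACG -> AUG);
#' one `internal_stop_removed` per internal genomic TAA/TAG (transcript
#' UAA/UAG -> CAA/CAG, a U-to-C edit); one `stop_created` iff the final
#' codon is CAA or CGA and the annotated CDS has no genomic stop.  GTG is
#' accepted as a genomic start for genes listed in `gtg_start_genes`.
#' Internal TGA cannot be rescued by a C<->U edit and is flagged with a
#' warning instead of an event.
#'
#' @param cds DNA coding sequence (exon-joined), length divisible by 3.
#' @param gene gene symbol, used in reports and for the GTG-start exception.
#' @param gtg_start_genes genes whose genomic start codon is GTG.
#' @return data.frame of events with columns `gene`, `kind`, `codon_pos`,
#'   `from_codon`, `to_codon` (RNA triplets) and `direction`
#'   (`"C>U"`/`"U>C"`).
#' @export
reconstitute <- function(cds, gene = "", gtg_start_genes = "rpl16") {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0)
    stop(sprintf("CDS of '%s' has length %d, not a multiple of 3",
                 gene, nchar(cds)))
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  nc <- length(codons)
  ev <- list()
  add <- function(kind, pos, from, to, dir)
    ev[[length(ev) + 1L]] <<- data.frame(
      gene = gene, kind = kind, codon_pos = pos,
      from_codon = from, to_codon = to, direction = dir,
      stringsAsFactors = FALSE)
  first <- codons[1L]
  if (first == "ACG") add("start_created", 1L, "ACG", "AUG", "C>U")
  else if (!(first == "ATG" || (first == "GTG" && gene %in% gtg_start_genes)))
    warning(sprintf("gene '%s': unusual genomic start codon %s", gene, first))
  if (nc > 2L) for (j in 2:(nc - 1L)) {
    cj <- codons[j]
    if (cj == "TAA") add("internal_stop_removed", j, "UAA", "CAA", "U>C")
    else if (cj == "TAG") add("internal_stop_removed", j, "UAG", "CAG", "U>C")
    else if (cj == "TGA")
      warning(sprintf(
        "gene '%s': internal TGA at codon %d cannot be restored by C<->U editing",
        gene, j))
  }
  last <- codons[nc]
  if (last == "CAA") add("stop_created", nc, "CAA", "UAA", "C>U")
  else if (last == "CGA") add("stop_created", nc, "CGA", "UGA", "C>U")
  else if (!(last %in% c("TAA", "TAG", "TGA")))
    warning(sprintf("gene '%s': no genomic stop codon and no editable %s",
                    gene, last))
  if (!length(ev))
    return(data.frame(gene = character(0), kind = character(0),
                      codon_pos = integer(0), from_codon = character(0),
                      to_codon = character(0), direction = character(0)))
  do.call(rbind, ev)
}

#' Build a minimal CDS embodying annotated codon states
#'
#' Expands a gene's annotated start/internal-stop/terminal codon states
#' (as collected in reconstitution surveys) into a minimal coding sequence
#' on which [reconstitute()] can run: the given start codon, a padding of
#' alanine codons around each listed internal stop, and the given terminal
#' codon.
#'
#' @param start_codon genomic first codon (`"ATG"`, `"ACG"`, `"GTG"`...).
#' @param internal_stops character vector of genomic internal stop codons
#'   (`"TAA"`/`"TAG"`), or `"-"`/empty for none.
#' @param terminal_codon genomic final codon (`"TAA"`, `"CAA"`, `"CGA"`...).
#' @param pad number of padding codons between the listed codons.
#' @return DNA string, length a multiple of 3.
#' @export
codon_state_cds <- function(start_codon, internal_stops = character(0),
                            terminal_codon = "TAA", pad = 6L) {
  internal_stops <- internal_stops[!(internal_stops %in% c("-", "", NA))]
  padding <- strrep("GCT", pad)
  body <- paste0(vapply(internal_stops, function(s) paste0(s, padding),
                        character(1)), collapse = "")
  paste0(start_codon, padding, body, terminal_codon)
}

#' @keywords internal
min_cu_edits <- function(codon, target_aa) {
  # minimal C<->T substitution set turning `codon` into a codon encoding
  # target_aa; ties broken toward more C>U (C->T) edits.
  # Returns c(c2u, u2c) or NULL when unexplainable by C<->U editing.
  bases <- strsplit(codon, "")[[1]]
  editable <- which(bases %in% c("C", "T"))
  best <- NULL
  for (mask in 0:(2^length(editable) - 1L)) {
    sel <- editable[bitwAnd(mask, 2^(seq_along(editable) - 1L)) > 0L]
    nb <- bases
    nb[sel] <- ifelse(nb[sel] == "C", "T", "C")
    cand <- paste(nb, collapse = "")
    if (identical(unname(GENETIC_CODE1[cand]), target_aa)) {
      c2u <- sum(bases[sel] == "C")
      u2c <- sum(bases[sel] == "T")
      n <- c2u + u2c
      if (is.null(best) || n < sum(best) ||
          (n == sum(best) && c2u > best[1L]))
        best <- c(c2u, u2c)
    }
  }
  best
}

#' Predict C-to-U and U-to-C editing sites against an unedited reference
#'
#' The translated CDS is globally aligned to the reference protein; each
#' aligned codon whose translation differs from the reference residue
#' contributes the minimal number of C<->U substitutions that makes the
#' codon encode that residue (ties resolved toward more C-to-U, the
#' predominant direction of plant organelle editing).  Gap columns and
#' codons unexplainable by C<->U changes contribute nothing.
#'
#' @param cds DNA coding sequence, length divisible by 3.
#' @param reference reference as an amino-acid sequence, or a cDNA/DNA
#'   sequence (translated first).
#' @param gene gene symbol for reporting.
#' @param reference_name label of the reference set (e.g. the species).
#' @param score_floor minimal acceptable global alignment score.
#' @return object of class `editing_prediction`: `gene`, `c_to_u`,
#'   `u_to_c`, `total`, `reference_name`.
#' @export
predict_edits <- function(cds, reference, gene = "",
                          reference_name = "reference", score_floor = 0) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0)
    stop(sprintf("CDS of '%s' has length %d, not a multiple of 3",
                 gene, nchar(cds)))
  reference <- toupper(gsub("\\s", "", reference))
  if (!grepl("[^ACGTUN]", reference)) {
    reference <- gsub("U", "T", reference)
    if (nchar(reference) %% 3 != 0)
      stop(sprintf("cDNA reference for '%s' not a multiple of 3", gene))
    reference <- translate_cds(reference)
  }
  reference <- sub("\\*$", "", reference)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- unname(GENETIC_CODE1[codons]); aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
    codons <- codons[-length(codons)]
  }
  pat <- paste(aa, collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(gsub("\\*", "X", pat)),
    Biostrings::AAString(gsub("\\*", "X", reference)),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  if (Biostrings::score(aln) < score_floor)
    stop(sprintf("no acceptable alignment of '%s' to reference '%s' (score %.1f)",
                 gene, reference_name, Biostrings::score(aln)))
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_chars <- strsplit(reference, "")[[1]]
  c2u <- 0L; u2c <- 0L
  ci <- 0L; ri <- 0L
  for (col in seq_along(p)) {
    if (p[col] != "-") ci <- ci + 1L
    if (s[col] != "-") ri <- ri + 1L
    if (p[col] == "-" || s[col] == "-") next
    target <- ref_chars[ri]               # original residue (X-masking aside)
    if (aa[ci] == target) next
    e <- min_cu_edits(codons[ci], target)
    if (!is.null(e)) { c2u <- c2u + e[1L]; u2c <- u2c + e[2L] }
  }
  structure(list(gene = gene, c_to_u = c2u, u_to_c = u2c,
                 total = c2u + u2c, reference_name = reference_name),
            class = "editing_prediction")
}

#' @export
print.editing_prediction <- function(x, ...) {
  cat(sprintf("%s vs %s: %d C>U + %d U>C = %d predicted edits\n",
              x$gene, x$reference_name, x$c_to_u, x$u_to_c, x$total))
  invisible(x)
}

#' Aggregate per-gene editing predictions into per-reference totals
#'
#' @param predictions list of `editing_prediction` objects, or a
#'   data.frame with columns `gene`, `reference_name` (or `reference`),
#'   `c_to_u`, `u_to_c` (and optionally `total`).
#' @return data.frame with one row per reference: `reference_name`,
#'   `n_genes`, `c_to_u`, `u_to_c`, `total`.
#' @export
aggregate_edits <- function(predictions) {
  if (is.data.frame(predictions)) df <- predictions
  else df <- do.call(rbind, lapply(predictions, function(p)
    data.frame(gene = p$gene, reference_name = p$reference_name,
               c_to_u = p$c_to_u, u_to_c = p$u_to_c,
               stringsAsFactors = FALSE)))
  if (is.null(df) || !nrow(df))
    return(data.frame(reference_name = character(0), n_genes = integer(0),
                      c_to_u = integer(0), u_to_c = integer(0),
                      total = integer(0)))
  if (!"reference_name" %in% names(df) && "reference" %in% names(df))
    names(df)[names(df) == "reference"] <- "reference_name"
  agg <- stats::aggregate(cbind(c_to_u, u_to_c) ~ reference_name, df, sum)
  agg$n_genes <- stats::aggregate(gene ~ reference_name, df,
                                  function(x) length(unique(x)))$gene
  agg$total <- agg$c_to_u + agg$u_to_c
  agg[, c("reference_name", "n_genes", "c_to_u", "u_to_c", "total")]
}
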