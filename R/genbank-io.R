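# GenBank flat-file, FASTA and GFF3 input/output for annotated genomes.
#
# The GenBank parser is deliberately small: it understands LOCUS, the
# FEATURES table (gene/CDS/rRNA/tRNA/intron keys with join/complement
# locations) and ORIGIN, which covers organelle records.  Coordinates are
# converted between GenBank's 1-based inclusive convention and the
# package's 0-based half-open one.

#' Read an annotated genome from a GenBank flat file
#'
#' `join()`/`complement()` locations become strand-aware exon lists;
#' features carrying `/pseudo` are flagged; a location of the form
#' `join(x..L,1..y)` on a circular record is folded back into one
#' wrap-around interval.
#'
#' @param path path to a GenBank flat file with gene/CDS/rRNA/tRNA features.
#' @return an [annotated_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file: no LOCUS line")
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  identifier <- toks[2]
  is_circular <- any(grepl("circular", locus[1], ignore.case = TRUE))

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("malformed GenBank record: no ORIGIN section")
  oend <- grep("^//", lines)
  oend <- if (length(oend)) oend[oend > ostart[1]][1] else length(lines) + 1L
  seq_lines <- lines[seq(ostart[1] + 1L, oend - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  entries <- list()
  if (length(fstart)) {
    flines <- lines[seq(fstart[1] + 1L, ostart[1] - 1L)]
    cur <- NULL
    for (ln in flines) {
      if (grepl("^ {5}\\S", ln)) {           # new feature entry
        if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
        key <- trimws(substr(ln, 1, 20))
        cur <- list(key = key, loc = trimws(substr(ln, 21, nchar(ln))),
                    quals = character(0))
      } else if (grepl("^ {21}", ln) && !is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
        else if (length(cur$quals)) {
          n <- length(cur$quals)
          cur$quals[n] <- paste0(cur$quals[n], txt)
        } else cur$loc <- paste0(cur$loc, txt)
      }
    }
    if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
  }

  L <- nchar(sequence)
  feats <- gb_build_features(entries, L, is_circular)
  annotated_genome(identifier, sequence, is_circular, feats)
}

#' @keywords internal
gb_qual <- function(e, name) {
  hit <- grep(paste0("^/", name, "(=|$)"), e$quals, value = TRUE)
  if (!length(hit)) return(NULL)
  val <- sub(paste0("^/", name, "=?"), "", hit[1])
  gsub('"', "", val)
}

#' Parse a GenBank location string into (exons list, strand)
#' @keywords internal
gb_parse_location <- function(loc, L, is_circular, feature_key = "?") {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\(", "", loc)
    loc <- sub("\\)$", "", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\(", "", loc)
    loc <- sub("\\)$", "", loc)
  }
  parts <- strsplit(loc, ",")[[1]]
  ivs <- lapply(parts, function(p) {
    if (grepl("^complement\\(", p)) {
      # per-piece complement (rare) -> treat whole feature as minus strand
      p <- sub("^complement\\(", "", sub("\\)$", "", p))
      strand <<- "-"
    }
    m <- regmatches(p, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", p))[[1]]
    if (length(m) != 3) {
      m1 <- regmatches(p, regexec("^<?(\\d+)>?$", p))[[1]]
      if (length(m1) == 2) return(c(as.numeric(m1[2]) - 1, as.numeric(m1[2])))
      stop(sprintf("cannot parse location '%s' of feature '%s'",
                   p, feature_key))
    }
    c(as.numeric(m[2]) - 1, as.numeric(m[3]))  # 1-based incl -> 0-based half-open
  })
  # fold join(x..L, 1..y) into one wrap-around interval on circular records
  if (is_circular && length(ivs) > 1L) {
    i <- 1L
    while (i < length(ivs)) {
      if (ivs[[i]][2L] == L && ivs[[i + 1L]][1L] == 0) {
        ivs[[i]] <- c(ivs[[i]][1L], L + ivs[[i + 1L]][2L])
        ivs <- ivs[-(i + 1L)]
      } else i <- i + 1L
    }
  }
  # exon lists are ordered along transcription: reverse for minus strand
  if (strand == "-") ivs <- rev(ivs)
  list(exons = ivs, strand = strand)
}

#' @keywords internal
gb_build_features <- function(entries, L, is_circular) {
  main_keys <- c(CDS = "protein", rRNA = "rRNA", tRNA = "tRNA")
  feats <- list()
  introns <- list()
  for (e in entries) {
    if (!(e$key %in% c(names(main_keys), "intron"))) next
    gene <- gb_qual(e, "gene")
    if (is.null(gene)) gene <- gb_qual(e, "note")
    if (is.null(gene)) stop(sprintf(
      "malformed GenBank feature: %s at '%s' has no /gene qualifier",
      e$key, e$loc))
    loc <- gb_parse_location(e$loc, L, is_circular, e$key)
    if (e$key == "intron") {
      note <- gb_qual(e, "note")
      rec <- gb_intron_from_note(gene, note, loc$exons[[1L]])
      introns[[length(introns) + 1L]] <- rec
    } else {
      copy <- gb_qual(e, "copy_index")
      copy <- if (is.null(copy)) 1L else as.integer(copy)
      feats[[length(feats) + 1L]] <- gene_feature(
        name = gene, category = main_keys[[e$key]], strand = loc$strand,
        exons = loc$exons,
        is_pseudo = !is.null(gb_qual(e, "pseudo")),
        copy_index = copy)
    }
  }
  # attach introns to the host feature copy whose span contains them
  for (rec in introns) {
    hit <- NA_integer_
    for (i in seq_along(feats)) {
      f <- feats[[i]]
      if (f$name != rec$host_gene) next
      sp <- feature_span(f, L)
      if (rec$interval[1L] >= sp[1L] && rec$interval[2L] <= sp[2L]) {
        hit <- i; break
      }
    }
    if (is.na(hit))
      stop(sprintf("intron '%s' has no host feature spanning it",
                   intron_name(rec)))
    feats[[hit]]$introns <- c(feats[[hit]]$introns, list(rec))
  }
  # introns in transcription order
  lapply(feats, function(f) {
    if (length(f$introns) > 1L) {
      st <- vapply(f$introns, function(it) it$interval[1L], numeric(1))
      f$introns <- f$introns[order(if (f$strand == "+") st else -st)]
    }
    f
  })
}

#' @keywords internal
gb_intron_from_note <- function(gene, note, interval) {
  m <- if (!is.null(note))
    regmatches(note, regexec("([A-Za-z0-9]+)i(\\d+)(g[12])", note))[[1]]
  else character(0)
  splicing <- if (!is.null(note) && grepl("trans", note)) "trans" else "cis"
  if (length(m) == 4)
    intron_record(m[2], as.integer(m[3]), m[4], splicing, interval)
  else
    intron_record(gene, as.integer(interval[1L] + 1L), "g2", splicing,
                  interval)
}

## writer --------------------------------------------------------------------

#' @keywords internal
gb_format_location <- function(exons, strand, L, is_circular) {
  fmt1 <- function(iv) {
    if (iv[2L] <= L) sprintf("%d..%d", iv[1L] + 1L, iv[2L])
    else sprintf("%d..%d,%d..%d", iv[1L] + 1L, L, 1L, iv[2L] - L)
  }
  # genomic order for output
  ivs <- exons
  if (strand == "-") ivs <- rev(ivs)
  body <- paste(vapply(ivs, fmt1, character(1)), collapse = ",")
  multi <- grepl(",", body)
  if (multi) body <- sprintf("join(%s)", body)
  if (strand == "-") body <- sprintf("complement(%s)", body)
  body
}

#' Write an annotated genome as a GenBank flat file
#'
#' @param genome an [annotated_genome()].
#' @param path output path.
#' @export
write_genbank <- function(genome, path) {
  L <- genome$length_bp
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2000",
     genome$identifier, L, if (genome$is_circular) "circular" else "linear")
  wl("DEFINITION  %s, annotated genome.", genome$identifier)
  wl("FEATURES             Location/Qualifiers")
  emit <- function(key, loc, quals) {
    wl("     %-16s%s", key, loc)
    for (q in quals) wl("                     %s", q)
  }
  emit("source", sprintf("1..%d", L), character(0))
  keymap <- c(protein = "CDS", rRNA = "rRNA", tRNA = "tRNA")
  for (f in genome$features) {
    loc <- gb_format_location(f$exons, f$strand, L, genome$is_circular)
    quals <- sprintf('/gene="%s"', f$name)
    if (f$copy_index != 1L)
      quals <- c(quals, sprintf('/copy_index="%d"', f$copy_index))
    if (f$is_pseudo) quals <- c(quals, "/pseudo")
    emit(keymap[[f$category]], loc, quals)
    for (it in f$introns) {
      iloc <- gb_format_location(list(it$interval), "+", L, genome$is_circular)
      emit("intron", iloc,
           c(sprintf('/gene="%s"', f$name),
             sprintf('/note="%s; group II; %s-spliced"',
                     intron_name(it), it$splicing)))
    }
  }
  wl("ORIGIN")
  s <- tolower(genome$sequence)
  pos <- seq(1L, L, 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, L))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    wl("%9d %s", p, paste(blocks, collapse = " "))
  }
  wl("//")
  invisible(path)
}

## FASTA / GFF3 --------------------------------------------------------------

#' Write a genome sequence as FASTA
#' @param genome an [annotated_genome()].
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$identifier
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a (single-record) FASTA as an unannotated genome
#' @param path FASTA path.
#' @param is_circular logical.
#' @export
read_fasta_genome <- function(path, is_circular = TRUE) {
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("empty FASTA")
  annotated_genome(names(x)[1], as.character(x[[1]]), is_circular)
}

#' Read an annotated genome from GFF3 + FASTA
#'
#' Understands the feature layout [write_gff3()] emits: gene-level rows
#' (`gene`/`rRNA_gene`/`tRNA_gene`) with `ID`, `Name` and `category`
#' attributes, `exon` rows attached by `Parent`, and `intron` rows whose
#' `Name` carries the canonical intron name.
#'
#' @param gff_path GFF3 file path.
#' @param fasta_path FASTA file with the genome sequence.
#' @param is_circular logical.
#' @return an [annotated_genome()].
#' @export
read_gff3_genome <- function(gff_path, fasta_path, is_circular = TRUE) {
  g <- read_fasta_genome(fasta_path, is_circular)
  lines <- readLines(gff_path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(g)
  f <- do.call(rbind, strsplit(lines, "\t"))
  attr1 <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]*)"), a))[[1]]
    if (length(m) == 3L) m[3L] else NA_character_
  }
  genes <- list()
  catmap <- c(gene = "protein", rRNA_gene = "rRNA", tRNA_gene = "tRNA")
  for (r in seq_len(nrow(f))) {
    if (!(f[r, 3L] %in% names(catmap))) next
    a <- f[r, 9L]
    id <- attr1(a, "ID")
    genes[[id]] <- list(name = attr1(a, "Name"), category = catmap[[f[r, 3L]]],
                        strand = f[r, 7L],
                        is_pseudo = identical(attr1(a, "pseudo"), "true"),
                        copy_index = as.integer(sub(".*\\.", "", id)),
                        exons = list(), introns = list())
  }
  for (r in seq_len(nrow(f))) {
    type <- f[r, 3L]
    if (!(type %in% c("exon", "intron"))) next
    a <- f[r, 9L]
    parent <- attr1(a, "Parent")
    if (is.null(genes[[parent]])) next
    iv <- c(as.numeric(f[r, 4L]) - 1, as.numeric(f[r, 5L]))
    if (type == "exon") {
      genes[[parent]]$exons <- c(genes[[parent]]$exons, list(iv))
    } else {
      nm <- attr1(a, "Name")
      m <- regmatches(nm, regexec("([A-Za-z0-9]+)i(\\d+)(g[12])", nm))[[1]]
      rec <- if (length(m) == 4L)
        intron_record(m[2L], as.integer(m[3L]), m[4L], "cis", iv)
      else intron_record(genes[[parent]]$name, as.integer(iv[1L] + 1L),
                         "g2", "cis", iv)
      genes[[parent]]$introns <- c(genes[[parent]]$introns, list(rec))
    }
  }
  feats <- lapply(genes, function(gg) {
    ex <- gg$exons
    if (length(ex) > 1L) {
      st <- vapply(ex, `[`, numeric(1), 1L)
      ex <- ex[order(if (gg$strand == "+") st else -st)]
    }
    it <- gg$introns
    if (length(it) > 1L) {
      st <- vapply(it, function(x) x$interval[1L], numeric(1))
      it <- it[order(if (gg$strand == "+") st else -st)]
    }
    gene_feature(gg$name, gg$category, gg$strand, ex, it,
                 is_pseudo = gg$is_pseudo, copy_index = gg$copy_index)
  })
  names(feats) <- NULL
  annotated_genome(g$identifier, g$sequence, is_circular, feats)
}

#' Write gene/exon/intron features as GFF3
#' @param genome an [annotated_genome()].
#' @param path output path.
#' @export
write_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  L <- genome$length_bp
  typemap <- c(protein = "gene", rRNA = "rRNA_gene", tRNA = "tRNA_gene")
  rows <- character(0)
  for (f in genome$features) {
    sp <- feature_span(f, L)
    id <- sprintf("%s.%d", f$name, f$copy_index)
    attr1 <- sprintf("ID=%s;Name=%s;category=%s%s", id, f$name, f$category,
                     if (f$is_pseudo) ";pseudo=true" else "")
    rows <- c(rows, sprintf("%s\tchondromics\t%s\t%d\t%d\t.\t%s\t.\t%s",
                            genome$identifier, typemap[[f$category]],
                            sp[1L] + 1L, min(sp[2L], L), f$strand, attr1))
    for (iv in f$exons)
      rows <- c(rows, sprintf("%s\tchondromics\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                              genome$identifier, iv[1L] + 1L, min(iv[2L], L),
                              f$strand, id))
    for (it in f$introns)
      rows <- c(rows, sprintf(
        "%s\tchondromics\tintron\t%d\t%d\t.\t%s\t.\tParent=%s;Name=%s",
        genome$identifier, it$interval[1L] + 1L, min(it$interval[2L], L),
        f$strand, id, intron_name(it)))
  }
  writeLines(rows, con)
  invisible(path)
}
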