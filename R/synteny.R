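# Signed circular gene-order comparison: conserved adjacencies, conserved
# gene clusters, and a DCJ-based rearrangement-event estimate.
#
# Orders are cyclic sequences of signed gene labels.  Adjacencies are
# encoded on gene extremities (head/tail), the representation in which a
# circular chromosome is a perfect matching and the DCJ distance between
# two single circular chromosomes is n minus the number of cycles of the
# combined adjacency graph.

#' @keywords internal
order_elements <- function(go, restrict = NULL, dedupe = TRUE) {
  tab <- go$tab
  if (!is.null(restrict)) tab <- tab[tab$gene %in% restrict, , drop = FALSE]
  if (dedupe && anyDuplicated(tab$gene)) {
    keep <- !duplicated(tab$gene)
    tab <- tab[keep, , drop = FALSE]
  }
  tab
}

#' @keywords internal
extremity_adjacencies <- function(tab) {
  # returns character vector of canonical "x|y" extremity pairs
  n <- nrow(tab)
  if (n < 2L) return(character(0))
  left <- ifelse(tab$strand == "+", paste0(tab$gene, ".t"),
                 paste0(tab$gene, ".h"))
  right <- ifelse(tab$strand == "+", paste0(tab$gene, ".h"),
                  paste0(tab$gene, ".t"))
  nxt <- c(2:n, 1L)
  a <- right
  b <- left[nxt]
  vapply(seq_len(n), function(i)
    paste(sort(c(a[i], b[i])), collapse = "|"), character(1))
}

#' Conserved and orientation-reversed adjacencies between two gene orders
#'
#' Both orders are restricted to their shared gene labels; a pair of genes
#' adjacent in both with matching extremities is `conserved`, a pair
#' adjacent in both but with flipped relative orientation is `reversed`.
#'
#' @param a,b `gene_order` objects.
#' @return data.frame with columns `gene1`, `gene2`, `status`.
#' @export
shared_adjacencies <- function(a, b) {
  shared <- intersect(a$tab$gene, b$tab$gene)
  if (length(shared) < 2L)
    stop("fewer than 2 shared gene labels between the two orders")
  ta <- order_elements(a, shared)
  tb <- order_elements(b, shared)
  adjA <- extremity_adjacencies(ta)
  adjB <- extremity_adjacencies(tb)
  genes_of <- function(adj) {
    g <- sub("\\.(h|t)$", "", strsplit(adj, "|", fixed = TRUE)[[1]])
    paste(sort(g), collapse = "|")
  }
  pairsA <- vapply(adjA, genes_of, character(1))
  pairsB <- vapply(adjB, genes_of, character(1))
  conserved <- adjA[adjA %in% adjB]
  both_pairs <- intersect(pairsA, pairsB)
  conserved_pairs <- vapply(conserved, genes_of, character(1))
  reversed_pairs <- setdiff(both_pairs, conserved_pairs)
  rows <- list()
  for (p in conserved_pairs) {
    g <- strsplit(p, "|", fixed = TRUE)[[1]]
    rows[[length(rows) + 1L]] <- data.frame(gene1 = g[1L], gene2 = g[2L],
                                            status = "conserved")
  }
  for (p in reversed_pairs) {
    g <- strsplit(p, "|", fixed = TRUE)[[1]]
    rows[[length(rows) + 1L]] <- data.frame(gene1 = g[1L], gene2 = g[2L],
                                            status = "reversed")
  }
  if (!length(rows))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      status = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
signed_vec <- function(tab) paste0(tab$strand, tab$gene)

#' @keywords internal
run_conserved_in <- function(run_signed, tab) {
  # is the signed run a consecutive co-oriented block (possibly reversed as
  # a whole) of the circular order `tab`?
  n <- nrow(tab)
  k <- length(run_signed)
  if (k > n) return(FALSE)
  v <- signed_vec(tab)
  vv <- c(v, v)
  flip <- function(x) {
    sgn <- ifelse(substr(x, 1, 1) == "+", "-", "+")
    paste0(sgn, substr(x, 2, nchar(x)))
  }
  pats <- list(run_signed, rev(flip(run_signed)))
  for (pat in pats) {
    for (i in seq_len(n)) {
      if (identical(vv[i:(i + k - 1L)], pat)) return(TRUE)
    }
  }
  FALSE
}

#' Maximal gene clusters conserved across genomes
#'
#' Restricting all orders to their common gene set, finds maximal runs of
#' the first order that appear as consecutive, co-oriented blocks (allowing
#' whole-block reversal, the circular-chromosome symmetry) in at least
#' `min_genomes` of the orders.
#'
#' @param orders list of `gene_order` objects (>= 2).
#' @param min_genomes minimal number of supporting genomes (default: all).
#' @return list of clusters, each a list with `member_genes` (signed
#'   labels, reference orientation) and `n_support`.
#' @export
conserved_clusters <- function(orders, min_genomes = length(orders)) {
  stopifnot(length(orders) >= 2L)
  common <- Reduce(intersect, lapply(orders, function(o) o$tab$gene))
  if (length(common) < 2L) return(list())
  tabs <- lapply(orders, order_elements, restrict = common)
  ref <- tabs[[1L]]
  n <- nrow(ref)
  v <- signed_vec(ref)
  support <- function(run) sum(vapply(tabs, function(t)
    run_conserved_in(run, t), logical(1)))
  clusters <- list()
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    # grow a maximal run starting at ref position i
    best <- NULL
    k <- 2L
    while (k <= n) {
      idx <- ((i - 1L + seq_len(k) - 1L) %% n) + 1L
      run <- v[idx]
      if (support(run) >= min_genomes) { best <- run; k <- k + 1L }
      else break
    }
    if (!is.null(best))
      clusters[[length(clusters) + 1L]] <- list(member_genes = best,
                                                n_support = support(best))
  }
  if (!length(clusters)) return(list())
  # drop clusters contained in longer ones (cyclic containment incl. flip)
  lens <- vapply(clusters, function(cl) length(cl$member_genes), integer(1))
  o <- order(-lens)
  clusters <- clusters[o]
  kept <- list()
  for (cl in clusters) {
    contained <- FALSE
    for (kc in kept) {
      big <- kc$member_genes
      if (length(cl$member_genes) <= length(big)) {
        tab_big <- data.frame(
          gene = sub("^[+-]", "", big),
          strand = substr(big, 1, 1),
          copy = 1L, stringsAsFactors = FALSE)
        if (run_conserved_in(cl$member_genes, tab_big)) contained <- TRUE
        # linear containment check within the block is enough here
        vv <- c(big, big)
        k <- length(cl$member_genes)
        flip <- function(x) paste0(ifelse(substr(x, 1, 1) == "+", "-", "+"),
                                   substr(x, 2, nchar(x)))
        for (i in seq_along(big)) {
          if (i + k - 1L > length(vv)) break
          seg <- vv[i:(i + k - 1L)]
          if (identical(seg, cl$member_genes) ||
              identical(seg, rev(flip(cl$member_genes)))) contained <- TRUE
        }
      }
      if (contained) break
    }
    if (!contained) kept[[length(kept) + 1L]] <- cl
  }
  kept
}

#' Read a signed gene order from a plain text file
#'
#' One signed label per line (e.g. `+nad5`, `-cob`); `#`-prefixed lines
#' are comments (a `#circular` header is conventional).
#'
#' @param path file path.
#' @param genome_id identifier; defaults to the file name.
#' @return a `gene_order`.
#' @export
read_gene_order <- function(path, genome_id = NULL) {
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parse_gene_order(genome_id, lines)
}

#' Write a signed gene order as a plain text file
#' @param order a `gene_order`.
#' @param path file path.
#' @export
write_gene_order <- function(order, path) {
  writeLines(c("#circular", paste0(order$tab$strand, order$tab$gene)), path)
  invisible(path)
}

## rearrangement distance ----------------------------------------------------

#' @keywords internal
private_runs <- function(tab, shared) {
  # number of maximal circular runs of genes absent from `shared`
  priv <- !(tab$gene %in% shared)
  n <- length(priv)
  if (!any(priv)) return(0L)
  if (all(priv)) return(1L)
  starts <- sum(priv & !c(priv[n], priv[-n]))
  starts
}

#' @keywords internal
dcj_cycles <- function(adjA, adjB) {
  # count cycles of the adjacency graph given two perfect matchings
  # (each as canonical "x|y" strings over the same extremity set)
  edge_list <- c(adjA, adjB)
  ends <- strsplit(edge_list, "|", fixed = TRUE)
  nodes <- unique(unlist(ends))
  idx <- stats::setNames(seq_along(nodes), nodes)
  nb <- vector("list", length(nodes))
  for (e in ends) {
    i <- idx[[e[1L]]]; j <- idx[[e[2L]]]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  seen <- logical(length(nodes))
  cycles <- 0L
  for (v in seq_along(nodes)) {
    if (seen[v]) next
    cycles <- cycles + 1L
    stack <- v
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[x]) next
      seen[x] <- TRUE
      stack <- c(stack, nb[[x]])
    }
  }
  cycles
}

#' @keywords internal
select_exemplars <- function(tab, other_tab, shared) {
  # keep, per duplicated shared gene, the copy whose neighbourhood agrees
  # best with the other order; ties -> first (lowest-coordinate) copy
  dup_genes <- unique(tab$gene[duplicated(tab$gene) & tab$gene %in% shared])
  if (!length(dup_genes)) return(tab)
  other_adj <- extremity_adjacencies(
    order_elements(list(tab = other_tab), shared))
  for (g in dup_genes) {
    cand <- which(tab$gene == g)
    score <- vapply(cand, function(ci) {
      tmp <- tab[-setdiff(cand, ci), , drop = FALSE]
      tmp <- tmp[tmp$gene %in% shared, , drop = FALSE]
      adj <- extremity_adjacencies(tmp)
      pos <- which(tmp$gene == g)
      n <- nrow(tmp)
      mine <- adj[c(pos, ((pos - 2L) %% n) + 1L)]
      sum(mine %in% other_adj)
    }, numeric(1))
    best <- cand[which.max(score)]
    tab <- tab[-setdiff(cand, best), , drop = FALSE]
  }
  tab
}

#' Estimate the rearrangement events separating two gene orders
#'
#' Genes private to one genome are charged as deletion events (one per
#' maximal run); duplicate copies are reduced to exemplars, the extra
#' copies charged as duplications; on the resulting pair of signed
#' circular permutations the DCJ distance (n minus adjacency-graph cycles)
#' counts the remaining elementary rearrangements.  Each elementary DCJ
#' operation -- an inversion, or a fission/fusion through a circular
#' intermediate -- counts as one event and is reported under `inversion`
#' in the breakdown; the `method` field records the model.
#'
#' @param a,b `gene_order` objects.
#' @return object of class `rearrangement_estimate`: `genome_a`,
#'   `genome_b`, `shared_gene_count`, `event_count`, `breakdown`,
#'   `method`.
#' @export
rearrangement_distance <- function(a, b) {
  shared <- intersect(a$tab$gene, b$tab$gene)
  if (!length(shared))
    stop("disjoint gene sets: no rearrangement distance defined")
  del_a <- private_runs(a$tab, shared)
  del_b <- private_runs(b$tab, shared)
  # duplications: copy-number differences of shared genes (copies present
  # in both genomes are not rearrangement events)
  cnt_a <- table(factor(a$tab$gene[a$tab$gene %in% shared], levels = shared))
  cnt_b <- table(factor(b$tab$gene[b$tab$gene %in% shared], levels = shared))
  dup_total <- sum(abs(cnt_a - cnt_b))
  ta <- select_exemplars(a$tab, b$tab, shared)
  tb <- select_exemplars(b$tab, a$tab, shared)
  ta <- ta[ta$gene %in% shared, , drop = FALSE]
  tb <- tb[tb$gene %in% shared, , drop = FALSE]
  n <- nrow(ta)
  dcj <- if (n < 2L) 0L else {
    adjA <- extremity_adjacencies(ta)
    adjB <- extremity_adjacencies(tb)
    n - dcj_cycles(adjA, adjB)
  }
  structure(list(
    genome_a = a$genome_id, genome_b = b$genome_id,
    shared_gene_count = length(shared),
    event_count = dcj + del_a + del_b + dup_total,
    breakdown = c(inversion = dcj, translocation = 0L,
                  duplication = dup_total, deletion = del_a + del_b),
    method = paste("DCJ (n - cycles) on exemplar-reduced shared signed",
                   "circular orders; private-gene runs charged once as",
                   "deletions; extra duplicate copies charged once as",
                   "duplications; elementary DCJ operations reported as",
                   "inversions")),
    class = "rearrangement_estimate")
}

#' @export
print.rearrangement_estimate <- function(x, ...) {
  cat(sprintf("%s vs %s: %d events (%s) over %d shared genes\n",
              x$genome_a, x$genome_b, x$event_count,
              paste(names(x$breakdown), x$breakdown, sep = "=",
                    collapse = ", "),
              x$shared_gene_count))
  invisible(x)
}

## event simulation ----------------------------------------------------------

#' Apply random rearrangement events to a gene order
#'
#' Samples `n` events from the mix of inversion, translocation,
#' duplication and deletion, applies them in sequence and logs each.
#'
#' @param order a `gene_order`.
#' @param n number of events (>= 0).
#' @param mix named probability weights over
#'   `c("inversion","translocation","duplication","deletion")`.
#' @param seed optional integer seed.
#' @return list with the new `gene_order` and a `rearrangement_log`
#'   data.frame (`event`, `type`, `pos`, `len`, `detail`).
#' @export
apply_events <- function(order, n, mix = c(inversion = 0.4,
                                           translocation = 0.3,
                                           duplication = 0.15,
                                           deletion = 0.15),
                         seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  tab <- order$tab
  log <- list()
  if (n > 0) for (e in seq_len(n)) {
    type <- sample(names(mix), 1L, prob = mix)
    m <- nrow(tab)
    if (m <= 1L && type == "deletion")
      stop("deletion would empty the gene order")
    if (type == "inversion") {
      len <- sample.int(max(1L, m - 1L), 1L)
      i <- sample.int(m, 1L)
      idx <- ((i - 1L + seq_len(len) - 1L) %% m) + 1L
      blk <- tab[rev(idx), , drop = FALSE]
      blk$strand <- ifelse(blk$strand == "+", "-", "+")
      tab[idx, ] <- blk
      log[[e]] <- data.frame(event = e, type = type, pos = i, len = len,
                             detail = paste(blk$gene, collapse = ","))
    } else if (type == "translocation") {
      len <- sample.int(max(1L, m %/% 3L), 1L)
      i <- sample.int(m, 1L)
      idx <- ((i - 1L + seq_len(len) - 1L) %% m) + 1L
      blk <- tab[idx, , drop = FALSE]
      rest <- tab[-idx, , drop = FALSE]
      j <- sample.int(nrow(rest) + 1L, 1L) - 1L
      tab <- rbind(rest[seq_len(j), , drop = FALSE], blk,
                   if (j < nrow(rest)) rest[(j + 1L):nrow(rest), , drop = FALSE])
      log[[e]] <- data.frame(event = e, type = type, pos = i, len = len,
                             detail = paste(blk$gene, collapse = ","))
    } else if (type == "duplication") {
      i <- sample.int(m, 1L)
      blk <- tab[i, , drop = FALSE]
      blk$copy <- max(tab$copy[tab$gene == blk$gene]) + 1L
      j <- sample.int(m + 1L, 1L) - 1L
      tab <- rbind(tab[seq_len(j), , drop = FALSE], blk,
                   if (j < m) tab[(j + 1L):m, , drop = FALSE])
      log[[e]] <- data.frame(event = e, type = type, pos = i, len = 1L,
                             detail = blk$gene)
    } else {                               # deletion
      i <- sample.int(m, 1L)
      g <- tab$gene[i]
      tab <- tab[-i, , drop = FALSE]
      log[[e]] <- data.frame(event = e, type = type, pos = i, len = 1L,
                             detail = g)
    }
  }
  rownames(tab) <- NULL
  list(order = gene_order_obj(order$genome_id, tab$gene, tab$strand,
                              tab$copy),
       rearrangement_log = if (length(log)) do.call(rbind, log)
       else data.frame(event = integer(0), type = character(0),
                       pos = integer(0), len = integer(0),
                       detail = character(0)))
}
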