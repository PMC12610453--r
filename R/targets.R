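# Validated miRNA -> gene target handling: interaction snapshots,
# convergence counting over significant miRNAs, and hypergeometric
# over-representation against a term map with a union-of-targets universe.

#' Load a validated-interaction snapshot
#'
#' Reads a local snapshot of validated miRNA-target interactions
#' (columns mirna, gene_symbol, support_type, source), deduplicates on
#' (mirna, gene_symbol) concatenating sources, and optionally restricts
#' to functionally supported interactions.
#'
#' The functional filter keeps rows whose support label begins with
#' "Functional MTI"; weakly supported rows ("Functional MTI (Weak)") are
#' excluded unless `include_weak = TRUE`.
#'
#' @param path `.tsv`/`.csv` snapshot file.
#' @param functional_only keep only functionally supported interactions
#'   (default TRUE).
#' @param include_weak when filtering, also keep "Functional MTI (Weak)"
#'   rows (default FALSE).
#' @return data.frame of class `interaction_table` with columns mirna,
#'   gene_symbol, support_type, source (deduplicated pairs).
#' @export
load_interactions <- function(path, functional_only = TRUE,
                              include_weak = FALSE) {
  df <- read_delim_auto(path)
  interaction_table(df, functional_only = functional_only,
                    include_weak = include_weak)
}

#' @rdname load_interactions
#' @param df data.frame already in snapshot layout.
#' @export
interaction_table <- function(df, functional_only = TRUE,
                              include_weak = FALSE) {
  need <- c("mirna", "gene_symbol", "support_type", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("interaction table missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[need]
  if (nrow(df) && functional_only) {
    keep <- startsWith(df$support_type, "Functional MTI")
    if (!include_weak)
      keep <- keep & !startsWith(df$support_type, "Functional MTI (Weak)")
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df)) {
    key <- paste(df$mirna, df$gene_symbol, sep = "\r")
    agg <- function(x) paste(sort(unique(x)), collapse = ";")
    first <- !duplicated(key)
    src <- tapply(df$source, key, agg)
    sup <- tapply(df$support_type, key, agg)
    out <- df[first, , drop = FALSE]
    k <- key[first]
    out$source <- unname(src[k])
    out$support_type <- unname(sup[k])
    df <- out[order(out$mirna, out$gene_symbol), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Gene convergence counts over significant miRNAs
#'
#' Within one regulation direction, counts for each gene the number of
#' distinct significant miRNAs with a validated interaction targeting it.
#' Counts are based on unique miRNA-gene pairs so repeated database
#' entries never inflate support. Genes are ranked by descending count,
#' ties broken lexicographically by gene symbol.
#'
#' @param interactions an [interaction_table()].
#' @param significant character vector of significant miRNA names for the
#'   direction.
#' @param direction `"up"` or `"down"` (label carried into the output).
#' @param top_k truncate the ranking (default 20; `Inf` for all).
#' @return data.frame with columns direction, gene_symbol, n_mirnas,
#'   mirnas (semicolon-joined), rank.
#' @export
convergence_counts <- function(interactions, significant,
                               direction = c("up", "down"), top_k = 20) {
  direction <- match.arg(direction)
  stopifnot(inherits(interactions, "interaction_table"))
  sub <- interactions[interactions$mirna %in% significant, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(direction = character(0), gene_symbol = character(0),
                      n_mirnas = integer(0), mirnas = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  counts <- tapply(sub$mirna, sub$gene_symbol,
                   function(x) length(unique(x)))
  genes <- names(counts)
  o <- order(-as.integer(counts), genes)
  genes <- genes[o]; counts <- as.integer(counts)[o]
  keep <- seq_len(min(length(genes), top_k))
  mir_lists <- vapply(genes[keep], function(g)
    paste(sort(unique(sub$mirna[sub$gene_symbol == g])), collapse = ";"),
    character(1))
  data.frame(direction = direction, gene_symbol = genes[keep],
             n_mirnas = counts[keep], mirnas = unname(mir_lists),
             rank = keep, stringsAsFactors = FALSE)
}

#' Union-of-targets enrichment universe
#'
#' The background for over-representation is the union of validated
#' targets across all retained miRNAs, the same universe for both
#' regulation directions (mitigates target-retrieval bias).
#'
#' @param interactions an [interaction_table()].
#' @param mirnas the retained miRNAs (both directions combined).
#' @return character vector of gene symbols.
#' @export
target_universe <- function(interactions, mirnas) {
  stopifnot(inherits(interactions, "interaction_table"))
  sort(unique(
    interactions$gene_symbol[interactions$mirna %in% mirnas]))
}

#' Hypergeometric over-representation of terms in a gene set
#'
#' Upper-tail hypergeometric test per term: with universe size N, term
#' size K (after intersecting the term's genes with the universe), gene
#' set size n and overlap k, p = P(X >= k) for X ~ Hypergeom(N, K, n).
#' BH adjustment across the tested terms. Results are ordered by
#' descending overlap count (the display convention), ties by FDR.
#'
#' @param target_set character vector of genes (must lie in `universe`).
#' @param term_map data.frame with columns term_id, term_name, gene_symbol.
#' @param universe background gene set.
#' @return data.frame with columns term_id, term_name, overlap_count,
#'   set_size, term_size_in_universe, universe_size, p, fdr, genes.
#' @export
hypergeom_enrich <- function(target_set, term_map, universe) {
  need <- c("term_id", "term_name", "gene_symbol")
  miss <- setdiff(need, names(term_map))
  if (length(miss))
    stop("term map missing column(s): ", paste(miss, collapse = ", "))
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  target_set <- unique(target_set)
  out_t <- setdiff(target_set, universe)
  if (length(out_t))
    stop("target gene(s) outside the universe: ",
         paste(out_t, collapse = ", "))
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      overlap_count = integer(0), set_size = integer(0),
                      term_size_in_universe = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      fdr = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE)
  if (length(target_set) == 0L || nrow(term_map) == 0L) return(empty)
  N <- length(universe); n <- length(target_set)
  terms <- unique(term_map[c("term_id", "term_name")])
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    tg <- intersect(
      term_map$gene_symbol[term_map$term_id == terms$term_id[i]], universe)
    K <- length(tg)
    if (K == 0L) return(NULL)
    hit <- intersect(target_set, tg)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               overlap_count = k, set_size = n,
               term_size_in_universe = K, universe_size = N, p = p,
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p)
  res <- res[order(-res$overlap_count, res$fdr, res$term_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[c("term_id", "term_name", "overlap_count", "set_size",
        "term_size_in_universe", "universe_size", "p", "fdr", "genes")]
}
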