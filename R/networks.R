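#' Build a tissue cooperation network from specific pairs
#'
#' One undirected edge per specific TF pair, annotated with the pair's
#' z-score and `pmi_specific`; homodimer pairs become self-loops.
#'
#' @param result a `specificity_result` from [classify_pairs()].
#' @param tissue optional tissue label stored as a graph attribute.
#' @return an undirected `igraph` graph with edge attributes `z` and
#'   `pmi_specific`.
#' @export
build_network <- function(result, tissue = NULL) {
  sp <- result[!is.na(result$class) & result$class == "specific", , drop = FALSE]
  if (!nrow(sp)) {
    warnf("no specific pairs%s; empty network",
          if (!is.null(tissue)) paste0(" for tissue '", tissue, "'") else "")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = sp$motif_a, to = sp$motif_b,
                 z = sp$z, pmi_specific = sp$pmi_specific,
                 stringsAsFactors = FALSE),
      directed = FALSE)
  }
  if (!is.null(tissue)) g <- igraph::set_graph_attr(g, "tissue", tissue)
  g
}

#' Node degrees of a cooperation network, hubs first
#'
#' Degree counts incident edges with self-loops counting 2 (the
#' graph-theory convention); the result is sorted by decreasing degree
#' with ties broken by node identifier.
#'
#' @param net an `igraph` network from [build_network()].
#' @return named integer vector of degrees, descending.
#' @export
hub_degrees <- function(net) {
  d <- igraph::degree(net, loops = TRUE)
  d[order(-d, names(d))]
}

#' Top specific pairs ranked by z-score
#'
#' Default ordering is descending z (strongest cooperation first); with
#' `ascending = TRUE` the list is ordered by increasing z-score instead.
#' Ties are broken by the pair identifier.
#'
#' @param result a `specificity_result`.
#' @param k number of pairs to return.
#' @param ascending sort by increasing z-score.
#' @return data frame of up to `k` specific pairs (columns `motif_a`,
#'   `motif_b`, `z`, `pmi_specific`).
#' @export
rank_pairs <- function(result, k, ascending = FALSE) {
  if (k < 1) stopf("k must be >= 1")
  sp <- result[!is.na(result$class) & result$class == "specific", , drop = FALSE]
  id <- paste(sp$motif_a, sp$motif_b)
  o <- if (ascending) order(sp$z, id) else order(-sp$z, id)
  sp <- sp[o, c("motif_a", "motif_b", "z", "pmi_specific"), drop = FALSE]
  if (nrow(sp) < k) {
    warnf("only %d specific pairs available (k = %d)", nrow(sp), k)
    k <- nrow(sp)
  }
  out <- head(sp, k)
  rownames(out) <- NULL
  out
}

#' Exclusive cross-tissue overlap counts (UpSet semantics)
#'
#' Each item (TF or pair identifier) is assigned to the exact
#' combination of tissues containing it; the count of items per
#' nonempty combination is returned. Counts sum to the number of
#' distinct items.
#'
#' @param items_per_tissue named list: tissue -> character vector.
#' @return data frame `combination` (tissue names joined by `&`, in
#'   input order), `degree` (number of tissues) and `count`, sorted by
#'   decreasing count.
#' @export
overlap_table <- function(items_per_tissue) {
  if (!length(items_per_tissue)) stopf("need at least one tissue")
  tissues <- names(items_per_tissue)
  items <- unique(unlist(items_per_tissue, use.names = FALSE))
  membership <- vapply(items_per_tissue, function(s) items %in% s,
                       logical(length(items)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = length(items))
  combo <- apply(membership, 1, function(m) paste(tissues[m], collapse = "&"))
  tab <- table(combo)
  out <- data.frame(combination = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$combination), ]
  rownames(out) <- NULL
  out
}

#' Write / read a network edge list as TSV
#'
#' Columns: tissue, motif_a, motif_b, z, pmi_specific. Scores are
#' serialized at full precision so a write-read round trip preserves the
#' edges exactly.
#'
#' @param net an `igraph` network from [build_network()].
#' @param path output file.
#' @return `write_network_edges` returns `path` invisibly;
#'   `read_network_edges` the edge data frame.
#' @export
write_network_edges <- function(net, path) {
  tissue <- igraph::graph_attr(net, "tissue") %||% NA_character_
  if (igraph::ecount(net)) {
    el <- igraph::as_data_frame(net, what = "edges")
    df <- data.frame(tissue = tissue, motif_a = el$from, motif_b = el$to,
                     z = sprintf("%.17g", el$z),
                     pmi_specific = sprintf("%.17g", el$pmi_specific),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(tissue = character(), motif_a = character(),
                     motif_b = character(), z = character(),
                     pmi_specific = character())
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
read_network_edges <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "numeric", "numeric"))
  df
}
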