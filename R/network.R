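# Herb network construction from ranked pairs, hub-module extraction, and
# recovery evaluation against reference herb-pair lists.

#' Build a herb network from the top-ranked pairs
#'
#' @param pairs a ranked pair table from [score_all_pairs()].
#' @param top_n number of top-ranked pairs to keep as edges.  If it exceeds
#'   the number of scored pairs, all pairs are used with a warning.
#' @param properties optional named character vector of herb natural
#'   properties attached as a vertex attribute.
#' @return an undirected `igraph` graph whose edges carry `weight` (the
#'   DMIM score), `p_value` and `rank`, and whose vertices carry `name`,
#'   `natural_property` and `degree`.
#' @export
build_network <- function(pairs, top_n, properties = NULL) {
  if (top_n < 1L) stop("top_n must be at least 1")
  if (top_n > nrow(pairs)) {
    warning(sprintf("top_n = %d exceeds the %d scored pairs; using all",
                    top_n, nrow(pairs)))
    top_n <- nrow(pairs)
  }
  sel <- pairs[order(pairs$rank), , drop = FALSE][seq_len(top_n), , drop = FALSE]
  ed <- data.frame(from = sel$herb_x, to = sel$herb_y, weight = sel$score,
                   p_value = sel$p_value, rank = sel$rank,
                   n_xy = sel$n_xy, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  .decorate_vertices(g, properties)
}

.decorate_vertices <- function(g, properties = NULL) {
  if (!is.null(properties)) {
    p <- unname(properties[igraph::V(g)$name])
    p[is.na(p)] <- "Unknown"
    igraph::V(g)$natural_property <- p
  }
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Extract the hub module of significant pairs around given hub herbs
#'
#' Takes every pair significant at level `alpha` that touches a hub herb,
#' then adds the significant pairs among the herbs so included (one-hop
#' closure).  Node degree within the module is attached for sizing.
#'
#' @param pairs a pair table from [score_all_pairs()].
#' @param hubs character vector of hub herb names (must occur in `pairs`).
#' @param alpha significance level; edges require `p < alpha` (strict).
#' @param p_adjust `"none"` (default, raw per-pair p-values) or `"BH"` for
#'   Benjamini-Hochberg adjustment before thresholding.
#' @param properties optional named vector of natural properties.
#' @return an undirected `igraph` graph (hub herbs are kept as vertices even
#'   when isolated) with graph attributes `alpha` and `p_adjust`.
#' @export
extract_hub_module <- function(pairs, hubs, alpha = 0.05,
                               p_adjust = c("none", "BH"),
                               properties = NULL) {
  p_adjust <- match.arg(p_adjust)
  if (!length(hubs)) stop("hubs must be non-empty")
  universe <- union(pairs$herb_x, pairs$herb_y)
  missing <- setdiff(hubs, universe)
  if (length(missing))
    stop("hub herb(s) not found in the scored pairs: ",
         paste(missing, collapse = ", "))

  p <- if (p_adjust == "BH") stats::p.adjust(pairs$p_value, "BH") else pairs$p_value
  sig <- pairs[p < alpha, , drop = FALSE]
  touch <- sig$herb_x %in% hubs | sig$herb_y %in% hubs
  nodes <- union(hubs, c(sig$herb_x[touch], sig$herb_y[touch]))
  keep <- sig[sig$herb_x %in% nodes & sig$herb_y %in% nodes, , drop = FALSE]

  ed <- data.frame(from = keep$herb_x, to = keep$herb_y, weight = keep$score,
                   p_value = keep$p_value, rank = keep$rank,
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g <- .decorate_vertices(g, properties)
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  igraph::set_graph_attr(g, "p_adjust", p_adjust)
}

#' Read a two-column reference herb-pair list
#'
#' @param path TSV with two columns of canonical herb names, one pair per
#'   line.
#' @return data.frame with columns `herb_x`, `herb_y`.
#' @export
read_reference_pairs <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  data.frame(herb_x = trimws(df[[1L]]), herb_y = trimws(df[[2L]]),
             stringsAsFactors = FALSE)
}

#' Evaluate recovery of reference herb pairs by a network
#'
#' Compares the network's edges (unordered name pairs) with a reference
#' pair list; reference herbs that form no network edge are simply absent
#' from the comparison (edges are compared, not nodes).
#'
#' @param network an `igraph` herb network, e.g. from [build_network()].
#' @param reference_pairs two-column data.frame of canonical herb names
#'   (e.g. from [read_reference_pairs()]).
#' @return list with `n_edges`, `n_in_reference`, `n_novel`, overall
#'   `precision`, `edges` (the edge table with an `in_reference` flag, in
#'   rank order when ranks are present) and `precision_at_k` (top-k
#'   precision for each k).
#' @export
evaluate_recovery <- function(network, reference_pairs) {
  ed <- igraph::as_data_frame(network, what = "edges")
  if (nrow(ed) && "rank" %in% names(ed)) ed <- ed[order(ed$rank), , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ref <- unique(key(reference_pairs[[1L]], reference_pairs[[2L]]))
  inref <- if (nrow(ed)) key(ed$from, ed$to) %in% ref else logical(0)
  ed$in_reference <- inref
  rownames(ed) <- NULL
  k <- seq_len(nrow(ed))
  list(n_edges = nrow(ed),
       n_in_reference = sum(inref),
       n_novel = sum(!inref),
       precision = if (nrow(ed)) mean(inref) else NA_real_,
       edges = ed,
       precision_at_k = data.frame(k = k, precision = cumsum(inref) / k))
}

#' Export a herb network to GraphML or an edge-list TSV
#'
#' @param network an `igraph` graph.
#' @param path output file path.
#' @param format `"graphml"` (node attributes name/property/degree, edge
#'   attributes score/p_value/rank) or `"edgelist_tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "edgelist_tsv")) {
  format <- match.arg(format)
  network <- .decorate_vertices(network)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(network, what = "edges")
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
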