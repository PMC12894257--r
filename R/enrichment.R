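# Specificity enrichment (Fisher's exact test + Benjamini-Hochberg FDR
# over tissue / cell-type / developmental specificity panels) and
# degree-based hub detection in confidence-scored interaction networks.

#' Fisher-exact enrichment of a candidate gene set against a panel
#'
#' One 2x2 table per panel label: membership in the candidate set versus
#' membership in the label's specificity set, over the background
#' universe. Two-sided Fisher exact p, Benjamini-Hochberg q across the
#' panel.
#'
#' @param candidate character vector of gene ids (subset of background).
#' @param panel named list of gene-id sets (e.g. per tissue at a stated
#'   pSI threshold).
#' @param background gene universe; panel sets are intersected with it.
#' @param alpha significance threshold on q (default 0.05).
#' @return data.frame per label: overlap counts, odds ratio, p, q,
#'   significant.
#' @export
fisher_enrichment <- function(candidate, panel, background, alpha = 0.05) {
  if (!length(candidate) || !length(background)) {
    stop("candidate and background must be nonempty")
  }
  if (!all(candidate %in% background)) {
    stop("candidate genes must be drawn from the background universe")
  }
  rows <- lapply(names(panel), function(lbl) {
    set <- intersect(panel[[lbl]], background)
    a <- length(intersect(candidate, set))
    b <- length(setdiff(candidate, set))
    c_ <- length(setdiff(set, candidate))
    d <- length(background) - a - b - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    data.frame(label = lbl, overlap = a, candidate_size = a + b,
               set_size = a + c_, odds_ratio = unname(ft$estimate),
               p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < alpha
  out[order(out$q, out$p), ]
}

#' Benjamini-Hochberg step-up q-values
#' @param p numeric vector of p-values in [0, 1].
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Degree-based hub detection in a scored interaction network
#'
#' Edges below the confidence cutoff are removed; duplicates are
#' deduplicated keeping the maximum score per pair and self-loops are
#' dropped. Hubs are the top ceiling(fraction * n) nodes by degree among
#' nodes with at least one retained edge, ties broken by (degree,
#' lexicographic id).
#'
#' @param edges data.frame (node1, node2, combined_score in [0, 1]).
#' @param cutoff minimum confidence score (default 0.9).
#' @param fraction hub fraction (default 0.10).
#' @return a `hub_report`: degrees data.frame, hub ids, cutoff, fraction.
#' @export
hub_detection <- function(edges, cutoff = 0.9, fraction = 0.10) {
  keep <- edges$combined_score >= cutoff & edges$node1 != edges$node2
  edges <- edges[keep, , drop = FALSE]
  if (!nrow(edges)) {
    warning("no edges survive the confidence cutoff: empty hub report")
    return(structure(list(
      degrees = data.frame(node = character(0), degree = integer(0)),
      hubs = character(0), cutoff = cutoff, fraction = fraction),
      class = "hub_report"))
  }
  # canonical pair ordering, then max-score deduplication
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -edges$combined_score)
  dedup <- !duplicated(key[ord])
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[ord][dedup], to = b[ord][dedup]),
    directed = FALSE)
  deg <- igraph::degree(g)
  degrees <- data.frame(node = names(deg), degree = as.integer(deg))
  degrees <- degrees[order(-degrees$degree, degrees$node), ]
  rownames(degrees) <- NULL
  n_hub <- ceiling(fraction * nrow(degrees))
  structure(list(degrees = degrees, hubs = degrees$node[seq_len(n_hub)],
                 cutoff = cutoff, fraction = fraction),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("<hub_report> %d nodes with degree >= 1, %d hubs (cutoff %.2f)\n",
              nrow(x$degrees), length(x$hubs), x$cutoff))
  if (length(x$hubs)) cat("hubs:", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a scored edge list TSV
#' @param path TSV with columns node1, node2, combined_score.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("node1", "node2", "combined_score") %in% names(df)))
  df
}

#' @rdname read_edge_list
#' @param edges edge data.frame.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export the filtered network as GraphML for external viewers
#' @param report a `hub_report`.
#' @param edges the original scored edge list.
#' @param path .graphml output path.
#' @export
write_graphml <- function(report, edges, path) {
  keep <- edges$combined_score >= report$cutoff &
    edges$node1 != edges$node2
  g <- igraph::graph_from_data_frame(edges[keep, 1:2], directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$is_hub <- igraph::V(g)$name %in% report$hubs
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
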