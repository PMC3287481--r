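#' Build the partially directed association network
#'
#' Keeps the pair records passing both significance thresholds and turns
#' each into an edge of a signed, partially directed graph. The edge sign
#' is the sign of the LS score (positive = co-varying, negative =
#' contra-varying). Direction follows the aligned interval starts: if the
#' best-scoring interval starts earlier in X than in Y (`Xs < Ys`), X
#' leads (possibly activates) Y and the edge points from X to Y;
#' `Xs > Ys` points from Y to X; equal starts give an undirected edge.
#'
#' @param records Data frame of pair records carrying q-values (the full
#'   table from [analyze_all()]).
#' @param p_max,q_max Significance thresholds applied to the permutation
#'   `P` and q-value `Q` columns.
#' @return An [igraph][igraph::igraph-package] directed graph whose
#'   vertices are all factors appearing in `records` and whose edges
#'   carry attributes `sign` (+1/-1), `direction` (`"x_leads_y"`,
#'   `"y_leads_x"` or `"undirected"`), `ls`, `p`, `q`, and `delay`.
#'   Undirected edges are stored X -> Y with `direction = "undirected"`.
#' @export
build_network <- function(records, p_max = 0.05, q_max = 0.05) {
  stopifnot(is.data.frame(records))
  need <- c("X", "Y", "LS", "Xs", "Ys", "D", "P", "Q")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(records) > 0 && anyNA(records$Q))
    stop("records carry no q-values; run analyze_all() on the full table")
  nodes <- unique(c(records$X, records$Y))
  keep <- records[!is.na(records$P) & records$P <= p_max &
                  records$Q <= q_max, , drop = FALSE]
  edges <- data.frame(
    from = ifelse(keep$Xs > keep$Ys, keep$Y, keep$X),
    to = ifelse(keep$Xs > keep$Ys, keep$X, keep$Y),
    sign = ifelse(keep$LS >= 0, 1, -1),
    direction = ifelse(keep$Xs == keep$Ys, "undirected",
                       ifelse(keep$Xs < keep$Ys, "x_leads_y", "y_leads_x")),
    ls = keep$LS, p = keep$P, q = keep$Q, delay = keep$D,
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = nodes))
}

#' Degree distribution of an association network
#'
#' Degrees ignore edge direction (each edge contributes one degree to both
#' endpoints). The mean degree is computed over the nodes participating in
#' at least one significant edge, i.e. `2 |E| / |{v : deg(v) >= 1}|`;
#' isolated factors are excluded from the denominator (set
#' `connected_only = FALSE` to include them).
#'
#' @param network Graph from [build_network()].
#' @param connected_only Restrict the mean-degree denominator to nodes
#'   with at least one edge.
#' @return List with `counts`, a table mapping degree to node count (over
#'   all nodes), and `mean_degree`.
#' @export
degree_distribution <- function(network, connected_only = TRUE) {
  deg <- igraph::degree(network, mode = "all")
  denom <- if (connected_only) sum(deg > 0) else length(deg)
  list(counts = table(deg),
       mean_degree = if (denom > 0) 2 * igraph::ecount(network) / denom
                     else 0)
}

#' Export an association network
#'
#' Writes three files sharing `basename`: a Cytoscape SIF file
#' (`<basename>.sif`, interaction type `pa` for positive, `na` for
#' negative edges), a tab-delimited edge-attribute table
#' (`<basename>.edges.tsv` with columns `edge`, `ls`, `p`, `q`, `delay`,
#' `direction`), and a GraphML file (`<basename>.graphml`) carrying all
#' attributes.
#'
#' @param network Graph from [build_network()].
#' @param basename Output path prefix.
#' @return Invisibly, a character vector of the three file paths.
#' @export
export_network <- function(network, basename) {
  el <- igraph::as_edgelist(network)
  type <- ifelse(igraph::edge_attr(network, "sign") >= 0, "pa", "na")
  sif <- file.path(paste0(basename, ".sif"))
  if (nrow(el) > 0) {
    writeLines(paste(el[, 1L], type, el[, 2L], sep = "\t"), sif)
  } else {
    writeLines(character(0), sif)
  }
  attrs <- data.frame(
    edge = if (nrow(el) > 0)
      paste0(el[, 1L], " (", type, ") ", el[, 2L]) else character(0),
    ls = igraph::edge_attr(network, "ls") %||% numeric(0),
    p = igraph::edge_attr(network, "p") %||% numeric(0),
    q = igraph::edge_attr(network, "q") %||% numeric(0),
    delay = igraph::edge_attr(network, "delay") %||% numeric(0),
    direction = igraph::edge_attr(network, "direction") %||% character(0),
    stringsAsFactors = FALSE)
  tsv <- paste0(basename, ".edges.tsv")
  utils::write.table(attrs, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gml <- paste0(basename, ".graphml")
  igraph::write_graph(network, gml, format = "graphml")
  invisible(c(sif = sif, edges = tsv, graphml = gml))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
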