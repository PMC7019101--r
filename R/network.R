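# Topology analysis of protein-protein interaction networks: edge-list
# I/O, subnetwork merging, per-node centralities, neighborhood-connectivity
# assortativity and hub ranking. Graphs are undirected and simple
# (duplicate and reversed edges collapsed, self-loops dropped).

#' Read a PPI edge list
#'
#' Supports Cytoscape SIF (`node interaction target1 [target2 ...]`; a
#' single token declares an isolated node) and plain 2- or 3-column TSV
#' (`from`, `to`, optional interaction type). Interaction types are kept as
#' an edge attribute but ignored by all metrics.
#'
#' @param path Input path.
#' @param format `"sif"` or `"tsv"`; defaults from the file extension.
#' @return An undirected simple `igraph` graph with named vertices.
#' @export
read_edge_list <- function(path, format = c("auto", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  edges <- list(); isolated <- character(0); types <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (format == "sif") {
      if (length(tok) == 1L) {
        isolated <- c(isolated, tok)
      } else if (length(tok) == 2L) {
        stop(sprintf("line %d: SIF line with 2 tokens (missing target)", i),
             call. = FALSE)
      } else {
        for (t in tok[3:length(tok)]) {
          edges[[length(edges) + 1L]] <- c(tok[1L], t)
          types <- c(types, tok[2L])
        }
      }
    } else {
      if (i == 1L && identical(tolower(tok[1:2]), c("from", "to"))) next
      if (length(tok) == 1L) {
        isolated <- c(isolated, tok)
      } else if (length(tok) %in% c(2L, 3L)) {
        edges[[length(edges) + 1L]] <- tok[1:2]
        types <- c(types, if (length(tok) == 3L) tok[3L] else NA_character_)
      } else {
        stop(sprintf("line %d: expected 2 or 3 columns, found %d",
                     i, length(tok)), call. = FALSE)
      }
    }
  }
  build_ppi_graph(edges, isolated, types)
}

build_ppi_graph <- function(edges, isolated = character(0),
                            types = NULL) {
  if (length(edges)) {
    em <- do.call(rbind, edges)
    loops <- em[, 1L] == em[, 2L]
    if (any(loops)) {
      warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
    }
  } else {
    em <- matrix(character(0), 0, 2)
    loops <- logical(0)
  }
  # loop endpoints stay in the graph as isolated nodes
  nodes <- unique(c(as.vector(t(em)), isolated))
  em <- em[!loops, , drop = FALSE]
  if (!is.null(types)) types <- types[!loops]
  g <- igraph::graph_from_data_frame(
    d = if (nrow(em)) data.frame(from = em[, 1L], to = em[, 2L],
                                 interaction = types %||% rep(NA_character_, nrow(em)),
                                 stringsAsFactors = FALSE)
        else data.frame(from = character(0), to = character(0),
                        interaction = character(0)),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

#' Write a graph as SIF
#'
#' @param graph An `igraph` graph with named vertices.
#' @param path Output path.
#' @param default_interaction Interaction label used where the edge
#'   attribute is missing (default `"pp"`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path, default_interaction = "pp") {
  el <- igraph::as_edgelist(graph, names = TRUE)
  ty <- if ("interaction" %in% igraph::edge_attr_names(graph)) {
    igraph::edge_attr(graph, "interaction")
  } else rep(NA_character_, nrow(el))
  ty[is.na(ty)] <- default_interaction
  lines <- if (nrow(el)) paste(el[, 1L], ty, el[, 2L], sep = "\t") else character(0)
  iso <- setdiff(igraph::V(graph)$name,
                 unique(as.vector(el)))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Merge PPI subnetworks
#'
#' Union of node and edge sets; nodes shared between subnetworks are fused
#' by label. Idempotent and commutative.
#'
#' @param graphs List of `igraph` graphs with named vertices.
#' @return The merged undirected simple graph.
#' @export
merge_networks <- function(graphs) {
  if (length(graphs) < 1L) stop_config("need at least one graph")
  edges <- list(); types <- character(0); nodes <- character(0)
  for (g in graphs) {
    el <- igraph::as_edgelist(g, names = TRUE)
    for (r in seq_len(nrow(el))) edges[[length(edges) + 1L]] <- el[r, ]
    ty <- if ("interaction" %in% igraph::edge_attr_names(g)) {
      igraph::edge_attr(g, "interaction")
    } else rep(NA_character_, nrow(el))
    types <- c(types, ty)
    nodes <- c(nodes, igraph::V(g)$name)
  }
  build_ppi_graph(edges, unique(nodes), types)
}

#' Per-node topology metrics
#'
#' Computes, for every node: degree; neighborhood connectivity (mean degree
#' over neighbors; `NaN` for isolates); betweenness centrality normalized
#' by `(n-1)(n-2)/2`; and closeness centrality using the
#' fraction-reachable scaling for disconnected graphs,
#' `(r/(n-1)) * (r / sum of distances to the r reachable nodes)` (0 for
#' isolates), which reduces to the usual normalized closeness on connected
#' graphs.
#'
#' @param graph An `igraph` graph with named vertices.
#' @return Data frame with columns `node`, `degree`,
#'   `neighborhood_connectivity`, `betweenness`, `closeness`.
#' @export
node_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) {
    return(data.frame(node = character(0), degree = integer(0),
                      neighborhood_connectivity = numeric(0),
                      betweenness = numeric(0), closeness = numeric(0)))
  }
  deg <- igraph::degree(graph)
  adj <- igraph::as_adj_list(graph)
  knn <- vapply(adj, function(nb) {
    if (length(nb) == 0L) NaN else mean(deg[as.integer(nb)])
  }, numeric(1))
  btw <- if (n > 2L) {
    igraph::betweenness(graph, directed = FALSE) / ((n - 1) * (n - 2) / 2)
  } else rep(0, n)
  d <- igraph::distances(graph)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r == 0L || n == 1L) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
  data.frame(node = igraph::V(graph)$name, degree = as.integer(deg),
             neighborhood_connectivity = knn,
             betweenness = unname(btw), closeness = clo,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Degree-class assortativity fit
#'
#' Least-squares fit of log mean neighborhood connectivity against log
#' degree over degree classes `k >= 1`. A negative slope (beyond a 1e-9
#' tolerance) indicates disassortative mixing — high-degree hubs attached
#' preferentially to low-degree nodes.
#'
#' @param graph An `igraph` graph.
#' @return List with `slope`, `intercept`, `mixing` (one of
#'   `"disassortative"`, `"assortative"`, `"neutral/undefined"`) and
#'   `classes` (per-degree-class mean neighborhood connectivity). With
#'   fewer than two degree classes the slope is `NA` and mixing is
#'   `"neutral/undefined"`.
#' @export
assortativity_fit <- function(graph, tol = 1e-9) {
  nm <- node_metrics(graph)
  ok <- nm$degree >= 1L & is.finite(nm$neighborhood_connectivity)
  if (!any(ok)) {
    return(list(slope = NA_real_, intercept = NA_real_,
                mixing = "neutral/undefined",
                classes = data.frame(degree = integer(0),
                                     mean_knn = numeric(0))))
  }
  agg <- stats::aggregate(nm$neighborhood_connectivity[ok],
                   by = list(degree = nm$degree[ok]), FUN = mean)
  names(agg)[2] <- "mean_knn"
  if (nrow(agg) < 2L) {
    return(list(slope = NA_real_, intercept = NA_real_,
                mixing = "neutral/undefined", classes = agg))
  }
  fit <- stats::lm(log(mean_knn) ~ log(degree), data = agg)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  mixing <- if (slope < -tol) "disassortative"
            else if (slope > tol) "assortative"
            else "neutral/undefined"
  list(slope = slope, intercept = intercept, mixing = mixing, classes = agg)
}

#' Rank hub nodes
#'
#' Descending order by the chosen centrality; ties break by the other
#' centrality (descending), then by node label ascending.
#'
#' @param metrics Data frame from [node_metrics()].
#' @param k Number of hubs to return.
#' @param key `"betweenness"` or `"closeness"`.
#' @return The top `k` rows of `metrics`, re-ranked; if `k` exceeds the
#'   node count all nodes are returned with a warning.
#' @export
top_hubs <- function(metrics, k, key = c("betweenness", "closeness")) {
  key <- match.arg(key)
  stopifnot(k >= 1)
  other <- setdiff(c("betweenness", "closeness"), key)
  ord <- order(-metrics[[key]], -metrics[[other]], metrics$node,
               method = "radix")
  if (k > nrow(metrics)) {
    warning(sprintf("k = %d exceeds node count %d; returning all nodes",
                    k, nrow(metrics)), call. = FALSE)
    k <- nrow(metrics)
  }
  out <- metrics[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
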