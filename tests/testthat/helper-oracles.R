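# Independent brute-force oracles used to check the package's
# implementations on small inputs. These deliberately share no code with
# the package internals.

# Step-up BH by direct evaluation of q_(i) = min_{j >= i} p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(n), function(i) {
    min(1, min(ps[i:n] * n / (i:n)))
  }, numeric(1))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Venn region counts by per-id membership enumeration.
oracle_venn <- function(sources) {
  ids <- unique(unlist(sources))
  labels <- names(sources)
  sig <- vapply(ids, function(id) {
    paste(labels[vapply(sources, function(s) id %in% s, logical(1))],
          collapse = "&")
  }, "")
  table(sig)
}

# Minimal span containing c elements of a position vector, by checking
# every window over the sorted values.
oracle_min_width <- function(positions, c) {
  p <- sort(positions)
  m <- length(p)
  min(vapply(seq_len(m - c + 1), function(j) p[j + c - 1] - p[j] + 1,
             numeric(1)))
}

# Exact null cluster probabilities by full enumeration of all L^m draws.
# Returns P(min_width(c) <= span) as a function.
oracle_exact_null <- function(m, L) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), m)))
  widths <- lapply(seq_len(m), function(c) {
    apply(grid, 1, function(row) oracle_min_width(row, c))
  })
  function(c, span) mean(widths[[c]] <= span)
}

# Interval membership count by direct enumeration.
oracle_interval_count <- function(positions, start, end) {
  sum(positions >= start & positions <= end)
}

# --- graph oracles -------------------------------------------------------

# All shortest paths between a and b in an adjacency matrix, by DFS over
# simple paths. Returns a list of node-index vectors.
oracle_shortest_paths <- function(adj, a, b) {
  n <- nrow(adj)
  best <- Inf
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == b) {
      len <- length(path) - 1
      if (len < best) {
        best <<- len
        paths <<- list(path)
      } else if (len == best) {
        paths[[length(paths) + 1]] <<- path
      }
      return()
    }
    if (length(path) - 1 >= best) return()
    for (nxt in which(adj[last, ] == 1)) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(a)
  paths
}

# Degree, mean neighbor degree, normalized betweenness and
# fraction-reachable-scaled closeness, all by path enumeration.
oracle_node_metrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  knn <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) == 0) NaN else mean(deg[nb])
  }, numeric(1))
  btw <- numeric(n)
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  if (n >= 2) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      paths <- oracle_shortest_paths(adj, a, b)
      if (length(paths) == 0) next
      dist[a, b] <- dist[b, a] <- length(paths[[1]]) - 1
      for (v in seq_len(n)) {
        if (v == a || v == b) next
        through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + through / length(paths)
      }
    }
  }
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  clo <- vapply(seq_len(n), function(i) {
    di <- dist[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
  data.frame(degree = deg, neighborhood_connectivity = knn,
             betweenness = btw / norm, closeness = clo)
}

# igraph from a 0/1 adjacency matrix with letter names, via the package's
# own edge-list entry point (not graph_from_adjacency_matrix) so the
# comparison covers the reader path.
graph_from_adj <- function(adj) {
  n <- nrow(adj)
  names_ <- LETTERS[seq_len(n)]
  lines <- character(0)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b > a && adj[a, b] == 1) {
      lines <- c(lines, paste(names_[a], "pp", names_[b], sep = "\t"))
    }
  }
  lines <- c(lines, names_[rowSums(adj) == 0])
  tf <- tempfile(fileext = ".sif")
  writeLines(lines, tf)
  g <- read_edge_list(tf)
  unlink(tf)
  g
}

# Align node_metrics() output (ordered by graph vertex ids) to adjacency
# index order A, B, C, ...
align_metrics <- function(nm, n) {
  nm[match(LETTERS[seq_len(n)], nm$node), ]
}
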