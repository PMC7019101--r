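# Bootstrap detection of positional mutation clusters along a protein.
#
# The null model places the observed number of variant positions i.i.d.
# uniformly over residues 1..L (resampling with replacement), B times. For
# every replicate and every cluster size c, the minimal span of a window
# containing c resampled positions is recorded; a candidate cluster of n
# variants over span s is then scored by how often the null achieves a span
# of at most s for c = n. Benjamini-Hochberg correction across all
# candidates yields the called clusters, whose per-residue coverage counts
# form the hotspot track.

#' Enumerate candidate clusters
#'
#' One candidate per ordered pair (i <= j) of distinct position values,
#' spanning `v[i]..v[j]` and counting all variants inside with
#' multiplicity. `d` distinct values yield `d(d+1)/2` candidates
#' (singletons included).
#'
#' @param positions Integer vector of variant residue positions (duplicates
#'   allowed).
#' @return Data frame with columns `start`, `end`, `n_variants`, `span`;
#'   empty for empty input.
#' @export
enumerate_candidate_clusters <- function(positions) {
  positions <- as.integer(positions)
  if (length(positions) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_variants = integer(0), span = integer(0)))
  }
  if (any(is.na(positions)) || any(positions < 1L)) {
    stop_config("positions must be positive integers")
  }
  v <- sort(unique(positions))
  d <- length(v)
  idx <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  start <- v[idx[, 1L]]
  end <- v[idx[, 2L]]
  # cumulative multiplicity up to each distinct value gives interval counts
  mult <- cumsum(tabulate(match(sort(positions), v), nbins = d))
  below <- c(0L, mult[-d])
  n <- mult[idx[, 2L]] - below[idx[, 1L]]
  data.frame(start = start, end = end, n_variants = as.integer(n),
             span = end - start + 1L)
}

#' Build the bootstrap null model
#'
#' Draws `B` replicates of `m` positions i.i.d. uniform over `1..L` and
#' records, for each replicate and each cluster size `c` in `1..m`, the
#' minimal span containing `c` of the resampled positions (min over `j` of
#' `p[j + c - 1] - p[j] + 1` on the sorted replicate).
#'
#' @param m Number of variant positions.
#' @param L Protein length in residues.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed; the caller's RNG stream is left
#'   untouched.
#' @return An object of class `"hotspot_null"`: list with `m`, `L`, `B`,
#'   `seed` and `min_width` (a `B x m` integer matrix, non-decreasing in
#'   `c` within each replicate).
#' @export
build_null <- function(m, L, B = 1000, seed = NULL) {
  stopifnot(m >= 1, L >= 1, B >= 1)
  m <- as.integer(m); L <- as.integer(L); B <- as.integer(B)
  min_width <- with_seed(seed, {
    smp <- matrix(sample.int(L, B * m, replace = TRUE), nrow = B, ncol = m)
    smp <- matrix(smp[order(row(smp), smp)], nrow = B, byrow = TRUE)
    mw <- matrix(NA_integer_, B, m)
    for (c in seq_len(m)) {
      w <- smp[, c] - smp[, 1L]
      nwin <- m - c + 1L
      if (nwin > 1L) {
        for (j in 2:nwin) w <- pmin(w, smp[, j + c - 1L] - smp[, j])
      }
      mw[, c] <- w + 1L
    }
    mw
  })
  structure(list(m = m, L = L, B = B, seed = seed, min_width = min_width),
            class = "hotspot_null")
}

#' Bootstrap p-value of candidate clusters
#'
#' For a candidate of `n` variants over span `s`, the p-value is the
#' pseudocounted fraction of null replicates at least as clustered:
#' `(1 + #{min_width(c = n) <= s}) / (B + 1)`.
#'
#' @param candidates Data frame as from [enumerate_candidate_clusters()].
#' @param null A `"hotspot_null"` from [build_null()].
#' @return Numeric vector of raw p-values in `(0, 1]`, one per candidate.
#' @export
cluster_pvalue <- function(candidates, null) {
  stopifnot(inherits(null, "hotspot_null"))
  if (nrow(candidates) == 0L) return(numeric(0))
  if (any(candidates$n_variants > null$m)) {
    stop_config("candidate contains more variants than the null model's m")
  }
  sorted_widths <- lapply(seq_len(null$m),
                          function(c) sort(null$min_width[, c]))
  counts <- mapply(function(n, s) findInterval(s, sorted_widths[[n]]),
                   candidates$n_variants, candidates$span)
  (1 + counts) / (null$B + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control:
#' `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @param alpha Significance level on the adjusted values (default 0.05).
#' @return List with `q` (adjusted values, input order) and `significant`
#'   (logical, `q <= alpha`).
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, significant = q <= alpha)
}

#' Call mutation hotspots along a protein
#'
#' Full pipeline: enumerate candidate clusters over the observed positions,
#' build the uniform-placement bootstrap null, score every candidate,
#' correct with Benjamini-Hochberg, and sum the significant clusters
#' covering each residue into the hotspot track. Deterministic given
#' `seed`.
#'
#' @param positions Nonempty integer vector of variant residue positions.
#' @param L Protein length (default 1391, the NUP155 residue count); must
#'   be at least `max(positions)`.
#' @param B Bootstrap replicates (default 1000).
#' @param alpha FDR level (default 0.05).
#' @param seed Optional integer seed.
#' @return An object of class `"hotspot_scan"`: list with `clusters` (data
#'   frame `start`, `end`, `n_variants`, `span`, `p_raw`, `q_bh`,
#'   `significant`), `track` (integer vector of length `L`; entry `i`
#'   counts the significant clusters covering residue `i`), and the call
#'   parameters.
#' @export
call_hotspots <- function(positions, L = 1391, B = 1000, alpha = 0.05,
                          seed = NULL) {
  positions <- as.integer(positions)
  if (length(positions) == 0L) stop_config("positions must be nonempty")
  if (any(is.na(positions)) || any(positions < 1L)) {
    stop_config("positions must be positive integers")
  }
  if (max(positions) > L) {
    stop_config("protein length L = %d smaller than max position %d",
                L, max(positions))
  }
  clusters <- enumerate_candidate_clusters(positions)
  null <- build_null(m = length(positions), L = L, B = B, seed = seed)
  clusters$p_raw <- cluster_pvalue(clusters, null)
  adj <- bh_adjust(clusters$p_raw, alpha = alpha)
  clusters$q_bh <- adj$q
  clusters$significant <- adj$significant
  track <- integer(L)
  sig <- clusters[clusters$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    idx <- sig$start[i]:sig$end[i]
    track[idx] <- track[idx] + 1L
  }
  structure(list(clusters = clusters, track = track, L = L, B = B,
                 alpha = alpha, seed = seed,
                 positions = positions),
            class = "hotspot_scan")
}

#' Write a hotspot track as bedGraph-like text
#'
#' Converts the 1-based inclusive per-residue track to 0-based half-open
#' intervals, merging runs of equal counts.
#'
#' @param track Integer vector of per-residue counts.
#' @param path Output path.
#' @param name Sequence name for the first column (default
#'   `"protein"`).
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path, name = "protein") {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts0 <- c(0L, ends[-length(ends)])
  df <- data.frame(name = name, start = starts0, end = ends,
                   count = r$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
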