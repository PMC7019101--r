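# Synthetic inputs with the statistical structure the analysis assumes:
# annotated missense variant tables with configurable positional hotspots
# and class-dependent score distributions, and preferential-attachment PPI
# graphs with planted hubs. Every generator is deterministic given a seed
# and writes/returns the same generic formats the readers consume.

# Default beta shapes per metric and class, drawn over each metric's
# declared range (low -> high). Chosen so the default thresholds separate
# "damaging" from "benign" imperfectly (roughly 5-15% class overlap per
# metric) rather than perfectly.
DEFAULT_SCORE_DISTS <- list(
  polyphen2_score = list(range = c(0, 1),
                         damaging = c(14, 1), benign = c(1, 6)),
  grantham        = list(range = c(5, 215),
                         damaging = c(3, 1.5), benign = c(1.5, 3)),
  provean         = list(range = c(-13, 4),      # deleterious = low
                         damaging = c(1.2, 4), benign = c(4, 1.2)),
  sift            = list(range = c(0, 1),        # deleterious = low
                         damaging = c(1, 60), benign = c(3, 1.2)),
  phastcons       = list(range = c(0, 1),
                         damaging = c(60, 1), benign = c(2, 2)),
  gerp            = list(range = c(-12.3, 6.17),
                         damaging = c(12, 1.5), benign = c(2, 2))
)

draw_score <- function(n, spec, class) {
  shp <- spec[[class]]
  spec$range[1] + diff(spec$range) * stats::rbeta(n, shp[1], shp[2])
}

#' Generate a synthetic annotated variant table
#'
#' Positions are drawn from a mixture of weighted hotspot intervals and a
#' uniform background over `1..L`; each variant is independently labeled
#' `"damaging"` or `"benign"` (probability `class_mix`) and its six
#' predictor scores drawn from class-specific beta distributions over the
#' metrics' declared ranges. Allele frequencies are log-uniform over
#' `10^af_log10_range`. Output parses cleanly through
#' [read_variant_table()] with the generic dialect.
#'
#' @param n_variants Number of variants.
#' @param L Protein length (default 1391).
#' @param hotspot_intervals Optional data frame `start`, `end`, `weight`;
#'   each weight is the mixture probability of drawing a position uniformly
#'   inside that interval, the remaining mass `1 - sum(weight)` being
#'   uniform background over the whole protein.
#' @param class_mix Fraction of variants drawn from the damaging score
#'   distributions (default 0.5).
#' @param af_log10_range Log10 allele-frequency range, default
#'   `c(-5.4, -3.15)` (about 4e-6 to 7e-4, the span observed for rare
#'   pathogenic-candidate missense alleles).
#' @param gene Gene symbol written to the table (default `"NUP155"`).
#' @param damaging_scores Optional named list of fixed score values used
#'   for the damaging class instead of random draws (e.g. to pin every
#'   damaging row to a known pass-all profile).
#' @param seed Optional integer seed; same seed, same table.
#' @return List with `variants` (generic-schema data frame) and `truth`
#'   (data frame `rsid`, `class`, `in_hotspot`).
#' @export
gen_variant_table <- function(n_variants, L = 1391,
                              hotspot_intervals = NULL,
                              class_mix = 0.5,
                              af_log10_range = c(-5.4, -3.15),
                              gene = "NUP155",
                              damaging_scores = NULL,
                              seed = NULL) {
  stopifnot(n_variants >= 1, L >= 1, class_mix >= 0, class_mix <= 1)
  hi <- hotspot_intervals
  if (!is.null(hi)) {
    stopifnot(all(c("start", "end", "weight") %in% names(hi)))
    if (any(hi$weight < 0)) stop_config("hotspot weights must be >= 0")
    if (sum(hi$weight) > 1) stop_config("hotspot weights must sum to <= 1")
    if (any(hi$start < 1 | hi$end > L | hi$start > hi$end)) {
      stop_config("hotspot intervals must lie within 1..L")
    }
    if (sum(hi$weight) == 1 && sum(hi$end - hi$start + 1) == 0) {
      stop_config("spec assigns all weight to zero-length intervals")
    }
  }
  with_seed(seed, {
    n <- n_variants
    # mixture component per variant: 0 = background, i = interval i
    wts <- c(1 - sum(hi$weight %||% 0), hi$weight %||% numeric(0))
    comp <- sample.int(length(wts), n, replace = TRUE, prob = wts) - 1L
    position <- integer(n)
    bg <- comp == 0L
    position[bg] <- sample.int(L, sum(bg), replace = TRUE)
    for (i in seq_len(length(wts) - 1L)) {
      sel <- comp == i
      if (any(sel)) {
        width <- hi$end[i] - hi$start[i] + 1L
        position[sel] <- hi$start[i] +
          sample.int(width, sum(sel), replace = TRUE) - 1L
      }
    }
    cls <- ifelse(stats::runif(n) < class_mix, "damaging", "benign")
    score <- function(metric) {
      out <- numeric(n)
      for (cl in c("damaging", "benign")) {
        sel <- cls == cl
        if (!any(sel)) next
        if (cl == "damaging" && !is.null(damaging_scores) &&
            !is.null(damaging_scores[[metric]])) {
          out[sel] <- damaging_scores[[metric]]
        } else {
          out[sel] <- draw_score(sum(sel), DEFAULT_SCORE_DISTS[[metric]], cl)
        }
      }
      out
    }
    pp2 <- round(score("polyphen2_score"), 4)
    pp2_class <- ifelse(pp2 > 0.85, "probably-damaging",
                        ifelse(pp2 > 0.45, "possibly-damaging", "benign"))
    if (!is.null(damaging_scores$polyphen2_class)) {
      pp2_class[cls == "damaging"] <- damaging_scores$polyphen2_class
    }
    af <- 10^stats::runif(n, af_log10_range[1], af_log10_range[2])
    ref <- sample(AA1, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(AA1, r), 1L), "")
    rsid <- sprintf("rs9%08d", seq_len(n))
    allele_count <- pmax(1L, stats::rpois(n, lambda = af * 250000))
    variants <- data.frame(
      rsid = rsid, gene = gene,
      protein_change = paste0(ref, position, alt),
      consequence = "missense", variant_class = "snv",
      allele_frequency = af,
      allele_count = allele_count,
      hom_count = 0L,
      polyphen2_class = pp2_class,
      polyphen2_score = pp2,
      grantham = round(score("grantham"), 1),
      provean = round(score("provean"), 2),
      sift = round(score("sift"), 4),
      phastcons = round(score("phastcons"), 3),
      gerp = round(score("gerp"), 2),
      stringsAsFactors = FALSE
    )
    in_hotspot <- rep(FALSE, n)
    if (!is.null(hi)) {
      for (i in seq_len(nrow(hi))) {
        in_hotspot <- in_hotspot | (position >= hi$start[i] &
                                      position <= hi$end[i])
      }
    }
    truth <- data.frame(rsid = rsid, class = cls, in_hotspot = in_hotspot,
                        position = position, stringsAsFactors = FALSE)
    list(variants = variants, truth = truth)
  })
}

#' Generate a preferential-attachment PPI graph with planted hubs
#'
#' Grows a simple undirected graph by preferential attachment: each new
#' node connects to `edges_per_node` existing nodes chosen with
#' probability proportional to degree + 1, multiplied by `hub_boost` for
#' planted hub nodes (which are seeded into the initial core).
#'
#' @param n_nodes Total node count (default 35, a typical curated
#'   subnetwork size; use e.g. 175 for a merged five-subnetwork graph).
#' @param planted_hubs Character vector of node labels to plant as hubs.
#' @param edges_per_node Edges added per incoming node (default 2).
#' @param hub_boost Attachment multiplier for planted hubs (default 20).
#' @param prefix Label prefix for ordinary nodes (default `"P"`).
#' @param seed Optional integer seed.
#' @return List with `graph` (an `igraph`), `edges` (two-column data
#'   frame) and `hubs` (the planted labels).
#' @export
gen_ppi_graph <- function(n_nodes = 35, planted_hubs = character(0),
                          edges_per_node = 2, hub_boost = 20,
                          prefix = "P", seed = NULL) {
  stopifnot(n_nodes >= 2)
  n_ord <- n_nodes - length(planted_hubs)
  if (n_ord < 0) stop_config("more planted hubs than nodes")
  labels <- c(planted_hubs, sprintf("%s%03d", prefix, seq_len(n_ord)))
  with_seed(seed, {
    core <- min(max(2L, length(planted_hubs) + 1L), n_nodes)
    deg <- integer(n_nodes)
    edges <- list()
    add_edge <- function(a, b) {
      edges[[length(edges) + 1L]] <<- c(labels[a], labels[b])
      deg[a] <<- deg[a] + 1L
      deg[b] <<- deg[b] + 1L
    }
    for (i in 2:core) add_edge(i - 1L, i)
    boost <- rep(1, n_nodes)
    boost[seq_along(planted_hubs)] <- hub_boost
    if (core < n_nodes) {
      for (i in (core + 1L):n_nodes) {
        avail <- seq_len(i - 1L)
        w <- (deg[avail] + 1) * boost[avail]
        k <- min(edges_per_node, length(avail))
        targets <- sample(avail, k, prob = w)
        for (t in targets) add_edge(t, i)
      }
    }
    g <- build_ppi_graph(edges, labels)
    el <- igraph::as_edgelist(g, names = TRUE)
    list(graph = g,
         edges = data.frame(from = el[, 1L], to = el[, 2L],
                            stringsAsFactors = FALSE),
         hubs = planted_hubs)
  })
}

#' Packaged table of 24 rare NUP155 missense variants
#'
#' Returns the bundled annotation table of 24 rare NUP155 missense
#' variants (rsID, protein change, PolyPhen-2 class and score, Grantham,
#' PROVEAN, SIFT, PhastCons, GERP, gnomAD allele frequency) transcribed
#' from published population-database reports; all 24 are heterozygous
#' probably-damaging candidates on the 1391-residue NUP155 protein.
#'
#' @return A variant table as from [read_variant_table()], 24 rows.
#' @export
nup155_variants <- function() {
  path <- system.file("extdata", "nup155_missense24.tsv",
                      package = "varhotspot")
  read_variant_table(path, dialect = "generic")
}

#' Illustrative NUP155 subdomain intervals
#'
#' Returns the bundled synthetic stand-in for NUP155's beta-propeller /
#' crescent alpha-helical / C-terminal stack subdomain boundaries. The true
#' residue boundaries are not published; these intervals are illustrative
#' only and should be replaced for any real analysis.
#'
#' @return Domain interval data frame (`name`, `start`, `end`).
#' @export
nup155_domains_example <- function() {
  path <- system.file("extdata", "nup155_domains_synthetic.tsv",
                      package = "varhotspot")
  read_domain_table(path, L = 1391)
}
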