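# Consensus deleteriousness prioritization: per-metric thresholds, consensus
# rules, minor-allele-frequency benchmarking, ranking.

METRICS <- c("polyphen2", "grantham", "provean", "sift", "phastcons", "gerp")

#' Deleteriousness threshold configuration
#'
#' Bundles the per-metric cutoffs, the consensus rule and the MAF
#' benchmarks used by [score_flags()], [consensus_prioritize()] and
#' [rank_variants()].
#'
#' Metric conventions: PolyPhen-2 passes when the class equals
#' `polyphen2_required_class` *and* the score is at least
#' `polyphen2_score_min`; Grantham passes at `>= grantham_min` (the
#' published starred values include the boundary itself); PROVEAN and SIFT
#' are strict (`< provean_max`, `< sift_max`); PhastCons and GERP pass at
#' `>=` their minima. The default MAF benchmarks are the gnomAD frequencies
#' of two pathogenic SCN5A alleles used as rarity yardsticks
#' (S216L, 6.5e-4; F2004L, 1.9e-3).
#'
#' @param polyphen2_required_class Class required for a PolyPhen-2 pass.
#' @param polyphen2_score_min Minimum PolyPhen-2 score (default 0.85, the
#'   conventional confident probably-damaging bound; 0.97 reproduces the
#'   published 24-variant list).
#' @param grantham_min Minimum Grantham distance (default 125).
#' @param provean_max Strict upper bound on PROVEAN (default -2.5).
#' @param sift_max Strict upper bound on SIFT (default 0.05).
#' @param phastcons_min Minimum PhastCons (default 0.95).
#' @param gerp_min Minimum GERP (default 2.0).
#' @param consensus_mode `"class_only"` (PolyPhen-2 flag alone),
#'   `"all_metrics"` (all six must pass) or `"k_of_n"` (`n_pass >= k`).
#' @param k Required pass count for `"k_of_n"`.
#' @param maf_benchmarks Named numeric vector of benchmark allele
#'   frequencies, ordered or not; the smallest defines the strict-rare tier.
#' @param maf_mode `"strict_rare"` (single benchmark, the smallest) or
#'   `"two_tier"` (rarer benchmark first, survivors of the second reported
#'   separately).
#' @return An object of class `"threshold_config"`.
#' @export
threshold_config <- function(polyphen2_required_class = "probably-damaging",
                             polyphen2_score_min = 0.85,
                             grantham_min = 125,
                             provean_max = -2.5,
                             sift_max = 0.05,
                             phastcons_min = 0.95,
                             gerp_min = 2.0,
                             consensus_mode = c("class_only", "all_metrics",
                                                "k_of_n"),
                             k = NULL,
                             maf_benchmarks = c(S216L = 6.5e-4,
                                                F2004L = 1.9e-3),
                             maf_mode = c("strict_rare", "two_tier")) {
  consensus_mode <- match.arg(consensus_mode)
  maf_mode <- match.arg(maf_mode)
  if (!polyphen2_required_class %in% POLYPHEN2_CLASSES) {
    stop_config("unknown PolyPhen-2 class '%s'", polyphen2_required_class)
  }
  in_range <- function(x, rng, name) {
    if (x < rng[1] || x > rng[2]) {
      stop_config("cutoff %s = %g outside declared metric range [%g, %g]",
                  name, x, rng[1], rng[2])
    }
  }
  in_range(polyphen2_score_min, SCORE_RANGES$polyphen2_score, "polyphen2_score_min")
  in_range(grantham_min, SCORE_RANGES$grantham, "grantham_min")
  in_range(sift_max, SCORE_RANGES$sift, "sift_max")
  in_range(phastcons_min, SCORE_RANGES$phastcons, "phastcons_min")
  in_range(gerp_min, SCORE_RANGES$gerp, "gerp_min")
  if (consensus_mode == "k_of_n") {
    if (is.null(k)) stop_config("consensus_mode 'k_of_n' requires k")
    if (k < 1 || k > length(METRICS)) stop_config("k must be in 1..6")
  }
  if (any(maf_benchmarks <= 0 | maf_benchmarks > 1)) {
    stop_config("maf_benchmarks must lie in (0, 1]")
  }
  structure(list(
    polyphen2_required_class = polyphen2_required_class,
    polyphen2_score_min = polyphen2_score_min,
    grantham_min = grantham_min,
    provean_max = provean_max,
    sift_max = sift_max,
    phastcons_min = phastcons_min,
    gerp_min = gerp_min,
    consensus_mode = consensus_mode,
    k = k,
    maf_benchmarks = sort(maf_benchmarks),
    maf_mode = maf_mode
  ), class = "threshold_config")
}

as_threshold_config <- function(config) {
  if (inherits(config, "threshold_config")) return(config)
  if (is.list(config)) return(do.call(threshold_config, config))
  stop_config("config must be a threshold_config or an argument list")
}

#' Per-metric pass/fail/missing flags
#'
#' Evaluates each of the six deleteriousness metrics against the cutoffs in
#' `config`. A missing score yields `"missing"`, never a pass.
#'
#' @param variants Variant table.
#' @param config A [threshold_config()].
#' @return Data frame with one `"pass"`/`"fail"`/`"missing"` column per
#'   metric plus `n_pass`, row-aligned with `variants`.
#' @export
score_flags <- function(variants, config = threshold_config()) {
  config <- as_threshold_config(config)
  df <- variants
  flag <- function(value, ok) {
    ifelse(is.na(value), "missing", ifelse(ok, "pass", "fail"))
  }
  pp2_val <- ifelse(is.na(df$polyphen2_class) | is.na(df$polyphen2_score),
                    NA_real_, df$polyphen2_score)
  out <- data.frame(
    polyphen2 = flag(pp2_val,
                     !is.na(df$polyphen2_class) &
                       df$polyphen2_class == config$polyphen2_required_class &
                       df$polyphen2_score >= config$polyphen2_score_min),
    grantham = flag(df$grantham, df$grantham >= config$grantham_min),
    provean = flag(df$provean, df$provean < config$provean_max),
    sift = flag(df$sift, df$sift < config$sift_max),
    phastcons = flag(df$phastcons, df$phastcons >= config$phastcons_min),
    gerp = flag(df$gerp, df$gerp >= config$gerp_min),
    stringsAsFactors = FALSE
  )
  out$n_pass <- rowSums(out == "pass")
  out
}

maf_tier <- function(allele_frequency, config) {
  bm <- config$maf_benchmarks
  ifelse(is.na(allele_frequency), "fail",
         ifelse(allele_frequency < bm[1], "rare_pass",
                ifelse(allele_frequency < bm[length(bm)], "tier2_pass",
                       "fail")))
}

#' Consensus prioritization of variants
#'
#' Applies the configured consensus rule to the per-metric flags:
#' `"class_only"` prioritizes on the PolyPhen-2 flag alone,
#' `"all_metrics"` requires all six metrics to pass, `"k_of_n"` requires
#' `n_pass >= k`. Input order is preserved.
#'
#' @param variants Variant table.
#' @param config A [threshold_config()].
#' @return Data frame with `rsid`, `protein_change`, the six metric flag
#'   columns, `n_pass`, `prioritized` and `maf_tier`.
#' @export
consensus_prioritize <- function(variants, config = threshold_config()) {
  config <- as_threshold_config(config)
  flags <- score_flags(variants, config)
  prioritized <- switch(
    config$consensus_mode,
    class_only = flags$polyphen2 == "pass",
    all_metrics = rowSums(flags[METRICS] == "pass") == length(METRICS),
    k_of_n = flags$n_pass >= config$k
  )
  cbind(
    data.frame(rsid = variants$rsid,
               protein_change = variants$protein_change,
               stringsAsFactors = FALSE),
    flags,
    data.frame(prioritized = prioritized,
               maf_tier = maf_tier(variants$allele_frequency, config),
               stringsAsFactors = FALSE)
  )
}

#' Minor-allele-frequency filter
#'
#' Retains variants whose allele frequency is strictly below `threshold`.
#'
#' @param variants Variant table.
#' @param threshold Allele frequency in (0, 1].
#' @return The retained rows of `variants`, original order preserved.
#' @export
maf_filter <- function(variants, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop_config("MAF threshold must lie in (0, 1]")
  }
  keep <- !is.na(variants$allele_frequency) &
    variants$allele_frequency < threshold
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank variants by predicted pathogenicity
#'
#' Orders variants by descending lexicographic key
#' (`n_pass`, PolyPhen-2 score, -SIFT, -PROVEAN); ties after all four keys
#' break by ascending rsID. Missing scores sort after present ones within
#' each key. Rank 1 is the most pathogenic.
#'
#' @param variants Variant table.
#' @param config A [threshold_config()] used to compute `n_pass`.
#' @return `variants` augmented with `n_pass` and `rank`, sorted by rank.
#' @export
rank_variants <- function(variants, config = threshold_config()) {
  flags <- score_flags(variants, config)
  pp2 <- ifelse(is.na(variants$polyphen2_score), -Inf,
                variants$polyphen2_score)
  sift <- ifelse(is.na(variants$sift), Inf, variants$sift)
  provean <- ifelse(is.na(variants$provean), Inf, variants$provean)
  ord <- order(-flags$n_pass, -pp2, sift, provean, variants$rsid,
               method = "radix")
  out <- variants[ord, , drop = FALSE]
  out$n_pass <- flags$n_pass[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
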