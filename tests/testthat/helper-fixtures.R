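# Small in-code fixtures shared across tests.

# Build a minimal generic-schema variant data frame; any column can be
# overridden by name.
mk_variants <- function(n = 1, ...) {
  base <- data.frame(
    rsid = sprintf("rs%05d", seq_len(n)),
    gene = "NUP155",
    protein_change = sprintf("R%dG", seq_len(n) * 10),
    ref_aa = "R",
    position = seq_len(n) * 10L,
    alt_aa = "G",
    consequence = "missense",
    variant_class = "snv",
    allele_frequency = 1e-5,
    allele_count = 2L,
    hom_count = 0L,
    male = 1L,
    female = 1L,
    polyphen2_class = "probably-damaging",
    polyphen2_score = 0.99,
    grantham = 130,
    provean = -5,
    sift = 0.01,
    phastcons = 0.99,
    gerp = 5,
    stringsAsFactors = FALSE
  )
  override <- list(...)
  for (col in names(override)) base[[col]] <- override[[col]]
  base
}

# Write a variant data frame as a generic-dialect TSV and return the path.
write_tmp_table <- function(df) {
  tf <- tempfile(fileext = ".tsv")
  write_variant_table(df, tf)
  tf
}

# The synthetic coding-filter fixture: 645 clean SNVs plus 12
# indel/start-stop-loss records, 55 duplicate-excess rows and 12 rows
# without rsIDs, shuffled deterministically (724 rows total).
mk_coding_filter_fixture <- function() {
  clean <- mk_variants(645)
  indels <- mk_variants(12, rsid = sprintf("rs7%04d", 1:12),
                        variant_class = rep(c("indel", "startstop_loss"), 6))
  dups <- clean[rep(1:11, c(rep(5, 10), 5)), ]  # 55 extra copies of kept rsids
  nors <- mk_variants(12, rsid = NA_character_)
  all_rows <- rbind(clean, indels, dups, nors)
  set.seed(99)
  out <- all_rows[sample.int(nrow(all_rows)), ]
  rownames(out) <- NULL
  out
}
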