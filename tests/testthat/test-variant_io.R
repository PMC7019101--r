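test_that("protein change strings parse in compact and HGVS form", {
  pc <- parse_protein_change(c("R672G", "p.Arg672Gly", NA, "V402M"))
  expect_equal(pc$ref_aa, c("R", "R", NA, "V"))
  expect_equal(pc$position, c(672L, 672L, NA, 402L))
  expect_equal(pc$alt_aa, c("G", "G", NA, "M"))
  expect_error(parse_protein_change("R672"), "malformed protein change")
  expect_error(parse_protein_change("rs12345"), "rs12345")
})

test_that("reading a table parses rows, splits class:score, and keeps order", {
  df <- mk_variants(3, polyphen2_class = "Probably-damaging:0.971",
                    polyphen2_score = NA_real_,
                    allele_frequency = c(7e-6, 2e-5, 7.04e-4))
  tf <- tempfile(fileext = ".tsv")
  write.table(df[, setdiff(names(df), c("ref_aa", "position", "alt_aa"))],
              tf, sep = "\t", quote = FALSE, row.names = FALSE)
  v <- read_variant_table(tf)
  expect_equal(nrow(v), 3)
  expect_equal(v$rsid, df$rsid)
  expect_equal(v$polyphen2_class, rep("probably-damaging", 3))
  expect_equal(v$polyphen2_score, rep(0.971, 3))
  expect_equal(v$allele_frequency[1], 7e-6)
  expect_equal(v$ref_aa[1], "R")
  expect_equal(v$position, df$position)
})

test_that("an empty file with a valid header yields an empty table", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(paste(c("rsid", "gene", "protein_change", "consequence",
                     "variant_class", "allele_frequency"), collapse = "\t"),
             tf)
  v <- read_variant_table(tf)
  expect_equal(nrow(v), 0)
})

test_that("out-of-range scores are load errors naming row and column", {
  df <- mk_variants(2, gerp = c(5, 9))
  tf <- write_tmp_table(df)
  expect_error(read_variant_table(tf), "row 2, column 'gerp'")
  df2 <- mk_variants(1, grantham = 2)
  expect_error(read_variant_table(write_tmp_table(df2)),
               "row 1, column 'grantham'")
  expect_error(read_variant_table(write_tmp_table(mk_variants(1, sift = 1.2))),
               "column 'sift'")
})

test_that("unknown dialect is a config error; shipped dialects resolve", {
  expect_error(read_variant_table(tempfile(), dialect = "nope"),
               "unknown dialect")
  expect_named(dialect_spec("gnomad")["columns"], "columns")
  expect_equal(dialect_spec("dbnsfp")$default_consequence, "missense")
})

test_that("gnomad dialect remaps columns and converts HGVS protein changes", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("rsIDs", "Gene", "Protein Consequence", "VEP Annotation",
          "Allele Frequency", "Allele Count", "Number of Homozygotes",
          sep = "\t"),
    paste("rs373376199", "NUP155", "p.Arg672Gly", "missense_variant",
          "0.000007", "2", "0", sep = "\t")), tf)
  v <- read_variant_table(tf, dialect = "gnomad")
  expect_equal(v$protein_change, "R672G")
  expect_equal(v$consequence, "missense")
  expect_equal(v$allele_frequency, 7e-6)
})

test_that("consequence classification follows the annotation vocabulary", {
  expect_equal(classify_consequence("stop gained"), "lof")
  expect_equal(classify_consequence(c("splice_donor_variant",
                                      "frameshift_variant")),
               c("lof", "lof"))
  expect_equal(classify_consequence("missense_variant"), "missense")
  expect_equal(classify_consequence("synonymous_variant"), "synonymous")
  expect_equal(classify_consequence("5_prime_UTR_variant"), "other")
  expect_equal(classify_consequence(c("intron_variant",
                                      "splice_region_variant")),
               c("other", "other"))
  expect_warning(out <- classify_consequence("weird_new_term"),
                 "weird_new_term")
  expect_equal(out, "other")
  expect_error(classify_consequence(""), "empty")
})

test_that("coding filter removes indels, missing rsids, then duplicates", {
  two_dups <- mk_variants(2, rsid = c("rs1", "rs1"))
  res <- filter_coding(two_dups)
  expect_equal(nrow(res$retained), 1)
  expect_equal(unname(res$removal_report["duplicate"]), 1L)

  fx <- mk_coding_filter_fixture()
  expect_equal(nrow(fx), 724)
  res <- filter_coding(fx)
  expect_equal(nrow(res$retained), 645)
  expect_equal(sum(res$removal_report), 79L)
  expect_equal(unname(res$removal_report["indel_startstop_loss"]), 12L)
  expect_equal(unname(res$removal_report["missing_rsid"]), 12L)
  expect_equal(unname(res$removal_report["duplicate"]), 55L)
})

test_that("coding filter is the identity on clean input and idempotent", {
  clean <- mk_variants(10)
  res <- filter_coding(clean)
  expect_equal(res$retained, clean)
  expect_true(all(res$removal_report == 0))
  fx <- mk_coding_filter_fixture()
  once <- filter_coding(fx)
  twice <- filter_coding(once$retained)
  expect_equal(twice$retained, once$retained)
  expect_true(all(twice$removal_report == 0))
})

test_that("source intersection matches brute-force membership enumeration", {
  same <- list(g = c("a", "b"), e = c("a", "b"), d = c("a", "b"))
  res <- intersect_sources(same)
  expect_equal(unname(res$counts["g&e&d"]), 2L)
  expect_equal(sum(res$counts), 2L)
  expect_equal(res$common, c("a", "b"))

  disjoint <- list(g = c("a"), e = c("b"), d = c("c"))
  res <- intersect_sources(disjoint)
  expect_equal(unname(res$counts["g&e&d"]), 0L)
  expect_equal(length(res$common), 0L)

  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    sources <- setNames(
      lapply(seq_len(k), function(i) {
        sample(letters[1:20], sample(0:12, 1))
      }), paste0("S", seq_len(k)))
    res <- intersect_sources(sources)
    expect_equal(sum(res$counts), length(unique(unlist(sources))))
    oracle <- oracle_venn(sources)
    for (region in names(oracle)) {
      expect_equal(unname(res$counts[region]),
                   unname(as.integer(oracle[region])))
    }
    expect_equal(res$common,
                 sort(Reduce(intersect, lapply(sources, unique))))
  }
})

test_that("intersection rejects bad inputs", {
  expect_error(intersect_sources(list(a = "x")), "at least 2")
  expect_error(intersect_sources(list(a = "x", a = "y")), "duplicate")
  expect_error(intersect_sources(list(a = c("x", ""), b = "y")), "empty")
})

test_that("population summary picks the dominant population with tie rules", {
  v <- mk_variants(3, pop_nfe = c(5L, 2L, NA), pop_afr = c(1L, 2L, NA))
  s <- summarize_population(v)
  expect_equal(s$dominant_population, c("nfe", "afr", "unknown"))
  expect_equal(s$tie, c(FALSE, TRUE, FALSE))
  # ties break to the lexicographically smallest label
  v2 <- mk_variants(1, pop_b = 2L, pop_a = 2L)
  expect_equal(summarize_population(v2)$dominant_population, "a")
  # all-heterozygous fixture reports zero homozygotes
  expect_equal(sum(summarize_population(nup155_variants())$hom_count), 0)
})

test_that("generic write/read round-trips all parsed fields exactly", {
  gen <- gen_variant_table(40, hotspot_intervals =
                             data.frame(start = 100, end = 199, weight = 0.3),
                           seed = 21)
  tf <- write_tmp_table(gen$variants)
  back <- read_variant_table(tf)
  for (col in names(gen$variants)) {
    expect_identical(back[[col]], gen$variants[[col]], label = col)
  }
  tf2 <- write_tmp_table(back)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("load-time invariants reject impossible count structures", {
  expect_error(read_variant_table(write_tmp_table(
    mk_variants(1, hom_count = 5L, allele_count = 2L))),
    "hom_count")
  expect_error(read_variant_table(write_tmp_table(
    mk_variants(1, male = 3L, female = 3L, allele_count = 2L))),
    "sex counts")
})
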