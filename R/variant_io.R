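# Reading, classifying, deduplicating and intersecting variant annotation
# tables exported from population databases (gnomAD / dbNSFP style).

# Canonical generic-dialect column order. pop_* columns float in between
# hom_count and male.
GENERIC_CORE <- c("rsid", "gene", "protein_change", "consequence",
                  "variant_class", "allele_frequency")
GENERIC_OPTIONAL <- c("allele_count", "hom_count", "male", "female",
                      "polyphen2_class", "polyphen2_score", "grantham",
                      "provean", "sift", "phastcons", "gerp")

# Declared score ranges, enforced at load time.
SCORE_RANGES <- list(
  allele_frequency = c(0, 1),
  polyphen2_score  = c(0, 1),
  grantham         = c(5, 215),
  sift             = c(0, 1),
  phastcons        = c(0, 1),
  gerp             = c(-12.3, 6.17)
)

POLYPHEN2_CLASSES <- c("benign", "possibly-damaging", "probably-damaging")
CONSEQUENCE_LEVELS <- c("missense", "lof", "synonymous", "other")
VARIANT_CLASSES <- c("snv", "indel", "startstop_loss")

#' Column remapping for a variant-table dialect
#'
#' Dialects translate the column names of a source export (e.g. a gnomAD
#' download or a dbNSFP extract) onto the generic schema used internally.
#' The built-in `"gnomad"` and `"dbnsfp"` remappings ship as YAML files
#' under `inst/extdata/dialects/` and can serve as templates for custom
#' dialects.
#'
#' @param dialect `"generic"`, `"gnomad"`, `"dbnsfp"`, a path to a dialect
#'   YAML file, or an already-parsed dialect list.
#' @return A list with elements `columns` (named character vector mapping
#'   generic names to source column names), and optionally
#'   `compose_protein_change` (three source columns holding reference amino
#'   acid, position, alternate amino acid), `class_codes` (named map from
#'   source PolyPhen-2 codes to canonical class strings) and
#'   `default_consequence`.
#' @export
dialect_spec <- function(dialect = "generic") {
  if (is.list(dialect)) return(dialect)
  stopifnot(is.character(dialect), length(dialect) == 1L)
  if (dialect == "generic") return(list(columns = NULL))
  path <- if (file.exists(dialect)) {
    dialect
  } else {
    system.file("extdata", "dialects", paste0(dialect, ".yaml"),
                package = "varhotspot")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_config("unknown dialect '%s' (no remapping file found)", dialect)
  }
  spec <- yaml::read_yaml(path)
  spec$columns <- unlist(spec$columns)
  spec
}

#' Parse protein-change strings
#'
#' Accepts the compact one-letter form (`"R672G"`) and the HGVS-style
#' three-letter form (`"p.Arg672Gly"`).
#'
#' @param x Character vector of protein-change strings.
#' @return Data frame with columns `ref_aa`, `position`, `alt_aa`; `NA`
#'   rows for missing input cells.
#' @export
parse_protein_change <- function(x) {
  x <- as.character(x)
  out <- data.frame(ref_aa = NA_character_, position = NA_integer_,
                    alt_aa = NA_character_,
                    stringsAsFactors = FALSE)[rep(1L, length(x)), , drop = FALSE]
  rownames(out) <- NULL
  present <- !is_missing_cell(x)
  if (!any(present)) return(out)
  v <- trimws(x[present])
  compact <- grepl("^[A-Z][0-9]+[A-Z]$", v)
  hgvs <- grepl("^p\\.[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}$", v)
  bad <- !compact & !hgvs
  if (any(bad)) {
    stop(sprintf(
      "malformed protein change value(s): %s (expected e.g. 'R672G' or 'p.Arg672Gly')",
      paste(sQuote(unique(v[bad])), collapse = ", ")), call. = FALSE)
  }
  ref <- alt <- character(length(v))
  pos <- integer(length(v))
  ref[compact] <- substr(v[compact], 1L, 1L)
  alt[compact] <- substring(v[compact], nchar(v[compact]))
  pos[compact] <- as.integer(gsub("[^0-9]", "", v[compact]))
  if (any(hgvs)) {
    h <- sub("^p\\.", "", v[hgvs])
    r3 <- substr(h, 1L, 3L)
    a3 <- substring(h, nchar(h) - 2L)
    unknown <- !(r3 %in% names(AA3TO1)) | !(a3 %in% names(AA3TO1))
    if (any(unknown)) {
      stop(sprintf("malformed protein change value(s): %s",
                   paste(sQuote(unique(v[hgvs][unknown])), collapse = ", ")),
           call. = FALSE)
    }
    ref[hgvs] <- AA3TO1[r3]
    alt[hgvs] <- AA3TO1[a3]
    pos[hgvs] <- as.integer(gsub("[^0-9]", "", h))
  }
  out$ref_aa[present] <- ref
  out$alt_aa[present] <- alt
  out$position[present] <- pos
  out
}

normalize_polyphen2_class <- function(x, codes = NULL) {
  x <- as.character(x)
  score <- rep(NA_real_, length(x))
  combined <- !is_missing_cell(x) & grepl(":", x, fixed = TRUE)
  if (any(combined)) {
    parts <- strsplit(x[combined], ":", fixed = TRUE)
    x[combined] <- vapply(parts, `[`, "", 1L)
    score[combined] <- suppressWarnings(
      as.numeric(vapply(parts, `[`, "", 2L)))
  }
  cls <- tolower(trimws(x))
  cls <- gsub("[ _]+", "-", cls)
  if (!is.null(codes)) {
    mapped <- unlist(codes)[as.character(x)]
    cls <- ifelse(!is.na(mapped), unname(mapped), cls)
  }
  cls[is_missing_cell(cls)] <- NA_character_
  bad <- !is.na(cls) & !(cls %in% POLYPHEN2_CLASSES)
  if (any(bad)) {
    stop(sprintf("unrecognized PolyPhen-2 class value(s): %s",
                 paste(sQuote(unique(cls[bad])), collapse = ", ")),
         call. = FALSE)
  }
  list(class = cls, score = score)
}

#' Classify a raw consequence annotation
#'
#' Maps source vocabulary (including Sequence Ontology terms) onto the four
#' working categories: `"missense"`, `"lof"` (stop gained, splice donor,
#' frameshift), `"synonymous"` and `"other"` (UTR, splice region, intronic,
#' and anything else). Unrecognized strings degrade to `"other"` with a
#' warning rather than failing, since source vocabularies drift.
#'
#' @param raw_annotation Character vector of annotation strings.
#' @return Character vector over
#'   `c("missense", "lof", "synonymous", "other")`.
#' @export
classify_consequence <- function(raw_annotation) {
  x <- as.character(raw_annotation)
  if (any(is_missing_cell(x))) {
    stop("empty consequence annotation", call. = FALSE)
  }
  key <- gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
  key <- gsub("^_|_$", "", key)
  lof <- c("stop_gained", "splice_donor", "splice_donor_variant",
           "frameshift", "frameshift_variant")
  missense <- c("missense", "missense_variant")
  synonymous <- c("synonymous", "synonymous_variant")
  other_known <- c(
    "other", "5_prime_utr_variant", "3_prime_utr_variant", "utr",
    "5_prime_utr", "3_prime_utr", "splice_region_variant", "splice_region",
    "splice_acceptor_variant", "intron_variant", "intronic", "intron",
    "upstream_gene_variant", "downstream_gene_variant",
    "non_coding_transcript_exon_variant", "inframe_insertion",
    "inframe_deletion", "start_lost", "stop_lost", "stop_retained_variant",
    "coding_sequence_variant")
  out <- rep("other", length(key))
  out[key %in% lof] <- "lof"
  out[key %in% missense] <- "missense"
  out[key %in% synonymous] <- "synonymous"
  unknown <- !(key %in% c(lof, missense, synonymous, other_known))
  if (any(unknown)) {
    warning(sprintf("unrecognized consequence annotation(s) mapped to 'other': %s",
                    paste(sQuote(unique(x[unknown])), collapse = ", ")),
            call. = FALSE)
  }
  out
}

validate_variant_table <- function(df) {
  for (col in names(SCORE_RANGES)) {
    if (!col %in% names(df)) next
    rng <- SCORE_RANGES[[col]]
    bad <- which(!is.na(df[[col]]) & (df[[col]] < rng[1] | df[[col]] > rng[2]))
    if (length(bad)) {
      stop(sprintf("row %d, column '%s': value %g outside [%g, %g]",
                   bad[1], col, df[[col]][bad[1]], rng[1], rng[2]),
           call. = FALSE)
    }
  }
  if (all(c("hom_count", "allele_count") %in% names(df))) {
    bad <- which(!is.na(df$hom_count) & !is.na(df$allele_count) &
                   df$hom_count > df$allele_count)
    if (length(bad)) {
      stop(sprintf("row %d: hom_count exceeds allele_count", bad[1]),
           call. = FALSE)
    }
  }
  if (all(c("male", "female", "allele_count") %in% names(df))) {
    sex_sum <- ifelse(is.na(df$male), 0L, df$male) +
      ifelse(is.na(df$female), 0L, df$female)
    bad <- which(!is.na(df$allele_count) & sex_sum > df$allele_count)
    if (length(bad)) {
      stop(sprintf("row %d: sex counts exceed allele_count", bad[1]),
           call. = FALSE)
    }
  }
  if ("position" %in% names(df)) {
    bad <- which(!is.na(df$position) & df$position < 1L)
    if (length(bad)) {
      stop(sprintf("row %d: residue position below 1", bad[1]), call. = FALSE)
    }
  }
  mis <- which(!is.na(df$consequence) & df$consequence == "missense")
  if (length(mis)) {
    bad <- mis[is.na(df$ref_aa[mis]) | is.na(df$alt_aa[mis]) |
                 df$ref_aa[mis] == df$alt_aa[mis]]
    if (length(bad)) {
      stop(sprintf(
        "row %d: missense record lacks a valid protein change (ref != alt)",
        bad[1]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a variant annotation table
#'
#' Parses a TSV export into the internal variant table: one row per
#' variant, protein changes split into `ref_aa`/`position`/`alt_aa`,
#' PolyPhen-2 `"class:score"` strings split into class and numeric score,
#' raw consequence vocabulary collapsed to the four working categories, and
#' declared score ranges enforced (an out-of-range value is a load error
#' naming the row and column). Empty cells become `NA`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Dialect name or spec understood by [dialect_spec()].
#' @return A `data.frame` of annotated variants in the generic schema
#'   (columns `rsid`, `gene`, `protein_change`, `ref_aa`, `position`,
#'   `alt_aa`, `consequence`, `variant_class`, `allele_frequency`,
#'   `allele_count`, `hom_count`, any `pop_*` columns, `male`, `female`,
#'   and the six predictor scores). Row order follows the file.
#' @seealso [write_variant_table()] for the inverse operation.
#' @export
read_variant_table <- function(path, dialect = "generic") {
  spec <- dialect_spec(dialect)
  if (!file.exists(path)) stop_config("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", na.strings = c("", "NA"))
  if (!is.null(spec$columns)) {
    hit <- spec$columns[spec$columns %in% names(raw)]
    names(raw)[match(hit, names(raw))] <- names(hit)
  }
  if (!is.null(spec$compose_protein_change) &&
      all(spec$compose_protein_change %in% names(raw))) {
    cc <- spec$compose_protein_change
    raw$protein_change <- ifelse(
      is_missing_cell(raw[[cc[1]]]) | is_missing_cell(raw[[cc[2]]]) |
        is_missing_cell(raw[[cc[3]]]),
      NA_character_,
      paste0(raw[[cc[1]]], raw[[cc[2]]], raw[[cc[3]]]))
  }
  missing_core <- setdiff(c("rsid", "protein_change"), names(raw))
  if (length(missing_core)) {
    stop_config("input lacks required column(s): %s",
                paste(missing_core, collapse = ", "))
  }
  n <- nrow(raw)
  num <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_real_, n))
    suppressWarnings(as.numeric(raw[[col]]))
  }
  int <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_integer_, n))
    suppressWarnings(as.integer(raw[[col]]))
  }
  chr <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_character_, n))
    x <- as.character(raw[[col]])
    x[is_missing_cell(x)] <- NA_character_
    x
  }

  pc <- parse_protein_change(chr("protein_change"))
  pp2 <- normalize_polyphen2_class(chr("polyphen2_class"), spec$class_codes)
  pp2_score <- num("polyphen2_score")
  pp2_score[is.na(pp2_score)] <- pp2$score[is.na(pp2_score)]

  csq <- chr("consequence")
  if (all(is.na(csq)) && !is.null(spec$default_consequence)) {
    csq <- rep(spec$default_consequence, n)
  }
  needs_map <- !is.na(csq) & !(csq %in% CONSEQUENCE_LEVELS)
  if (any(needs_map)) csq[needs_map] <- classify_consequence(csq[needs_map])

  vclass <- chr("variant_class")
  bad_class <- !is.na(vclass) & !(vclass %in% VARIANT_CLASSES)
  if (any(bad_class)) {
    stop(sprintf("row %d, column 'variant_class': unknown value '%s'",
                 which(bad_class)[1], vclass[which(bad_class)[1]]),
         call. = FALSE)
  }

  pop_cols <- grep("^pop_", names(raw), value = TRUE)
  out <- data.frame(
    rsid = chr("rsid"),
    gene = chr("gene"),
    protein_change = ifelse(is.na(pc$position), NA_character_,
                            paste0(pc$ref_aa, pc$position, pc$alt_aa)),
    ref_aa = pc$ref_aa,
    position = pc$position,
    alt_aa = pc$alt_aa,
    consequence = csq,
    variant_class = vclass,
    allele_frequency = num("allele_frequency"),
    allele_count = int("allele_count"),
    hom_count = int("hom_count"),
    stringsAsFactors = FALSE
  )
  for (p in pop_cols) out[[p]] <- int(p)
  out$male <- int("male")
  out$female <- int("female")
  out$polyphen2_class <- pp2$class
  out$polyphen2_score <- pp2_score
  out$grantham <- num("grantham")
  out$provean <- num("provean")
  out$sift <- num("sift")
  out$phastcons <- num("phastcons")
  out$gerp <- num("gerp")
  validate_variant_table(out)
  out
}

#' Write a variant table in the generic dialect
#'
#' Inverse of [read_variant_table()] for the generic dialect: reading the
#' written file reproduces all parsed fields exactly.
#'
#' @param variants Variant table as returned by [read_variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  df <- variants
  optional <- c("allele_count", "hom_count",
                grep("^pop_", names(df), value = TRUE),
                "male", "female", "polyphen2_class", "polyphen2_score",
                "grantham", "provean", "sift", "phastcons", "gerp")
  cols <- c(GENERIC_CORE, optional)
  cols <- intersect(cols, names(df))
  # wholly-missing optional columns are not serialized (empty cell = missing)
  all_na <- vapply(cols, function(cl) {
    !(cl %in% GENERIC_CORE) && all(is.na(df[[cl]]))
  }, logical(1))
  cols <- cols[!all_na]
  out <- df[, cols, drop = FALSE]
  for (col in names(out)) {
    x <- out[[col]]
    out[[col]] <- if (is.numeric(x) && !is.integer(x)) {
      ifelse(is.na(x), "", sprintf("%.17g", x))
    } else {
      ifelse(is.na(x), "", as.character(x))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter protein-coding variants for analysis
#'
#' Applies, in order: removal of insertion/deletion and start/stop-loss
#' records (`variant_class`), removal of records without an rsID, and
#' deduplication by rsID (first occurrence by row order kept).
#'
#' @param variants Variant table restricted to protein-coding (missense)
#'   records by the caller.
#' @return List with `retained` (filtered table) and `removal_report`
#'   (named integer counts per removal reason); `nrow(retained)` equals the
#'   input row count minus the report total. Idempotent on clean input.
#' @export
filter_coding <- function(variants) {
  df <- variants
  is_indel <- !is.na(df$variant_class) &
    df$variant_class %in% c("indel", "startstop_loss")
  df1 <- df[!is_indel, , drop = FALSE]
  no_rsid <- is_missing_cell(df1$rsid)
  df2 <- df1[!no_rsid, , drop = FALSE]
  dup <- duplicated(df2$rsid)
  df3 <- df2[!dup, , drop = FALSE]
  rownames(df3) <- NULL
  list(
    retained = df3,
    removal_report = c(indel_startstop_loss = sum(is_indel),
                       missing_rsid = sum(no_rsid),
                       duplicate = sum(dup))
  )
}

#' Intersect variant sources by rsID
#'
#' Computes the Venn decomposition of two or more rsID sets (one per source
#' database): every rsID in the union is assigned to exactly one region, so
#' region counts sum to the union size.
#'
#' @param sources Named list of character vectors of rsIDs, one per source
#'   (names are the source labels, e.g. `"gnomAD"`). Labels must be unique;
#'   members must not be empty or `NA`.
#' @return List with `counts` (named integer vector over all
#'   `2^k - 1` membership regions, labels joined with `"&"`) and `common`
#'   (sorted rsIDs present in every source).
#' @export
intersect_sources <- function(sources) {
  if (length(sources) < 2L) stop_config("need at least 2 sources")
  labels <- names(sources)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop_config("sources must be a named list")
  }
  if (anyDuplicated(labels)) stop_config("duplicate source labels")
  sets <- lapply(sources, function(s) {
    s <- as.character(s)
    if (any(is_missing_cell(s))) {
      stop_config("source sets must not contain absent/empty rsids")
    }
    unique(s)
  })
  ids <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 0L) {
    member <- matrix(logical(0), 0, length(sets))
  }
  member <- matrix(member, ncol = length(sets))
  k <- length(sets)
  region_labels <- character(0)
  counts <- integer(0)
  for (size in seq_len(k)) {
    combos <- utils::combn(seq_len(k), size, simplify = FALSE)
    for (cmb in combos) {
      in_region <- rowSums(member[, cmb, drop = FALSE]) == length(cmb) &
        rowSums(member) == length(cmb)
      region_labels <- c(region_labels, paste(labels[cmb], collapse = "&"))
      counts <- c(counts, sum(in_region))
    }
  }
  names(counts) <- region_labels
  common <- ids[rowSums(member) == k]
  list(counts = counts, common = common)
}

#' Per-variant population and zygosity summary
#'
#' For each variant, reports the dominant population (the `pop_*` column
#' with the largest allele count; ties resolved to the lexicographically
#' smallest label and flagged), the per-sex allele counts, and the
#' homozygote count. Rows with no population counts at all get dominant
#' label `"unknown"`.
#'
#' @param variants Variant table.
#' @return Data frame with columns `rsid`, `protein_change`,
#'   `dominant_population`, `tie`, `male`, `female`, `hom_count`.
#' @export
summarize_population <- function(variants) {
  df <- variants
  pop_cols <- sort(grep("^pop_", names(df), value = TRUE))
  n <- nrow(df)
  dominant <- rep("unknown", n)
  tie <- rep(FALSE, n)
  if (length(pop_cols)) {
    mat <- as.matrix(df[, pop_cols, drop = FALSE])
    labels <- sub("^pop_", "", pop_cols)
    for (i in seq_len(n)) {
      row <- mat[i, ]
      if (all(is.na(row))) next
      mx <- max(row, na.rm = TRUE)
      at_max <- which(!is.na(row) & row == mx)
      dominant[i] <- labels[at_max[1]]  # labels sorted, so first = smallest
      tie[i] <- length(at_max) > 1L
    }
  }
  data.frame(
    rsid = df$rsid,
    protein_change = if ("protein_change" %in% names(df)) df$protein_change else NA_character_,
    dominant_population = dominant,
    tie = tie,
    male = if ("male" %in% names(df)) df$male else NA_integer_,
    female = if ("female" %in% names(df)) df$female else NA_integer_,
    hom_count = if ("hom_count" %in% names(df)) df$hom_count else NA_integer_,
    stringsAsFactors = FALSE
  )
}
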