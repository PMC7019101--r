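# Protein subdomain assignment and enrichment.
#
# Domain intervals use 1-based inclusive protein coordinates (NOT genomic
# BED semantics). Exact residue boundaries for NUP155's beta-propeller /
# crescent alpha-helical / C-terminal stack subdomains are not published;
# the packaged example file (`nup155_domains_synthetic.tsv`) is an
# illustrative stand-in and analyses should supply their own intervals.

#' Read a domain interval table
#'
#' @param path Three-column TSV (`name`, `start`, `end`), 1-based inclusive
#'   protein coordinates.
#' @param L Optional protein length used to validate interval bounds.
#' @return Data frame of validated, non-overlapping intervals.
#' @export
read_domain_table <- function(path, L = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("name", "start", "end")
  if (!all(required %in% names(df))) {
    stop_config("domain table must have columns: %s",
                paste(required, collapse = ", "))
  }
  validate_domains(df, L)
}

validate_domains <- function(domains, L = NULL) {
  df <- domains
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyDuplicated(df$name)) stop_config("domain names must be unique")
  if (any(df$start < 1L) || any(df$start > df$end)) {
    stop_config("domain intervals require 1 <= start <= end")
  }
  if (!is.null(L) && any(df$end > L)) {
    stop_config("domain interval extends beyond protein length L = %d", L)
  }
  if (nrow(df) > 1L) {
    o <- order(df$start)
    s <- df$start[o]; e <- df$end[o]
    if (any(s[-1L] <= e[-length(e)])) {
      stop_config("domain intervals must not overlap")
    }
  }
  df
}

#' Assign residue positions to domains
#'
#' Each position receives the name of the unique interval containing it
#' (boundaries inclusive), or `"unassigned"`.
#'
#' @param positions Integer vector of residue positions.
#' @param domains Domain interval data frame (`name`, `start`, `end`).
#' @param L Protein length; positions must not exceed it.
#' @return Character vector of labels, one per position.
#' @export
assign_domains <- function(positions, domains, L) {
  domains <- validate_domains(domains, L)
  positions <- as.integer(positions)
  if (any(positions < 1L) || any(positions > L)) {
    stop_config("positions must lie in 1..L")
  }
  out <- rep("unassigned", length(positions))
  for (i in seq_len(nrow(domains))) {
    inside <- positions >= domains$start[i] & positions <= domains$end[i]
    out[inside] <- domains$name[i]
  }
  out
}

#' Domain enrichment of variant positions
#'
#' Tests whether more variant positions fall inside a domain than expected
#' under uniform placement along the protein, with a one-sided exact
#' binomial tail: `p = P(X >= observed)`, `X ~ Binomial(m, span/L)`.
#'
#' @param positions Integer vector of variant residue positions (length
#'   `m >= 1`).
#' @param domain A single-row domain interval (`name`, `start`, `end`).
#' @param L Protein length.
#' @return List with `domain`, `observed`, `expected` (`m * span / L`) and
#'   `p_value`.
#' @export
domain_enrichment <- function(positions, domain, L) {
  positions <- as.integer(positions)
  m <- length(positions)
  if (m < 1L) stop_config("need at least one position")
  if (any(positions < 1L) || any(positions > L)) {
    stop_config("positions must lie in 1..L")
  }
  start <- as.integer(domain$start); end <- as.integer(domain$end)
  if (length(start) != 1L) stop_config("domain must be a single interval")
  span <- end - start + 1L
  pr <- span / L
  if (pr >= 1) {
    warning("domain covers the whole protein; enrichment p-value is 1",
            call. = FALSE)
  }
  observed <- sum(positions >= start & positions <= end)
  p <- stats::pbinom(observed - 1L, size = m, prob = pr, lower.tail = FALSE)
  list(domain = as.character(domain$name), observed = observed,
       expected = m * pr, p_value = min(1, max(p, .Machine$double.xmin)))
}
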