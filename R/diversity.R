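# Amplicon alpha-diversity statistics and taxonomy aggregation.

frequency_counts <- function(counts) {
  counts <- counts[counts > 0]
  c(f1 = sum(counts == 1), f2 = sum(counts == 2),
    f3 = sum(counts == 3), f4 = sum(counts == 4))
}

#' Chao1 richness estimator
#'
#' Classic bias-corrected Chao1: `S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))`,
#' where `f1`/`f2` are the singleton and doubleton counts. With
#' `corrected_singletons = TRUE` the observed `f1` — which is inflated by
#' sequencing errors in amplicon data — is first replaced by a moment
#' estimate of the true singleton count derived from the higher-order
#' frequency counts under a Poisson model for rare species,
#' `f1_hat = 2 * f2^2 / (3 * f3)`, before applying the same formula. When
#' `f3 = 0` the corrected variant is undefined and the classic form is used
#' with a warning.
#'
#' @param counts Non-negative integer abundance vector (zeros allowed).
#' @param corrected_singletons Use the corrected-singleton variant.
#' @return Estimated richness (>= observed richness for the classic form).
#' @export
chao1 <- function(counts, corrected_singletons = FALSE) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all counts are zero")
  s_obs <- length(counts)
  f <- frequency_counts(counts)
  f1 <- f[["f1"]]
  if (corrected_singletons) {
    if (f[["f3"]] == 0) {
      warning("corrected-singleton variant undefined (f3 = 0); ",
              "falling back to the classic estimator")
    } else {
      f1 <- 2 * f[["f2"]]^2 / (3 * f[["f3"]])
    }
  }
  s_obs + f1 * (f1 - 1) / (2 * (f[["f2"]] + 1))
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over positive counts, with proportions
#' `p_i = count_i / total`. Natural log by default (nats); `log_base = 2`
#' gives bits.
#'
#' @param counts Non-negative abundance vector with at least one positive.
#' @param log_base Logarithm base, `exp(1)` (default) or `2`.
#' @return H, in `[0, log(S_obs)]`.
#' @export
shannon_index <- function(counts, log_base = exp(1)) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all counts are zero")
  p <- counts / sum(counts)
  -sum(p * log(p, base = log_base))
}

#' Coverage of the estimated richness
#'
#' `100 * S_obs / chao1`: how much of the estimated true richness the
#' observed ASVs account for.
#'
#' @param s_obs Observed richness (> 0).
#' @param chao1 Chao1 estimate (>= `s_obs`).
#' @return List with `coverage_pct` (full precision) and `coverage_rounded`
#'   (integer display form).
#' @export
coverage_estimate <- function(s_obs, chao1) {
  stopifnot(s_obs > 0)
  if (chao1 < s_obs) stop("chao1 estimate below observed richness")
  pct <- 100 * s_obs / chao1
  list(coverage_pct = pct, coverage_rounded = round(pct))
}

#' Full diversity summary of an abundance vector
#'
#' @param counts Non-negative abundance vector.
#' @param corrected_singletons Passed to [chao1()].
#' @param log_base Passed to [shannon_index()].
#' @return One-row data.frame: `s_obs`, `f1`..`f4`, `chao1`, `shannon`,
#'   `coverage_pct`.
#' @export
diversity_summary <- function(counts, corrected_singletons = FALSE,
                              log_base = exp(1)) {
  f <- frequency_counts(counts)
  est <- chao1(counts, corrected_singletons = corrected_singletons)
  s_obs <- sum(counts > 0)
  data.frame(
    s_obs = s_obs, f1 = f[["f1"]], f2 = f[["f2"]], f3 = f[["f3"]],
    f4 = f[["f4"]], chao1 = est,
    shannon = shannon_index(counts, log_base = log_base),
    coverage_pct = coverage_estimate(s_obs, est)$coverage_pct
  )
}

#' Aggregate ASV relative abundance at a taxonomic rank
#'
#' Sums counts by the group named at position `rank` of the
#' semicolon-delimited taxonomy string, converts to percentages of total
#' reads, and applies the display filter: only groups with relative
#' abundance strictly greater than `min_display_fraction` are shown, the
#' remainder collapsing into a single `"other"` bucket. ASVs whose taxonomy
#' has no assignment at the rank are grouped as `"unclassified"`.
#'
#' @param asv_table data.frame with `count` and `taxonomy` columns.
#' @param rank Integer position in the taxonomy string (1 = domain) or a
#'   rank name among domain, phylum, class, order, family, genus, species.
#' @param min_display_fraction Display cutoff as a fraction (default 0.01,
#'   i.e. groups must exceed 1%).
#' @return List with `full` (data.frame `group`, `percent`, all groups,
#'   summing to 100) and `display` (filtered, with an `other` row).
#' @export
aggregate_relative_abundance <- function(asv_table, rank = "genus",
                                         min_display_fraction = 0.01) {
  stopifnot(is.data.frame(asv_table),
            all(c("count", "taxonomy") %in% names(asv_table)))
  rank_names <- c("domain", "phylum", "class", "order", "family", "genus",
                  "species")
  if (is.character(rank)) {
    idx <- match(tolower(rank), rank_names)
    if (is.na(idx)) stop("unknown rank: ", rank)
  } else {
    idx <- as.integer(rank)
  }
  levels <- strsplit(as.character(asv_table$taxonomy), ";", fixed = TRUE)
  group <- vapply(levels, function(x) {
    g <- if (length(x) >= idx) trimws(x[idx]) else ""
    if (is.na(g) || g == "") "unclassified" else g
  }, character(1))
  totals <- tapply(asv_table$count, group, sum)
  totals <- totals[totals > 0]
  pct <- 100 * totals / sum(totals)
  full <- data.frame(group = names(pct), percent = as.numeric(pct),
                     stringsAsFactors = FALSE)
  full <- full[order(-full$percent, full$group), , drop = FALSE]
  rownames(full) <- NULL
  keep <- full$percent > 100 * min_display_fraction
  display <- full[keep, , drop = FALSE]
  other <- sum(full$percent[!keep])
  if (other > 0) {
    display <- rbind(display, data.frame(group = "other", percent = other,
                                         stringsAsFactors = FALSE))
  }
  rownames(display) <- NULL
  list(full = full, display = display)
}
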