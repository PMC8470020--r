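# MAG summary-ledger operations: completeness bands, complete-16S counts,
# phylum abundance roll-ups, genome-fraction arithmetic, report rendering.
#
# The ledger schema is one row per genome bin: bin_id, domain (A/B), taxon,
# completeness_pct, contamination_pct, n_contigs, genome_size_mbp,
# s16_length_bp (NA when no 16S rRNA gene was recovered), abundance_pct.

LEDGER_COLUMNS <- c("bin_id", "domain", "taxon", "completeness_pct",
                    "contamination_pct", "n_contigs", "genome_size_mbp",
                    "s16_length_bp", "abundance_pct")

#' Read a MAG summary ledger from TSV
#'
#' @param path TSV file with the ledger column schema.
#' @return data.frame with typed columns, rows in natural bin order.
#' @export
read_mag_ledger <- function(path) {
  df <- read_tsv_file(path)
  missing <- setdiff(LEDGER_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("ledger lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, LEDGER_COLUMNS]
  num <- c("completeness_pct", "contamination_pct", "n_contigs",
           "genome_size_mbp", "s16_length_bp", "abundance_pct")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  if (any(df$completeness_pct < 0 | df$completeness_pct > 100)) {
    stop("completeness out of [0, 100]")
  }
  if (any(df$contamination_pct < 0) || any(df$abundance_pct < 0)) {
    stop("negative contamination or abundance")
  }
  df <- df[natural_order(df$bin_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' The packaged Karabetova Gora mud-volcano MAG ledger
#'
#' Summary statistics of the 33 genome bins (>50% complete, <5%
#' contamination) recovered from the Karabetova Gora terrestrial-mud-volcano
#' metagenome, as distributed with the package: completeness and
#' contamination, contig count, genome size, recovered 16S rRNA gene length
#' (NA where none was binned) and relative abundance from read mapping.
#'
#' @return data.frame of 33 ledger rows.
#' @export
karabetova_ledger <- function() {
  path <- system.file("extdata", "karabetova_mag_ledger.tsv",
                      package = "magpot", mustWork = TRUE)
  df <- read_mag_ledger(path)
  if (nrow(df) != 33) stop("packaged ledger corrupt: expected 33 records")
  df
}

#' The packaged bin-to-phylum mapping for the Karabetova Gora MAGs
#'
#' The ledger's taxon column mixes ranks (orders, families, genera), so the
#' phylum-level roll-ups use this explicit mapping (GTDB phylum names).
#'
#' @return data.frame with `bin_id`, `phylum`.
#' @export
karabetova_phyla <- function() {
  path <- system.file("extdata", "karabetova_mag_phyla.tsv",
                      package = "magpot", mustWork = TRUE)
  read_tsv_file(path)
}

#' Count MAGs in a completeness band
#'
#' @param records Ledger data.frame.
#' @param lo,hi Band limits in percent.
#' @param lo_closed,hi_closed Interval closure; defaults give `[lo, hi)`.
#'   Use `lo == hi` with both ends closed for an exact-value band such as
#'   exactly 100% complete.
#' @return Integer count.
#' @export
band_count <- function(records, lo, hi, lo_closed = TRUE, hi_closed = FALSE) {
  stopifnot(is.data.frame(records))
  if (lo > hi) stop("lo > hi")
  if (lo == hi && !(lo_closed && hi_closed)) {
    stop("degenerate band needs both ends closed")
  }
  x <- records$completeness_pct
  above <- if (lo_closed) x >= lo else x > lo
  below <- if (hi_closed) x <= hi else x < hi
  sum(above & below)
}

#' Count MAGs with a complete 16S rRNA gene
#'
#' "Complete" means a recovered 16S length strictly greater than
#' `min_len_bp` (default 1400 bp) when `strict`, else greater-or-equal.
#' MAGs with no recovered 16S (NA) never count.
#'
#' @param records Ledger data.frame.
#' @param min_len_bp Length cutoff in bp.
#' @param strict Strict inequality (default TRUE).
#' @return Integer count.
#' @export
count_complete_16s <- function(records, min_len_bp = 1400, strict = TRUE) {
  stopifnot(is.data.frame(records), min_len_bp >= 0)
  len <- records$s16_length_bp
  hit <- if (strict) len > min_len_bp else len >= min_len_bp
  sum(hit, na.rm = TRUE)
}

#' Sum MAG relative abundance by phylum
#'
#' @param records Ledger data.frame.
#' @param phyla Either a data.frame mapping `bin_id` to `phylum`, or a
#'   character vector of lineage substrings named by phylum to match
#'   against the ledger's taxon column.
#' @return data.frame `phylum`, `abundance_pct` (full precision; display at
#'   1 d.p.), `n_mags`, plus an attribute `unresolved` listing bins that
#'   matched no phylum (reported, never silently dropped).
#' @export
phylum_abundance_sum <- function(records, phyla) {
  stopifnot(is.data.frame(records))
  if (is.data.frame(phyla)) {
    stopifnot(all(c("bin_id", "phylum") %in% names(phyla)))
    idx <- match(records$bin_id, phyla$bin_id)
    assignment <- phyla$phylum[idx]
  } else {
    stopifnot(is.character(phyla), !is.null(names(phyla)))
    assignment <- rep(NA_character_, nrow(records))
    for (ph in names(phyla)) {
      hit <- grepl(phyla[[ph]], records$taxon, fixed = TRUE)
      assignment[hit & is.na(assignment)] <- ph
    }
  }
  unresolved <- records$bin_id[is.na(assignment)]
  keep <- !is.na(assignment)
  sums <- tapply(records$abundance_pct[keep], assignment[keep], sum)
  ns <- tapply(records$abundance_pct[keep], assignment[keep], length)
  out <- data.frame(phylum = names(sums),
                    abundance_pct = as.numeric(sums),
                    n_mags = as.integer(ns),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance_pct, out$phylum), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unresolved") <- unresolved
  out
}

#' Protein-coding fraction of a genome
#'
#' `100 * 3 * protein_length_aa / genome_size_bp`: the share of the genome
#' occupied by the coding sequence of a protein of the given length (3 bp
#' per residue). Used for giant-protein bookkeeping, e.g. SPEARE-type
#' attachment proteins of DPANN archaea that can take up several percent of
#' their host-dependent genome.
#'
#' @param protein_length_aa Protein length in amino acids (> 0).
#' @param genome_size_bp Genome size in bp (> 0).
#' @return Percent (full precision; display at 2 d.p.).
#' @export
coding_fraction <- function(protein_length_aa, genome_size_bp) {
  stopifnot(all(protein_length_aa > 0), all(genome_size_bp > 0))
  100 * 3 * protein_length_aa / genome_size_bp
}

#' Render the report bundle
#'
#' Writes deterministic TSV reports: the ledger, per-MAG MHC summaries, the
#' carbon-fixation completeness matrix (wide and long form) and metabolism
#' calls. Columns and row order are fixed so repeated runs are byte-stable.
#'
#' @param ledger Ledger data.frame.
#' @param mhc_summaries data.frame of [summarize_mhc()] rows, or NULL.
#' @param completeness Matrix from [completeness_matrix()], or NULL.
#' @param metabolism_calls List of `metabolism_call` objects, or NULL.
#' @param dir Output directory (created if needed).
#' @return Invisibly, named character vector of written file paths.
#' @export
render_reports <- function(ledger, mhc_summaries = NULL, completeness = NULL,
                           metabolism_calls = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  p <- file.path(dir, "mag_ledger.tsv")
  write_tsv_file(ledger[natural_order(ledger$bin_id), , drop = FALSE], p)
  paths["ledger"] <- p
  if (!is.null(mhc_summaries)) {
    p <- file.path(dir, "mhc_summary.tsv")
    write_tsv_file(
      mhc_summaries[natural_order(mhc_summaries$mag_id), , drop = FALSE], p)
    paths["mhc"] <- p
  }
  if (!is.null(completeness)) {
    wide <- data.frame(mag_id = rownames(completeness), completeness,
                       check.names = FALSE, stringsAsFactors = FALSE)
    p <- file.path(dir, "carbon_fixation_completeness.tsv")
    write_tsv_file(wide, p)
    paths["completeness"] <- p
    long <- expand.grid(mag_id = rownames(completeness),
                        pathway = colnames(completeness),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    long$completeness_pct <- completeness[cbind(long$mag_id, long$pathway)]
    long <- long[order(match(long$mag_id, rownames(completeness)),
                       match(long$pathway, colnames(completeness))), ]
    p <- file.path(dir, "carbon_fixation_completeness_long.tsv")
    write_tsv_file(long, p)
    paths["completeness_long"] <- p
  }
  if (!is.null(metabolism_calls)) {
    rows <- lapply(metabolism_calls, function(call) {
      data.frame(mag_id = call$mag_id,
                 labels = paste(call$labels, collapse = "; "),
                 evidence = paste(unlist(call$evidence), collapse = "; "),
                 stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, rows)
    p <- file.path(dir, "metabolism_calls.tsv")
    write_tsv_file(calls[natural_order(calls$mag_id), , drop = FALSE], p)
    paths["metabolism"] <- p
  }
  invisible(paths)
}
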