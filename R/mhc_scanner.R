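# Multiheme c-type cytochrome (MHC) detection.
#
# A c-type heme is covalently attached at a CxxCH motif (Cys-any-any-Cys-His).
# Proteins carrying several such motifs are multiheme cytochromes, the
# electron conduits implicated in extracellular electron transfer; an MHC
# whose C-terminus threads the membrane is presumed surface-exposed.

# Kyte-Doolittle hydropathy scale; ambiguity codes score 0 (neutral).
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Locate CxxCH heme c binding motifs in a protein sequence
#'
#' Scans every start position for the pattern Cys-any-any-Cys-His. The two
#' wildcard positions match any residue (including ambiguity codes), but the
#' C and H anchor positions match only literal `C`/`H`; `X` never matches an
#' anchor. Overlapping matches are all reported.
#'
#' @param sequence Amino-acid string (single protein). Case-insensitive.
#' @return A list of class `motif_scan` with `motif_positions` (1-based,
#'   strictly increasing start indices), `motif_count`, and `length`.
#' @examples
#' find_heme_motifs("CAACH")$motif_positions  # 1
#' find_heme_motifs("CAACHCAACH")$motif_count # 2
#' @export
find_heme_motifs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq_up <- toupper(sequence)
  if (nchar(seq_up) < 5L) {
    return(structure(
      list(motif_positions = integer(0), motif_count = 0L,
           length = nchar(seq_up)),
      class = "motif_scan"
    ))
  }
  # lookahead so overlapping motifs are all found
  m <- gregexpr("(?=C..CH)", seq_up, perl = TRUE)[[1]]
  pos <- if (m[1] == -1L) integer(0) else as.integer(m)
  structure(
    list(motif_positions = pos, motif_count = length(pos),
         length = nchar(seq_up)),
    class = "motif_scan"
  )
}

#' Predict a C-terminal transmembrane helix by hydropathy
#'
#' Slides a window of `window` residues over the sequence and flags the
#' protein when some window starting within the last `c_term_window`
#' residues has mean Kyte-Doolittle hydropathy at or above `threshold`.
#' The reported span is the maximal-scoring qualifying window.
#'
#' @param sequence Amino-acid string.
#' @param window Odd window width in residues.
#' @param threshold Mean-hydropathy cutoff for a transmembrane call.
#' @param c_term_window Windows must start within this many residues of the
#'   C-terminus to count as C-terminal.
#' @return List with `has_tm` (flag), `tm_start`, `tm_end` (NA when no call)
#'   `score` (best qualifying mean hydropathy) and `reason` for negatives.
#' @export
predict_c_terminal_tm <- function(sequence, window = 19L, threshold = 1.6,
                                  c_term_window = 40L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (window %% 2L != 1L) stop("`window` must be odd")
  n <- nchar(sequence)
  no_call <- function(reason) {
    list(has_tm = FALSE, tm_start = NA_integer_, tm_end = NA_integer_,
         score = NA_real_, reason = reason)
  }
  if (n < window) return(no_call("sequence shorter than window"))
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  h <- unname(KD_HYDROPATHY[aa])
  h[is.na(h)] <- 0
  # rolling mean over `window` residues via cumulative sums
  cs <- c(0, cumsum(h))
  starts <- seq_len(n - window + 1L)
  means <- (cs[starts + window] - cs[starts]) / window
  first_ct <- max(1L, n - c_term_window + 1L)
  ct <- starts >= first_ct
  if (!any(ct)) return(no_call("no window starts in the C-terminal region"))
  cand <- which(ct & means >= threshold)
  if (length(cand) == 0L) {
    return(no_call("no C-terminal window reaches the hydropathy threshold"))
  }
  best <- cand[which.max(means[cand])]
  list(has_tm = TRUE, tm_start = best, tm_end = best + window - 1L,
       score = means[best], reason = NA_character_)
}

#' Classify a protein as a multiheme cytochrome
#'
#' A protein is called an MHC when its CxxCH motif count reaches
#' `min_motifs` (default 2: genuine multiheme cytochromes carry at least two
#' heme-binding sites, and surveyed MAGs encode MHCs with as few as two).
#'
#' @param scan A `motif_scan` from [find_heme_motifs()].
#' @param tm Result of [predict_c_terminal_tm()] on the same protein (or a
#'   plain logical flag).
#' @param protein_id Identifier carried into the record.
#' @param min_motifs Minimum motif count for an MHC call; must be >= 1.
#' @return A one-row data.frame (`protein_id`, `motif_count`,
#'   `has_c_terminal_tm`, `tm_start`, `tm_end`) or `NULL` below threshold.
#' @export
classify_mhc <- function(scan, tm, protein_id = "protein", min_motifs = 2L) {
  if (min_motifs < 1L) stop("`min_motifs` must be >= 1")
  stopifnot(inherits(scan, "motif_scan"))
  if (is.logical(tm)) {
    tm <- list(has_tm = tm, tm_start = NA_integer_, tm_end = NA_integer_)
  }
  if (scan$motif_count < min_motifs) return(NULL)
  data.frame(
    protein_id = protein_id,
    motif_count = scan$motif_count,
    has_c_terminal_tm = isTRUE(tm$has_tm),
    tm_start = tm$tm_start %||% NA_integer_,
    tm_end = tm$tm_end %||% NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Scan a protein set for multiheme cytochromes
#'
#' Runs motif scanning and C-terminal transmembrane prediction over every
#' protein and returns the per-protein table; MHC records are the subset
#' with `motif_count >= min_motifs`.
#'
#' @param proteins A named character vector or [Biostrings::AAStringSet];
#'   names of the form `"magid|proteinid"` are split into a `mag_id` column.
#' @param min_motifs,window,threshold,c_term_window See
#'   [classify_mhc()] and [predict_c_terminal_tm()].
#' @return data.frame with one row per protein: `mag_id`, `protein_id`,
#'   `length`, `motif_count`, `motif_positions` (comma-joined),
#'   `has_c_terminal_tm`, `tm_start`, `tm_end`, `is_mhc`.
#' @export
scan_mhc <- function(proteins, min_motifs = 2L, window = 19L,
                     threshold = 1.6, c_term_window = 40L) {
  if (methods::is(proteins, "AAStringSet")) {
    proteins <- setNames(as.character(proteins), names(proteins))
  }
  stopifnot(is.character(proteins))
  ids <- names(proteins) %||% paste0("protein_", seq_along(proteins))
  if (is.null(names(proteins))) names(proteins) <- ids
  has_mag <- grepl("|", ids, fixed = TRUE)
  mag_id <- ifelse(has_mag, sub("\\|.*$", "", ids), NA_character_)
  protein_id <- ifelse(has_mag, sub("^[^|]*\\|", "", ids), ids)
  rows <- lapply(seq_along(proteins), function(i) {
    scan <- find_heme_motifs(proteins[[i]])
    tm <- predict_c_terminal_tm(proteins[[i]], window = window,
                                threshold = threshold,
                                c_term_window = c_term_window)
    data.frame(
      mag_id = mag_id[i],
      protein_id = protein_id[i],
      length = scan$length,
      motif_count = scan$motif_count,
      motif_positions = paste(scan$motif_positions, collapse = ","),
      has_c_terminal_tm = isTRUE(tm$has_tm),
      tm_start = tm$tm_start,
      tm_end = tm$tm_end,
      is_mhc = scan$motif_count >= min_motifs,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Summarize the MHC inventory of one MAG
#'
#' Per-MAG roll-up of MHC records: total MHCs, MHCs with strictly more than
#' ten motifs, the maximal motif count in a single protein, and the number
#' predicted to carry a C-terminal transmembrane helix.
#'
#' @param mag_id Genome-bin identifier.
#' @param records data.frame of MHC rows (e.g. the `is_mhc` subset of a
#'   [scan_mhc()] table); may have zero rows.
#' @return One-row data.frame: `mag_id`, `n_mhc`, `n_mhc_gt10`,
#'   `max_motifs` (0 when no MHCs), `n_with_tm`.
#' @export
summarize_mhc <- function(mag_id, records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    return(data.frame(mag_id = mag_id, n_mhc = 0L, n_mhc_gt10 = 0L,
                      max_motifs = 0L, n_with_tm = 0L,
                      stringsAsFactors = FALSE))
  }
  data.frame(
    mag_id = mag_id,
    n_mhc = nrow(records),
    n_mhc_gt10 = sum(records$motif_count > 10L),
    max_motifs = max(records$motif_count),
    n_with_tm = sum(records$has_c_terminal_tm),
    stringsAsFactors = FALSE
  )
}
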