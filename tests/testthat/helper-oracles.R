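# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately use naive position-by-position logic, not the package's
# regex/cumsum implementations.

# brute-force CxxCH scan: check every window explicitly
oracle_motif_positions <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 5) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(n - 4L)) {
    if (chars[p] == "C" && chars[p + 3L] == "C" && chars[p + 4L] == "H") {
      hits <- c(hits, p)
    }
  }
  hits
}

# brute-force sliding-window hydropathy: returns all window starts whose
# mean Kyte-Doolittle hydropathy reaches the threshold
oracle_tm_window_starts <- function(seq, window = 19L, threshold = 1.6) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  h <- unname(kd[chars]); h[is.na(h)] <- 0
  n <- length(h)
  if (n < window) return(integer(0))
  starts <- integer(0)
  for (s in seq_len(n - window + 1L)) {
    if (mean(h[s:(s + window - 1L)]) >= threshold) starts <- c(starts, s)
  }
  starts
}

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# packaged marker-set table (gene complements and expected labels per bin)
read_marker_sets <- function() {
  path <- system.file("extdata", "karabetova_marker_sets.tsv",
                      package = "magpot", mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             na.strings = c("NA", ""))
}

# Rebuild per-bin annotation tables from the marker-set table. Bins whose
# expected label is anaerobic methane oxidation additionally receive the
# full seven-step methanogenesis complement (those genomes encode all core
# steps; the summary table lists only mcrA as shorthand).
marker_set_annotations <- function(row, catalog) {
  ids <- c(row$donor_ids, row$acceptor_ids)
  ids <- unlist(strsplit(ids[!is.na(ids)], ";", fixed = TRUE))
  if (identical(row$putative_metabolism, "Anaerobic methane oxidation")) {
    ids <- c(ids, unlist(catalog$methanogenesis$core_steps))
  }
  ids <- unique(ids[nzchar(ids)])
  if (length(ids) == 0) {
    return(data.frame(mag_id = character(0), annotation_id = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(mag_id = row$bin_id, annotation_id = ids,
             stringsAsFactors = FALSE)
}

# run the full classification for one marker-set row
classify_marker_set_row <- function(row, catalog) {
  ann <- marker_set_annotations(row, catalog)
  presence <- if (nrow(ann) > 0) {
    detect_markers(ann, catalog)[1, ]
  } else {
    setNames(rep(FALSE, length(catalog$markers)), names(catalog$markers))
  }
  check <- if (nrow(ann) > 0) {
    check_reverse_methanogenesis(ann, catalog)
  } else {
    NULL
  }
  autotroph <- !is.na(row$autotrophic_pathway) &&
    nzchar(row$autotrophic_pathway)
  assign_metabolism(
    presence,
    autotroph = autotroph,
    wl_complete = identical(row$autotrophic_pathway, "WL"),
    methanogenesis = check,
    mag_id = row$bin_id
  )
}
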