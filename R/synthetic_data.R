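# Seeded synthetic-data generators.
#
# Every generator is a pure function of (spec, seed): identical inputs give
# byte-identical outputs. The generators emulate the statistical structure
# the downstream stages assume — protein sets with a known number of
# planted CxxCH motifs against a guaranteed motif-free background,
# annotation tables with chosen pathway completeness fractions and marker
# sets, ASV tables with a chosen richness and abundance shape, qPCR runs
# with chosen efficiency and Cq noise, and tracer incubations with a known
# oxidation rate plus a killed control.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
# approximate natural amino-acid frequencies (UniProt-like), for realistic
# background composition
AA_FREQ <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
             G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
             P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
# scaffold for planted proteins: no C, no H, so only planted motifs match
AA_SCAFFOLD <- setdiff(AA_ALPHABET, c("C", "H"))
TM_RESIDUES <- c("L", "I", "V", "F", "A")
POLAR_RESIDUES <- c("D", "E", "N", "Q", "S", "T", "G", "K", "R")

random_residues <- function(n, alphabet = AA_ALPHABET, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# sample one element of a vector (safe for length-1 vectors, unlike sample())
sample_one <- function(v) v[sample.int(length(v), 1L)]

# Rewrite accidental CxxCH motifs in a background sequence: mutate the
# His anchor to Gln. Removing an anchor cannot create a new motif, but we
# re-scan until clean anyway.
erase_motifs <- function(seq) {
  repeat {
    m <- gregexpr("(?=C..CH)", seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[as.integer(m) + 4L] <- "Q"
    seq <- paste(chars, collapse = "")
  }
}

#' Specification for one synthetic MAG
#'
#' @param mag_id Bin identifier.
#' @param n_background_proteins Number of motif-free background proteins.
#' @param background_length_range Length interval (aa) for background and
#'   planted proteins.
#' @param planted_mhcs data.frame with columns `motif_count` (>= 1) and
#'   `has_c_terminal_tm` (logical), one row per planted multiheme protein;
#'   or a list of `list(motif_count =, has_c_terminal_tm =)`.
#' @param pathway_fractions Named numeric vector, pathway name -> fraction
#'   of essential genes to include, each in `[0, 1]`.
#' @param marker_genes Character vector of marker symbols to plant.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return Object of class `mag_spec`.
#' @export
mag_spec <- function(mag_id, n_background_proteins = 50,
                     background_length_range = c(120, 400),
                     planted_mhcs = NULL, pathway_fractions = numeric(0),
                     marker_genes = character(0), seed = 1) {
  if (is.list(planted_mhcs) && !is.data.frame(planted_mhcs)) {
    planted_mhcs <- do.call(rbind, lapply(planted_mhcs, function(p) {
      data.frame(motif_count = p$motif_count,
                 has_c_terminal_tm = isTRUE(p$has_c_terminal_tm))
    }))
  }
  if (is.null(planted_mhcs)) {
    planted_mhcs <- data.frame(motif_count = integer(0),
                               has_c_terminal_tm = logical(0))
  }
  stopifnot(all(planted_mhcs$motif_count >= 1),
            length(background_length_range) == 2,
            background_length_range[1] <= background_length_range[2],
            all(pathway_fractions >= 0 & pathway_fractions <= 1))
  structure(list(
    mag_id = mag_id,
    n_background_proteins = n_background_proteins,
    background_length_range = background_length_range,
    planted_mhcs = planted_mhcs,
    pathway_fractions = pathway_fractions,
    marker_genes = marker_genes,
    seed = seed
  ), class = "mag_spec")
}

# Assemble one planted multiheme protein: a C/H-free scaffold carrying
# exactly `motif_count` CxxCH blocks, optionally ending in a 21-residue
# hydrophobic tail (drawn from L/I/V/F/A) inside the last 40 positions so
# the default hydropathy detector fires.
build_planted_protein <- function(motif_count, has_tm, length_range) {
  spacer <- 6L
  tail_len <- if (has_tm) 21L + 8L else 0L
  need <- 15L + motif_count * (5L + spacer) + tail_len + 5L
  if (length_range[2] < need) {
    stop("background_length_range too short to host ", motif_count,
         " motifs", if (has_tm) " plus a transmembrane tail")
  }
  target <- sample_one(seq(max(length_range[1], need), length_range[2]))
  parts <- random_residues(15L, AA_SCAFFOLD)
  for (i in seq_len(motif_count)) {
    motif <- paste0("C", random_residues(2L, AA_SCAFFOLD), "CH")
    parts <- paste0(parts, motif, random_residues(spacer, AA_SCAFFOLD))
  }
  filler <- target - nchar(parts) - tail_len
  if (filler > 0) parts <- paste0(parts, random_residues(filler, AA_SCAFFOLD))
  if (has_tm) {
    parts <- paste0(parts, random_residues(21L, TM_RESIDUES),
                    random_residues(8L, POLAR_RESIDUES))
  }
  parts
}

#' Generate a synthetic protein set with planted multiheme cytochromes
#'
#' Background proteins are drawn from a realistic amino-acid composition
#' and post-processed so they contain zero CxxCH matches (any accidental
#' motif has its His anchor rewritten). Planted proteins are built on a
#' Cys/His-free scaffold so they contain exactly the requested number of
#' motifs, with an optional 21-residue hydrophobic C-terminal tail.
#'
#' @param spec A [mag_spec()].
#' @return List with `proteins` (named character vector,
#'   `"magid|proteinid"` names) and `truth` (data.frame `protein_id`,
#'   `is_mhc`, `motif_count`, `has_c_terminal_tm`).
#' @export
simulate_proteins <- function(spec) {
  stopifnot(inherits(spec, "mag_spec"))
  with_seed(spec$seed, {
    lr <- spec$background_length_range
    n_bg <- spec$n_background_proteins
    bg <- vapply(seq_len(n_bg), function(i) {
      erase_motifs(random_residues(sample_one(seq(lr[1], lr[2])),
                                   AA_ALPHABET, AA_FREQ))
    }, character(1))
    planted <- spec$planted_mhcs
    pl <- vapply(seq_len(nrow(planted)), function(i) {
      build_planted_protein(planted$motif_count[i],
                            planted$has_c_terminal_tm[i], lr)
    }, character(1))
    ids <- c(
      if (n_bg > 0) sprintf("bg_%03d", seq_len(n_bg)),
      if (nrow(planted) > 0) sprintf("mhc_%03d", seq_len(nrow(planted)))
    )
    proteins <- setNames(c(bg, pl), paste0(spec$mag_id, "|", ids))
    truth <- data.frame(
      protein_id = ids,
      is_mhc = c(rep(FALSE, n_bg), rep(TRUE, nrow(planted))),
      motif_count = c(rep(0L, n_bg), planted$motif_count),
      has_c_terminal_tm = c(rep(FALSE, n_bg), planted$has_c_terminal_tm),
      stringsAsFactors = FALSE
    )
    list(proteins = proteins, truth = truth)
  })
}

#' Write a protein set to FASTA
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' Read a protein FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Generate an annotation table with chosen pathway completeness
#'
#' For each pathway named in the spec's `pathway_fractions`, exactly
#' `round(fraction * |essential set|)` distinct essential genes are
#' included, chosen by a seeded shuffle-then-prefix (deterministic and
#' uniform). Marker symbols are expanded to all their catalog aliases.
#'
#' @param spec A [mag_spec()].
#' @param defs Pathway definitions from [load_pathway_definitions()].
#' @param catalog Marker catalog from [load_marker_catalog()].
#' @param extra_ids Additional raw annotation identifiers to append (e.g. a
#'   full methanogenesis complement).
#' @return data.frame with `mag_id`, `gene_id`, `annotation_id`.
#' @export
simulate_annotations <- function(spec, defs, catalog, extra_ids = character(0)) {
  stopifnot(inherits(spec, "mag_spec"))
  fr <- spec$pathway_fractions
  unknown <- setdiff(names(fr), names(defs))
  if (length(unknown) > 0) {
    stop("pathway_fractions name unknown pathway(s): ",
         paste(unknown, collapse = ", "))
  }
  unknown <- setdiff(spec$marker_genes, names(catalog$markers))
  if (length(unknown) > 0) {
    stop("unknown marker symbol(s): ", paste(unknown, collapse = ", "))
  }
  with_seed(spec$seed + 1L, {
    ids <- character(0)
    for (p in names(fr)) {
      ess <- defs[[p]]$essential_genes
      n_take <- round(fr[[p]] * length(ess))
      ids <- c(ids, sample(ess)[seq_len(n_take)])
    }
    for (sym in spec$marker_genes) {
      ids <- c(ids, catalog$markers[[sym]])
    }
    ids <- c(ids, as.character(extra_ids))
    ids <- unique(ids)
    if (length(ids) == 0) {
      return(data.frame(mag_id = character(0), gene_id = character(0),
                        annotation_id = character(0), stringsAsFactors = FALSE))
    }
    data.frame(
      mag_id = spec$mag_id,
      gene_id = sprintf("%s_%05d", spec$mag_id, seq_along(ids)),
      annotation_id = ids,
      stringsAsFactors = FALSE
    )
  })
}

# draw one value from the log-series pmf P(k) proportional to x^k / k
rlogseries <- function(n, x) {
  stopifnot(x > 0, x < 1)
  kmax <- 1L
  # extend support until the tail mass is negligible
  repeat {
    k <- seq_len(kmax)
    w <- x^k / k
    if (w[kmax] / sum(w) < 1e-12 || kmax > 1e6) break
    kmax <- kmax * 2L
  }
  sample.int(kmax, n, replace = TRUE, prob = w)
}

#' Generate a synthetic ASV count table
#'
#' Species relative abundances follow the chosen shape — log-normal
#' (`sigma` on the log scale), Fisher log-series (`x` parameter), or
#' uniform — and `depth` reads are drawn by multinomial sampling, so the
#' total count is conserved exactly and observed richness can fall below
#' `true_richness` at modest depth.
#'
#' @param true_richness Number of species in the pool.
#' @param abundance_model `"lognormal"`, `"logseries"`, or `"uniform"`.
#' @param depth Total reads (>= `true_richness`).
#' @param seed Integer seed.
#' @param sigma Log-normal shape (> 0).
#' @param x Log-series parameter in (0, 1).
#' @param taxonomy Optional character vector (length `true_richness`) of
#'   rank-delimited lineage strings; a generic mock lineage is used when
#'   omitted.
#' @return data.frame `asv_id`, `count`, `taxonomy` (zero-count ASVs are
#'   dropped); `sum(count) == depth`.
#' @export
simulate_asv_table <- function(true_richness, abundance_model = "lognormal",
                               depth = 10000, seed = 1, sigma = 1.5,
                               x = 0.995, taxonomy = NULL) {
  stopifnot(true_richness >= 1)
  if (depth < true_richness) stop("depth must be >= true_richness")
  abundance_model <- match.arg(abundance_model,
                               c("lognormal", "logseries", "uniform"))
  if (abundance_model == "lognormal" && sigma <= 0) stop("sigma must be > 0")
  if (abundance_model == "logseries" && !(x > 0 && x < 1)) {
    stop("log-series x must be in (0, 1)")
  }
  with_seed(seed, {
    w <- switch(abundance_model,
      lognormal = rlnorm(true_richness, meanlog = 0, sdlog = sigma),
      logseries = as.numeric(rlogseries(true_richness, x)),
      uniform = rep(1, true_richness)
    )
    counts <- as.integer(rmultinom(1, size = depth, prob = w / sum(w)))
    if (is.null(taxonomy)) {
      taxonomy <- sprintf(
        "Bacteria;Phylum_%02d;Class;Order;Family;Genus_%03d",
        (seq_len(true_richness) - 1L) %% 10L + 1L, seq_len(true_richness))
    }
    stopifnot(length(taxonomy) == true_richness)
    keep <- counts > 0
    out <- data.frame(
      asv_id = sprintf("ASV_%04d", seq_len(true_richness))[keep],
      count = counts[keep],
      taxonomy = taxonomy[keep],
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic qPCR run
#'
#' Standards and samples follow the line `Cq = intercept + slope *
#' log10(copies)` with `slope = -1 / log10(1 + E)` for amplification
#' efficiency `E`, plus Gaussian Cq noise. Standards, like samples, are run
#' in replicate.
#'
#' @param true_copies Named numeric vector of true copy numbers per sample
#'   (all > 0).
#' @param efficiency_pct Amplification efficiency in percent, in (0, 120].
#' @param cq_noise_sd Gaussian noise SD on Cq.
#' @param n_replicates Replicates per standard/sample (default 3).
#' @param standards Copy numbers of the dilution series; must span at least
#'   3 decades.
#' @param intercept Cq at 1 copy.
#' @param seed Integer seed.
#' @return List of class `qpcr_run` with `standards` (data.frame `copies`,
#'   `cq`), `samples` (data.frame `label`, `replicate`, `cq`), and the true
#'   curve parameters.
#' @export
simulate_qpcr_run <- function(true_copies, efficiency_pct = 100,
                              cq_noise_sd = 0, n_replicates = 3,
                              standards = 10^(3:8), intercept = 38,
                              seed = 1) {
  stopifnot(all(true_copies > 0))
  if (!(efficiency_pct > 0 && efficiency_pct <= 120)) {
    stop("efficiency_pct must be in (0, 120]")
  }
  if (log10(max(standards) / min(standards)) < 3) {
    stop("standards must span at least 3 decades")
  }
  if (is.null(names(true_copies))) {
    names(true_copies) <- sprintf("sample_%02d", seq_along(true_copies))
  }
  slope <- -1 / log10(1 + efficiency_pct / 100)
  with_seed(seed, {
    std <- expand.grid(replicate = seq_len(n_replicates), copies = standards,
                       KEEP.OUT.ATTRS = FALSE)
    std$cq <- intercept + slope * log10(std$copies) +
      rnorm(nrow(std), sd = cq_noise_sd)
    smp <- expand.grid(replicate = seq_len(n_replicates),
                       label = names(true_copies),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    smp$cq <- intercept + slope * log10(true_copies[smp$label]) +
      rnorm(nrow(smp), sd = cq_noise_sd)
    structure(list(
      standards = data.frame(copies = std$copies, cq = std$cq),
      samples = data.frame(label = smp$label, replicate = smp$replicate,
                           cq = smp$cq, stringsAsFactors = FALSE),
      true_slope = slope, true_intercept = intercept,
      true_copies = true_copies
    ), class = "qpcr_run")
  })
}

#' Generate synthetic radiotracer incubation records
#'
#' The fraction of added label recovered in oxidation products is
#' `true_rate * days / ch4_pool`, perturbed by multiplicative Gaussian
#' noise; killed controls get the same treatment at `control_rate`. The
#' defaults mirror a typical sediment incubation: 1 uCi of labelled methane
#' (~12.8 nmol cm^-3 at 1.16 GBq/mmol in 2.5 cm^3) incubated for 5 days,
#' with a low-but-nonzero killed-control blank.
#'
#' @param true_rate True oxidation rate, nmol cm^-3 day^-1 (>= 0).
#' @param ch4_pool Methane pool, nmol cm^-3.
#' @param days Incubation length, days.
#' @param noise_cv Coefficient of variation of the product activity.
#' @param n Live replicates (killed controls get the same count).
#' @param a_total Total added activity per sample (arbitrary units).
#' @param control_rate Apparent rate in killed controls.
#' @param seed Integer seed.
#' @return data.frame `replicate`, `is_control`, `a_product`, `a_total`.
#' @export
simulate_tracer_samples <- function(true_rate, ch4_pool = 12.8, days = 5,
                                    noise_cv = 0.05, n = 3, a_total = 1e5,
                                    control_rate = 0.02, seed = 1) {
  stopifnot(true_rate >= 0, control_rate >= 0, ch4_pool > 0, days > 0)
  frac <- true_rate * days / ch4_pool
  frac_control <- control_rate * days / ch4_pool
  if (frac > 1 || frac_control > 1) {
    stop("label fraction would exceed 1: methane pool too small for this ",
         "rate and incubation time")
  }
  with_seed(seed, {
    noise <- function(k) pmax(0, 1 + rnorm(k, sd = noise_cv))
    live <- data.frame(replicate = seq_len(n), is_control = FALSE,
                       a_product = a_total * frac * noise(n),
                       a_total = a_total)
    ctrl <- data.frame(replicate = seq_len(n), is_control = TRUE,
                       a_product = a_total * frac_control * noise(n),
                       a_total = a_total)
    rbind(live, ctrl)
  })
}
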