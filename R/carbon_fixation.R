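# CO2-fixation pathway completeness scoring.
#
# Each of the seven known carbon-fixation pathways is described by a set of
# essential genes (orthology identifiers) plus a diagnostic key-gene subset.
# A MAG's completeness for a pathway is the percentage of essential genes
# with at least one matching annotation row; a MAG with full genomic
# potential (100% plus key genes) is called a putative autotroph.

#' Load carbon-fixation pathway definitions
#'
#' Reads a YAML config of pathway blocks (`name`, `essential_genes`,
#' `key_genes`, optional `label`). The packaged default describes the seven
#' known CO2-fixation pathways with curated essential-gene sets in the KEGG
#' orthology namespace; the file is a documented, editable stand-in that
#' users may replace with their own curation.
#'
#' @param path YAML file; defaults to the packaged pathway config.
#' @param override Optional named list `pathway name -> character vector of
#'   essential genes` replacing that pathway's gene set (key genes for an
#'   overridden pathway are intersected with the new set); other pathways
#'   are untouched.
#' @return Named list of `pathway_definition` objects, each with `name`,
#'   `label`, `essential_genes`, `key_genes`.
#' @export
load_pathway_definitions <- function(path = NULL, override = NULL) {
  path <- path %||% system.file("extdata", "carbon_fixation_pathways.yaml",
                                package = "magpot", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  blocks <- cfg$pathways %||% cfg
  defs <- lapply(blocks, function(b) {
    stopifnot(!is.null(b$name), !is.null(b$essential_genes))
    ess <- unique(as.character(b$essential_genes))
    key <- unique(as.character(b$key_genes %||% character(0)))
    if (length(ess) == 0) stop("pathway '", b$name, "' has an empty gene set")
    if (!all(key %in% ess)) {
      stop("pathway '", b$name, "': key_genes must be a subset of essential_genes")
    }
    structure(list(name = b$name, label = b$label %||% b$name,
                   essential_genes = ess, key_genes = key),
              class = "pathway_definition")
  })
  nms <- vapply(defs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate pathway names in config")
  names(defs) <- nms
  if (!is.null(override)) {
    stopifnot(is.list(override), !is.null(names(override)))
    unknown <- setdiff(names(override), nms)
    if (length(unknown) > 0) {
      stop("override names unknown pathway(s): ", paste(unknown, collapse = ", "))
    }
    for (nm in names(override)) {
      ess <- unique(as.character(override[[nm]]))
      if (length(ess) == 0) stop("override for '", nm, "' is empty")
      defs[[nm]]$essential_genes <- ess
      defs[[nm]]$key_genes <- intersect(defs[[nm]]$key_genes, ess)
    }
  }
  defs
}

#' Score one MAG's completeness for one pathway
#'
#' Completeness is `100 * |essential genes with >= 1 annotation| /
#' |essential genes|`. Presence is binary per identifier; copy number does
#' not weight the score.
#'
#' @param annotation_ids Character vector of annotation identifiers observed
#'   in one MAG (repeats allowed).
#' @param def A `pathway_definition`.
#' @return Percent in `[0, 100]`.
#' @export
score_pathway <- function(annotation_ids, def) {
  stopifnot(inherits(def, "pathway_definition"))
  present <- sum(def$essential_genes %in% annotation_ids)
  100 * present / length(def$essential_genes)
}

#' MAG-by-pathway completeness matrix
#'
#' @param annotations data.frame with `mag_id` and `annotation_id` columns
#'   covering all MAGs of interest.
#' @param defs Pathway definitions from [load_pathway_definitions()].
#' @param mag_ids Optional MAG universe (rows); defaults to the MAGs seen in
#'   `annotations`. MAGs with no annotation rows score 0 everywhere.
#' @return Numeric matrix, rows = MAG ids in natural order, columns =
#'   pathways in the order of `defs`; cells are percent completeness.
#' @export
completeness_matrix <- function(annotations, defs, mag_ids = NULL) {
  check_annotations(annotations)
  mag_ids <- mag_ids %||% unique(annotations$mag_id)
  if (length(mag_ids) == 0) stop("need at least one MAG")
  mag_ids <- mag_ids[natural_order(mag_ids)]
  m <- matrix(0, nrow = length(mag_ids), ncol = length(defs),
              dimnames = list(mag_ids, names(defs)))
  ann_by_mag <- split(annotations$annotation_id, annotations$mag_id)
  for (mag in mag_ids) {
    ids <- ann_by_mag[[mag]] %||% character(0)
    for (p in names(defs)) m[mag, p] <- score_pathway(ids, defs[[p]])
  }
  m
}

#' Call putative autotrophs from a completeness matrix
#'
#' A (MAG, pathway) pair is called when its completeness reaches
#' `threshold` and, with the key-gene guard on, every diagnostic key gene of
#' the pathway is annotated. The roTCA cycle gets an additional guard: a
#' call requires the full essential-gene complement (the TCA-cycle enzymes)
#' regardless of `threshold`, because citrate synthase alone is common in
#' heterotrophs running an ordinary oxidative TCA cycle.
#'
#' @param matrix Completeness matrix from [completeness_matrix()].
#' @param defs Pathway definitions (same set used to build `matrix`).
#' @param annotations Annotation table (for the key-gene guard).
#' @param threshold Percent completeness required; in `(0, 100]`.
#' @param key_gene_guard Require all key genes present (default TRUE).
#' @return data.frame with columns `mag_id`, `pathway`, `completeness_pct`;
#'   zero rows when nothing qualifies.
#' @export
call_autotrophs <- function(matrix, defs, annotations, threshold = 100,
                            key_gene_guard = TRUE) {
  if (!(threshold > 0 && threshold <= 100)) stop("`threshold` must be in (0, 100]")
  check_annotations(annotations)
  ann_by_mag <- split(annotations$annotation_id, annotations$mag_id)
  out <- list()
  for (mag in rownames(matrix)) {
    ids <- ann_by_mag[[mag]] %||% character(0)
    for (p in colnames(matrix)) {
      cell <- matrix[mag, p]
      if (cell < threshold) next
      def <- defs[[p]]
      if (key_gene_guard && !all(def$key_genes %in% ids)) next
      if (identical(p, "roTCA") && cell < 100) next
      out[[length(out) + 1L]] <- data.frame(
        mag_id = mag, pathway = p, completeness_pct = cell,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mag_id = character(0), pathway = character(0),
                      completeness_pct = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
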