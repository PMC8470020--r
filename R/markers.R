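# Marker-gene detection and rule-based metabolism classification.
#
# A curated catalog maps marker symbols (mcrA, dsrAB, coxA, ...) to sets of
# annotation identifiers; a marker is present when any alias is annotated.
# Putative-metabolism labels are assigned by a fixed, documented rule order
# over the presence row, the autotrophy call and the reverse-methanogenesis
# check. The rule order is a reconstruction of how such summary labels are
# conventionally drawn from gene content; it is configuration, not ground
# truth, and every label carries the markers that fired it.

METABOLISM_VOCABULARY <- c(
  "anaerobic methane oxidation", "aerobic methane oxidation", "autotrophic",
  "sulfite/sulfate reduction", "denitrification", "nitrate reduction",
  "sulfur compound oxidation", "aerobic", "facultatively anaerobic",
  "fermentation", "H2 utilization", "carbohydrate utilization",
  "aromatic compound utilization", "acetogenic", "Unidentified"
)

#' Load the functional marker-gene catalog
#'
#' Reads a YAML catalog with a `markers` section (marker symbol -> character
#' vector of annotation-identifier aliases) and a `methanogenesis` section
#' grouping the gene families used by [check_reverse_methanogenesis()]. The
#' packaged default covers the electron-donor/acceptor markers of
#' methane-seep MAG surveys (mcrA, pMMO, dsrAB, nap/nar/nos, sox/sqr/soe,
#' cox/cco, coo, hydrogenases, GH1, bzd).
#'
#' @param path YAML file; defaults to the packaged catalog.
#' @return List of class `marker_catalog` with elements `markers` and
#'   `methanogenesis`.
#' @export
load_marker_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "marker_catalog.yaml",
                                package = "magpot", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$markers))
  markers <- lapply(cfg$markers, as.character)
  if (anyDuplicated(names(markers))) stop("duplicate marker symbols in catalog")
  if (any(lengths(markers) == 0)) stop("marker with empty identifier set")
  structure(list(markers = markers,
                 methanogenesis = cfg$methanogenesis %||% list()),
            class = "marker_catalog")
}

#' Detect marker presence across MAGs
#'
#' @param annotations data.frame with `mag_id`, `annotation_id`.
#' @param catalog A `marker_catalog`.
#' @param mag_ids Optional MAG universe; defaults to MAGs in `annotations`.
#' @return Logical matrix, rows = MAGs (natural order), columns = marker
#'   symbols; `TRUE` when any alias of the marker has an annotation row.
#' @export
detect_markers <- function(annotations, catalog, mag_ids = NULL) {
  check_annotations(annotations)
  stopifnot(inherits(catalog, "marker_catalog"))
  mag_ids <- mag_ids %||% unique(annotations$mag_id)
  mag_ids <- mag_ids[natural_order(mag_ids)]
  ann_by_mag <- split(annotations$annotation_id, annotations$mag_id)
  m <- matrix(FALSE, nrow = length(mag_ids), ncol = length(catalog$markers),
              dimnames = list(mag_ids, names(catalog$markers)))
  for (mag in mag_ids) {
    ids <- ann_by_mag[[mag]] %||% character(0)
    m[mag, ] <- vapply(catalog$markers, function(al) any(al %in% ids),
                       logical(1))
  }
  m
}

group_presence <- function(groups, ids) {
  vapply(groups, function(al) any(as.character(al) %in% ids), logical(1))
}

#' Reverse-methanogenesis presence/absence check for one MAG
#'
#' Anaerobic methanotrophic (ANME) archaea are thought to oxidize methane
#' by running the seven central steps of the methanogenic pathway (fmd,
#' ftr, mch, mtd, mer, mtr, mcr) in reverse. A MAG is a
#' reverse-methanogenesis candidate when all seven core steps are encoded
#' while the canonical hydrogenases of methanogens (Ech, Vho, Mvh, Frh) and
#' the methylotrophy methyltransferases are absent. The check also reports
#' nitrate- and sulfate-reduction gene groups (for electron-acceptor
#' reasoning) and the Fpo/Hdr/Rnf electron-transfer complexes.
#'
#' @param annotations Annotation table for a single MAG, or a character
#'   vector of annotation identifiers.
#' @param catalog A `marker_catalog` whose `methanogenesis` section defines
#'   the gene groups.
#' @return List of class `methanogenesis_check`: per-group presence flags,
#'   `missing_steps`, and logical `verdict`.
#' @export
check_reverse_methanogenesis <- function(annotations, catalog) {
  stopifnot(inherits(catalog, "marker_catalog"))
  mg <- catalog$methanogenesis
  if (length(mg) == 0) stop("catalog has no methanogenesis section")
  ids <- if (is.data.frame(annotations)) {
    if (length(unique(annotations$mag_id)) > 1) {
      stop("check_reverse_methanogenesis() expects a single MAG")
    }
    annotations$annotation_id
  } else {
    as.character(annotations)
  }
  core <- group_presence(mg$core_steps, ids)
  hyd <- group_presence(mg$hydrogenases, ids)
  mtase <- group_presence(mg$methyltransferases, ids)
  nitrate <- group_presence(mg$nitrate_reduction, ids)
  sulfate <- group_presence(mg$sulfate_reduction, ids)
  etc <- group_presence(mg$electron_transfer, ids)
  structure(list(
    core_steps_present = core,
    hydrogenases_present = hyd,
    methyltransferases_present = mtase,
    nitrate_genes_present = nitrate,
    sulfate_genes_present = sulfate,
    electron_transfer_present = etc,
    missing_steps = names(core)[!core],
    verdict = all(core) && !any(hyd) && !any(mtase)
  ), class = "methanogenesis_check")
}

#' @export
print.methanogenesis_check <- function(x, ...) {
  cat("Reverse-methanogenesis check\n")
  cat("  core steps present:",
      paste(names(x$core_steps_present)[x$core_steps_present], collapse = " "),
      "\n")
  if (length(x$missing_steps)) {
    cat("  missing steps:", paste(x$missing_steps, collapse = " "), "\n")
  }
  cat("  hydrogenases present:",
      paste(names(x$hydrogenases_present)[x$hydrogenases_present],
            collapse = " ") , "\n")
  cat("  verdict:",
      if (x$verdict) "reverse-methanogenesis candidate" else "not a candidate",
      "\n")
  invisible(x)
}

#' Assign putative-metabolism labels to one MAG
#'
#' Applies a fixed, documented rule order to a marker presence row, the
#' autotrophy call and the reverse-methanogenesis verdict. Labels come from
#' a closed vocabulary; `"Unidentified"` is returned alone when no rule
#' fires. The order and its suppression clauses (see the methods vignette)
#' are configuration reconstructed from how gene content conventionally
#' maps to such summary labels:
#'
#' 1. reverse-methanogenesis candidate -> "anaerobic methane oxidation"
#' 2. pMMO -> "aerobic methane oxidation"
#' 3. autotrophy call -> "autotrophic"
#' 4. dsrAB -> "sulfite/sulfate reduction"
#' 5. narG and nosZ -> "denitrification"; else napA or narG ->
#'    "nitrate reduction" (nosZ alone fires nothing)
#' 6. sox or sqr or soeA -> "sulfur compound oxidation"
#' 7. coxA (aa3-type oxidase) -> "facultatively anaerobic" when Fe-hyd is
#'    also present, else "aerobic"; suppressed for autotrophs and aerobic
#'    methanotrophs, whose lifestyle is already labelled; cbb3-type ccoN
#'    alone (microaerobic) does not fire this rule
#' 8. Fe-hyd with no respiratory acceptor genes (coxA, ccoN, napA, narG,
#'    nosZ, dsrAB) -> "fermentation"
#' 9. hybC or hyaB -> "H2 utilization", unless the MAG was called
#'    fermentative, or is an autotroph with no anaerobic respiratory
#'    acceptor (napA/narG/dsrAB)
#' 10. GH1 -> "carbohydrate utilization"
#' 11. bzd -> "aromatic compound utilization"
#' 12. complete WL pathway with cooS and cooF -> "acetogenic"
#'
#' @param presence Named logical vector (one row of [detect_markers()]).
#' @param autotroph Logical: does this MAG have an autotrophy call?
#' @param wl_complete Logical: is the Wood-Ljungdahl pathway 100% complete?
#' @param methanogenesis Optional `methanogenesis_check` for this MAG.
#' @param mag_id Identifier carried into the result.
#' @return List of class `metabolism_call`: `mag_id`, `labels` (character),
#'   `evidence` (named list label -> markers that fired it).
#' @export
assign_metabolism <- function(presence, autotroph = FALSE,
                              wl_complete = FALSE, methanogenesis = NULL,
                              mag_id = NA_character_) {
  if (is.matrix(presence)) {
    stopifnot(nrow(presence) == 1L)
    presence <- presence[1L, ]
  }
  stopifnot(is.logical(presence), !is.null(names(presence)))
  has <- function(sym) isTRUE(presence[[sym]])
  labels <- character(0)
  evidence <- list()
  add <- function(label, ev) {
    labels <<- c(labels, label)
    evidence[[label]] <<- ev
  }

  anme <- !is.null(methanogenesis) && isTRUE(methanogenesis$verdict)
  if (anme) add("anaerobic methane oxidation", "mcr + seven core steps, no canonical hydrogenases")
  if (has("pMMO")) add("aerobic methane oxidation", "pMMO")
  if (isTRUE(autotroph)) add("autotrophic", "complete CO2-fixation pathway")
  if (has("dsrAB")) add("sulfite/sulfate reduction", "dsrAB")
  if (has("narG") && has("nosZ")) {
    add("denitrification", "narG+nosZ")
  } else if (has("napA") || has("narG")) {
    add("nitrate reduction", paste(intersect(c("napA", "narG"),
                                             names(which(presence))),
                                   collapse = "+"))
  }
  sulfox <- intersect(c("sox", "sqr", "soeA"), names(which(presence)))
  if (length(sulfox) > 0) add("sulfur compound oxidation",
                              paste(sulfox, collapse = "+"))
  aerobic_lifestyle_labelled <- isTRUE(autotroph) || has("pMMO")
  if (has("coxA") && !aerobic_lifestyle_labelled) {
    if (has("Fe-hyd")) add("facultatively anaerobic", "coxA + Fe-hyd")
    else add("aerobic", "coxA")
  }
  respiratory <- c("coxA", "ccoN", "napA", "narG", "nosZ", "dsrAB")
  fermentative <- has("Fe-hyd") && !any(vapply(respiratory, has, logical(1)))
  if (fermentative) add("fermentation", "Fe-hyd, no respiratory acceptors")
  anaerobic_acceptor <- has("napA") || has("narG") || has("dsrAB")
  if ((has("hybC") || has("hyaB")) && !fermentative &&
      !(isTRUE(autotroph) && !anaerobic_acceptor)) {
    add("H2 utilization", paste(intersect(c("hybC", "hyaB"),
                                          names(which(presence))),
                                collapse = "+"))
  }
  if (has("GH1")) add("carbohydrate utilization", "GH1")
  if (has("bzd")) add("aromatic compound utilization", "bzd")
  if (isTRUE(wl_complete) && has("cooS") && has("cooF")) {
    add("acetogenic", "complete WL + cooS/cooF cluster")
  }
  if (length(labels) == 0L) add("Unidentified", "no rule fired")
  stopifnot(all(labels %in% METABOLISM_VOCABULARY))
  structure(list(mag_id = mag_id, labels = labels, evidence = evidence),
            class = "metabolism_call")
}

#' @export
print.metabolism_call <- function(x, ...) {
  cat(x$mag_id %||% "MAG", ": ", paste(x$labels, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
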