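#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef rnorm rlnorm sd setNames rmultinom runif
#' @importFrom utils read.delim write.table
#' @importFrom methods is
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators funnel through this so that identical (spec, seed) inputs
# give byte-identical outputs without clobbering the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Order MAG/bin identifiers naturally: "KA2" before "KA10"; ids that do not
# match <alpha><digits> fall back to plain lexicographic order.
natural_order <- function(ids) {
  ids <- as.character(ids)
  prefix <- sub("([0-9]+)$", "", ids)
  digits <- regmatches(ids, regexpr("[0-9]+$", ids))
  num <- rep(NA_real_, length(ids))
  has_num <- grepl("[0-9]+$", ids)
  num[has_num] <- as.numeric(regmatches(ids, regexpr("[0-9]+$", ids))[])
  order(prefix, num, ids, na.last = TRUE)
}

read_tsv_file <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("NA", ""), quote = "", ...)
}

write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "")
  invisible(path)
}

# Validate a (mag_id, gene_id, annotation_id) annotation table.
check_annotations <- function(annotations) {
  stopifnot(is.data.frame(annotations))
  need <- c("mag_id", "annotation_id")
  missing <- setdiff(need, names(annotations))
  if (length(missing) > 0) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  annotations
}
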