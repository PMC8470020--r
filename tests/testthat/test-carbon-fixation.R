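defs <- load_pathway_definitions()
catalog <- load_marker_catalog()

toy_def <- function(name, genes, key = character(0)) {
  structure(list(name = name, label = name, essential_genes = genes,
                 key_genes = key), class = "pathway_definition")
}

test_that("the default config defines the seven fixation pathways in order", {
  expect_length(defs, 7L)
  expect_equal(names(defs),
               c("CBB", "WL", "rTCA", "3-HP", "3-HP/4-HB", "DC/4-HB", "roTCA"))
  for (d in defs) {
    expect_gt(length(d$essential_genes), 0)
    expect_true(all(d$key_genes %in% d$essential_genes))
  }
})

test_that("config validation rejects bad pathway definitions", {
  bad_key <- tempfile(fileext = ".yaml")
  writeLines(c("pathways:",
               "  - name: CBB",
               "    essential_genes: [K1, K2]",
               "    key_genes: [K9]"), bad_key)
  expect_error(load_pathway_definitions(bad_key), "subset")
  dup <- tempfile(fileext = ".yaml")
  writeLines(c("pathways:",
               "  - name: CBB",
               "    essential_genes: [K1]",
               "  - name: CBB",
               "    essential_genes: [K2]"), dup)
  expect_error(load_pathway_definitions(dup), "duplicate")
  empty <- tempfile(fileext = ".yaml")
  writeLines(c("pathways:",
               "  - name: CBB",
               "    essential_genes: []"), empty)
  expect_error(load_pathway_definitions(empty), "empty gene set")
})

test_that("an override replaces one pathway's genes and leaves the rest", {
  over <- load_pathway_definitions(override = list(WL = c("a", "b")))
  expect_equal(over$WL$essential_genes, c("a", "b"))
  expect_equal(over$CBB$essential_genes, defs$CBB$essential_genes)
  expect_error(load_pathway_definitions(override = list(NOPE = "x")),
               "unknown pathway")
})

test_that("pathway scoring is exact set arithmetic", {
  def <- toy_def("T", c("k1", "k2", "k3", "k4"))
  expect_equal(score_pathway(c("k1", "k2", "k3", "k4"), def), 100)
  expect_equal(score_pathway(character(0), def), 0)
  expect_equal(score_pathway(c("k1", "k2", "k4", "zz"), def), 75)
  # presence is binary: duplicate rows do not inflate the score
  expect_equal(score_pathway(c("k1", "k1", "k1"), def), 25)
})

test_that("the completeness matrix recovers planted fractions exactly", {
  # pathways share genes (the TCA-cycle enzymes appear in rTCA, roTCA and
  # DC/4-HB), so exact fraction recovery is asserted on the planted pathway
  # and the remaining cells are checked against set arithmetic on the
  # planted gene list
  set.seed(42)
  for (rep in 1:20) {
    p <- sample(names(defs), 1)
    f <- round(runif(1), 2)
    spec <- mag_spec(paste0("SM", rep), pathway_fractions = setNames(f, p),
                     seed = rep)
    ann <- simulate_annotations(spec, defs, catalog)
    cm <- completeness_matrix(ann, defs, mag_ids = spec$mag_id)
    n <- length(defs[[p]]$essential_genes)
    expect_equal(cm[spec$mag_id, p], 100 * round(f * n) / n)
    for (q in names(defs)) {
      ess <- defs[[q]]$essential_genes
      expect_equal(cm[spec$mag_id, q],
                   100 * length(intersect(ess, ann$annotation_id)) /
                     length(ess))
    }
  }
})

test_that("matrix rows and columns are deterministic and zero-filled", {
  ann <- data.frame(mag_id = c("KA10", "KA2"),
                    annotation_id = c("K01601", "K01601"))
  cm <- completeness_matrix(ann, defs)
  expect_equal(rownames(cm), c("KA2", "KA10"))  # natural bin order
  expect_equal(colnames(cm), names(defs))
  empty <- data.frame(mag_id = character(0), annotation_id = character(0))
  cm0 <- completeness_matrix(empty, defs, mag_ids = "M1")
  expect_true(all(cm0 == 0))
})

test_that("adding an annotation row never decreases any cell", {
  set.seed(5)
  spec <- mag_spec("M1", pathway_fractions = c(CBB = 0.5, WL = 0.4), seed = 5)
  ann <- simulate_annotations(spec, defs, catalog)
  cm1 <- completeness_matrix(ann, defs, mag_ids = "M1")
  ann2 <- rbind(ann, data.frame(mag_id = "M1", gene_id = "M1_x",
                                annotation_id = "K01601"))
  cm2 <- completeness_matrix(ann2, defs, mag_ids = "M1")
  expect_true(all(cm2 >= cm1))
})

test_that("autotroph calls require full completeness and the key genes", {
  # a community with exactly six planted complete pathways yields six calls
  plan <- list(A1 = "CBB", A2 = "WL", A3 = "rTCA", A4 = "3-HP/4-HB",
               A5 = "WL", A6 = "DC/4-HB")
  anns <- do.call(rbind, lapply(names(plan), function(mag) {
    fr <- setNames(1.0, plan[[mag]])
    simulate_annotations(mag_spec(mag, pathway_fractions = fr,
                                  seed = match(mag, names(plan))),
                         defs, catalog)
  }))
  # plus a heterotroph with a partial pathway
  anns <- rbind(anns, simulate_annotations(
    mag_spec("H1", pathway_fractions = c(CBB = 0.8), seed = 99),
    defs, catalog))
  cm <- completeness_matrix(anns, defs)
  calls <- call_autotrophs(cm, defs, anns)
  expect_equal(nrow(calls), 6L)
  expect_setequal(calls$mag_id, names(plan))
  expect_false("H1" %in% calls$mag_id)
})

test_that("one missing essential gene blocks the call at threshold 100", {
  ess <- defs$CBB$essential_genes
  ann <- data.frame(mag_id = "M1",
                    annotation_id = ess[-length(ess)])
  cm <- completeness_matrix(ann, defs)
  expect_lt(cm["M1", "CBB"], 100)
  expect_equal(nrow(call_autotrophs(cm, defs, ann)), 0L)
})

test_that("citrate synthase alone never yields a roTCA call", {
  # citrate synthase (the roTCA key gene) plus a partial TCA complement
  ann <- data.frame(mag_id = "M1",
                    annotation_id = c("K01647", "K01681", "K00031", "K00024"))
  cm <- completeness_matrix(ann, defs)
  expect_gt(cm["M1", "roTCA"], 0)
  # even with a permissive threshold the roTCA guard demands the full cycle
  calls <- call_autotrophs(cm, defs, ann, threshold = 30)
  expect_false("roTCA" %in% calls$pathway)
  # with the complete gene set the call goes through
  full <- data.frame(mag_id = "M2",
                     annotation_id = defs$roTCA$essential_genes)
  cm2 <- completeness_matrix(full, defs)
  calls2 <- call_autotrophs(cm2, defs, full)
  expect_true(any(calls2$mag_id == "M2" & calls2$pathway == "roTCA"))
})

test_that("the key-gene guard blocks calls when diagnostic genes are absent", {
  # full score by count is impossible without key genes here since key genes
  # are members of the essential set; use a lowered threshold instead
  ess <- setdiff(defs$CBB$essential_genes, defs$CBB$key_genes)
  ann <- data.frame(mag_id = "M1", annotation_id = ess)
  cm <- completeness_matrix(ann, defs)
  expect_equal(nrow(call_autotrophs(cm, defs, ann, threshold = 80)), 0L)
  calls <- call_autotrophs(cm, defs, ann, threshold = 80,
                           key_gene_guard = FALSE)
  expect_true("CBB" %in% calls$pathway)
})
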