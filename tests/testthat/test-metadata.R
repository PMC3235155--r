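test_that("experiment creation assigns fresh private accessions and validates title", {
  repo <- repo_create()
  e1 <- create_experiment(repo, "MLL-AF9 leukemia expression", "A. Researcher")
  expect_match(e1$id, "^EXP-\\d{4}$")
  expect_identical(e1$visibility, "private")
  expect_identical(sum(repo$bioassays$experiment_id == e1$id), 0L)

  e2 <- create_experiment(repo, "MLL-AF9 leukemia expression", "A. Researcher")
  expect_false(e1$id == e2$id)

  expect_error(create_experiment(repo, ""), class = "generepo_validation_error")
})

test_that("biomaterials validate vocabulary terms and normalize marker polarity", {
  repo <- repo_create()
  bm <- add_biomaterial(
    repo, organism = "mouse", cell_type = "GMP",
    genetic_modifications = c("MLL-AF9" = "fusion expressed to model leukemia"),
    markers = list(c("C-kit", "+"), c("FcR", "+"), c("CD34", "+"),
                   c("Lin", "−")))
  mk <- repo$biomaterial_markers[repo$biomaterial_markers$biomaterial_id == bm, ]
  expect_identical(nrow(mk), 4L)
  expect_setequal(mk$polarity, c("+", "-"))
  expect_identical(mk$polarity[mk$marker == "Lin"], "-")

  bm2 <- add_biomaterial(repo, organism = "human",
                         disease_state = "Parkinson's disease",
                         age = 72, age_unit = "years", sex = "male")
  row <- repo$biomaterials[repo$biomaterials$id == bm2, ]
  expect_identical(row$disease_state, "Parkinson's disease")
  expect_identical(row$age, 72)

  err <- tryCatch(add_biomaterial(repo, organism = "mouse",
                                  cell_type = "Glarbocyte"),
                  error = identity)
  expect_s3_class(err, "generepo_validation_error")
  expect_match(conditionMessage(err), "cell_type")
  expect_match(conditionMessage(err), "Glarbocyte")
})

test_that("bioassays enforce registries, references and platform presence", {
  repo <- repo_create()
  exp <- create_experiment(repo, "assay linkage")
  bm <- add_biomaterial(repo, organism = "mouse")
  a1 <- add_bioassay(repo, exp$id, bm, "gene_expression", "microarray",
                     "HG-U133", "a.CEL")
  expect_identical(repo$bioassays$experiment_id[repo$bioassays$id == a1],
                   exp$id)
  a2 <- add_bioassay(repo, exp$id, bm, "histone_modification", "sequencing",
                     "Illumina GA", "r.fastq")
  expect_identical(repo$bioassays$technology[repo$bioassays$id == a2],
                   "sequencing")

  expect_error(add_bioassay(repo, exp$id, bm, "dna_methylation", "sequencing"),
               class = "generepo_validation_error")
  register_assay_type(repo, measurement_type = "dna_methylation")
  expect_no_error(add_bioassay(repo, exp$id, bm, "dna_methylation",
                               "sequencing"))

  expect_error(add_bioassay(repo, "EXP-9999", bm, "gene_expression",
                            "microarray", "P"),
               class = "generepo_notfound_error")
  expect_error(add_bioassay(repo, exp$id, bm, "gene_expression", "microarray",
                            platform = ""),
               class = "generepo_validation_error")
})

test_that("comparison groups must be disjoint, non-empty and within-experiment", {
  repo <- repo_create()
  exp <- create_experiment(repo, "cmp")
  other <- create_experiment(repo, "other")
  bm <- add_biomaterial(repo, organism = "mouse")
  a <- vapply(1:6, function(i)
    add_bioassay(repo, exp$id, bm, "gene_expression", "microarray", "P"), "")
  ax <- add_bioassay(repo, other$id, bm, "gene_expression", "microarray", "P")

  cmp <- define_comparison(repo, exp$id, a[1:3], a[4:6], "3v3")
  expect_identical(comparison_assays(repo, cmp, "case"), a[1:3])
  expect_identical(comparison_assays(repo, cmp, "control"), a[4:6])

  expect_error(define_comparison(repo, exp$id, a[1], a[1]),
               class = "generepo_validation_error")
  expect_error(define_comparison(repo, exp$id, a[1], ax),
               class = "generepo_validation_error")
  expect_error(define_comparison(repo, exp$id, character(), a[1]),
               class = "generepo_validation_error")
})

test_that("visibility transitions gate listing and data access", {
  fix <- tiny_annotated_repo(n_genes = 4, organisms = "human")
  repo <- fix$repo
  h <- add_tiny_experiment(repo, fix$ann$platforms[["human"]])
  vals <- setNames(rnorm(4), fix$ann$probes[[1]]$probeset_id)
  for (a in c(h$case, h$control)) store_expression(repo, a, vals)
  sel <- assay_selector("expression", bioassay = h$case[1])

  # private: invisible everywhere for anonymous viewers
  expect_false(h$experiment %in% list_experiments(repo)$id)
  expect_length(fetch_values(repo, sel), 0L)

  set_visibility(repo, h$experiment, "metadata_public")
  expect_true(h$experiment %in% list_experiments(repo)$id)
  expect_length(fetch_values(repo, sel), 0L)

  set_visibility(repo, h$experiment, "public")
  expect_identical(sort(names(fetch_values(repo, sel))), sort(names(vals)))

  expect_error(set_visibility(repo, h$experiment, "secret"),
               class = "generepo_validation_error")
})

test_that("deletion of referenced entities is rejected", {
  repo <- repo_create()
  exp <- create_experiment(repo, "refint")
  bm <- add_biomaterial(repo, organism = "mouse")
  a <- add_bioassay(repo, exp$id, bm, "gene_expression", "microarray", "P")
  expect_error(repo_delete(repo, bm), class = "generepo_validation_error")
  expect_error(repo_delete(repo, exp$id), class = "generepo_validation_error")
  expect_true(repo_delete(repo, a))
  expect_true(repo_delete(repo, bm))
  expect_true(repo_delete(repo, exp$id))
})

test_that("repositories survive a save/open round trip", {
  fix <- tiny_annotated_repo(n_genes = 3, organisms = c("human", "mouse"))
  repo <- fix$repo
  h <- add_tiny_experiment(repo, fix$ann$platforms[["human"]])
  vals <- setNames(c(1.5, -2.25, 0.125), fix$ann$probes[[1]]$probeset_id)
  store_expression(repo, h$case[1], vals)
  dir <- tempfile("repo")
  repo_save(repo, dir)
  back <- repo_open(dir)
  for (tab in c("experiments", "bioassays", "biomaterials", "genes",
                "transcripts", "probesets", "data_matrix", "vocab"))
    expect_equal(back[[tab]], repo[[tab]], ignore_attr = TRUE)
  expect_identical(back$counters, repo$counters)
})
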