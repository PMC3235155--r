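# cross-experiment gene queries, heatmap preparation, scatter joins

query_fixture <- function(seed = 31, n_genes = 30) {
  build_fixture_repository(simulation_spec(seed = seed, n_genes = n_genes,
                                           n_planted = 5))
}

test_that("gene queries hit every organism via ortholog expansion and filters only shrink", {
  fix <- query_fixture()
  repo <- fix$repo
  hits <- gene_query(repo, "GENE3")
  expect_setequal(unique(hits$gene_organism),
                  c("human", "mouse", "zebrafish"))
  # ordering: |log2_fc| descending
  expect_true(all(diff(abs(hits$log2_fc)) <= 1e-12))

  # any alias of any ortholog yields the same hit set
  members <- resolve_symbol(repo, "GENE3")
  g <- repo$genes[match(members$gene_id, repo$genes$gene_id), ]
  for (q in c(g$symbol, unlist(strsplit(g$aliases, "|", fixed = TRUE)))) {
    expect_setequal(gene_query(repo, q)$feature_id, hits$feature_id)
  }

  # organism filter gives a subset
  mouse <- gene_query(repo, "GENE3", query_filter(organism = "mouse"))
  expect_true(all(mouse$feature_id %in% hits$feature_id))
  expect_setequal(unique(mouse$organism), "mouse")

  # every single filter can only shrink the set
  filters <- list(query_filter(cell_type = "L-GMP"),
                  query_filter(max_p = 0.2),
                  query_filter(max_fdr = 0.5),
                  query_filter(min_abs_log2_fc = 0.2),
                  query_filter(title_contains = "mouse"),
                  query_filter(disease_state = "leukemia"))
  for (f in filters) {
    sub <- gene_query(repo, "GENE3", f)
    expect_true(all(sub$feature_id %in% hits$feature_id))
  }

  # degenerate filter empties the result
  expect_identical(nrow(gene_query(repo, "GENE3",
                                   query_filter(min_abs_log2_fc = Inf))), 0L)
  # expansion off with an organism-specific alias restricts to that organism
  local <- gene_query(repo, "hu-gene3", expand_orthologs = FALSE)
  expect_setequal(unique(local$gene_organism), "human")
  expect_lt(nrow(local), nrow(hits))

  expect_error(gene_query(repo, "GENE3", query_filter(organism = "martian")),
               class = "generepo_validation_error")
  expect_identical(nrow(gene_query(repo, "NOSUCH")), 0L)
})

test_that("quantile normalization satisfies its defining properties", {
  expect_equal(quantile_normalize(matrix(c(1, 2, 3, 4, 5, 6), ncol = 2)),
               matrix(c(2.5, 3.5, 4.5, 2.5, 3.5, 4.5), ncol = 2))
  # single column unchanged
  one <- matrix(c(3, 1, 2), ncol = 1)
  expect_identical(quantile_normalize(one), one)
  # ties share the mean of the tied ranks' reference values
  tied <- matrix(c(1, 1, 5, 2, 4, 6), ncol = 2)
  got <- quantile_normalize(tied)
  expect_equal(got[, 1], c(2, 2, 5.5))
  expect_equal(got[, 2], c(1.5, 2.5, 5.5))
  expect_equal(got, qn_oracle(tied))

  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rnorm(60, mean = rnorm(1, 8)), nrow = 12)
    q1 <- quantile_normalize(m)
    # identical sorted columns
    for (j in seq_len(ncol(m))[-1])
      expect_equal(sort(q1[, j]), sort(q1[, 1]))
    # equal column means and idempotence
    cm <- colMeans(q1)
    expect_lt(diff(range(cm)), 1e-12)
    expect_equal(quantile_normalize(q1), q1)
    # agreement with limma on tie-free matrices (independent route)
    expect_equal(unname(q1), unname(limma::normalizeQuantiles(m)),
                 tolerance = 1e-12)
  }
  expect_error(quantile_normalize(matrix(c(1, NA), 1)), "missing")
})

test_that("heatmap matrices label probesets per symbol and normalize columns", {
  fix <- query_fixture()
  repo <- fix$repo
  exp <- fix$experiments[["human"]]
  hm <- heatmap_matrix(repo, c("GENE1", "GENE2", "GENE5"), exp)
  expect_identical(nrow(hm$matrix), 3L)
  expect_identical(ncol(hm$matrix), 6L)
  expect_match(rownames(hm$matrix), "^GENE[125]\\|human_g\\d+_ps$")
  for (j in 2:6)
    expect_equal(sort(hm$matrix[, j]), sort(hm$matrix[, 1]),
                 ignore_attr = TRUE)
  expect_identical(hm$unmapped, character())

  hm2 <- heatmap_matrix(repo, c("GENE1", "NOPE"), exp)
  expect_identical(hm2$unmapped, "NOPE")
  err <- tryCatch(heatmap_matrix(repo, "NOPE", exp), error = identity)
  expect_s3_class(err, "generepo_validation_error")
  expect_match(conditionMessage(err), "NOPE")
})

test_that("scatter tables inner-join axes and left-join color on gene id", {
  fix <- tiny_annotated_repo(n_genes = 6, organisms = "human")
  repo <- fix$repo
  sq <- add_tiny_experiment(repo, "", n_case = 1, n_control = 1,
                            technology = "sequencing",
                            measurement = "histone_modification")
  set_visibility(repo, sq$experiment, "public")
  tx <- fix$ann$transcripts
  mk_scores <- function(rows, scores)
    data.frame(chrom = tx$chrom[rows], start = tx$tx_start[rows],
               end = tx$tx_end[rows], score = scores,
               score_type = "fpkm_window", transcript_id = tx$transcript_id[rows])
  store_locus_scores(repo, sq$case[1], mk_scores(1:5, c(1, 2, 3, 4, 5)))
  store_locus_scores(repo, sq$control[1], mk_scores(2:6, c(10, 20, 30, 40, 50)))

  st <- scatter_table(repo,
                      x = assay_selector("fpkm", bioassay = sq$control[1]),
                      y = assay_selector("fpkm", bioassay = sq$case[1]))
  # genes 2..5 have both channels; 1 and 6 are dropped by the inner join
  expect_identical(st$gene_id, tx$gene_id[2:5])
  expect_equal(st$x, c(10, 20, 30, 40))
  expect_equal(st$y, c(2, 3, 4, 5))

  # log2 selector transform
  st2 <- scatter_table(repo,
                       x = assay_selector("fpkm", bioassay = sq$control[1],
                                          log2 = TRUE),
                       y = assay_selector("fpkm", bioassay = sq$case[1]))
  expect_equal(st2$x, log2(c(10, 20, 30, 40) + 1))
})

test_that("hidden channels are distinguished from absent ones", {
  fix <- tiny_annotated_repo(n_genes = 4, organisms = "human")
  repo <- fix$repo
  sq <- add_tiny_experiment(repo, "", n_case = 1, n_control = 1,
                            technology = "sequencing",
                            measurement = "histone_modification")
  tx <- fix$ann$transcripts
  store_locus_scores(repo, sq$case[1], data.frame(
    chrom = tx$chrom[1], start = tx$tx_start[1], end = tx$tx_end[1],
    score = 3, score_type = "fpkm_window", transcript_id = tx$transcript_id[1]))
  sel_case <- assay_selector("fpkm", bioassay = sq$case[1])
  sel_ctrl <- assay_selector("fpkm", bioassay = sq$control[1])

  # private experiment: hidden
  err <- tryCatch(scatter_table(repo, sel_case, sel_case), error = identity)
  expect_match(conditionMessage(err), "hidden")
  # public but empty: absent
  set_visibility(repo, sq$experiment, "public")
  err2 <- tryCatch(scatter_table(repo, sel_ctrl, sel_ctrl), error = identity)
  expect_match(conditionMessage(err2), "absent")
})
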