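write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

small_gene_tables <- function(dir = tempfile("ann")) {
  dir.create(dir)
  genes <- data.frame(
    gene_id = c("h1", "m1", "z1"),
    symbol = c("GATA1", "Gata1", "gata1"),
    aliases = c("ERYF1|GF-1", "Gata-1", "zgata1"),
    organism = c("human", "mouse", "zebrafish"),
    homolog_group_id = c("1556", "1556", "1556"))
  tx <- data.frame(
    transcript_id = c("h1.t1", "m1.t1", "z1.t1", "z1.t2"),
    gene_id = c("h1", "m1", "z1", "z1"),
    chrom = c("chrX", "chrX", "chr11", "chr11"),
    strand = c("+", "-", "+", "+"),
    tx_start = c(1000L, 5000L, 1000L, 1200L),
    tx_end = c(3000L, 8000L, 2000L, 2200L),
    exon_starts = c("1000,2500", "5000", "1000", "1200"),
    exon_ends = c("1400,3000", "8000", "2000", "2200"))
  list(genes = write_tsv(genes, file.path(dir, "g.tsv")),
       tx = write_tsv(tx, file.path(dir, "t.tsv")), dir = dir,
       genes_df = genes, tx_df = tx)
}

test_that("annotation loading counts entities and enforces integrity", {
  tabs <- small_gene_tables()
  repo <- repo_create()
  n <- load_annotation(repo, tabs$genes, tabs$tx)
  expect_identical(unname(n), c(3L, 4L))

  # dangling transcript
  bad <- tabs$tx_df
  bad$gene_id[1] <- "nope"
  repo2 <- repo_create()
  err <- tryCatch(load_annotation(repo2, tabs$genes,
                                  write_tsv(bad, tempfile())),
                  error = identity)
  expect_s3_class(err, "generepo_validation_error")
  expect_match(conditionMessage(err), "h1.t1")

  # inverted coordinates
  bad2 <- tabs$tx_df
  bad2$tx_start[2] <- 9000L
  expect_error(load_annotation(repo_create(), tabs$genes,
                               write_tsv(bad2, tempfile())),
               "tx_start >= tx_end")
})

test_that("platform registration is unique per platform and reports unmapped probesets", {
  tabs <- small_gene_tables()
  repo <- repo_create()
  load_annotation(repo, tabs$genes, tabs$tx)
  pm <- data.frame(probeset_id = c("p1", "p2", "p3"),
                   transcript_id = c("h1.t1", "m1.t1", ""))
  f <- write_tsv(pm, tempfile())
  expect_warning(n <- register_platform(repo, "A1", f), "no transcript")
  expect_identical(n, 3L)
  expect_error(register_platform(repo, "A1", f),
               class = "generepo_validation_error")
  # same ids under another platform are fine
  expect_warning(register_platform(repo, "A2", f), "no transcript")
})

test_that("ortholog index rejects multi-group genes and tolerates empty tables", {
  tabs <- small_gene_tables()
  repo <- repo_create()
  load_annotation(repo, tabs$genes, tabs$tx)
  hom <- data.frame(homolog_group_id = "1556", gene_id = c("h1", "m1", "z1"))
  expect_identical(build_ortholog_index(repo, write_tsv(hom, tempfile())), 1L)

  conflicted <- rbind(hom, data.frame(homolog_group_id = "9", gene_id = "h1"))
  expect_error(build_ortholog_index(repo, write_tsv(conflicted, tempfile())),
               class = "generepo_validation_error")

  empty <- hom[0, ]
  expect_identical(build_ortholog_index(repo, write_tsv(empty, tempfile())),
                   0L)
  # with no groups, an organism-specific alias resolves to its gene only
  # (the shared symbol still co-resolves case-insensitively by design)
  expect_identical(nrow(resolve_symbol(repo, "ERYF1", TRUE)), 1L)
  expect_identical(nrow(resolve_symbol(repo, "GATA1", TRUE)), 3L)
})

test_that("symbol resolution is case-insensitive, alias-closed and ortholog-expanding", {
  tabs <- small_gene_tables()
  repo <- repo_create()
  load_annotation(repo, tabs$genes, tabs$tx)
  hom <- data.frame(homolog_group_id = "1556", gene_id = c("h1", "m1", "z1"))
  build_ortholog_index(repo, write_tsv(hom, tempfile()))

  hits <- resolve_symbol(repo, "GATA1", expand_orthologs = TRUE)
  expect_identical(nrow(hits), 3L)
  expect_setequal(hits$organism, c("human", "mouse", "zebrafish"))

  # alias symmetry: every alias of every member resolves to the same set
  all_names <- c("GATA1", "ERYF1", "GF-1", "Gata1", "Gata-1", "gata1",
                 "zgata1", "eryf1", "GATA-1"[0])
  for (q in all_names) {
    expect_identical(resolve_symbol(repo, q, TRUE)$gene_id, hits$gene_id,
                     info = q)
  }
  # expansion off restricts to direct matches
  expect_identical(resolve_symbol(repo, "Gata-1", FALSE)$gene_id, "m1")
  expect_identical(nrow(resolve_symbol(repo, "nosuchgene", TRUE)), 0L)
})

test_that("interval index agrees with a brute-force scan on random annotation", {
  repo <- repo_create()
  set.seed(99)
  tx <- random_transcripts(60)
  genes <- data.frame(gene_id = tx$gene_id, symbol = toupper(tx$gene_id),
                      aliases = "", organism = "human",
                      homolog_group_id = "")
  load_annotation(repo, write_tsv(genes, tempfile()),
                  write_tsv(tx, tempfile()))
  for (i in 1:50) {
    s <- sample.int(200000, 1); e <- s + sample.int(5000, 1)
    got <- transcripts_in_range(repo, "chrT", s, e)$transcript_id
    want <- tx$transcript_id[tx$tx_start < e & tx$tx_end > s]
    expect_setequal(got, want)
  }
})

test_that("reloading identical tables into fresh repositories is idempotent", {
  tabs <- small_gene_tables()
  r1 <- repo_create(); r2 <- repo_create()
  load_annotation(r1, tabs$genes, tabs$tx)
  load_annotation(r2, tabs$genes, tabs$tx)
  expect_identical(r1$genes, r2$genes)
  expect_identical(r1$transcripts, r2$transcripts)
})
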