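# Seeded synthetic-data generators with planted ground truth: toy multi-
# species annotation, expression matrices with planted fold changes, ChIP
# fragment sets with planted TSS enrichment, rank-coupled expression/mark
# simulations, and SOFT fixture files. Every generator is a pure function of
# (spec, seed): identical inputs give byte-identical outputs.

#' Build a simulation specification
#'
#' The spec fixes every condition of the synthetic study: genome/annotation
#' shape, replicate counts, planted differential-expression effects,
#' replicate noise, ChIP enrichment and the rank coupling between mark and
#' expression changes.
#'
#' @param seed integer seed driving all generators.
#' @param n_genes genes per organism.
#' @param organisms organisms sharing ortholog groups (one toy chromosome
#'   each).
#' @param n_case,n_control replicate counts of the expression contrast.
#' @param n_planted number of genes given a planted expression effect.
#' @param effect_size absolute planted effect, log2 units (half planted up,
#'   half down).
#' @param noise_sd replicate noise SD on the log2 scale.
#' @param chip list: `n_enriched`, `enrichment_factor`, `library_size`
#'   (fragments), `fragment_bp`.
#' @param coupling_rho Spearman correlation between planted mark change and
#'   planted expression effect in [simulate_coupled()]; in `[-1, 1]`.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, n_genes = 1000L,
                            organisms = c("human", "mouse", "zebrafish"),
                            n_case = 3L, n_control = 3L, n_planted = 50L,
                            effect_size = 2, noise_sd = 0.5,
                            chip = list(n_enriched = 50L,
                                        enrichment_factor = 10,
                                        library_size = 300000L,
                                        fragment_bp = 200L),
                            coupling_rho = 0.7) {
  if (noise_sd <= 0) stop_validation("noise_sd must be > 0")
  if (n_case < 2L || n_control < 2L)
    stop_validation("need >= 2 replicates per group")
  if (n_planted > n_genes)
    stop_validation("cannot plant more effects than genes")
  if (!is.null(coupling_rho) && abs(coupling_rho) > 1)
    stop_validation("|coupling_rho| must be <= 1")
  if (!is.null(chip) && chip$library_size < 1000L)
    stop_validation("chip library size < 1000: FPKM unstable")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 organisms = organisms, n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_planted = as.integer(n_planted),
                 effect_size = effect_size, noise_sd = noise_sd,
                 chip = chip, coupling_rho = coupling_rho),
            class = "simulation_spec")
}

# toy genome geometry: one chromosome per organism, TSS every `spacing` bp
GENE_SPACING <- 10000L
TX_LEN <- 2000L

#' Generate toy multi-species annotation tables
#'
#' One chromosome per organism with TSS spaced 10 kb apart (so default
#' promoter windows never overlap), alternating strands, one transcript of
#' 2 kb with two 800 bp exons per gene, one probeset per transcript on a
#' per-organism platform, and one cross-organism homolog group per gene
#' index. Symbols are organism-cased variants of a shared family name
#' (`GENE7` / `Gene7` / `gene7`) with per-organism aliases, so
#' case-insensitive and alias resolution are exercised.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory for the TSV tables; created if needed.
#' @return List: `gene_table`, `transcript_table`, `homolog_table`,
#'   `probe_maps` (named by platform), `platforms`, and the in-memory data
#'   frames `genes`, `transcripts`, `homologs`, `probes`.
#' @export
make_annotation <- function(spec, dir = tempfile("annotation")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genes <- list(); txs <- list(); probes <- list(); homo <- list()
  for (oi in seq_along(spec$organisms)) {
    org <- spec$organisms[oi]
    chrom <- paste0("chr_", org)
    idx <- seq_len(spec$n_genes)
    gid <- sprintf("%s_g%04d", org, idx)
    base <- paste0("GENE", idx)
    sym <- switch(org, human = toupper(base),
                  mouse = paste0("G", tolower(substring(base, 2))),
                  tolower(base))
    alias <- paste0(tolower(substring(org, 1, 2)), "-", tolower(base))
    tss <- 5000L + (idx - 1L) * GENE_SPACING
    strand <- ifelse(idx %% 2L == 0L, "+", "-")
    tx_start <- ifelse(strand == "+", tss, tss - TX_LEN)
    tx_end <- ifelse(strand == "+", tss + TX_LEN, tss)
    genes[[org]] <- data.frame(
      gene_id = gid, symbol = sym, aliases = alias, organism = org,
      homolog_group_id = as.character(1000L + idx), stringsAsFactors = FALSE)
    txs[[org]] <- data.frame(
      transcript_id = paste0(gid, "_t1"), gene_id = gid, chrom = chrom,
      strand = strand, tx_start = as.integer(tx_start),
      tx_end = as.integer(tx_end),
      exon_starts = paste(tx_start, tx_end - 800L, sep = ","),
      exon_ends = paste(tx_start + 800L, tx_end, sep = ","),
      stringsAsFactors = FALSE)
    probes[[org]] <- data.frame(
      probeset_id = paste0(gid, "_ps"), transcript_id = paste0(gid, "_t1"),
      stringsAsFactors = FALSE)
    homo[[org]] <- data.frame(homolog_group_id = as.character(1000L + idx),
                              gene_id = gid, stringsAsFactors = FALSE)
  }
  gene_df <- do.call(rbind, genes); row.names(gene_df) <- NULL
  tx_df <- do.call(rbind, txs); row.names(tx_df) <- NULL
  homo_df <- do.call(rbind, homo); row.names(homo_df) <- NULL

  gene_path <- file.path(dir, "genes.tsv")
  tx_path <- file.path(dir, "transcripts.tsv")
  homo_path <- file.path(dir, "homologs.tsv")
  utils::write.table(gene_df, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tx_df, tx_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(homo_df, homo_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  platforms <- stats::setNames(paste0("ARRAY_", toupper(spec$organisms)),
                               spec$organisms)
  probe_paths <- stats::setNames(
    file.path(dir, paste0("probes_", spec$organisms, ".tsv")),
    platforms)
  for (org in spec$organisms)
    utils::write.table(probes[[org]], probe_paths[platforms[org]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(gene_table = gene_path, transcript_table = tx_path,
       homolog_table = homo_path, probe_maps = probe_paths,
       platforms = platforms, genes = gene_df, transcripts = tx_df,
       homologs = homo_df,
       probes = stats::setNames(probes, unname(platforms)))
}

# deterministic planted-gene selection and signed effects
planted_effects <- function(spec) {
  set.seed(spec$seed + 11L)
  idx <- sort(sample.int(spec$n_genes, spec$n_planted))
  sign <- rep(c(1, -1), length.out = spec$n_planted)
  data.frame(gene_index = idx, effect = sign * spec$effect_size)
}

#' Simulate a probeset-level expression matrix with planted fold changes
#'
#' Per-gene baselines are uniform on `[4, 12]` (log2 scale); case replicates
#' add the planted effect; every replicate gets independent Normal(0,
#' `noise_sd`) noise. Returned both on the log2 scale (as stored
#' post-summarization) and on the raw scale (`2^log2`, suitable for
#' [summarize_expression()]).
#'
#' @param spec a [simulation_spec()].
#' @param organism which organism's probesets to label rows with (default
#'   first).
#' @return List: `log2_matrix` (probesets x assays), `raw_matrix`, `case`,
#'   `control` (column names), `truth` (planted `gene_index`,
#'   `probeset_id`, `effect`).
#' @export
simulate_expression <- function(spec, organism = spec$organisms[1]) {
  set.seed(spec$seed + 23L)
  n <- spec$n_genes
  planted <- planted_effects(spec)
  effect <- numeric(n)
  effect[planted$gene_index] <- planted$effect
  baseline <- stats::runif(n, 4, 12)
  case_cols <- paste0("case_", seq_len(spec$n_case))
  ctrl_cols <- paste0("control_", seq_len(spec$n_control))
  m <- matrix(stats::rnorm(n * (spec$n_case + spec$n_control),
                           sd = spec$noise_sd),
              nrow = n)
  m <- m + baseline + outer(effect, c(rep(1, spec$n_case),
                                      rep(0, spec$n_control)))
  ps <- sprintf("%s_g%04d_ps", organism, seq_len(n))
  dimnames(m) <- list(ps, c(case_cols, ctrl_cols))
  truth <- data.frame(gene_index = planted$gene_index,
                      probeset_id = ps[planted$gene_index],
                      effect = planted$effect, stringsAsFactors = FALSE)
  list(log2_matrix = m, raw_matrix = 2^m, case = case_cols,
       control = ctrl_cols, truth = truth)
}

# sample fragment midpoints: background uniform over [0, L) plus per-window
# extra mass proportional to (factor_g - 1) * window_len
sample_chip_midpoints <- function(n, chrom_len, win_start, win_end, factors) {
  extra <- pmax(factors - 1, 0) * (win_end - win_start)
  cum <- cumsum(extra)
  mass <- chrom_len + sum(extra)
  u <- stats::runif(n, 0, mass)
  mid <- integer(n)
  bg <- u < chrom_len
  mid[bg] <- as.integer(floor(u[bg]))
  if (any(!bg)) {
    v <- u[!bg] - chrom_len
    wi <- findInterval(v, c(0, cum), rightmost.closed = FALSE,
                       left.open = TRUE)
    off <- (v - c(0, cum)[wi]) / pmax(factors[wi] - 1, 1e-12)
    mid[!bg] <- as.integer(win_start[wi] + floor(off))
  }
  mid
}

#' Simulate ChIP fragments with planted TSS-window enrichment
#'
#' Fragments fall uniformly over the organism's toy chromosome except in the
#' TSS +/- 1 kb windows of the enriched genes, where the density is
#' `enrichment_factor` times background. Fragment length is fixed (200 bp
#' default); the fragment's midpoint carries the planted position.
#'
#' @param spec a [simulation_spec()] with a `chip` component.
#' @param annotation output of [make_annotation()].
#' @param organism organism to simulate (default first).
#' @param factors optional per-gene enrichment factors overriding the
#'   binary enriched-set model (used by [simulate_coupled()]).
#' @param seed_offset internal offset so multiple libraries from one spec
#'   differ.
#' @return List: `alignments` (chrom/start/end data frame), `truth`
#'   (per-gene `gene_id`, `factor`, `expected_window_count`), `total`.
#' @export
simulate_chip <- function(spec, annotation, organism = spec$organisms[1],
                          factors = NULL, seed_offset = 0L) {
  if (is.null(spec$chip)) stop_validation("spec has no chip settings")
  set.seed(spec$seed + 37L + seed_offset)
  chrom <- paste0("chr_", organism)
  tx <- annotation$transcripts[annotation$transcripts$chrom == chrom, ,
                               drop = FALSE]
  win <- tss_window(tx, 1000L, 1000L)
  n_genes <- nrow(win)
  if (is.null(factors)) {
    enriched <- sort(sample.int(n_genes, spec$chip$n_enriched))
    factors <- rep(1, n_genes)
    factors[enriched] <- spec$chip$enrichment_factor
  }
  chrom_len <- max(win$end) + 5000L
  N <- spec$chip$library_size
  mid <- sample_chip_midpoints(N, chrom_len, win$start, win$end, factors)
  half <- spec$chip$fragment_bp %/% 2L
  alignments <- data.frame(chrom = chrom,
                           start = pmax(mid - half, 0L),
                           end = mid - half + spec$chip$fragment_bp,
                           stringsAsFactors = FALSE)
  mass <- chrom_len + sum(pmax(factors - 1, 0) * (win$end - win$start))
  truth <- data.frame(gene_id = win$gene_id, factor = factors,
                      expected_window_count =
                        N * factors * (win$end - win$start) / mass,
                      stringsAsFactors = FALSE)
  list(alignments = alignments, truth = truth, total = N)
}

#' Simulate rank-coupled expression and histone-mark changes
#'
#' Per-gene expression effects and log2 mark changes are drawn from a
#' Gaussian copula with latent correlation `r = 2 sin(pi * rho / 6)`, which
#' makes the population Spearman correlation exactly `coupling_rho`. The
#' expression simulator plants the drawn effects (scaled to SD 2 log2
#' units); two ChIP libraries ("control" and "case" states) split the mark
#' change symmetrically around a shared per-gene baseline enrichment.
#'
#' @param spec a [simulation_spec()] with `coupling_rho` set.
#' @param annotation output of [make_annotation()].
#' @return List: `expression` (as [simulate_expression()] but with the
#'   coupled effects), `chip_control`, `chip_case` (as [simulate_chip()]),
#'   `truth` (per-gene `gene_id`, `expr_effect`, `mark_change`).
#' @export
simulate_coupled <- function(spec, annotation) {
  if (is.null(spec$coupling_rho))
    stop_validation("spec has no coupling_rho")
  rho <- spec$coupling_rho
  set.seed(spec$seed + 53L)
  n <- spec$n_genes
  r <- 2 * sin(pi * rho / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  expr_effect <- 2 * z1
  mark_change <- z2

  org <- spec$organisms[1]
  baseline <- stats::runif(n, 4, 12)
  case_cols <- paste0("case_", seq_len(spec$n_case))
  ctrl_cols <- paste0("control_", seq_len(spec$n_control))
  m <- matrix(stats::rnorm(n * (spec$n_case + spec$n_control),
                           sd = spec$noise_sd), nrow = n)
  m <- m + baseline + outer(expr_effect,
                            c(rep(1, spec$n_case), rep(0, spec$n_control)))
  ps <- sprintf("%s_g%04d_ps", org, seq_len(n))
  dimnames(m) <- list(ps, c(case_cols, ctrl_cols))
  expression <- list(log2_matrix = m, raw_matrix = 2^m, case = case_cols,
                     control = ctrl_cols,
                     truth = data.frame(gene_index = seq_len(n),
                                        probeset_id = ps,
                                        effect = expr_effect,
                                        stringsAsFactors = FALSE))

  # baseline enrichment ~ 8x background in every window, split by the mark
  base_factor <- 8
  f_control <- base_factor * 2^(-mark_change / 2)
  f_case <- base_factor * 2^(mark_change / 2)
  chip_control <- simulate_chip(spec, annotation, org, factors = f_control,
                                seed_offset = 101L)
  chip_case <- simulate_chip(spec, annotation, org, factors = f_case,
                             seed_offset = 202L)
  gene_ids <- sprintf("%s_g%04d", org, seq_len(n))
  list(expression = expression, chip_control = chip_control,
       chip_case = chip_case,
       truth = data.frame(gene_id = gene_ids, expr_effect = expr_effect,
                          mark_change = mark_change,
                          stringsAsFactors = FALSE))
}

#' Build a complete in-memory fixture repository
#'
#' Loads the toy annotation, registers platforms and orthologs, creates one
#' public expression experiment per organism (same planted effects in each,
#' independent noise) with a case/control comparison, runs the differential
#' pipeline, and returns the populated repository. This is the standard
#' harness for exercising query, visualization and export against known
#' ground truth.
#'
#' @param spec a [simulation_spec()].
#' @param visibility visibility applied to every experiment.
#' @return List: `repo`, `annotation`, per-organism `experiments`,
#'   `comparisons` and `truth`.
#' @export
build_fixture_repository <- function(spec, visibility = "public") {
  ann <- make_annotation(spec)
  repo <- repo_create()
  load_annotation(repo, ann$gene_table, ann$transcript_table)
  for (pf in names(ann$probe_maps))
    suppressWarnings(register_platform(repo, pf, ann$probe_maps[[pf]]))
  build_ortholog_index(repo, ann$homolog_table)

  experiments <- character(); comparisons <- character(); truths <- list()
  for (oi in seq_along(spec$organisms)) {
    org <- spec$organisms[oi]
    sub <- spec
    sub$seed <- spec$seed + 1000L * oi
    class(sub) <- class(spec)
    sim <- simulate_expression(sub, organism = org)
    exp <- create_experiment(repo, paste0("Planted expression study (", org,
                                          ")"),
                             researcher = "Fixture Generator")
    bm_case <- add_biomaterial(repo, organism = org, cell_type = "L-GMP",
                               tissue = "bone marrow",
                               disease_state = "leukemia")
    bm_ctrl <- add_biomaterial(repo, organism = org, cell_type = "GMP",
                               tissue = "bone marrow",
                               disease_state = "healthy")
    platform <- ann$platforms[org]
    assay_of <- character()
    for (col in colnames(sim$log2_matrix)) {
      bm <- if (col %in% sim$case) bm_case else bm_ctrl
      a <- add_bioassay(repo, exp$id, bm, "gene_expression", "microarray",
                        platform, paste0(col, ".CEL"))
      store_expression(repo, a, sim$log2_matrix[, col])
      assay_of[col] <- a
    }
    cmp <- define_comparison(repo, exp$id, assay_of[sim$case],
                             assay_of[sim$control],
                             label = paste0("L-GMP vs GMP (", org, ")"))
    run_differential(repo, cmp)
    set_visibility(repo, exp$id, visibility)
    experiments[org] <- exp$id
    comparisons[org] <- cmp
    truths[[org]] <- sim$truth
  }
  list(repo = repo, annotation = ann, experiments = experiments,
       comparisons = comparisons, truth = truths)
}

#' Build a repository around the coupled expression/ChIP simulation
#'
#' Creates one public experiment holding the simulated expression assays
#' (with a case/control comparison run through the differential pipeline)
#' and two sequencing assays carrying the windowed FPKM scores of the
#' "control" and "case" chromatin states. The returned selectors feed
#' [scatter_table()] directly, reproducing the marks-versus-expression
#' integrative view.
#'
#' @param spec a [simulation_spec()] with `coupling_rho` set.
#' @return List: `repo`, `comparison`, `assay_chip_control`,
#'   `assay_chip_case`, `truth` (the coupled per-gene effects), `coupled`
#'   (raw simulation output).
#' @export
build_coupled_repository <- function(spec) {
  ann <- make_annotation(spec)
  repo <- repo_create()
  load_annotation(repo, ann$gene_table, ann$transcript_table)
  org <- spec$organisms[1]
  pf <- ann$platforms[org]
  suppressWarnings(register_platform(repo, pf, ann$probe_maps[[pf]]))
  cp <- simulate_coupled(spec, ann)

  exp <- create_experiment(repo, "Coupled marks and expression",
                           researcher = "Fixture Generator")
  bm_case <- add_biomaterial(repo, organism = org, cell_type = "L-GMP")
  bm_ctrl <- add_biomaterial(repo, organism = org, cell_type = "GMP")
  assay_of <- character()
  for (col in colnames(cp$expression$log2_matrix)) {
    bm <- if (col %in% cp$expression$case) bm_case else bm_ctrl
    a <- add_bioassay(repo, exp$id, bm, "gene_expression", "microarray", pf)
    store_expression(repo, a, cp$expression$log2_matrix[, col])
    assay_of[col] <- a
  }
  cmp <- define_comparison(repo, exp$id, assay_of[cp$expression$case],
                           assay_of[cp$expression$control],
                           label = "L-GMP vs GMP")
  run_differential(repo, cmp)

  tx <- ann$transcripts[ann$transcripts$chrom == paste0("chr_", org), ,
                        drop = FALSE]
  a_ctrl <- add_bioassay(repo, exp$id, bm_ctrl, "histone_modification",
                         "sequencing", "Illumina GA")
  a_case <- add_bioassay(repo, exp$id, bm_case, "histone_modification",
                         "sequencing", "Illumina GA")
  store_locus_scores(repo, a_ctrl,
                     window_fpkm(cp$chip_control$alignments, tx))
  store_locus_scores(repo, a_case,
                     window_fpkm(cp$chip_case$alignments, tx))
  set_visibility(repo, exp$id, "public")
  list(repo = repo, comparison = cmp, assay_chip_control = a_ctrl,
       assay_chip_case = a_case, truth = cp$truth, coupled = cp)
}

#' Write a SOFT fixture file for a simulated experiment
#'
#' Builds a small public expression experiment from the spec (first
#' organism only) and serializes it as a SOFT family file, characteristics
#' drawn from the seeded vocabularies.
#'
#' @param spec a [simulation_spec()].
#' @param path output file path.
#' @return List: `path`, `repo`, `experiment` (id) for round-trip
#'   comparisons.
#' @export
make_soft_fixture <- function(spec, path = tempfile(fileext = ".soft")) {
  fix <- build_fixture_repository_single(spec)
  writeLines(write_soft(fix$repo, fix$experiment, viewer = "owner"), path)
  c(fix, list(path = path))
}

# one-organism variant used for SOFT fixtures (smaller, faster)
build_fixture_repository_single <- function(spec) {
  ann <- make_annotation(spec)
  repo <- repo_create()
  load_annotation(repo, ann$gene_table, ann$transcript_table)
  org <- spec$organisms[1]
  pf <- ann$platforms[org]
  suppressWarnings(register_platform(repo, pf, ann$probe_maps[[pf]]))
  sim <- simulate_expression(spec, organism = org)
  exp <- create_experiment(repo, paste0("SOFT fixture ", spec$seed),
                           researcher = "Fixture Generator",
                           design = "simulated two-group contrast")
  bm_case <- add_biomaterial(repo, organism = org, cell_type = "L-GMP",
                             tissue = "bone marrow")
  bm_ctrl <- add_biomaterial(repo, organism = org, cell_type = "GMP",
                             tissue = "bone marrow")
  for (col in colnames(sim$log2_matrix)) {
    bm <- if (col %in% sim$case) bm_case else bm_ctrl
    a <- add_bioassay(repo, exp$id, bm, "gene_expression", "microarray",
                      pf, paste0(col, ".CEL"))
    store_expression(repo, a, sim$log2_matrix[, col])
  }
  set_visibility(repo, exp$id, "public")
  list(repo = repo, experiment = exp$id, simulated = sim, annotation = ann)
}
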