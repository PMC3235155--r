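# Gene-centric cross-experiment queries, heatmap matrix preparation and
# cross-assay scatter joins.

#' Build a gene-query filter
#'
#' All fields are optional; vocabulary-typed fields are validated against
#' the repository's vocabularies at query time. Adding a filter can only
#' shrink a result set.
#'
#' @param organism,cell_type,tissue,disease_state vocabulary terms of the
#'   sample context.
#' @param min_abs_log2_fc keep hits with `|log2_fc|` at or above this.
#' @param max_p,max_fdr keep hits with p-value / FDR at or below these.
#' @param title_contains,researcher_contains case-insensitive substring
#'   matches on the experiment title / researcher.
#' @return An object of class `query_filter`.
#' @export
query_filter <- function(organism = NULL, cell_type = NULL, tissue = NULL,
                         disease_state = NULL, min_abs_log2_fc = NULL,
                         max_p = NULL, max_fdr = NULL, title_contains = NULL,
                         researcher_contains = NULL) {
  if (!is.null(min_abs_log2_fc) && min_abs_log2_fc < 0)
    stop_validation("min_abs_log2_fc must be >= 0")
  structure(list(organism = organism, cell_type = cell_type, tissue = tissue,
                 disease_state = disease_state,
                 min_abs_log2_fc = min_abs_log2_fc, max_p = max_p,
                 max_fdr = max_fdr, title_contains = title_contains,
                 researcher_contains = researcher_contains),
            class = "query_filter")
}

validate_filter <- function(repo, f) {
  for (field in c("organism", "cell_type", "tissue", "disease_state")) {
    term <- f[[field]]
    if (!is.null(term) && !vocab_has(repo, field, term))
      stop_validation("unknown ", field, " term in filter: '", term, "'")
  }
  invisible(f)
}

# sample context of a comparison: taken from the biomaterial of its first
# case assay (comparisons contrast samples of one context against controls)
comparison_context <- function(repo, comparison) {
  case <- comparison_assays(repo, comparison, "case")
  bm_id <- repo$bioassays$biomaterial_id[match(case[1], repo$bioassays$id)]
  bm <- repo$biomaterials[match(bm_id, repo$biomaterials$id), , drop = FALSE]
  data.frame(organism = bm$organism, cell_type = bm$cell_type,
             tissue = bm$tissue, disease_state = bm$disease_state,
             stringsAsFactors = FALSE)
}

#' Query fold changes of a gene (and its orthologs) across all experiments
#'
#' Resolves `symbol` case-insensitively over symbols and aliases, expands
#' across HomoloGene-style ortholog groups when requested, collects every
#' stored fold-change record of the resolved genes' features (probesets and
#' transcripts) from experiments whose visibility permits data access, and
#' applies the filters. Hits are ordered by `|log2_fc|` descending, then
#' experiment id.
#'
#' @param repo a repository.
#' @param symbol gene symbol or alias.
#' @param filters a [query_filter()].
#' @param expand_orthologs include ortholog-group members (default TRUE).
#' @param viewer `"anonymous"` or `"owner"`.
#' @return Data frame of hits: `gene_id`, `symbol`, `gene_organism`,
#'   `experiment_id`, `comparison_id`, `feature_id`, `log2_fc`, `p_value`,
#'   `fdr`, `organism`, `cell_type`, `tissue`, `disease_state`.
#' @export
gene_query <- function(repo, symbol, filters = query_filter(),
                       expand_orthologs = TRUE, viewer = "anonymous") {
  check_viewer(viewer)
  validate_filter(repo, filters)
  genes <- resolve_symbol(repo, symbol, expand_orthologs)
  empty <- data.frame(gene_id = character(), symbol = character(),
                      gene_organism = character(), experiment_id = character(),
                      comparison_id = character(), feature_id = character(),
                      log2_fc = numeric(), p_value = numeric(),
                      fdr = numeric(), organism = character(),
                      cell_type = character(), tissue = character(),
                      disease_state = character(), stringsAsFactors = FALSE)
  if (nrow(genes) == 0L || nrow(repo$fc_matrix) == 0L) return(empty)

  fc <- repo$fc_matrix
  fc$gene_id <- feature_to_gene(repo, fc$feature_id)
  fc <- fc[fc$gene_id %in% genes$gene_id, , drop = FALSE]
  if (nrow(fc) == 0L) return(empty)

  fc$experiment_id <- repo$comparisons$experiment_id[
    match(fc$comparison_id, repo$comparisons$id)]
  vis <- repo$experiments$visibility[
    match(fc$experiment_id, repo$experiments$id)]
  fc <- fc[visible_data(vis, viewer), , drop = FALSE]
  if (nrow(fc) == 0L) return(empty)

  ctx <- do.call(rbind, lapply(unique(fc$comparison_id),
                               function(cid) cbind(comparison_id = cid,
                                 comparison_context(repo, cid))))
  fc <- merge(fc, ctx, by = "comparison_id", sort = FALSE)
  gi <- match(fc$gene_id, genes$gene_id)
  out <- data.frame(
    gene_id = fc$gene_id, symbol = genes$symbol[gi],
    gene_organism = genes$organism[gi], experiment_id = fc$experiment_id,
    comparison_id = fc$comparison_id, feature_id = fc$feature_id,
    log2_fc = fc$log2_fc, p_value = fc$p_value, fdr = fc$fdr,
    organism = fc$organism, cell_type = fc$cell_type, tissue = fc$tissue,
    disease_state = fc$disease_state, stringsAsFactors = FALSE)

  keep <- rep(TRUE, nrow(out))
  f <- filters
  if (!is.null(f$organism)) keep <- keep & !is.na(out$organism) &
      out$organism == f$organism
  if (!is.null(f$cell_type)) keep <- keep & !is.na(out$cell_type) &
      out$cell_type == f$cell_type
  if (!is.null(f$tissue)) keep <- keep & !is.na(out$tissue) &
      out$tissue == f$tissue
  if (!is.null(f$disease_state)) keep <- keep & !is.na(out$disease_state) &
      out$disease_state == f$disease_state
  if (!is.null(f$min_abs_log2_fc)) keep <- keep &
      abs(out$log2_fc) >= f$min_abs_log2_fc
  if (!is.null(f$max_p)) keep <- keep & out$p_value <= f$max_p
  if (!is.null(f$max_fdr)) keep <- keep & out$fdr <= f$max_fdr
  if (!is.null(f$title_contains) || !is.null(f$researcher_contains)) {
    ei <- match(out$experiment_id, repo$experiments$id)
    if (!is.null(f$title_contains))
      keep <- keep & grepl(f$title_contains,
                           repo$experiments$title[ei], ignore.case = TRUE,
                           fixed = FALSE)
    if (!is.null(f$researcher_contains))
      keep <- keep & grepl(f$researcher_contains,
                           repo$experiments$researcher[ei],
                           ignore.case = TRUE)
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(-abs(out$log2_fc), out$experiment_id, out$comparison_id,
                   out$feature_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Quantile-normalize a features x assays matrix
#'
#' Each column is replaced by the rank-wise means across columns (the
#' reference distribution is the mean of the columns' sorted values), so
#' every column shares one empirical distribution afterwards. Ties within a
#' column receive the mean of the tied ranks' reference values. The
#' transform is idempotent and leaves a single column unchanged.
#'
#' @param m numeric matrix with no missing values.
#' @return The normalized matrix, dimnames preserved.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (any(is.na(m)))
    stop_validation("missing values not allowed; filter them before ",
                    "normalization")
  if (ncol(m) == 0L) stop_validation("need at least one column")
  sorted <- apply(m, 2L, sort)
  if (is.null(dim(sorted)))                  # single-feature matrix
    sorted <- matrix(sorted, nrow = 1L)
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    sx <- m[o, j]
    grp <- cumsum(!duplicated(sx))          # tied runs share a group
    means <- tapply(ref, grp, mean)
    out[o, j] <- means[grp]
  }
  dimnames(out) <- dimnames(m)
  out
}

#' Heatmap matrix for a gene list within one experiment
#'
#' Rows are the probesets mapping to the queried symbols on the platforms
#' of the experiment's assays, labeled `symbol|probeset` (one row per
#' probeset, never averaged); columns are all of the experiment's bioassays
#' with expression data. Values are quantile-normalized across columns for
#' display comparability.
#'
#' @param repo a repository.
#' @param symbols character vector of gene symbols/aliases.
#' @param experiment experiment id; its data must be visible to the viewer.
#' @param viewer `"anonymous"` or `"owner"`.
#' @return List with `matrix` (quantile-normalized, labeled) and
#'   `unmapped` (symbols that matched no feature).
#' @export
heatmap_matrix <- function(repo, symbols, experiment, viewer = "anonymous") {
  check_viewer(viewer)
  vis <- get_experiment_row(repo, experiment)$visibility
  if (!visible_data(vis, viewer))
    stop_validation("experiment ", experiment,
                    " data not visible at this viewer level")
  assays <- repo$bioassays$id[repo$bioassays$experiment_id == experiment]
  d <- repo$data_matrix[repo$data_matrix$bioassay_id %in% assays, ,
                        drop = FALSE]
  assays <- intersect(assays, unique(d$bioassay_id))
  if (!length(assays)) stop_validation("experiment ", experiment,
                                       " has no expression data")
  rows <- list(); labels <- character(); unmapped <- character()
  for (s in symbols) {
    genes <- resolve_symbol(repo, s, expand_orthologs = FALSE)
    tx <- repo$transcripts$transcript_id[
      repo$transcripts$gene_id %in% genes$gene_id]
    ps <- repo$probesets[repo$probesets$transcript_id %in% tx, , drop = FALSE]
    ps <- ps$probeset_id[ps$probeset_id %in% d$probeset_id]
    if (!length(ps)) { unmapped <- c(unmapped, s); next }
    for (p in unique(ps)) {
      vals <- vapply(assays, function(a) {
        v <- d$value[d$bioassay_id == a & d$probeset_id == p]
        if (length(v)) v[1] else NA_real_
      }, 0)
      rows[[length(rows) + 1L]] <- vals
      sym <- genes$symbol[1]
      labels <- c(labels, paste0(sym, "|", p))
    }
  }
  if (!length(rows))
    stop_validation("no queried symbol maps to any measured feature; ",
                    "unmapped: ", paste(unmapped, collapse = ", "))
  m <- do.call(rbind, rows)
  dimnames(m) <- list(labels, assays)
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  list(matrix = quantile_normalize(m), unmapped = unmapped)
}

#' Gene-keyed scatter table joining up to four value channels
#'
#' Joins the x and y channels on gene id (inner join: genes must have both),
#' then left-joins optional color and size channels. Typical use: windowed
#' histone FPKM of two cell states on x/y with expression fold change as
#' color, to relate chromatin marks to transcription.
#'
#' @param repo a repository.
#' @param x,y [assay_selector()]s for the axes.
#' @param color,size optional selectors.
#' @param viewer `"anonymous"` or `"owner"`.
#' @return Data frame ordered by `gene_id`: `gene_id`, `x`, `y`, and
#'   `color`/`size` when requested (NA where the channel lacks the gene).
#' @export
scatter_table <- function(repo, x, y, color = NULL, size = NULL,
                          viewer = "anonymous") {
  check_viewer(viewer)
  vx <- fetch_gene_values(repo, x, viewer)
  vy <- fetch_gene_values(repo, y, viewer)
  genes <- sort(intersect(names(vx), names(vy)))
  out <- data.frame(gene_id = genes, x = unname(vx[genes]),
                    y = unname(vy[genes]), stringsAsFactors = FALSE)
  if (!is.null(color)) {
    vc <- fetch_gene_values(repo, color, viewer)
    out$color <- unname(vc[match(out$gene_id, names(vc))])
  }
  if (!is.null(size)) {
    vs <- fetch_gene_values(repo, size, viewer)
    out$size <- unname(vs[match(out$gene_id, names(vs))])
  }
  row.names(out) <- NULL
  out
}
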