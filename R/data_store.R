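# The three genomic data tables: probe-level expression matrix rows
# (one row per assay x probeset), locus scores (region-anchored FPKM / peak
# values) and the fold-change matrix, plus visibility-honoring retrieval.

SCORE_TYPES <- c("fpkm_window", "fpkm_transcript", "peak")
VALUE_CHANNELS <- c("expression", "fpkm", "peak", "log2_fc")

#' Store summarized expression values for a bioassay
#'
#' Values are log2-scale post-summarization expression, one per probeset of
#' the assay's platform. The write is atomic (all rows or none) and
#' re-ingestion replaces previous values per (assay, probeset) key.
#'
#' @param repo a repository.
#' @param bioassay bioassay id; must use a probe-based technology
#'   (e.g. microarray) with a registered platform.
#' @param values named numeric vector, names = probeset ids.
#' @return Number of rows written.
#' @export
store_expression <- function(repo, bioassay, values) {
  assay <- get_bioassay_row(repo, bioassay)
  if (assay$technology == "sequencing")
    stop_validation("store_expression needs a probe-based assay; ",
                    bioassay, " uses sequencing")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop_validation("values must be named by probeset id")
  if (anyDuplicated(names(values)))
    stop_validation("duplicate probeset ids in values")
  if (any(!is.finite(values)))
    stop_validation("expression values must be finite")
  on_platform <- repo$probesets$probeset_id[
    repo$probesets$platform == assay$platform]
  foreign <- setdiff(names(values), on_platform)
  if (length(foreign))
    stop_validation("probesets not on platform ", assay$platform, ": ",
                    paste(foreign, collapse = ", "))
  keep <- !(repo$data_matrix$bioassay_id == bioassay &
              repo$data_matrix$probeset_id %in% names(values))
  repo$data_matrix <- rbind(
    repo$data_matrix[keep, , drop = FALSE],
    data.frame(bioassay_id = bioassay, probeset_id = names(values),
               value = as.numeric(values), stringsAsFactors = FALSE))
  row.names(repo$data_matrix) <- NULL
  length(values)
}

#' Store locus scores (windowed FPKM, transcript FPKM or peak scores)
#'
#' @param repo a repository.
#' @param bioassay a sequencing bioassay id.
#' @param scores data frame with columns `chrom`, `start`, `end`, `score`,
#'   `score_type` and optional `transcript_id`, `gene_id`. Coordinates are
#'   0-based half-open; scores must be finite and non-negative. A missing
#'   `gene_id` is back-filled from `transcript_id` via the annotation.
#' @return Number of rows written.
#' @export
store_locus_scores <- function(repo, bioassay, scores) {
  assay <- get_bioassay_row(repo, bioassay)
  if (assay$technology != "sequencing")
    stop_validation("locus scores require a sequencing assay")
  if (nrow(scores) == 0L) return(0L)
  need <- c("chrom", "start", "end", "score", "score_type")
  if (!all(need %in% names(scores)))
    stop_validation("scores need columns: ", paste(need, collapse = ", "))
  if (is.null(scores$transcript_id)) scores$transcript_id <- NA_character_
  if (is.null(scores$gene_id)) scores$gene_id <- NA_character_
  if (any(scores$start >= scores$end))
    stop_validation("locus score with end <= start")
  if (any(!is.finite(scores$score)) || any(scores$score < 0))
    stop_validation("scores must be finite and >= 0")
  if (!all(scores$score_type %in% SCORE_TYPES))
    stop_validation("score_type must be one of ",
                    paste(SCORE_TYPES, collapse = ", "))
  fill <- is.na(scores$gene_id) & !is.na(scores$transcript_id)
  if (any(fill)) {
    i <- match(scores$transcript_id[fill], repo$transcripts$transcript_id)
    scores$gene_id[fill] <- repo$transcripts$gene_id[i]
  }
  repo$locus_scores <- rbind(repo$locus_scores, data.frame(
    bioassay_id = bioassay, chrom = scores$chrom,
    start = as.integer(scores$start), end = as.integer(scores$end),
    score = scores$score, score_type = scores$score_type,
    transcript_id = scores$transcript_id, gene_id = scores$gene_id,
    stringsAsFactors = FALSE))
  row.names(repo$locus_scores) <- NULL
  nrow(scores)
}

#' Store fold-change records for a comparison
#'
#' Records normally come from [differential_stats()]. Validation enforces the
#' statistical coherences a Benjamini-Hochberg-adjusted two-group contrast
#' must satisfy: p and FDR in `[0, 1]` with `fdr >= p` (step-up adjustment
#' can only raise a p-value), the CI bracketing the fold change, and
#' `mean_case - mean_control == log2_fc` on the log2 scale.
#'
#' @param repo a repository.
#' @param comparison comparison id.
#' @param records data frame with columns `feature_id`, `log2_fc`,
#'   `t_statistic`, `p_value`, `fdr`, `ci_lower`, `ci_upper`, `sd_case`,
#'   `sd_control`, `mean_case`, `mean_control`.
#' @return Number of rows written.
#' @export
store_fc <- function(repo, comparison, records) {
  if (!(comparison %in% repo$comparisons$id))
    stop_notfound("unknown comparison: ", comparison)
  need <- c("feature_id", "log2_fc", "t_statistic", "p_value", "fdr",
            "ci_lower", "ci_upper", "sd_case", "sd_control", "mean_case",
            "mean_control")
  if (!all(need %in% names(records)))
    stop_validation("fc records need columns: ", paste(need, collapse = ", "))
  dup <- records$feature_id[duplicated(records$feature_id)]
  if (length(dup))
    stop_validation("duplicate feature(s) in batch: ",
                    paste(unique(dup), collapse = ", "))
  if (any(records$p_value < 0 | records$p_value > 1, na.rm = FALSE))
    stop_validation("p_value outside [0, 1]")
  if (any(records$fdr < records$p_value - 1e-12))
    stop_validation("fdr below p_value: BH adjustment cannot lower a p-value")
  if (any(records$fdr > 1 + 1e-12))
    stop_validation("fdr outside [0, 1]")
  if (any(records$ci_lower > records$log2_fc | records$log2_fc > records$ci_upper))
    stop_validation("confidence interval does not bracket log2_fc")
  if (any(records$sd_case < 0 | records$sd_control < 0))
    stop_validation("group SDs must be >= 0")
  if (any(abs(records$mean_case - records$mean_control - records$log2_fc) > 1e-9))
    stop_validation("log2_fc must equal mean_case - mean_control (log2 scale)")
  keep <- !(repo$fc_matrix$comparison_id == comparison &
              repo$fc_matrix$feature_id %in% records$feature_id)
  repo$fc_matrix <- rbind(repo$fc_matrix[keep, , drop = FALSE],
                          cbind(data.frame(comparison_id = comparison,
                                           stringsAsFactors = FALSE),
                                records[, need]))
  row.names(repo$fc_matrix) <- NULL
  nrow(records)
}

#' Build an assay/value-channel selector
#'
#' A selector names exactly one value column of the store: an expression
#' channel of one bioassay, an FPKM or peak channel of one bioassay, or the
#' log2 fold-change channel of one comparison. Used by [fetch_values()] and
#' [scatter_table()].
#'
#' @param channel `"expression"`, `"fpkm"`, `"peak"` or `"log2_fc"`.
#' @param bioassay bioassay id (expression/fpkm/peak channels).
#' @param comparison comparison id (log2_fc channel).
#' @param log2 apply `log2(x + 1)` to the fetched values (useful for FPKM
#'   channels feeding scatter axes).
#' @return An object of class `assay_selector`.
#' @export
assay_selector <- function(channel, bioassay = NULL, comparison = NULL,
                           log2 = FALSE) {
  if (!(channel %in% VALUE_CHANNELS))
    stop_validation("channel must be one of ",
                    paste(VALUE_CHANNELS, collapse = ", "))
  if (channel == "log2_fc") {
    if (is.null(comparison))
      stop_validation("log2_fc channel needs a comparison id")
  } else if (is.null(bioassay)) {
    stop_validation(channel, " channel needs a bioassay id")
  }
  structure(list(channel = channel, bioassay = bioassay,
                 comparison = comparison, log2 = isTRUE(log2)),
            class = "assay_selector")
}

# experiment owning whatever the selector points at
selector_experiment <- function(repo, sel) {
  if (sel$channel == "log2_fc") {
    i <- match(sel$comparison, repo$comparisons$id)
    if (is.na(i)) stop_notfound("unknown comparison: ", sel$comparison)
    repo$comparisons$experiment_id[i]
  } else {
    get_bioassay_row(repo, sel$bioassay)$experiment_id
  }
}

# raw feature->value rows for a selector, before visibility filtering.
# Feature key: probeset (expression), transcript-or-region (fpkm), gene
# (peak), stored feature id (log2_fc).
selector_rows <- function(repo, sel) {
  if (sel$channel == "expression") {
    d <- repo$data_matrix[repo$data_matrix$bioassay_id == sel$bioassay, ,
                          drop = FALSE]
    data.frame(feature = d$probeset_id, value = d$value,
               stringsAsFactors = FALSE)
  } else if (sel$channel %in% c("fpkm", "peak")) {
    types <- if (sel$channel == "fpkm") c("fpkm_window", "fpkm_transcript")
             else "peak"
    d <- repo$locus_scores[repo$locus_scores$bioassay_id == sel$bioassay &
                             repo$locus_scores$score_type %in% types, ,
                           drop = FALSE]
    key <- ifelse(is.na(d$transcript_id),
                  paste0(d$chrom, ":", d$start, "-", d$end), d$transcript_id)
    data.frame(feature = key, value = d$score, stringsAsFactors = FALSE)
  } else {
    d <- repo$fc_matrix[repo$fc_matrix$comparison_id == sel$comparison, ,
                        drop = FALSE]
    data.frame(feature = d$feature_id, value = d$log2_fc,
               stringsAsFactors = FALSE)
  }
}

#' Fetch values for a selector, honoring experiment visibility
#'
#' Values are only returned when the owning experiment's visibility permits
#' data access for the viewer: `public` experiments (or any experiment for
#' the `"owner"` viewer). At `metadata_public` or `private` the result is an
#' empty map, not an error. Requested features without a stored value are
#' absent from the result rather than NA-filled.
#'
#' @param repo a repository.
#' @param selector an [assay_selector()].
#' @param features optional character vector restricting the result.
#' @param viewer `"anonymous"` (default) or `"owner"`.
#' @return Named numeric vector, names = feature ids.
#' @export
fetch_values <- function(repo, selector, features = NULL,
                         viewer = "anonymous") {
  check_viewer(viewer)
  if (!inherits(selector, "assay_selector"))
    stop_validation("selector must be created with assay_selector()")
  exp_id <- selector_experiment(repo, selector)
  vis <- get_experiment_row(repo, exp_id)$visibility
  if (!visible_data(vis, viewer)) return(stats::setNames(numeric(), character()))
  d <- selector_rows(repo, selector)
  if (!is.null(features)) d <- d[d$feature %in% features, , drop = FALSE]
  v <- stats::setNames(d$value, d$feature)
  if (selector$log2) v <- log2(v + 1)
  v
}

# gene-keyed view of a selector's values, for scatter joins. Aggregation to
# gene: max over a gene's peaks (matching the per-gene peak score rule),
# mean over a gene's transcripts/probesets/features otherwise.
fetch_gene_values <- function(repo, sel, viewer = "anonymous") {
  exp_id <- selector_experiment(repo, sel)
  vis <- get_experiment_row(repo, exp_id)$visibility
  hidden <- !visible_data(vis, viewer)

  if (sel$channel == "expression") {
    d <- repo$data_matrix[repo$data_matrix$bioassay_id == sel$bioassay, ,
                          drop = FALSE]
    assay <- get_bioassay_row(repo, sel$bioassay)
    ps <- repo$probesets[repo$probesets$platform == assay$platform, ,
                         drop = FALSE]
    tx_of <- ps$transcript_id[match(d$probeset_id, ps$probeset_id)]
    gene <- repo$transcripts$gene_id[
      match(tx_of, repo$transcripts$transcript_id)]
    d <- data.frame(gene_id = gene, value = d$value, stringsAsFactors = FALSE)
  } else if (sel$channel %in% c("fpkm", "peak")) {
    types <- if (sel$channel == "fpkm") c("fpkm_window", "fpkm_transcript")
             else "peak"
    ls <- repo$locus_scores[repo$locus_scores$bioassay_id == sel$bioassay &
                              repo$locus_scores$score_type %in% types, ,
                            drop = FALSE]
    d <- data.frame(gene_id = ls$gene_id, value = ls$score,
                    stringsAsFactors = FALSE)
  } else {
    fc <- repo$fc_matrix[repo$fc_matrix$comparison_id == sel$comparison, ,
                         drop = FALSE]
    d <- data.frame(gene_id = feature_to_gene(repo, fc$feature_id),
                    value = fc$log2_fc, stringsAsFactors = FALSE)
  }
  d <- d[!is.na(d$gene_id), , drop = FALSE]
  if (nrow(d) == 0L) {
    if (hidden) stop_validation("selector channel is hidden or empty: ",
                                "experiment ", exp_id, " is not public")
    stop_validation("selector channel has no gene-linked values (absent)")
  }
  if (hidden)
    stop_validation("selector channel hidden: experiment ", exp_id,
                    " is not public to this viewer")
  agg_fun <- if (sel$channel == "peak") max else mean
  v <- tapply(d$value, d$gene_id, agg_fun)
  v <- stats::setNames(as.numeric(v), names(v))
  if (sel$log2) v <- log2(v + 1)
  v[order(names(v))]
}

# map stored fc feature ids (probeset or transcript) to gene ids
feature_to_gene <- function(repo, feature_id) {
  g <- repo$transcripts$gene_id[
    match(feature_id, repo$transcripts$transcript_id)]
  miss <- is.na(g)
  if (any(miss)) {
    tx <- repo$probesets$transcript_id[
      match(feature_id[miss], repo$probesets$probeset_id)]
    g[miss] <- repo$transcripts$gene_id[
      match(tx, repo$transcripts$transcript_id)]
  }
  # features that already are gene ids
  miss <- is.na(g)
  g[miss] <- ifelse(feature_id[miss] %in% repo$genes$gene_id,
                    feature_id[miss], NA_character_)
  g
}
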