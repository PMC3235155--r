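# Processing pipeline: expression summarization, two-sample differential
# statistics with BH FDR, windowed and per-transcript FPKM, and promoter
# peak-to-gene assignment.

#' Summarize a probe-level expression matrix to probesets
#'
#' RMA-style processing: log2 transform, quantile normalization across
#' assays, then a median-polish collapse of each probeset's probes (the
#' summarized value per assay is the fitted overall + column effect).
#' Probes absent from the probe map are dropped with a warning.
#'
#' @param probe_level numeric matrix, probes x assays, raw scale (> 0),
#'   with probe row names and assay column names.
#' @param probe_to_probeset named character vector mapping probe id ->
#'   probeset id.
#' @return Numeric matrix, probesets x assays, log2 scale.
#' @export
summarize_expression <- function(probe_level, probe_to_probeset) {
  if (is.null(rownames(probe_level)) || is.null(colnames(probe_level)))
    stop_validation("probe_level needs probe row names and assay column names")
  if (any(probe_level <= 0))
    stop_validation("raw probe values must be > 0 before log2")
  unmapped <- setdiff(rownames(probe_level), names(probe_to_probeset))
  if (length(unmapped)) {
    warning(length(unmapped), " probe(s) absent from probe map, excluded",
            call. = FALSE)
    probe_level <- probe_level[setdiff(rownames(probe_level), unmapped), ,
                               drop = FALSE]
  }
  if (nrow(probe_level) == 0L) stop_validation("no mapped probes left")
  lg <- quantile_normalize(log2(probe_level))
  probeset <- unname(probe_to_probeset[rownames(lg)])
  sets <- unique(probeset)
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(lg),
                dimnames = list(sets, colnames(lg)))
  for (s in sets) {
    block <- lg[probeset == s, , drop = FALSE]
    if (nrow(block) == 1L) {
      out[s, ] <- block[1L, ]
    } else {
      fit <- stats::medpolish(block, trace.iter = FALSE, maxiter = 50L)
      out[s, ] <- fit$overall + fit$col
    }
  }
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: for sorted p-values the adjusted value is
#' `min over j >= i of p_(j) * n / j`, clipped to 1, returned in the input
#' order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop_validation("p-values must lie in [0, 1]")
  n <- length(p_values)
  o <- order(p_values)
  ranked <- p_values[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Per-feature two-sample differential statistics
#'
#' For each feature (row) of a log2 expression matrix, computes the
#' case-minus-control mean difference (`log2_fc`), a pooled-variance
#' Student t statistic with `n_case + n_control - 2` degrees of freedom,
#' its two-sided p-value, the Benjamini-Hochberg FDR across all features
#' jointly, the confidence interval on the mean difference at `ci_level`,
#' and the group means and SDs. When both groups have zero variance the
#' statistic degenerates: equal means give `t = 0, p = 1`, unequal means
#' give an infinite t and `p = 0`.
#'
#' @param expr numeric matrix, features x assays, log2 scale, with feature
#'   row names and assay column names.
#' @param case,control column names of the case and control assays
#'   (at least 2 each).
#' @param ci_level confidence level for the interval (default 0.95).
#' @return Data frame with one row per feature: `feature_id`, `log2_fc`,
#'   `t_statistic`, `p_value`, `fdr`, `ci_lower`, `ci_upper`, `sd_case`,
#'   `sd_control`, `mean_case`, `mean_control`; attributes `n_case`,
#'   `n_control`, `ci_level`.
#' @export
differential_stats <- function(expr, case, control, ci_level = 0.95) {
  if (length(case) < 2L || length(control) < 2L)
    stop_validation("need >= 2 case and >= 2 control assays ",
                    "(variance undefined otherwise)")
  missing_cols <- setdiff(c(case, control), colnames(expr))
  if (length(missing_cols))
    stop_validation("assays absent from expression matrix: ",
                    paste(missing_cols, collapse = ", "))
  if (!(ci_level > 0 && ci_level < 1))
    stop_validation("ci_level must be in (0, 1)")
  x <- expr[, case, drop = FALSE]
  y <- expr[, control, drop = FALSE]
  n1 <- length(case); n2 <- length(control)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, stats::var); v2 <- apply(y, 1L, stats::var)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t_stat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df),
              0)
  p[se == 0 & diff == 0] <- 1
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df)
  out <- data.frame(
    feature_id = rownames(expr), log2_fc = diff, t_statistic = t_stat,
    p_value = p, fdr = bh_fdr(p), ci_lower = diff - tcrit * se,
    ci_upper = diff + tcrit * se, sd_case = sqrt(v1), sd_control = sqrt(v2),
    mean_case = m1, mean_control = m2, stringsAsFactors = FALSE)
  row.names(out) <- NULL
  attr(out, "n_case") <- n1
  attr(out, "n_control") <- n2
  attr(out, "ci_level") <- ci_level
  out
}

#' Run the differential pipeline for a stored comparison
#'
#' Pulls the expression rows of the comparison's assays from the data
#' matrix, computes [differential_stats()] over the probesets common to all
#' assays, and stores the resulting fold-change records.
#'
#' @param repo a repository.
#' @param comparison comparison id.
#' @param ci_level confidence level (default 0.95).
#' @return The differential result data frame, invisibly (records are
#'   stored in the fc matrix).
#' @export
run_differential <- function(repo, comparison, ci_level = 0.95) {
  case <- comparison_assays(repo, comparison, "case")
  control <- comparison_assays(repo, comparison, "control")
  assays <- c(case, control)
  d <- repo$data_matrix[repo$data_matrix$bioassay_id %in% assays, ,
                        drop = FALSE]
  if (nrow(d) == 0L) stop_validation("no expression data for comparison ",
                                     comparison)
  counts <- table(d$probeset_id)
  common <- names(counts)[counts == length(assays)]
  if (!length(common))
    stop_validation("no probeset measured in every assay of ", comparison)
  expr <- matrix(NA_real_, nrow = length(common), ncol = length(assays),
                 dimnames = list(common, assays))
  for (a in assays) {
    da <- d[d$bioassay_id == a, , drop = FALSE]
    expr[, a] <- da$value[match(common, da$probeset_id)]
  }
  res <- differential_stats(expr, case, control, ci_level)
  store_fc(repo, comparison, res)
  invisible(res)
}

# alignment/window geometry helpers -------------------------------------------

# midpoint of half-open interval [start, end)
interval_midpoint <- function(start, end) floor((start + end) / 2)

# count alignment midpoints falling in each half-open window (same chrom
# handled by caller); windows may overlap
count_midpoints_in_windows <- function(win_start, win_end, midpoints) {
  if (length(win_start) == 0L) return(integer())
  if (length(midpoints) == 0L) return(integer(length(win_start)))
  w <- IRanges::IRanges(start = win_start + 1L, end = win_end)
  m <- IRanges::IRanges(start = midpoints + 1L, width = 1L)
  IRanges::countOverlaps(w, m)
}

check_alignments <- function(alignments) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(alignments)))
    stop_validation("alignments need columns chrom, start, end")
  if (any(alignments$start >= alignments$end))
    stop_validation("alignment with start >= end")
  if (nrow(alignments) == 0L)
    stop_validation("zero total alignments: FPKM undefined")
  alignments
}

#' Windowed FPKM around transcription start sites
#'
#' For every transcript, counts the alignments whose midpoint falls in the
#' strand-oriented window from `upstream_bp` upstream to `downstream_bp`
#' downstream of the TSS, and converts to FPKM:
#' `count / (window_kb * total_alignments_millions)`. This is the promoter
#' histone-modification score (e.g. H3K4me3/H3K27me3 at TSS +/- 1 kb).
#'
#' @param alignments data frame of aligned fragments: `chrom`, `start`,
#'   `end` (0-based half-open). Every row counts once.
#' @param transcripts transcript table rows (as loaded by
#'   [load_annotation()]).
#' @param upstream_bp,downstream_bp window extent around the TSS, in bp.
#' @return Locus-score data frame (`chrom`, `start`, `end`, `score`,
#'   `score_type = "fpkm_window"`, `transcript_id`, `gene_id`), one row per
#'   transcript.
#' @export
window_fpkm <- function(alignments, transcripts, upstream_bp = 1000L,
                        downstream_bp = 1000L) {
  check_alignments(alignments)
  win_len <- upstream_bp + downstream_bp
  if (win_len <= 0) stop_validation("window of zero length")
  total <- nrow(alignments)
  win <- tss_window(transcripts, upstream_bp, downstream_bp)
  counts <- integer(nrow(win))
  for (ch in unique(win$chrom)) {
    wi <- which(win$chrom == ch)
    al <- alignments[alignments$chrom == ch, , drop = FALSE]
    counts[wi] <- count_midpoints_in_windows(
      win$start[wi], win$end[wi],
      interval_midpoint(al$start, al$end))
  }
  data.frame(chrom = win$chrom, start = win$start, end = win$end,
             score = counts / ((win_len / 1000) * (total / 1e6)),
             score_type = "fpkm_window", transcript_id = win$transcript_id,
             gene_id = win$gene_id, stringsAsFactors = FALSE)
}

#' Per-transcript FPKM over exon models
#'
#' Counts alignments whose midpoint falls in any exon of the transcript and
#' divides by `summed_exon_kb * total_millions`. A midpoint inside exons of
#' several transcripts counts for each of them.
#'
#' @param alignments data frame of aligned fragments (`chrom`, `start`,
#'   `end`).
#' @param transcripts transcript table rows with non-empty exon models.
#' @return Locus-score data frame with `score_type = "fpkm_transcript"`,
#'   one row per transcript spanning `[tx_start, tx_end)`.
#' @export
transcript_fpkm <- function(alignments, transcripts) {
  check_alignments(alignments)
  total <- nrow(alignments)
  n <- nrow(transcripts)
  counts <- integer(n)
  exlen <- numeric(n)
  for (i in seq_len(n)) {
    es <- parse_int_list(transcripts$exon_starts[i])
    ee <- parse_int_list(transcripts$exon_ends[i])
    if (length(es) == 0L)
      stop_validation("transcript with empty exon list: ",
                      transcripts$transcript_id[i])
    exlen[i] <- sum(ee - es)
    al <- alignments[alignments$chrom == transcripts$chrom[i], , drop = FALSE]
    if (nrow(al)) {
      m <- interval_midpoint(al$start, al$end)
      counts[i] <- sum(vapply(m, function(x) any(x >= es & x < ee), TRUE))
    }
  }
  data.frame(chrom = transcripts$chrom, start = transcripts$tx_start,
             end = transcripts$tx_end,
             score = counts / ((exlen / 1000) * (total / 1e6)),
             score_type = "fpkm_transcript",
             transcript_id = transcripts$transcript_id,
             gene_id = transcripts$gene_id, stringsAsFactors = FALSE)
}

#' Assign peaks to transcripts by promoter containment or nearest TSS
#'
#' Each peak is anchored at its summit (when present) or midpoint. If the
#' anchor lies inside one or more strand-oriented promoter windows
#' (TSS - `promoter_upstream` to TSS + `promoter_downstream` in transcript
#' orientation), the peak is assigned to the contained transcript whose TSS
#' is nearest the anchor; otherwise to the transcript with the nearest TSS
#' on that chromosome. Distance ties break on the lexicographically
#' smallest transcript id, so assignment is deterministic under any input
#' order. Peaks on chromosomes without transcripts are reported in the
#' `unassigned` attribute, not an error.
#'
#' @param peaks data frame: `chrom`, `start`, `end`, `score`, optional
#'   `summit` (absolute coordinate).
#' @param transcripts transcript table rows.
#' @param promoter_upstream,promoter_downstream promoter window extent in bp.
#' @return Locus-score data frame (`score_type = "peak"`), one row per
#'   assigned peak, sorted by (chrom, start, end, transcript); attribute
#'   `unassigned` holds the unassignable peak rows.
#' @export
assign_peaks <- function(peaks, transcripts, promoter_upstream = 1000L,
                         promoter_downstream = 1000L) {
  need <- c("chrom", "start", "end", "score")
  if (!all(need %in% names(peaks)))
    stop_validation("peaks need columns: ", paste(need, collapse = ", "))
  if (nrow(peaks) && any(peaks$start >= peaks$end))
    stop_validation("peak with start >= end")
  if (is.null(peaks$summit)) peaks$summit <- NA_integer_
  bad_summit <- !is.na(peaks$summit) &
    (peaks$summit < peaks$start | peaks$summit >= peaks$end)
  if (any(bad_summit))
    stop_validation("peak summit outside [start, end)")
  anchor <- ifelse(is.na(peaks$summit),
                   interval_midpoint(peaks$start, peaks$end), peaks$summit)
  win <- tss_window(transcripts, promoter_upstream, promoter_downstream)

  assigned_tx <- rep(NA_character_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    wi <- which(win$chrom == ch)
    if (!length(wi)) next
    for (p in pi) {
      a <- anchor[p]
      inside <- wi[a >= win$start[wi] & a < win$end[wi]]
      cand <- if (length(inside)) inside else wi
      dist <- abs(win$tss[cand] - a)
      best <- cand[order(dist, win$transcript_id[cand])][1L]
      assigned_tx[p] <- win$transcript_id[best]
    }
  }
  ok <- !is.na(assigned_tx)
  i <- match(assigned_tx[ok], win$transcript_id)
  out <- data.frame(chrom = peaks$chrom[ok], start = as.integer(peaks$start[ok]),
                    end = as.integer(peaks$end[ok]), score = peaks$score[ok],
                    score_type = rep("peak", sum(ok)),
                    transcript_id = assigned_tx[ok],
                    gene_id = win$gene_id[i], stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$transcript_id,
                   out$score), , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "unassigned") <- peaks[!ok, , drop = FALSE]
  out
}

#' Per-gene peak score: the maximum over a gene's assigned peaks
#'
#' @param assigned output of [assign_peaks()].
#' @return Named numeric vector, names = gene ids.
#' @export
peak_gene_scores <- function(assigned) {
  if (nrow(assigned) == 0L) return(stats::setNames(numeric(), character()))
  v <- tapply(assigned$score, assigned$gene_id, max)
  v <- stats::setNames(as.numeric(v), names(v))
  v[order(names(v))]
}
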