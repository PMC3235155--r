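# GCT 1.2: '#1.2' version line, '<rows>\t<cols>' dims line, then a
# Name/Description/<assays...> table of expression values.

#' Export an experiment's expression matrix as GCT 1.2 text
#'
#' One row per probeset with stored values, one column per bioassay with
#' expression data; `Description` carries the probeset's gene symbol (via
#' its transcript) or `NA` when unannotated. Values print at full
#' precision. Probesets missing from some assays are reported as `NA`.
#'
#' @param repo a repository.
#' @param experiment experiment id; expression must be visible to the
#'   viewer.
#' @param viewer `"anonymous"` or `"owner"`.
#' @return Character vector of GCT lines.
#' @export
write_gct <- function(repo, experiment, viewer = "anonymous") {
  check_viewer(viewer)
  vis <- get_experiment_row(repo, experiment)$visibility
  if (!visible_data(vis, viewer))
    stop_validation("experiment ", experiment,
                    " expression not visible at this viewer level")
  assays <- repo$bioassays$id[repo$bioassays$experiment_id == experiment]
  d <- repo$data_matrix[repo$data_matrix$bioassay_id %in% assays, ,
                        drop = FALSE]
  if (nrow(d) == 0L)
    stop_validation("experiment ", experiment, " has no expression data")
  assays <- intersect(assays, unique(d$bioassay_id))
  probesets <- sort(unique(d$probeset_id))

  tx <- repo$probesets$transcript_id[
    match(probesets, repo$probesets$probeset_id)]
  gene <- repo$transcripts$gene_id[match(tx, repo$transcripts$transcript_id)]
  symbol <- repo$genes$symbol[match(gene, repo$genes$gene_id)]
  symbol[is.na(symbol)] <- "NA"

  m <- matrix(NA_real_, nrow = length(probesets), ncol = length(assays),
              dimnames = list(probesets, assays))
  for (a in assays) {
    da <- d[d$bioassay_id == a, , drop = FALSE]
    m[match(da$probeset_id, probesets), a] <- da$value
  }
  body <- vapply(seq_along(probesets), function(i) {
    paste(c(probesets[i], symbol[i], format_value(m[i, ])), collapse = "\t")
  }, "")
  c("#1.2",
    paste(length(probesets), length(assays), sep = "\t"),
    paste(c("Name", "Description", assays), collapse = "\t"),
    body)
}

#' Read a GCT 1.2 file
#'
#' @param path file path, or a character vector of GCT lines.
#' @return List with `matrix` (features x samples), `description` (named by
#'   feature).
#' @export
read_gct <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else path
  if (length(lines) < 3L || trimws(lines[1]) != "#1.2")
    stop_validation("not a GCT 1.2 file")
  dims <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != dims[2] + 2L)
    stop_validation("GCT header width disagrees with dims line")
  body <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  if (length(body) != dims[1])
    stop_validation("GCT row count ", length(body),
                    " disagrees with dims line ", dims[1])
  m <- matrix(NA_real_, nrow = dims[1], ncol = dims[2],
              dimnames = list(vapply(body, `[`, "", 1), header[-(1:2)]))
  for (i in seq_along(body)) {
    if (length(body[[i]]) != dims[2] + 2L)
      stop_validation("GCT data row ", i, " has wrong width")
    m[i, ] <- suppressWarnings(as.numeric(body[[i]][-(1:2)]))
  }
  list(matrix = m,
       description = stats::setNames(vapply(body, `[`, "", 2), rownames(m)))
}
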