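# BED input: 3+ tab-separated columns, 0-based half-open coordinates,
# optional strand (column 6), optional user-flagged score and summit columns.

#' Read a BED file of alignments or peaks
#'
#' Minimum three columns (`chrom`, `start`, `end`); strand is taken from
#' column 6 when present. `score_col` / `summit_col` flag 1-based column
#' indices carrying a peak score and an absolute summit coordinate.
#' Malformed coordinates raise a parse error naming the line.
#'
#' @param path BED file path.
#' @param score_col optional 1-based column index of the score.
#' @param summit_col optional 1-based column index of the summit
#'   (absolute coordinate in `[start, end)`).
#' @return Data frame: `chrom`, `start`, `end`, `strand`, plus `score` /
#'   `summit` when flagged.
#' @export
read_bed <- function(path, score_col = NULL, summit_col = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L))
    stop_validation("fewer than 3 columns at line ", idx[which(n < 3L)[1]])
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop_validation("non-numeric coordinate at line ", idx[bad[1]])
  bad <- which(start >= end)
  if (length(bad))
    stop_validation("start >= end at line ", idx[bad[1]])
  out <- data.frame(chrom = chrom, start = start, end = end,
                    strand = NA_character_, stringsAsFactors = FALSE)
  has6 <- n >= 6L
  out$strand[has6] <- vapply(fields[has6], `[`, "", 6L)
  out$strand[!(out$strand %in% c("+", "-"))] <- NA_character_
  grab_col <- function(col, what) {
    if (any(n < col))
      stop_validation(what, " column ", col, " missing at line ",
                      idx[which(n < col)[1]])
    v <- suppressWarnings(as.numeric(vapply(fields, `[`, "", col)))
    if (anyNA(v))
      stop_validation("non-numeric ", what, " at line ", idx[which(is.na(v))[1]])
    v
  }
  if (!is.null(score_col)) {
    out$score <- grab_col(score_col, "score")
    if (any(out$score < 0)) stop_validation("negative score in BED file")
  }
  if (!is.null(summit_col)) {
    out$summit <- as.integer(grab_col(summit_col, "summit"))
    bad <- which(out$summit < out$start | out$summit >= out$end)
    if (length(bad))
      stop_validation("summit outside [start, end) at line ", idx[bad[1]])
  }
  if (nrow(out) == 0L) stop_validation("empty BED file: ", path)
  out
}

#' Write intervals as BED text
#'
#' @param x data frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(x$name) || !is.null(x$score) || !is.null(x$strand)) {
    cols <- c(cols, list(if (is.null(x$name)) "." else x$name,
                         if (is.null(x$score)) 0 else x$score,
                         if (is.null(x$strand)) "." else x$strand))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}
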