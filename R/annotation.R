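# Genome annotation: genes, transcripts, probesets, platforms and ortholog
# groups, with case-insensitive symbol/alias resolution and cross-species
# expansion via HomoloGene-style group ids.
#
# Coordinates are 0-based half-open (BED convention) throughout.

#' Load gene and transcript annotation tables
#'
#' Gene table columns: `gene_id`, `symbol`, `aliases` (pipe-separated),
#' `organism`, `homolog_group_id` (may be empty). Transcript table columns:
#' `transcript_id`, `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`,
#' `exon_starts`, `exon_ends` (comma-separated, half-open). All coordinates
#' 0-based half-open.
#'
#' @param repo a repository.
#' @param gene_table,transcript_table TSV paths.
#' @return Named integer vector `c(genes =, transcripts =)` of loaded counts.
#' @export
load_annotation <- function(repo, gene_table, transcript_table) {
  genes <- utils::read.table(gene_table, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "\"",
                             colClasses = "character",
                             fileEncoding = "UTF-8")
  need <- c("gene_id", "symbol", "aliases", "organism", "homolog_group_id")
  if (!all(need %in% names(genes)))
    stop_validation("gene table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop_validation("duplicate gene_id in gene table: ",
                    paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                          collapse = ", "))

  tx_raw <- utils::read.table(transcript_table, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, quote = "\"",
                              colClasses = "character",
                              fileEncoding = "UTF-8")
  needt <- c("transcript_id", "gene_id", "chrom", "strand", "tx_start",
             "tx_end", "exon_starts", "exon_ends")
  if (!all(needt %in% names(tx_raw)))
    stop_validation("transcript table must have columns: ",
                    paste(needt, collapse = ", "))

  tx_start <- suppressWarnings(as.integer(tx_raw$tx_start))
  tx_end <- suppressWarnings(as.integer(tx_raw$tx_end))
  bad <- which(is.na(tx_start) | is.na(tx_end))
  if (length(bad))
    stop_validation("malformed transcript coordinates at line ",
                    bad[1] + 1L, " of ", transcript_table)
  bad <- which(tx_start >= tx_end)
  if (length(bad))
    stop_validation("tx_start >= tx_end at line ", bad[1] + 1L, " of ",
                    transcript_table, " (transcript ",
                    tx_raw$transcript_id[bad[1]], ")")
  if (!all(tx_raw$strand %in% c("+", "-")))
    stop_validation("transcript strand must be '+' or '-'")
  orphan <- setdiff(tx_raw$gene_id, genes$gene_id)
  if (length(orphan)) {
    offenders <- tx_raw$transcript_id[tx_raw$gene_id %in% orphan]
    stop_validation("transcripts reference missing genes: ",
                    paste(offenders, collapse = ", "))
  }
  # exon sanity: within [tx_start, tx_end), starts < ends
  for (i in seq_len(nrow(tx_raw))) {
    es <- parse_int_list(tx_raw$exon_starts[i])
    ee <- parse_int_list(tx_raw$exon_ends[i])
    if (length(es) != length(ee))
      stop_validation("exon_starts/exon_ends length mismatch for transcript ",
                      tx_raw$transcript_id[i])
    if (length(es) && (any(es >= ee) || any(es < tx_start[i]) ||
                       any(ee > tx_end[i])))
      stop_validation("exons outside transcript bounds for ",
                      tx_raw$transcript_id[i])
  }

  tx <- data.frame(transcript_id = tx_raw$transcript_id,
                   gene_id = tx_raw$gene_id, chrom = tx_raw$chrom,
                   strand = tx_raw$strand, tx_start = tx_start,
                   tx_end = tx_end, exon_starts = tx_raw$exon_starts,
                   exon_ends = tx_raw$exon_ends, stringsAsFactors = FALSE)
  genes$homolog_group_id[!nzchar(genes$homolog_group_id)] <- NA_character_
  repo$genes <- rbind(repo$genes, genes[, need])
  if (anyDuplicated(repo$genes$gene_id))
    stop_validation("gene ids collide with previously loaded annotation")
  repo$transcripts <- rbind(repo$transcripts, tx)
  c(genes = nrow(genes), transcripts = nrow(tx))
}

parse_int_list <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer())
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Register a microarray platform's probeset-to-transcript map
#'
#' @param repo a repository.
#' @param platform platform label; probeset ids are unique per platform.
#' @param probe_map TSV with columns `probeset_id`, `transcript_id`
#'   (`transcript_id` may be empty for unmapped probesets).
#' @return Number of probesets registered; the unmapped count is reported as
#'   a warning.
#' @export
register_platform <- function(repo, platform, probe_map) {
  tab <- utils::read.table(probe_map, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("probeset_id", "transcript_id") %in% names(tab)))
    stop_validation("probe map must have columns probeset_id, transcript_id")
  tab$transcript_id[!nzchar(tab$transcript_id)] <- NA_character_
  existing <- repo$probesets$probeset_id[repo$probesets$platform == platform]
  dups <- c(existing[existing %in% tab$probeset_id],
            tab$probeset_id[duplicated(tab$probeset_id)])
  if (length(dups))
    stop_validation("duplicate probesets on platform ", platform, ": ",
                    paste(unique(dups), collapse = ", "))
  repo$probesets <- rbind(repo$probesets, data.frame(
    probeset_id = tab$probeset_id, platform = platform,
    transcript_id = tab$transcript_id, stringsAsFactors = FALSE))
  n_unmapped <- sum(is.na(tab$transcript_id))
  if (n_unmapped > 0)
    warning(n_unmapped, " probeset(s) on platform ", platform,
            " have no transcript mapping", call. = FALSE)
  nrow(tab)
}

#' Load HomoloGene-style ortholog groups
#'
#' @param repo a repository.
#' @param homolog_table TSV with columns `homolog_group_id`, `gene_id`.
#'   Each gene may belong to at most one group.
#' @return Number of groups indexed.
#' @export
build_ortholog_index <- function(repo, homolog_table) {
  tab <- utils::read.table(homolog_table, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("homolog_group_id", "gene_id") %in% names(tab)))
    stop_validation("homolog table must have columns homolog_group_id, gene_id")
  tab <- unique(tab[, c("homolog_group_id", "gene_id")])
  multi <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(multi))
    stop_validation("gene(s) listed in more than one ortholog group: ",
                    paste(unique(multi), collapse = ", "))
  repo$homologs <- tab
  i <- match(repo$genes$gene_id, tab$gene_id)
  repo$genes$homolog_group_id <- tab$homolog_group_id[i]
  length(unique(tab$homolog_group_id))
}

# long-format (gene row index, lowercased name) lookup over symbols + aliases
symbol_lookup_table <- function(repo) {
  g <- repo$genes
  names_per_gene <- lapply(seq_len(nrow(g)), function(i) {
    al <- strsplit(g$aliases[i], "|", fixed = TRUE)[[1]]
    unique(tolower(c(g$symbol[i], al[nzchar(al)])))
  })
  data.frame(row = rep(seq_len(nrow(g)), lengths(names_per_gene)),
             name = unlist(names_per_gene), stringsAsFactors = FALSE)
}

#' Resolve a gene symbol or alias, optionally expanding to orthologs
#'
#' Matching is case-insensitive over canonical symbols and aliases. With
#' `expand_orthologs = TRUE` the result is the union of all genes sharing a
#' homolog group with any directly matched gene, so a human symbol retrieves
#' its mouse and zebrafish counterparts. Results are ordered by organism,
#' then symbol; the string each gene matched through is recorded in
#' `matched_via` (ortholog-expanded genes carry the group id).
#'
#' @param repo a repository.
#' @param query symbol or alias; case-insensitive.
#' @param expand_orthologs expand hits across homolog groups.
#' @return Data frame of genes (possibly empty): `gene_id`, `symbol`,
#'   `organism`, `homolog_group_id`, `matched_via`.
#' @export
resolve_symbol <- function(repo, query, expand_orthologs = TRUE) {
  assert_scalar_chr(query, "query")
  g <- repo$genes
  empty <- data.frame(gene_id = character(), symbol = character(),
                      organism = character(), homolog_group_id = character(),
                      matched_via = character(), stringsAsFactors = FALSE)
  if (nrow(g) == 0L) return(empty)
  lut <- symbol_lookup_table(repo)
  direct <- unique(lut$row[lut$name == tolower(query)])
  if (!length(direct)) return(empty)
  via <- stats::setNames(rep(query, length(direct)), g$gene_id[direct])
  rows <- direct
  if (expand_orthologs) {
    grp <- stats::na.omit(unique(g$homolog_group_id[direct]))
    if (length(grp)) {
      extra <- which(g$homolog_group_id %in% grp)
      extra <- setdiff(extra, direct)
      via <- c(via, stats::setNames(g$homolog_group_id[extra],
                                    g$gene_id[extra]))
      rows <- c(rows, extra)
    }
  }
  out <- g[rows, c("gene_id", "symbol", "organism", "homolog_group_id")]
  out$matched_via <- unname(via[out$gene_id])
  out <- out[order(out$organism, out$symbol, out$gene_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}

# transcription start site coordinate: 5' end of the transcript
transcript_tss <- function(tx) {
  ifelse(tx$strand == "+", tx$tx_start, tx$tx_end)
}

# strand-oriented window around the TSS, half-open. "upstream" is 5' of the
# TSS in transcript orientation.
tss_window <- function(tx, upstream, downstream) {
  tss <- transcript_tss(tx)
  start <- ifelse(tx$strand == "+", tss - upstream, tss - downstream)
  end <- ifelse(tx$strand == "+", tss + downstream, tss + upstream)
  data.frame(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
             chrom = tx$chrom, start = as.integer(start),
             end = as.integer(end), tss = as.integer(tss),
             stringsAsFactors = FALSE)
}

#' Transcripts overlapping a genomic interval
#'
#' Interval lookups run through an IRanges overlap index per chromosome.
#'
#' @param repo a repository.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open query interval.
#' @return The overlapping rows of the transcript table.
#' @export
transcripts_in_range <- function(repo, chrom, start, end) {
  tx <- repo$transcripts
  onchr <- tx[tx$chrom == chrom, , drop = FALSE]
  if (nrow(onchr) == 0L) return(onchr)
  # half-open to IRanges closed: [start, end) -> [start+1, end]
  subject <- IRanges::IRanges(start = onchr$tx_start + 1L, end = onchr$tx_end)
  q <- IRanges::IRanges(start = start + 1L, end = end)
  hits <- IRanges::findOverlaps(q, subject)
  out <- onchr[sort(unique(S4Vectors::subjectHits(hits))), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Entity counts of the loaded annotation
#' @param repo a repository.
#' @return Named integer vector.
#' @export
annotation_counts <- function(repo) {
  c(genes = nrow(repo$genes), transcripts = nrow(repo$transcripts),
    probesets = nrow(repo$probesets),
    ortholog_groups = length(unique(stats::na.omit(repo$homologs$homolog_group_id))))
}
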