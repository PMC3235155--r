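# Repository object: an environment holding the relational-style tables of a
# genomics-experiment store, mutated in place by the API functions.

#' Create an empty experiment repository
#'
#' A repository bundles every table the toolkit operates on: experiment
#' metadata (experiments, bioassays, biomaterials, comparison groups),
#' controlled vocabularies, genome annotation (genes, transcripts, probesets,
#' ortholog groups), and the three genomic data tables (expression matrix
#' rows, locus scores, fold-change records). It is an environment, so API
#' functions update it in place; use [repo_save()] / [repo_open()] to persist
#' it as a directory of plain-text TSV tables.
#'
#' @param seed_vocabularies logical; seed the controlled vocabularies with the
#'   default organism/tissue/cell-type/stage/disease/treatment term lists.
#' @return An object of class `generepo` (an environment).
#' @export
#' @examples
#' repo <- repo_create()
#' exp <- create_experiment(repo, "Leukemia expression", "A. Researcher")
#' exp$visibility
repo_create <- function(seed_vocabularies = TRUE) {
  repo <- new.env(parent = emptyenv())

  repo$vocab <- data.frame(vocabulary = character(), term = character(),
                           term_id = character(), stringsAsFactors = FALSE)

  repo$experiments <- data.frame(
    id = character(), title = character(), researcher = character(),
    design = character(), publications = character(),
    visibility = character(), stringsAsFactors = FALSE)

  repo$biomaterials <- data.frame(
    id = character(), organism = character(), development_stage = character(),
    tissue = character(), cell_type = character(), treatment = character(),
    disease_state = character(), age = numeric(), age_unit = character(),
    sex = character(), notes = character(), stringsAsFactors = FALSE)

  repo$biomaterial_markers <- data.frame(
    biomaterial_id = character(), marker = character(),
    polarity = character(), stringsAsFactors = FALSE)

  repo$biomaterial_genmods <- data.frame(
    biomaterial_id = character(), gene = character(),
    description = character(), stringsAsFactors = FALSE)

  repo$bioassays <- data.frame(
    id = character(), experiment_id = character(),
    biomaterial_id = character(), measurement_type = character(),
    technology = character(), platform = character(),
    raw_file_ref = character(), stringsAsFactors = FALSE)

  repo$comparisons <- data.frame(
    id = character(), experiment_id = character(), label = character(),
    stringsAsFactors = FALSE)

  repo$comparison_members <- data.frame(
    comparison_id = character(), bioassay_id = character(),
    role = character(), ord = integer(), stringsAsFactors = FALSE)

  # extensible registries (measurement types / technologies)
  repo$measurement_types <- c("gene_expression", "histone_modification",
                              "transcription_factor_binding", "rna_seq")
  repo$technologies <- c("microarray", "sequencing")

  # annotation tables
  repo$genes <- data.frame(
    gene_id = character(), symbol = character(), aliases = character(),
    organism = character(), homolog_group_id = character(),
    stringsAsFactors = FALSE)
  repo$transcripts <- data.frame(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), tx_start = integer(), tx_end = integer(),
    exon_starts = character(), exon_ends = character(),
    stringsAsFactors = FALSE)
  repo$probesets <- data.frame(
    probeset_id = character(), platform = character(),
    transcript_id = character(), stringsAsFactors = FALSE)
  repo$homologs <- data.frame(
    homolog_group_id = character(), gene_id = character(),
    stringsAsFactors = FALSE)

  # genomic data tables
  repo$data_matrix <- data.frame(
    bioassay_id = character(), probeset_id = character(), value = numeric(),
    stringsAsFactors = FALSE)
  repo$locus_scores <- data.frame(
    bioassay_id = character(), chrom = character(), start = integer(),
    end = integer(), score = numeric(), score_type = character(),
    transcript_id = character(), gene_id = character(),
    stringsAsFactors = FALSE)
  repo$fc_matrix <- data.frame(
    comparison_id = character(), feature_id = character(), log2_fc = numeric(),
    t_statistic = numeric(), p_value = numeric(), fdr = numeric(),
    ci_lower = numeric(), ci_upper = numeric(), sd_case = numeric(),
    sd_control = numeric(), mean_case = numeric(), mean_control = numeric(),
    stringsAsFactors = FALSE)

  repo$counters <- c(EXP = 0L, ASY = 0L, BIO = 0L, CMP = 0L)
  class(repo) <- "generepo"

  if (seed_vocabularies) seed_default_vocabularies(repo)
  repo
}

#' @export
print.generepo <- function(x, ...) {
  cat("<generepo repository>\n")
  cat(sprintf("  experiments: %d | bioassays: %d | biomaterials: %d | comparisons: %d\n",
              nrow(x$experiments), nrow(x$bioassays), nrow(x$biomaterials),
              nrow(x$comparisons)))
  cat(sprintf("  genes: %d | transcripts: %d | probesets: %d | ortholog groups: %d\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$probesets),
              length(unique(x$homologs$homolog_group_id))))
  cat(sprintf("  expression rows: %d | locus scores: %d | fc records: %d\n",
              nrow(x$data_matrix), nrow(x$locus_scores), nrow(x$fc_matrix)))
  invisible(x)
}

# next accession of a given prefix, zero-padded and sequential
next_accession <- function(repo, prefix) {
  repo$counters[prefix] <- repo$counters[prefix] + 1L
  sprintf("%s-%04d", prefix, repo$counters[prefix])
}

repo_tables <- function() {
  c("vocab", "experiments", "biomaterials", "biomaterial_markers",
    "biomaterial_genmods", "bioassays", "comparisons", "comparison_members",
    "genes", "transcripts", "probesets", "homologs",
    "data_matrix", "locus_scores", "fc_matrix")
}

#' Save a repository to a directory of TSV tables
#'
#' Every table is written as a UTF-8 tab-separated file; registries and
#' accession counters go to a small key-value file. The directory can be
#' reopened with [repo_open()].
#'
#' @param repo a repository.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
repo_save <- function(repo, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in repo_tables()) {
    utils::write.table(repo[[tab]], file.path(dir, paste0(tab, ".tsv")),
                       sep = "\t", quote = TRUE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  meta <- c(
    paste0("measurement_types\t", paste(repo$measurement_types, collapse = ",")),
    paste0("technologies\t", paste(repo$technologies, collapse = ",")),
    paste0("counters\t", paste(sprintf("%s=%d", names(repo$counters),
                                       repo$counters), collapse = ",")))
  writeLines(meta, file.path(dir, "repository.meta"))
  invisible(dir)
}

#' Open a repository saved with [repo_save()]
#'
#' @param dir directory previously written by [repo_save()].
#' @return A repository.
#' @export
repo_open <- function(dir) {
  if (!file.exists(file.path(dir, "repository.meta")))
    stop("not a repository directory: ", dir, call. = FALSE)
  repo <- repo_create(seed_vocabularies = FALSE)
  for (tab in repo_tables()) {
    f <- file.path(dir, paste0(tab, ".tsv"))
    template <- repo[[tab]]
    got <- utils::read.table(f, sep = "\t", header = TRUE,
                             colClasses = vapply(template, class, ""),
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    repo[[tab]] <- got
  }
  meta <- strsplit(readLines(file.path(dir, "repository.meta")), "\t",
                   fixed = TRUE)
  kv <- stats::setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  repo$measurement_types <- strsplit(kv[["measurement_types"]], ",")[[1]]
  repo$technologies <- strsplit(kv[["technologies"]], ",")[[1]]
  pairs <- strsplit(strsplit(kv[["counters"]], ",")[[1]], "=", fixed = TRUE)
  repo$counters <- stats::setNames(
    as.integer(vapply(pairs, `[`, "", 2)), vapply(pairs, `[`, "", 1))
  repo
}

# shared validation helpers ---------------------------------------------------

stop_validation <- function(...) {
  msg <- paste0(...)
  cond <- structure(class = c("generepo_validation_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

stop_notfound <- function(...) {
  msg <- paste0(...)
  cond <- structure(class = c("generepo_notfound_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

assert_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop_validation(what, " must be a single string")
  x
}

get_experiment_row <- function(repo, experiment) {
  i <- match(experiment, repo$experiments$id)
  if (is.na(i)) stop_notfound("unknown experiment: ", experiment)
  repo$experiments[i, , drop = FALSE]
}

get_bioassay_row <- function(repo, bioassay) {
  i <- match(bioassay, repo$bioassays$id)
  if (is.na(i)) stop_notfound("unknown bioassay: ", bioassay)
  repo$bioassays[i, , drop = FALSE]
}
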