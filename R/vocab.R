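# Controlled vocabularies: flat (vocabulary, term, term_id) table on the
# repository; every vocabulary-typed biomaterial field is validated against it.

#' Add a term to a controlled vocabulary
#'
#' @param repo a repository.
#' @param vocabulary vocabulary name, e.g. `"organism"`, `"cell_type"`.
#' @param term the term itself; must be non-empty and unique within the
#'   vocabulary.
#' @param term_id optional external ontology identifier.
#' @return The term, invisibly.
#' @export
vocab_add <- function(repo, vocabulary, term, term_id = NA_character_) {
  assert_scalar_chr(vocabulary, "vocabulary")
  assert_scalar_chr(term, "term")
  if (!nzchar(term)) stop_validation("vocabulary term must be non-empty")
  if (vocab_has(repo, vocabulary, term))
    stop_validation("term '", term, "' already present in vocabulary '",
                    vocabulary, "'")
  repo$vocab <- rbind(repo$vocab, data.frame(
    vocabulary = vocabulary, term = term, term_id = term_id,
    stringsAsFactors = FALSE))
  invisible(term)
}

#' List the terms of a vocabulary
#'
#' @param repo a repository.
#' @param vocabulary vocabulary name; `NULL` returns the whole term table.
#' @return A data frame with columns `vocabulary`, `term`, `term_id`.
#' @export
vocab_terms <- function(repo, vocabulary = NULL) {
  v <- repo$vocab
  if (!is.null(vocabulary)) v <- v[v$vocabulary == vocabulary, , drop = FALSE]
  row.names(v) <- NULL
  v
}

vocab_has <- function(repo, vocabulary, term) {
  any(repo$vocab$vocabulary == vocabulary & repo$vocab$term == term)
}

# validate an optional vocabulary-typed field; returns NA for absent values
check_vocab_field <- function(repo, vocabulary, term, field) {
  if (is.null(term) || length(term) == 0L || is.na(term)) return(NA_character_)
  assert_scalar_chr(term, field)
  if (!vocab_has(repo, vocabulary, term))
    stop_validation("unknown ", vocabulary, " term in field '", field,
                    "': '", term, "'")
  term
}

#' Load vocabulary terms from a TSV file
#'
#' The file needs columns `vocabulary`, `term` and optionally `term_id`.
#' Terms already present are skipped.
#'
#' @param repo a repository.
#' @param path TSV path.
#' @return Number of terms added.
#' @export
vocab_load <- function(repo, path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           fileEncoding = "UTF-8")
  if (!all(c("vocabulary", "term") %in% names(tab)))
    stop_validation("vocabulary file must have 'vocabulary' and 'term' columns")
  if (is.null(tab$term_id)) tab$term_id <- NA_character_
  added <- 0L
  for (i in seq_len(nrow(tab))) {
    if (!vocab_has(repo, tab$vocabulary[i], tab$term[i])) {
      vocab_add(repo, tab$vocabulary[i], tab$term[i], tab$term_id[i])
      added <- added + 1L
    }
  }
  added
}

# Default seed terms: the hematopoietic and neurodegeneration sample
# descriptors the toolkit's worked examples use. Editable after creation via
# vocab_add()/vocab_load().
seed_default_vocabularies <- function(repo) {
  seeds <- list(
    organism = c("mouse", "human", "zebrafish"),
    tissue = c("bone marrow", "peripheral blood", "brain",
               "substantia nigra", "kidney marrow"),
    cell_type = c("GMP", "L-GMP", "CMP", "MEP", "HSC",
                  "dopamine neuron", "embryonic stem cell"),
    development_stage = c("embryonic", "fetal", "adult"),
    disease_state = c("leukemia", "Parkinson's disease", "healthy"),
    treatment = c("none", "siRNA knockdown", "vehicle"))
  for (v in names(seeds))
    for (trm in seeds[[v]]) vocab_add(repo, v, trm)
  invisible(repo)
}
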