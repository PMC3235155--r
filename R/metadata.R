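# Experiment metadata triplet: Experiment -> Bioassay -> Biomaterial, plus
# comparison groups and the three-level visibility model.

VISIBILITY_LEVELS <- c("private", "metadata_public", "public")
MARKER_POLARITIES <- c("+", "-", "high", "low")
SEX_LEVELS <- c("male", "female", "unknown")

#' Create an experiment
#'
#' Experiments are the top-level unit: a titled study owned by a researcher,
#' holding bioassays and comparison groups. New experiments start `private`
#' and accumulate bioassays through [add_bioassay()].
#'
#' @param repo a repository.
#' @param title experiment title (non-empty).
#' @param researcher researcher name.
#' @param design free-text study design description.
#' @param publications character vector of publication identifiers.
#' @return The experiment as a one-row data frame (including its fresh
#'   accession in `id`).
#' @export
create_experiment <- function(repo, title, researcher = "", design = "",
                              publications = character()) {
  assert_scalar_chr(title, "title")
  if (!nzchar(trimws(title))) stop_validation("experiment title must be non-empty")
  id <- next_accession(repo, "EXP")
  row <- data.frame(id = id, title = title, researcher = researcher,
                    design = design,
                    publications = paste(publications, collapse = "|"),
                    visibility = "private", stringsAsFactors = FALSE)
  repo$experiments <- rbind(repo$experiments, row)
  row
}

# normalize marker polarity spellings ("neg", "pos", unicode minus) to the
# four-value set
normalize_polarity <- function(p) {
  p <- tolower(trimws(p))
  p[p %in% c("+", "pos", "positive")] <- "+"
  p[p %in% c("-", "−", "neg", "negative")] <- "-"
  bad <- !(p %in% MARKER_POLARITIES)
  if (any(bad))
    stop_validation("unknown marker polarity: ",
                    paste(unique(p[bad]), collapse = ", "))
  p
}

#' Add a biomaterial (biological sample)
#'
#' Biomaterials carry the structured sample annotation: organism (mandatory),
#' development stage, tissue, cell type, disease state and treatment as
#' controlled-vocabulary terms; sorting markers with polarity; genetic
#' modifications; age, sex and free-text notes.
#'
#' @param repo a repository.
#' @param organism organism term (must exist in the `organism` vocabulary).
#' @param development_stage,tissue,cell_type,disease_state optional terms from
#'   their vocabularies.
#' @param treatment optional; accepted either as a `treatment` vocabulary term
#'   or as free text.
#' @param markers list of `c(marker, polarity)` pairs or a named character
#'   vector `c("C-kit" = "+")`; polarities normalized to `+`, `-`, `high`,
#'   `low`.
#' @param genetic_modifications character vector of gene identifiers or a
#'   named vector `c(gene = "description")`.
#' @param age,age_unit optional numeric age with unit (e.g. `72`, `"years"`).
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param notes free text.
#' @return The biomaterial id.
#' @export
add_biomaterial <- function(repo, organism, development_stage = NA,
                            tissue = NA, cell_type = NA, treatment = NA,
                            disease_state = NA, markers = list(),
                            genetic_modifications = character(),
                            age = NA_real_, age_unit = NA_character_,
                            sex = NA_character_, notes = "") {
  assert_scalar_chr(organism, "organism")
  if (!vocab_has(repo, "organism", organism))
    stop_validation("unknown organism term in field 'organism': '", organism, "'")
  development_stage <- check_vocab_field(repo, "development_stage",
                                         development_stage, "development_stage")
  tissue <- check_vocab_field(repo, "tissue", tissue, "tissue")
  cell_type <- check_vocab_field(repo, "cell_type", cell_type, "cell_type")
  disease_state <- check_vocab_field(repo, "disease_state", disease_state,
                                     "disease_state")
  # treatment may be a vocabulary term or free text
  if (!is.null(treatment) && length(treatment) == 1L && !is.na(treatment))
    assert_scalar_chr(treatment, "treatment")
  else treatment <- NA_character_
  if (!is.na(sex) && !(sex %in% SEX_LEVELS))
    stop_validation("sex must be one of ", paste(SEX_LEVELS, collapse = ", "))

  id <- next_accession(repo, "BIO")
  repo$biomaterials <- rbind(repo$biomaterials, data.frame(
    id = id, organism = organism, development_stage = development_stage,
    tissue = tissue, cell_type = cell_type, treatment = treatment,
    disease_state = disease_state, age = as.numeric(age),
    age_unit = age_unit, sex = sex, notes = notes, stringsAsFactors = FALSE))

  if (length(markers)) {
    if (is.character(markers) && !is.null(names(markers)))
      markers <- mapply(c, names(markers), unname(markers), SIMPLIFY = FALSE)
    mk <- do.call(rbind, lapply(markers, function(m) {
      if (length(m) != 2L) stop_validation("each marker must be (name, polarity)")
      data.frame(biomaterial_id = id, marker = m[[1]],
                 polarity = normalize_polarity(m[[2]]),
                 stringsAsFactors = FALSE)
    }))
    repo$biomaterial_markers <- rbind(repo$biomaterial_markers, mk)
  }
  if (length(genetic_modifications)) {
    desc <- if (is.null(names(genetic_modifications)))
      rep("", length(genetic_modifications)) else unname(genetic_modifications)
    gene <- if (is.null(names(genetic_modifications)))
      genetic_modifications else names(genetic_modifications)
    repo$biomaterial_genmods <- rbind(repo$biomaterial_genmods, data.frame(
      biomaterial_id = id, gene = gene, description = desc,
      stringsAsFactors = FALSE))
  }
  id
}

#' Register a new measurement type or technology
#'
#' The assay-type registries are extensible so new kinds of measurements
#' (e.g. DNA methylation) can be admitted without code changes.
#'
#' @param repo a repository.
#' @param measurement_type,technology values to add to the registries.
#' @return The repository, invisibly.
#' @export
register_assay_type <- function(repo, measurement_type = NULL,
                                technology = NULL) {
  if (!is.null(measurement_type))
    repo$measurement_types <- union(repo$measurement_types, measurement_type)
  if (!is.null(technology))
    repo$technologies <- union(repo$technologies, technology)
  invisible(repo)
}

#' Add a bioassay to an experiment
#'
#' A bioassay is one measured assay: it links an experiment to the
#' biomaterial measured and records the measurement type, technology,
#' platform and raw data file reference that drive downstream processing.
#'
#' @param repo a repository.
#' @param experiment experiment id.
#' @param biomaterial biomaterial id.
#' @param measurement_type a registered measurement type.
#' @param technology a registered technology; microarray assays must name a
#'   platform.
#' @param platform platform accession/label (e.g. `"HG-U133"`).
#' @param raw_file optional path/URI of the raw output file.
#' @return The bioassay id.
#' @export
add_bioassay <- function(repo, experiment, biomaterial, measurement_type,
                         technology, platform = "", raw_file = NA_character_) {
  get_experiment_row(repo, experiment)
  if (!(biomaterial %in% repo$biomaterials$id))
    stop_notfound("unknown biomaterial: ", biomaterial)
  if (!(measurement_type %in% repo$measurement_types))
    stop_validation("unregistered measurement_type: ", measurement_type)
  if (!(technology %in% repo$technologies))
    stop_validation("unregistered technology: ", technology)
  if (technology == "microarray" && !nzchar(platform))
    stop_validation("platform must be non-empty for microarray assays")
  id <- next_accession(repo, "ASY")
  repo$bioassays <- rbind(repo$bioassays, data.frame(
    id = id, experiment_id = experiment, biomaterial_id = biomaterial,
    measurement_type = measurement_type, technology = technology,
    platform = platform, raw_file_ref = raw_file, stringsAsFactors = FALSE))
  id
}

#' Group bioassays into a case/control comparison
#'
#' @param repo a repository.
#' @param experiment experiment id.
#' @param case,control non-empty, disjoint vectors of bioassay ids, all
#'   belonging to `experiment`; order is preserved.
#' @param label display label for the comparison.
#' @return The comparison id.
#' @export
define_comparison <- function(repo, experiment, case, control, label = "") {
  get_experiment_row(repo, experiment)
  if (length(case) == 0L || length(control) == 0L)
    stop_validation("case and control groups must be non-empty")
  if (length(intersect(case, control)))
    stop_validation("case and control groups overlap: ",
                    paste(intersect(case, control), collapse = ", "))
  own <- repo$bioassays$id[repo$bioassays$experiment_id == experiment]
  foreign <- setdiff(c(case, control), own)
  if (length(foreign))
    stop_validation("bioassays not in experiment ", experiment, ": ",
                    paste(foreign, collapse = ", "))
  id <- next_accession(repo, "CMP")
  repo$comparisons <- rbind(repo$comparisons, data.frame(
    id = id, experiment_id = experiment, label = label,
    stringsAsFactors = FALSE))
  repo$comparison_members <- rbind(repo$comparison_members, data.frame(
    comparison_id = id, bioassay_id = c(case, control),
    role = rep(c("case", "control"), c(length(case), length(control))),
    ord = c(seq_along(case), seq_along(control)), stringsAsFactors = FALSE))
  id
}

#' Bioassay ids of one side of a comparison, in definition order
#' @param repo a repository.
#' @param comparison comparison id.
#' @param role `"case"` or `"control"`.
#' @return Character vector of bioassay ids.
#' @export
comparison_assays <- function(repo, comparison, role = c("case", "control")) {
  role <- match.arg(role)
  if (!(comparison %in% repo$comparisons$id))
    stop_notfound("unknown comparison: ", comparison)
  m <- repo$comparison_members
  m <- m[m$comparison_id == comparison & m$role == role, , drop = FALSE]
  m$bioassay_id[order(m$ord)]
}

#' Set the visibility level of an experiment
#'
#' `private` hides everything from unprivileged viewers; `metadata_public`
#' exposes the experiment, assay and sample metadata but suppresses all data
#' values; `public` exposes both. Query and export layers enforce the level.
#'
#' @param repo a repository.
#' @param experiment experiment id.
#' @param level `"private"`, `"metadata_public"` or `"public"`.
#' @return The updated experiment row.
#' @export
set_visibility <- function(repo, experiment, level) {
  if (!(level %in% VISIBILITY_LEVELS))
    stop_validation("unknown visibility level: ", level)
  i <- match(experiment, repo$experiments$id)
  if (is.na(i)) stop_notfound("unknown experiment: ", experiment)
  repo$experiments$visibility[i] <- level
  repo$experiments[i, , drop = FALSE]
}

# visibility predicates used by every data-exposing layer ---------------------

# can `viewer` see metadata of an experiment at `visibility`?
visible_metadata <- function(visibility, viewer) {
  viewer == "owner" | visibility %in% c("metadata_public", "public")
}

# can `viewer` see data values?
visible_data <- function(visibility, viewer) {
  viewer == "owner" | visibility == "public"
}

check_viewer <- function(viewer) {
  if (!(viewer %in% c("anonymous", "owner")))
    stop_validation("viewer must be 'anonymous' or 'owner'")
  viewer
}

#' List experiments visible to a viewer
#'
#' Unprivileged viewers see the metadata of `metadata_public` and `public`
#' experiments; `private` experiments are omitted entirely.
#'
#' @param repo a repository.
#' @param viewer `"anonymous"` or `"owner"`.
#' @return The visible rows of the experiment table.
#' @export
list_experiments <- function(repo, viewer = "anonymous") {
  check_viewer(viewer)
  e <- repo$experiments
  out <- e[visible_metadata(e$visibility, viewer), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Delete a biomaterial or experiment
#'
#' Deletion is refused while other entities still reference the target, so
#' referential integrity can never be broken.
#'
#' @param repo a repository.
#' @param id accession of the entity to delete.
#' @return `TRUE` invisibly on success.
#' @export
repo_delete <- function(repo, id) {
  if (id %in% repo$biomaterials$id) {
    if (id %in% repo$bioassays$biomaterial_id)
      stop_validation("biomaterial ", id, " is referenced by bioassays")
    repo$biomaterials <- repo$biomaterials[repo$biomaterials$id != id, ,
                                           drop = FALSE]
    repo$biomaterial_markers <- repo$biomaterial_markers[
      repo$biomaterial_markers$biomaterial_id != id, , drop = FALSE]
    repo$biomaterial_genmods <- repo$biomaterial_genmods[
      repo$biomaterial_genmods$biomaterial_id != id, , drop = FALSE]
  } else if (id %in% repo$experiments$id) {
    if (id %in% repo$bioassays$experiment_id)
      stop_validation("experiment ", id, " still has bioassays")
    repo$experiments <- repo$experiments[repo$experiments$id != id, ,
                                         drop = FALSE]
  } else if (id %in% repo$bioassays$id) {
    if (id %in% repo$comparison_members$bioassay_id)
      stop_validation("bioassay ", id, " is used in a comparison group")
    if (id %in% repo$data_matrix$bioassay_id ||
        id %in% repo$locus_scores$bioassay_id)
      stop_validation("bioassay ", id, " still has stored data")
    repo$bioassays <- repo$bioassays[repo$bioassays$id != id, , drop = FALSE]
  } else {
    stop_notfound("unknown entity: ", id)
  }
  invisible(TRUE)
}
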