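# ISA-Tab v1 export: investigation / study / assay file triplet. Targets
# structural validity: required investigation sections, rectangular
# tab-separated study and assay tables, quoted fields.

isa_quote <- function(x) {
  x[is.na(x)] <- ""
  needs <- grepl("[\t\"\n]", x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

isa_row <- function(...) paste(isa_quote(c(...)), collapse = "\t")

#' Export an experiment as an ISA-Tab file triplet
#'
#' Writes `i_<exp>.txt` (investigation: study metadata, publications,
#' contacts), `s_<exp>.txt` (one row per biomaterial with
#' `Characteristics[...]` columns) and `a_<exp>.txt` (one row per bioassay
#' with measurement, technology, platform and raw-file reference).
#'
#' @param repo a repository.
#' @param experiment experiment id; its metadata must be visible to the
#'   viewer (ISA-Tab carries no data values, so `metadata_public` suffices).
#' @param out_dir output directory, created if needed.
#' @param viewer `"anonymous"` or `"owner"`.
#' @return Named character vector of the three file paths.
#' @export
write_isatab <- function(repo, experiment, out_dir, viewer = "anonymous") {
  check_viewer(viewer)
  row <- get_experiment_row(repo, experiment)
  if (!visible_metadata(row$visibility, viewer))
    stop_validation("experiment ", experiment,
                    " is private; refusing to export")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  s_file <- paste0("s_", experiment, ".txt")
  a_file <- paste0("a_", experiment, ".txt")
  i_path <- file.path(out_dir, paste0("i_", experiment, ".txt"))

  pubs <- strsplit(row$publications, "|", fixed = TRUE)[[1]]
  inv <- c(
    "ONTOLOGY SOURCE REFERENCE",
    isa_row("Term Source Name"), isa_row("Term Source File"),
    isa_row("Term Source Version"), isa_row("Term Source Description"),
    "INVESTIGATION",
    isa_row("Investigation Identifier", experiment),
    isa_row("Investigation Title", row$title),
    isa_row("Investigation Description", row$design),
    "INVESTIGATION PUBLICATIONS",
    isa_row("Investigation PubMed ID"),
    "INVESTIGATION CONTACTS",
    isa_row("Investigation Person Last Name", row$researcher),
    "STUDY",
    isa_row("Study Identifier", experiment),
    isa_row("Study Title", row$title),
    isa_row("Study Description", row$design),
    isa_row("Study File Name", s_file),
    "STUDY DESIGN DESCRIPTORS",
    isa_row("Study Design Type"),
    "STUDY PUBLICATIONS",
    isa_row("Study PubMed ID", if (length(pubs)) pubs else ""),
    "STUDY FACTORS",
    isa_row("Study Factor Name"),
    "STUDY ASSAYS",
    isa_row("Study Assay File Name", a_file),
    isa_row("Study Assay Measurement Type"),
    isa_row("Study Assay Technology Type"),
    "STUDY PROTOCOLS",
    isa_row("Study Protocol Name"),
    "STUDY CONTACTS",
    isa_row("Study Person Last Name", row$researcher))
  writeLines(inv, i_path, useBytes = TRUE)

  assays <- repo$bioassays[repo$bioassays$experiment_id == experiment, ,
                           drop = FALSE]
  bms <- repo$biomaterials[repo$biomaterials$id %in% assays$biomaterial_id, ,
                           drop = FALSE]
  s_path <- file.path(out_dir, s_file)
  s_header <- c("Source Name", "Characteristics[organism]",
                "Characteristics[development stage]",
                "Characteristics[tissue]", "Characteristics[cell type]",
                "Characteristics[disease state]", "Characteristics[age]",
                "Characteristics[sex]", "Comment[notes]", "Sample Name")
  s_rows <- vapply(seq_len(nrow(bms)), function(i) {
    b <- bms[i, ]
    isa_row(b$id, b$organism, b$development_stage, b$tissue, b$cell_type,
            b$disease_state,
            if (is.na(b$age)) "" else format(b$age, trim = TRUE),
            b$sex, b$notes, b$id)
  }, "")
  writeLines(c(paste(isa_quote(s_header), collapse = "\t"), s_rows), s_path,
             useBytes = TRUE)

  a_path <- file.path(out_dir, a_file)
  a_header <- c("Sample Name", "Assay Name",
                "Parameter Value[measurement type]",
                "Parameter Value[technology]", "Parameter Value[platform]",
                "Raw Data File")
  a_rows <- vapply(seq_len(nrow(assays)), function(i) {
    a <- assays[i, ]
    isa_row(a$biomaterial_id, a$id, a$measurement_type, a$technology,
            a$platform, a$raw_file_ref)
  }, "")
  writeLines(c(paste(isa_quote(a_header), collapse = "\t"), a_rows), a_path,
             useBytes = TRUE)
  c(investigation = i_path, study = s_path, assay = a_path)
}
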