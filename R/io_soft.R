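# GEO SOFT family-file dialect: ^ENTITY = id lines, !attribute = value lines,
# #column = description lines, and data tables delimited by
# !<entity>_table_begin / !<entity>_table_end. Attribute order is preserved
# and unknown attributes pass through verbatim.

soft_entity <- function(id, attrs = NULL, col_desc = NULL, table = NULL) {
  if (is.null(attrs))
    attrs <- data.frame(key = character(), value = character(),
                        stringsAsFactors = FALSE)
  list(id = id, attrs = attrs, col_desc = col_desc, table = table)
}

soft_attr <- function(entity, key) {
  v <- entity$attrs$value[entity$attrs$key == key]
  if (length(v)) v else character()
}

#' Read a GEO SOFT family file
#'
#' Supports SERIES, SAMPLE and PLATFORM entities with attribute lines,
#' column-description lines and delimited data tables. Attribute keys and
#' their order are preserved verbatim, so documents survive a write/read
#' round trip losslessly.
#'
#' @param path SOFT file path (UTF-8; DOS or Unix line endings).
#' @return An object of class `soft_document`: list with `series`,
#'   `samples`, `platforms`, each a named list of entities (`id`, `attrs`
#'   key/value data frame, `col_desc`, `table`).
#' @export
read_soft <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  doc <- list(series = list(), samples = list(), platforms = list())
  cur <- NULL; cur_kind <- NULL
  i <- 1L
  flush <- function() {
    if (is.null(cur)) return()
    doc[[cur_kind]][[cur$id]] <<- cur
  }
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\^", ln)) {
      flush()
      m <- regmatches(ln, regexec("^\\^(\\S+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L)
        stop_validation("malformed entity line ", i, ": ", ln)
      kind <- switch(toupper(m[2]), SERIES = "series", SAMPLE = "samples",
                     PLATFORM = "platforms",
                     stop_validation("unsupported entity '", m[2],
                                     "' at line ", i))
      cur <- soft_entity(trimws(m[3]))
      cur_kind <- kind
    } else if (grepl("^!.*_table_begin\\s*$", ln)) {
      if (is.null(cur)) stop_validation("table outside entity at line ", i)
      header_i <- i + 1L
      if (header_i > length(lines))
        stop_validation("table_begin without table_end at line ", i)
      header <- strsplit(lines[header_i], "\t", fixed = TRUE)[[1]]
      rows <- list(); j <- header_i + 1L; closed <- FALSE
      while (j <= length(lines)) {
        if (grepl("^!.*_table_end\\s*$", lines[j])) { closed <- TRUE; break }
        fields <- strsplit(lines[j], "\t", fixed = TRUE)[[1]]
        if (length(fields) != length(header))
          stop_validation("table row width ", length(fields),
                          " != header width ", length(header),
                          " at line ", j)
        rows[[length(rows) + 1L]] <- fields
        j <- j + 1L
      }
      if (!closed)
        stop_validation("table_begin at line ", i, " without table_end")
      tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      if (nrow(tab) == 0L)
        tab <- as.data.frame(matrix(character(), ncol = length(header)),
                             stringsAsFactors = FALSE)
      names(tab) <- header
      cur$table <- tab
      i <- j
    } else if (grepl("^!", ln)) {
      if (is.null(cur)) stop_validation("attribute outside entity at line ", i)
      m <- regmatches(ln, regexec("^!(\\S+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) == 3L)
        cur$attrs <- rbind(cur$attrs, data.frame(
          key = m[2], value = m[3], stringsAsFactors = FALSE))
    } else if (grepl("^#", ln)) {
      if (is.null(cur)) stop_validation("column line outside entity at line ", i)
      m <- regmatches(ln, regexec("^#(\\S+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) == 3L)
        cur$col_desc <- rbind(cur$col_desc, data.frame(
          column = m[2], description = m[3], stringsAsFactors = FALSE))
    }
    i <- i + 1L
  }
  flush()
  structure(doc, class = "soft_document")
}

# serialize one entity block
format_soft_entity <- function(kind, entity) {
  tag <- c(series = "SERIES", samples = "SAMPLE", platforms = "PLATFORM")[kind]
  prefix <- c(series = "Series", samples = "Sample",
              platforms = "Platform")[kind]
  out <- sprintf("^%s = %s", tag, entity$id)
  if (nrow(entity$attrs))
    out <- c(out, sprintf("!%s = %s", entity$attrs$key, entity$attrs$value))
  if (!is.null(entity$col_desc) && nrow(entity$col_desc))
    out <- c(out, sprintf("#%s = %s", entity$col_desc$column,
                          entity$col_desc$description))
  if (!is.null(entity$table)) {
    out <- c(out, sprintf("!%s_table_begin", tolower(prefix)),
             paste(names(entity$table), collapse = "\t"),
             apply(entity$table, 1L, paste, collapse = "\t"),
             sprintf("!%s_table_end", tolower(prefix)))
  }
  out
}

#' Serialize a SOFT document to text lines
#' @param doc a `soft_document`.
#' @return Character vector of SOFT lines (platforms, series, samples).
#' @export
format_soft <- function(doc) {
  unlist(c(lapply(doc$platforms, function(e) format_soft_entity("platforms", e)),
           lapply(doc$series, function(e) format_soft_entity("series", e)),
           lapply(doc$samples, function(e) format_soft_entity("samples", e))),
         use.names = FALSE)
}

#' Default mapping from SOFT characteristic keys to biomaterial fields
#'
#' Read from the package's editable YAML table
#' (`inst/extdata/soft_characteristic_map.yaml`).
#'
#' @param path optional path to a custom YAML mapping.
#' @return Named character vector: characteristic key -> biomaterial field.
#' @export
default_soft_mapping <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "soft_characteristic_map.yaml",
                        package = "generepo", mustWork = TRUE)
  unlist(yaml::read_yaml(path))
}

#' Import a SOFT document as an experiment
#'
#' Creates one experiment per series and one bioassay + biomaterial per
#' sample. `!Sample_characteristics_ch1 = key: value` lines are mapped to
#' biomaterial fields via `vocab_mapping`; unmapped characteristics are
#' appended to the biomaterial notes so the import is loss-tolerant.
#' Vocabulary terms encountered during import are added to the
#' vocabularies when absent. Sample data tables with `ID_REF`/`VALUE`
#' columns are ingested as expression (probesets are auto-registered on the
#' sample's platform when unknown).
#'
#' @param repo a repository.
#' @param doc a `soft_document` from [read_soft()].
#' @param vocab_mapping named vector, characteristic key -> biomaterial
#'   field; defaults to [default_soft_mapping()].
#' @return The new experiment id(s), one per series.
#' @export
soft_to_experiment <- function(repo, doc,
                               vocab_mapping = default_soft_mapping()) {
  if (!length(doc$series)) stop_validation("SOFT document has no series")
  if (!length(doc$samples))
    stop_validation("SOFT document has samples outside any series or none")
  out <- character()
  for (series in doc$series) {
    title <- c(soft_attr(series, "Series_title"), "Untitled import")[1]
    exp <- create_experiment(
      repo, title,
      researcher = c(soft_attr(series, "Series_contributor"), "")[1],
      design = c(soft_attr(series, "Series_summary"), "")[1],
      publications = soft_attr(series, "Series_pubmed_id"))
    for (smp in doc$samples) {
      fields <- list(notes = character())
      org_attr <- soft_attr(smp, "Sample_organism_ch1")
      if (length(org_attr)) fields$organism <- org_attr[1]
      for (ch in soft_attr(smp, "Sample_characteristics_ch1")) {
        kv <- regmatches(ch, regexec("^\\s*([^:]+?)\\s*:\\s*(.*)$", ch))[[1]]
        if (length(kv) != 3L) { fields$notes <- c(fields$notes, ch); next }
        field <- vocab_mapping[tolower(kv[2])]
        if (is.na(field)) fields$notes <- c(fields$notes, ch)
        else fields[[field]] <- kv[3]
      }
      if (is.null(fields$organism))
        stop_validation("sample ", smp$id, " has no mappable organism ",
                        "(organism is mandatory)")
      for (vf in c("organism", "tissue", "cell_type", "development_stage",
                   "disease_state")) {
        if (!is.null(fields[[vf]]) && !vocab_has(repo, vf, fields[[vf]]))
          vocab_add(repo, vf, fields[[vf]])
      }
      age <- if (!is.null(fields$age))
        suppressWarnings(as.numeric(sub("^([0-9.]+).*$", "\\1", fields$age)))
        else NA_real_
      sex <- if (!is.null(fields$sex) && tolower(fields$sex) %in% SEX_LEVELS)
        tolower(fields$sex) else NA_character_
      bm <- add_biomaterial(
        repo, organism = fields$organism,
        development_stage = fields$development_stage %||% NA,
        tissue = fields$tissue %||% NA, cell_type = fields$cell_type %||% NA,
        treatment = fields$treatment %||% NA,
        disease_state = fields$disease_state %||% NA, age = age, sex = sex,
        notes = paste(fields$notes, collapse = "; "))
      platform <- c(soft_attr(smp, "Sample_platform_id"), "unknown")[1]
      technology <- c(soft_attr(smp, "Sample_technology"), "microarray")[1]
      mtype <- c(soft_attr(smp, "Sample_measurement_type"),
                 "gene_expression")[1]
      if (!(mtype %in% repo$measurement_types))
        register_assay_type(repo, measurement_type = mtype)
      if (!(technology %in% repo$technologies))
        register_assay_type(repo, technology = technology)
      asy <- add_bioassay(repo, exp$id, bm, mtype, technology, platform,
                         c(soft_attr(smp, "Sample_supplementary_file"),
                           NA_character_)[1])
      tab <- smp$table
      if (!is.null(tab) && all(c("ID_REF", "VALUE") %in% names(tab)) &&
          nrow(tab)) {
        known <- repo$probesets$probeset_id[
          repo$probesets$platform == platform]
        new_ps <- setdiff(tab$ID_REF, known)
        if (length(new_ps))
          repo$probesets <- rbind(repo$probesets, data.frame(
            probeset_id = new_ps, platform = platform,
            transcript_id = NA_character_, stringsAsFactors = FALSE))
        store_expression(repo, asy,
                         stats::setNames(as.numeric(tab$VALUE), tab$ID_REF))
      }
    }
    out <- c(out, exp$id)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an experiment as SOFT text
#'
#' Emits a `^SERIES` block with the experiment metadata and one `^SAMPLE`
#' block per bioassay with its biomaterial's characteristics. Expression
#' data tables are included only when the experiment is `public` (or the
#' viewer is the owner); a `private` experiment is refused outright.
#'
#' @param repo a repository.
#' @param experiment experiment id.
#' @param viewer `"anonymous"` or `"owner"`.
#' @return Character vector of SOFT lines.
#' @export
write_soft <- function(repo, experiment, viewer = "anonymous") {
  check_viewer(viewer)
  row <- get_experiment_row(repo, experiment)
  if (!visible_metadata(row$visibility, viewer))
    stop_validation("experiment ", experiment,
                    " is private; refusing to export")
  with_data <- visible_data(row$visibility, viewer)

  sattrs <- data.frame(key = "Series_title", value = row$title,
                       stringsAsFactors = FALSE)
  if (nzchar(row$researcher))
    sattrs <- rbind(sattrs, data.frame(key = "Series_contributor",
                                       value = row$researcher))
  if (nzchar(row$design))
    sattrs <- rbind(sattrs, data.frame(key = "Series_summary",
                                       value = row$design))
  for (p in strsplit(row$publications, "|", fixed = TRUE)[[1]])
    if (nzchar(p)) sattrs <- rbind(sattrs, data.frame(
      key = "Series_pubmed_id", value = p))
  doc <- structure(list(series = list(), samples = list(),
                        platforms = list()), class = "soft_document")
  doc$series[[experiment]] <- soft_entity(experiment, sattrs)

  assays <- repo$bioassays[repo$bioassays$experiment_id == experiment, ,
                           drop = FALSE]
  for (i in seq_len(nrow(assays))) {
    a <- assays[i, ]
    bm <- repo$biomaterials[match(a$biomaterial_id, repo$biomaterials$id), ]
    attrs <- data.frame(key = c("Sample_series_id", "Sample_platform_id",
                                "Sample_organism_ch1", "Sample_technology",
                                "Sample_measurement_type"),
                        value = c(experiment, a$platform, bm$organism,
                                  a$technology, a$measurement_type),
                        stringsAsFactors = FALSE)
    chars <- c(cell_type = "cell type", tissue = "tissue",
               development_stage = "development stage",
               disease_state = "disease state", treatment = "treatment")
    for (f in names(chars)) {
      if (!is.na(bm[[f]]))
        attrs <- rbind(attrs, data.frame(
          key = "Sample_characteristics_ch1",
          value = paste0(chars[f], ": ", bm[[f]])))
    }
    if (!is.na(bm$age))
      attrs <- rbind(attrs, data.frame(
        key = "Sample_characteristics_ch1",
        value = paste0("age: ", format(bm$age, trim = TRUE),
                       if (!is.na(bm$age_unit)) paste0(" ", bm$age_unit)
                       else "")))
    if (!is.na(bm$sex))
      attrs <- rbind(attrs, data.frame(key = "Sample_characteristics_ch1",
                                       value = paste0("sex: ", bm$sex)))
    if (nzchar(bm$notes) && !is.na(bm$notes))
      attrs <- rbind(attrs, data.frame(key = "Sample_description",
                                       value = bm$notes))
    if (!is.na(a$raw_file_ref))
      attrs <- rbind(attrs, data.frame(key = "Sample_supplementary_file",
                                       value = a$raw_file_ref))
    ent <- soft_entity(a$id, attrs)
    if (with_data) {
      d <- repo$data_matrix[repo$data_matrix$bioassay_id == a$id, ,
                            drop = FALSE]
      if (nrow(d)) {
        d <- d[order(d$probeset_id), ]
        ent$col_desc <- data.frame(
          column = c("ID_REF", "VALUE"),
          description = c("probeset identifier",
                          "log2 summarized expression"),
          stringsAsFactors = FALSE)
        ent$table <- data.frame(
          ID_REF = d$probeset_id,
          VALUE = format_value(d$value), stringsAsFactors = FALSE)
      }
    }
    doc$samples[[a$id]] <- ent
  }
  format_soft(doc)
}

# full-precision numeric formatting for text round trips
format_value <- function(x) {
  formatC(x, format = "g", digits = 17)
}
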