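cf_checksum <- function(path) unname(tools::md5sum(path))

version_tag <- function(v) sprintf("v%03d", v)

#' List generated versions in a project directory
#'
#' @param project_dir project directory.
#' @return a `data.table` of `version_id` and manifest path, ascending.
#' @export
list_versions <- function(project_dir) {
  files <- list.files(project_dir, pattern = "^v\\d+_manifest\\.json$",
                      full.names = TRUE)
  v <- as.integer(sub("^v(\\d+)_manifest\\.json$", "\\1", basename(files)))
  out <- data.table::data.table(version_id = v, manifest = files)
  data.table::setorderv(out, "version_id")
  out
}

next_version <- function(project_dir) {
  v <- list_versions(project_dir)$version_id
  if (length(v)) max(v) + 1L else 1L
}

# metadata rows for engine-generated dataset columns not in the catalog
builtin_column_metadata <- function(columns) {
  meta <- cf_engine_column_metadata()
  extra <- list()
  flat <- grep("^cancer\\d+_", columns, value = TRUE)
  for (col in flat) {
    i <- sub("^cancer(\\d+)_.*$", "\\1", col)
    f <- sub("^cancer\\d+_", "", col)
    lab <- c(diagnosis_date = "diagnosis date", site_code = "ICD-O-3 site",
             histology_code = "ICD-O-3 histology",
             seer_group = "SEER site group", stage = "stage",
             grade = "grade")[f]
    extra[[col]] <- data.table::data.table(
      name = col, label = sprintf("Primary cancer %s: %s", i, lab),
      dtype = if (f == "diagnosis_date") "date" else "character",
      value_labels = "", units = "", source = "engine")
  }
  ph <- grep("^pheno_", columns, value = TRUE)
  for (col in ph) {
    is_date <- grepl("_date$", col)
    nm <- sub("^pheno_(.*?)(_date)?$", "\\1", col)
    extra[[col]] <- data.table::data.table(
      name = col,
      label = if (is_date) sprintf("Phenotype '%s': first qualifying admission date", nm)
              else sprintf("Phenotype '%s' met during follow-up", nm),
      dtype = if (is_date) "date" else "flag",
      value_labels = if (is_date) "" else "0=No|1=Yes",
      units = "", source = "engine")
  }
  data.table::rbindlist(c(list(meta), extra), fill = TRUE)
}

#' Render the custom data dictionary
#'
#' One entry per dataset column and none extra: selected catalog covariates
#' are documented from the catalog (label, type, value labels, questionnaire
#' provenance); engine-generated columns (person-time, statuses, flattened
#' events, phenotypes) from built-in metadata. A column with no metadata is
#' a completeness error.
#'
#' @param catalog the covariate catalog.
#' @param columns dataset column names, in dataset order.
#' @param version_id integer dataset version.
#' @return a `data.table` with columns
#'   `name,label,dtype,value_labels,source,units,version_id`.
#' @export
render_dictionary <- function(catalog, columns, version_id = 1L) {
  builtin <- builtin_column_metadata(columns)
  units_lookup <- c(q1_height_m = "m", q1_weight_kg = "kg", bmi = "kg/m2")
  rows <- lapply(columns, function(col) {
    i <- match(col, catalog$name)
    if (!is.na(i)) {
      src <- if (catalog$derived[i]) "derived" else
        sprintf("questionnaire %d / %s / q%s", catalog$questionnaire_number[i],
                catalog$section[i], catalog$question_number[i])
      data.table::data.table(
        name = col, label = catalog$label[i], dtype = catalog$dtype[i],
        value_labels = catalog$value_labels[i] %||% "",
        source = src, units = unname(units_lookup[col]) %||% "")
    } else {
      j <- match(col, builtin$name)
      if (is.na(j)) {
        cf_stop("cf_completeness_error",
                "dataset column has no dictionary metadata: ", col)
      }
      builtin[j, c("name", "label", "dtype", "value_labels", "units",
                   "source")]
    }
  })
  dict <- data.table::rbindlist(rows, use.names = TRUE)
  dict$value_labels[is.na(dict$value_labels)] <- ""
  dict$units[is.na(dict$units)] <- ""
  dict$version_id <- as.integer(version_id)
  data.table::setcolorder(dict, c("name", "label", "dtype", "value_labels",
                                  "source", "units", "version_id"))
  dict
}

parse_value_labels <- function(vl) {
  if (is.na(vl) || !nzchar(vl)) return(NULL)
  parts <- strsplit(vl, "|", fixed = TRUE)[[1]]
  kv <- regmatches(parts, regexpr("=", parts), invert = TRUE)
  codes <- vapply(kv, `[[`, character(1), 1L)
  labels <- vapply(kv, `[[`, character(1), 2L)
  setNames(labels, codes)
}

sas_format_name <- function(col, char) {
  paste0(if (char) "$" else "", toupper(substr(col, 1, 31)), "F")
}

#' Render the value-label formats file (commercial dialect)
#'
#' Emits one format block per categorical dataset column, codes and labels
#' exactly as cataloged, in the fixed grammar: `proc format;`, then per
#' column `value <NAME>F` followed by one `<code>='<label>'` line per code
#' and a closing `;`, then `run;`. Quote characters in labels are doubled.
#' Continuous columns are skipped; a dataset with no categorical column
#' yields an empty-but-valid file.
#'
#' @param dictionary output of [render_dictionary()].
#' @return the formats file contents as a single string.
#' @export
render_formats_file <- function(dictionary) {
  lines <- c("proc format;")
  for (i in seq_len(nrow(dictionary))) {
    vl <- parse_value_labels(dictionary$value_labels[i])
    if (is.null(vl)) next
    char_codes <- anyNA(suppressWarnings(as.numeric(names(vl))))
    fmt <- sas_format_name(dictionary$name[i], char_codes)
    lines <- c(lines, paste0("value ", fmt))
    esc <- gsub("'", "''", vl)
    code_lit <- if (char_codes) paste0("'", names(vl), "'") else names(vl)
    lines <- c(lines, paste0("  ", code_lit, "='", esc, "'"), ";")
  }
  paste(c(lines, "run;", ""), collapse = "\n")
}

#' Render a reader script for the versioned dataset
#'
#' Two dialects: `"sas"` emits a data step that reads the versioned CSV,
#' declares every column with an informat, and applies the value-label
#' formats from the formats file; `"r"` emits a script that reads the CSV
#' with explicit column classes and applies value labels as factor levels
#' inline. Every dataset column is named exactly once.
#'
#' @param dialect `"sas"` or `"r"`.
#' @param dataset_path path to the versioned dataset, as the script should
#'   reference it.
#' @param formats_path path to the formats file (commercial dialect).
#' @param dictionary output of [render_dictionary()].
#' @return script text.
#' @export
render_reader_script <- function(dialect, dataset_path, formats_path,
                                 dictionary) {
  if (!dialect %in% c("sas", "r")) {
    cf_stop("cf_spec_error", "unknown reader dialect: ", dialect)
  }
  cols <- dictionary$name
  is_date <- dictionary$dtype == "date"
  is_num <- dictionary$dtype %in% c("continuous", "flag")
  # categorical columns are numeric only when all their codes are numeric;
  # unlabeled categoricals (free strings such as site groups) stay character
  is_cat_num <- dictionary$dtype == "categorical" &
    vapply(seq_len(nrow(dictionary)), function(i) {
      vl <- parse_value_labels(dictionary$value_labels[i])
      !is.null(vl) && !anyNA(suppressWarnings(as.numeric(names(vl))))
    }, logical(1))

  if (dialect == "sas") {
    informats <- ifelse(is_date, "yymmdd10.",
                        ifelse(is_num | is_cat_num, "best32.", "$200."))
    input_spec <- ifelse(is_date | is_num | is_cat_num, cols,
                         paste0(cols, " $"))
    fmt_lines <- character()
    for (i in seq_len(nrow(dictionary))) {
      vl <- parse_value_labels(dictionary$value_labels[i])
      if (is.null(vl)) next
      fmt_lines <- c(fmt_lines, paste0(
        "  format ", cols[i], " ",
        sas_format_name(cols[i], !is_cat_num[i]), ".;"))
    }
    txt <- c(
      sprintf("/* reads the versioned dataset %s */", basename(dataset_path)),
      sprintf("%%include '%s';", formats_path),
      "data cohort;",
      sprintf("  infile '%s' dsd firstobs=2 truncover;", dataset_path),
      paste0("  informat ", cols, " ", informats, ";"),
      ifelse(is_date, paste0("  format ", cols, " yymmdd10.;"),
             character(length(cols)))[is_date],
      paste0("  input ", paste(input_spec, collapse = " "), ";"),
      fmt_lines,
      "run;", "")
    return(paste(txt, collapse = "\n"))
  }

  # open-source dialect: explicit column classes, labels applied inline
  classes <- ifelse(is_date, "Date",
                    ifelse(is_num | is_cat_num, "numeric", "character"))
  factor_lines <- character()
  for (i in seq_len(nrow(dictionary))) {
    vl <- parse_value_labels(dictionary$value_labels[i])
    if (is.null(vl)) next
    factor_lines <- c(factor_lines, sprintf(
      "cohort[[\"%s\"]] <- factor(cohort[[\"%s\"]], levels = c(%s), labels = c(%s))",
      cols[i], cols[i],
      paste(sprintf('"%s"', names(vl)), collapse = ", "),
      paste(sprintf('"%s"', gsub('"', '\\\\"', vl)), collapse = ", ")))
  }
  txt <- c(
    sprintf("# reads the versioned dataset %s", basename(dataset_path)),
    "# missing-by-design cells carry the sentinel '.D' in the CSV (see the",
    "# data dictionary); both plain missing and '.D' read as NA here",
    "cohort <- utils::read.csv(",
    sprintf("  \"%s\",", dataset_path),
    "  na.strings = c(\"\", \".D\"), stringsAsFactors = FALSE,",
    "  colClasses = c(",
    paste0("    ", sprintf('%s = "%s"', cols, classes),
           c(rep(",", length(cols) - 1), "")),
    "  )", ")",
    factor_lines,
    "")
  paste(txt, collapse = "\n")
}

#' Render the selection summary document
#'
#' A plain-markdown restatement of every selection choice (endpoint, start
#' of follow-up, censoring rules, exclusions, covariate selectors), the
#' attrition table, and the version id. The generation timestamp line is
#' excluded from determinism checks.
#'
#' @param spec the selection spec.
#' @param attrition the attrition log.
#' @param version_id integer version.
#' @return summary text.
#' @export
render_summary <- function(spec, attrition, version_id) {
  ep <- spec$endpoint
  ep_txt <- if (is.null(ep)) "none (covariate-only extract)"
  else switch(ep$type,
    cancer = paste0("cancer; site prefixes: ",
                    paste(ep$site_prefixes, collapse = ", ") %||% "",
                    if (length(ep$seer_groups))
                      paste0("; SEER groups: ",
                             paste(ep$seer_groups, collapse = ", ")) else "",
                    if (length(ep$histology_include))
                      paste0("; histology include: ",
                             paste(ep$histology_include, collapse = ", "))
                    else "",
                    if (length(ep$histology_exclude))
                      paste0("; histology exclude: ",
                             paste(ep$histology_exclude, collapse = ", "))
                    else ""),
    mortality = paste0("mortality; cause prefixes: ",
                       if (length(ep$cause_prefixes))
                         paste(ep$cause_prefixes, collapse = ", ")
                       else "(all-cause)"),
    phenotype = paste0("hospitalization phenotype(s): ",
                       paste(vapply(ep$phenotypes, `[[`, character(1),
                                    "name"), collapse = ", ")))
  st <- spec$start
  start_txt <- if (is.null(st)) "(not set)"
  else switch(st$rule,
    baseline = "baseline survey (enrollment)",
    survey_k = sprintf("follow-up survey %d", st$k),
    fixed_date = sprintf("fixed date %s", st$date))
  cz <- spec$censoring
  sel_txt <- if (!length(spec$covariates)) "essential set only"
  else paste(vapply(spec$covariates, function(s)
    sprintf("%s: %s", s$type, paste(s$value, collapse = ", ")),
    character(1)), collapse = "; ")

  lines <- c(
    sprintf("# Cohort selection summary (version %d)", version_id),
    "",
    sprintf("project: %s", spec$metadata$project),
    sprintf("design: %s", spec$metadata$design),
    if (!is.null(spec$metadata$reference_date))
      sprintf("reference date: %s", spec$metadata$reference_date),
    "",
    "## Choices",
    sprintf("- endpoint: %s", ep_txt),
    sprintf("- start of follow-up: %s", start_txt),
    sprintf("- end of study: %s", cz$end_of_study %||% "(not set)"),
    sprintf("- censor other cancers: %s",
            if (isTRUE(cz$censor_other_cancers)) "yes" else "no"),
    sprintf("- automatic surgery censoring: %s",
            if (is.null(cz$auto_surgery_censoring)) "automatic by endpoint"
            else if (isTRUE(cz$auto_surgery_censoring)) "yes" else "no"),
    sprintf("- prevalent cancer excluded: %s",
            if (isFALSE(cz$exclude_prevalent_cancer)) "no" else "yes"),
    sprintf("- covariate selection: %s", sel_txt),
    "",
    "## Attrition",
    "| criterion | excluded | remaining |",
    "| --- | ---: | ---: |",
    sprintf("| %s | %d | %d |", attrition$criterion, attrition$n_excluded,
            attrition$n_remaining),
    "",
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    "")
  paste(lines, collapse = "\n")
}

write_text <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(text, con, sep = "", useBytes = TRUE)
  invisible(path)
}

#' Generate the six deliverables for a completed run
#'
#' Writes, as one atomic versioned set: (1) the dataset CSV and (2) its
#' value-label formats file into the read-only data directory; (3) a
#' commercial-package (SAS) data-call script, (4) an open-source (R) reader
#' script, (5) the custom data dictionary, and (6) the selection summary
#' into the project directory. The version id is the previous maximum plus
#' one; prior versions are never touched; the data files are made
#' read-only; regeneration from identical inputs yields byte-identical
#' files apart from the summary timestamp.
#'
#' @param dataset the analytic dataset.
#' @param spec the selection spec.
#' @param catalog the covariate catalog.
#' @param attrition the attrition log.
#' @param project_dir,data_dir output directories (created if needed).
#' @return the manifest: a list with `version_id` and six entries
#'   (`role`, `path`, `checksum`, `read_only`), also written as
#'   `v<NNN>_manifest.json` in the project directory.
#' @export
generate_deliverables <- function(dataset, spec, catalog, attrition,
                                  project_dir, data_dir) {
  dir.create(project_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
  v <- next_version(project_dir)
  tag <- version_tag(v)

  dataset_path <- file.path(data_dir, paste0(tag, "_dataset.csv"))
  formats_path <- file.path(data_dir, paste0(tag, "_formats.sas"))
  paths <- list(
    dataset = dataset_path,
    formats = formats_path,
    sas_reader = file.path(project_dir, paste0(tag, "_read_dataset.sas")),
    r_reader = file.path(project_dir, paste0(tag, "_read_dataset.R")),
    dictionary = file.path(project_dir, paste0(tag, "_dictionary.csv")),
    summary = file.path(project_dir, paste0(tag, "_summary.md")))
  clash <- vapply(paths, file.exists, logical(1))
  if (any(clash)) {
    cf_stop("cf_immutability_error", "version ", v, " files already exist: ",
            paste(unlist(paths)[clash], collapse = ", "))
  }

  dict <- render_dictionary(catalog, names(dataset), v)
  tmp <- vapply(names(paths), function(nm)
    tempfile(tmpdir = dirname(paths[[nm]])), character(1))
  ok <- FALSE
  # rollback on any failure: no partial version may survive
  on.exit(if (!ok) unlink(c(tmp, unlist(paths))), add = TRUE)

  write_table(dataset, tmp[["dataset"]])
  write_text(render_formats_file(dict), tmp[["formats"]])
  write_text(render_reader_script("sas", dataset_path, formats_path, dict),
             tmp[["sas_reader"]])
  write_text(render_reader_script("r", dataset_path, formats_path, dict),
             tmp[["r_reader"]])
  data.table::fwrite(dict, tmp[["dictionary"]], na = "", quote = "auto")
  write_text(render_summary(spec, attrition, v), tmp[["summary"]])

  for (nm in names(paths)) {
    if (!file.rename(tmp[[nm]], paths[[nm]])) {
      cf_stop("cf_io_error", "cannot move deliverable into place: ",
              paths[[nm]])
    }
  }
  ok <- TRUE
  Sys.chmod(dataset_path, "0444")
  Sys.chmod(formats_path, "0444")

  roles <- c("dataset", "formats", "sas_reader", "r_reader", "dictionary",
             "summary")
  manifest <- list(
    version_id = v,
    generated = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    entries = lapply(roles, function(r) list(
      role = r, path = paths[[r]], checksum = cf_checksum(paths[[r]]),
      read_only = r %in% c("dataset", "formats"))))
  manifest_path <- file.path(project_dir, paste0(tag, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  manifest$manifest_path <- manifest_path
  structure(manifest, class = "cf_manifest")
}

#' Verify deliverable integrity against a manifest
#'
#' Recomputes every entry's checksum; a tampered or missing file is
#' reported as a mismatch.
#'
#' @param manifest a manifest list or path to a manifest JSON.
#' @return a `data.table` with `role`, `path`, `ok`.
#' @export
verify_manifest <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  rows <- lapply(manifest$entries, function(e) {
    actual <- if (file.exists(e$path)) cf_checksum(e$path) else NA_character_
    data.table::data.table(role = e$role, path = e$path,
                           ok = identical(actual, e$checksum))
  })
  data.table::rbindlist(rows)
}

#' Generate a join script and key-validation report for custom data
#'
#' Custom data excerpts share the universal key (`participant_id`); the
#' generated script left-joins the excerpt onto the versioned dataset on
#' that key, preserving the dataset's row count. The validation report
#' lists excerpt keys absent from the dataset and duplicated excerpt keys.
#'
#' @param excerpt_path path to the excerpt CSV.
#' @param manifest the run's manifest ([generate_deliverables()]).
#' @return `list(script, report)`; `report` has `keys_not_in_dataset` and
#'   `duplicate_keys`.
#' @export
emit_custom_join <- function(excerpt_path, manifest) {
  excerpt <- read_table(excerpt_path)
  if (!"participant_id" %in% names(excerpt)) {
    cf_stop("cf_join_error", "excerpt lacks the universal key column ",
            "'participant_id': ", excerpt_path)
  }
  dataset_path <- NULL
  for (e in manifest$entries) if (e$role == "dataset") dataset_path <- e$path
  ds_keys <- read_table(dataset_path)$participant_id
  ex_keys <- as.character(excerpt$participant_id)
  report <- list(
    keys_not_in_dataset = setdiff(ex_keys, as.character(ds_keys)),
    duplicate_keys = unique(ex_keys[duplicated(ex_keys)]))
  script <- paste(c(
    "# left-join a custom data excerpt onto the versioned dataset",
    "# join key: participant_id (universal key)",
    sprintf("cohort <- utils::read.csv(\"%s\", na.strings = \"\")",
            dataset_path),
    sprintf("excerpt <- utils::read.csv(\"%s\", na.strings = \"\")",
            excerpt_path),
    "stopifnot(!anyDuplicated(excerpt$participant_id))",
    "merged <- merge(cohort, excerpt, by = \"participant_id\",",
    "                all.x = TRUE, sort = FALSE)",
    "stopifnot(nrow(merged) == nrow(cohort))",
    ""), collapse = "\n")
  list(script = script, report = report)
}
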