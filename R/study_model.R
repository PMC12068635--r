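#' Bundle the four normalized study tables and the covariate catalog
#'
#' The engine's sole data input is a set of four normalized domain tables plus
#' the covariate catalog:
#' \describe{
#'   \item{participants}{one row per participant: `participant_id`,
#'     `date_of_birth`, `enrollment_date` (baseline survey),
#'     `survey2_date`..`survey6_date` (follow-up surveys, `NA` when never
#'     completed), `vital_status` (`alive`/`dead`/`lost`), `date_of_death`,
#'     `cause_of_death` (ICD), `race_ethnicity`, `end_of_linkage`.}
#'   \item{cancers}{one row per primary cancer: `participant_id`,
#'     `diagnosis_date`, `site_code` (ICD-O-3 topography, e.g. `"C50.9"`),
#'     `histology_code` (4-digit ICD-O-3 morphology), `seer_group`, `stage`,
#'     `grade`, `sequence_number` (1 = first primary).}
#'   \item{hospitalizations}{one row per admission: `participant_id`,
#'     `admission_date`, `discharge_date`, `diagnosis_codes` and
#'     `procedure_codes` (pipe-separated ICD code lists), `length_of_stay`
#'     (days, `discharge - admission`).}
#'   \item{surveys}{one row per participant; one column per survey covariate.
#'     Cells of questionnaires the participant never completed carry the
#'     missing-by-design sentinel (see [is_missing_by_design()]).}
#'   \item{catalog}{the covariate catalog, see [read_catalog()].}
#' }
#'
#' @param participants,cancers,hospitalizations,surveys,catalog data.frames
#'   with the columns described above.
#' @return an object of class `study_tables` (a named list of data.tables).
#' @export
study_tables <- function(participants, cancers, hospitalizations, surveys,
                         catalog) {
  tabs <- list(participants = data.table::as.data.table(participants),
               cancers = data.table::as.data.table(cancers),
               hospitalizations = data.table::as.data.table(hospitalizations),
               surveys = data.table::as.data.table(surveys),
               catalog = data.table::as.data.table(catalog))
  required <- list(
    participants = c("participant_id", "date_of_birth", "enrollment_date",
                     paste0("survey", 2:6, "_date"), "vital_status",
                     "date_of_death", "cause_of_death", "race_ethnicity",
                     "end_of_linkage"),
    cancers = c("participant_id", "diagnosis_date", "site_code",
                "histology_code", "seer_group", "stage", "grade",
                "sequence_number"),
    hospitalizations = c("participant_id", "admission_date", "discharge_date",
                         "diagnosis_codes", "procedure_codes",
                         "length_of_stay"),
    surveys = "participant_id",
    catalog = c("name", "label", "dtype", "value_labels",
                "questionnaire_number", "section", "question_number",
                "essential", "derived"))
  for (nm in names(required)) {
    miss <- setdiff(required[[nm]], names(tabs[[nm]]))
    if (length(miss)) {
      cf_stop("cf_schema_error", "table '", nm, "' is missing column(s): ",
              paste(miss, collapse = ", "))
    }
  }
  structure(tabs, class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  cat("<study_tables>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-17s %8d rows x %d cols\n", nm, nrow(x[[nm]]),
                ncol(x[[nm]])))
  }
  invisible(x)
}

survey_date_col <- function(q) {
  if (q == 1) "enrollment_date" else paste0("survey", q, "_date")
}

# survey covariate names in catalog order; optionally one questionnaire only
catalog_survey_covariates <- function(catalog, questionnaire = NULL) {
  keep <- !catalog$derived & !is.na(catalog$questionnaire_number)
  if (!is.null(questionnaire)) {
    keep <- keep & catalog$questionnaire_number %in% questionnaire
  }
  catalog$name[keep]
}

add_violation <- function(acc, table, rule, ids, detail) {
  if (!length(ids)) return(acc)
  c(acc, list(data.table::data.table(
    table = table, rule = rule, participant_id = as.character(ids),
    detail = detail)))
}

#' Validate study tables against the domain invariants
#'
#' Checks every structural invariant of the domain model: key uniqueness,
#' date ordering (enrollment <= follow-up surveys <= death), the
#' missing-by-design contract (no survey response after death, survey-wave
#' columns marked missing-by-design exactly when that wave was never
#' completed), death-date/vital-status consistency, per-participant cancer
#' sequence numbering, admission/discharge ordering, length-of-stay
#' derivation, and catalog well-formedness.
#'
#' @param tables a [study_tables()] object.
#' @return a `data.table` with one row per violation (columns `table`,
#'   `rule`, `participant_id`, `detail`); zero rows iff all invariants hold.
#' @export
validate_tables <- function(tables) {
  stopifnot(inherits(tables, "study_tables"))
  p <- tables$participants
  viol <- list()

  dup <- unique(p$participant_id[duplicated(p$participant_id)])
  viol <- add_violation(viol, "participants", "duplicate participant_id", dup,
                        "participant_id occurs more than once")

  dead <- !is.na(p$vital_status) & p$vital_status == "dead"
  bad <- p$participant_id[dead & is.na(p$date_of_death)]
  viol <- add_violation(viol, "participants", "death date missing for dead",
                        bad, "vital_status is 'dead' but date_of_death is NA")
  bad <- p$participant_id[!dead & !is.na(p$date_of_death)]
  viol <- add_violation(viol, "participants", "death date without dead status",
                        bad, "date_of_death present but vital_status != 'dead'")

  sdates <- as.matrix(p[, lapply(.SD, as.numeric),
                        .SDcols = paste0("survey", 2:6, "_date")])
  enr <- as.numeric(p$enrollment_date)
  dth <- as.numeric(p$date_of_death)
  bad_before <- rowSums(sdates < enr, na.rm = TRUE) > 0
  viol <- add_violation(viol, "participants", "survey before enrollment",
                        p$participant_id[bad_before],
                        "a follow-up survey date precedes enrollment_date")
  bad_after <- !is.na(dth) & rowSums(sdates > dth, na.rm = TRUE) > 0
  viol <- add_violation(viol, "participants", "missing-by-design breach",
                        p$participant_id[bad_after],
                        "a survey date falls after date_of_death")
  # strictly increasing where present (row-wise over the 5 wave columns)
  nondec <- rep(FALSE, nrow(p))
  for (k in seq_len(ncol(sdates) - 1)) {
    for (j in seq(k + 1, ncol(sdates))) {
      nondec <- nondec | (!is.na(sdates[, k]) & !is.na(sdates[, j]) &
                            sdates[, j] <= sdates[, k])
    }
  }
  viol <- add_violation(viol, "participants", "survey dates not increasing",
                        p$participant_id[nondec],
                        "follow-up survey dates are not strictly increasing")

  ca <- tables$cancers
  if (nrow(ca)) {
    dob <- p$date_of_birth[match(ca$participant_id, p$participant_id)]
    viol <- add_violation(viol, "cancers", "unknown participant",
                          unique(ca$participant_id[is.na(dob) &
                            !ca$participant_id %in% p$participant_id]),
                          "cancer event references an unknown participant_id")
    bad <- ca$participant_id[!is.na(dob) & ca$diagnosis_date < dob]
    viol <- add_violation(viol, "cancers", "diagnosis before birth", bad,
                          "diagnosis_date precedes date_of_birth")
    seqbad <- ca[, .(ok = identical(sort(as.integer(sequence_number)),
                                    seq_len(.N))), by = participant_id]
    viol <- add_violation(viol, "cancers", "sequence numbers not contiguous",
                          seqbad$participant_id[!seqbad$ok],
                          "sequence_number not a permutation of 1..n")
  }

  h <- tables$hospitalizations
  if (nrow(h)) {
    bad <- h$participant_id[h$discharge_date < h$admission_date]
    viol <- add_violation(viol, "hospitalizations", "discharge before admission",
                          unique(bad), "discharge_date precedes admission_date")
    los <- days_between(h$admission_date, h$discharge_date)
    bad <- h$participant_id[!is.na(h$length_of_stay) & h$length_of_stay != los]
    viol <- add_violation(viol, "hospitalizations", "length_of_stay mismatch",
                          unique(bad),
                          "length_of_stay != discharge_date - admission_date")
    bad <- unique(h$participant_id[!h$participant_id %in% p$participant_id])
    viol <- add_violation(viol, "hospitalizations", "unknown participant", bad,
                          "admission references an unknown participant_id")
  }

  cat_ <- tables$catalog
  dupn <- unique(cat_$name[duplicated(cat_$name)])
  viol <- add_violation(viol, "catalog", "duplicate covariate name", dupn,
                        "catalog name not unique")
  is_catg <- cat_$dtype == "categorical"
  has_vl <- !is.na(cat_$value_labels) & nzchar(cat_$value_labels)
  viol <- add_violation(viol, "catalog", "value labels/dtype mismatch",
                        cat_$name[is_catg != has_vl],
                        "value_labels present iff dtype is categorical")
  tag_missing <- !cat_$derived &
    (is.na(cat_$questionnaire_number) | is.na(cat_$section) |
       !nzchar(as.character(cat_$section)) | is.na(cat_$question_number) |
       !nzchar(as.character(cat_$question_number)))
  viol <- add_violation(viol, "catalog", "incomplete questionnaire tags",
                        cat_$name[tag_missing],
                        "non-derived entry lacks questionnaire/section/question tag")

  s <- tables$surveys
  dup <- unique(s$participant_id[duplicated(s$participant_id)])
  viol <- add_violation(viol, "surveys", "duplicate participant row", dup,
                        "more than one survey row for participant")
  bad <- setdiff(s$participant_id, p$participant_id)
  viol <- add_violation(viol, "surveys", "unknown participant", bad,
                        "survey row references an unknown participant_id")
  # missing-by-design closure: wave-k cells are MBD iff wave k never completed
  ord <- match(p$participant_id, s$participant_id)
  for (q in 1:6) {
    cols <- intersect(catalog_survey_covariates(cat_, q), names(s))
    if (!length(cols)) next
    completed <- !is.na(p[[survey_date_col(q)]])
    n_mbd <- rowSums(s[, lapply(.SD, is_missing_by_design), .SDcols = cols])
    n_mbd <- n_mbd[ord]
    bad <- p$participant_id[!is.na(ord) &
                              ((completed & n_mbd > 0) |
                                 (!completed & n_mbd < length(cols)))]
    viol <- add_violation(viol, "surveys",
                          sprintf("missing-by-design closure (survey %d)", q),
                          bad,
                          "wave columns must be missing-by-design iff wave not completed")
  }

  if (!length(viol)) {
    return(data.table::data.table(table = character(), rule = character(),
                                  participant_id = character(),
                                  detail = character()))
  }
  data.table::rbindlist(viol)
}

#' Build the wide, column-oriented presentation table
#'
#' Flattens the normalized domain tables into one row per participant — the
#' wide OLAP-style table the selection engine queries. Columns span the
#' participant fields, the first `k_primaries` cancers flattened by sequence
#' number (`cancer1_*` .. `cancer<k>_*`), every survey covariate in the
#' catalog, and the derived covariates (`bmi` from self-reported height and
#' weight, `smoking_status`). Survey-wave columns of waves a participant
#' never completed carry the missing-by-design marker.
#'
#' @param tables a [study_tables()] object (assumed validated).
#' @param k_primaries number of primaries to flatten (default 3; multiple
#'   primaries are rare).
#' @return a `data.table`, one row per participant.
#' @export
build_presentation_table <- function(tables, k_primaries = 3) {
  stopifnot(inherits(tables, "study_tables"))
  p <- tables$participants
  cat_ <- tables$catalog
  s <- tables$surveys

  cov_cols <- catalog_survey_covariates(cat_)
  miss <- setdiff(cov_cols, names(s))
  if (length(miss)) {
    cf_stop("cf_schema_error", "catalog names covariate(s) absent from the ",
            "survey table: ", paste(head(miss, 5), collapse = ", "))
  }

  wide <- data.table::copy(p)

  # flatten the first k primaries by sequence number
  ca <- tables$cancers
  flat_fields <- c("diagnosis_date", "site_code", "histology_code",
                   "seer_group", "stage", "grade")
  for (i in seq_len(k_primaries)) {
    ci <- ca[ca$sequence_number == i, ]
    m <- match(wide$participant_id, ci$participant_id)
    for (f in flat_fields) {
      wide[[paste0("cancer", i, "_", f)]] <- ci[[f]][m]
    }
  }

  # survey covariates, aligned to the participant rows, wave gaps marked MBD
  m <- match(wide$participant_id, s$participant_id)
  for (q in 1:6) {
    cols <- catalog_survey_covariates(cat_, q)
    if (!length(cols)) next
    not_done <- is.na(wide[[survey_date_col(q)]])
    for (col in cols) {
      x <- s[[col]][m]
      if (is.numeric(x)) x[not_done] <- NaN else x[not_done] <- CF_MBD_TOKEN
      wide[[col]] <- x
    }
  }

  # derived covariates
  if ("bmi" %in% cat_$name) {
    wide$bmi <- derive_bmi(wide[["q1_height_m"]], wide[["q1_weight_kg"]])
  }
  if ("smoking_status" %in% cat_$name && "q1_smoking_status" %in% names(wide)) {
    wide$smoking_status <- wide[["q1_smoking_status"]]
  }
  wide
}

#' Write / read a table as RFC-4180 CSV with missing-by-design markers
#'
#' Serialization is lossless: plain missing cells are written empty,
#' missing-by-design cells are written as the reserved token `".D"`, dates
#' are ISO-8601. `write_table()` refuses to overwrite a read-only file
#' (versioned data deliverables are written read-only).
#'
#' @param table a data.frame.
#' @param path file path.
#' @return `write_table()` returns `path` invisibly; `read_table()` returns a
#'   `data.table` (columns containing the `".D"` token are read as character;
#'   [read_study_tables()] restores numeric types using the catalog).
#' @export
write_table <- function(table, path) {
  if (file.exists(path) && cf_is_readonly(path)) {
    cf_stop("cf_immutability_error",
            "refusing to overwrite read-only file: ", path)
  }
  out <- data.table::as.data.table(table)
  for (col in names(out)) {
    x <- out[[col]]
    if (is.numeric(x) && anyNA(x) && any(is.nan(x))) {
      y <- as.character(x)
      y[is.nan(x)] <- CF_MBD_TOKEN
      data.table::set(out, j = col, value = y)
    }
  }
  data.table::fwrite(out, path, na = "", quote = "auto", dateTimeAs = "ISO",
                     logical01 = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) {
    cf_stop("cf_format_error", "file not found: ", path)
  }
  data.table::fread(path, na.strings = "", integer64 = "double",
                    data.table = TRUE)
}

# restore numeric survey covariates (".D" -> NaN, "" -> NA) after fread
restore_mbd_numeric <- function(dt, cols) {
  for (col in intersect(cols, names(dt))) {
    x <- dt[[col]]
    if (is.character(x)) {
      y <- suppressWarnings(as.numeric(x))
      y[!is.na(x) & x == CF_MBD_TOKEN] <- NaN
      data.table::set(dt, j = col, value = y)
    } else if (is.logical(x)) {
      # an all-missing column has no type evidence in CSV
      data.table::set(dt, j = col, value = as.numeric(x))
    }
  }
  dt
}

as_date_cols <- function(dt, cols) {
  for (col in intersect(cols, names(dt))) {
    data.table::set(dt, j = col, value = as.Date(dt[[col]]))
  }
  dt
}

#' Write / read a full set of study tables
#'
#' The on-disk layout is five CSV files in one directory: `participants.csv`,
#' `cancers.csv`, `hospitalizations.csv`, `surveys.csv`, `catalog.csv`.
#'
#' @param tables a [study_tables()] object.
#' @param dir directory path (created if needed by `write_study_tables()`).
#' @return `read_study_tables()` returns a [study_tables()] object with all
#'   column types (dates, numeric covariates, sentinels) restored.
#' @export
write_study_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "study_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    write_table(tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_study_tables
#' @export
read_study_tables <- function(dir) {
  fp <- function(nm) file.path(dir, paste0(nm, ".csv"))
  for (nm in c("participants", "cancers", "hospitalizations", "surveys",
               "catalog")) {
    if (!file.exists(fp(nm))) {
      cf_stop("cf_format_error", "missing study table file: ", fp(nm))
    }
  }
  p <- read_table(fp("participants"))
  as_date_cols(p, c("date_of_birth", "enrollment_date",
                    paste0("survey", 2:6, "_date"), "date_of_death",
                    "end_of_linkage"))
  p$participant_id <- as.character(p$participant_id)
  for (col in c("vital_status", "cause_of_death", "race_ethnicity")) {
    data.table::set(p, j = col, value = as.character(p[[col]]))
  }
  ca <- read_table(fp("cancers"))
  as_date_cols(ca, "diagnosis_date")
  if (nrow(ca)) ca$participant_id <- as.character(ca$participant_id)
  h <- read_table(fp("hospitalizations"))
  as_date_cols(h, c("admission_date", "discharge_date"))
  if (nrow(h)) {
    h$participant_id <- as.character(h$participant_id)
    h$diagnosis_codes <- as.character(h$diagnosis_codes)
    h$procedure_codes <- as.character(h$procedure_codes)
  }
  cat_ <- read_catalog(fp("catalog"))
  s <- read_table(fp("surveys"))
  s$participant_id <- as.character(s$participant_id)
  numeric_cov <- cat_$name[!cat_$derived &
                             cat_$dtype %in% c("continuous", "categorical",
                                               "flag")]
  restore_mbd_numeric(s, numeric_cov)
  study_tables(p, ca, h, s, cat_)
}
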