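# Deterministic edge-case injection. Each scenario appends one fully
# specified participant so corner cases (same-day event and death, prevalent
# cancer, surgery preceding diagnosis, never-responder, second primary) are
# guaranteed present and findable regardless of the random draw.

cf_scenarios <- function() {
  c("same_day_event_death", "prevalent_cancer", "surgery_before_diagnosis",
    "never_responder", "second_primary")
}

scenario_definition <- function(name, pid) {
  base <- list(
    participant = list(
      participant_id = pid, date_of_birth = as.Date("1950-04-01"),
      enrollment_date = as.Date("1996-06-01"), vital_status = "alive",
      date_of_death = as.Date(NA), cause_of_death = NA_character_,
      race_ethnicity = "1"),
    waves = as.Date(rep(NA, 5)), cancers = NULL, hospitalizations = NULL)
  switch(name,
    same_day_event_death = {
      base$participant$vital_status <- "dead"
      base$participant$date_of_death <- as.Date("2005-06-15")
      base$participant$cause_of_death <- "C50.9"
      base$waves[1] <- as.Date("1998-03-01")
      base$cancers <- data.table::data.table(
        participant_id = pid, diagnosis_date = as.Date("2005-06-15"),
        site_code = "C50.9", histology_code = "8500",
        seer_group = "Breast", stage = "IV", grade = "3",
        sequence_number = 1L)
      base
    },
    prevalent_cancer = {
      base$participant$enrollment_date <- as.Date("1997-01-15")
      base$cancers <- data.table::data.table(
        participant_id = pid, diagnosis_date = as.Date("1994-06-15"),
        site_code = "C50.9", histology_code = "8500",
        seer_group = "Breast", stage = "I", grade = "2",
        sequence_number = 1L)
      base
    },
    surgery_before_diagnosis = {
      base$waves[1] <- as.Date("1998-06-01")
      base$cancers <- data.table::data.table(
        participant_id = pid, diagnosis_date = as.Date("2004-01-01"),
        site_code = "C50.9", histology_code = "8500",
        seer_group = "Breast", stage = "II", grade = "2",
        sequence_number = 1L)
      base$hospitalizations <- data.table::data.table(
        participant_id = pid, admission_date = as.Date("2003-05-10"),
        discharge_date = as.Date("2003-05-14"),
        diagnosis_codes = "D25.9", procedure_codes = "8542",
        length_of_stay = 4L)
      base
    },
    never_responder = {
      base$participant$enrollment_date <- as.Date("1998-05-20")
      base
    },
    second_primary = {
      base$waves[1] <- as.Date("1998-06-01")
      base$waves[2] <- as.Date("2001-06-01")
      base$cancers <- data.table::data.table(
        participant_id = pid,
        diagnosis_date = as.Date(c("2002-03-03", "2006-07-07")),
        site_code = c("C50.9", "C56.9"), histology_code = c("8500", "8441"),
        seer_group = c("Breast", "Ovary"), stage = c("II", "III"),
        grade = c("2", "3"), sequence_number = 1:2)
      base
    },
    cf_stop("cf_spec_error", "unknown scenario patch: ", name))
}

# deterministic survey-response row for a scenario participant
scenario_survey_row <- function(catalog, survey_cols, pid, waves_done) {
  row <- vector("list", length(survey_cols) + 1L)
  names(row) <- c("participant_id", survey_cols)
  row[["participant_id"]] <- pid
  for (col in survey_cols) {
    e <- catalog[catalog$name == col, ]
    q <- e$questionnaire_number
    done <- q == 1L || (q >= 2L && waves_done[q - 1L])
    val <- if (!done) NaN
      else if (e$dtype == "categorical") 1
      else if (e$dtype == "flag") 0
      else if (col == "q1_height_m") 1.65
      else if (col == "q1_weight_kg") 66
      else 50
    row[[col]] <- val
  }
  data.table::as.data.table(row)
}

#' Inject deterministic edge-case scenarios into study tables
#'
#' Appends one fully specified participant per requested scenario:
#' `"same_day_event_death"` (cancer diagnosis on the date of death),
#' `"prevalent_cancer"` (diagnosis before enrollment),
#' `"surgery_before_diagnosis"` (an admission carrying a
#' bilateral-mastectomy procedure code predating a breast cancer),
#' `"never_responder"` (no follow-up surveys), and `"second_primary"`
#' (two primaries with contiguous sequence numbers). The returned tables
#' still pass [validate_tables()].
#'
#' @param tables a [study_tables()] object.
#' @param patches character vector of scenario names.
#' @return the augmented [study_tables()]; the injected ids are in the
#'   `"scenario_ids"` attribute, named by scenario.
#' @export
inject_scenario <- function(tables, patches) {
  stopifnot(inherits(tables, "study_tables"))
  patches <- as.character(unlist(patches))
  bad <- setdiff(patches, cf_scenarios())
  if (length(bad)) {
    cf_stop("cf_spec_error", "unknown scenario patch(es): ",
            paste(bad, collapse = ", "), " (known: ",
            paste(cf_scenarios(), collapse = ", "), ")")
  }
  p <- data.table::copy(tables$participants)
  ca <- data.table::copy(tables$cancers)
  h <- data.table::copy(tables$hospitalizations)
  s <- data.table::copy(tables$surveys)
  catalog <- tables$catalog
  survey_cols <- setdiff(names(s), "participant_id")

  ids <- character(0)
  for (k in seq_along(patches)) {
    pid <- sprintf("SCN%02d_%s", k, patches[k])
    def <- scenario_definition(patches[k], pid)
    if (pid %in% p$participant_id) next
    waves_done <- !is.na(def$waves)
    prow <- data.table::as.data.table(c(
      def$participant[c("participant_id", "date_of_birth",
                        "enrollment_date")],
      setNames(as.list(def$waves), paste0("survey", 2:6, "_date")),
      def$participant[c("vital_status", "date_of_death", "cause_of_death",
                        "race_ethnicity")],
      list(end_of_linkage = p$end_of_linkage[1])))
    data.table::setcolorder(prow, names(p))
    p <- rbind(p, prow)
    if (!is.null(def$cancers)) ca <- rbind(ca, def$cancers)
    if (!is.null(def$hospitalizations)) h <- rbind(h, def$hospitalizations)
    s <- rbind(s, scenario_survey_row(catalog, survey_cols, pid, waves_done))
    ids <- c(ids, setNames(pid, patches[k]))
  }

  # linkage coverage must extend past every injected event
  latest <- max(c(as.numeric(p$date_of_death), as.numeric(ca$diagnosis_date),
                  as.numeric(h$discharge_date),
                  as.numeric(p$enrollment_date)), na.rm = TRUE)
  if (as.numeric(p$end_of_linkage[1]) <= latest) {
    p$end_of_linkage <- as.Date(latest + 1, origin = "1970-01-01")
  }
  data.table::setorderv(ca, c("participant_id", "sequence_number"))
  out <- study_tables(p, ca, h, s, catalog)
  attr(out, "scenario_ids") <- ids
  out
}
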