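#' Exit-status precedence
#'
#' Same-date ties at exit are broken by a fixed precedence:
#' `event > other_cancer > surgery > death > admin_censor`. The ordering
#' favors sensitivity of event capture and makes output deterministic.
#'
#' @return character vector of status levels, highest precedence first.
#' @export
cf_status_levels <- function() {
  c("event", "other_cancer", "surgery", "death", "admin_censor")
}

#' Determine each participant's start of follow-up
#'
#' Follow-up can start at the baseline survey, at any completed follow-up
#' survey wave (participants who never completed that wave are ineligible),
#' or at a fixed calendar date (entered as MM/DD/YYYY or ISO). Under a fixed
#' date, participants who died before it, whose linkage coverage ended
#' before it, or who enrolled after it are ineligible.
#'
#' @param participants the participant table.
#' @param start_rule a list: `list(rule = "baseline")`,
#'   `list(rule = "survey_k", k = 3)`, or
#'   `list(rule = "fixed_date", date = "01/01/2005")`.
#' @return a `Date` vector aligned with `participants` rows; `NA` marks
#'   ineligible participants.
#' @export
determine_start <- function(participants, start_rule) {
  p <- participants
  rule <- start_rule$rule %||% start_rule[[1]]
  if (rule == "baseline") return(p$enrollment_date)
  if (rule == "survey_k") {
    k <- as.integer(start_rule$k)
    if (is.na(k) || k < 2L || k > 6L) {
      cf_stop("cf_spec_error", "survey_k start rule needs k in 2..6")
    }
    return(p[[survey_date_col(k)]])
  }
  if (rule == "fixed_date") {
    d <- parse_user_date(start_rule$date)
    if (is.na(d)) cf_stop("cf_spec_error", "fixed_date start rule needs a date")
    if (d < min(p$enrollment_date) || d > max(p$end_of_linkage)) {
      cf_stop("cf_spec_error", "fixed start date ", format(d),
              " is outside the enrollment-linkage window")
    }
    start <- rep(d, nrow(p))
    dead_before <- !is.na(p$date_of_death) & p$date_of_death < d
    out_of_linkage <- p$end_of_linkage < d
    late_enrollment <- p$enrollment_date > d
    start[dead_before | out_of_linkage | late_enrollment] <- NA
    return(start)
  }
  cf_stop("cf_spec_error", "unknown start rule: ", rule)
}

# endpoint events for a spec endpoint section, over the full history
resolve_spec_endpoint <- function(tables, endpoint,
                                  mapping = load_seer_mapping()) {
  if (is.null(endpoint) || identical(endpoint$type, "none")) return(NULL)
  switch(endpoint$type,
    cancer = resolve_cancer_endpoint(tables$cancers, endpoint, mapping),
    mortality = resolve_mortality_endpoint(tables$participants, endpoint),
    phenotype = {
      res <- resolve_phenotype(tables$hospitalizations,
                               endpoint$phenotypes[[1]])
      data.table::data.table(participant_id = res$participant_id,
                             event_date = res$first_qualifying_date)
    },
    cf_stop("cf_spec_error", "unknown endpoint type: ", endpoint$type))
}

#' Apply eligibility criteria and log attrition
#'
#' Sequentially applies, and logs in order: (1) a valid start of follow-up;
#' (2) alive at start; (3) if `exclude_prevalent_cancer`, no cancer
#' diagnosed before start; (4) any user-supplied extra criteria. An empty
#' cohort raises a warning, never an error.
#'
#' @param tables a [study_tables()] object.
#' @param spec a selection spec ([selection_spec()]).
#' @param starts optional precomputed start dates ([determine_start()]).
#' @param extra named list of functions `f(tables, starts)` returning a
#'   keep-mask over participants.
#' @return `list(included, starts, attrition)`: included participant ids,
#'   their start dates, and the attrition log (`criterion`, `n_excluded`,
#'   `n_remaining`).
#' @export
apply_eligibility <- function(tables, spec, starts = NULL, extra = list()) {
  p <- tables$participants
  if (is.null(starts)) starts <- determine_start(p, spec$start)
  n0 <- nrow(p)
  log_ <- list(data.table::data.table(criterion = "source population",
                                      n_excluded = 0L, n_remaining = n0))
  keep <- rep(TRUE, n0)
  note <- function(label, newkeep) {
    excl <- sum(keep & !newkeep)
    keep <<- keep & newkeep
    log_[[length(log_) + 1L]] <<- data.table::data.table(
      criterion = label, n_excluded = excl, n_remaining = sum(keep))
  }

  note("no valid start of follow-up", !is.na(starts))
  alive <- is.na(p$date_of_death) | p$date_of_death >= starts
  alive[is.na(starts)] <- FALSE
  note("died before start of follow-up", alive)

  if (!is.null(spec$censoring$end_of_study)) {
    eos <- parse_user_date(spec$censoring$end_of_study)
    in_study <- !is.na(starts) & starts <= eos
    note("start of follow-up after end of study", in_study)
  }

  excl_prev <- !is.null(spec$censoring) &&
    !isFALSE(spec$censoring$exclude_prevalent_cancer)
  if (excl_prev) {
    ca <- tables$cancers
    prev_ids <- if (nrow(ca)) {
      st <- starts[match(ca$participant_id, p$participant_id)]
      unique(ca$participant_id[!is.na(st) & ca$diagnosis_date < st])
    } else character()
    note("prevalent cancer before start", !p$participant_id %in% prev_ids)
  }
  for (label in names(extra)) {
    note(label, extra[[label]](tables, starts))
  }
  if (!any(keep)) {
    warning("eligibility criteria exclude every participant; ",
            "the cohort is empty", call. = FALSE)
  }
  list(included = p$participant_id[keep], starts = starts,
       attrition = data.table::rbindlist(log_))
}

#' Resolve one participant's exit
#'
#' Given a start date and a set of candidate exits `(date, status)`, the
#' exit is the earliest candidate on/after start; same-date ties are broken
#' by the fixed precedence [cf_status_levels()]. Candidates before start are
#' ignored. An administrative candidate must always be present.
#'
#' @param start a `Date`.
#' @param candidates a data.frame with columns `date`, `status`.
#' @return `list(exit_date, status, person_days)`.
#' @export
resolve_exit <- function(start, candidates) {
  cand <- data.table::as.data.table(candidates)
  cand <- cand[!is.na(cand$date) & cand$date >= start, ]
  if (!nrow(cand)) {
    cf_stop("cf_internal_error",
            "no exit candidate on/after start (administrative candidate ",
            "is mandatory)")
  }
  cand$rank <- match(cand$status, cf_status_levels())
  data.table::setorderv(cand, c("date", "rank"))
  list(exit_date = cand$date[1], status = cand$status[1],
       person_days = days_between(start, cand$date[1]))
}

# vectorized exit resolution: `cand` has participant_id, date, status
resolve_exits <- function(included, starts, cand) {
  cand <- cand[!is.na(cand$date), ]
  cand <- cand[cand$participant_id %in% included, ]
  st <- starts[match(cand$participant_id, names(starts))]
  cand <- cand[cand$date >= st, ]
  cand$rank <- match(cand$status, cf_status_levels())
  data.table::setorderv(cand, c("participant_id", "date", "rank"))
  first <- cand[, .SD[1L], by = "participant_id"]
  first$rank <- NULL
  first
}

# censoring candidates shared by dataset builders
build_exit_candidates <- function(tables, spec, included, starts_named,
                                  events, mapping, surgery_codes) {
  p <- tables$participants
  endpoint <- spec$endpoint
  end_of_study <- parse_user_date(spec$censoring$end_of_study)
  cand <- list()
  add <- function(ids, dates, status) {
    ok <- !is.na(dates)
    cand[[length(cand) + 1L]] <<- data.table::data.table(
      participant_id = ids[ok], date = dates[ok], status = status)
  }

  # administrative censoring: end of study or end of linkage coverage
  admin <- pmin(rep(end_of_study, nrow(p)), p$end_of_linkage)
  add(p$participant_id, admin, "admin_censor")
  add(p$participant_id, p$date_of_death, "death")

  if (!is.null(events) && nrow(events)) {
    ev <- events[events$event_date <= end_of_study, ]
    add(ev$participant_id, ev$event_date, "event")
  }

  if (isTRUE(spec$censoring$censor_other_cancers)) {
    ca <- tables$cancers
    if (nrow(ca)) {
      other <- if (!is.null(endpoint) && identical(endpoint$type, "cancer")) {
        ca[!cancer_event_matches(ca, endpoint, mapping), ]
      } else ca
      if (nrow(other)) {
        agg <- other[, .(date = min(diagnosis_date)), by = "participant_id"]
        add(agg$participant_id, agg$date, "other_cancer")
      }
    }
  }

  group <- infer_endpoint_group(endpoint)
  auto <- spec$censoring$auto_surgery_censoring %||% (group != "none")
  if (group != "none" && isTRUE(auto)) {
    surg <- surgery_censor_dates(tables$hospitalizations, group,
                                 surgery_codes)
    add(surg$participant_id, surg$surgery_date, "surgery")
  }
  data.table::rbindlist(cand)
}

#' Build a cohort (time-to-event) analytic dataset
#'
#' Applies the full selection spec — endpoint resolution, start of
#' follow-up, eligibility, censoring — and assembles one row per included
#' participant: identifiers, `start_date`, `exit_date`, `status`,
#' `person_days`, endpoint event details (populated only when
#' `status == "event"`), phenotype indicator/date pairs when phenotypes are
#' defined, the 62 essential covariates and every user-selected covariate.
#' Rows with zero days of follow-up are excluded and logged.
#'
#' @param tables a [study_tables()] object.
#' @param spec a complete cohort [selection_spec()].
#' @param wide optional precomputed [build_presentation_table()] output.
#' @param mapping,surgery_codes reference tables (bundled defaults).
#' @return `list(dataset, attrition)`.
#' @export
build_cohort_dataset <- function(tables, spec, wide = NULL,
                                 mapping = load_seer_mapping(),
                                 surgery_codes = load_surgery_codes()) {
  validate_spec(spec, require_complete = TRUE)
  p <- tables$participants
  if (is.null(wide)) wide <- build_presentation_table(tables)

  events <- resolve_spec_endpoint(tables, spec$endpoint, mapping)
  elig <- apply_eligibility(tables, spec)
  included <- elig$included
  starts_named <- setNames(elig$starts, p$participant_id)

  cand <- build_exit_candidates(tables, spec, included, starts_named,
                                events, mapping, surgery_codes)
  exits <- resolve_exits(included, starts_named, cand)
  exits$start_date <- as.Date(starts_named[exits$participant_id])
  exits$person_days <- days_between(exits$start_date, exits$date)

  attrition <- elig$attrition
  zero <- exits$person_days == 0L
  attrition <- rbind(attrition, data.table::data.table(
    criterion = "zero days of follow-up", n_excluded = sum(zero),
    n_remaining = attrition$n_remaining[nrow(attrition)] - sum(zero)))
  exits <- exits[!zero, ]

  ds <- data.table::data.table(
    participant_id = exits$participant_id,
    start_date = exits$start_date,
    exit_date = exits$date,
    status = exits$status,
    person_days = exits$person_days)

  # endpoint detail columns, present only on event rows
  if (!is.null(events) && nrow(events) >= 0 &&
      !identical(spec$endpoint$type %||% "none", "none")) {
    m <- match(ds$participant_id, events$participant_id)
    is_event <- ds$status == "event"
    detail_cols <- setdiff(names(events), "participant_id")
    for (col in detail_cols) {
      x <- events[[col]][m]
      x[!is_event] <- NA
      ds[[col]] <- x
    }
  }

  # one indicator/date pair per defined phenotype, assessed within follow-up
  if (identical(spec$endpoint$type %||% "", "phenotype")) {
    for (ph in spec$endpoint$phenotypes) {
      res <- resolve_phenotype(tables$hospitalizations, as_phenotype(ph))
      m <- match(ds$participant_id, res$participant_id)
      d <- res$first_qualifying_date[m]
      in_window <- !is.na(d) & d >= ds$start_date & d <= ds$exit_date
      ds[[paste0("pheno_", ph$name)]] <- as.integer(in_window)
      dd <- d
      dd[!in_window] <- NA
      ds[[paste0("pheno_", ph$name, "_date")]] <- dd
    }
  }

  cols <- dataset_covariate_columns(tables$catalog, spec)
  m <- match(ds$participant_id, wide$participant_id)
  for (col in cols) {
    if (!col %in% names(ds)) ds[[col]] <- wide[[col]][m]
  }
  list(dataset = ds, attrition = attrition)
}

# covariate columns included in every dataset: cause of death, the essential
# set, then user selections, in catalog order
dataset_covariate_columns <- function(catalog, spec) {
  selected <- select_covariates(catalog, spec_selectors(spec))
  unique(c("cause_of_death", selected))
}

#' Build a cross-sectional analytic dataset
#'
#' Rows are participants enrolled, alive, and under linkage coverage at the
#' reference date; when an endpoint is defined, `endpoint_indicator` marks a
#' qualifying event on/before the reference date. There are no start, exit
#' or person-time columns. With no endpoint section the result is a
#' covariate-only extract.
#'
#' @inheritParams build_cohort_dataset
#' @return `list(dataset, attrition)`.
#' @export
build_cross_sectional_dataset <- function(tables, spec, wide = NULL,
                                          mapping = load_seer_mapping()) {
  ref <- parse_user_date(spec$metadata$reference_date)
  if (is.na(ref)) {
    cf_stop("cf_spec_error",
            "cross-sectional design needs metadata$reference_date")
  }
  p <- tables$participants
  if (is.null(wide)) wide <- build_presentation_table(tables)
  n0 <- nrow(p)
  log_ <- list(data.table::data.table(criterion = "source population",
                                      n_excluded = 0L, n_remaining = n0))
  keep <- p$enrollment_date <= ref
  log_[[2]] <- data.table::data.table(
    criterion = "not yet enrolled at reference date",
    n_excluded = n0 - sum(keep), n_remaining = sum(keep))
  alive <- is.na(p$date_of_death) | p$date_of_death >= ref
  k2 <- keep & alive & p$end_of_linkage >= ref
  log_[[3]] <- data.table::data.table(
    criterion = "dead or out of linkage at reference date",
    n_excluded = sum(keep) - sum(k2), n_remaining = sum(k2))
  keep <- k2
  if (!any(keep)) {
    warning("no participant is eligible at the reference date", call. = FALSE)
  }

  ds <- data.table::data.table(participant_id = p$participant_id[keep])
  events <- resolve_spec_endpoint(tables, spec$endpoint)
  if (!is.null(events)) {
    m <- match(ds$participant_id, events$participant_id)
    d <- events$event_date[m]
    hit <- !is.na(d) & d <= ref
    ds$endpoint_indicator <- as.integer(hit)
    dd <- d
    dd[!hit] <- NA
    ds$event_date <- dd
  }
  cols <- dataset_covariate_columns(tables$catalog, spec)
  m <- match(ds$participant_id, wide$participant_id)
  for (col in cols) {
    if (!col %in% names(ds)) ds[[col]] <- wide[[col]][m]
  }
  list(dataset = ds, attrition = data.table::rbindlist(log_))
}

#' Real-time frequency summaries under a (possibly partial) spec
#'
#' Computes the counts the selection screens display while choices are being
#' made: eligible participants under whatever criteria are present so far,
#' participants with a qualifying endpoint event, the endpoint distribution
#' by SEER site group, and per-category counts (with explicit missing and
#' missing-by-design buckets) for requested categorical covariates.
#'
#' @param tables a [study_tables()] object.
#' @param spec a selection spec; any prefix (endpoint alone, endpoint +
#'   start, ...) is accepted.
#' @param covariates names of categorical covariates to tabulate.
#' @return a list of class `cf_frequency_summary`.
#' @export
summarize_frequencies <- function(tables, spec, covariates = character()) {
  p <- tables$participants
  eligible_ids <- p$participant_id
  if (!is.null(spec$start)) {
    elig <- apply_eligibility(tables, spec)
    eligible_ids <- elig$included
  }
  events <- resolve_spec_endpoint(tables, spec$endpoint)
  event_n <- if (is.null(events)) NA_integer_
             else sum(events$participant_id %in% eligible_ids)

  by_group <- NULL
  if (!is.null(events) && "event_seer_group" %in% names(events)) {
    ev <- events[events$participant_id %in% eligible_ids, ]
    if (nrow(ev)) {
      by_group <- ev[, .N, by = "event_seer_group"]
      data.table::setorderv(by_group, "N", order = -1L)
    }
  }

  cov_tabs <- list()
  if (length(covariates)) {
    s <- tables$surveys
    m <- match(eligible_ids, s$participant_id)
    for (col in covariates) {
      if (!col %in% names(s)) next
      x <- s[[col]][m]
      lab <- ifelse(is_missing_by_design(x), "missing-by-design",
                    ifelse(is.na(x), "missing", as.character(x)))
      tab <- data.table::as.data.table(table(value = lab))
      cov_tabs[[col]] <- tab
    }
  }
  structure(list(total_n = nrow(p), eligible_n = length(eligible_ids),
                 event_n = event_n, endpoint_by_group = by_group,
                 covariate_counts = cov_tabs),
            class = "cf_frequency_summary")
}

#' @export
print.cf_frequency_summary <- function(x, ...) {
  cat("<frequency summary>\n")
  cat("  participants:", x$total_n, " eligible:", x$eligible_n, "\n")
  if (!is.na(x$event_n)) cat("  with qualifying endpoint event:",
                             x$event_n, "\n")
  if (!is.null(x$endpoint_by_group)) {
    cat("  endpoint by site group:\n")
    for (i in seq_len(nrow(x$endpoint_by_group))) {
      cat(sprintf("    %-12s %d\n", x$endpoint_by_group$event_seer_group[i],
                  x$endpoint_by_group$N[i]))
    }
  }
  invisible(x)
}
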