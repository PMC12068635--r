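#' Simulation configuration presets
#'
#' Returns a simulation configuration for one of three scales:
#' \describe{
#'   \item{unit}{100 participants, 150 survey covariates — fast fixtures.}
#'   \item{desk}{10,000 participants, 1200 survey covariates — workstation
#'     scale checks.}
#'   \item{cts_scale}{133,477 participants, 1200 survey covariates, five
#'     follow-up surveys — the full size of the emulated cohort (133,477
#'     women enrolled at baseline between 1995-10-27 and 1999-08-20).}
#' }
#'
#' Event histories use constant hazards (exponential waiting times). The
#' default annual hazards — cancer 0.011/person-year, mortality
#' 0.012/person-year, hospitalization 0.08 admissions/person-year — are
#' chosen so that, over roughly 25 years of follow-up at full scale, the
#' expected numbers of participants with cancer, deaths, and ever-hospitalized
#' participants approximate the emulated cohort's published tallies.
#'
#' @param preset one of `"unit"`, `"desk"`, `"cts_scale"`.
#' @param seed integer seed stored in the configuration; every run logs it.
#' @return an object of class `cf_sim_config`.
#' @examples
#' default_config("unit")$n_participants
#' @export
default_config <- function(preset = c("unit", "desk", "cts_scale"),
                           seed = 1L) {
  if (!is.character(preset) || !preset[1] %in% c("unit", "desk", "cts_scale")) {
    cf_stop("cf_config_error", "unknown preset: ", preset[1])
  }
  preset <- match.arg(preset)
  n <- switch(preset, unit = 100L, desk = 10000L, cts_scale = 133477L)
  ncov <- switch(preset, unit = 150L, desk = 1200L, cts_scale = 1200L)
  structure(list(
    preset = preset,
    n_participants = n,
    enrollment_start = as.Date("1995-10-27"),
    enrollment_end = as.Date("1999-08-20"),
    n_followup_surveys = 5L,
    n_survey_covariates = ncov,
    cancer_hazard = 0.011,
    mortality_hazard = 0.012,
    hospitalization_rate = 0.08,
    surgery_code_fraction = 0.05,
    second_primary_factor = 0.15,
    response_prob = 0.80,
    never_responder_prob = 0.05,
    lost_fraction = 0.02,
    item_nonresponse = 0.03,
    simulation_end = as.Date("2020-12-31"),
    seed = as.integer(seed)
  ), class = "cf_sim_config")
}

validate_config <- function(config) {
  stopifnot(inherits(config, "cf_sim_config"))
  rates <- c(config$cancer_hazard, config$mortality_hazard,
             config$hospitalization_rate, config$surgery_code_fraction)
  if (any(rates < 0)) cf_stop("cf_config_error", "rates must be >= 0")
  if (config$enrollment_start > config$enrollment_end) {
    cf_stop("cf_config_error", "enrollment window start must be <= end")
  }
  if (config$n_followup_surveys < 0 || config$n_followup_surveys > 5) {
    cf_stop("cf_config_error", "n_followup_surveys must be in [0, 5]")
  }
  if (config$n_survey_covariates < 60) {
    cf_stop("cf_config_error", "need at least 60 survey covariates ",
            "(the essential set spans 48 baseline items)")
  }
  if (config$n_participants < 1) {
    cf_stop("cf_config_error", "n_participants must be positive")
  }
  invisible(config)
}

# value-label pools for generated categorical covariates
cf_label_pools <- function() {
  list(
    yn = "1=No|2=Yes",
    freq = "1=Never|2=Rarely|3=Sometimes|4=Often|5=Daily",
    level = "1=Low|2=Medium|3=High",
    agree = "1=Strongly disagree|2=Disagree|3=Agree|4=Strongly agree")
}

#' Build the default synthetic covariate catalog
#'
#' Defines `n_survey` questionnaire covariates spread over the baseline
#' survey and five follow-up waves (the baseline survey carries the largest
#' share), a block of participant-level entries (dates, vital status,
#' race/ethnicity), and two derived covariates (BMI from self-reported
#' height and weight; smoking status). Exactly 62 entries are flagged
#' essential: the participant-level block, the derived pair, and the leading
#' 48 baseline items (which include height, weight and smoking status).
#'
#' @param n_survey number of survey covariates (>= 60).
#' @param n_waves number of follow-up waves with covariates (<= 5).
#' @return a catalog `data.table` ([read_catalog()] layout).
#' @export
build_default_catalog <- function(n_survey = 1200L, n_waves = 5L) {
  n_survey <- as.integer(n_survey)
  q1_n <- max(50L, as.integer(ceiling(n_survey / 3)))
  rest <- n_survey - q1_n
  per_wave <- if (n_waves > 0) rest %/% n_waves else 0L
  wave_n <- if (n_waves > 0) {
    x <- rep(per_wave, n_waves)
    x[1] <- x[1] + rest - sum(x)
    x
  } else integer()

  sections <- c("demographics", "medical_history", "reproductive", "diet",
                "physical_activity", "smoking", "alcohol", "medications",
                "environment")
  pools <- cf_label_pools()

  make_wave <- function(q, n, specials) {
    rows <- list()
    if (specials) {
      rows <- list(data.table::data.table(
        name = c("q1_height_m", "q1_weight_kg", "q1_smoking_status"),
        label = c("Height, self-reported (m)",
                  "Weight, self-reported (kg)", "Smoking status"),
        dtype = c("continuous", "continuous", "categorical"),
        value_labels = c(NA, NA, "1=Never|2=Former|3=Current"),
        questionnaire_number = 1L,
        section = c("anthropometry", "anthropometry", "smoking"),
        question_number = c("1.1", "1.2", "1.3"),
        essential = FALSE, derived = FALSE))
      n <- n - 3L
    }
    i <- seq_len(n)
    sec <- sections[(i - 1L) %% length(sections) + 1L]
    kind <- rep(c("categorical", "continuous", "categorical", "flag",
                  "continuous"), length.out = n)
    pool <- names(pools)[(i - 1L) %% length(pools) + 1L]
    vl <- ifelse(kind == "categorical", unlist(pools)[pool],
                 ifelse(kind == "flag", "0=No|1=Yes", NA))
    # flags carry labels too, so dtype 'flag' keeps value_labels empty:
    vl[kind == "flag"] <- NA
    rows <- c(rows, list(data.table::data.table(
      name = sprintf("q%d_%s_%03d", q, sec, i),
      label = sprintf("Wave %d %s item %d", q, gsub("_", " ", sec), i),
      dtype = kind,
      value_labels = vl,
      questionnaire_number = as.integer(q),
      section = sec,
      question_number = sprintf("%d.%d", q, i + 3L),
      essential = FALSE, derived = FALSE)))
    data.table::rbindlist(rows)
  }

  waves <- list(make_wave(1L, q1_n, specials = TRUE))
  for (q in seq_len(n_waves)) {
    if (wave_n[q] > 0) waves <- c(waves, list(make_wave(q + 1L, wave_n[q],
                                                        specials = FALSE)))
  }
  survey_cat <- data.table::rbindlist(waves)

  participant_cat <- data.table::data.table(
    name = c("date_of_birth", "enrollment_date",
             paste0("survey", 2:6, "_date"), "date_of_death", "vital_status",
             "race_ethnicity", "end_of_linkage"),
    label = c("Date of birth", "Baseline survey (enrollment) date",
              paste("Follow-up survey", 2:6, "date"), "Date of death",
              "Vital status", "Race/ethnicity",
              "End of registry linkage coverage"),
    dtype = c(rep("date", 8L), "categorical", "categorical", "date"),
    value_labels = c(rep(NA, 8L),
                     "alive=Alive|dead=Dead|lost=Lost to follow-up",
                     paste("1=White|2=Black|3=Hispanic|4=Asian/Pacific",
                           "Islander|5=American Indian|6=Other/unknown"),
                     NA),
    questionnaire_number = NA_integer_, section = NA_character_,
    question_number = NA_character_, essential = TRUE, derived = TRUE)

  derived_cat <- data.table::data.table(
    name = c("bmi", "smoking_status"),
    label = c("Body mass index (kg/m2), from self-reported height and weight",
              "Smoking status (baseline)"),
    dtype = c("continuous", "categorical"),
    value_labels = c(NA, "1=Never|2=Former|3=Current"),
    questionnaire_number = NA_integer_, section = NA_character_,
    question_number = NA_character_, essential = TRUE, derived = TRUE)

  cat_ <- data.table::rbindlist(list(participant_cat, derived_cat,
                                     survey_cat))
  n_more <- 62L - sum(cat_$essential)
  q1_names <- cat_$name[!cat_$derived & cat_$questionnaire_number %in% 1L]
  cat_$essential[cat_$name %in% head(q1_names, n_more)] <- TRUE
  cat_
}

# one simulated value column for a catalog row; length n
simulate_covariate_column <- function(entry, n, item_nonresponse) {
  x <- switch(entry$dtype,
    categorical = {
      k <- length(strsplit(entry$value_labels, "|", fixed = TRUE)[[1]])
      as.numeric(sample.int(k, n, replace = TRUE))
    },
    flag = as.numeric(rbinom(n, 1L, 0.25)),
    continuous = {
      if (entry$name == "q1_height_m") round(rnorm(n, 1.63, 0.07), 2)
      else if (entry$name == "q1_weight_kg") round(rnorm(n, 68, 12), 1)
      else round(rnorm(n, 50, 10), 2)
    },
    as.numeric(rnorm(n)))
  if (item_nonresponse > 0) {
    x[runif(n) < item_nonresponse] <- NA_real_
  }
  x
}

#' Generate a synthetic study cohort
#'
#' Draws a complete set of study tables with the structural properties of a
#' large women's prospective cohort: one baseline survey per participant
#' inside the enrollment window, up to five follow-up surveys with
#' missing-by-design gaps (no responses after death), cancer events with
#' ICD-O-3 site/histology/SEER group/stage/grade and contiguous sequence
#' numbers, hospitalizations with ICD diagnosis and procedure codes and
#' derived length of stay, and ICD-coded causes of death. All waiting times
#' are exponential with the configured constant hazards; output is
#' deterministic for a fixed `(config, seed)`.
#'
#' @param config a `cf_sim_config` ([default_config()]).
#' @return a [study_tables()] object that passes [validate_tables()] with an
#'   empty report.
#' @export
generate_cohort <- function(config = default_config("unit")) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  horizon <- config$simulation_end

  ## participants ------------------------------------------------------
  id <- sprintf("CTS%07d", seq_len(n))
  win <- days_between(config$enrollment_start, config$enrollment_end)
  enrollment <- config$enrollment_start + floor(runif(n, 0, win + 1))
  age <- pmin(pmax(rnorm(n, 54, 11), 25), 90)
  dob <- enrollment - round(age * 365.25) - sample.int(365L, n, replace = TRUE)

  # exponential waiting time in days; a zero hazard means the event never fires
  rexp_days <- function(m, annual_hazard) {
    if (annual_hazard <= 0) return(rep(Inf, m))
    round(rexp(m, annual_hazard / 365.25))
  }

  death_offset <- rexp_days(n, config$mortality_hazard)
  death_offset <- pmax(death_offset, 1)
  death_date <- enrollment + death_offset
  dead <- death_date <= horizon
  date_of_death <- as.Date(ifelse(dead, death_date, NA),
                           origin = "1970-01-01")
  vital_status <- ifelse(dead, "dead", "alive")
  lost <- !dead & runif(n) < config$lost_fraction
  vital_status[lost] <- "lost"

  race <- sample(as.character(1:6), n, replace = TRUE,
                 prob = c(0.72, 0.05, 0.10, 0.08, 0.01, 0.04))

  ## follow-up survey waves --------------------------------------------
  # wave offsets (days after baseline); the last wave plus jitter fits the
  # simulation horizon even for the latest enrollees, so a responder who
  # stays alive completes every wave
  wave_base <- c(730, 1825, 3650, 5840, 7400)
  never <- runif(n) < config$never_responder_prob
  wave_dates <- vector("list", 5L)
  for (k in seq_len(5L)) {
    if (k <= config$n_followup_surveys) {
      offs <- wave_base[k] + floor(runif(n, 0, 180))
      d <- enrollment + offs
      responds <- !never & runif(n) < config$response_prob
      ok <- responds & d <= horizon & (!dead | d <= death_date)
      wave_dates[[k]] <- as.Date(ifelse(ok, d, NA), origin = "1970-01-01")
    } else {
      wave_dates[[k]] <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
    }
  }

  participants <- data.table::data.table(
    participant_id = id, date_of_birth = dob, enrollment_date = enrollment,
    survey2_date = wave_dates[[1]], survey3_date = wave_dates[[2]],
    survey4_date = wave_dates[[3]], survey5_date = wave_dates[[4]],
    survey6_date = wave_dates[[5]], vital_status = vital_status,
    date_of_death = date_of_death, cause_of_death = NA_character_,
    race_ethnicity = race, end_of_linkage = as.Date(NA))

  ## cancers ------------------------------------------------------------
  sites <- cf_cancer_sites()
  exposure_end <- as.Date(ifelse(dead, pmin(death_date, horizon), horizon),
                          origin = "1970-01-01")
  draw_events <- function(onset_date, hazard, at_risk) {
    t <- rexp_days(sum(at_risk), hazard)
    d <- onset_date[at_risk] + pmax(t, 1)
    keep <- d <= exposure_end[at_risk]
    list(idx = which(at_risk)[keep], date = d[keep])
  }
  first <- draw_events(enrollment, config$cancer_hazard, rep(TRUE, n))
  second_at_risk <- rep(FALSE, n)
  second_at_risk[first$idx] <- TRUE
  onset2 <- enrollment
  onset2[first$idx] <- first$date
  second <- draw_events(onset2,
                        config$cancer_hazard * config$second_primary_factor,
                        second_at_risk)

  make_cancers <- function(idx, date, seqno) {
    m <- length(idx)
    if (!m) return(NULL)
    si <- sample.int(nrow(sites), m, replace = TRUE, prob = sites$weight)
    hist <- vapply(si, function(j) sample(sites$histology[[j]], 1L),
                   character(1))
    data.table::data.table(
      participant_id = id[idx], diagnosis_date = date,
      site_code = sites$site_code[si], histology_code = hist,
      seer_group = seer_recode(sites$site_code[si], hist),
      stage = sample(c("I", "II", "III", "IV", "unknown"), m, replace = TRUE,
                     prob = c(0.35, 0.3, 0.18, 0.1, 0.07)),
      grade = sample(c("1", "2", "3", "4", "unknown"), m, replace = TRUE,
                     prob = c(0.2, 0.35, 0.25, 0.05, 0.15)),
      sequence_number = seqno)
  }
  cancers <- data.table::rbindlist(list(
    make_cancers(first$idx, first$date, 1L),
    make_cancers(second$idx, second$date, 2L)))
  if (is.null(cancers) || !nrow(cancers)) {
    cancers <- data.table::data.table(
      participant_id = character(), diagnosis_date = as.Date(character()),
      site_code = character(), histology_code = character(),
      seer_group = character(), stage = character(), grade = character(),
      sequence_number = integer())
  }
  data.table::setorderv(cancers, c("participant_id", "sequence_number"))

  # cause of death: cancer deaths carry their cancer's site code
  cause <- rep(NA_character_, n)
  if (any(dead)) {
    first_site <- rep(NA_character_, n)
    if (nrow(cancers)) {
      first_site[first$idx] <-
        cancers$site_code[match(id[first$idx], cancers$participant_id)]
    }
    cancer_death <- dead & !is.na(first_site) & runif(n) < 0.5
    cause[cancer_death] <- first_site[cancer_death]
    other <- dead & is.na(cause)
    cause[other] <- sample(cf_noncancer_causes(), sum(other), replace = TRUE)
  }
  participants$cause_of_death <- cause

  ## hospitalizations ---------------------------------------------------
  exp_days <- days_between(enrollment, exposure_end)
  n_adm <- rpois(n, config$hospitalization_rate * exp_days / 365.25)
  pid <- rep(seq_len(n), n_adm)
  total <- length(pid)
  if (total) {
    admission <- enrollment[pid] +
      floor(runif(total) * pmax(exp_days[pid], 1))
    los <- rgeom(total, 0.35)
    discharge <- admission + los
    dd <- as.numeric(date_of_death)[pid]
    cap <- !is.na(dd) & as.numeric(discharge) > dd
    discharge[cap] <- as.Date(dd[cap], origin = "1970-01-01")
    los <- days_between(admission, discharge)

    dxpool <- cf_hospital_dx_codes()
    ndx <- sample.int(3L, total, replace = TRUE)
    dx <- vapply(ndx, function(k) paste(sample(dxpool, k), collapse = "|"),
                 character(1))
    procpool <- cf_hospital_proc_codes()
    surgery <- load_surgery_codes()
    has_surg <- runif(total) < config$surgery_code_fraction
    proc <- character(total)
    nproc <- sample.int(2L, total, replace = TRUE) - 1L
    for (i in seq_len(total)) {
      p <- if (nproc[i] > 0) sample(procpool, nproc[i]) else character()
      if (has_surg[i]) p <- c(sample(surgery$code, 1L), p)
      proc[i] <- paste(p, collapse = "|")
    }
    hospitalizations <- data.table::data.table(
      participant_id = id[pid], admission_date = admission,
      discharge_date = discharge, diagnosis_codes = dx,
      procedure_codes = proc, length_of_stay = los)
    data.table::setorderv(hospitalizations,
                          c("participant_id", "admission_date"))
  } else {
    hospitalizations <- data.table::data.table(
      participant_id = character(), admission_date = as.Date(character()),
      discharge_date = as.Date(character()), diagnosis_codes = character(),
      procedure_codes = character(), length_of_stay = integer())
  }

  ## end of linkage: last observed event date + 1 day -------------------
  all_dates <- c(as.numeric(enrollment), as.numeric(date_of_death),
                 as.numeric(cancers$diagnosis_date),
                 as.numeric(hospitalizations$discharge_date),
                 unlist(lapply(wave_dates, as.numeric)))
  eol <- as.Date(max(all_dates, na.rm = TRUE) + 1, origin = "1970-01-01")
  participants$end_of_linkage <- eol

  ## survey covariates --------------------------------------------------
  catalog <- build_default_catalog(config$n_survey_covariates,
                                   config$n_followup_surveys)
  cov_entries <- catalog[!catalog$derived & !is.na(catalog$questionnaire_number), ]
  cols <- vector("list", nrow(cov_entries) + 1L)
  names(cols) <- c("participant_id", cov_entries$name)
  cols[["participant_id"]] <- id
  wave_mat <- vapply(wave_dates, function(d) !is.na(d), logical(n))
  if (n == 1L) wave_mat <- matrix(wave_mat, nrow = 1L)
  wave_done <- cbind(rep(TRUE, n), wave_mat)
  for (i in seq_len(nrow(cov_entries))) {
    e <- cov_entries[i, ]
    x <- simulate_covariate_column(e, n, config$item_nonresponse)
    q <- e$questionnaire_number
    if (q > 1L) x[!wave_done[, q]] <- NaN
    cols[[e$name]] <- x
  }
  surveys <- data.table::as.data.table(cols)

  structure(list(participants = participants, cancers = cancers,
                 hospitalizations = hospitalizations, surveys = surveys,
                 catalog = catalog), class = "study_tables")
}
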