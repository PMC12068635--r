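# Shared fixtures and independent oracles. The oracles are deliberately
# naive per-participant linear scans written against the same reference
# data (SEER mapping, surgery code sets) but with independent logic, so
# they can arbitrate the vectorized engine.

unit_tables <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) cache <<- generate_cohort(default_config("unit",
                                                                 seed = seed))
    cache
  }
})

small_config <- function(n, seed = 1, ...) {
  cfg <- default_config("unit", seed = seed)
  cfg$n_participants <- as.integer(n)
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  cfg
}

# hand-built six-participant fixture: one prevalent cancer, one other-cancer
# censored, one endpoint event, one death, one surgery-censored, one
# administratively censored
toy_catalog <- function() build_default_catalog(60L)

toy_tables <- function() {
  catalog <- toy_catalog()
  mk_date <- function(x) as.Date(x)
  ids <- paste0("P", 1:6)
  p <- data.table::data.table(
    participant_id = ids,
    date_of_birth = mk_date("1950-01-01"),
    enrollment_date = mk_date("1996-01-01"),
    survey2_date = mk_date(NA), survey3_date = mk_date(NA),
    survey4_date = mk_date(NA), survey5_date = mk_date(NA),
    survey6_date = mk_date(NA),
    vital_status = c("alive", "alive", "alive", "dead", "alive", "alive"),
    date_of_death = mk_date(c(NA, NA, NA, "2004-04-04", NA, NA)),
    cause_of_death = c(NA, NA, NA, "I21.0", NA, NA),
    race_ethnicity = "1",
    end_of_linkage = mk_date("2021-01-01"))
  cancers <- data.table::data.table(
    participant_id = c("P1", "P2", "P3"),
    diagnosis_date = mk_date(c("1995-05-05", "2003-03-03", "2005-05-05")),
    site_code = c("C50.9", "C34.9", "C50.9"),
    histology_code = c("8500", "8140", "8500"),
    seer_group = c("Breast", "Lung", "Breast"),
    stage = "II", grade = "2", sequence_number = 1L)
  hosp <- data.table::data.table(
    participant_id = "P5",
    admission_date = mk_date("2002-02-02"),
    discharge_date = mk_date("2002-02-06"),
    diagnosis_codes = "D25.9", procedure_codes = "8542",
    length_of_stay = 4L)
  cols <- setdiff(
    catalog$name[!catalog$derived & !is.na(catalog$questionnaire_number)],
    character(0))
  surveys <- data.table::rbindlist(lapply(ids, function(pid)
    cohortforge:::scenario_survey_row(catalog, cols, pid, rep(FALSE, 5))))
  study_tables(p, cancers, hosp, surveys, catalog)
}

toy_spec <- function(...) {
  args <- list(...)
  base <- list(
    endpoint = list(type = "cancer", site_prefixes = "C50"),
    start = list(rule = "baseline"),
    censoring = list(end_of_study = "2010-12-31",
                     censor_other_cancers = TRUE,
                     exclude_prevalent_cancer = TRUE),
    metadata = list(project = "toy"))
  base[names(args)] <- args
  do.call(selection_spec, base)
}

## ------------------------------------------------------------------ oracles

# independent SEER recode: first matching row by priority, else "other"
oracle_seer <- function(site, hist, mapping = load_seer_mapping()) {
  s <- gsub(".", "", toupper(trimws(site)), fixed = TRUE)
  for (i in seq_len(nrow(mapping))) {
    if (s >= mapping$site_low[i] && s <= mapping$site_high[i] &&
        hist >= mapping$hist_low[i] && hist <= mapping$hist_high[i]) {
      return(mapping$group[i])
    }
  }
  "other"
}

oracle_norm <- function(x) gsub(".", "", toupper(trimws(x)), fixed = TRUE)

oracle_prefix_hit <- function(code, prefixes) {
  if (!length(prefixes)) return(FALSE)
  code <- oracle_norm(code)
  for (p in prefixes) {
    if (substr(code, 1, nchar(p)) == p) return(TRUE)
  }
  FALSE
}

oracle_cancer_match <- function(row, ep) {
  hit <- oracle_prefix_hit(row$site_code, ep$site_prefixes)
  if (!hit && length(ep$seer_groups)) {
    grp <- row$seer_group
    if (is.na(grp) || !nzchar(grp)) {
      grp <- oracle_seer(row$site_code, row$histology_code)
    }
    hit <- grp %in% ep$seer_groups
  }
  if (hit && length(ep$histology_include)) {
    hit <- row$histology_code %in% ep$histology_include
  }
  if (hit && length(ep$histology_exclude)) {
    hit <- !row$histology_code %in% ep$histology_exclude
  }
  hit
}

# first qualifying cancer event per participant, earliest date then lowest
# sequence number
oracle_resolve_cancer <- function(cancers, ep) {
  out <- list()
  by_pid <- split(as.data.frame(cancers), cancers$participant_id)
  for (pid in names(by_pid)) {
    ev <- by_pid[[pid]]
    best <- NULL
    for (i in seq_len(nrow(ev))) {
      if (!oracle_cancer_match(ev[i, ], ep)) next
      if (is.null(best) || ev$diagnosis_date[i] < best$diagnosis_date ||
          (ev$diagnosis_date[i] == best$diagnosis_date &&
             ev$sequence_number[i] < best$sequence_number)) {
        best <- ev[i, ]
      }
    }
    if (!is.null(best)) out[[pid]] <- best
  }
  out
}

# linear-scan exit resolution: earliest candidate on/after start, precedence
# event > other_cancer > surgery > death > admin_censor on ties
oracle_exit <- function(start, dates, statuses) {
  prec <- c(event = 1, other_cancer = 2, surgery = 3, death = 4,
            admin_censor = 5)
  keep <- !is.na(dates) & dates >= start
  dates <- dates[keep]; statuses <- statuses[keep]
  if (!length(dates)) return(NULL)
  best <- 1L
  for (i in seq_along(dates)) {
    if (dates[i] < dates[best] ||
        (dates[i] == dates[best] && prec[statuses[i]] < prec[statuses[best]])) {
      best <- i
    }
  }
  list(exit_date = dates[best], status = statuses[best])
}

oracle_surgery_group <- function(ep) {
  if (is.null(ep) || !identical(ep$type, "cancer")) return("none")
  pfx <- ep$site_prefixes
  grp <- tolower(ep$seer_groups)
  test <- function(stems, label) {
    for (s in stems) {
      for (q in pfx) {
        if (substr(q, 1, nchar(s)) == s || substr(s, 1, nchar(q)) == q) {
          return(TRUE)
        }
      }
    }
    label %in% grp
  }
  if (test("C50", "breast")) return("breast")
  if (test(c("C54", "C55"), "uterus")) return("uterus")
  if (test("C56", "ovary")) return("ovary")
  "none"
}

# full per-participant brute force of the cohort build: eligibility, every
# censoring source, exit resolution; returns id/start/exit/status rows
oracle_cohort <- function(tables, spec,
                          surgery_codes = load_surgery_codes()) {
  p <- tables$participants
  ep <- spec$endpoint
  eos <- as.Date(spec$censoring$end_of_study)
  empty_ca <- as.data.frame(tables$cancers)[0, ]
  ca_split <- split(as.data.frame(tables$cancers),
                    tables$cancers$participant_id)
  empty_h <- as.data.frame(tables$hospitalizations)[0, ]
  h_split <- split(as.data.frame(tables$hospitalizations),
                   tables$hospitalizations$participant_id)
  rows <- list()
  for (i in seq_len(nrow(p))) {
    pid <- p$participant_id[i]
    start <- switch(spec$start$rule,
      baseline = p$enrollment_date[i],
      survey_k = p[[paste0("survey", spec$start$k, "_date")]][i],
      fixed_date = {
        d <- as.Date(spec$start$date)
        dead_before <- !is.na(p$date_of_death[i]) && p$date_of_death[i] < d
        if (dead_before || p$end_of_linkage[i] < d ||
            p$enrollment_date[i] > d) as.Date(NA) else d
      })
    if (is.na(start)) next
    if (!is.na(p$date_of_death[i]) && p$date_of_death[i] < start) next
    if (start > eos) next
    ca <- ca_split[[pid]] %||% empty_ca
    if (!isFALSE(spec$censoring$exclude_prevalent_cancer) &&
        nrow(ca) && any(ca$diagnosis_date < start)) next

    dates <- min(eos, p$end_of_linkage[i])
    statuses <- "admin_censor"
    if (!is.na(p$date_of_death[i])) {
      dates <- c(dates, p$date_of_death[i]); statuses <- c(statuses, "death")
    }
    # endpoint event
    ev_date <- as.Date(NA)
    if (!is.null(ep) && ep$type == "cancer") {
      matched <- logical(nrow(ca))
      for (j in seq_len(nrow(ca))) matched[j] <- oracle_cancer_match(ca[j, ], ep)
      mdates <- ca$diagnosis_date[matched]
      mdates <- mdates[mdates <= eos]
      if (length(mdates)) ev_date <- min(mdates)
    } else if (!is.null(ep) && ep$type == "mortality") {
      if (!is.na(p$date_of_death[i])) {
        ok <- if (!length(ep$cause_prefixes)) TRUE
              else !is.na(p$cause_of_death[i]) &&
                oracle_prefix_hit(p$cause_of_death[i], ep$cause_prefixes)
        if (ok && p$date_of_death[i] <= eos) ev_date <- p$date_of_death[i]
      }
    } else if (!is.null(ep) && ep$type == "phenotype") {
      ph <- ep$phenotypes[[1]]
      h <- h_split[[pid]] %||% empty_h
      h <- h[order(h$admission_date), ]
      qd <- as.Date(character())
      for (j in seq_len(nrow(h))) {
        cl <- strsplit(h$diagnosis_codes[j], "|", fixed = TRUE)[[1]]
        if (identical(ph$position_rule, "principal_only")) cl <- cl[1]
        hit <- any(vapply(cl, oracle_prefix_hit, logical(1),
                          prefixes = ph$diagnosis_prefixes))
        if (hit && h$length_of_stay[j] >= (ph$min_length_of_stay %||% 0)) {
          qd <- c(qd, h$admission_date[j])
        }
      }
      k <- ph$min_qualifying_admissions %||% 1
      if (length(qd) >= k && qd[k] <= eos) ev_date <- qd[k]
    }
    if (!is.na(ev_date)) {
      dates <- c(dates, ev_date); statuses <- c(statuses, "event")
    }
    # other-cancer censoring
    if (isTRUE(spec$censoring$censor_other_cancers) && nrow(ca)) {
      other <- if (!is.null(ep) && ep$type == "cancer") {
        keep <- logical(nrow(ca))
        for (j in seq_len(nrow(ca))) keep[j] <- !oracle_cancer_match(ca[j, ], ep)
        ca$diagnosis_date[keep]
      } else ca$diagnosis_date
      if (length(other)) {
        dates <- c(dates, min(other)); statuses <- c(statuses, "other_cancer")
      }
    }
    # automatic surgery censoring
    grp <- oracle_surgery_group(ep)
    auto <- if (is.null(spec$censoring$auto_surgery_censoring)) grp != "none"
            else isTRUE(spec$censoring$auto_surgery_censoring)
    if (grp != "none" && auto) {
      wanted <- surgery_codes$code[surgery_codes$endpoint_group == grp]
      h <- h_split[[pid]] %||% empty_h
      sd <- as.Date(character())
      for (j in seq_len(nrow(h))) {
        cl <- strsplit(h$procedure_codes[j], "|", fixed = TRUE)[[1]]
        if (any(oracle_norm(cl) %in% wanted)) sd <- c(sd, h$admission_date[j])
      }
      if (length(sd)) {
        dates <- c(dates, min(sd)); statuses <- c(statuses, "surgery")
      }
    }
    res <- oracle_exit(start, dates, statuses)
    if (is.null(res) || res$exit_date == start) next
    rows[[pid]] <- data.table::data.table(
      participant_id = pid, start_date = start, exit_date = res$exit_date,
      status = res$status)
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out)) data.table::setorderv(out, "participant_id")
  out
}

# a random but valid selection spec drawn from the current RNG state
random_spec <- function(tag = "rand") {
  ep <- switch(sample(c("cancer", "cancer", "mortality", "phenotype"), 1),
    cancer = {
      e <- list(type = "cancer")
      if (runif(1) < 0.8) {
        e$site_prefixes <- sample(c("C50", "C34", "C18", "C5", "C56", "C64",
                                    "C44", "C509"),
                                  sample(1:2, 1))
      }
      if (is.null(e$site_prefixes) || runif(1) < 0.3) {
        e$seer_groups <- sample(c("Breast", "Ovary", "Colon", "Lung",
                                  "Melanoma"), sample(1:2, 1))
      }
      if (runif(1) < 0.3) e$histology_exclude <- sample(c("8520", "8480"), 1)
      if (runif(1) < 0.15) e$histology_include <- c("8500", "8140", "8380",
                                                    "8441", "8720", "8312")
      e
    },
    mortality = list(type = "mortality",
                     cause_prefixes = if (runif(1) < 0.5) character()
                                      else sample(c("I", "C", "J", "I21"),
                                                  sample(1:2, 1))),
    phenotype = list(type = "phenotype", phenotypes = list(list(
      name = "pheno_a",
      diagnosis_prefixes = sample(c("I21", "I50", "J18", "K80", "N39", "I"),
                                  sample(1:2, 1)),
      min_length_of_stay = sample(0:3, 1),
      min_qualifying_admissions = sample(1:2, 1),
      position_rule = sample(c("any_listed", "principal_only"), 1)))))
  start <- switch(sample(c("baseline", "baseline", "survey_k", "fixed_date"),
                         1),
    baseline = list(rule = "baseline"),
    survey_k = list(rule = "survey_k", k = sample(2:4, 1)),
    fixed_date = list(rule = "fixed_date", date = "01/01/2005"))
  selection_spec(
    endpoint = ep, start = start,
    censoring = list(
      end_of_study = sample(c("2008-12-31", "2012-12-31", "2016-12-31",
                              "2019-12-31"), 1),
      censor_other_cancers = runif(1) < 0.5,
      exclude_prevalent_cancer = runif(1) < 0.7),
    covariates = if (runif(1) < 0.4)
      list(list(type = "search", value = "smok")) else list(),
    metadata = list(project = tag))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
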