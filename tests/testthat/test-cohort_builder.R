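test_that("start-of-follow-up rules resolve dates and eligibility", {
  tab <- toy_tables()
  tab$participants$survey3_date[2] <- as.Date("2001-03-03")
  tab$participants$survey2_date[2] <- as.Date("1998-02-02")

  expect_identical(determine_start(tab$participants,
                                   list(rule = "baseline")),
                   tab$participants$enrollment_date)
  s3 <- determine_start(tab$participants, list(rule = "survey_k", k = 3))
  expect_identical(s3[2], as.Date("2001-03-03"))
  expect_true(all(is.na(s3[-2])))  # never completed wave 3 -> ineligible

  # user-convention date entry is normalized
  fx <- determine_start(tab$participants,
                        list(rule = "fixed_date", date = "01/01/2005"))
  expect_identical(fx[1], as.Date("2005-01-01"))
  # P4 died 2004-04-04, before the fixed start
  expect_true(is.na(fx[4]))
  expect_error(
    determine_start(tab$participants,
                    list(rule = "fixed_date", date = "01/01/1970")),
    class = "cf_spec_error")
})

test_that("eligibility is sequential, logged, and toggleable", {
  tab <- toy_tables()
  elig <- apply_eligibility(tab, toy_spec())
  expect_false("P1" %in% elig$included)  # prevalent cancer
  expect_identical(
    elig$attrition$n_excluded[
      elig$attrition$criterion == "prevalent cancer before start"], 1L)
  expect_identical(elig$attrition$n_remaining[1], 6L)
  expect_true(all(diff(elig$attrition$n_remaining) <= 0))

  keep <- apply_eligibility(tab, toy_spec(censoring = list(
    end_of_study = "2010-12-31", censor_other_cancers = TRUE,
    exclude_prevalent_cancer = FALSE)))
  expect_true("P1" %in% keep$included)

  # with no criteria beyond a valid start, everyone with a start is in
  all_in <- apply_eligibility(tab, selection_spec(start = list(rule = "baseline")))
  expect_setequal(all_in$included, tab$participants$participant_id)
})

test_that("exit resolution picks the earliest candidate with fixed tie precedence", {
  start <- as.Date("2000-01-01")
  res <- resolve_exit(start, data.frame(
    date = as.Date(c("2005-03-01", "2005-03-01", "2010-12-31")),
    status = c("death", "event", "admin_censor")))
  expect_identical(res$status, "event")
  expect_identical(res$person_days, as.integer(as.Date("2005-03-01") - start))

  only_admin <- resolve_exit(start, data.frame(
    date = as.Date("2010-12-31"), status = "admin_censor"))
  expect_identical(only_admin$status, "admin_censor")

  # candidates before start are ignored; an empty set is an internal error
  expect_error(resolve_exit(start, data.frame(
    date = as.Date("1999-01-01"), status = "admin_censor")),
    class = "cf_internal_error")

  # randomized agreement with the linear-scan oracle
  set.seed(31)
  statuses <- cf_status_levels()
  for (i in 1:50) {
    k <- sample(1:5, 1)
    cand <- data.frame(
      date = start + sample(-50:400, k, replace = TRUE),
      status = sample(statuses, k, replace = TRUE))
    cand <- rbind(cand, data.frame(date = as.Date("2010-12-31"),
                                   status = "admin_censor"))
    got <- resolve_exit(start, cand)
    want <- oracle_exit(start, cand$date, cand$status)
    expect_identical(got$exit_date, want$exit_date)
    expect_identical(got$status, want$status)
  }
})

test_that("the six-participant fixture resolves to the hand-derived statuses", {
  tab <- toy_tables()
  built <- build_cohort_dataset(tab, toy_spec())
  ds <- built$dataset
  # hand-resolved by linear scan: P1 prevalent (excluded); P2 censored at
  # its non-qualifying lung cancer; P3 breast event; P4 dies; P5 censored
  # at bilateral mastectomy (automatic for a breast endpoint); P6 reaches
  # the end of study
  expect_false("P1" %in% ds$participant_id)
  status <- setNames(ds$status, ds$participant_id)
  expect_identical(status[["P2"]], "other_cancer")
  expect_identical(status[["P3"]], "event")
  expect_identical(status[["P4"]], "death")
  expect_identical(status[["P5"]], "surgery")
  expect_identical(status[["P6"]], "admin_censor")
  expect_identical(ds$exit_date[ds$participant_id == "P5"],
                   as.Date("2002-02-02"))
  expect_identical(ds$exit_date[ds$participant_id == "P6"],
                   as.Date("2010-12-31"))
  # event details populated only on event rows
  expect_identical(ds$event_site[ds$participant_id == "P3"], "C50.9")
  expect_true(all(is.na(ds$event_site[ds$participant_id != "P3"])))
  # the full brute-force oracle agrees
  orc <- oracle_cohort(tab, toy_spec())
  got <- ds[, c("participant_id", "start_date", "exit_date", "status")]
  data.table::setorderv(got, "participant_id")
  expect_equal(as.data.frame(got), as.data.frame(orc))
})

test_that("person-days are exact calendar arithmetic over the follow-up window", {
  tab <- toy_tables()
  tab$participants$enrollment_date <- as.Date("1995-10-27")
  spec <- toy_spec(
    endpoint = list(type = "mortality", cause_prefixes = "X99"),
    censoring = list(end_of_study = "1999-08-20",
                     censor_other_cancers = FALSE,
                     exclude_prevalent_cancer = FALSE))
  ds <- build_cohort_dataset(tab, spec)$dataset
  p6 <- ds[ds$participant_id == "P6", ]
  expect_identical(p6$status, "admin_censor")
  expect_identical(p6$person_days,
                   as.integer(as.Date("1999-08-20") - as.Date("1995-10-27")))
  expect_identical(p6$person_days, 1393L)
})

test_that("surgery censoring before diagnosis wins over the later event", {
  tab <- inject_scenario(generate_cohort(small_config(50, seed = 8)),
                         "surgery_before_diagnosis")
  sg <- attr(tab, "scenario_ids")[["surgery_before_diagnosis"]]
  ds <- build_cohort_dataset(tab, toy_spec(censoring = list(
    end_of_study = "2015-12-31", censor_other_cancers = TRUE)))$dataset
  row <- ds[ds$participant_id == sg, ]
  expect_identical(row$status, "surgery")
  expect_identical(row$exit_date, as.Date("2003-05-10"))
})

test_that("phenotype endpoints add one indicator/date pair per phenotype", {
  tab <- generate_cohort(small_config(300, seed = 21))
  spec <- selection_spec(
    endpoint = list(type = "phenotype", phenotypes = list(
      list(name = "heart_failure", diagnosis_prefixes = "I50"),
      list(name = "pneumonia", diagnosis_prefixes = "J18",
           min_length_of_stay = 2L))),
    start = list(rule = "baseline"),
    censoring = list(end_of_study = "2018-12-31",
                     censor_other_cancers = FALSE),
    metadata = list(project = "pheno"))
  ds <- build_cohort_dataset(tab, spec)$dataset
  expect_true(all(c("pheno_heart_failure", "pheno_heart_failure_date",
                    "pheno_pneumonia", "pheno_pneumonia_date") %in%
                    names(ds)))
  # the indicator is confined to the follow-up window
  flagged <- ds[ds$pheno_pneumonia == 1L, ]
  expect_true(all(flagged$pheno_pneumonia_date >= flagged$start_date &
                    flagged$pheno_pneumonia_date <= flagged$exit_date))
  # first phenotype drives the event status
  ev <- ds[ds$status == "event", ]
  expect_true(all(ev$pheno_heart_failure == 1L))
  expect_true(all(ev$event_date == ev$exit_date))
})

test_that("no-censoring cross-sectional indicator matches the cohort event count", {
  cfg <- small_config(400, seed = 13, mortality_hazard = 0)
  tab <- generate_cohort(cfg)
  endpoint <- list(type = "cancer", site_prefixes = "C18")
  ref <- "2015-12-31"
  coh <- build_cohort_dataset(tab, selection_spec(
    endpoint = endpoint, start = list(rule = "baseline"),
    censoring = list(end_of_study = ref, censor_other_cancers = FALSE,
                     exclude_prevalent_cancer = FALSE),
    metadata = list(project = "eq")))$dataset
  xs <- build_cross_sectional_dataset(tab, selection_spec(
    endpoint = endpoint,
    metadata = list(project = "eq", design = "cross_sectional",
                    reference_date = ref)))$dataset
  expect_identical(sum(xs$endpoint_indicator), sum(coh$status == "event"))
  expect_false(any(c("start_date", "exit_date", "person_days") %in%
                     names(xs)))
})

test_that("cross-sectional eligibility excludes the dead and supports covariate-only extracts", {
  tab <- toy_tables()
  spec <- selection_spec(
    endpoint = list(type = "cancer", site_prefixes = "C50"),
    metadata = list(project = "xs", design = "cross_sectional",
                    reference_date = "2010-06-30"))
  ds <- build_cross_sectional_dataset(tab, spec)$dataset
  expect_false("P4" %in% ds$participant_id)  # died 2004
  expect_identical(ds$endpoint_indicator[ds$participant_id == "P3"], 1L)
  expect_identical(ds$endpoint_indicator[ds$participant_id == "P6"], 0L)

  # no endpoint section: a covariate-only extract
  cov_only <- build_cross_sectional_dataset(tab, selection_spec(
    metadata = list(project = "xs", design = "cross_sectional",
                    reference_date = "2010-06-30")))$dataset
  expect_false("endpoint_indicator" %in% names(cov_only))
  expect_true("bmi" %in% names(cov_only))

  expect_warning(build_cross_sectional_dataset(tab, selection_spec(
    metadata = list(project = "xs", design = "cross_sectional",
                    reference_date = "1980-01-01"))), "eligible")
})

test_that("frequency summaries honor spec prefixes and are monotone", {
  tab <- unit_tables()
  # empty spec: everyone eligible
  s0 <- summarize_frequencies(tab, selection_spec())
  expect_identical(s0$eligible_n, nrow(tab$participants))
  expect_true(is.na(s0$event_n))

  # endpoint only: events counted over all participants
  ep <- list(type = "cancer", site_prefixes = "C50")
  s1 <- summarize_frequencies(tab, selection_spec(endpoint = ep))
  expect_identical(s1$event_n,
                   nrow(resolve_cancer_endpoint(tab$cancers,
                                                cancer_endpoint("C50"))))
  # adding criteria never grows the eligible pool
  s2 <- summarize_frequencies(tab, selection_spec(
    endpoint = ep, start = list(rule = "survey_k", k = 3)))
  expect_lte(s2$eligible_n, s1$eligible_n)
  s3 <- summarize_frequencies(tab, selection_spec(
    endpoint = ep, start = list(rule = "survey_k", k = 3),
    censoring = list(end_of_study = "2015-12-31")))
  expect_lte(s3$eligible_n, s2$eligible_n)

  # categorical counts include explicit missing buckets and sum to eligible
  sc <- summarize_frequencies(tab, selection_spec(endpoint = ep),
                              covariates = "q2_demographics_001")
  counts <- sc$covariate_counts[["q2_demographics_001"]]
  expect_identical(sum(counts$N), sc$eligible_n)
  expect_true("missing-by-design" %in% counts$value)
  # idempotent
  sc2 <- summarize_frequencies(tab, selection_spec(endpoint = ep),
                               covariates = "q2_demographics_001")
  expect_identical(sc2$covariate_counts, sc$covariate_counts)
})
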