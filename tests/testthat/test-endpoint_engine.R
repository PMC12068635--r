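test_that("ICD codes normalize to a canonical matching form", {
  expect_identical(normalize_icd("c50.9"), "C509")
  expect_identical(normalize_icd(" I21 "), "I21")
  expect_identical(normalize_icd(c("C50.4", "8542")), c("C504", "8542"))
  expect_error(normalize_icd(""), class = "cf_code_format_error")
  expect_error(normalize_icd("C50-9!"), class = "cf_code_format_error")
})

test_that("prefix matching is leading-substring matching", {
  expect_true(icd_prefix_match("C509", "C50"))
  expect_false(icd_prefix_match("C509", "C501"))
  expect_true(icd_prefix_match("C50", "C50"))
  expect_identical(icd_prefix_match(c("C509", "I219", "J189"),
                                    c("C50", "I21")),
                   c(TRUE, TRUE, FALSE))
  expect_false(icd_prefix_match("C509", character()))
})

test_that("the bundled SEER recode maps the expected site groups", {
  expect_identical(seer_recode("C50.4", "8500"), "Breast")
  expect_identical(seer_recode("C56.9", "8000"), "Ovary")
  expect_identical(seer_recode("C99.9", "8000"), "other")
  # histology override: melanoma of the skin beats the site fallback
  expect_identical(seer_recode("C44.5", "8720"), "Melanoma")
  expect_identical(seer_recode("C44.5", "8070"), "other")
  expect_identical(seer_recode(c("C54.1", "C34.9", "C18.9"),
                               c("8380", "8140", "8140")),
                   c("Uterus", "Lung", "Colon"))
})

test_that("cancer endpoints resolve to the earliest qualifying event", {
  ca <- data.table::data.table(
    participant_id = c("A", "A", "B", "C", "C"),
    diagnosis_date = as.Date(c("2003-01-01", "2001-06-01", "2002-02-02",
                               "2004-04-04", "2004-04-04")),
    site_code = c("C50.9", "C34.1", "C50.2", "C50.9", "C50.4"),
    histology_code = c("8500", "8140", "8520", "8500", "8500"),
    seer_group = c("Breast", "Lung", "Breast", "Breast", "Breast"),
    stage = "II", grade = "2", sequence_number = c(1L, 2L, 1L, 2L, 1L))

  ep <- cancer_endpoint(site_prefixes = "C50")
  res <- resolve_cancer_endpoint(ca, ep)
  # A's lung 2001 does not qualify: the 2003 breast event is returned
  expect_identical(res$event_date[res$participant_id == "A"],
                   as.Date("2003-01-01"))
  # same-day tie broken by lowest sequence number
  expect_identical(res$event_sequence[res$participant_id == "C"], 1L)
  expect_identical(res$event_site[res$participant_id == "C"], "C50.4")

  # histology exclusion removes B's only event
  ep2 <- cancer_endpoint(site_prefixes = "C50", histology_exclude = "8520")
  res2 <- resolve_cancer_endpoint(ca, ep2)
  expect_false("B" %in% res2$participant_id)

  # selection by SEER group alone
  ep3 <- cancer_endpoint(seer_groups = "Breast")
  res3 <- resolve_cancer_endpoint(ca, ep3)
  expect_setequal(res3$participant_id, c("A", "B", "C"))

  expect_error(cancer_endpoint(), class = "cf_spec_error")
  expect_error(cancer_endpoint(site_prefixes = "C50",
                               histology_include = "8500",
                               histology_exclude = "8500"),
               class = "cf_spec_error")
})

test_that("mortality endpoints gate on vital status and cause prefix", {
  p <- data.table::data.table(
    participant_id = c("A", "B", "C"),
    vital_status = c("dead", "alive", "dead"),
    date_of_death = as.Date(c("2010-01-01", NA, "2012-02-02")),
    cause_of_death = c("I21.0", NA, "C50.9"))
  res <- resolve_mortality_endpoint(p, mortality_endpoint("I21"))
  expect_identical(res$participant_id, "A")
  expect_identical(res$event_date, as.Date("2010-01-01"))
  # empty prefix set = all-cause
  res_all <- resolve_mortality_endpoint(p, mortality_endpoint())
  expect_setequal(res_all$participant_id, c("A", "C"))
})

test_that("hospitalization phenotypes honor stay, count and position rules", {
  h <- data.table::data.table(
    participant_id = c("A", "A", "A", "B", "C"),
    admission_date = as.Date(c("2001-01-01", "2003-03-03", "2005-05-05",
                               "2002-02-02", "2004-04-04")),
    discharge_date = as.Date(c("2001-01-04", "2003-03-04", "2005-05-12",
                               "2002-02-03", "2004-04-05")),
    diagnosis_codes = c("I50.9|E11.9", "I50.1", "J18.9|I50.9", "I50.9",
                        "E11.9|I50.9"),
    procedure_codes = "", length_of_stay = c(3L, 1L, 7L, 1L, 1L))

  # the 2nd qualifying admission is the qualifying date
  ph2 <- hospital_phenotype("hf", "I50", min_qualifying_admissions = 2L)
  res <- resolve_phenotype(h, ph2)
  expect_identical(res$first_qualifying_date[res$participant_id == "A"],
                   as.Date("2003-03-03"))
  expect_false("B" %in% res$participant_id)

  # a matching code with too short a stay does not qualify
  ph_los <- hospital_phenotype("hf", "I50", min_length_of_stay = 3L)
  res_los <- resolve_phenotype(h, ph_los)
  expect_false("B" %in% res_los$participant_id)
  expect_identical(res_los$first_qualifying_date[res_los$participant_id == "A"],
                   as.Date("2001-01-01"))

  # principal-only ignores secondary-position codes
  ph_pr <- hospital_phenotype("hf", "I50", position_rule = "principal_only")
  res_pr <- resolve_phenotype(h, ph_pr)
  expect_false("C" %in% res_pr$participant_id)
  expect_true("A" %in% res_pr$participant_id)

  # count monotonicity: tightening requirements never adds qualifiers
  for (k in 1:3) {
    a <- nrow(resolve_phenotype(h, hospital_phenotype(
      "x", "I50", min_qualifying_admissions = k)))
    b <- nrow(resolve_phenotype(h, hospital_phenotype(
      "x", "I50", min_qualifying_admissions = k + 1L)))
    expect_lte(b, a)
  }
  for (los in 0:3) {
    a <- nrow(resolve_phenotype(h, hospital_phenotype(
      "x", "I50", min_length_of_stay = los)))
    b <- nrow(resolve_phenotype(h, hospital_phenotype(
      "x", "I50", min_length_of_stay = los + 1L)))
    expect_lte(b, a)
  }
})

test_that("surgery-censoring dates are organ-specific", {
  h <- data.table::data.table(
    participant_id = c("A", "A", "B"),
    admission_date = as.Date(c("2003-05-10", "2001-01-01", "2005-05-05")),
    discharge_date = as.Date(c("2003-05-12", "2001-01-02", "2005-05-06")),
    diagnosis_codes = "D25.9",
    procedure_codes = c("8542", "3722", "68.4"),
    length_of_stay = c(2L, 1L, 1L))
  br <- surgery_censor_dates(h, "breast")
  expect_identical(br$surgery_date[br$participant_id == "A"],
                   as.Date("2003-05-10"))
  expect_false("B" %in% br$participant_id)
  # hysterectomy codes do not censor an ovarian endpoint
  ov <- surgery_censor_dates(h, "ovary")
  expect_identical(nrow(ov), 0L)
  ut <- surgery_censor_dates(h, "uterus")
  expect_identical(ut$participant_id, "B")
  expect_identical(nrow(surgery_censor_dates(h, "none")), 0L)
  expect_error(surgery_censor_dates(h, "prostate"))
})

test_that("endpoint resolution agrees with the brute-force oracle", {
  tab <- generate_cohort(small_config(400, seed = 77))
  eps <- list(
    cancer_endpoint(site_prefixes = "C50"),
    cancer_endpoint(site_prefixes = c("C5", "C34")),
    cancer_endpoint(seer_groups = c("Breast", "Ovary")),
    cancer_endpoint(site_prefixes = "C50", histology_exclude = "8520"),
    cancer_endpoint(site_prefixes = "C44", histology_include = c("8720",
                                                                 "8743")))
  for (ep in eps) {
    res <- resolve_cancer_endpoint(tab$cancers, ep)
    orc <- oracle_resolve_cancer(tab$cancers, ep)
    expect_setequal(res$participant_id, names(orc))
    for (pid in names(orc)) {
      expect_identical(res$event_date[res$participant_id == pid],
                       orc[[pid]]$diagnosis_date)
      expect_identical(res$event_sequence[res$participant_id == pid],
                       as.integer(orc[[pid]]$sequence_number))
    }
  }
})

test_that("widening a site prefix set never loses qualifying participants", {
  tab <- generate_cohort(small_config(400, seed = 78))
  nested <- list("C509", "C50", c("C50", "C34"), c("C5", "C34", "C1"),
                 c("C", "8"))
  counts <- vapply(nested, function(pfx) {
    nrow(resolve_cancer_endpoint(tab$cancers,
                                 cancer_endpoint(site_prefixes = pfx)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
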