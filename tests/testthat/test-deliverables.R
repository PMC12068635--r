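run_toy <- function(project_dir, data_dir, spec = toy_spec(), tab = NULL) {
  if (is.null(tab)) tab <- toy_tables()
  run_pipeline(spec, tab, project_dir, data_dir, quiet = TRUE)
}

manifest_path_of <- function(manifest, role) {
  for (e in manifest$entries) if (e$role == role) return(e$path)
  NULL
}

test_that("a completed run emits exactly six deliverables, routed correctly", {
  proj <- withr::local_tempdir()
  dat <- withr::local_tempdir()
  m <- run_toy(proj, dat)
  expect_identical(length(m$entries), 6L)
  expect_setequal(vapply(m$entries, `[[`, character(1), "role"),
                  c("dataset", "formats", "sas_reader", "r_reader",
                    "dictionary", "summary"))
  for (e in m$entries) {
    expect_true(file.exists(e$path))
    in_data <- dirname(e$path) == dat
    expect_identical(in_data, e$role %in% c("dataset", "formats"))
    expect_identical(e$read_only, e$role %in% c("dataset", "formats"))
  }
  # data deliverables are read-only on disk (owner write bit cleared)
  expect_true(cohortforge:::cf_is_readonly(manifest_path_of(m, "dataset")))
  expect_true(cohortforge:::cf_is_readonly(manifest_path_of(m, "formats")))
})

test_that("regeneration versions up and never touches prior outputs", {
  proj <- withr::local_tempdir()
  dat <- withr::local_tempdir()
  m1 <- run_toy(proj, dat)
  sum1 <- cohortforge:::cf_checksum(manifest_path_of(m1, "dataset"))
  m2 <- run_toy(proj, dat)
  expect_identical(m1$version_id, 1L)
  expect_identical(m2$version_id, 2L)
  # identical inputs: identical dataset bytes under a new version
  expect_identical(cohortforge:::cf_checksum(manifest_path_of(m2, "dataset")),
                   sum1)
  expect_identical(cohortforge:::cf_checksum(manifest_path_of(m1, "dataset")),
                   sum1)
  expect_identical(nrow(list_versions(proj)), 2L)
  # version 3 reader script embeds its own version
  m3 <- run_toy(proj, dat)
  expect_match(manifest_path_of(m3, "sas_reader"), "v003")
  expect_match(paste(readLines(manifest_path_of(m3, "r_reader")),
                     collapse = "\n"), "v003_dataset.csv")
})

test_that("tampering with a read-only deliverable is detected by checksum", {
  proj <- withr::local_tempdir()
  dat <- withr::local_tempdir()
  m <- run_toy(proj, dat)
  expect_true(all(verify_manifest(m)$ok))
  target <- manifest_path_of(m, "dataset")
  Sys.chmod(target, "0644")
  cat("tampered\n", file = target, append = TRUE)
  v <- verify_manifest(m)
  expect_false(v$ok[v$role == "dataset"])
  expect_true(all(v$ok[v$role != "dataset"]))
})

test_that("the dictionary is a bijection onto dataset columns", {
  proj <- withr::local_tempdir()
  dat <- withr::local_tempdir()
  m <- run_toy(proj, dat,
               spec = toy_spec(covariates = list(selector_section("diet"))))
  ds <- read_table(manifest_path_of(m, "dataset"))
  dict <- read_table(manifest_path_of(m, "dictionary"))
  expect_identical(dict$name, names(ds))
  # unselected covariates are omitted
  expect_false("q2_medical_history_002" %in% dict$name)
  # engine columns are documented from built-in metadata
  expect_identical(dict$units[dict$name == "person_days"], "days")
  expect_true(all(dict$version_id == m$version_id))
  # a column without metadata is a completeness error
  ds2 <- data.table::copy(ds)
  ds2$mystery <- 1
  expect_error(render_dictionary(toy_catalog(), names(ds2)),
               class = "cf_completeness_error")
})

test_that("the formats file follows the fixed grammar and escapes quotes", {
  catalog <- data.table::copy(toy_catalog())
  catalog$label[catalog$name == "q1_smoking_status"] <-
    "Smoker's status"
  catalog$value_labels[catalog$name == "q1_smoking_status"] <-
    "1=Never|2=Former|3=Current smoker's"
  dict <- render_dictionary(catalog, c("q1_smoking_status", "q1_height_m"))
  txt <- render_formats_file(dict)
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines[1], "proc format;")
  expect_identical(lines[length(lines)], "run;")
  expect_true("value Q1_SMOKING_STATUSF" %in% lines)
  block <- grep("^  \\d+='", lines, value = TRUE)
  expect_identical(length(block), 3L)  # one line per code
  expect_true(any(grepl("smoker''s", block)))  # quote doubled
  # continuous columns are skipped; none categorical -> empty but valid
  txt0 <- render_formats_file(render_dictionary(catalog, "q1_height_m"))
  expect_identical(strsplit(txt0, "\n")[[1]], c("proc format;", "run;"))
})

test_that("reader scripts declare every dataset column exactly once", {
  proj <- withr::local_tempdir()
  dat <- withr::local_tempdir()
  m <- run_toy(proj, dat)
  ds <- read_table(manifest_path_of(m, "dataset"))
  r_script <- readLines(manifest_path_of(m, "r_reader"))
  sas_script <- readLines(manifest_path_of(m, "sas_reader"))
  for (col in names(ds)) {
    expect_identical(sum(grepl(paste0('^    ', col, ' = "'), r_script)), 1L,
                     label = paste("r declaration of", col))
    expect_identical(sum(grepl(paste0("^  informat ", col, " "),
                               sas_script)), 1L,
                     label = paste("sas informat of", col))
  }
  # the generated R script actually reads the dataset back
  env <- new.env()
  sys.source(manifest_path_of(m, "r_reader"), envir = env)
  expect_identical(dim(env$cohort), dim(ds))
  expect_s3_class(env$cohort$status, "factor")
})

test_that("the summary restates the choices and the attrition table", {
  proj <- withr::local_tempdir()
  dat <- withr::local_tempdir()
  m <- run_toy(proj, dat)
  txt <- readLines(manifest_path_of(m, "summary"))
  expect_true(any(grepl("prevalent cancer excluded: yes", txt)))
  expect_true(any(grepl("site prefixes: C50", txt)))
  expect_true(any(grepl("end of study: 2010-12-31", txt)))
  # attrition rows transcribed one-to-one (2 header lines in the table)
  built <- build_cohort_dataset(toy_tables(), toy_spec())
  expect_identical(sum(grepl("^\\| ", txt)) - 2L, nrow(built$attrition))
  # a revised spec summary reflects only the new choices
  proj2 <- withr::local_tempdir(); dat2 <- withr::local_tempdir()
  spec2 <- revise_spec(toy_spec(), "censoring",
                       list(end_of_study = "2010-12-31",
                            censor_other_cancers = TRUE,
                            exclude_prevalent_cancer = FALSE))
  m2 <- run_toy(proj2, dat2, spec = spec2)
  expect_true(any(grepl("prevalent cancer excluded: no",
                        readLines(manifest_path_of(m2, "summary")))))
})

test_that("custom excerpts join on the universal key with validation", {
  proj <- withr::local_tempdir()
  dat <- withr::local_tempdir()
  m <- run_toy(proj, dat)
  ds <- read_table(manifest_path_of(m, "dataset"))

  excerpt <- withr::local_tempfile(fileext = ".csv")
  write_table(data.table::data.table(
    participant_id = c(head(ds$participant_id, 3), "GHOST1"),
    crp = c(1.2, 3.4, 5.6, 7.8)), excerpt)
  out <- emit_custom_join(excerpt, m)
  expect_identical(out$report$keys_not_in_dataset, "GHOST1")
  expect_identical(out$report$duplicate_keys, character(0))
  # the emitted script runs and preserves the dataset row count
  env <- new.env()
  eval(parse(text = out$script), envir = env)
  expect_identical(nrow(env$merged), nrow(ds))
  expect_true("crp" %in% names(env$merged))

  dup <- withr::local_tempfile(fileext = ".csv")
  write_table(data.table::data.table(
    participant_id = rep(ds$participant_id[1], 2), crp = c(1, 2)), dup)
  expect_identical(emit_custom_join(dup, m)$report$duplicate_keys,
                   ds$participant_id[1])

  nokey <- withr::local_tempfile(fileext = ".csv")
  write_table(data.table::data.table(id = "x", crp = 1), nokey)
  expect_error(emit_custom_join(nokey, m), class = "cf_join_error")
})
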