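cf_log <- function(stage, ..., logfile = NULL) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the full selection pipeline
#'
#' Orchestrates a complete generation run: table validation, endpoint
#' resolution, eligibility and exit resolution, dataset assembly, and
#' deliverable generation, logging counts at every stage. Re-running an
#' unchanged spec yields a new version with identical data checksums.
#'
#' @param spec a complete [selection_spec()].
#' @param tables a [study_tables()] object.
#' @param project_dir,data_dir output directories.
#' @param wide optional precomputed presentation table (rebuilt otherwise).
#' @param quiet suppress stage logging.
#' @return the deliverable manifest ([generate_deliverables()]).
#' @export
run_pipeline <- function(spec, tables, project_dir, data_dir, wide = NULL,
                         quiet = FALSE) {
  dir.create(project_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(project_dir, "cohortforge.log")
  log_ <- function(stage, ...) {
    if (!quiet) cf_log(stage, ..., logfile = logfile)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cf_stop("cf_pipeline_error", "stage '", name, "' failed: ",
              conditionMessage(e))
    })
  }

  validate_spec(spec, require_complete = TRUE)
  log_("validate", "checking study tables (",
       nrow(tables$participants), " participants)")
  report <- stage("validate", validate_tables(tables))
  if (nrow(report)) {
    cf_stop("cf_pipeline_error", "stage 'validate' failed: ", nrow(report),
            " invariant violation(s); first: ", report$rule[1])
  }
  if (is.null(wide)) {
    log_("presentation", "building wide presentation table")
    wide <- stage("presentation", build_presentation_table(tables))
  }
  log_("build", "design=", spec$metadata$design)
  built <- stage("build", if (spec$metadata$design == "cross_sectional") {
    build_cross_sectional_dataset(tables, spec, wide)
  } else {
    build_cohort_dataset(tables, spec, wide)
  })
  log_("build", "dataset rows=", nrow(built$dataset), " cols=",
       ncol(built$dataset))
  manifest <- stage("deliverables",
                    generate_deliverables(built$dataset, spec,
                                          tables$catalog, built$attrition,
                                          project_dir, data_dir))
  log_("deliverables", "version=", manifest$version_id, " entries=",
       length(manifest$entries))
  manifest
}
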