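CF_SPEC_SCHEMA <- "1.0"
CF_SPEC_SECTIONS <- c("endpoint", "start", "censoring", "covariates",
                      "custom_data", "metadata")

#' Create a selection specification
#'
#' The selection spec is the declarative document capturing every researcher
#' choice, in six sections mirroring the selection workflow's steps:
#' \enumerate{
#'   \item \strong{endpoint} — a [cancer_endpoint()], [mortality_endpoint()],
#'     a list of [hospital_phenotype()]s, or `NULL` (covariate-only extract);
#'   \item \strong{start} — start-of-follow-up rule (`baseline`,
#'     `survey_k`, or `fixed_date`; user dates may be MM/DD/YYYY);
#'   \item \strong{censoring} — end of study, other-cancer censoring,
#'     automatic surgery censoring (forced on for breast/uterus/ovary
#'     endpoints), prevalent-cancer exclusion (default on);
#'   \item \strong{covariates} — a list of selectors ([selector_names()]);
#'   \item \strong{custom_data} — declared excerpt schemas for
#'     [emit_custom_join()];
#'   \item \strong{metadata} — project slug, design (`cohort` or
#'     `cross_sectional`), reference date (cross-sectional), schema version.
#' }
#' Partial specs are legal (the workflow saves interim progress); use
#' [spec_completeness()] to see which sections are still open.
#'
#' @param endpoint,start,censoring,covariates,custom_data,metadata the six
#'   sections (see above).
#' @return an object of class `cf_selection_spec`.
#' @export
selection_spec <- function(endpoint = NULL, start = NULL, censoring = NULL,
                           covariates = list(), custom_data = list(),
                           metadata = list()) {
  spec <- list(endpoint = endpoint, start = start, censoring = censoring,
               covariates = covariates, custom_data = custom_data,
               metadata = metadata)
  as_selection_spec(spec)
}

# plain phenotype list -> cf_endpoint phenotype object
as_phenotype <- function(ph) {
  if (inherits(ph, "cf_endpoint")) return(ph)
  hospital_phenotype(ph$name, ph$diagnosis_prefixes,
                     ph$min_length_of_stay %||% 0L,
                     ph$min_qualifying_admissions %||% 1L,
                     ph$position_rule %||% "any_listed")
}

normalize_endpoint <- function(endpoint) {
  if (is.null(endpoint) || identical(endpoint$type %||% "none", "none")) {
    return(NULL)
  }
  switch(endpoint$type,
    cancer = unclass(cancer_endpoint(endpoint$site_prefixes,
                                     endpoint$seer_groups,
                                     endpoint$histology_include,
                                     endpoint$histology_exclude)),
    mortality = unclass(mortality_endpoint(endpoint$cause_prefixes %||%
                                             character())),
    phenotype = {
      phs <- lapply(endpoint$phenotypes, function(ph) unclass(as_phenotype(ph)))
      nms <- vapply(phs, `[[`, character(1), "name")
      if (anyDuplicated(nms)) {
        cf_stop("cf_spec_error", "duplicate phenotype names: ",
                paste(unique(nms[duplicated(nms)]), collapse = ", "))
      }
      list(type = "phenotype", phenotypes = phs)
    },
    cf_stop("cf_spec_error", "unknown endpoint type: ", endpoint$type))
}

normalize_start <- function(start) {
  if (is.null(start)) return(NULL)
  rule <- start$rule %||% cf_stop("cf_spec_error", "start section needs a rule")
  if (!rule %in% c("baseline", "survey_k", "fixed_date")) {
    cf_stop("cf_spec_error", "unknown start rule: ", rule)
  }
  out <- list(rule = rule)
  if (rule == "survey_k") out$k <- as.integer(start$k)
  if (rule == "fixed_date") {
    out$date <- format(parse_user_date(start$date))
  }
  out
}

normalize_censoring <- function(censoring) {
  if (is.null(censoring)) return(NULL)
  if (is.null(censoring$end_of_study)) {
    cf_stop("cf_spec_error", "censoring section needs end_of_study")
  }
  list(end_of_study = format(parse_user_date(censoring$end_of_study)),
       censor_other_cancers = isTRUE(censoring$censor_other_cancers),
       auto_surgery_censoring =
         if (is.null(censoring$auto_surgery_censoring)) NULL
         else isTRUE(censoring$auto_surgery_censoring),
       exclude_prevalent_cancer =
         !isFALSE(censoring$exclude_prevalent_cancer))
}

normalize_selectors <- function(covariates) {
  lapply(covariates, function(sel) {
    if (inherits(sel, "cf_selector")) sel <- unclass(sel)
    if (is.null(sel$type)) {
      cf_stop("cf_spec_error", "covariate selector needs a type")
    }
    value <- if (sel$type == "questionnaire") as.integer(sel$value)
             else as.character(sel$value)
    list(type = sel$type, value = value)
  })
}

as_selection_spec <- function(spec) {
  unknown <- setdiff(names(spec), CF_SPEC_SECTIONS)
  if (length(unknown)) {
    cf_stop("cf_spec_error", "unknown spec section(s): ",
            paste(unknown, collapse = ", "))
  }
  md <- spec$metadata %||% list()
  md$project <- as.character(md$project %||% "project")
  md$design <- match.arg(md$design %||% "cohort",
                         c("cohort", "cross_sectional"))
  md$reference_date <- if (is.null(md$reference_date)) NULL
                       else format(parse_user_date(md$reference_date))
  md$schema_version <- md$schema_version %||% CF_SPEC_SCHEMA
  out <- list(endpoint = normalize_endpoint(spec$endpoint),
              start = normalize_start(spec$start),
              censoring = normalize_censoring(spec$censoring),
              covariates = normalize_selectors(spec$covariates %||% list()),
              custom_data = lapply(spec$custom_data %||% list(), function(cd)
                list(name = as.character(cd$name),
                     expected_columns = as.character(cd$expected_columns))),
              metadata = md)
  structure(out, class = "cf_selection_spec")
}

# tagged selector objects for the resolver
spec_selectors <- function(spec) {
  lapply(spec$covariates, function(sel) {
    structure(list(type = sel$type, value = sel$value),
              class = "cf_selector")
  })
}

#' Section completeness of a (possibly partial) spec
#'
#' @param spec a `cf_selection_spec`.
#' @return named logical vector over the six sections.
#' @export
spec_completeness <- function(spec) {
  c(endpoint = !is.null(spec$endpoint),
    start = !is.null(spec$start),
    censoring = !is.null(spec$censoring),
    covariates = length(spec$covariates) > 0,
    custom_data = length(spec$custom_data) > 0,
    metadata = !is.null(spec$metadata$project))
}

#' Validate a selection spec
#'
#' @param spec a `cf_selection_spec`.
#' @param require_complete when `TRUE`, a cohort-design spec must have its
#'   endpoint, start and censoring sections complete (a `NULL` endpoint is a
#'   deliberate covariate-only choice and counts as complete only for
#'   cross-sectional designs).
#' @return the spec, invisibly.
#' @export
validate_spec <- function(spec, require_complete = FALSE) {
  if (!inherits(spec, "cf_selection_spec")) {
    cf_stop("cf_spec_error", "not a selection spec")
  }
  if (require_complete && spec$metadata$design == "cohort") {
    missing_ <- c(endpoint = is.null(spec$endpoint),
                  start = is.null(spec$start),
                  censoring = is.null(spec$censoring))
    if (any(missing_)) {
      cf_stop("cf_spec_error", "cohort spec is missing required section(s): ",
              paste(names(missing_)[missing_], collapse = ", "))
    }
  }
  if (require_complete && spec$metadata$design == "cross_sectional" &&
      is.null(spec$metadata$reference_date)) {
    cf_stop("cf_spec_error",
            "cross-sectional spec is missing metadata$reference_date")
  }
  invisible(spec)
}

#' Save / load a selection spec (JSON or YAML)
#'
#' The serialization round-trip is the identity on normalized specs. The
#' format follows the file extension (`.json`, `.yaml`/`.yml`). Loading a
#' file with a different schema version raises a migration error naming both
#' versions; a corrupt file raises a parse error.
#'
#' @param spec a `cf_selection_spec`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `load_spec()` returns the spec with a `completeness` attribute
#'   (see [spec_completeness()]).
#' @export
save_spec <- function(spec, path) {
  spec <- as_selection_spec(unclass(spec))
  plain <- unclass(spec)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path)
  } else {
    cf_stop("cf_spec_error", "unknown spec format: .", ext)
  }
  invisible(path)
}

#' @rdname save_spec
#' @export
load_spec <- function(path) {
  if (!file.exists(path)) cf_stop("cf_format_error", "spec not found: ", path)
  ext <- tolower(tools::file_ext(path))
  plain <- tryCatch({
    if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    } else if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(path)
    } else {
      cf_stop("cf_spec_error", "unknown spec format: .", ext)
    }
  }, error = function(e) {
    cf_stop("cf_parse_error", "cannot parse spec file ", path, ": ",
            conditionMessage(e))
  })
  ver <- plain$metadata$schema_version %||% CF_SPEC_SCHEMA
  if (!identical(as.character(ver), CF_SPEC_SCHEMA)) {
    cf_stop("cf_migration_error", "spec schema version ", ver,
            " cannot be loaded by engine schema ", CF_SPEC_SCHEMA)
  }
  # drop JSON nulls so normalization treats absent and null alike
  plain <- lapply(plain, function(x) if (is.null(x)) NULL else x)
  spec <- as_selection_spec(plain[!vapply(plain, is.null, logical(1))])
  attr(spec, "completeness") <- spec_completeness(spec)
  spec
}

#' Revise one section of a spec
#'
#' Replaces exactly one of the six sections and revalidates; every other
#' section is untouched and the original spec object is never mutated, so
#' any individual choice can be changed mid-project without starting over.
#'
#' @param spec a `cf_selection_spec`.
#' @param section one of `"endpoint"`, `"start"`, `"censoring"`,
#'   `"covariates"`, `"custom_data"`, `"metadata"`.
#' @param patch the new section content; `NULL` patch with `drop = FALSE`
#'   leaves the spec unchanged.
#' @param drop set `TRUE` to clear the section.
#' @return a new `cf_selection_spec`.
#' @export
revise_spec <- function(spec, section, patch = NULL, drop = FALSE) {
  if (length(section) != 1L || !section %in% CF_SPEC_SECTIONS) {
    cf_stop("cf_spec_error", "patch must target exactly one of: ",
            paste(CF_SPEC_SECTIONS, collapse = ", "))
  }
  if (is.null(patch) && !drop) return(spec)
  plain <- unclass(spec)
  plain[[section]] <- if (drop) NULL else patch
  as_selection_spec(plain)
}

#' @export
print.cf_selection_spec <- function(x, ...) {
  done <- spec_completeness(x)
  cat("<selection spec> project:", x$metadata$project,
      " design:", x$metadata$design, "\n")
  for (s in CF_SPEC_SECTIONS) {
    cat(sprintf("  %-12s %s\n", s, if (done[[s]]) "set" else "(incomplete)"))
  }
  invisible(x)
}
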