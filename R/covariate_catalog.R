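#' Read a covariate catalog
#'
#' The catalog (codebook) documents every available covariate: `name`,
#' `label`, `dtype` (`categorical`/`continuous`/`date`/`flag`),
#' `value_labels` (`"code=label|code=label"`, categorical only),
#' `questionnaire_number` (1 = baseline, 2-6 = follow-up waves),
#' `section`, `question_number`, `essential` (always included in every
#' dataset), `derived` (computed, e.g. BMI, rather than asked).
#'
#' @param path path to `catalog.csv`.
#' @return a `data.table` with one row per covariate.
#' @export
read_catalog <- function(path) {
  cat_ <- data.table::fread(path, na.strings = "", colClasses = list(
    character = c("name", "label", "dtype", "value_labels", "section",
                  "question_number"),
    integer = "questionnaire_number",
    logical = c("essential", "derived")))
  cat_
}

#' Search the covariate catalog
#'
#' Case-insensitive substring match over covariate names and labels, in
#' stable catalog order.
#'
#' @param catalog a catalog `data.table` ([read_catalog()]).
#' @param term non-empty search term.
#' @return the matching catalog rows (possibly zero).
#' @examples
#' \dontrun{search_catalog(catalog, "smok")}
#' @export
search_catalog <- function(catalog, term) {
  if (!is.character(term) || length(term) != 1L || !nzchar(term)) {
    cf_stop("cf_spec_error", "search term must be a non-empty string")
  }
  hit <- grepl(term, catalog$name, ignore.case = TRUE, fixed = FALSE) |
    grepl(term, catalog$label, ignore.case = TRUE, fixed = FALSE)
  catalog[hit, ]
}

#' Covariate selectors
#'
#' Covariates can be chosen individually (by name) or hierarchically — by
#' questionnaire number, questionnaire section, question number, or free-text
#' search. A selection is the union of its selectors.
#'
#' @param names,questionnaire,section,question,term the selector value.
#' @return a tagged selector object for [select_covariates()].
#' @export
selector_names <- function(names) {
  structure(list(type = "names", value = as.character(names)),
            class = "cf_selector")
}
#' @rdname selector_names
#' @export
selector_questionnaire <- function(questionnaire) {
  structure(list(type = "questionnaire", value = as.integer(questionnaire)),
            class = "cf_selector")
}
#' @rdname selector_names
#' @export
selector_section <- function(section) {
  structure(list(type = "section", value = as.character(section)),
            class = "cf_selector")
}
#' @rdname selector_names
#' @export
selector_question <- function(question) {
  structure(list(type = "question", value = as.character(question)),
            class = "cf_selector")
}
#' @rdname selector_names
#' @export
selector_search <- function(term) {
  structure(list(type = "search", value = as.character(term)),
            class = "cf_selector")
}

resolve_selector <- function(catalog, sel) {
  switch(sel$type,
    names = {
      unknown <- setdiff(sel$value, catalog$name)
      if (length(unknown)) {
        cf_stop("cf_unknown_covariate_error", "unknown covariate(s): ",
                paste(unknown, collapse = ", "))
      }
      sel$value
    },
    questionnaire = catalog$name[!is.na(catalog$questionnaire_number) &
                                   catalog$questionnaire_number %in% sel$value],
    section = catalog$name[!is.na(catalog$section) &
                             catalog$section %in% sel$value],
    question = catalog$name[!is.na(catalog$question_number) &
                              catalog$question_number %in% sel$value],
    search = search_catalog(catalog, sel$value)$name,
    cf_stop("cf_spec_error", "unknown selector type: ", sel$type))
}

#' Resolve covariate selectors into an ordered column list
#'
#' Takes the union of all selector matches, deduplicated in catalog order,
#' and appends the essential covariate set if absent. A pure function of
#' (catalog, selectors): re-running a revised selection never depends on
#' earlier selections.
#'
#' @param catalog a catalog `data.table`.
#' @param selectors a list of selectors (see [selector_names()]); an empty
#'   list selects exactly the essential set.
#' @return character vector of covariate names, catalog order.
#' @export
select_covariates <- function(catalog, selectors = list()) {
  if (inherits(selectors, "cf_selector")) selectors <- list(selectors)
  picked <- unlist(lapply(selectors, resolve_selector, catalog = catalog))
  picked <- union(picked, essential_set(catalog)$name)
  catalog$name[catalog$name %in% picked]
}

#' The essential covariate set
#'
#' Every generated dataset automatically includes a fixed set of 62
#' essential covariates (identifiers, dates of birth/death/baseline survey,
#' vital status, BMI, smoking status, and a core block of baseline
#' questionnaire items). The count is enforced as a configuration contract
#' at catalog load.
#'
#' @param catalog a catalog `data.table`.
#' @return the 62 essential catalog rows, fixed (catalog) order.
#' @export
essential_set <- function(catalog) {
  ess <- catalog[catalog$essential %in% TRUE, ]
  if (nrow(ess) != 62L) {
    cf_stop("cf_config_error", "catalog must flag exactly 62 essential ",
            "covariates; found ", nrow(ess))
  }
  ess
}

#' Derive body mass index from self-reported height and weight
#'
#' BMI = weight / height^2 (kg/m^2). Missing inputs propagate to a missing
#' result; non-positive heights yield a missing result and are counted in
#' the `n_flagged` attribute (a data-quality flag, never an error).
#'
#' @param height_m height in meters.
#' @param weight_kg weight in kilograms.
#' @return numeric vector of BMI values with attribute `n_flagged`.
#' @examples
#' derive_bmi(1.60, 64)   # 25
#' @export
derive_bmi <- function(height_m, weight_kg) {
  height_m <- as.numeric(height_m)
  weight_kg <- as.numeric(weight_kg)
  bad <- !is.na(height_m) & !is.nan(height_m) & height_m <= 0 &
    !is.na(weight_kg)
  out <- weight_kg / height_m^2
  out[!is.finite(out) & !is.nan(out)] <- NA_real_
  out[bad] <- NA_real_
  # preserve missing-by-design where both inputs were by design
  mbd <- is.nan(height_m) | is.nan(weight_kg)
  out[mbd] <- NaN
  attr(out, "n_flagged") <- sum(bad)
  out
}
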