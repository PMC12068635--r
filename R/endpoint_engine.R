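#' Normalize an ICD / ICD-O-3 code for matching
#'
#' Matching is performed on a canonical form: uppercased, surrounding
#' whitespace stripped, embedded dot removed (`"C50.9"` -> `"C509"`). The
#' original form is preserved wherever codes are displayed.
#'
#' @param code character vector of raw codes.
#' @return character vector of canonical codes.
#' @examples
#' normalize_icd(c("c50.9", " I21 "))
#' @export
normalize_icd <- function(code) {
  out <- gsub(".", "", toupper(trimws(as.character(code))), fixed = TRUE)
  bad <- is.na(out) | !grepl("^[A-Z0-9]+$", out)
  if (any(bad)) {
    cf_stop("cf_code_format_error", "invalid ICD code(s): ",
            paste(sQuote(code[bad]), collapse = ", "))
  }
  out
}

#' Prefix-match codes against a prefix set
#'
#' A code matches iff some prefix in the set is a leading substring of the
#' code. Both sides must already be in canonical form ([normalize_icd()]).
#'
#' @param code character vector of canonical codes.
#' @param prefixes character vector of canonical prefixes.
#' @return logical vector, one element per code.
#' @examples
#' icd_prefix_match(c("C509", "C349"), "C50")
#' @export
icd_prefix_match <- function(code, prefixes) {
  if (!length(prefixes)) return(rep(FALSE, length(code)))
  hit <- rep(FALSE, length(code))
  for (p in prefixes) hit <- hit | startsWith(code, p)
  hit & !is.na(code)
}

#' Load the bundled SEER site-group recode subset
#'
#' A small editable mapping from ICD-O-3 site/histology pairs to named site
#' groups (breast, uterus, ovary, colon, lung, melanoma of the skin),
#' constructed from the public recode definition. Histology-based rows
#' (melanoma) take priority over site ranges. A full recode table can be
#' supplied in the same format.
#'
#' @param path optional path to an alternative mapping CSV with columns
#'   `priority,group,site_low,site_high,hist_low,hist_high`.
#' @return a `data.table` sorted by priority.
#' @export
load_seer_mapping <- function(path = NULL) {
  path <- path %||% cf_extdata("seer_site_recode.csv")
  m <- data.table::fread(path, colClasses = list(
    character = c("group", "site_low", "site_high", "hist_low", "hist_high"),
    integer = "priority"))
  need <- c("priority", "group", "site_low", "site_high", "hist_low",
            "hist_high")
  if (!all(need %in% names(m)) || anyNA(m$priority)) {
    cf_stop("cf_config_error", "malformed SEER mapping file: ", path)
  }
  data.table::setorderv(m, "priority")
  m
}

#' Recode an ICD-O-3 site/histology pair to a SEER site group
#'
#' @param site_code ICD-O-3 topography (dot form accepted).
#' @param histology_code 4-digit ICD-O-3 morphology.
#' @param mapping a mapping table ([load_seer_mapping()]).
#' @return character vector of group labels; `"other"` when unmapped.
#' @examples
#' seer_recode("C50.4", "8500")
#' @export
seer_recode <- function(site_code, histology_code,
                        mapping = load_seer_mapping()) {
  site <- normalize_icd(site_code)
  hist <- trimws(as.character(histology_code))
  out <- rep("other", length(site))
  undecided <- rep(TRUE, length(site))
  for (i in seq_len(nrow(mapping))) {
    row <- mapping[i, ]
    hit <- undecided & site >= row$site_low & site <= row$site_high &
      hist >= row$hist_low & hist <= row$hist_high
    out[hit] <- row$group
    undecided <- undecided & !hit
  }
  out
}

#' Endpoint definitions
#'
#' Three endpoint families are supported:
#' \describe{
#'   \item{cancer}{incident cancer chosen by ICD-O-3 site prefixes and/or
#'     SEER site-group recode values, optionally refined by morphology
#'     (histology) include/exclude sets.}
#'   \item{mortality}{cause-specific death chosen by ICD cause-of-death
#'     prefixes; an empty prefix set means all-cause mortality.}
#'   \item{hospitalization phenotype}{a computable phenotype: ICD diagnosis
#'     prefixes plus optional minimum length-of-stay and a minimum count of
#'     qualifying admissions; `position_rule` selects whether any listed
#'     diagnosis or only the principal (first-listed) diagnosis counts.}
#' }
#'
#' @param site_prefixes,seer_groups,histology_include,histology_exclude
#'   cancer endpoint criteria (character vectors; `NULL` to omit).
#' @param cause_prefixes ICD prefixes for mortality (empty = all-cause).
#' @param name,diagnosis_prefixes,min_length_of_stay,min_qualifying_admissions,position_rule
#'   phenotype criteria.
#' @return a tagged endpoint object.
#' @export
cancer_endpoint <- function(site_prefixes = NULL, seer_groups = NULL,
                            histology_include = NULL,
                            histology_exclude = NULL) {
  if (!length(site_prefixes) && !length(seer_groups)) {
    cf_stop("cf_spec_error",
            "cancer endpoint needs site_prefixes or seer_groups")
  }
  if (length(intersect(histology_include, histology_exclude))) {
    cf_stop("cf_spec_error",
            "histology include and exclude sets must be disjoint")
  }
  structure(list(type = "cancer",
                 site_prefixes = if (length(site_prefixes))
                   normalize_icd(site_prefixes) else character(),
                 seer_groups = as.character(seer_groups %||% character()),
                 histology_include = as.character(histology_include %||%
                                                   character()),
                 histology_exclude = as.character(histology_exclude %||%
                                                   character())),
            class = "cf_endpoint")
}

#' @rdname cancer_endpoint
#' @export
mortality_endpoint <- function(cause_prefixes = character()) {
  pf <- if (length(cause_prefixes)) normalize_icd(cause_prefixes)
        else character()
  structure(list(type = "mortality", cause_prefixes = pf),
            class = "cf_endpoint")
}

#' @rdname cancer_endpoint
#' @export
hospital_phenotype <- function(name, diagnosis_prefixes,
                               min_length_of_stay = 0L,
                               min_qualifying_admissions = 1L,
                               position_rule = c("any_listed",
                                                 "principal_only")) {
  position_rule <- match.arg(position_rule)
  if (!is.character(name) || !nzchar(name)) {
    cf_stop("cf_spec_error", "phenotype needs a non-empty name")
  }
  if (min_length_of_stay < 0 || min_qualifying_admissions < 1) {
    cf_stop("cf_spec_error", "invalid phenotype stay/count constraints")
  }
  structure(list(type = "phenotype", name = name,
                 diagnosis_prefixes = normalize_icd(diagnosis_prefixes),
                 min_length_of_stay = as.integer(min_length_of_stay),
                 min_qualifying_admissions =
                   as.integer(min_qualifying_admissions),
                 position_rule = position_rule),
            class = "cf_endpoint")
}

# mask of cancer rows matching a cancer endpoint
cancer_event_matches <- function(cancers, endpoint,
                                 mapping = load_seer_mapping()) {
  stopifnot(endpoint$type == "cancer")
  if (!nrow(cancers)) return(logical())
  site <- normalize_icd(cancers$site_code)
  grp <- cancers$seer_group
  if (is.null(grp) || all(is.na(grp))) {
    grp <- seer_recode(cancers$site_code, cancers$histology_code, mapping)
  }
  hit <- icd_prefix_match(site, endpoint$site_prefixes) |
    (length(endpoint$seer_groups) > 0 & grp %in% endpoint$seer_groups)
  if (length(endpoint$histology_include)) {
    hit <- hit & cancers$histology_code %in% endpoint$histology_include
  }
  if (length(endpoint$histology_exclude)) {
    hit <- hit & !cancers$histology_code %in% endpoint$histology_exclude
  }
  hit
}

#' Resolve a cancer endpoint to first qualifying events
#'
#' For each participant, finds the earliest cancer event matching the
#' endpoint (site prefix OR SEER group, then histology include/exclude);
#' same-date ties are broken by lowest sequence number. Participants with no
#' qualifying event are absent from the result.
#'
#' @param cancers the cancer event table.
#' @param endpoint a [cancer_endpoint()].
#' @param mapping SEER mapping used when `seer_group` is absent from the
#'   table.
#' @return a `data.table` keyed by `participant_id` with the first
#'   qualifying event's `event_date`, site, histology, SEER group, stage,
#'   grade and sequence number.
#' @export
resolve_cancer_endpoint <- function(cancers, endpoint,
                                    mapping = load_seer_mapping()) {
  hit <- cancer_event_matches(cancers, endpoint, mapping)
  q <- cancers[hit, ]
  if (!nrow(q)) {
    return(data.table::data.table(
      participant_id = character(), event_date = as.Date(character()),
      event_site = character(), event_histology = character(),
      event_seer_group = character(), event_stage = character(),
      event_grade = character(), event_sequence = integer()))
  }
  data.table::setorderv(q, c("participant_id", "diagnosis_date",
                             "sequence_number"))
  first <- q[, .SD[1L], by = "participant_id"]
  data.table::data.table(
    participant_id = first$participant_id,
    event_date = first$diagnosis_date,
    event_site = first$site_code,
    event_histology = first$histology_code,
    event_seer_group = first$seer_group,
    event_stage = first$stage,
    event_grade = first$grade,
    event_sequence = as.integer(first$sequence_number))
}

#' Resolve a mortality endpoint
#'
#' A participant qualifies iff dead and the cause of death matches one of
#' the ICD prefixes (an empty prefix set means all-cause mortality).
#'
#' @param participants the participant table.
#' @param endpoint a [mortality_endpoint()].
#' @return a `data.table` of qualifying participants with `event_date`
#'   (= date of death) and `event_cause`.
#' @export
resolve_mortality_endpoint <- function(participants, endpoint) {
  stopifnot(endpoint$type == "mortality")
  p <- participants
  dead <- !is.na(p$vital_status) & p$vital_status == "dead" &
    !is.na(p$date_of_death)
  if (length(endpoint$cause_prefixes)) {
    cause <- rep(NA_character_, nrow(p))
    ok <- dead & !is.na(p$cause_of_death)
    cause[ok] <- normalize_icd(p$cause_of_death[ok])
    dead <- ok & icd_prefix_match(cause, endpoint$cause_prefixes)
  }
  data.table::data.table(participant_id = p$participant_id[dead],
                         event_date = p$date_of_death[dead],
                         event_cause = p$cause_of_death[dead])
}

# split pipe-separated code lists, normalized; position_rule may restrict to
# the principal (first-listed) code
admission_code_list <- function(codes, principal_only = FALSE) {
  parts <- strsplit(ifelse(is.na(codes), "", codes), "|", fixed = TRUE)
  if (principal_only) parts <- lapply(parts, function(x) head(x, 1L))
  parts
}

#' Resolve a hospitalization phenotype
#'
#' An admission qualifies iff a diagnosis code (any listed, or principal
#' only) matches the phenotype's ICD prefixes and the length of stay meets
#' the minimum. A participant qualifies when their
#' `min_qualifying_admissions`-th qualifying admission occurs; the first
#' qualifying date is that admission's date.
#'
#' @param hospitalizations the admission table.
#' @param phenotype a [hospital_phenotype()].
#' @return a `data.table` of qualifying participants with
#'   `first_qualifying_date` and `n_qualifying_admissions`.
#' @export
resolve_phenotype <- function(hospitalizations, phenotype) {
  stopifnot(phenotype$type == "phenotype")
  h <- hospitalizations
  if (!nrow(h)) {
    return(data.table::data.table(participant_id = character(),
                                  first_qualifying_date = as.Date(character()),
                                  n_qualifying_admissions = integer()))
  }
  codes <- admission_code_list(h$diagnosis_codes,
                               phenotype$position_rule == "principal_only")
  dx_hit <- vapply(codes, function(x) {
    length(x) > 0 && any(icd_prefix_match(normalize_icd(x),
                                          phenotype$diagnosis_prefixes))
  }, logical(1))
  q <- h[dx_hit & h$length_of_stay >= phenotype$min_length_of_stay, ]
  if (!nrow(q)) {
    return(data.table::data.table(participant_id = character(),
                                  first_qualifying_date = as.Date(character()),
                                  n_qualifying_admissions = integer()))
  }
  data.table::setorderv(q, c("participant_id", "admission_date"))
  k <- phenotype$min_qualifying_admissions
  agg <- q[, .(n_qualifying_admissions = .N,
               first_qualifying_date = if (.N >= k) admission_date[k]
                                       else as.Date(NA)),
           by = "participant_id"]
  agg[agg$n_qualifying_admissions >= k, ]
}

#' Load the bundled surgery procedure-code sets
#'
#' Minimal default code sets (ICD-9-CM volume 3) for bilateral mastectomy,
#' hysterectomy and bilateral oophorectomy, grouped by the cancer endpoint
#' group whose follow-up they censor. Real-world code-set curation is a
#' user-supplied configuration; any table with columns
#' `code,label,endpoint_group` can be substituted.
#'
#' @param path optional path to an alternative code-set CSV.
#' @return a `data.table` with normalized codes.
#' @export
load_surgery_codes <- function(path = NULL) {
  path <- path %||% cf_extdata("procedure_codes.csv")
  sc <- data.table::fread(path, colClasses = "character")
  if (!all(c("code", "label", "endpoint_group") %in% names(sc))) {
    cf_stop("cf_config_error", "malformed surgery code-set file: ", path)
  }
  sc$code <- normalize_icd(sc$code)
  sc
}

#' Derive automatic surgery-censoring dates
#'
#' For breast, uterine and ovarian cancer endpoints, follow-up is
#' automatically censored at the date of bilateral mastectomy, hysterectomy,
#' or bilateral oophorectomy, respectively — identified from procedure codes
#' on linked hospitalization records.
#'
#' @param hospitalizations the admission table.
#' @param endpoint_group one of `"breast"`, `"uterus"`, `"ovary"`, `"none"`.
#' @param surgery_codes a code-set table ([load_surgery_codes()]).
#' @return a `data.table` mapping `participant_id` to the earliest
#'   `surgery_date` carrying a relevant code; empty for `"none"`.
#' @export
surgery_censor_dates <- function(hospitalizations,
                                 endpoint_group = c("none", "breast",
                                                    "uterus", "ovary"),
                                 surgery_codes = load_surgery_codes()) {
  endpoint_group <- match.arg(endpoint_group)
  empty <- data.table::data.table(participant_id = character(),
                                  surgery_date = as.Date(character()))
  if (endpoint_group == "none" || !nrow(hospitalizations)) return(empty)
  wanted <- surgery_codes$code[surgery_codes$endpoint_group == endpoint_group]
  h <- hospitalizations
  codes <- admission_code_list(h$procedure_codes)
  hit <- vapply(codes, function(x) {
    length(x) > 0 && any(normalize_icd(x) %in% wanted)
  }, logical(1))
  q <- h[hit, ]
  if (!nrow(q)) return(empty)
  q[, .(surgery_date = min(admission_date)), by = "participant_id"]
}

# endpoint group implied by a cancer endpoint (drives automatic surgery
# censoring); based on site prefixes and SEER group labels
infer_endpoint_group <- function(endpoint) {
  if (is.null(endpoint) || endpoint$type != "cancer") return("none")
  pfx <- endpoint$site_prefixes
  grp <- tolower(endpoint$seer_groups)
  has <- function(stems, label) {
    any(vapply(stems, function(s) any(startsWith(pfx, s) | startsWith(s, pfx)),
               logical(1))) || label %in% grp
  }
  if (has("C50", "breast")) return("breast")
  if (has(c("C54", "C55"), "uterus")) return("uterus")
  if (has("C56", "ovary")) return("ovary")
  "none"
}
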