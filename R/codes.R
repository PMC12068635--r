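# Bundled code lists used by the synthetic generator. These are small,
# deliberately incomplete samples of real coding systems; they exist so that
# generated events carry realistic-looking ICD-O-3 / ICD codes, not to
# reproduce any coding standard.

# ICD-O-3 topography sites with sampling weights and per-site morphology pools
# (4-digit ICD-O-3 histology). Weights loosely reflect relative frequency of
# incident cancers in an adult female cohort.
cf_cancer_sites <- function() {
  data.table::data.table(
    site_code = c("C50.9", "C50.4", "C34.9", "C18.9", "C54.1", "C56.9",
                  "C44.5", "C25.9", "C64.9", "C67.9", "C73.9", "C16.9"),
    weight    = c(0.28,    0.10,    0.09,    0.10,    0.08,    0.05,
                  0.08,    0.05,    0.05,    0.04,    0.05,    0.03),
    histology = list(
      c("8500", "8520", "8522"),          # breast ductal/lobular/mixed
      c("8500", "8520"),
      c("8140", "8070", "8041"),          # lung adeno/squamous/small cell
      c("8140", "8480"),                  # colon adeno/mucinous
      c("8380", "8140"),                  # endometrioid
      c("8441", "8460", "8000"),          # serous ovarian
      c("8720", "8743"),                  # melanoma
      c("8140", "8500"),
      c("8312", "8140"),                  # renal cell
      c("8120", "8130"),                  # urothelial
      c("8260", "8330"),                  # papillary/follicular thyroid
      c("8140", "8490")
    )
  )
}

# hospitalization ICD diagnosis codes (dot form) sampled by the generator
cf_hospital_dx_codes <- function() {
  c("I21.0", "I25.1", "I50.9", "I63.9", "J18.9", "J44.9", "K80.2",
    "N39.0", "S72.0", "E11.9", "M17.1", "I48.9", "K57.3", "D25.9",
    "N83.2", "C50.9", "R07.9", "A41.9")
}

# non-surgical procedure codes occasionally attached to admissions
cf_hospital_proc_codes <- function() {
  c("3722", "8154", "4516", "5123", "3995", "8151", "7936", "3893")
}

# underlying causes of death (ICD-10) for deaths without a prior cancer
cf_noncancer_causes <- function() {
  c("I21.0", "I25.1", "I64", "J44.9", "E11.9", "G30.9", "J18.9",
    "N18.9", "K70.3", "V89.2")
}

# engine-generated dataset columns and their built-in dictionary metadata
cf_engine_column_metadata <- function() {
  data.table::data.table(
    name = c("participant_id", "cause_of_death", "start_date", "exit_date",
             "status", "person_days", "event_date", "event_site",
             "event_histology", "event_seer_group", "event_stage",
             "event_grade", "event_sequence", "event_cause",
             "endpoint_indicator"),
    label = c("Universal participant key",
              "Underlying cause of death (ICD)",
              "Start of follow-up", "End of follow-up (exit)",
              "Exit status", "Person-time under observation",
              "Qualifying endpoint event date", "Endpoint ICD-O-3 site",
              "Endpoint ICD-O-3 histology", "Endpoint SEER site group",
              "Endpoint stage at diagnosis", "Endpoint grade at diagnosis",
              "Endpoint primary sequence number",
              "Qualifying cause of death (ICD)",
              "Endpoint occurred on/before reference date"),
    dtype = c("character", "character", "date", "date", "categorical",
              "continuous", "date", "character", "character", "categorical",
              "categorical", "categorical", "continuous", "character",
              "flag"),
    value_labels = c("", "", "", "",
                     paste("event=Endpoint event",
                           "other_cancer=Censored: other cancer",
                           "surgery=Censored: surgery",
                           "death=Censored: death",
                           "admin_censor=Censored: administrative",
                           sep = "|"),
                     "", "", "", "", "", "", "", "", "", "0=No|1=Yes"),
    units = c("", "", "", "", "", "days", "", "", "", "", "", "", "", "",
              ""),
    source = "engine"
  )
}
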