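# Shared fixture builders: everything is generated in code at test time.

# claims table for a single patient
claims_df <- function(dates, setting = "outpatient", code = "428") {
  data.frame(patient_id = "P1", setting = rep_len(setting, length(dates)),
             service_date = as.Date(dates), code = rep_len(code, length(dates)),
             stringsAsFactors = FALSE)
}

# minimal linked dataset built by hand around one diagnosis date per patient
manual_dataset <- function(registry, claims = NULL, deaths = NULL,
                           enrollment = NULL) {
  if (is.null(claims)) {
    claims <- data.frame(patient_id = character(0), setting = character(0),
                         service_date = as.Date(character(0)),
                         code = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(deaths)) {
    deaths <- data.frame(patient_id = character(0),
                         death_date = as.Date(character(0)),
                         cause_code = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(enrollment)) {
    enrollment <- data.frame(patient_id = registry$patient_id,
                             last_seen = as.Date("2015-12-31"),
                             stringsAsFactors = FALSE)
  }
  structure(list(registry = registry, claims = claims, deaths = deaths,
                 enrollment = enrollment, truth = NULL),
            class = "linked_dataset")
}

manual_registry <- function(ids, diagnosis = "2010-06-15", site = "lung",
                            sex = "male", age = 70, stage = "localized") {
  data.frame(patient_id = ids, sex = rep_len(sex, length(ids)),
             birth_date = as.Date(diagnosis) - round(age * 365.25),
             site = rep_len(site, length(ids)),
             diagnosis_date = as.Date(rep_len(diagnosis, length(ids))),
             stage = rep_len(stage, length(ids)),
             histology = NA_character_,
             age = rep_len(age, length(ids)), stringsAsFactors = FALSE)
}

# small fast scenario for property tests
small_scenario <- function(n = 2000, seed = 1, claims_rate = 8,
                           claims_horizon_months = 36, ...) {
  scenario_config(n_patients = n, seed = seed, claims_rate = claims_rate,
                  claims_horizon_months = claims_horizon_months, ...)
}

# independent hand-coded Cox partial log-likelihood (no ties) used as the
# brute-force oracle; written against the definition, not fit_cox
hand_cox_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
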