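# Endpoint construction: classify each death as death from the index cancer
# vs death from other causes (simplified SEER-style prefix rule keyed by the
# index site), and assemble survival outcomes.

#' Cause-of-death map
#'
#' For each registry site, the set of underlying-cause code prefixes counted
#' as death from that cancer, plus ill-defined codes attributable to the
#' index cancer shared across sites. The full SEER cause-specific death
#' classification is an external multi-table document; this reduces it to a
#' configurable prefix map, which is exact for the sentinel codes the
#' synthetic generator emits and approximates it for real ICD codes.
#'
#' @param sites character vector of registry sites the map must cover.
#' @param extra named list site -> extra prefixes to merge in.
#' @param ill_defined prefixes attributable to the index cancer for every
#'   site (ill-defined/unknown primary deaths).
#' @return object of class `cause_map` (named list of prefix vectors).
#' @export
default_cause_map <- function(sites = site_levels(), extra = list(),
                              ill_defined = c("199", "C80", "R99")) {
  icd <- list(breast = c("174", "175", "C50"),
              colorectal = c("153", "154", "C18", "C19", "C20"),
              liver = c("155", "C22"),
              lung = c("162", "C34"),
              oral = c("140", "141", "143", "144", "145", "146", "148", "149",
                       "C0"))
  m <- lapply(sites, function(s) {
    unique(c(paste0("C-", s), icd[[s]] %||% character(0),
             extra[[s]] %||% character(0), ill_defined))
  })
  names(m) <- sites
  structure(m, class = "cause_map")
}

#' Classify one death as cancer vs noncancer
#'
#' @param cause_code underlying-cause code on the death record.
#' @param site the patient's index cancer site.
#' @param cause_map a [default_cause_map()]-style map.
#' @return `"cancer_death"` or `"noncancer_death"`.
#' @export
classify_death <- function(cause_code, site, cause_map = default_cause_map()) {
  bad <- setdiff(unique(site), names(cause_map))
  if (length(bad)) {
    stop("cause map has no entry for site(s): ", paste(bad, collapse = ", "))
  }
  out <- character(length(cause_code))
  for (s in unique(site)) {
    sel <- site == s
    out[sel] <- ifelse(codes_match(as.character(cause_code[sel]),
                                   cause_map[[s]]),
                       "cancer_death", "noncancer_death")
  }
  out
}

#' Build survival outcomes from the linked tables
#'
#' Patients with a death record (dated within the death-data horizon) get
#' the classified cause and time from diagnosis in days. Everyone else is
#' censored at the earlier of their enrollment last-seen date and the
#' enrollment horizon and is considered alive; censoring at the horizon is
#' tagged `admin_end`, earlier censoring `lost_to_followup`. Death records
#' dated before diagnosis are rejected with a logged id (patient then
#' censored on the no-death path). Patients in neither the death nor the
#' enrollment table are censored at diagnosis + 0 days and flagged
#' (`censor_source = "missing"`) — a linkage gap that should not occur.
#'
#' @param dataset a `linked_dataset`.
#' @param cause_map a `cause_map`; defaults to one covering the registry's
#'   sites.
#' @param death_horizon latest usable death date.
#' @param enrollment_horizon administrative censoring date for the living.
#' @return data.frame of class `survival_outcomes`: `patient_id`,
#'   `time_days`, `event` (`noncancer_death`/`cancer_death`/`censored`),
#'   `censor_source` (`none`/`admin_end`/`lost_to_followup`/`missing`).
#' @export
build_outcomes <- function(dataset,
                           cause_map = NULL,
                           death_horizon = "2016-12-31",
                           enrollment_horizon = "2015-12-31") {
  registry <- dataset$registry
  death_horizon <- as.Date(death_horizon)
  enrollment_horizon <- as.Date(enrollment_horizon)
  diag <- as.Date(registry$diagnosis_date)
  if (any(death_horizon < diag) || any(enrollment_horizon < diag)) {
    stop("horizons must not precede any diagnosis date")
  }
  if (is.null(cause_map)) {
    cause_map <- default_cause_map(unique(registry$site))
  }

  n <- nrow(registry)
  event <- rep("censored", n)
  censor_source <- rep("none", n)
  time_days <- rep(NA_real_, n)

  deaths <- dataset$deaths
  if (nrow(deaths)) {
    dd <- as.Date(deaths$death_date)
    m <- match(deaths$patient_id, registry$patient_id)
    pre <- dd < diag[m]
    if (any(pre)) {
      message("rejecting death record(s) dated before diagnosis: ",
              paste(deaths$patient_id[pre], collapse = ", "))
    }
    usable <- !pre & dd <= death_horizon
    mi <- m[usable]
    event[mi] <- classify_death(deaths$cause_code[usable],
                                registry$site[mi], cause_map)
    time_days[mi] <- as.numeric(dd[usable] - diag[mi])
  }

  alive <- event == "censored"
  last_seen <- rep(as.Date(NA), n)
  in_enroll <- registry$patient_id %in% dataset$enrollment$patient_id
  me <- match(registry$patient_id, dataset$enrollment$patient_id)
  last_seen[in_enroll] <- as.Date(dataset$enrollment$last_seen)[me[in_enroll]]

  cens_date <- pmin(last_seen, enrollment_horizon, na.rm = FALSE)
  sel <- alive & in_enroll
  time_days[sel] <- pmax(0, as.numeric(cens_date[sel] - diag[sel]))
  censor_source[sel] <- ifelse(cens_date[sel] >= enrollment_horizon,
                               "admin_end", "lost_to_followup")

  gap <- alive & !in_enroll
  if (any(gap)) {
    warning(sum(gap), " patient(s) in neither death nor enrollment data; ",
            "censored at diagnosis and flagged 'missing'")
    time_days[gap] <- 0
    censor_source[gap] <- "missing"
  }

  out <- data.frame(patient_id = registry$patient_id,
                    time_days = time_days, event = event,
                    censor_source = censor_source,
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_outcomes", "data.frame")
  out
}

#' Write survival outcomes as CSV
#' @param outcomes a `survival_outcomes` data.frame.
#' @param path output file.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}
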