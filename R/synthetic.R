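# Synthetic linked registry/claims/death data with known ground truth.
#
# The generator emulates the three-way linkage of a cancer registry, an
# insurance-claims database and a cause-of-death file: true comorbidity
# status is drawn from a one-factor Gaussian copula with configurable
# marginal prevalences; present conditions emit dated diagnosis claims as a
# homogeneous point process over a pre-diagnosis horizon; post-diagnosis
# survival follows two competing cause-specific exponential hazards, the
# noncancer hazard log-linear in the true condition weights. Every patient's
# true profile and uncensored event is kept in a truth table so downstream
# ascertainment and model fitting can be tested against known answers.

#' Scenario configuration for the synthetic cohort generator
#'
#' @param n_patients number of patients.
#' @param site_mix named proportions over cancer sites
#'   (breast/colorectal/liver/lung/oral); must sum to 1.
#' @param sex_mix named proportions over `c("female","male")`.
#' @param age_distribution named probabilities over age bands
#'   `"15-64","65-74","75-84","85-94"` (any subset); ages are drawn uniformly
#'   inside the band.
#' @param stage_mix named proportions over
#'   `c("localized","regional","distant","others")`.
#' @param comorbidity_prevalence named vector over the 18 conditions:
#'   marginal probability each condition is truly present.
#' @param comorbidity_correlation latent one-factor correlation in `[0,1)`
#'   inducing pairwise association between conditions.
#' @param claims_rate expected diagnosis claims per truly-present condition
#'   per year over the emission horizon.
#' @param inpatient_share probability a claim is an inpatient record.
#' @param washout_leak_rate probability (scalar or named per condition) that
#'   a present condition emits claims only inside the 6-month washout before
#'   diagnosis, i.e. looks cancer-caused to the ascertainment rules.
#' @param true_weights named log hazard ratios (noncancer death) for a subset
#'   of conditions; unnamed conditions contribute 0.
#' @param noncancer_baseline baseline noncancer death hazard, events/year.
#' @param cancer_hazard cancer death hazard, events/year: a scalar, a named
#'   per-site vector, or a site x stage matrix.
#' @param age_weight,sex_weight optional log-hazard effects on noncancer
#'   death: per year of age (centred at 75) and for male sex.
#' @param dropout_rate loss-to-follow-up hazard (events/year); 0 disables.
#' @param diagnosis_window two dates bounding diagnosis dates.
#' @param claims_horizon_months how far before diagnosis claims can occur.
#' @param histology_mix named proportions over lung histologies
#'   (ADC/SCC/SCLC); other sites get `NA`.
#' @param admin_end administrative end of death follow-up.
#' @param enrollment_end administrative end of enrollment data.
#' @param seed integer RNG seed; identical seed + config gives identical
#'   tables.
#' @param catalog a [condition_catalog()] supplying claim code prefixes.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_patients = 1000,
                            site_mix = c(breast = 0.08, colorectal = 0.3,
                                         liver = 0.26, lung = 0.29, oral = 0.07),
                            sex_mix = c(female = 0.4, male = 0.6),
                            age_distribution = c("65-74" = 0.5, "75-84" = 0.35,
                                                 "85-94" = 0.15),
                            stage_mix = c(localized = 0.35, regional = 0.25,
                                          distant = 0.25, others = 0.15),
                            comorbidity_prevalence = reference_condition_prevalence("colorectal"),
                            comorbidity_correlation = 0.2,
                            claims_rate = 4,
                            inpatient_share = 0.2,
                            washout_leak_rate = 0,
                            true_weights = c("CHF" = 0.75, "CRF" = 0.80,
                                             "Dementia" = 0.66, "COPD" = 0.26,
                                             "DM W/O CC" = 0.28, "CVD" = 0.37),
                            noncancer_baseline = 0.03,
                            cancer_hazard = c(breast = 0.05, colorectal = 0.12,
                                              liver = 0.35, lung = 0.45, oral = 0.15),
                            age_weight = 0,
                            sex_weight = 0,
                            dropout_rate = 0,
                            diagnosis_window = c("2004-01-01", "2014-12-31"),
                            claims_horizon_months = 84,
                            histology_mix = c(ADC = 0.55, SCC = 0.30, SCLC = 0.15),
                            admin_end = "2016-12-31",
                            enrollment_end = "2015-12-31",
                            seed = 1,
                            catalog = condition_catalog()) {
  cfg <- list(n_patients = n_patients, site_mix = site_mix, sex_mix = sex_mix,
              age_distribution = age_distribution, stage_mix = stage_mix,
              comorbidity_prevalence = comorbidity_prevalence,
              comorbidity_correlation = comorbidity_correlation,
              claims_rate = claims_rate, inpatient_share = inpatient_share,
              washout_leak_rate = washout_leak_rate,
              true_weights = true_weights,
              noncancer_baseline = noncancer_baseline,
              cancer_hazard = cancer_hazard,
              age_weight = age_weight, sex_weight = sex_weight,
              dropout_rate = dropout_rate,
              diagnosis_window = as.Date(diagnosis_window),
              claims_horizon_months = claims_horizon_months,
              histology_mix = histology_mix,
              admin_end = as.Date(admin_end),
              enrollment_end = as.Date(enrollment_end),
              seed = as.integer(seed), catalog = catalog)
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      cfg$n_patients < 1) {
    stop("n_patients must be a positive count")
  }
  for (nm in c("site_mix", "sex_mix", "age_distribution", "stage_mix",
               "histology_mix")) {
    v <- cfg[[nm]]
    if (any(v < 0)) stop(nm, " has negative entries")
    if (abs(sum(v) - 1) > 1e-9) {
      stop(nm, " must sum to 1 (got ", format(sum(v), digits = 12), ")")
    }
  }
  conds <- cfg$catalog$conditions
  p <- cfg$comorbidity_prevalence
  if (is.null(names(p)) || !all(names(p) %in% conds)) {
    stop("comorbidity_prevalence must be named by catalog conditions")
  }
  if (any(p < 0 | p > 1)) stop("prevalences must lie in [0, 1]")
  if (length(cfg$true_weights) &&
      !all(names(cfg$true_weights) %in% conds)) {
    stop("unknown condition in true_weights: ",
         paste(setdiff(names(cfg$true_weights), conds), collapse = ", "))
  }
  if (cfg$comorbidity_correlation < 0 || cfg$comorbidity_correlation >= 1) {
    stop("comorbidity_correlation must be in [0, 1)")
  }
  rates <- c(cfg$claims_rate, cfg$noncancer_baseline,
             unlist(cfg$cancer_hazard), cfg$dropout_rate)
  if (any(rates < 0)) stop("rates and hazards must be nonnegative")
  leak <- cfg$washout_leak_rate
  if (any(leak < 0 | leak > 1)) stop("washout_leak_rate must be in [0, 1]")
  invisible(cfg)
}

# expand a scalar / named-vector parameter to one value per catalog condition
per_condition <- function(x, conditions, default = 0) {
  out <- rep(default, length(conditions))
  names(out) <- conditions
  if (length(x) == 1 && is.null(names(x))) {
    out[] <- x
  } else if (length(x)) {
    out[names(x)] <- x
  }
  out
}

cancer_rate_for <- function(cancer_hazard, site, stage) {
  if (is.matrix(cancer_hazard)) {
    rate <- cancer_hazard[cbind(site, stage)]
  } else if (!is.null(names(cancer_hazard))) {
    rate <- unname(cancer_hazard[site])
    rate[is.na(rate)] <- 0
  } else {
    rate <- rep(cancer_hazard, length(site))
  }
  rate[site == "none"] <- 0
  rate
}

draw_band_ages <- function(bands, n) {
  lo <- as.integer(sub("-.*", "", bands))
  hi <- as.integer(sub(".*-", "", bands))
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

#' Generate a synthetic linked cohort
#'
#' Draws patients (site, sex, age, stage, diagnosis date), true comorbidity
#' profiles from the latent-factor copula, pre-diagnosis claims for present
#' conditions, and post-diagnosis competing-risk death times; administratively
#' censors deaths at `admin_end`. Cause-of-death codes use two sentinel
#' families: `"C-<site>"` for death from the index cancer and ordinary
#' ICD-9-style codes for other causes, so the same cause classifier runs on
#' synthetic and real data.
#'
#' @param config a [scenario_config()].
#' @param noncancer if `TRUE`, generate a cancer-free comparison arm: no
#'   cancer record (site `"none"`, no stage), index date sampled uniformly
#'   over the diagnosis window so ascertainment windows are well defined,
#'   and no cancer death hazard.
#' @return object of class `linked_dataset`: data.frames `registry`,
#'   `claims`, `deaths`, `enrollment`, `truth`, plus the config as an
#'   attribute.
#' @export
generate_cohort <- function(config, noncancer = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- as.integer(config$n_patients)
  conds <- config$catalog$conditions
  ids <- sprintf("P%07d", seq_len(n))

  sex <- sample(names(config$sex_mix), n, TRUE, config$sex_mix)
  if (noncancer) {
    site <- rep("none", n)
    stage <- rep(NA_character_, n)
    histology <- rep(NA_character_, n)
  } else {
    site <- sample(names(config$site_mix), n, TRUE, config$site_mix)
    stage <- sample(names(config$stage_mix), n, TRUE, config$stage_mix)
    histology <- rep(NA_character_, n)
    lung <- site == "lung"
    if (any(lung)) {
      histology[lung] <- sample(names(config$histology_mix), sum(lung), TRUE,
                                config$histology_mix)
    }
  }
  band <- sample(names(config$age_distribution), n, TRUE,
                 config$age_distribution)
  age <- draw_band_ages(band, n)
  win <- as.numeric(config$diagnosis_window)
  diagnosis_date <- as.Date(floor(stats::runif(n, win[1], win[2] + 1)),
                            origin = "1970-01-01")
  birth_date <- diagnosis_date - round(age * 365.25 + stats::runif(n, 0, 365))

  ## --- true comorbidity profiles: one-factor Gaussian copula ---
  p <- per_condition(config$comorbidity_prevalence, conds)
  rho <- config$comorbidity_correlation
  f <- stats::rnorm(n)
  z <- sqrt(rho) * f + sqrt(1 - rho) * matrix(stats::rnorm(n * length(conds)), n)
  profile <- sweep(z, 2, stats::qnorm(p), "<") * 1L
  colnames(profile) <- conds

  ## --- claims for present conditions ---
  leak <- per_condition(config$washout_leak_rate, conds)
  pres <- which(profile == 1L, arr.ind = TRUE)
  claims <- data.frame(patient_id = character(0), setting = character(0),
                       service_date = as.Date(character(0)),
                       code = character(0), stringsAsFactors = FALSE)
  if (nrow(pres)) {
    pat <- pres[, 1]
    cond_idx <- pres[, 2]
    is_leak <- stats::runif(nrow(pres)) < leak[cond_idx]
    horizon_y <- config$claims_horizon_months / 12
    n_claims <- ifelse(is_leak,
                       1L + stats::rpois(nrow(pres), config$claims_rate * 0.5),
                       stats::rpois(nrow(pres), config$claims_rate * horizon_y))
    keep <- n_claims > 0
    if (any(keep)) {
      pat <- pat[keep]; cond_idx <- cond_idx[keep]
      is_leak <- is_leak[keep]; n_claims <- n_claims[keep]
      row_pat <- rep(pat, n_claims)
      row_cond <- rep(cond_idx, n_claims)
      row_leak <- rep(is_leak, n_claims)
      diag_num <- as.numeric(diagnosis_date)[row_pat]
      lo <- ifelse(row_leak,
                   as.numeric(add_months(diagnosis_date, -6L))[row_pat],
                   diag_num - config$claims_horizon_months * 30.44)
      service <- as.Date(floor(stats::runif(length(row_pat), lo, diag_num)),
                         origin = "1970-01-01")
      prefixes <- config$catalog$code_map
      code <- character(length(row_cond))
      for (j in unique(row_cond)) {
        sel <- row_cond == j
        px <- prefixes[[j]]
        code[sel] <- px[sample.int(length(px), sum(sel), replace = TRUE)]
      }
      setting <- ifelse(stats::runif(length(row_pat)) < config$inpatient_share,
                        "inpatient", "outpatient")
      claims <- data.frame(patient_id = ids[row_pat], setting = setting,
                           service_date = service, code = code,
                           stringsAsFactors = FALSE)
      claims <- claims[order(claims$patient_id, claims$service_date,
                             claims$code), ]
      rownames(claims) <- NULL
    }
  }

  ## --- competing-risk death times (years from diagnosis) ---
  w <- per_condition(config$true_weights, conds)
  lp <- drop(profile %*% w) +
    config$age_weight * (age - 75) +
    config$sex_weight * (sex == "male")
  rate_nc <- config$noncancer_baseline * exp(lp)
  rate_ca <- if (noncancer) rep(0, n) else
    cancer_rate_for(config$cancer_hazard, site, stage)

  t_nc <- ifelse(rate_nc > 0, stats::rexp(n, pmax(rate_nc, 1e-300)), Inf)
  t_ca <- ifelse(rate_ca > 0, stats::rexp(n, pmax(rate_ca, 1e-300)), Inf)
  t_event <- pmin(t_nc, t_ca)
  true_cause <- ifelse(is.infinite(t_event), "none",
                       ifelse(t_ca <= t_nc, "cancer", "noncancer"))

  death_date <- diagnosis_date + round(t_event * 365.25)
  observed <- is.finite(t_event) & death_date <= config$admin_end
  noncancer_codes <- c("I10", "I21", "I50", "I60", "J44", "N18", "K74", "E11")
  cause_code <- ifelse(true_cause == "cancer", paste0("C-", site),
                       sample(noncancer_codes, n, TRUE))
  deaths <- data.frame(patient_id = ids[observed],
                       death_date = death_date[observed],
                       cause_code = cause_code[observed],
                       stringsAsFactors = FALSE)

  last_seen <- rep(config$enrollment_end, n)
  if (config$dropout_rate > 0) {
    t_drop <- stats::rexp(n, config$dropout_rate)
    last_seen <- pmin(last_seen, diagnosis_date + round(t_drop * 365.25))
  }

  registry <- data.frame(patient_id = ids, sex = sex, birth_date = birth_date,
                         site = site, diagnosis_date = diagnosis_date,
                         stage = stage, histology = histology,
                         age = age, stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = ids, profile, check.names = FALSE,
                      stringsAsFactors = FALSE)
  truth$true_cause <- true_cause
  truth$true_time_years <- t_event
  enrollment <- data.frame(patient_id = ids, last_seen = last_seen,
                           stringsAsFactors = FALSE)

  ds <- structure(list(registry = registry, claims = claims, deaths = deaths,
                       enrollment = enrollment, truth = truth),
                  class = "linked_dataset")
  attr(ds, "config") <- config
  validate_linked_dataset(ds)
  ds
}

#' @rdname generate_cohort
#' @export
generate_noncancer_arm <- function(config) {
  generate_cohort(config, noncancer = TRUE)
}

#' Validate a linked dataset's relational invariants
#'
#' Checks that claims and death patient ids resolve in the registry, that
#' there is at most one death per patient, that recorded post-diagnosis
#' deaths are not dated before diagnosis, and (when a truth table is present)
#' that it covers every patient.
#'
#' @param ds a `linked_dataset`.
#' @return the dataset, invisibly; errors on violation.
#' @export
validate_linked_dataset <- function(ds) {
  ids <- ds$registry$patient_id
  if (anyDuplicated(ids)) stop("duplicate patient ids in registry")
  if (!all(ds$claims$patient_id %in% ids)) {
    stop("claims reference unknown patient ids")
  }
  if (!all(ds$deaths$patient_id %in% ids)) {
    stop("deaths reference unknown patient ids")
  }
  if (anyDuplicated(ds$deaths$patient_id)) {
    stop("more than one death record for a patient")
  }
  m <- match(ds$deaths$patient_id, ids)
  dd <- as.Date(ds$deaths$death_date)
  if (any(dd < as.Date(ds$registry$diagnosis_date)[m])) {
    stop("death recorded before diagnosis date")
  }
  if (!is.null(ds$truth) && !setequal(ds$truth$patient_id, ids)) {
    stop("truth table must cover every registry patient")
  }
  invisible(ds)
}

#' @export
print.linked_dataset <- function(x, ...) {
  cat("linked dataset:", nrow(x$registry), "patients,",
      nrow(x$claims), "claims,", nrow(x$deaths), "deaths\n")
  invisible(x)
}

#' Write / read a linked dataset as delimited text
#'
#' Five CSV files (`registry.csv`, `claims.csv`, `deaths.csv`,
#' `enrollment.csv`, `truth.csv`) with fixed column schemas; the reader
#' validates schemas and relational invariants.
#'
#' @param ds a `linked_dataset`.
#' @param dir output/input directory.
#' @export
write_linked_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("registry", "claims", "deaths", "enrollment", "truth")) {
    utils::write.csv(ds[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_linked_dataset
#' @export
read_linked_dataset <- function(dir) {
  need <- list(
    registry = c("patient_id", "sex", "site", "diagnosis_date", "stage"),
    claims = c("patient_id", "setting", "service_date", "code"),
    deaths = c("patient_id", "death_date", "cause_code"),
    enrollment = c("patient_id", "last_seen")
  )
  out <- list()
  for (nm in names(need)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing input table: ", f)
    tab <- utils::read.csv(f, stringsAsFactors = FALSE,
                           colClasses = c(patient_id = "character"))
    miss <- setdiff(need[[nm]], names(tab))
    if (length(miss)) {
      stop(nm, ".csv lacks required columns: ", paste(miss, collapse = ", "))
    }
    for (dc in intersect(c("service_date", "diagnosis_date", "death_date",
                           "last_seen", "birth_date"), names(tab))) {
      tab[[dc]] <- as.Date(tab[[dc]])
    }
    out[[nm]] <- tab
  }
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) {
    out$truth <- utils::read.csv(tf, stringsAsFactors = FALSE,
                                 check.names = FALSE,
                                 colClasses = c(patient_id = "character"))
  }
  ds <- structure(out, class = "linked_dataset")
  validate_linked_dataset(ds)
  ds
}
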