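# Actual-prognosis outputs: per-stratum absolute probabilities of dying
# from cancer, dying from other causes, and surviving, at fixed horizons,
# under competing risks; cross-tabulations of stage x age x comorbidity
# level; and survivor-prevalence counts by calendar year.

horizon_to_days <- function(y) ifelse(y == 5, 1826, round(365 * y))

age_band_of <- function(age, breaks = c(65, 75, 85, 95)) {
  labs <- paste0(breaks[-length(breaks)], "-", breaks[-1] - 1)
  as.character(cut(age, c(breaks[-length(breaks)] - 0.5,
                          breaks[length(breaks)] - 0.5), labels = labs))
}

#' Actual-prognosis grid under competing risks
#'
#' For every stratum (by default site x sex x age band x stage x comorbidity
#' level), estimates the Aalen-Johansen cumulative incidence of cancer death
#' and of other-cause death and evaluates it at the horizons (1y = 365,
#' 2y = 730, 5y = 1826 days); survival is the complement, so the three
#' probabilities sum to one in every cell. Cells are flagged when based on
#' fewer than 100 or 50 patients, and cells with fewer than 5 patients are
#' suppressed (probabilities masked).
#'
#' @param outcomes `survival_outcomes`.
#' @param levels data.frame `patient_id`, `tcci`, `level` (see
#'   [assign_level()]).
#' @param registry registry data.frame.
#' @param horizons_years numeric horizons.
#' @param strata which keys to stratify by, from `site`, `sex`, `age_band`,
#'   `stage`, `level`, `histology`, `period`.
#' @param age_breaks ascending band edges; patients outside are excluded.
#'   The default gives bands 65-74 / 75-84 / 85-94; use
#'   `c(30, 95)` for the pooled 30-94 band used for distant-stage
#'   histology comparisons.
#' @param period_breaks diagnosis-year edges for the optional `period`
#'   stratifier (e.g. `c(2004, 2011, 2015)` for 2004-2010 vs 2011-2014).
#' @return data.frame: stratum keys, `n`, flags `small_100`, `small_50`,
#'   `suppressed`, then one row per horizon with `p_cancer_death`,
#'   `p_other_death`, `p_survival`.
#' @export
prognosis_grid <- function(outcomes, levels, registry,
                           horizons_years = c(1, 2, 5),
                           strata = c("site", "sex", "age_band", "stage",
                                      "level"),
                           age_breaks = c(65, 75, 85, 95),
                           period_breaks = c(2004, 2011, 2015)) {
  ml <- match(registry$patient_id, levels$patient_id)
  mo <- match(registry$patient_id, outcomes$patient_id)
  if (anyNA(mo)) stop("outcomes missing for some registry patients")

  keys <- data.frame(patient_id = registry$patient_id,
                     stringsAsFactors = FALSE)
  keys$site <- registry$site
  keys$sex <- registry$sex
  keys$age_band <- age_band_of(registry$age, age_breaks)
  keys$stage <- registry$stage
  keys$level <- levels$level[ml]
  if ("histology" %in% strata) keys$histology <- registry$histology
  if ("period" %in% strata) {
    yr <- as.integer(format(as.Date(registry$diagnosis_date), "%Y"))
    labs <- paste0(period_breaks[-length(period_breaks)], "-",
                   period_breaks[-1] - 1)
    keys$period <- as.character(cut(yr, period_breaks - 0.5, labels = labs))
  }
  strata <- intersect(strata, names(keys))
  complete <- stats::complete.cases(keys[, strata, drop = FALSE])

  time <- outcomes$time_days[mo]
  event <- outcomes$event[mo]
  grp <- interaction(keys[complete, strata, drop = FALSE], drop = TRUE,
                     sep = "\r")
  rows <- list()
  for (g in levels(grp)) {
    sel <- which(complete)[grp == g]
    n <- length(sel)
    fit <- cuminc(time[sel], event[sel])
    kv <- strsplit(g, "\r", fixed = TRUE)[[1]]
    for (h in horizons_years) {
      hd <- horizon_to_days(h)
      pc <- cif_at(fit, hd, "cancer_death")
      po <- cif_at(fit, hd, "noncancer_death")
      cell <- as.list(stats::setNames(kv, strata))
      cell$n <- n
      cell$horizon_years <- h
      if (n < 5) {
        cell$p_cancer_death <- NA_real_
        cell$p_other_death <- NA_real_
        cell$p_survival <- NA_real_
      } else {
        cell$p_cancer_death <- pc
        cell$p_other_death <- po
        cell$p_survival <- 1 - pc - po
      }
      cell$small_100 <- n < 100
      cell$small_50 <- n < 50
      cell$suppressed <- n < 5
      rows[[length(rows) + 1]] <- as.data.frame(cell,
                                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stage x age x comorbidity-level cross-tabulation
#'
#' Counts and percentages of patients by stage within each
#' site x age band x level column; percentages sum to 100 within a column
#' (up to printed rounding) and counts partition the cohort.
#'
#' @param registry registry data.frame.
#' @param levels data.frame with `patient_id` and `level`.
#' @param age_breaks band edges as in [prognosis_grid()].
#' @return data.frame `site`, `age_band`, `level`, `stage`, `n`, `pct`.
#' @export
stage_age_level_table <- function(registry, levels,
                                  age_breaks = c(65, 75, 85, 95)) {
  ml <- match(registry$patient_id, levels$patient_id)
  df <- data.frame(site = registry$site,
                   age_band = age_band_of(registry$age, age_breaks),
                   level = levels$level[ml],
                   stage = registry$stage, stringsAsFactors = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          df[, c("site", "age_band", "level", "stage")],
                          FUN = sum)
  tot <- stats::aggregate(list(col_n = agg$n),
                          agg[, c("site", "age_band", "level")], FUN = sum)
  agg <- merge(agg, tot, by = c("site", "age_band", "level"))
  agg$pct <- round_half_up(agg$n / agg$col_n * 100, 1)
  agg$col_n <- NULL
  agg[order(agg$site, agg$age_band, agg$level,
            match(agg$stage, stage_levels())), ]
}

#' Survivor prevalence by calendar year and time since diagnosis
#'
#' A patient counts as a survivor at the end of year `Y` if diagnosed in or
#' before `Y`, not recorded dead in or before `Y`, and covered by enrollment
#' through the end of `Y`. Survival-time bands are `Y` minus the diagnosis
#' year: 0-4, 5-9, 10-15, and more than 15 years.
#'
#' @param registry registry data.frame.
#' @param deaths deaths data.frame (`patient_id`, `death_date`).
#' @param enrollment enrollment data.frame (`patient_id`, `last_seen`).
#' @param as_of_years calendar years to evaluate.
#' @return data.frame `year`, `band`, `n` (plus a `total` row per year with
#'   band `"all"`).
#' @export
survivor_prevalence <- function(registry, deaths, enrollment, as_of_years) {
  diag_year <- as.integer(format(as.Date(registry$diagnosis_date), "%Y"))
  md <- match(registry$patient_id, deaths$patient_id)
  death_year <- ifelse(is.na(md), NA_integer_,
                       as.integer(format(as.Date(deaths$death_date), "%Y"))[md])
  me <- match(registry$patient_id, enrollment$patient_id)
  last_seen <- as.Date(enrollment$last_seen)[me]

  rows <- list()
  for (Y in as_of_years) {
    eoy <- as.Date(sprintf("%04d-12-31", Y))
    alive <- diag_year <= Y &
      (is.na(death_year) | death_year > Y) &
      !is.na(last_seen) & last_seen >= eoy
    ys <- Y - diag_year[alive]
    band <- cut(ys, c(-1, 4, 9, 15, Inf),
                labels = c("0-4", "5-9", "10-15", ">15"))
    tab <- table(band)
    rows[[length(rows) + 1]] <- data.frame(
      year = Y, band = c(names(tab), "all"),
      n = c(as.numeric(tab), sum(alive)), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
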