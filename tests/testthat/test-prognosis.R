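make_levels <- function(ids, level = 0L, tcci = 0) {
  data.frame(patient_id = ids, tcci = tcci, level = level,
             stringsAsFactors = FALSE)
}

test_that("a stratum with no deaths reports certain survival", {
  reg <- manual_registry(sprintf("P%02d", 1:8))
  out <- build_outcomes(manual_dataset(reg))
  grid <- prognosis_grid(out, make_levels(reg$patient_id), reg,
                         strata = c("site", "stage"))
  expect_true(all(grid$p_survival == 1))
  expect_true(all(grid$p_cancer_death == 0))
})

test_that("the hand-computed competing-risks cell is reproduced", {
  # the 5-subject Aalen-Johansen toy mapped through the grid at t = 4 days
  reg <- manual_registry(sprintf("P%d", 1:5))
  out <- data.frame(patient_id = reg$patient_id, time_days = 1:5,
                    event = c("cancer_death", "noncancer_death", "censored",
                              "cancer_death", "censored"),
                    censor_source = "none", stringsAsFactors = FALSE)
  grid <- prognosis_grid(out, make_levels(reg$patient_id), reg,
                         horizons_years = 4 / 365, strata = "site")
  expect_equal(grid$p_cancer_death, 0.5)
  expect_equal(grid$p_other_death, 0.2)
  expect_equal(grid$p_survival, 0.3)
  expect_true(grid$small_50 && grid$small_100)
})

test_that("probabilities conserve to one in every cell at every horizon", {
  cfg <- small_scenario(n = 3000, seed = 61)
  ds <- generate_cohort(cfg)
  out <- build_outcomes(ds)
  pm <- published_index_model()
  prof <- build_profiles(ds)
  sc <- tcci_score(prof, pm)
  lv <- data.frame(patient_id = prof$patient_id, tcci = sc,
                   level = assign_level(prof, sc))
  grid <- prognosis_grid(out, lv, ds$registry,
                         strata = c("site", "sex", "stage", "level"))
  ok <- !grid$suppressed
  expect_gt(sum(ok), 50)
  expect_lt(max(abs(grid$p_cancer_death[ok] + grid$p_other_death[ok] +
                      grid$p_survival[ok] - 1)), 1e-10)
  expect_true(all(grid$p_cancer_death[ok] >= 0 & grid$p_cancer_death[ok] <= 1))
})

test_that("small-stratum flags trip at exactly 100, 50 and 5", {
  mk <- function(n, site) {
    reg <- manual_registry(sprintf("%s%03d", site, 1:n), site = site)
    out <- build_outcomes(manual_dataset(reg))
    grid <- prognosis_grid(out, make_levels(reg$patient_id), reg,
                           horizons_years = 1, strata = "site")
    grid[, c("n", "small_100", "small_50", "suppressed")]
  }
  expect_equal(unlist(mk(100, "a")[, -1]), c(small_100 = FALSE,
                                             small_50 = FALSE,
                                             suppressed = FALSE))
  expect_equal(unlist(mk(99, "b")[, -1]), c(small_100 = TRUE,
                                            small_50 = FALSE,
                                            suppressed = FALSE))
  expect_equal(unlist(mk(49, "c")[, -1]), c(small_100 = TRUE,
                                            small_50 = TRUE,
                                            suppressed = FALSE))
  g4 <- mk(4, "d")
  expect_true(g4$suppressed)
  g5 <- mk(5, "e")
  expect_false(g5$suppressed)
})

test_that("pooled strata recompute identically to a direct pooled estimate", {
  cfg <- small_scenario(n = 2000, seed = 62)
  ds <- generate_cohort(cfg)
  out <- build_outcomes(ds)
  lv <- make_levels(ds$registry$patient_id)
  # grid pooled over everything (single stratum) vs direct cuminc
  reg <- ds$registry
  reg$site <- "pooled"
  grid <- prognosis_grid(out, lv, reg, strata = "site")
  mo <- match(reg$patient_id, out$patient_id)
  ci <- cuminc(out$time_days[mo], out$event[mo])
  for (h in c(1, 2, 5)) {
    hd <- comorbindex:::horizon_to_days(h)
    expect_identical(grid$p_cancer_death[grid$horizon_years == h],
                     cif_at(ci, hd, "cancer_death"))
    expect_identical(grid$p_other_death[grid$horizon_years == h],
                     cif_at(ci, hd, "noncancer_death"))
  }
})

test_that("other-cause mortality rises with comorbidity level by construction", {
  cfg <- scenario_config(
    n_patients = 25000, seed = 63, claims_rate = 8,
    claims_horizon_months = 36,
    true_weights = c("CHF" = 0.75, "CRF" = 0.8, "Dementia" = 0.66,
                     "COPD" = 0.26, "DM W/O CC" = 0.28, "CVD" = 0.37,
                     "MS LD" = 0.81),
    noncancer_baseline = 0.04)
  ds <- generate_cohort(cfg)
  prof <- build_profiles(ds)
  out <- build_outcomes(ds)
  pm <- published_index_model()
  sc <- tcci_score(prof, pm)
  lv <- data.frame(patient_id = prof$patient_id, tcci = sc,
                   level = assign_level(prof, sc))
  reg <- ds$registry
  reg$site <- "all"                       # pool sites; stratify by level only
  grid <- prognosis_grid(out, lv, reg, horizons_years = 5,
                         strata = c("site", "level"))
  p5 <- grid$p_other_death[order(grid$level)]
  expect_equal(length(p5), 3)
  expect_true(all(diff(p5) > 0))
})

test_that("stage-age-level tables partition the cohort and sum to 100", {
  cfg <- small_scenario(n = 4000, seed = 64)
  ds <- generate_cohort(cfg)
  lv <- make_levels(ds$registry$patient_id,
                    level = sample(0:2, 4000, TRUE))
  tab <- stage_age_level_table(ds$registry, lv)
  expect_equal(sum(tab$n), sum(!is.na(comorbindex:::age_band_of(ds$registry$age))))
  sums <- aggregate(pct ~ site + age_band + level, tab, sum)
  expect_true(all(abs(sums$pct - 100) <= 0.3))
  # a single homogeneous stratum is 100% by itself
  reg1 <- manual_registry("solo")
  t1 <- stage_age_level_table(reg1, make_levels("solo", 1L))
  expect_equal(t1$pct, 100)
  expect_equal(t1$n, 1)
})

test_that("survivor prevalence counts years alive under coverage", {
  reg <- manual_registry(c("A", "B"),
                         diagnosis = c("2003-05-01", "1996-07-01"))
  deaths <- data.frame(patient_id = "A", death_date = as.Date("2005-02-01"),
                       cause_code = "I10", stringsAsFactors = FALSE)
  enr <- data.frame(patient_id = c("A", "B"),
                    last_seen = as.Date(c("2015-12-31", "2015-12-31")))
  sp <- survivor_prevalence(reg, deaths, enr, 2003:2006)
  tot <- sp[sp$band == "all", ]
  # A diagnosed 2003, dead 2005: counted at ends of 2003 and 2004 only
  expect_equal(tot$n[tot$year == 2003], 2)
  expect_equal(tot$n[tot$year == 2004], 2)
  expect_equal(tot$n[tot$year == 2005], 1)
  expect_equal(tot$n[tot$year == 2006], 1)
  # banding: diagnosed 1996, evaluated 2014 -> > 15 years
  sp14 <- survivor_prevalence(reg, deaths, enr, 2014)
  expect_equal(sp14$n[sp14$band == ">15"], 1)
  # with no deaths, prevalence is nondecreasing in calendar year
  sp_nd <- survivor_prevalence(reg, deaths[0, , drop = FALSE], enr, 2000:2010)
  expect_true(all(diff(sp_nd$n[sp_nd$band == "all"]) >= 0))
})

test_that("period and histology stratifiers are available for subtype tables", {
  cfg <- small_scenario(n = 3000, seed = 65)
  ds <- generate_cohort(cfg)
  out <- build_outcomes(ds)
  lv <- make_levels(ds$registry$patient_id)
  lung <- ds$registry$site == "lung" & ds$registry$stage == "distant"
  reg <- ds$registry[lung, ]
  grid <- prognosis_grid(out, lv, reg, horizons_years = 1,
                         strata = c("histology", "period"),
                         age_breaks = c(30, 95),
                         period_breaks = c(2004, 2011, 2015))
  expect_true(all(grid$histology %in% c("ADC", "SCC", "SCLC")))
  expect_setequal(unique(grid$period), c("2004-2010", "2011-2014"))
})
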