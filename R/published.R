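# Published reference values shipped with the package: the national-data
# index weights (coefficient and hazard-ratio columns as printed) and the
# cohort prevalence/status/count margins for the five cancer cohorts and the
# noncancer cohort, ages 65-94. These are reporting-layer inputs: generator
# calibration targets, worked-example weights, and consistency-check material.
# The index itself can always be re-estimated from data with
# negative_deletion_fit().

#' Published index weight table (coefficients and hazard ratios)
#'
#' The fitted negative-deletion Cox model on the national five-cancer training
#' data: age and sex covariates, 15 retained condition main effects (Mild LD,
#' Ulcer and HT C were deleted for negative main effects), and the 28 pairwise
#' interactions among the 8 surviving members of the 11 most common
#' conditions. Coefficients are log hazard ratios for noncancer death.
#'
#' @return data.frame with columns `term`, `type` ("covariate", "main",
#'   "interaction"), `coef`, `hr` (the hazard ratio as printed, at its
#'   original rounding).
#' @export
published_weight_table <- function() {
  main <- data.frame(
    term = c("age", "sex", "AMI", "Old MI", "CHF", "PVD", "CVD", "COPD",
             "Dementia", "Paralysis", "DM W/O CC", "DM W CC", "CRF",
             "MS LD", "RD", "AIDS", "HT UC"),
    type = c("covariate", "covariate", rep("main", 15)),
    coef = c(0.06, 0.49, 0.27, 0.08, 0.75, 0.24, 0.37, 0.26,
             0.66, 0.34, 0.28, 0.38, 0.80, 0.81, 0.29, 1.65, 0.02),
    hr   = c(1.07, 1.63, 1.30, 1.08, 2.11, 1.27, 1.45, 1.30,
             1.94, 1.40, 1.32, 1.46, 2.23, 2.24, 1.33, 5.22, 1.02),
    stringsAsFactors = FALSE
  )
  inter <- data.frame(
    term = c("CHF:CVD", "CHF:COPD", "CHF:Dementia", "CHF:DM W/O CC",
             "CHF:DM W CC", "CHF:CRF", "CHF:HT UC",
             "CVD:COPD", "CVD:Dementia", "CVD:DM W/O CC", "CVD:DM W CC",
             "CVD:CRF", "CVD:HT UC",
             "COPD:Dementia", "COPD:DM W/O CC", "COPD:DM W CC", "COPD:CRF",
             "COPD:HT UC",
             "Dementia:DM W/O CC", "Dementia:DM W CC", "Dementia:CRF",
             "Dementia:HT UC",
             "DM W/O CC:DM W CC", "DM W/O CC:CRF", "DM W/O CC:HT UC",
             "DM W CC:CRF", "DM W CC:HT UC",
             "CRF:HT UC"),
    type = "interaction",
    coef = c(-0.12, -0.11, -0.31, 0.02, -0.08, 0.03, -0.17,
             0.01, -0.07, 0.12, -0.08, -0.16, 0.06,
             0.05, -0.10, -0.02, -0.17, 0.01,
             -0.02, -0.05, -0.35, -0.04,
             -0.11, 0.07, 0.05,
             0.11, 0.00,
             -0.05),
    hr   = c(0.88, 0.90, 0.74, 1.02, 0.93, 1.03, 0.85,
             1.01, 0.93, 1.13, 0.92, 0.85, 1.06,
             1.05, 0.90, 0.98, 0.84, 1.01,
             0.98, 0.95, 0.71, 0.96,
             0.89, 1.07, 1.05,
             1.12, 1.00,
             0.95),
    stringsAsFactors = FALSE
  )
  rbind(main, inter)
}

#' Published index model ready for scoring
#'
#' Wraps [published_weight_table()] into an `index_model` object so
#' [tcci_score()] and [assign_level()] can be used without refitting: the
#' worked-example path for users without access to the restricted source data.
#'
#' @return an `index_model` (see [negative_deletion_fit()]).
#' @export
published_index_model <- function() {
  w <- published_weight_table()
  main <- w[w$type == "main", ]
  inter <- w[w$type == "interaction", ]
  cov <- w[w$type == "covariate", ]
  new_index_model(
    condition_coef = stats::setNames(main$coef, main$term),
    interaction_coef = stats::setNames(inter$coef, inter$term),
    covariate_coef = stats::setNames(cov$coef, cov$term),
    deleted = c("Mild LD", "Ulcer", "HT C"),
    deletion_history = list(),
    top11 = c("HT UC", "DM W/O CC", "HT C", "COPD", "Ulcer", "Mild LD",
              "CVD", "DM W CC", "CRF", "CHF", "Dementia"),
    fit = NULL
  )
}

#' Published cohort margins: prevalence, status and comorbidity-count bands
#'
#' Reference counts for the five cancer cohorts (first invasive primary,
#' 2004-2014 diagnoses, ages 65-94) and the sampled noncancer cohort:
#' per-condition ascertained prevalence, vital status at end of follow-up,
#' and the distribution of the number of comorbid conditions (band "4+" pools
#' four or more). `pct` columns carry the percentages as printed (1 decimal,
#' half-up, cells with count < 5 suppressed).
#'
#' @return list with elements `cohort_sizes` (named numeric), `status`,
#'   `bands`, `conditions` (data.frames in long form), and `pooled_top11`
#'   (named numeric: the 11 most common conditions across the five cancer
#'   cohorts with their pooled counts, in published order).
#' @export
reference_prevalence <- function() {
  cohorts <- c("breast", "colorectal", "liver", "lung", "oral", "noncancer")
  sizes <- c(breast = 16734, colorectal = 65771, liver = 57201,
             lung = 64196, oral = 14351, noncancer = 268379)

  status <- data.frame(
    cohort = rep(cohorts[1:5], each = 3),
    status = rep(c("alive", "cancer_death", "other_death"), 5),
    n = c(11231, 3454, 2049,
          27239, 28723, 9809,
          9416, 43164, 4621,
          6759, 53193, 4244,
          5022, 7043, 2286),
    pct = c(67.1, 20.6, 12.2,
            41.4, 43.7, 14.9,
            16.5, 75.5, 8.1,
            10.5, 82.9, 6.6,
            35.0, 49.1, 15.9),
    stringsAsFactors = FALSE
  )

  bands <- data.frame(
    cohort = rep(cohorts, each = 5),
    band = rep(c("0", "1", "2", "3", "4+"), 6),
    n = c(4466, 4405, 3902, 2177, 1784,
          17696, 16241, 14554, 8805, 8475,
          9848, 11088, 13227, 10505, 12533,
          17633, 15767, 14092, 8539, 8165,
          4664, 3410, 2907, 1770, 1600,
          90435, 62370, 52817, 31694, 31063),
    pct = c(26.7, 26.3, 23.3, 13.0, 10.7,
            26.9, 24.7, 22.1, 13.4, 12.9,
            17.2, 19.4, 23.1, 18.4, 21.9,
            27.5, 24.6, 22.0, 13.3, 12.7,
            32.5, 23.8, 20.3, 12.3, 11.1,
            33.7, 23.2, 19.7, 11.8, 11.6),
    stringsAsFactors = FALSE
  )

  cond_order <- c("HT UC", "DM W/O CC", "HT C", "Ulcer", "COPD", "CVD",
                  "DM W CC", "Mild LD", "CHF", "CRF", "Dementia", "PVD",
                  "RD", "Paralysis", "AMI", "Old MI", "MS LD", "AIDS")
  counts <- list(
    "HT UC"     = c(7993, 29984, 26850, 27797, 5835, 112034),
    "DM W/O CC" = c(4211, 15080, 16482, 11851, 2993, 52033),
    "HT C"      = c(3619, 13783, 11555, 12387, 2379, 49735),
    "Ulcer"     = c(2384, 10565, 13707, 10632, 2024, 38874),
    "COPD"      = c(1758, 10554, 9651, 16045, 2500, 38696),
    "CVD"       = c(1909, 9360, 7341, 9159, 1865, 35611),
    "DM W CC"   = c(1399, 5045, 5734, 3901, 955, 17267),
    "Mild LD"   = c(1194, 4021, 23934, 3767, 1084, 16412),
    "CHF"       = c(689, 3780, 3358, 3682, 607, 13666),
    "CRF"       = c(679, 3847, 4146, 3206, 691, 12902),
    "Dementia"  = c(558, 2533, 1865, 2206, 364, 10563),
    "PVD"       = c(213, 962, 873, 1053, 208, 3799),
    "RD"        = c(191, 551, 587, 600, 126, 2653),
    "Paralysis" = c(116, 603, 440, 546, 146, 2456),
    "AMI"       = c(58, 567, 389, 578, 98, 2199),
    "Old MI"    = c(48, 483, 374, 611, 109, 1793),
    "MS LD"     = c(32, 142, 2564, 85, 65, 584),
    "AIDS"      = c(0, 0, 13, 5, 0, 22)
  )
  pcts <- list(
    "HT UC"     = c(47.8, 45.6, 46.9, 43.3, 40.7, 41.7),
    "DM W/O CC" = c(25.2, 22.9, 28.8, 18.5, 20.9, 19.4),
    "HT C"      = c(21.6, 21.0, 20.2, 19.3, 16.6, 18.5),
    "Ulcer"     = c(14.3, 16.1, 24.0, 16.6, 14.1, 14.5),
    "COPD"      = c(10.5, 16.0, 16.9, 25.0, 17.4, 14.4),
    "CVD"       = c(11.4, 14.2, 12.8, 14.3, 13.0, 13.3),
    "DM W CC"   = c(8.4, 7.7, 10.0, 6.1, 6.7, 6.4),
    "Mild LD"   = c(7.1, 6.1, 41.8, 5.9, 7.6, 6.1),
    "CHF"       = c(4.1, 5.7, 5.9, 5.7, 4.2, 5.1),
    "CRF"       = c(4.1, 5.8, 7.2, 5.0, 4.8, 4.8),
    "Dementia"  = c(3.3, 3.9, 3.3, 3.4, 2.5, 3.9),
    "PVD"       = c(1.3, 1.5, 1.5, 1.6, 1.4, 1.4),
    "RD"        = c(1.1, 0.8, 1.0, 0.9, 0.9, 1.0),
    "Paralysis" = c(0.7, 0.9, 0.8, 0.9, 1.0, 0.9),
    "AMI"       = c(0.4, 0.9, 0.7, 0.9, 0.7, 0.8),
    "Old MI"    = c(0.3, 0.7, 0.7, 1.0, 0.8, 0.7),
    "MS LD"     = c(0.2, 0.2, 4.5, 0.1, 0.5, 0.2),
    "AIDS"      = c(0, 0, 0.0, 0.0, 0, 0.0)
  )
  conditions <- data.frame(
    cohort = rep(cohorts, times = length(cond_order)),
    condition = rep(cond_order, each = length(cohorts)),
    n = unlist(counts[cond_order], use.names = FALSE),
    pct = unlist(pcts[cond_order], use.names = FALSE),
    stringsAsFactors = FALSE
  )

  pooled_top11 <- c("HT UC" = 98458, "DM W/O CC" = 50617, "HT C" = 43723,
                    "COPD" = 40508, "Ulcer" = 39312, "Mild LD" = 34000,
                    "CVD" = 29634, "DM W CC" = 17034, "CRF" = 12569,
                    "CHF" = 12116, "Dementia" = 7526)

  list(cohort_sizes = sizes, status = status, bands = bands,
       conditions = conditions, pooled_top11 = pooled_top11)
}

#' Default per-condition prevalence for the synthetic generator
#'
#' Ascertained prevalence proportions in a chosen reference cohort,
#' usable as `comorbidity_prevalence` in [scenario_config()].
#'
#' @param cohort one of "breast", "colorectal", "liver", "lung", "oral",
#'   "noncancer".
#' @return named numeric vector over the 18 conditions, in catalog order.
#' @export
reference_condition_prevalence <- function(cohort = "colorectal") {
  ref <- reference_prevalence()
  cohort <- match.arg(cohort, names(ref$cohort_sizes))
  sub <- ref$conditions[ref$conditions$cohort == cohort, ]
  p <- stats::setNames(sub$n / ref$cohort_sizes[[cohort]], sub$condition)
  p[condition_names()]
}
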