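# profiles whose column sums reproduce given carrier counts
profiles_with_counts <- function(counts, n) {
  conds <- condition_names()
  m <- matrix(0L, n, length(conds), dimnames = list(NULL, conds))
  for (cd in names(counts)) if (counts[[cd]] > 0) m[seq_len(counts[[cd]]), cd] <- 1L
  out <- data.frame(patient_id = sprintf("P%05d", seq_len(n)), m,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$n_conditions <- as.integer(rowSums(m))
  out
}

test_that("the most-common ranking reproduces the published ordering", {
  ref <- reference_prevalence()
  pooled <- ref$conditions[ref$conditions$cohort != "noncancer", ]
  counts <- tapply(pooled$n, pooled$condition, sum)
  # scale down 50x (order-preserving) to keep the fixture small
  scaled <- setNames(ceiling(counts / 50), names(counts))
  prof <- profiles_with_counts(as.list(scaled), max(scaled))
  expect_equal(select_top11(prof),
               c("HT UC", "DM W/O CC", "HT C", "COPD", "Ulcer", "Mild LD",
                 "CVD", "DM W CC", "CRF", "CHF", "Dementia"))
  # permutation invariance
  expect_equal(select_top11(prof[sample(nrow(prof)), ]), select_top11(prof))
})

test_that("count ties break alphabetically and scarcity errors", {
  counts <- as.list(setNames(rep(7, 12), condition_names()[1:12]))
  prof <- profiles_with_counts(counts, 20)
  expect_message(top <- select_top11(prof), "alphabetically")
  expect_equal(top, sort(condition_names()[1:12])[1:11])
  expect_error(select_top11(profiles_with_counts(list(CHF = 3), 10)),
               "need 11")
})

test_that("model_spec builds the full 18 + 55 term set", {
  top <- published_index_model()$top11
  spec <- model_spec(top)
  expect_length(spec$main, 18)
  expect_length(spec$interactions, 55)
  expect_false(anyDuplicated(spec$interactions) > 0)
  expect_length(model_spec(top, preset = "main_only")$interactions, 0)
  expect_equal(model_spec(top, preset = "common_only")$main, top)
})

test_that("deletion contract on the published term list leaves 28 pairs", {
  pm <- published_index_model()
  survivors <- setdiff(pm$top11, pm$deleted)
  expect_length(survivors, 8)
  expect_setequal(survivors, c("CHF", "CVD", "COPD", "Dementia", "DM W/O CC",
                               "DM W CC", "CRF", "HT UC"))
  idx <- combn(length(survivors), 2)
  cat18 <- condition_catalog()
  expected <- comorbindex:::canonical_pair(survivors[idx[1, ]],
                                           survivors[idx[2, ]], cat18)
  expect_length(expected, 28)
  expect_setequal(names(pm$interaction_coef), expected)
})

test_that("published single- and two-condition worked examples score right", {
  pm <- published_index_model()
  empty <- setNames(rep(0, 18), condition_names())
  expect_equal(tcci_score(empty, pm), 0)
  crf <- empty; crf["CRF"] <- 1
  expect_equal(tcci_score(crf, pm), 0.80)
  # CHF + CVD: 0.75 + 0.37 + interaction (-0.12) = 1.00
  chfcvd <- empty; chfcvd[c("CHF", "CVD")] <- 1
  expect_equal(tcci_score(chfcvd, pm), 1.00)
  # a deleted condition contributes nothing
  ulcer <- empty; ulcer["Ulcer"] <- 1
  expect_equal(tcci_score(ulcer, pm), 0)
})

test_that("scores are additive: mains plus pairwise interactions", {
  pm <- published_index_model()
  survivors <- setdiff(pm$top11, pm$deleted)
  # exhaustive over all 2^8 subsets of the surviving common conditions
  w <- published_weight_table()
  for (mask in 0:255) {
    present <- survivors[bitwAnd(mask, 2^(0:7)) > 0]
    prof <- setNames(as.numeric(condition_names() %in% present),
                     condition_names())
    expected <- sum(w$coef[w$type == "main" & w$term %in% present])
    for (i in seq_along(present)) for (j in seq_len(i - 1)) {
      pair <- w$coef[w$type == "interaction" &
                       w$term %in% paste(c(present[i], present[j]),
                                         c(present[j], present[i]),
                                         sep = ":")]
      expected <- expected + sum(pair)
    }
    expect_equal(tcci_score(prof, pm), expected, tolerance = 1e-12)
  }
})

test_that("level assignment reproduces the single-condition truth table", {
  pm <- published_index_model()
  cat18 <- condition_catalog()
  w <- published_weight_table()
  for (cd in condition_names()) {
    prof <- setNames(as.numeric(condition_names() == cd), condition_names())
    sc <- tcci_score(prof, pm)
    lvl <- assign_level(prof, sc, cat18$severe)
    weight <- if (cd %in% w$term[w$type == "main"])
      w$coef[w$term == cd & w$type == "main"] else 0
    expected <- if (weight > 0.66 || cd %in% cat18$severe) 2L else 1L
    expect_equal(lvl, expected, info = cd)
  }
  # the named anchor cases
  none <- setNames(rep(0, 18), condition_names())
  expect_equal(assign_level(none, tcci_score(none, pm)), 0L)
  copd <- none; copd["COPD"] <- 1   # 0.26 < 0.66 but severe
  expect_equal(assign_level(copd, tcci_score(copd, pm)), 2L)
  ami <- none; ami["AMI"] <- 1      # 0.27, not severe
  expect_equal(assign_level(ami, tcci_score(ami, pm)), 1L)
  crf <- none; crf["CRF"] <- 1      # 0.80 > 0.66
  expect_equal(assign_level(crf, tcci_score(crf, pm)), 2L)
  ulcer <- none; ulcer["Ulcer"] <- 1 # deleted: score 0 but not level 0
  expect_equal(assign_level(ulcer, tcci_score(ulcer, pm)), 1L)
})

test_that("negative-deletion loop removes protective conditions wholesale", {
  cfg <- scenario_config(
    n_patients = 8000, seed = 51, claims_rate = 8, claims_horizon_months = 36,
    comorbidity_prevalence = c("CHF" = 0.25, "CRF" = 0.2, "CVD" = 0.3,
                               "DM W/O CC" = 0.3, "HT UC" = 0.4),
    true_weights = c("CHF" = 0.7, "CRF" = 0.8, "CVD" = 0.4,
                     "DM W/O CC" = 0.35, "HT UC" = -0.5),
    noncancer_baseline = 0.06)
  ds <- generate_cohort(cfg)
  prof <- build_profiles(ds)
  out <- build_outcomes(ds)
  spec <- model_spec(c("CHF", "CRF", "CVD", "DM W/O CC", "HT UC"),
                     preset = "common_only")
  m <- suppressMessages(negative_deletion_fit(ds$registry, prof, out, spec))
  expect_true("HT UC" %in% m$deleted)
  expect_false("HT UC" %in% names(m$condition_coef))
  expect_false(any(grepl("HT UC", names(m$interaction_coef), fixed = TRUE)))
  expect_true(all(m$condition_coef >= 0))
  expect_gt(length(m$deletion_history), 0)
  expect_lte(length(m$deletion_history), 18)
  # deleted set grows monotonically across iterations
  dels <- lapply(m$deletion_history, `[[`, "deleted")
  expect_equal(length(unlist(dels)), length(unique(unlist(dels))))
  # scores of patients without deleted conditions are unchanged by deletion
  keep <- prof$`HT UC` == 0
  full <- m
  full$condition_coef <- c(full$condition_coef, "HT UC" = 0.123)
  expect_equal(tcci_score(prof[keep, ], m), tcci_score(prof[keep, ], full))
})

test_that("all-positive truth yields an empty deletion history", {
  cfg <- scenario_config(
    n_patients = 8000, seed = 52, claims_rate = 8, claims_horizon_months = 36,
    comorbidity_prevalence = c("CHF" = 0.3, "CRF" = 0.3),
    true_weights = c("CHF" = 0.9, "CRF" = 0.9),
    noncancer_baseline = 0.06)
  ds <- generate_cohort(cfg)
  spec <- model_spec(c("CHF", "CRF"), preset = "common_only")
  m <- suppressMessages(negative_deletion_fit(
    ds$registry, build_profiles(ds), build_outcomes(ds), spec))
  expect_length(m$deletion_history, 0)
  expect_length(m$deleted, 0)
})

test_that("nested splits are deterministic, proportional and restriction-compatible", {
  ids <- sprintf("ID%06d", 1:10000)
  s1 <- nested_split(ids, seed = 7)
  s2 <- nested_split(ids, seed = 7)
  expect_identical(s1, s2)
  expect_false(identical(nested_split(ids, seed = 8)$fold, s1$fold))
  pr <- table(s1$fold) / length(ids)
  expect_lt(abs(pr[["train"]] - 0.5), 0.02)
  expect_lt(abs(pr[["validation"]] - 0.25), 0.02)
  expect_lt(abs(pr[["test"]] - 0.25), 0.02)
  # restriction property: any subset inherits the global assignment
  set.seed(2)
  for (k in 1:5) {
    sub <- sample(ids, 500)
    ss <- nested_split(sub, seed = 7)
    expect_equal(ss$fold, s1$fold[match(sub, s1$patient_id)])
  }
  expect_error(nested_split(c("A", "A")), "unique")
})

test_that("index validation guards leakage and detects informative markers", {
  cfg <- scenario_config(
    n_patients = 6000, seed = 53, claims_rate = 8, claims_horizon_months = 36,
    comorbidity_prevalence = c("CHF" = 0.3, "CRF" = 0.25),
    true_weights = c("CHF" = 1.0, "CRF" = 1.1),
    noncancer_baseline = 0.05)
  ds <- generate_cohort(cfg)
  prof <- build_profiles(ds)
  out <- build_outcomes(ds)
  split <- nested_split(ds$registry$patient_id, 3)
  train_ids <- split$patient_id[split$fold == "train"]
  spec <- model_spec(c("CHF", "CRF"), preset = "common_only")
  reg_tr <- ds$registry[ds$registry$patient_id %in% train_ids, ]
  m <- suppressMessages(negative_deletion_fit(reg_tr, prof, out, spec))
  expect_error(validate_index(m, ds, prof, out, split, fold = "validation",
                              train_ids = split$patient_id),
               "leakage")
  auc <- validate_index(m, ds, prof, out, split, fold = "validation",
                        train_ids = train_ids, horizons_years = 5)
  expect_true(all(auc$auc > 0.5))
  # an uninformative marker sits near one half on the pooled fold
  val <- split$patient_id[split$fold == "validation"]
  sel <- ds$registry$patient_id %in% val
  mo <- match(ds$registry$patient_id[sel], out$patient_id)
  set.seed(4)
  a0 <- td_auc(rnorm(sum(sel)), out$time_days[mo],
               as.integer(out$event[mo] == "noncancer_death"), 1826)
  expect_lt(abs(a0 - 0.5), 0.06)
})

test_that("index models round-trip bit-exactly through the weights file", {
  pm <- published_index_model()
  pm$condition_coef["CRF"] <- 0.1 + 0.2   # not exactly representable sum
  f <- withr::local_tempfile(fileext = ".tsv")
  write_index_model(pm, f)
  back <- read_index_model(f)
  expect_identical(back$condition_coef, pm$condition_coef)
  expect_identical(back$interaction_coef, pm$interaction_coef)
  expect_identical(back$covariate_coef, pm$covariate_coef)
  expect_setequal(back$deleted, pm$deleted)
})
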