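# The engines are checked two ways: against brute-force oracles written from
# the definitions (grid scans, hand Aalen-Johansen, exhaustive pair
# enumeration) and against the independent survival / cmprsk implementations.

test_that("Newton fit equals the brute-force partial-likelihood maximizer", {
  # non-separating 6-subject toy: the event at time 3 has x = 0 inside a
  # mixed risk set, so the partial likelihood has an interior maximum
  time <- 1:6
  status <- c(1, 0, 1, 0, 1, 0)
  x <- c(1, 0, 0, 1, 1, 0)
  oracle <- optimize(function(b) hand_cox_loglik(b, time, status, x),
                     c(-5, 5), maximum = TRUE)$maximum
  f <- fit_cox(matrix(x, dimnames = list(NULL, "x")), time, status)
  expect_lt(abs(f$coef[["x"]] - oracle), 1e-3)
  expect_true(f$converged)
})

test_that("complete separation is flagged, not silently reported", {
  # events exactly when x = 1: the partial likelihood is monotone in beta
  time <- 1:6
  status <- c(1, 0, 1, 0, 1, 0)
  x <- c(1, 0, 1, 0, 1, 0)
  expect_warning(f <- fit_cox(matrix(x, dimnames = list(NULL, "x")),
                              time, status),
                 "diverging|separation")
  expect_true(f$diverged)
})

test_that("Efron and Breslow fits match the reference implementation", {
  library(survival)
  set.seed(7)
  for (rep in 1:4) {
    n <- 150
    x <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n), c = rbinom(n, 1, 0.2))
    eta <- 0.6 * x[, 1] - 0.3 * x[, 2]
    t_ev <- round(rexp(n, 0.1 * exp(eta)) * 20) + 1  # heavy ties
    t_cn <- round(rexp(n, 0.06) * 20) + 1
    time <- pmin(t_ev, t_cn)
    status <- as.integer(t_ev <= t_cn)
    for (tie in c("efron", "breslow")) {
      ours <- fit_cox(x, time, status, ties = tie)
      ref <- coxph(Surv(time, status) ~ x, ties = tie)
      expect_lt(max(abs(ours$coef - coef(ref))), 1e-4)
      expect_lt(max(abs(ours$se - sqrt(diag(vcov(ref))))), 1e-4)
      expect_lt(abs(ours$loglik["final"] - ref$loglik[2]), 1e-6)
    }
  }
})

test_that("a covariate unrelated to outcome stays within 3 SE of zero", {
  set.seed(11)
  n <- 5000
  x <- matrix(rbinom(n, 1, 0.3), dimnames = list(NULL, "noise"))
  time <- rexp(n, 0.1)
  status <- rbinom(n, 1, 0.7)
  f <- fit_cox(x, time, status)
  expect_lt(abs(f$coef[["noise"]]), 3 * f$se[["noise"]])
})

test_that("degenerate designs are rejected with clear errors", {
  x <- cbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0))
  expect_error(fit_cox(x, 1:4, c(1, 1, 0, 0)), "duplicate columns")
  expect_error(fit_cox(cbind(a = c(1, 0, 1, 0)), 1:4, rep(0, 4)), "no events")
  expect_error(fit_cox(cbind(a = rep(1, 4)), 1:4, c(1, 0, 1, 0)), "constant")
})

test_that("Kaplan-Meier matches closed forms and the reference", {
  # all events, no ties: S = 3/4, 2/4, 1/4, 0
  k <- km(1:4, rep(1, 4))
  expect_equal(k$surv, c(0.75, 0.5, 0.25, 0))
  # no events: S identically 1
  expect_equal(km_at(km(1:5, rep(0, 5)), 1:5), rep(1, 5))
  library(survival)
  set.seed(3)
  time <- round(rexp(80, 0.2) * 10) + 1
  status <- rbinom(80, 1, 0.6)
  ref <- survfit(Surv(time, status) ~ 1)
  expect_equal(km_at(km(time, status), ref$time), ref$surv, tolerance = 1e-12)
})

test_that("Aalen-Johansen reproduces the hand computation and identities", {
  # hand oracle: times 1(c1), 2(c2), 3(censor), 4(c1), 5(censor)
  # CIF1: 1/5 at t=1; + S(4-) * 1/2 = 3/5 * 1/2 at t=4 -> 0.2 then 0.5
  # CIF2: 4/5 * 1/4 = 0.2 at t=2
  ci <- cuminc(1:5, c("cancer_death", "noncancer_death", "censored",
                      "cancer_death", "censored"))
  expect_equal(cif_at(ci, 4, "cancer_death"), 0.5)
  expect_equal(cif_at(ci, 4, "noncancer_death"), 0.2)
  expect_equal(cif_at(ci, 0.5, "cancer_death"), 0)    # before first event
  expect_equal(cif_at(ci, 1, "cancer_death"), 0.2)
  # all censored: CIFs identically zero
  ci0 <- cuminc(1:4, rep("censored", 4))
  expect_equal(cif_at(ci0, 10, "cancer_death"), 0)
  # single cause: CIF = 1 - KM exactly
  set.seed(5)
  time <- round(rexp(60, 0.2) * 10) + 1
  status <- rbinom(60, 1, 0.7)
  ev <- ifelse(status == 1, "cancer_death", "censored")
  ci1 <- cuminc(time, ev)
  expect_equal(cif_at(ci1, ci1$time, "cancer_death"),
               1 - km_at(km(time, status), ci1$time), tolerance = 1e-12)
})

test_that("CIF conservation and monotonicity hold on random data", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 120
    time <- round(rexp(n, 0.2) * 15) + 1
    ev <- sample(c("cancer_death", "noncancer_death", "censored"), n, TRUE)
    ci <- cuminc(time, ev)
    expect_lt(max(abs(rowSums(ci$cif) + ci$surv - 1)), 1e-10)
    expect_true(all(diff(ci$cif[, 1]) >= 0))
    expect_true(all(diff(ci$cif[, 2]) >= 0))
    expect_true(all(ci$cif >= 0 & ci$cif <= 1))
  }
})

test_that("Aalen-Johansen agrees with the cmprsk implementation", {
  set.seed(8)
  n <- 200
  time <- round(rexp(n, 0.15) * 20) + 1
  ev <- sample(c("cancer_death", "noncancer_death", "censored"), n, TRUE,
               prob = c(0.4, 0.3, 0.3))
  ci <- cuminc(time, ev)
  code <- match(ev, c("cancer_death", "noncancer_death")) # NA = censored
  code[is.na(code)] <- 0
  ref <- cmprsk::cuminc(time, code, cencode = 0)
  for (j in 1:2) {
    est <- cmprsk::timepoints(ref, ci$time)$est[j, ]
    expect_equal(unname(cif_at(ci, ci$time, ci$causes[j])), unname(est),
                 tolerance = 1e-10)
  }
})

test_that("time-dependent AUC matches exhaustive pair enumeration", {
  # 4 subjects, all events at 1,2,3,4 with markers 4,3,1,2:
  # AUC(1)=1 (3/3 pairs), AUC(2)=1 (2/2), AUC(3)=0 (0/1), t=4 has no controls.
  # KM weights 2*f*S: .375, .25, .125 -> integrated = .625/.75
  expect_equal(td_auc(c(4, 3, 1, 2), 1:4, rep(1, 4), 4), 0.625 / 0.75)
  expect_equal(td_auc(c(4, 3, 1, 2), 1:4, rep(1, 4), 4, mode = "at_time"), 0)
  expect_equal(td_auc(c(4, 3, 1, 2), 1:4, rep(1, 4), 2, mode = "at_time"), 1)
  # perfect marker: every case outranks every control
  expect_equal(td_auc(-(1:10), 1:10, rep(1, 10), 10), 1)
  # ties in the marker count one half
  expect_equal(td_auc(c(1, 1), c(1, 2), c(1, 0), 2), 0.5)
  expect_error(td_auc(1:3, 1:3, rep(0, 3), 3), "no events")
})

test_that("AUC is invariant to monotone marker transforms and near 1/2 under the null", {
  set.seed(9)
  n <- 300
  marker <- rnorm(n)
  time <- round(rexp(n, 0.2) * 10) + 1
  status <- rbinom(n, 1, 0.6)
  a1 <- td_auc(marker, time, status, 8)
  expect_equal(td_auc(exp(marker), time, status, 8), a1)
  expect_equal(td_auc(marker * 100 - 3, time, status, 8), a1)
  set.seed(10)
  n <- 5000
  a0 <- td_auc(rnorm(n), round(rexp(n, 0.2) * 10) + 1,
               rbinom(n, 1, 0.6), 8)
  expect_lt(abs(a0 - 0.5), 0.03)
})

test_that("reporting rounds coefficients and hazard ratios independently", {
  f <- list(coef = c(a = 0.065, b = -0.125))
  rep_tab <- report_cox(f)
  expect_equal(rep_tab$coef, c(0.07, -0.13))       # half-up on the coef
  expect_equal(rep_tab$hr, c(1.07, 0.88))          # 2 dp of exp(unrounded)
})

test_that("design_matrix builds interactions as indicator products", {
  reg <- manual_registry(c("A", "B", "C"), sex = c("male", "female", "male"),
                         age = c(70, 80, 90))
  prof <- build_profiles(manual_dataset(reg))
  prof$CHF <- c(1L, 1L, 0L)
  prof$CVD <- c(1L, 0L, 0L)
  prof$n_conditions <- as.integer(rowSums(prof[, condition_names()]))
  expect_message(des <- design_matrix(reg, prof, "CHF:CVD"), "constant-zero")
  expect_equal(des$x[, "CHF:CVD"], des$x[, "CHF"] * des$x[, "CVD"])
  expect_equal(unname(des$x[, "sex"]), c(1, 0, 1))
  expect_false(any(colSums(abs(des$x)) == 0))
  expect_error(design_matrix(reg, prof, "CHF:Gout"), "malformed interaction")
})
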