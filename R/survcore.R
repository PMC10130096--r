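# Numerical engines: Cox proportional hazards by Newton maximization of the
# Efron (or Breslow) partial likelihood, the Kaplan-Meier product-limit
# estimator, the Aalen-Johansen cumulative incidence estimator under
# competing risks, and the incident/dynamic time-dependent AUC.
#
# The Efron score and information are accumulated in O(n p + m p^2) using
# risk-set reverse cumulative sums: for each unique event time k with d_k
# tied events, the tie-corrected denominators are
#   phi_{k,l} = R_k - (l/d_k) s_k ,  l = 0..d_k-1,
# with R_k the risk-set sum of exp(eta) and s_k the tied-death sum. Setting
# the l/d_k fraction to zero reproduces Breslow exactly, so both tie rules
# share one code path.

#' Build a design matrix of main effects and pairwise interactions
#'
#' Columns: `age` in years at diagnosis, `sex` (male = 1), one 0/1 indicator
#' per catalog condition, and for each requested pair `"A:B"` the elementwise
#' product of the two condition indicators. Constant-zero columns (condition
#' never observed, pair never co-occurring) are dropped with a message:
#' they carry no partial-likelihood information.
#'
#' @param registry registry data.frame with `patient_id`, `age`, `sex`.
#' @param profiles `comorbidity_profiles` aligned by `patient_id`.
#' @param interactions character vector of `"A:B"` pair names (see
#'   [model_spec()]), or `NULL` for main effects only.
#' @return list of class `cox_design`: `x` (numeric matrix), `patient_id`,
#'   `dropped` (names of removed constant columns).
#' @export
design_matrix <- function(registry, profiles, interactions = NULL) {
  m <- match(registry$patient_id, profiles$patient_id)
  if (anyNA(m)) stop("profiles missing for some registry patients")
  conds <- setdiff(names(profiles), c("patient_id", "n_conditions"))
  p <- as.matrix(profiles[m, conds, drop = FALSE])
  storage.mode(p) <- "double"
  x <- cbind(age = as.numeric(registry$age),
             sex = as.numeric(registry$sex == "male"),
             p)
  if (length(interactions)) {
    parts <- strsplit(interactions, ":", fixed = TRUE)
    bad <- interactions[!vapply(parts, function(pp)
      length(pp) == 2 && all(pp %in% conds), logical(1))]
    if (length(bad)) stop("malformed interaction terms: ",
                          paste(bad, collapse = ", "))
    ints <- vapply(parts, function(pp) p[, pp[1]] * p[, pp[2]],
                   numeric(nrow(p)))
    if (nrow(p) == 1) ints <- matrix(ints, nrow = 1)
    colnames(ints) <- interactions
    x <- cbind(x, ints)
  }
  keep <- colSums(abs(x)) > 0
  dropped <- colnames(x)[!keep]
  if (length(dropped)) {
    message("dropping ", length(dropped), " constant-zero column(s): ",
            paste(dropped, collapse = ", "))
  }
  structure(list(x = x[, keep, drop = FALSE],
                 patient_id = registry$patient_id,
                 dropped = dropped),
            class = "cox_design")
}

# per-unique-event-time Efron aggregates shared by loglik/score/information
efron_parts <- function(time, status, eta, x, frac_scale) {
  E <- exp(eta)
  ut <- sort(unique(time[status == 1]))
  m <- length(ut)
  pos <- findInterval(time, ut)           # subject at risk at ut[k] iff k <= pos
  ev_k <- findInterval(time, ut) * (status == 1)

  # risk-set reverse cumulative sums over unique-time groups (index 1..m)
  grp_sum <- function(v) {
    s <- rep(0, m + 1)
    agg <- rowsum(v, pos + 1L)            # groups 0..m -> rows
    s[as.integer(rownames(agg))] <- agg
    rev(cumsum(rev(s[-1])))               # R_k = sum over pos >= k
  }
  R <- grp_sum(E)
  U <- apply(x * E, 2, grp_sum)           # m x p risk sums of E * x
  if (m == 1) U <- matrix(U, nrow = 1)

  ev <- status == 1
  d <- tabulate(ev_k[ev], nbins = m)
  s_d <- rep(0, m)
  agg <- rowsum(E[ev], ev_k[ev])
  s_d[as.integer(rownames(agg))] <- agg
  V <- matrix(0, m, ncol(x))
  aggx <- rowsum((x * E)[ev, , drop = FALSE], ev_k[ev])
  V[as.integer(rownames(aggx)), ] <- aggx

  # all (k, l) tie terms at once; frac_scale 1 = Efron, 0 = Breslow
  k_all <- rep(seq_len(m), d)
  l_all <- sequence(d) - 1
  frac <- frac_scale * l_all / d[k_all]
  phi <- R[k_all] - frac * s_d[k_all]
  agg_by_k <- function(v) {
    out <- rep(0, m)
    a <- rowsum(v, k_all)
    out[as.integer(rownames(a))] <- a
    out
  }
  list(ut = ut, pos = pos, ev_k = ev_k, E = E, d = d,
       R = R, U = U, V = V, s_d = s_d, phi = phi, k_all = k_all,
       c1 = agg_by_k(1 / phi),
       c2 = agg_by_k(frac / phi),
       a1 = agg_by_k(1 / phi^2),
       a2 = agg_by_k(frac / phi^2),
       a3 = agg_by_k(frac^2 / phi^2))
}

cox_loglik <- function(parts, eta, status) {
  sum(eta[status == 1]) - sum(log(parts$phi))
}

cox_score_info <- function(parts, x, status) {
  m <- length(parts$ut)
  Ccum <- cumsum(parts$c1)
  w <- c(0, Ccum)[parts$pos + 1L]
  ev <- status == 1
  w[ev] <- w[ev] - parts$c2[parts$ev_k[ev]]
  Ew <- parts$E * w
  score <- colSums(x[ev, , drop = FALSE]) - colSums(x * Ew)
  info <- crossprod(x, x * Ew) -
    (crossprod(parts$U, parts$U * parts$a1) -
       crossprod(parts$U, parts$V * parts$a2) -
       crossprod(parts$V, parts$U * parts$a2) +
       crossprod(parts$V, parts$V * parts$a3))
  list(score = score, info = info)
}

#' Fit a Cox proportional-hazards model by partial likelihood
#'
#' Newton-type maximization of the Efron-tie partial likelihood (Breslow
#' available via `ties`), with step-halving. Convergence is declared when the
#' maximal absolute score falls below `tol_grad` or the relative change in
#' log partial likelihood falls below `tol_ll`. Monotone likelihoods
#' (complete separation) are flagged with a diverging-coefficient warning at
#' the iteration cap rather than an error.
#'
#' @param x numeric design matrix (rows = subjects) with unique column names,
#'   or a `cox_design`.
#' @param time follow-up times (any nonnegative scale).
#' @param status 1 = event of interest, 0 = censored (for cause-specific
#'   hazards, competing events are coded 0).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param init optional starting coefficients.
#' @param max_iter,tol_grad,tol_ll iteration controls.
#' @return object of class `cox_fit`: `coef`, `se`, `loglik` (initial and
#'   final), `score_norm`, `iter`, `converged`, `diverged`, `ties`, `n`,
#'   `n_event`, `var` (inverse information).
#' @export
fit_cox <- function(x, time, status, ties = c("efron", "breslow"),
                    init = NULL, max_iter = 30, tol_grad = 1e-8,
                    tol_ll = 1e-10) {
  ties <- match.arg(ties)
  if (inherits(x, "cox_design")) x <- x$x
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(time) == n, length(status) == n)
  status <- as.integer(status)
  if (sum(status) == 0) stop("no events: cannot fit")
  if (any(apply(x, 2, function(col) length(unique(col))) == 1)) {
    stop("constant column(s) in design: ",
         paste(colnames(x)[apply(x, 2, function(col)
           length(unique(col))) == 1], collapse = ", "))
  }
  if (anyDuplicated(t(x))) {
    dup <- colnames(x)[duplicated(t(x)) | duplicated(t(x), fromLast = TRUE)]
    stop("collinear duplicate columns: ", paste(dup, collapse = ", "))
  }

  frac_scale <- if (ties == "efron") 1 else 0
  xc <- sweep(x, 2, colMeans(x))          # centre for numerical stability
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)

  eta <- drop(xc %*% beta)
  parts <- efron_parts(time, status, eta, xc, frac_scale)
  ll <- cox_loglik(parts, eta, status)
  ll0 <- ll
  converged <- FALSE
  iter <- 0
  si <- cox_score_info(parts, xc, status)
  repeat {
    if (max(abs(si$score)) < tol_grad) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1
    step <- tryCatch(solve(si$info, si$score),
                     error = function(e) stop(
                       "singular information matrix (collinear design?)"))
    halving <- 0
    repeat {
      beta_new <- beta + step
      eta_new <- drop(xc %*% beta_new)
      parts_new <- efron_parts(time, status, eta_new, xc, frac_scale)
      ll_new <- cox_loglik(parts_new, eta_new, status)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      halving <- halving + 1
      if (halving > 20) { ll_new <- ll; beta_new <- beta; parts_new <- parts; break }
    }
    moved <- abs(ll_new - ll)
    beta <- beta_new; parts <- parts_new
    eta <- eta_new
    ll_prev <- ll; ll <- ll_new
    si <- cox_score_info(parts, xc, status)
    if (moved < tol_ll * (abs(ll) + tol_ll) &&
        max(abs(si$score)) < sqrt(tol_grad)) { converged <- TRUE; break }
  }

  diverged <- any(abs(beta) > 15)
  if (diverged) {
    warning("diverging coefficient(s) (monotone likelihood / separation): ",
            paste(colnames(x)[abs(beta) > 15], collapse = ", "))
  } else if (!converged) {
    warning("Cox fit did not converge in ", max_iter, " iterations")
  }

  var <- tryCatch(solve(si$info), error = function(e) matrix(NA, p, p))
  se <- sqrt(pmax(diag(var), 0))
  names(beta) <- names(se) <- colnames(x)
  structure(list(coef = beta, se = se,
                 loglik = c(initial = ll0, final = ll),
                 score_norm = max(abs(si$score)),
                 iter = iter, converged = converged, diverged = diverged,
                 ties = ties, n = n, n_event = sum(status), var = var),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox partial-likelihood fit (", x$ties, " ties): n = ", x$n,
      ", events = ", x$n_event, "\n", sep = "")
  tab <- data.frame(coef = round(x$coef, 4),
                    `exp(coef)` = round(exp(x$coef), 4),
                    se = round(x$se, 4), check.names = FALSE)
  print(utils::head(tab, 25))
  if (length(x$coef) > 25) cat("... (", length(x$coef) - 25, " more)\n")
  cat("log partial likelihood:", format(x$loglik["final"]),
      "| iterations:", x$iter,
      "| max |score|:", format(x$score_norm, digits = 3), "\n")
  invisible(x)
}

#' Round a fitted model for reporting
#'
#' Printed-table convention: coefficients to 2 decimals, hazard ratios to
#' 2 decimals of the *unrounded* coefficient's exponential.
#'
#' @param fit a `cox_fit`.
#' @return data.frame `term`, `coef`, `hr`.
#' @export
report_cox <- function(fit) {
  data.frame(term = names(fit$coef),
             coef = round_half_up(fit$coef, 2),
             hr = round_half_up(exp(fit$coef), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

# right-continuous step-function evaluation: value[i] holds on [times[i], times[i+1])
step_eval <- function(times, values, t, before = 1) {
  idx <- findInterval(t, times)
  c(before, values)[idx + 1L]
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time follow-up times.
#' @param status 1 = event, 0 = censored.
#' @return object of class `km_fit`: `time` (unique event times), `surv`
#'   (right-continuous), `n_risk`, `n_event`.
#' @export
km <- function(time, status) {
  stopifnot(length(time) >= 1, length(time) == length(status))
  ut <- sort(unique(time[status == 1]))
  if (length(ut) == 0) {
    return(structure(list(time = numeric(0), surv = numeric(0),
                          n_risk = numeric(0), n_event = numeric(0), n = length(time)),
                     class = "km_fit"))
  }
  st <- sort(time)
  n_risk <- length(time) - findInterval(ut, st, left.open = TRUE)
  n_event <- tabulate(match(time[status == 1], ut), nbins = length(ut))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = ut, surv = surv, n_risk = n_risk,
                 n_event = n_event, n = length(time)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve at times t
#' @param fit a `km_fit`.
#' @param t evaluation times.
#' @export
km_at <- function(fit, t) step_eval(fit$time, fit$surv, t)

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Nonparametric cumulative incidence of each cause in the presence of the
#' others: `CIF_k(t) = sum over event times s <= t of S(s-) d_k(s)/n(s)`,
#' with `S` the all-cause Kaplan-Meier. By construction the cause-specific
#' incidences and overall survival partition probability:
#' `sum_k CIF_k(t) + S(t) = 1` at every `t`.
#'
#' @param time follow-up times.
#' @param event character/factor per subject: one of `causes` or anything
#'   else for censored.
#' @param causes the competing causes to estimate.
#' @return object of class `cif_estimate`: `time` (unique uncensored event
#'   times), `cif` (matrix, one column per cause), `surv` (all-cause KM),
#'   `n`, `causes`.
#' @export
cuminc <- function(time, event,
                   causes = c("cancer_death", "noncancer_death")) {
  stopifnot(length(time) == length(event), all(time >= 0))
  event <- as.character(event)
  any_event <- event %in% causes
  ut <- sort(unique(time[any_event]))
  m <- length(ut)
  cif <- matrix(0, m, length(causes), dimnames = list(NULL, causes))
  surv <- numeric(m)
  if (m) {
    st <- sort(time)
    n_risk <- length(time) - findInterval(ut, st, left.open = TRUE)
    d <- vapply(causes, function(cz)
      tabulate(match(time[event == cz], ut), nbins = m), numeric(m))
    if (m == 1) d <- matrix(d, nrow = 1, dimnames = list(NULL, causes))
    surv <- cumprod(1 - rowSums(d) / n_risk)
    s_before <- c(1, surv[-m])
    cif <- vapply(seq_along(causes), function(j)
      cumsum(s_before * d[, j] / n_risk), numeric(m))
    if (m == 1) cif <- matrix(cif, nrow = 1)
    colnames(cif) <- causes
  }
  structure(list(time = ut, cif = cif, surv = surv, n = length(time),
                 causes = causes),
            class = "cif_estimate")
}

#' Evaluate cumulative incidence (or overall survival) at times t
#'
#' @param fit a `cif_estimate`.
#' @param t evaluation times.
#' @param cause one of the fitted causes, or `"surv"` for overall survival.
#' @export
cif_at <- function(fit, t, cause) {
  if (cause == "surv") return(step_eval(fit$time, fit$surv, t, before = 1))
  step_eval(fit$time, fit$cif[, cause], t, before = 0)
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat("Aalen-Johansen estimate: n =", x$n, ",",
      length(x$time), "event times, causes:",
      paste(x$causes, collapse = ", "), "\n")
  invisible(x)
}

#' Incident/dynamic time-dependent AUC
#'
#' Discrimination of a risk marker for event timing: at each event time `s`,
#' cases are the subjects with an event at `s` and controls are at-risk
#' subjects with follow-up beyond `s`; `AUC(s)` is the fraction of
#' case-control pairs ordered correctly by the marker (ties count 1/2). The
#' integrated summary up to horizon `t` weights each `AUC(s)` by the
#' concordance weight `2 f(s) S(s)` (Kaplan-Meier mass times survival), the
#' time-dependent generalization of Kendall-type concordance; `"at_time"`
#' returns `AUC(s)` at the last event time at or before `t`. Both are
#' invariant to strictly increasing transforms of the marker.
#'
#' @param marker numeric risk score, higher = higher risk.
#' @param time,status follow-up and event indicator (1 = event of interest).
#' @param t horizon on the same scale as `time`.
#' @param mode `"integrated_to"` (default) or `"at_time"`.
#' @return AUC in `[0, 1]`.
#' @export
td_auc <- function(marker, time, status, t,
                   mode = c("integrated_to", "at_time")) {
  mode <- match.arg(mode)
  stopifnot(length(marker) == length(time), all(is.finite(marker)))
  ev_times <- sort(unique(time[status == 1 & time <= t]))
  if (length(ev_times) == 0) stop("no events at or before the horizon")

  auc_k <- rep(NA_real_, length(ev_times))
  for (k in seq_along(ev_times)) {
    s <- ev_times[k]
    ctl <- marker[time > s]
    if (length(ctl) == 0) next
    cs <- marker[time == s & status == 1]
    sct <- sort(ctl)
    n_lt <- findInterval(cs, sct, left.open = TRUE)
    n_le <- findInterval(cs, sct)
    auc_k[k] <- mean((n_lt + 0.5 * (n_le - n_lt)) / length(ctl))
  }
  keep <- !is.na(auc_k)
  if (!any(keep)) stop("no event time with a nonempty control set")

  if (mode == "at_time") {
    return(auc_k[max(which(keep))])
  }
  fit <- km(time, status)
  # ev_times is exactly the leading run of the KM event-time grid
  K <- length(ev_times)
  s_at <- fit$surv[seq_len(K)]
  s_before <- c(1, fit$surv)[seq_len(K)]
  w <- 2 * (s_before - s_at) * s_at
  w <- w[keep]; auc_k <- auc_k[keep]
  if (sum(w) <= 0) return(mean(auc_k))
  sum(w * auc_k) / sum(w)
}

#' Bootstrap standard error for the time-dependent AUC
#'
#' Nonparametric subject-level bootstrap (no closed-form variance exists for
#' the integrated incident/dynamic AUC under ties and censoring).
#'
#' @inheritParams td_auc
#' @param B bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @return list with `auc`, `se`, `B`.
#' @export
td_auc_se <- function(marker, time, status, t,
                      mode = "integrated_to", B = 40, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  point <- td_auc(marker, time, status, t, mode)
  n <- length(marker)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(td_auc(marker[idx], time[idx], status[idx], t, mode),
             error = function(e) NA_real_)
  }, numeric(1))
  list(auc = point, se = stats::sd(reps, na.rm = TRUE), B = B)
}
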