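# Index construction: the main-effects + pairwise-interaction Cox model,
# the iterative negative-coefficient deletion loop, patient scoring, the
# three comorbidity levels, and deterministic nested data splits.

canonical_pair <- function(a, b, catalog = condition_catalog()) {
  i <- match(a, catalog$conditions); j <- match(b, catalog$conditions)
  ifelse(i <= j, paste(a, b, sep = ":"), paste(b, a, sep = ":"))
}

#' Select the most common conditions from pooled profiles
#'
#' Conditions ranked by descending pooled carrier count; ties broken
#' alphabetically (logged). Errors if fewer than `k` conditions are ever
#' present.
#'
#' @param profiles a `comorbidity_profiles` data.frame.
#' @param k how many to select (11 for the index interaction set).
#' @return character vector of `k` condition names, most common first.
#' @export
select_top11 <- function(profiles, k = 11) {
  conds <- setdiff(names(profiles), c("patient_id", "n_conditions"))
  if (nrow(profiles) == 0) stop("empty profile set")
  counts <- colSums(profiles[, conds, drop = FALSE])
  if (sum(counts > 0) < k) {
    stop("only ", sum(counts > 0), " conditions ever present; need ", k)
  }
  ord <- order(-counts, conds)
  if (anyDuplicated(counts[counts > 0])) {
    message("ties in condition counts broken alphabetically")
  }
  conds[ord][seq_len(k)]
}

#' Model specification: main effects plus common-pair interactions
#'
#' The index model's term set: age, sex and all 18 condition main effects,
#' plus the pairwise interactions of the `length(top)` most common
#' conditions (55 pairs for the default 11). Presets: `"main_interactions"`
#' (the default, main effects + pairs), `"main_only"` (no interactions),
#' `"common_only"` (only the common conditions, with their pairs) — the
#' model-comparison harness.
#'
#' @param top character vector of common conditions (see [select_top11()]).
#' @param preset one of `"main_interactions"`, `"main_only"`,
#'   `"common_only"`.
#' @param catalog a [condition_catalog()].
#' @return list of class `model_spec`: `main` (condition terms),
#'   `interactions` (pair terms `"A:B"`), `top`, `preset`.
#' @export
model_spec <- function(top, preset = c("main_interactions", "main_only",
                                       "common_only"),
                       catalog = condition_catalog()) {
  preset <- match.arg(preset)
  stopifnot(all(top %in% catalog$conditions))
  pairs <- if (preset == "main_only") character(0) else {
    idx <- utils::combn(length(top), 2)
    canonical_pair(top[idx[1, ]], top[idx[2, ]], catalog)
  }
  main <- if (preset == "common_only") top else catalog$conditions
  structure(list(main = main, interactions = pairs, top = top,
                 preset = preset, catalog = catalog),
            class = "model_spec")
}

new_index_model <- function(condition_coef, interaction_coef, covariate_coef,
                            deleted, deletion_history, top11, fit,
                            dropped = character(0)) {
  stopifnot(all(condition_coef >= 0))
  structure(list(condition_coef = condition_coef,
                 interaction_coef = interaction_coef,
                 covariate_coef = covariate_coef,
                 deleted = deleted,
                 deletion_history = deletion_history,
                 top11 = top11, fit = fit, dropped = dropped),
            class = "index_model")
}

#' @export
print.index_model <- function(x, ...) {
  cat("comorbidity index model:", length(x$condition_coef),
      "condition terms,", length(x$interaction_coef), "interaction terms\n")
  if (length(x$deleted)) {
    cat("  deleted (negative main effect):",
        paste(x$deleted, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit the index model with iterative negative-coefficient deletion
#'
#' Fits the cause-specific Cox model (event = noncancer death; cancer death
#' and loss to follow-up censor) on the supplied rows, then repeatedly
#' deletes *all* conditions whose main-effect coefficient is negative —
#' together with every interaction involving them — and refits, until all
#' retained condition main effects are nonnegative. Age and sex are never
#' deleted; interaction terms may keep negative coefficients. Terminates in
#' at most 18 iterations (each deletes at least one of 18 conditions);
#' deleting everything raises a "model degenerate" error.
#'
#' @param registry registry rows of the training fold.
#' @param profiles `comorbidity_profiles` (any superset of the fold).
#' @param outcomes `survival_outcomes` (any superset of the fold).
#' @param spec a [model_spec()].
#' @param ties passed to [fit_cox()].
#' @return an `index_model`: nonnegative `condition_coef`, retained
#'   `interaction_coef`, reported-but-not-scored `covariate_coef` (age,
#'   sex), the `deleted` set, a `deletion_history` of
#'   `(iteration, deleted conditions)`, and the final `cox_fit`.
#' @export
negative_deletion_fit <- function(registry, profiles, outcomes, spec,
                                  ties = "efron") {
  mo <- match(registry$patient_id, outcomes$patient_id)
  if (anyNA(mo)) stop("outcomes missing for some training patients")
  time <- outcomes$time_days[mo]
  status <- as.integer(outcomes$event[mo] == "noncancer_death")

  active <- spec$main
  pairs <- spec$interactions
  history <- list()
  dropped_all <- character(0)
  fit <- NULL
  for (iter in seq_len(length(spec$catalog$conditions))) {
    des <- design_matrix(registry, profiles, interactions = pairs)
    keep_cols <- c("age", "sex", intersect(colnames(des$x), c(active, pairs)))
    x <- des$x[, intersect(colnames(des$x), keep_cols), drop = FALSE]
    dropped_all <- union(dropped_all, des$dropped)
    fit <- fit_cox(x, time, status, ties = ties)
    cond_terms <- intersect(names(fit$coef), active)
    neg <- cond_terms[fit$coef[cond_terms] < 0]
    if (length(neg) == 0) break
    history[[length(history) + 1]] <- list(iteration = iter, deleted = neg)
    active <- setdiff(active, neg)
    pairs <- pairs[!vapply(strsplit(pairs, ":", fixed = TRUE),
                           function(pp) any(pp %in% neg), logical(1))]
    if (length(active) == 0) {
      stop("model degenerate: negative-deletion removed every condition")
    }
  }

  cond_terms <- intersect(names(fit$coef), active)
  pair_terms <- intersect(names(fit$coef), pairs)
  new_index_model(
    condition_coef = fit$coef[cond_terms],
    interaction_coef = fit$coef[pair_terms],
    covariate_coef = fit$coef[intersect(names(fit$coef), c("age", "sex"))],
    deleted = setdiff(spec$main, active),
    deletion_history = history,
    top11 = spec$top,
    fit = fit,
    dropped = dropped_all)
}

profile_matrix <- function(profiles) {
  if (is.data.frame(profiles)) {
    conds <- setdiff(names(profiles), c("patient_id", "n_conditions"))
    m <- as.matrix(profiles[, conds, drop = FALSE])
  } else {
    m <- matrix(as.numeric(profiles), nrow = 1,
                dimnames = list(NULL, names(profiles)))
  }
  storage.mode(m) <- "double"
  m
}

#' Score patients with a fitted index model
#'
#' The index value is the sum of the retained condition coefficients for the
#' patient's present conditions plus the retained interaction coefficients
#' for present pairs. Age and sex are reported by the model but excluded
#' from the score; conditions deleted by the negative-deletion loop
#' contribute 0.
#'
#' @param profiles a `comorbidity_profiles` data.frame or a single named
#'   0/1 vector over conditions.
#' @param model an `index_model` (fitted, or [published_index_model()]).
#' @return numeric score per profile row.
#' @export
tcci_score <- function(profiles, model) {
  m <- profile_matrix(profiles)
  score <- rep(0, nrow(m))
  cc <- model$condition_coef
  have <- intersect(names(cc), colnames(m))
  if (length(have)) score <- score + drop(m[, have, drop = FALSE] %*% cc[have])
  for (pt in names(model$interaction_coef)) {
    pp <- strsplit(pt, ":", fixed = TRUE)[[1]]
    if (all(pp %in% colnames(m))) {
      score <- score + model$interaction_coef[[pt]] * m[, pp[1]] * m[, pp[2]]
    }
  }
  unname(score)
}

#' Assign comorbidity levels 0 / 1 / 2
#'
#' Level 0: none of the 18 conditions present. Level 2: index score
#' strictly above the `cutoff` (0.66) *or* any severe-illness condition
#' present (conditions that frequently lead to organ failure or systemic
#' dysfunction override the score — e.g. COPD alone scores well below the
#' cutoff but is still coded severe). Everything else is level 1
#' (low/moderate) — including patients whose only conditions were deleted
#' from the index (score 0 but not condition-free).
#'
#' @param profiles `comorbidity_profiles` data.frame or single named vector.
#' @param tcci scores from [tcci_score()], aligned with `profiles`.
#' @param severe severe-illness condition names.
#' @param cutoff severe-score threshold (strict).
#' @return integer vector of levels in `{0, 1, 2}`.
#' @export
assign_level <- function(profiles, tcci,
                         severe = condition_catalog()$severe,
                         cutoff = 0.66) {
  m <- profile_matrix(profiles)
  stopifnot(length(tcci) == nrow(m))
  n_cond <- rowSums(m)
  any_severe <- rowSums(m[, intersect(severe, colnames(m)), drop = FALSE]) > 0
  lvl <- ifelse(n_cond == 0, 0L, ifelse(tcci > cutoff | any_severe, 2L, 1L))
  as.integer(lvl)
}

#' Deterministic nested train/validation/test assignment
#'
#' Each id is hashed (with the seed) to the unit interval and cut at 1/2 and
#' 3/4: about half the ids train, a quarter validate, a quarter test. The
#' assignment is a pure function of (id, seed), so the split of *any* subset
#' of patients is the restriction of the global split — the compatibility
#' needed when the same patients appear in pooled, per-site and
#' per-site-by-sex cohorts.
#'
#' @param ids unique patient ids.
#' @param seed integer.
#' @return data.frame of class `split_assignment`: `patient_id`, `fold`.
#' @export
nested_split <- function(ids, seed = 1) {
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  u <- hash_unit(ids, seed)
  fold <- cut(u, c(-1e-9, 0.5, 0.75, 1),
              labels = c("train", "validation", "test"))
  out <- data.frame(patient_id = as.character(ids),
                    fold = as.character(fold), stringsAsFactors = FALSE)
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Linear predictor of an index model (age + sex + score)
#'
#' The marker whose discrimination is validated: the fitted age and sex
#' coefficients applied to the covariates plus the comorbidity score.
#'
#' @param registry registry rows.
#' @param profiles aligned profiles.
#' @param model an `index_model`.
#' @return numeric vector.
#' @export
index_linear_predictor <- function(registry, profiles, model) {
  m <- match(registry$patient_id, profiles$patient_id)
  sc <- tcci_score(profiles[m, , drop = FALSE], model)
  cov <- model$covariate_coef
  a <- if ("age" %in% names(cov)) cov[["age"]] else 0
  s <- if ("sex" %in% names(cov)) cov[["sex"]] else 0
  a * as.numeric(registry$age) + s * as.numeric(registry$sex == "male") + sc
}

#' Validate index discrimination on a held-out fold
#'
#' Computes the incident/dynamic time-dependent AUC of the model's linear
#' predictor for noncancer death at the requested horizons, within each
#' sex-by-site cohort of the chosen fold. Asserts the leakage guard: the
#' evaluation fold must be disjoint from the training fold.
#'
#' @param model an `index_model` fitted on the training fold.
#' @param dataset the `linked_dataset`.
#' @param profiles,outcomes cohort-wide profiles and outcomes.
#' @param split a [nested_split()] assignment.
#' @param fold which fold to evaluate (`"validation"` or `"test"`).
#' @param train_ids ids the model was trained on (for the disjointness
#'   assertion).
#' @param horizons_years evaluation horizons; days = 365 * years with the
#'   5-year point at 1826 days.
#' @param mode AUC mode, see [td_auc()].
#' @param boot_B if > 0, bootstrap SE replicates per cohort.
#' @return data.frame: `cohort`, `horizon_years`, `n`, `n_event`, `auc`,
#'   `se` (NA unless `boot_B > 0`).
#' @export
validate_index <- function(model, dataset, profiles, outcomes, split,
                           fold = "validation", train_ids = NULL,
                           horizons_years = c(1, 2, 5),
                           mode = "integrated_to", boot_B = 0) {
  eval_ids <- split$patient_id[split$fold == fold]
  if (!is.null(train_ids) && length(intersect(train_ids, eval_ids))) {
    stop("leakage: evaluation fold overlaps the training ids")
  }
  registry <- dataset$registry[dataset$registry$patient_id %in% eval_ids, ,
                               drop = FALSE]
  marker <- index_linear_predictor(registry, profiles, model)
  mo <- match(registry$patient_id, outcomes$patient_id)
  time <- outcomes$time_days[mo]
  status <- as.integer(outcomes$event[mo] == "noncancer_death")

  horizon_days <- function(y) if (y == 5) 1826 else round(365 * y)
  cohort <- paste(registry$sex, registry$site, sep = "-")
  rows <- list()
  for (g in sort(unique(cohort))) {
    sel <- cohort == g
    for (h in horizons_years) {
      hd <- horizon_days(h)
      n_ev <- sum(status[sel] == 1 & time[sel] <= hd)
      if (sum(sel) == 0 || n_ev == 0) {
        warning("cohort ", g, " has no events before ", h, "y; skipped")
        next
      }
      if (boot_B > 0) {
        r <- td_auc_se(marker[sel], time[sel], status[sel], hd,
                       mode = mode, B = boot_B)
        auc <- r$auc; se <- r$se
      } else {
        auc <- td_auc(marker[sel], time[sel], status[sel], hd, mode = mode)
        se <- NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        cohort = g, horizon_years = h, n = sum(sel), n_event = n_ev,
        auc = auc, se = se, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Serialize / read an index model as a plain-text weights file
#'
#' Tab-separated `term`, `type`, `coef` with full `%.17g` precision, so a
#' round trip reproduces the coefficients bit-exactly.
#'
#' @param model an `index_model`.
#' @param path file path.
#' @export
write_index_model <- function(model, path) {
  fmt <- function(v, type) if (!length(v)) NULL else
    data.frame(term = names(v), type = type,
               coef = sprintf("%.17g", v), stringsAsFactors = FALSE)
  tab <- rbind(fmt(model$covariate_coef, "covariate"),
               fmt(model$condition_coef, "condition"),
               fmt(model$interaction_coef, "interaction"),
               if (length(model$deleted))
                 data.frame(term = model$deleted, type = "deleted",
                            coef = "", stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_index_model
#' @export
read_index_model <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  pick <- function(type) {
    sub <- tab[tab$type == type, ]
    stats::setNames(as.numeric(sub$coef), sub$term)
  }
  new_index_model(condition_coef = pick("condition"),
                  interaction_coef = pick("interaction"),
                  covariate_coef = pick("covariate"),
                  deleted = tab$term[tab$type == "deleted"],
                  deletion_history = list(), top11 = NULL, fit = NULL)
}
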