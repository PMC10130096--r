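# Comorbidity ascertainment from claims: lookback window, washout, and
# setting-specific claim-count rules.

#' Ascertainment policy: window, washout, claim-count rules
#'
#' A condition counts as present if, inside the qualifying window before
#' diagnosis, the patient has at least one inpatient claim for it, or at
#' least two outpatient claims with a pair of service dates more than 30 days
#' apart. The qualifying window is the half-open calendar-month interval
#' `[diagnosis - window_months, diagnosis - washout_months)`: the six months
#' immediately before diagnosis are always excluded (washout) so diagnoses
#' triggered by the cancer work-up do not masquerade as pre-existing
#' comorbidity.
#'
#' @param window_months lookback span: 30, 54 or 78 months (giving qualifying
#'   windows of 24, 48, 72 months once the washout is removed).
#' @param washout_months fixed at 6.
#' @param outpatient_min_claims,outpatient_min_gap_days outpatient rule:
#'   at least this many claims with some pair strictly more than
#'   `outpatient_min_gap_days` apart ("gap > 1 month" read as > 30 days).
#' @param inpatient_min_claims inpatient rule threshold.
#' @return object of class `ascertainment_policy`.
#' @export
ascertainment_policy <- function(window_months = 30,
                                 washout_months = 6,
                                 outpatient_min_claims = 2,
                                 outpatient_min_gap_days = 30,
                                 inpatient_min_claims = 1) {
  if (!window_months %in% c(30, 54, 78)) {
    stop("window_months must be one of 30, 54, 78")
  }
  if (window_months <= washout_months) {
    stop("window_months must exceed washout_months")
  }
  structure(list(window_months = as.integer(window_months),
                 washout_months = as.integer(washout_months),
                 qualifying_months = as.integer(window_months - washout_months),
                 outpatient_min_claims = as.integer(outpatient_min_claims),
                 outpatient_min_gap_days = as.integer(outpatient_min_gap_days),
                 inpatient_min_claims = as.integer(inpatient_min_claims)),
            class = "ascertainment_policy")
}

# codes matching a condition's prefixes (vectorized over codes)
codes_match <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (px in prefixes) hit <- hit | startsWith(codes, px)
  hit
}

#' Ascertain one condition for one patient
#'
#' @param claims data.frame of one patient's claims with columns `setting`
#'   ("inpatient"/"outpatient"), `service_date`, `code`.
#' @param condition a catalog condition name.
#' @param diagnosis_date the cancer diagnosis (index) date.
#' @param policy an [ascertainment_policy()].
#' @param catalog a [condition_catalog()].
#' @return `TRUE` if the condition qualifies as present.
#' @export
ascertain_condition <- function(claims, condition, diagnosis_date,
                                policy = ascertainment_policy(),
                                catalog = condition_catalog()) {
  if (!condition %in% catalog$conditions) {
    stop("unknown condition: ", condition)
  }
  diagnosis_date <- as.Date(diagnosis_date)
  if (nrow(claims) == 0) return(FALSE)
  dates <- as.Date(claims$service_date)
  late <- dates >= diagnosis_date
  if (any(late)) {
    warning(sum(late), " claim(s) on/after the diagnosis date ignored")
    claims <- claims[!late, , drop = FALSE]
    dates <- dates[!late]
  }
  hit <- codes_match(as.character(claims$code),
                     catalog$code_map[[condition]])
  lo <- add_months(diagnosis_date, -policy$window_months)
  hi <- add_months(diagnosis_date, -policy$washout_months)
  in_win <- hit & dates >= lo & dates < hi
  if (!any(in_win)) return(FALSE)
  inpat <- in_win & claims$setting == "inpatient"
  if (sum(inpat) >= policy$inpatient_min_claims) return(TRUE)
  out_dates <- dates[in_win & claims$setting == "outpatient"]
  length(out_dates) >= policy$outpatient_min_claims &&
    diff(range(as.numeric(out_dates))) > policy$outpatient_min_gap_days
}

#' Ascertain all conditions for all patients of a linked dataset
#'
#' Vectorized batch version of [ascertain_condition()]: one profile per
#' registry patient, in registry order, independent of the row order of the
#' claims table. Claims dated on/after the diagnosis date are dropped with a
#' message.
#'
#' @param dataset a `linked_dataset` (see [generate_cohort()] /
#'   [read_linked_dataset()]).
#' @param policy an [ascertainment_policy()].
#' @param catalog a [condition_catalog()].
#' @return data.frame of class `comorbidity_profiles`: `patient_id`, one 0/1
#'   column per condition, and `n_conditions`.
#' @export
build_profiles <- function(dataset, policy = ascertainment_policy(),
                           catalog = condition_catalog()) {
  registry <- dataset$registry
  claims <- dataset$claims
  conds <- catalog$conditions
  prof <- matrix(0L, nrow(registry), length(conds),
                 dimnames = list(NULL, conds))

  if (nrow(claims)) {
    cl <- data.table::as.data.table(claims)
    cl[, service_date := as.Date(service_date)]
    reg <- data.table::data.table(
      patient_id = registry$patient_id,
      diagnosis_date = as.Date(registry$diagnosis_date))
    reg[, `:=`(win_lo = add_months(diagnosis_date, -policy$window_months),
               win_hi = add_months(diagnosis_date, -policy$washout_months))]
    cl <- merge(cl, reg, by = "patient_id", sort = FALSE)

    n_late <- sum(cl$service_date >= cl$diagnosis_date)
    if (n_late > 0) {
      message(n_late, " claim(s) on/after the diagnosis date ignored")
    }
    cl <- cl[service_date >= win_lo & service_date < win_hi]

    if (nrow(cl)) {
      uc <- unique(cl$code)
      maps <- lapply(conds, function(cd) {
        m <- uc[codes_match(uc, catalog$code_map[[cd]])]
        if (length(m)) data.table::data.table(code = m, condition = cd)
      })
      code_map <- data.table::rbindlist(maps)
      if (nrow(code_map)) {
        cl <- merge(cl, code_map, by = "code", allow.cartesian = TRUE)
        agg <- cl[, .(
          n_inpat = sum(setting == "inpatient"),
          n_out = sum(setting == "outpatient"),
          out_gap = {
            d <- as.numeric(service_date[setting == "outpatient"])
            if (length(d) >= 2) diff(range(d)) else 0
          }
        ), by = .(patient_id, condition)]
        agg[, present := n_inpat >= policy$inpatient_min_claims |
              (n_out >= policy$outpatient_min_claims &
                 out_gap > policy$outpatient_min_gap_days)]
        agg <- agg[present == TRUE]
        if (nrow(agg)) {
          i <- match(agg$patient_id, registry$patient_id)
          j <- match(agg$condition, conds)
          prof[cbind(i, j)] <- 1L
        }
      }
    }
  }

  out <- data.frame(patient_id = registry$patient_id, prof,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$n_conditions <- as.integer(rowSums(prof))
  class(out) <- c("comorbidity_profiles", "data.frame")
  out
}

#' Prevalence table with small-cell suppression
#'
#' Per-cohort counts and percentages for each condition and for the
#' comorbid-condition-count bands 0/1/2/3/4+. Percentages are printed-style:
#' one decimal, half-up rounding; cells with 0 < count < 5 are masked
#' (`n` and `pct` set to `NA`, `suppressed = TRUE`) following the usual
#' administrative-data disclosure rule.
#'
#' @param profiles a `comorbidity_profiles` data.frame from
#'   [build_profiles()].
#' @param grouping optional vector of cohort labels, one per profile row;
#'   `NULL` treats everything as one cohort.
#' @return long data.frame: `cohort`, `kind` ("condition"/"band"), `name`,
#'   `n`, `pct`, `suppressed`.
#' @export
prevalence_table <- function(profiles, grouping = NULL) {
  conds <- setdiff(names(profiles), c("patient_id", "n_conditions"))
  if (is.null(grouping)) grouping <- rep("all", nrow(profiles))
  if (nrow(profiles) == 0) {
    warning("empty cohort: returning empty prevalence table")
    return(data.frame(cohort = character(0), kind = character(0),
                      name = character(0), n = numeric(0), pct = numeric(0),
                      suppressed = logical(0)))
  }
  band <- cut(pmin(profiles$n_conditions, 4L), c(-1, 0, 1, 2, 3, 4),
              labels = c("0", "1", "2", "3", "4+"))
  rows <- list()
  for (g in unique(grouping)) {
    sel <- grouping == g
    N <- sum(sel)
    cn <- colSums(profiles[sel, conds, drop = FALSE])
    bn <- table(band[sel])
    rows[[g]] <- data.frame(
      cohort = g,
      kind = c(rep("condition", length(conds)), rep("band", 5)),
      name = c(conds, names(bn)),
      n = c(as.numeric(cn), as.numeric(bn)),
      stringsAsFactors = FALSE)
    rows[[g]]$pct <- round_half_up(rows[[g]]$n / N * 100, 1)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$suppressed <- out$n > 0 & out$n < 5
  out$n[out$suppressed] <- NA
  out$pct[out$suppressed] <- NA
  out
}
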