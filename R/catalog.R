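#' Catalog of the 18 comorbid conditions
#'
#' The conditions ascertained from claims are the Charlson/Deyo set minus the
#' malignancy items (solid tumour, leukemia, lymphoma are excluded because the
#' cohort is defined by a cancer diagnosis), with mild liver disease extended
#' to cover chronic viral hepatitis B/C, and hypertension split into
#' uncomplicated (HT UC) and complicated (HT C). Five conditions that
#' frequently lead to organ failure or systemic dysfunction form the
#' severe-illness override list used in comorbidity-level assignment.
#'
#' The diagnosis-code map is prefix-based ICD-9-CM and is configuration, not
#' doctrine: pass your own `code_map` (e.g. read from YAML with
#' [read_code_map()]) to match a local coding practice.
#'
#' @param code_map named list: condition -> character vector of code prefixes.
#' @param severe character vector of severe-illness conditions.
#' @return an object of class `condition_catalog` with elements `conditions`
#'   (ordered names), `code_map`, `severe`.
#' @export
condition_catalog <- function(code_map = default_code_map(),
                              severe = c("CHF", "COPD", "Dementia", "CRF", "MS LD")) {
  conditions <- condition_names()
  if (!setequal(names(code_map), conditions)) {
    missing <- setdiff(conditions, names(code_map))
    extra <- setdiff(names(code_map), conditions)
    stop("code_map must cover exactly the 18 catalog conditions",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(conditions)) stop("condition names must be unique")
  if (!all(severe %in% conditions)) {
    stop("severe set contains non-catalog conditions: ",
         paste(setdiff(severe, conditions), collapse = ", "))
  }
  structure(
    list(conditions = conditions,
         code_map = code_map[conditions],
         severe = severe),
    class = "condition_catalog"
  )
}

#' @export
print.condition_catalog <- function(x, ...) {
  cat("condition catalog:", length(x$conditions), "conditions\n")
  cat("  severe set:", paste(x$severe, collapse = ", "), "\n")
  invisible(x)
}

#' The 18 condition names, in catalog order
#' @export
condition_names <- function() {
  c("AMI", "Old MI", "CHF", "PVD", "CVD", "COPD", "Dementia", "Paralysis",
    "DM W/O CC", "DM W CC", "CRF", "Mild LD", "MS LD", "RD", "AIDS",
    "Ulcer", "HT UC", "HT C")
}

#' Default ICD-9-CM prefix map for the 18 conditions
#'
#' Deyo-style prefixes, with viral hepatitis B/C (070.2/070.3/070.4/070.5/070.7)
#' folded into mild liver disease and hypertension split into uncomplicated
#' (401) vs complicated (402-405). Matching is by string prefix on the claim
#' diagnosis code.
#'
#' @return named list of character vectors.
#' @export
default_code_map <- function() {
  list(
    "AMI"       = c("410"),
    "Old MI"    = c("412"),
    "CHF"       = c("428"),
    "PVD"       = c("441", "4439", "7854", "V434", "0930"),
    "CVD"       = c("430", "431", "432", "433", "434", "435", "436", "437", "438"),
    "COPD"      = c("490", "491", "492", "493", "494", "495", "496", "5064"),
    "Dementia"  = c("290", "2941", "3310"),
    "Paralysis" = c("342", "3441"),
    "DM W/O CC" = c("2500", "2501", "2502", "2503", "2507"),
    "DM W CC"   = c("2504", "2505", "2506"),
    "CRF"       = c("585", "586", "5880", "V420", "V451", "V56"),
    "Mild LD"   = c("5712", "5714", "5715", "5716", "5733",
                    "0702", "0703", "0704", "0705", "0707"),
    "MS LD"     = c("5722", "5723", "5724", "5728", "4560", "4561", "4562"),
    "RD"        = c("7100", "7101", "7104", "7140", "7141", "7142", "71481", "725"),
    "AIDS"      = c("042", "043", "044"),
    "Ulcer"     = c("531", "532", "533", "534"),
    "HT UC"     = c("401"),
    "HT C"      = c("402", "403", "404", "405")
  )
}

#' Read / write a condition code map as YAML
#' @param path file path.
#' @export
read_code_map <- function(path) {
  m <- yaml::read_yaml(path)
  lapply(m, as.character)
}

#' @rdname read_code_map
#' @param code_map named list as returned by [default_code_map()].
#' @export
write_code_map <- function(code_map, path) {
  yaml::write_yaml(code_map, path)
  invisible(path)
}
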