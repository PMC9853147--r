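#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' ItemBank: a bank of developmental items
#'
#' Container for item metadata: identifier, descriptor text, source instrument,
#' modality (caregiver report vs direct administration), developmental
#' subdomain, a difficulty on the D-score scale, and optional bookkeeping
#' columns (equate group, latent concept for synthetic banks, facility rank,
#' material tag, energy level).
#'
#' Mandatory columns of `items`: `item_id`, `descriptor`, `modality`, `domain`
#' and at least one of `difficulty` / `true_difficulty`.  `difficulties()`
#' prefers the estimated `difficulty` column and falls back to the synthetic
#' ground truth.
#'
#' @slot items data.frame, one row per item.
#' @export
setClass("ItemBank", representation(items = "data.frame"))

setValidity("ItemBank", function(object) {
  it <- object@items
  need <- c("item_id", "descriptor", "modality", "domain")
  miss <- setdiff(need, names(it))
  if (length(miss)) {
    return(paste("missing mandatory item columns:", paste(miss, collapse = ", ")))
  }
  if (!any(c("difficulty", "true_difficulty") %in% names(it))) {
    return("need a 'difficulty' or 'true_difficulty' column")
  }
  if (anyDuplicated(it$item_id)) {
    dup <- unique(it$item_id[duplicated(it$item_id)])
    return(paste("duplicate item_id:", paste(dup, collapse = ", ")))
  }
  if (!all(it$modality %in% c("caregiver_report", "direct_admin"))) {
    return("modality must be 'caregiver_report' or 'direct_admin'")
  }
  if (!all(it$domain %in% SUBDOMAINS)) {
    bad <- unique(it$domain[!it$domain %in% SUBDOMAINS])
    return(paste("unknown subdomain(s):", paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Construct an ItemBank from a data.frame
#'
#' @param items data.frame with at least `item_id`, `descriptor`, `modality`,
#'   `domain` and one of `difficulty` / `true_difficulty`.
#' @return An [ItemBank-class] object.
#' @export
ItemBank <- function(items) {
  items <- as.data.frame(items)
  rownames(items) <- NULL
  new("ItemBank", items = items)
}

#' ReferenceCurve: age-conditional ability reference
#'
#' The reference curve maps age in months to the median `mu` and spread `sigma`
#' of the D-score distribution at that age.  It powers development-for-age
#' z-scores (DAZ), the EAP prior, and expected pass-age quantiles.  `mu` must be
#' strictly increasing in age and `sigma` strictly positive.
#'
#' @slot ages numeric, age grid in months (covering the instrument age span).
#' @slot mu numeric, median D-score at each grid age.
#' @slot sigma numeric, SD of the D-score at each grid age.
#' @export
setClass("ReferenceCurve",
  representation(ages = "numeric", mu = "numeric", sigma = "numeric")
)

setValidity("ReferenceCurve", function(object) {
  if (length(object@ages) < 2L) return("age grid needs at least two points")
  if (length(object@mu) != length(object@ages) ||
    length(object@sigma) != length(object@ages)) {
    return("ages, mu and sigma must have equal length")
  }
  if (is.unsorted(object@ages, strictly = TRUE)) return("ages must be strictly increasing")
  if (any(diff(object@mu) <= 0)) return("mu must be strictly increasing in age")
  if (any(object@sigma <= 0)) return("sigma must be positive everywhere")
  TRUE
})

#' ResponseSet: child-by-item dichotomous responses
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one `status`
#' assay (items as rows, children as columns; entries 0/1 or NA for
#' not-administered), item metadata as rowData and child metadata (at least
#' `age` in months) as colData.
#'
#' @export
setClass("ResponseSet", contains = "SummarizedExperiment")

setValidity("ResponseSet", function(object) {
  if (!"status" %in% assayNames(object)) return("assay 'status' is required")
  st <- assay(object, "status")
  if (!all(st %in% c(0, 1, NA))) return("status entries must be 0, 1 or NA")
  if (!"age" %in% names(colData(object))) return("colData must contain 'age' (months)")
  if (any(colData(object)$age < 0, na.rm = TRUE)) return("ages must be non-negative")
  TRUE
})

#' Construct a ResponseSet
#'
#' @param status numeric matrix of 0/1/NA responses, items in rows, children in
#'   columns; dimnames give item and child ids.
#' @param age numeric vector of child ages in months (one per column).
#' @param rowData,colData optional extra metadata merged into the container.
#' @return A [ResponseSet-class] object.
#' @export
ResponseSet <- function(status, age, rowData = NULL, colData = NULL) {
  status <- as.matrix(status)
  cd <- S4Vectors::DataFrame(age = as.numeric(age))
  if (!is.null(colData)) cd <- cbind(cd, S4Vectors::DataFrame(colData))
  rownames(cd) <- colnames(status)
  se <- SummarizedExperiment(
    assays = list(status = status),
    colData = cd
  )
  if (!is.null(rowData)) rowData(se) <- S4Vectors::DataFrame(rowData, row.names = rownames(status))
  new("ResponseSet", se)
}

#' Form: an ordered, grouped instrument
#'
#' An assembled instrument: an ordered vector of item ids, the form kind
#' (caregiver-reported short form or directly administered long form), optional
#' A/B/C administration groups (long form), an age-bracket start-rule table, the
#' stop-rule run length, and a provenance table recording why each item was
#' selected and which equate group it represents.
#'
#' @slot form_id character scalar.
#' @slot kind `"short_form"` or `"long_form"`.
#' @slot items character, ordered item ids (administration order).
#' @slot groups character of `"A"/"B"/"C"` parallel to `items`, or zero-length.
#' @slot start_rule data.frame with `bracket_lower` (months) and `start_index`.
#' @slot stop_rule_k integer, contiguous failures that stop administration.
#' @slot provenance data.frame keyed by `item_id` (equate group, reason, ...).
#' @export
setClass("Form", representation(
  form_id = "character", kind = "character", items = "character",
  groups = "character", start_rule = "dfOrNULL", stop_rule_k = "integer",
  provenance = "dfOrNULL"
))

setValidity("Form", function(object) {
  if (!object@kind %in% c("short_form", "long_form")) {
    return("kind must be 'short_form' or 'long_form'")
  }
  if (anyDuplicated(object@items)) return("form items must be unique")
  if (length(object@groups) && length(object@groups) != length(object@items)) {
    return("groups must be empty or parallel to items")
  }
  if (length(object@groups) && !all(object@groups %in% c("A", "B", "C"))) {
    return("groups must be labelled A, B or C")
  }
  if (!is.null(object@start_rule)) {
    sr <- object@start_rule
    if (!all(c("bracket_lower", "start_index") %in% names(sr))) {
      return("start_rule needs columns bracket_lower, start_index")
    }
    if (is.unsorted(sr$bracket_lower)) return("start_rule brackets must be ordered")
    if (is.unsorted(sr$start_index)) {
      return("start_index must be non-decreasing in age bracket")
    }
  }
  if (length(object@stop_rule_k) != 1L || object@stop_rule_k < 1L) {
    return("stop_rule_k must be a positive integer")
  }
  TRUE
})

#' Construct a Form
#'
#' @param items ordered character vector of item ids.
#' @param kind `"short_form"` or `"long_form"`.
#' @param form_id identifier for the form.
#' @param groups optional A/B/C labels parallel to `items`.
#' @param start_rule optional data.frame (`bracket_lower`, `start_index`).
#' @param stop_rule_k stop after this many contiguous failures (default 5).
#' @param provenance optional per-item selection record.
#' @return A [Form-class] object.
#' @export
Form <- function(items, kind, form_id = "form", groups = character(),
                 start_rule = NULL, stop_rule_k = 5L, provenance = NULL) {
  new("Form",
    form_id = form_id, kind = kind, items = as.character(items),
    groups = as.character(groups), start_rule = start_rule,
    stop_rule_k = as.integer(stop_rule_k), provenance = provenance
  )
}

#' EvaluationReport: psychometric evaluation of an assembled form
#'
#' @slot form_id character.
#' @slot daz_correlation numeric, correlation of form DAZ with full-bank DAZ.
#' @slot reliability numeric, separation reliability of the form scores.
#' @slot sem_by_age data.frame: age bin -> mean standard error of measurement.
#' @slot info_by_domain_age data.frame: domain x age bin -> share of information.
#' @slot admin_length data.frame: summary of items administered under rules.
#' @export
setClass("EvaluationReport", representation(
  form_id = "character", daz_correlation = "numeric", reliability = "numeric",
  sem_by_age = "dfOrNULL", info_by_domain_age = "dfOrNULL",
  admin_length = "dfOrNULL"
))
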