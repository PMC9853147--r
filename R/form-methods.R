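#' Accessors for Form objects
#'
#' @param x a [Form-class].
#' @name Form-accessors
NULL

#' @rdname Form-accessors
#' @export
setMethod("formItems", "Form", function(x) x@items)

#' @rdname Form-accessors
#' @export
setMethod("formGroups", "Form", function(x) {
  if (length(x@groups)) setNames(x@groups, x@items) else NULL
})

#' @rdname Form-accessors
#' @export
setMethod("startRule", "Form", function(x) x@start_rule)

#' @rdname Form-accessors
#' @export
setMethod("stopRuleK", "Form", function(x) x@stop_rule_k)

#' @rdname Form-accessors
#' @export
setMethod("provenance", "Form", function(x) x@provenance)

setMethod("show", "Form", function(object) {
  cat(sprintf(
    "Form '%s' (%s): %d items%s\n", object@form_id,
    sub("_", " ", object@kind), length(object@items),
    if (length(object@groups)) {
      paste0(" in groups ", paste(sprintf(
        "%s=%d", names(table(object@groups)), as.integer(table(object@groups))
      ), collapse = ", "))
    } else ""
  ))
  if (!is.null(object@start_rule)) {
    cat("  start rule over", nrow(object@start_rule), "age brackets; stop after",
        object@stop_rule_k, "contiguous failures\n")
  }
  invisible(object)
})

formToList <- function(form) {
  list(
    form_id = form@form_id,
    kind = form@kind,
    tool_version = as.character(packageVersion("raschform")),
    stop_rule_k = form@stop_rule_k,
    items = form@items,
    groups = if (length(form@groups)) form@groups else NULL,
    start_rule = form@start_rule,
    provenance = form@provenance
  )
}

#' Read / write a Form as JSON
#'
#' Serialises the ordered items, groups, start-rule table, stop-rule parameter
#' and per-item provenance with stable key order, stamped with the tool
#' version.
#'
#' @param form a [Form-class].
#' @param path file path.
#' @return `readForm()` returns a [Form-class]; `writeForm()` returns `path`
#'   invisibly.
#' @export
writeForm <- function(form, path) {
  jsonlite::write_json(formToList(form), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeForm
#' @export
readForm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("Form",
    form_id = obj$form_id, kind = obj$kind,
    items = as.character(obj$items),
    groups = if (is.null(obj$groups)) character() else as.character(obj$groups),
    start_rule = if (is.null(obj$start_rule)) NULL else as.data.frame(obj$start_rule),
    stop_rule_k = as.integer(obj$stop_rule_k),
    provenance = if (is.null(obj$provenance)) NULL else as.data.frame(obj$provenance)
  )
}

#' Printable administration sheet
#'
#' Writes a plain-text administration sheet: one line per item with position,
#' group, id and descriptor, preceded by the start-rule table.
#'
#' @param form a [Form-class].
#' @param bank an [ItemBank-class] for descriptors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAdminSheet <- function(form, bank, path) {
  it <- itemData(bank)
  ids <- formItems(form)
  grp <- formGroups(form)
  lines <- c(
    sprintf("%s (%s) - %d items", form@form_id, form@kind, length(ids)),
    sprintf("stop rule: %d contiguous failures", stopRuleK(form))
  )
  if (!is.null(startRule(form))) {
    sr <- startRule(form)
    lines <- c(lines, "start rule (bracket lower bound -> first item):",
               sprintf("  %2g mo -> item %d", sr$bracket_lower, sr$start_index))
  }
  lines <- c(lines, "", sprintf(
    "%3d. %s%s  %s", seq_along(ids),
    if (is.null(grp)) "" else paste0("[", grp[ids], "] "),
    ids, it$descriptor[match(ids, it$item_id)]
  ))
  writeLines(lines, path)
  invisible(path)
}
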