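#' Accessors for ItemBank objects
#'
#' `itemIds()` returns item identifiers in bank order; `nItems()` the number of
#' items; `difficulties()` the working difficulty of each item (the estimated
#' `difficulty` column when present, otherwise the synthetic `true_difficulty`);
#' `modality()` the administration modality; `itemData()` the underlying
#' data.frame.
#'
#' @param x An `ItemBank`.
#' @param ... For `difficulties()`: `use` selects `"auto"` (default),
#'   `"estimated"` or `"true"`.
#' @name ItemBank-accessors
NULL

#' @rdname ItemBank-accessors
#' @export
setMethod("itemIds", "ItemBank", function(x) x@items$item_id)

#' @rdname ItemBank-accessors
#' @export
setMethod("nItems", "ItemBank", function(x) nrow(x@items))

#' @rdname ItemBank-accessors
#' @export
setMethod("difficulties", "ItemBank", function(x, use = c("auto", "estimated", "true")) {
  use <- match.arg(use)
  it <- x@items
  col <- switch(use,
    auto = if ("difficulty" %in% names(it)) "difficulty" else "true_difficulty",
    estimated = "difficulty",
    true = "true_difficulty"
  )
  stopIfNot(col %in% names(it), paste0("bank has no '", col, "' column"))
  setNames(it[[col]], it$item_id)
})

#' @rdname ItemBank-accessors
#' @export
setMethod("modality", "ItemBank", function(x) setNames(x@items$modality, x@items$item_id))

#' @rdname ItemBank-accessors
#' @export
setMethod("itemData", "ItemBank", function(x) x@items)

#' @describeIn ItemBank-accessors Subset a bank by item index, id or predicate.
#' @param i index vector (integer, logical, or item ids).
#' @param j,drop unused.
#' @export
setMethod("[", "ItemBank", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@items$item_id)
  ItemBank(x@items[i, , drop = FALSE])
})

setMethod("show", "ItemBank", function(object) {
  it <- object@items
  cat("ItemBank with", nrow(it), "items\n")
  cat("  modality:", paste(sprintf(
    "%s=%d", names(table(it$modality)),
    as.integer(table(it$modality))
  ), collapse = ", "), "\n")
  dd <- difficulties(object)
  cat(sprintf("  difficulty range: [%.2f, %.2f] D-score units\n", min(dd), max(dd)))
  if ("latent_concept_id" %in% names(it)) {
    cat("  latent concepts:", length(unique(it$latent_concept_id)), "\n")
  }
  if ("equate_group" %in% names(it)) {
    cat("  equate groups:", length(unique(stats::na.omit(it$equate_group))), "\n")
  }
  invisible(object)
})

#' Attach estimated difficulties to a bank
#'
#' Merges a fitted `ItemParams` table (see [fitDifficulties()]) into the bank's
#' `difficulty` / `se_difficulty` columns.
#'
#' @param bank An `ItemBank`.
#' @param params data.frame with `item_id`, `difficulty`, `se_difficulty`.
#' @return The updated `ItemBank`.
#' @export
setDifficulties <- function(bank, params) {
  it <- itemData(bank)
  idx <- match(it$item_id, params$item_id)
  it$difficulty <- params$difficulty[idx]
  it$se_difficulty <- params$se_difficulty[idx]
  ItemBank(it)
}

#' Attach equate-group membership to a bank
#'
#' @param bank An `ItemBank`.
#' @param groups data.frame with `item_id`, `group_id` (see
#'   [extractEquateGroups()]); items absent from `groups` get `NA` (ungrouped).
#' @return The updated `ItemBank`.
#' @export
setEquateGroups <- function(bank, groups) {
  it <- itemData(bank)
  it$equate_group <- groups$group_id[match(it$item_id, groups$item_id)]
  ItemBank(it)
}
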