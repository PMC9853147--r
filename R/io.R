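#' Read / write an item bank as CSV
#'
#' RFC-4180 comma-separated UTF-8 with a mandatory header.  Mandatory columns:
#' `item_id`, `descriptor`, `modality`, `domain` plus a difficulty column;
#' unknown columns are preserved through a round trip.  Duplicate item ids are
#' an error naming the ids.
#'
#' @param bank an [ItemBank-class].
#' @param path file path.
#' @return `readItemBank()` returns an [ItemBank-class]; writers return `path`
#'   invisibly.
#' @export
writeItemBank <- function(bank, path) {
  write.csv(itemData(bank), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeItemBank
#' @export
readItemBank <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("item_id", "descriptor", "modality", "domain")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("item bank file lacks mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$item_id)) {
    stop("duplicate item_id in bank file: ",
         paste(unique(df$item_id[duplicated(df$item_id)]), collapse = ", "),
         call. = FALSE)
  }
  ItemBank(df)
}

#' Read / write judge tables as CSV
#'
#' Match ratings (`judge_id`, `item_a`, `item_b`, `level`, `pass_number`),
#' domain votes (`item_id`, `subdomain`, `votes`) and feasibility flags
#' (`judge_id`, `item_id`, `criterion`, `comment`) travel as plain CSV with
#' documented headers.
#'
#' @param x the table to write.
#' @param path file path.
#' @return readers return the data.frame; writers return `path` invisibly.
#' @export
writeRatings <- function(x, path) {
  write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeRatings
#' @export
readRatings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("judge_id", "item_a", "item_b", "level")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("ratings file lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname writeRatings
#' @export
readVotes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("item_id", "subdomain", "votes")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("votes file lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname writeRatings
#' @export
readFeasibilityFlags <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("judge_id", "item_id", "criterion")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("feasibility file lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read / write a response matrix as CSV
#'
#' Wide format: one row per child with `child_id`, `age`, then one 0/1/NA
#' column per item (columns named by item id).
#'
#' @param responses a [ResponseSet-class].
#' @param path file path.
#' @return `readResponses()` returns a [ResponseSet-class]; the writer returns
#'   `path` invisibly.
#' @export
writeResponses <- function(responses, path) {
  X <- responseMatrix(responses)
  df <- data.frame(
    child_id = colnames(X),
    age = colData(responses)$age,
    t(X), check.names = FALSE, stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeResponses
#' @export
readResponses <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 fileEncoding = "UTF-8")
  stopIfNot(all(c("child_id", "age") %in% names(df)),
            "responses file needs child_id and age columns")
  items <- setdiff(names(df), c("child_id", "age"))
  X <- t(as.matrix(df[, items, drop = FALSE]))
  colnames(X) <- df$child_id
  ResponseSet(X, df$age)
}

#' Write the ground truth of a synthetic study as JSON
#'
#' Concept partition, true difficulties and the reference curve, for test
#' harnesses that compare recovered structure against the generator's truth.
#'
#' @param bank a synthetic [ItemBank-class].
#' @param curve the generating [ReferenceCurve-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(bank, curve, path) {
  it <- itemData(bank)
  obj <- list(
    items = it[, intersect(c("item_id", "true_difficulty", "latent_concept_id",
                             "facility_rank", "domain"), names(it))],
    curve = list(ages = curve@ages, mu = curve@mu, sigma = curve@sigma)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
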