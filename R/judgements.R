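#' Feasibility criteria by modality
#'
#' Directly administered items are screened for translation, adaptation,
#' administration and materials difficulties plus other concerns; caregiver
#' reported items drop administration/materials (nothing is administered or
#' handled) and add whether caregivers can know the behaviour at all.
#'
#' @param modality `"direct_admin"` or `"caregiver_report"`.
#' @return character vector of valid criterion names.
#' @export
feasibilityCriteria <- function(modality = c("direct_admin", "caregiver_report")) {
  modality <- match.arg(modality)
  if (modality == "direct_admin") {
    c("translation", "adaptation", "administration", "materials", "other")
  } else {
    c("translation", "adaptation", "caregiver_knowledge", "other")
  }
}

normalizePair <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

#' Aggregate multi-judge match ratings into matching coefficients
#'
#' Ratings on the ordinal scale none < partial < strong < very_strong are
#' mapped to numeric values (default equally spaced on \[0, 1\]) and averaged
#' over judges per unordered item pair.  A judge's second-pass rating of a pair
#' replaces their first-pass rating (the correction round); judges who did not
#' rate a pair contribute nothing to its mean.  The coefficient is 1 exactly
#' when every contributing rating is very_strong and 0 exactly when all are
#' none.
#'
#' @param ratings data.frame with columns `judge_id`, `item_a`, `item_b`,
#'   `level` (one of the four match levels) and optionally `pass_number`
#'   (1 or 2; defaults to 1).
#' @param mapping named numeric level mapping; see [defaultLevelMapping()].
#' @return data.frame of `MatchCoefficient`s: `item_a`, `item_b` (sorted within
#'   pair), `value` in \[0, 1\], `n_judges`.
#' @export
aggregateMatching <- function(ratings, mapping = defaultLevelMapping()) {
  stopIfNot(all(c("judge_id", "item_a", "item_b", "level") %in% names(ratings)),
            "ratings need judge_id, item_a, item_b, level")
  stopIfNot(all(ratings$level %in% names(mapping)),
            paste("unknown rating level(s):",
                  paste(setdiff(unique(ratings$level), names(mapping)), collapse = ", ")))
  stopIfNot(!any(ratings$item_a == ratings$item_b), "self-pairs are not allowed")
  if (is.null(ratings$pass_number)) ratings$pass_number <- 1L

  pr <- normalizePair(ratings$item_a, ratings$item_b)
  ratings$item_a <- pr$a
  ratings$item_b <- pr$b
  key <- paste(ratings$judge_id, ratings$item_a, ratings$item_b, sep = "\r")

  # second-pass overrides: at most one pass-2 rating per judge per pair
  p2 <- ratings$pass_number == 2L
  if (anyDuplicated(key[p2])) stop("multiple pass-2 ratings for the same judge and pair", call. = FALSE)
  keep <- !(key %in% key[p2]) | p2
  ratings <- ratings[keep, , drop = FALSE]
  if (nrow(ratings) == 0L) stop("no ratings left after override resolution", call. = FALSE)

  val <- mapping[ratings$level]
  pair <- paste(ratings$item_a, ratings$item_b, sep = "\r")
  mean_val <- tapply(val, pair, mean)
  n <- tapply(val, pair, length)
  parts <- do.call(rbind, strsplit(names(mean_val), "\r", fixed = TRUE))
  out <- data.frame(
    item_a = parts[, 1], item_b = parts[, 2],
    value = as.numeric(mean_val), n_judges = as.integer(n),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$item_a, out$item_b), , drop = FALSE]
}

#' Extract equate groups from matching coefficients
#'
#' Builds a graph over items with an edge for every pair whose mean mapped
#' coefficient reaches the threshold (default the value of a "strong" match,
#' 2/3) and returns its connected components of size >= 2 as equate groups:
#' clusters of items from different instruments judged to measure the same
#' behaviour.  Singletons are not groups.  `mode = "clique"` instead partitions
#' the thresholded graph greedily into maximal cliques, for the stricter
#' reading in which every pair in a group must match.
#'
#' @param coefficients data.frame from [aggregateMatching()].
#' @param threshold minimum coefficient for an edge (default 2/3).
#' @param mode `"component"` (default) or `"clique"`.
#' @return data.frame: `item_id`, `group_id` (`"eg001"`, ... ordered by group
#'   size then first item), one row per grouped item.
#' @export
extractEquateGroups <- function(coefficients, threshold = 2 / 3,
                                mode = c("component", "clique")) {
  mode <- match.arg(mode)
  if (nrow(coefficients) == 0L) {
    return(data.frame(item_id = character(), group_id = character(),
                      stringsAsFactors = FALSE))
  }
  edges <- coefficients[coefficients$value >= threshold - 1e-9, , drop = FALSE]
  if (nrow(edges) == 0L) {
    return(data.frame(item_id = character(), group_id = character(),
                      stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(edges[, c("item_a", "item_b")], directed = FALSE)
  if (mode == "component") {
    comp <- igraph::components(g)
    member <- split(names(comp$membership), comp$membership)
  } else {
    member <- list()
    remaining <- g
    while (igraph::vcount(remaining) > 0L && igraph::ecount(remaining) > 0L) {
      cl <- igraph::largest_cliques(remaining)[[1]]
      ids <- igraph::V(remaining)$name[as.integer(cl)]
      member[[length(member) + 1L]] <- ids
      remaining <- igraph::delete_vertices(remaining, ids)
    }
  }
  member <- Filter(function(m) length(m) >= 2L, member)
  if (!length(member)) {
    return(data.frame(item_id = character(), group_id = character(),
                      stringsAsFactors = FALSE))
  }
  member <- lapply(member, sort)
  ord <- order(-vapply(member, length, integer(1)),
               vapply(member, `[`, character(1), 1L))
  member <- member[ord]
  data.frame(
    item_id = unlist(member, use.names = FALSE),
    group_id = rep(sprintf("eg%03d", seq_along(member)),
                   vapply(member, length, integer(1))),
    stringsAsFactors = FALSE
  )
}

#' Build per-item domain profiles from judge votes
#'
#' Rescales vote counts to weights in \[0, 1\] by dividing by the panel size
#' (the maximum number of votes any subdomain can receive), so an item judged
#' unanimously to measure one subdomain gets weight 1 there.  Items may carry
#' several non-zero weights (multi-domain ascription); weights need not sum
#' to 1.  The primary domain is the argmax weight, ties broken lexicographically
#' with a recorded flag.
#'
#' @param votes data.frame: `item_id`, `subdomain`, `votes` (long format).
#' @param nJudges panel size; no item x subdomain count may exceed it.
#' @return data.frame with `item_id`, one weight column per subdomain (named as
#'   the subdomain), `primary_domain` and `primary_tie`.
#' @export
buildDomainProfiles <- function(votes, nJudges) {
  stopIfNot(all(c("item_id", "subdomain", "votes") %in% names(votes)),
            "votes need item_id, subdomain, votes")
  stopIfNot(all(votes$subdomain %in% SUBDOMAINS),
            paste("unknown subdomain(s):",
                  paste(setdiff(unique(votes$subdomain), SUBDOMAINS), collapse = ", ")))
  if (any(votes$votes > nJudges)) {
    stop("vote counts exceed the judge panel size", call. = FALSE)
  }
  wide <- voteMatrix(votes)
  w <- wide / nJudges
  prim <- apply(w, 1L, function(r) min(colnames(w)[r == max(r)]))
  is_tie <- apply(w, 1L, function(r) sum(r == max(r)) > 1L)
  out <- data.frame(item_id = rownames(wide), stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(w))
  out$primary_domain <- prim # lexicographically first among tied maxima
  out$primary_tie <- is_tie
  rownames(out) <- NULL
  out
}

# long votes -> item x subdomain count matrix (all 9 taxonomy columns)
voteMatrix <- function(votes) {
  items <- sort(unique(votes$item_id))
  m <- matrix(0L, length(items), length(SUBDOMAINS),
              dimnames = list(items, SUBDOMAINS))
  m[cbind(match(votes$item_id, items), match(votes$subdomain, SUBDOMAINS))] <-
    as.integer(votes$votes)
  m
}

#' Spearman correlations between subdomain ascriptions
#'
#' Rank-based correlation of per-item vote counts between subdomains, showing
#' which domains tend to be jointly ascribed to the same items.  Subdomains
#' with a constant vote column (no variation across items, including
#' all-zero columns) have undefined correlations and are reported as `NA`, not
#' zero; the diagonal is 1 by convention.
#'
#' @param votes data.frame: `item_id`, `subdomain`, `votes`.
#' @return symmetric numeric matrix over [SUBDOMAINS] with unit diagonal.
#' @export
subdomainCorrelations <- function(votes) {
  m <- voteMatrix(votes)
  stopIfNot(nrow(m) >= 3L, "need at least 3 items for correlations")
  constant <- apply(m, 2L, function(x) length(unique(x)) == 1L)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1
  rho
}

#' Tabulate feasibility flags
#'
#' Counts concerns per item and per criterion, checking criterion names against
#' the modality-appropriate set, and recomputes criterion percentages from the
#' counts.  Comments are carried verbatim, collated per item.
#'
#' @param flags data.frame: `judge_id`, `item_id`, `criterion`, optional
#'   `comment`.
#' @param modality the modality whose criterion set applies.
#' @return list with `items` (per-item counts per criterion, `total_concerns`,
#'   sorted descending, plus collated `comments`) and `totals` (per-criterion
#'   `n_comments` and `percent` recomputed from counts).
#' @export
tabulateFeasibility <- function(flags, modality = c("direct_admin", "caregiver_report")) {
  modality <- match.arg(modality)
  crits <- feasibilityCriteria(modality)
  if (nrow(flags)) {
    bad <- setdiff(unique(flags$criterion), crits)
    if (length(bad)) {
      stop(sprintf("unknown feasibility criterion for %s: %s",
                   modality, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  items <- sort(unique(flags$item_id))
  counts <- matrix(0L, length(items), length(crits), dimnames = list(items, crits))
  if (nrow(flags)) {
    tab <- table(factor(flags$item_id, levels = items),
                 factor(flags$criterion, levels = crits))
    counts[] <- as.integer(tab)
  }
  per_item <- data.frame(item_id = items, stringsAsFactors = FALSE)
  per_item <- cbind(per_item, as.data.frame(counts))
  per_item$total_concerns <- as.integer(rowSums(counts))
  comments <- if (!is.null(flags$comment)) {
    vapply(items, function(i) paste(flags$comment[flags$item_id == i], collapse = " | "),
           character(1))
  } else {
    rep("", length(items))
  }
  per_item$comments <- comments
  per_item <- per_item[order(-per_item$total_concerns, per_item$item_id), , drop = FALSE]
  rownames(per_item) <- NULL

  tot <- colSums(counts)
  totals <- data.frame(
    criterion = crits,
    n_comments = as.integer(tot),
    percent = if (sum(tot) > 0) round(100 * tot / sum(tot), 1) else rep(0, length(tot)),
    stringsAsFactors = FALSE
  )
  rownames(totals) <- NULL
  list(items = per_item, totals = totals)
}
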