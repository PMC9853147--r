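#' Select a representative item per equate group
#'
#' Within each equate group (items judged to measure the same behaviour),
#' retains the single best candidate after filtering by modality: the item with
#' the fewest feasibility concerns, ties broken by the shortest descriptor
#' (simplest wording proxy), then lexicographic item id.  Groups emptied by the
#' modality filter are skipped with a warning.
#'
#' @param groups data.frame from [extractEquateGroups()] (`item_id`,
#'   `group_id`).
#' @param bank an [ItemBank-class] providing descriptors and modality.
#' @param feasibility optional per-item feasibility table (`item_id`,
#'   `total_concerns`); items absent from it count zero concerns.
#' @param modality optional modality filter (`"caregiver_report"` or
#'   `"direct_admin"`).
#' @return data.frame: `group_id`, `item_id`, `reason`.
#' @export
selectRepresentatives <- function(groups, bank, feasibility = NULL, modality = NULL) {
  it <- itemData(bank)
  concerns <- setNames(rep(0L, nrow(it)), it$item_id)
  if (!is.null(feasibility) && nrow(feasibility)) {
    concerns[feasibility$item_id] <- feasibility$total_concerns
  }
  out <- list()
  for (g in unique(groups$group_id)) {
    ids <- groups$item_id[groups$group_id == g]
    ids <- ids[ids %in% it$item_id]
    if (!is.null(modality)) {
      ids <- ids[it$modality[match(ids, it$item_id)] == modality]
    }
    if (!length(ids)) {
      warning("equate group ", g, " has no items after modality filter; skipped")
      next
    }
    if (length(ids) == 1L) {
      out[[g]] <- data.frame(group_id = g, item_id = ids,
                             reason = "singleton group", stringsAsFactors = FALSE)
      next
    }
    cc <- concerns[ids]
    nch <- nchar(it$descriptor[match(ids, it$item_id)])
    ord <- order(cc, nch, ids)
    best <- ids[ord[1]]
    reason <- if (sum(cc == cc[ord[1]]) == 1L) {
      "fewest feasibility concerns"
    } else if (sum(cc == cc[ord[1]] & nch == nch[ord[1]]) == 1L) {
      "tie on concerns; shortest descriptor"
    } else {
      "tie on concerns and length; first id"
    }
    out[[g]] <- data.frame(group_id = g, item_id = best, reason = reason,
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(group_id = character(), item_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Assemble a form by difficulty-uniform, domain-balanced selection
#'
#' Greedy fill over a grid of target median pass ages spanning the instrument
#' age range: the grid has one slot per requested item, and each slot takes the
#' eligible item whose median pass age (`a50`) is closest to the slot, subject
#' to running domain quotas derived from `domainTargets`.  Only
#' modality-appropriate items are eligible (caregiver-reported for the short
#' form, directly administered for the long form), and at most one item per
#' equate group is selected (duplicates of a behaviour are excluded; when
#' `representatives` is supplied, the group is represented by that item).
#' Slots left without an item within one grid step are reported as coverage
#' gaps, and unmet domain quotas as shortfalls.
#'
#' @param bank an [ItemBank-class]; uses `difficulties(bank)` and, when
#'   present, the `equate_group` and `primary_domain` columns.
#' @param kind `"short_form"` or `"long_form"`.
#' @param nItems target number of items.
#' @param curve a [ReferenceCurve-class] for pass-age computation.
#' @param domainTargets named weights over primary domains (default
#'   [defaultDomainMix()]); quotas are `ceiling(weight * nItems)`.
#' @param representatives optional data.frame from [selectRepresentatives()];
#'   grouped items other than the representative are ineligible.
#' @param ageRange grid span in months (default 0-36, clipped to the curve).
#' @param passAgeMode `"marginal"` or `"median"` (see [passAgeQuantiles()]).
#' @return A [Form-class], items in slot (age/difficulty) order; the
#'   `provenance` slot records slot, a50, equate group and reason; attributes
#'   `gaps` and `shortfall` carry the structured coverage report.
#' @export
assembleForm <- function(bank, kind = c("short_form", "long_form"),
                         nItems, curve = defaultReferenceCurve(),
                         domainTargets = defaultDomainMix(),
                         representatives = NULL,
                         ageRange = c(0, 36), passAgeMode = "marginal") {
  kind <- match.arg(kind)
  want_modality <- if (kind == "short_form") "caregiver_report" else "direct_admin"
  it <- itemData(bank)
  it$primary_domain <- it$primary_domain %||% primaryDomain(it$domain)
  if (!"equate_group" %in% names(it)) it$equate_group <- NA_character_

  eligible <- it$modality == want_modality
  if (!is.null(representatives) && nrow(representatives)) {
    grouped <- !is.na(it$equate_group)
    eligible <- eligible &
      (!grouped | it$item_id %in% representatives$item_id)
  }
  cand <- it[eligible, , drop = FALSE]
  dd_all <- difficulties(bank)
  cand <- cand[is.finite(dd_all[cand$item_id]), , drop = FALSE] # non-estimable items cannot be placed
  stopIfNot(nrow(cand) >= 1L, "no modality-eligible items to assemble from")

  span <- c(max(ageRange[1], ageSpan(curve)[1]), min(ageRange[2], ageSpan(curve)[2]))
  slots <- seq(span[1], span[2], length.out = nItems)
  step <- if (nItems > 1) diff(slots[1:2]) else diff(span)

  dd <- difficulties(bank)[cand$item_id]
  a50 <- medianPassAges(dd, curve, mode = passAgeMode)

  quota <- ceiling(domainTargets * nItems)
  used_groups <- character()
  taken <- rep(FALSE, nrow(cand))
  picked <- integer(0)
  slot_of <- integer(0)
  reason <- character(0)
  gaps <- data.frame(slot_age = numeric(), nearest = numeric())

  for (s in slots) {
    avail <- which(!taken)
    if (!length(avail)) break
    dist <- abs(a50[avail] - s)
    # domain quota: prefer items whose primary domain still has quota
    dom <- cand$primary_domain[avail]
    has_quota <- !is.na(quota[dom]) & quota[dom] > 0
    pool <- if (any(has_quota)) avail[has_quota] else avail
    pdist <- abs(a50[pool] - s)
    best <- pool[order(pdist, cand$item_id[pool])[1]]
    why <- if (any(has_quota)) "closest a50 within domain quota" else "quota exhausted; closest a50"
    if (abs(a50[best] - s) > step) {
      gaps <- rbind(gaps, data.frame(slot_age = s, nearest = abs(a50[best] - s)))
    }
    taken[best] <- TRUE
    g <- cand$equate_group[best]
    if (!is.na(g)) {
      used_groups <- c(used_groups, g)
      taken[!is.na(cand$equate_group) & cand$equate_group == g] <- TRUE
    }
    if (!is.na(quota[cand$primary_domain[best]]) && quota[cand$primary_domain[best]] > 0) {
      quota[cand$primary_domain[best]] <- quota[cand$primary_domain[best]] - 1L
    }
    picked <- c(picked, best)
    slot_of <- c(slot_of, length(picked))
    reason <- c(reason, why)
  }

  prov <- data.frame(
    item_id = cand$item_id[picked],
    slot_age = slots[seq_along(picked)],
    a50 = a50[picked],
    equate_group = ifelse(is.na(cand$equate_group[picked]), "ungrouped",
                          cand$equate_group[picked]),
    domain = cand$primary_domain[picked],
    reason = reason,
    stringsAsFactors = FALSE
  )
  shortfall <- quota[quota > 0]
  if (length(picked) < nItems) {
    warning("only ", length(picked), " of ", nItems, " slots could be filled")
  }
  form <- Form(
    items = cand$item_id[picked], kind = kind,
    form_id = paste0(substr(kind, 1, 1), "f_proto"),
    provenance = prov
  )
  attr(form, "gaps") <- gaps
  attr(form, "shortfall") <- as.list(shortfall)
  form
}

#' Order form items by difficulty with facility precedence
#'
#' Sorts items from easiest to hardest by difficulty, then repairs the order so
#' that every facility-precedence pair is respected: a semantically easier
#' variant ("says 5 words") precedes its harder sibling ("says 15 words") even
#' when the modelled difficulties disagree.  With no precedence pairs the
#' result is the pure difficulty sort.  Small instances (up to 12 items) are
#' repaired exactly - the linear extension with the fewest adjacent
#' transpositions away from the difficulty sort, found by dynamic programming
#' over item subsets; larger forms use a greedy topological sort emitting the
#' easiest available item, followed by adjacent-swap cleanup.  Cyclic
#' precedence is an error listing the cycle.
#'
#' @param form a [Form-class].
#' @param difficulties named numeric difficulty per item id.
#' @param precedence data.frame with columns `earlier`, `later` (item ids).
#' @return The reordered [Form-class].
#' @export
orderItems <- function(form, difficulties, precedence = NULL) {
  ids <- formItems(form)
  dd <- difficulties[ids]
  stopIfNot(!any(is.na(dd)), "every form item needs a difficulty")
  if (is.null(precedence) || nrow(precedence) == 0L) {
    ord <- ids[order(dd, ids)]
    return(replaceItems(form, ord))
  }
  pre <- precedence[precedence$earlier %in% ids & precedence$later %in% ids, , drop = FALSE]
  if (length(ids) <= 12L) {
    # small instances: exact minimal-inversion linear extension by subset DP
    return(replaceItems(form, orderExact(ids, dd, pre)))
  }
  succ <- split(pre$later, factor(pre$earlier, levels = ids))
  indeg <- setNames(integer(length(ids)), ids)
  tab <- table(factor(pre$later, levels = ids))
  indeg[names(tab)] <- as.integer(tab)

  out <- character(0)
  avail <- ids[indeg[ids] == 0L]
  while (length(avail)) {
    nxt <- avail[order(dd[avail], avail)[1]]
    out <- c(out, nxt)
    avail <- setdiff(avail, nxt)
    for (m in succ[[nxt]]) {
      indeg[m] <- indeg[m] - 1L
      if (indeg[m] == 0L) avail <- c(avail, m)
    }
  }
  if (length(out) < length(ids)) {
    cyc <- setdiff(ids, out)
    stop("cyclic facility precedence among: ", paste(cyc, collapse = ", "),
         call. = FALSE)
  }
  # bubble pass: remove any adjacent difficulty inversion not forced by a
  # direct precedence pair (each swap keeps the order a linear extension and
  # strictly reduces the distance to the difficulty sort)
  forced <- paste(pre$earlier, pre$later, sep = "\r")
  repeat {
    swapped <- FALSE
    for (i in seq_len(length(out) - 1L)) {
      a <- out[i]; b <- out[i + 1L]
      if (dd[a] > dd[b] && !(paste(a, b, sep = "\r") %in% forced)) {
        out[i] <- b; out[i + 1L] <- a
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  replaceItems(form, out)
}

# Exact minimal-Kendall-distance linear extension by DP over subsets
# (placed-prefix formulation); used for small instances.  Cycles surface as no
# completable state.
orderExact <- function(ids, dd, pre) {
  n <- length(ids)
  rank <- rank(dd[ids], ties.method = "first")
  pred_mask <- integer(n)
  if (!is.null(pre) && nrow(pre)) {
    for (r in seq_len(nrow(pre))) {
      li <- match(pre$later[r], ids)
      ei <- match(pre$earlier[r], ids)
      pred_mask[li] <- bitwOr(pred_mask[li], bitwShiftL(1L, ei - 1L))
    }
  }
  full <- bitwShiftL(1L, n) - 1L
  cost <- rep(Inf, full + 1L)
  from <- rep(NA_integer_, full + 1L)
  pick <- rep(NA_integer_, full + 1L)
  cost[1L] <- 0 # empty prefix (state index = mask + 1)
  for (S in 0:(full - 1L)) {
    if (!is.finite(cost[S + 1L])) next
    for (x in seq_len(n)) {
      bit <- bitwShiftL(1L, x - 1L)
      if (bitwAnd(S, bit) != 0L) next
      if (bitwAnd(pred_mask[x], S) != pred_mask[x]) next # predecessors unplaced
      # inversions created: remaining items (outside S, not x) with lower rank
      rem <- which(bitwAnd(S, bitwShiftL(1L, seq_len(n) - 1L)) == 0L)
      add <- sum(rank[setdiff(rem, x)] < rank[x])
      S2 <- bitwOr(S, bit)
      if (cost[S + 1L] + add < cost[S2 + 1L]) {
        cost[S2 + 1L] <- cost[S + 1L] + add
        from[S2 + 1L] <- S
        pick[S2 + 1L] <- x
      }
    }
  }
  if (!is.finite(cost[full + 1L])) {
    cyc <- ids[pred_mask > 0]
    stop("cyclic facility precedence among: ", paste(cyc, collapse = ", "),
         call. = FALSE)
  }
  out <- integer(n)
  S <- full
  for (i in n:1) {
    out[i] <- pick[S + 1L]
    S <- from[S + 1L]
  }
  ids[out]
}

replaceItems <- function(form, ids, groups = NULL) {
  stopifnot(setequal(ids, form@items))
  prov <- form@provenance
  if (!is.null(prov)) prov <- prov[match(ids, prov$item_id), , drop = FALSE]
  new("Form",
    form_id = form@form_id, kind = form@kind, items = ids,
    groups = if (is.null(groups)) character() else groups,
    start_rule = form@start_rule, stop_rule_k = form@stop_rule_k,
    provenance = prov
  )
}

runLengths <- function(domains) {
  r <- rle(domains)
  data.frame(domain = r$values, length = r$lengths,
             start = cumsum(c(1, head(r$lengths, -1))))
}

#' Break strings of same-domain items
#'
#' With a contiguous-failure stop rule, a long run of items from a single
#' domain could cut administration short for a child weak in that one domain.
#' This scans the form for runs of more than `maxRun` consecutive items sharing
#' a primary domain and splits each by moving down the nearest
#' earlier-positioned item from another domain (necessarily of lower
#' difficulty, the list being difficulty-ordered) into the run.  The output
#' contains no run longer than `maxRun`; difficulty order is violated only at
#' the moved positions, each recorded in the `moves` attribute.  Re-running on
#' its own output is the identity.
#'
#' @param form a [Form-class].
#' @param domains named character: primary domain per item id.
#' @param maxRun maximum tolerated run length (default 3; runs of 4 or more are
#'   broken).
#' @return The [Form-class] with runs broken; attribute `moves` logs each move.
#' @export
breakStrings <- function(form, domains, maxRun = 3L) {
  ids <- formItems(form)
  dom <- unname(domains[ids])
  stopIfNot(!any(is.na(dom)), "every form item needs a primary domain")
  if (length(unique(dom)) < 2L) {
    stop("cannot break strings: form has a single domain", call. = FALSE)
  }
  moves <- data.frame(item_id = character(), from = integer(), to = integer(),
                      stringsAsFactors = FALSE)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 10L * length(ids)) {
      warning("string breaking did not converge; returning best effort")
      break
    }
    rl <- runLengths(dom)
    bad <- which(rl$length > maxRun)
    if (!length(bad)) break
    b <- bad[1]
    run_start <- rl$start[b]
    insert_at <- run_start + maxRun # split after maxRun items of the run
    donors <- which(dom != rl$domain[b])
    if (!length(donors)) break
    # a donor is safe if removing it does not merge its same-domain
    # neighbours into a new over-long run (which would oscillate)
    safe <- vapply(donors, function(d) {
      l <- d - 1L
      r <- d + 1L
      if (l < 1L || r > length(ids) || dom[l] != dom[r]) return(TRUE)
      len <- 0L
      i <- l
      while (i >= 1L && dom[i] == dom[l]) { len <- len + 1L; i <- i - 1L }
      i <- r
      while (i <= length(ids) && dom[i] == dom[r]) { len <- len + 1L; i <- i + 1L }
      len <= maxRun
    }, logical(1))
    pool <- if (any(safe)) donors[safe] else donors
    # nearest to the split point, preferring the earlier-positioned (lower
    # difficulty) side on ties
    d <- pool[order(abs(pool - insert_at), pool >= insert_at)][1]
    moves <- rbind(moves, data.frame(item_id = ids[d], from = d, to = insert_at))
    idx <- seq_along(ids)
    idx <- append(idx[-d], d, after = insert_at - 1L - (d < insert_at))
    ids <- ids[idx]
    dom <- dom[idx]
  }
  out <- replaceItems(form, ids)
  attr(out, "moves") <- moves
  out
}

#' Partition a long form into three administration groups
#'
#' Directly administered items are split into three self-similar groups (A, B,
#' C) so that materials are presented parsimoniously (items sharing a material
#' land in one group) and items of similar energy level are administered
#' together, under a group-size balance constraint (sizes differ by at most
#' `maxImbalance`).  Items sharing a material tag form indivisible blocks that
#' are assigned greedily, largest first, to the group with the lowest added
#' cost (energy mixing + size pressure); blocks larger than the remaining
#' capacity of every group are split.  Items lacking metadata are assigned by a
#' domain heuristic (motor with group A, language with group B, the rest with
#' group C, mirroring the movement / verbal / table-top character of the
#' groups) with a warning.  Within groups, items keep difficulty order.
#'
#' @param form a [Form-class] of kind `"long_form"`.
#' @param bank an [ItemBank-class] carrying `material_tag` and `energy_level`.
#' @param maxImbalance largest allowed difference between group sizes
#'   (default 5).
#' @return The [Form-class] with `groups` filled (A/B/C per item).
#' @export
partitionLongForm <- function(form, bank, maxImbalance = 5L) {
  stopIfNot(form@kind == "long_form", "three-group partition applies to the long form")
  ids <- formItems(form)
  it <- itemData(bank)
  idx <- match(ids, it$item_id)
  mat <- it$material_tag[idx]
  energy <- it$energy_level[idx]
  missing_meta <- is.na(mat) | is.na(energy)
  if (any(missing_meta)) {
    warning(sum(missing_meta), " item(s) lack material/energy metadata; ",
            "assigned by domain heuristic")
  }
  n <- length(ids)
  cap <- ceiling(n / 3) + floor(maxImbalance / 2)

  groups <- setNames(rep(NA_character_, n), ids)
  gsize <- c(A = 0L, B = 0L, C = 0L)
  genergy <- list(A = character(), B = character(), C = character())

  # pre-assign metadata-poor items by domain character of the groups
  if (any(missing_meta)) {
    dom <- primaryDomain(it$domain[idx])
    groups[missing_meta] <- ifelse(dom[missing_meta] == "motor", "A",
                                   ifelse(dom[missing_meta] == "language", "B", "C"))
    for (g in c("A", "B", "C")) gsize[g] <- sum(groups == g, na.rm = TRUE)
  }

  blocks <- split(which(is.na(groups)), mat[is.na(groups)])
  # "none" items are free-floating singletons, real materials stay together
  units <- list()
  for (bn in names(blocks)) {
    if (bn == "none") {
      units <- c(units, as.list(blocks[[bn]]))
    } else {
      units <- c(units, list(blocks[[bn]]))
    }
  }
  sizes <- vapply(units, length, integer(1))
  units <- units[order(-sizes)]

  for (u in units) {
    while (length(u)) {
      free <- cap - gsize
      gs <- names(free)[free > 0]
      if (!length(gs)) gs <- names(which.max(free))
      maj <- names(which.max(table(energy[u])))
      cost <- vapply(gs, function(g) {
        mix <- if (length(genergy[[g]]) == 0 || maj %in% genergy[[g]]) 0 else 1
        mix + gsize[g] / cap
      }, numeric(1))
      g <- gs[order(cost, gs)[1]]
      take <- u[seq_len(min(length(u), max(1L, cap - gsize[g])))]
      groups[take] <- g
      gsize[g] <- gsize[g] + length(take)
      genergy[[g]] <- union(genergy[[g]], unique(energy[take]))
      u <- setdiff(u, take)
    }
  }
  # rebalance if the size spread exceeds the tolerance (move free singletons)
  guard <- 0L
  while (diff(range(gsize)) > maxImbalance && guard < n) {
    guard <- guard + 1L
    big <- names(which.max(gsize)); small <- names(which.min(gsize))
    movable <- which(groups == big & (mat == "none" | is.na(mat)))
    if (!length(movable)) movable <- which(groups == big)
    m <- movable[length(movable)]
    groups[m] <- small
    gsize[big] <- gsize[big] - 1L; gsize[small] <- gsize[small] + 1L
  }
  replaceItems(form, ids, groups = unname(groups[ids]))
}

#' Derive age-bracket start rules
#'
#' For each 6-month age bracket, finds the deepest safe entry point into the
#' form: the last position of the longest prefix of items that at least
#' `passThreshold` of children at the lower end of the bracket (ages within the
#' first month) pass empirically.  A bracket whose very first item falls below
#' the threshold starts at position 1; a bracket with no children inherits the
#' previous bracket's rule with a warning.  Start indices are made
#' non-decreasing across brackets (an older child never starts earlier).
#'
#' @param form a [Form-class] (items in administration order).
#' @param responses a [ResponseSet-class] with child ages.
#' @param bracketWidth bracket width in months (default 6).
#' @param passThreshold minimum empirical pass rate (default 0.90).
#' @param ageRange span covered by brackets (default 0-36 months).
#' @return The [Form-class] with its `start_rule` slot filled.
#' @export
deriveStartRules <- function(form, responses, bracketWidth = 6,
                             passThreshold = 0.90, ageRange = c(0, 36)) {
  X <- responseMatrix(responses)
  ages <- colData(responses)$age
  ids <- formItems(form)
  stopIfNot(all(ids %in% rownames(X)), "responses must cover all form items")
  X <- X[ids, , drop = FALSE]

  lowers <- seq(ageRange[1], ageRange[2] - bracketWidth, by = bracketWidth)
  start_idx <- integer(length(lowers))
  prev <- 1L
  for (i in seq_along(lowers)) {
    sel <- ages >= lowers[i] & ages < lowers[i] + 1
    if (!any(sel)) {
      warning("no children near the lower end of bracket starting at ",
              lowers[i], " months; falling back to the previous rule")
      start_idx[i] <- prev
      next
    }
    rates <- rowMeans(X[, sel, drop = FALSE], na.rm = TRUE)
    ok <- !is.na(rates) & rates >= passThreshold
    # longest qualifying prefix: deepest item such that it and everything
    # before it is passed by >= threshold of children entering the bracket
    m <- match(FALSE, ok, nomatch = length(ok) + 1L) - 1L
    start_idx[i] <- max(1L, m)
    prev <- start_idx[i]
  }
  start_idx <- cummax(start_idx) # monotone in age bracket
  sr <- data.frame(bracket_lower = lowers, start_index = start_idx)
  new("Form",
    form_id = form@form_id, kind = form@kind, items = form@items,
    groups = form@groups, start_rule = sr, stop_rule_k = form@stop_rule_k,
    provenance = form@provenance
  )
}

#' Stop-rule check
#'
#' Returns the position of the `k`-th consecutive failure in the first run of
#' at least `k` contiguous 0s, i.e. the item at which administration halts, or
#' `NA` when the rule never triggers.
#'
#' @param responses 0/1 vector in administration order.
#' @param k run length that triggers the stop (default 5).
#' @return integer position or `NA_integer_`.
#' @export
stopRuleCheck <- function(responses, k = 5L) {
  run <- 0L
  for (i in seq_along(responses)) {
    if (!is.na(responses[i]) && responses[i] == 0) {
      run <- run + 1L
      if (run == k) return(i)
    } else {
      run <- 0L
    }
  }
  NA_integer_
}
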