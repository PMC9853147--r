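#' Default primary-domain mix for synthetic item banks
#'
#' Motor items dominate real early-childhood banks (roughly half the items),
#' followed by cognition and language; socioemotional and adaptive content is
#' sparser.  The default reproduces that shape.
#'
#' @return Named simplex over the five primary domains.
#' @export
defaultDomainMix <- function() {
  c(motor = 0.45, cognition = 0.20, language = 0.20,
    socioemotional = 0.10, adaptive = 0.05)
}

verbFor <- function(domain) {
  switch(primaryDomain(domain),
    motor = "moves or handles",
    language = "says or understands",
    cognition = "solves or remembers",
    socioemotional = "responds to others about",
    adaptive = "manages"
  )
}

#' Simulate an item bank with known ground truth
#'
#' Generates `nItems` items grouped into `nConcepts` latent concepts (items
#' sharing a concept measure the same behaviour and are true matches for the
#' judging exercise).  Each concept is assigned a primary domain from
#' `domainMix`, a subdomain within it, and a target median pass age spread over
#' `ageRange` by stratified sampling so that item difficulties cover the whole
#' span.  Within a concept, items are ordered by `facility_rank` (semantically
#' easier variants first) with difficulty increments of `facilitySpacing`
#' D-score units plus jitter, emulating variants such as "walks with support" /
#' "walks without support".
#'
#' @param nItems number of items.
#' @param nConcepts number of latent concepts (`<= nItems`); every concept gets
#'   at least one item.
#' @param ageRange target span of median pass ages, months.
#' @param domainMix named simplex of primary-domain weights (must sum to 1).
#' @param modalitySplit probability that an item is directly administered (the
#'   remainder are caregiver-reported).
#' @param curve reference curve used to translate target ages into difficulties.
#' @param facilitySpacing D-score increment between consecutive facility ranks.
#' @param seed integer seed; identical seeds give identical banks.
#' @return An [ItemBank-class] whose `items` carry `true_difficulty`,
#'   `latent_concept_id`, `facility_rank`, `material_tag` and `energy_level`.
#' @export
simulateItemBank <- function(nItems = 200L, nConcepts = 98L,
                             ageRange = c(0.5, 36), domainMix = defaultDomainMix(),
                             modalitySplit = 0.6,
                             curve = defaultReferenceCurve(),
                             facilitySpacing = 1.5, seed = NULL) {
  nItems <- as.integer(nItems)
  nConcepts <- as.integer(nConcepts)
  stopIfNot(nItems >= 1L && nConcepts >= 1L, "nItems and nConcepts must be positive")
  stopIfNot(nConcepts <= nItems, "nConcepts must not exceed nItems")
  stopIfNot(abs(sum(domainMix) - 1) < 1e-8 && all(domainMix >= 0),
            "domainMix must be a simplex (non-negative, summing to 1)")
  stopIfNot(all(names(domainMix) %in% unique(primaryDomain(SUBDOMAINS))),
            "domainMix names must be primary domains")

  withSeed(seed, {
    # concept-level structure
    concept_domain <- sample(names(domainMix), nConcepts, replace = TRUE, prob = domainMix)
    concept_sub <- vapply(concept_domain, function(d) {
      subs <- SUBDOMAINS[primaryDomain(SUBDOMAINS) == d]
      subs[sample.int(length(subs), 1L)]
    }, character(1))
    # stratified target ages: one concept per stratum, shuffled
    u <- (seq_len(nConcepts) - runif(nConcepts)) / nConcepts
    target_age <- (ageRange[1] + u * (ageRange[2] - ageRange[1]))[sample.int(nConcepts)]
    base_delta <- curveMedian(curve, target_age)

    # concept sizes: every concept >= 1 item
    sizes <- rep(1L, nConcepts)
    extra <- nItems - nConcepts
    if (extra > 0L) {
      add <- table(factor(sample.int(nConcepts, extra, replace = TRUE),
                          levels = seq_len(nConcepts)))
      sizes <- sizes + as.integer(add)
    }

    concept <- rep(seq_len(nConcepts), sizes)
    rank <- unlist(lapply(sizes, seq_len), use.names = FALSE)
    delta <- base_delta[concept] +
      (rank - (sizes[concept] + 1) / 2) * facilitySpacing +
      rnorm(nItems, 0, 0.3)

    modality <- ifelse(runif(nItems) < modalitySplit, "direct_admin", "caregiver_report")
    domain <- concept_sub[concept]
    materials <- c("none", "block", "cup", "ball", "picture_book",
                   "pencil_paper", "beads", "mirror")
    material_tag <- ifelse(
      modality == "direct_admin",
      sample(materials, nItems, replace = TRUE, prob = c(0.40, 0.12, 0.10, 0.10, 0.10, 0.08, 0.05, 0.05)),
      "none"
    )
    energy <- ifelse(
      domain == "motor.gross",
      ifelse(runif(nItems) < 0.9, "active", "seated"),
      ifelse(runif(nItems) < 0.1, "active", "seated")
    )
    instrument <- sample(sprintf("bank%02d", 1:6), nItems, replace = TRUE)

    descriptor <- sprintf(
      "Child %s behaviour %03d%s", vapply(domain, verbFor, character(1)),
      concept,
      ifelse(sizes[concept] > 1L, sprintf(" at stage %d of %d", rank, sizes[concept]), "")
    )
    label <- sprintf("behaviour %03d / stage %d", concept, rank)

    ItemBank(data.frame(
      item_id = sprintf("itm%04d", seq_len(nItems)),
      label = label, descriptor = descriptor, instrument = instrument,
      modality = modality, domain = domain,
      true_difficulty = delta,
      latent_concept_id = concept, facility_rank = rank,
      material_tag = material_tag, energy_level = energy,
      stringsAsFactors = FALSE
    ))
  })
}

# Base (error-free) match level for a pair of items given the bank's latent
# concept structure: true matches are very strong for adjacent facility ranks
# and strong otherwise; unrelated pairs are no-match, occasionally partial when
# they share a subdomain.
trueMatchLevel <- function(same_concept, rank_gap, same_domain, partial_draw) {
  ifelse(same_concept,
    ifelse(rank_gap <= 1L, "very_strong", "strong"),
    ifelse(same_domain & partial_draw, "partial", "none")
  )
}

#' Simulate a panel of judges rating item-pair matches
#'
#' Each judge rates candidate item pairs on the ordinal scale none < partial <
#' strong < very_strong.  The error-free rating reflects the latent concept
#' structure (same-concept pairs rate strong or very strong, others none or
#' occasionally partial); judge error flips a rating to an adjacent level with
#' probability `errorRate` (symmetric ordinal noise).
#'
#' @param bank an [ItemBank-class] from [simulateItemBank()] (needs
#'   `latent_concept_id`).
#' @param nJudges panel size (>= 1).
#' @param errorRate per-rating probability of an adjacent-level flip, in
#'   `[0, 0.5)`.
#' @param pairs `"within_domain"` (default; judges see same-subdomain pairs plus
#'   all true-match pairs, emulating a matrix organised by behaviour) or
#'   `"all"`.
#' @param seed integer seed.
#' @return data.frame of match ratings: `judge_id`, `item_a`, `item_b`,
#'   `level`, `pass_number` (all pass 1).
#' @export
simulateJudgeMatchings <- function(bank, nJudges = 6L, errorRate = 0.1,
                                   pairs = c("within_domain", "all"),
                                   seed = NULL) {
  stopIfNot(nJudges >= 1L, "need at least one judge")
  stopIfNot(errorRate >= 0 && errorRate < 0.5, "errorRate must be in [0, 0.5)")
  pairs <- match.arg(pairs)
  it <- itemData(bank)
  stopIfNot("latent_concept_id" %in% names(it), "bank lacks latent_concept_id ground truth")

  idx <- utils::combn(nrow(it), 2L)
  a <- idx[1, ]; b <- idx[2, ]
  same_concept <- it$latent_concept_id[a] == it$latent_concept_id[b]
  same_domain <- it$domain[a] == it$domain[b]
  if (pairs == "within_domain") {
    keep <- same_domain | same_concept
    a <- a[keep]; b <- b[keep]
    same_concept <- same_concept[keep]; same_domain <- same_domain[keep]
  }
  np <- length(a)

  withSeed(seed, {
    partial_draw <- runif(np) < 0.15
    base <- trueMatchLevel(same_concept, abs(it$facility_rank[a] - it$facility_rank[b]),
                           same_domain, partial_draw)
    base_num <- match(base, MATCH_LEVELS)
    out <- vector("list", nJudges)
    for (j in seq_len(nJudges)) {
      lev <- base_num
      flip <- runif(np) < errorRate
      dir <- ifelse(runif(np) < 0.5, -1L, 1L)
      lev2 <- lev + ifelse(flip, dir, 0L)
      lev2[lev2 < 1L] <- 2L  # flip inward at the scale ends
      lev2[lev2 > 4L] <- 3L
      out[[j]] <- data.frame(
        judge_id = sprintf("judge%02d", j),
        item_a = it$item_id[a], item_b = it$item_id[b],
        level = MATCH_LEVELS[lev2], pass_number = 1L,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate judge domain votes
#'
#' Each judge casts one vote per item for the subdomain they believe it
#' measures, drawn from the row of `confusion` belonging to the item's true
#' subdomain; with probability `multiProb` the judge casts one additional vote
#' for a second subdomain (multi-domain ascription).  An identity confusion
#' matrix with `multiProb = 0` puts every vote on the true subdomain.
#'
#' @param bank an [ItemBank-class].
#' @param nJudges panel size (>= 1).
#' @param confusion row-stochastic matrix over [SUBDOMAINS] (rows: true
#'   subdomain, columns: voted subdomain).  Default identity.
#' @param multiProb probability of a second vote per judge per item.
#' @param seed integer seed.
#' @return data.frame of vote counts: `item_id`, `subdomain`, `votes` (long
#'   format; absent combinations have zero votes).
#' @export
simulateDomainVotes <- function(bank, nJudges = 9L, confusion = NULL,
                                multiProb = 0.15, seed = NULL) {
  stopIfNot(nJudges >= 1L, "need at least one judge (empty panel)")
  k <- length(SUBDOMAINS)
  if (is.null(confusion)) confusion <- diag(k)
  confusion <- as.matrix(confusion)
  stopIfNot(all(dim(confusion) == c(k, k)), "confusion must be 9 x 9 over the subdomain taxonomy")
  stopIfNot(all(confusion >= 0) && all(abs(rowSums(confusion) - 1) < 1e-8),
            "confusion rows must be probability vectors")
  it <- itemData(bank)
  ti <- match(it$domain, SUBDOMAINS)

  withSeed(seed, {
    counts <- matrix(0L, nrow(it), k, dimnames = list(it$item_id, SUBDOMAINS))
    for (j in seq_len(nJudges)) {
      v1 <- vapply(ti, function(t) sample.int(k, 1L, prob = confusion[t, ]), integer(1))
      counts[cbind(seq_len(nrow(it)), v1)] <- counts[cbind(seq_len(nrow(it)), v1)] + 1L
      extra <- runif(nrow(it)) < multiProb
      if (any(extra)) {
        v2 <- vapply(which(extra), function(i) {
          p <- confusion[ti[i], ]
          p[v1[i]] <- 0
          if (sum(p) <= 0) { # concentrated row: second vote spreads uniformly
            p <- rep(1, k)
            p[v1[i]] <- 0
          }
          sample.int(k, 1L, prob = p)
        }, integer(1))
        counts[cbind(which(extra), v2)] <- counts[cbind(which(extra), v2)] + 1L
      }
    }
    df <- data.frame(
      item_id = rep(rownames(counts), k),
      subdomain = rep(colnames(counts), each = nrow(counts)),
      votes = as.integer(counts),
      stringsAsFactors = FALSE
    )
    df[df$votes > 0L, ]
  })
}

#' Simulate judge feasibility flags
#'
#' Judges flag practical concerns per item on modality-appropriate criteria:
#' directly administered items can draw translation, adaptation,
#' administration, materials and other concerns; caregiver-reported items lack
#' administration/materials but add caregiver_knowledge.  Items using materials
#' are more likely to draw materials concerns.
#'
#' @param bank an [ItemBank-class].
#' @param nJudges panel size.
#' @param baseRate baseline probability of a flag per judge x item x criterion.
#' @param seed integer seed.
#' @return data.frame: `judge_id`, `item_id`, `criterion`, `comment`.
#' @export
simulateFeasibilityFlags <- function(bank, nJudges = 9L, baseRate = 0.03, seed = NULL) {
  stopIfNot(nJudges >= 1L, "need at least one judge")
  it <- itemData(bank)
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(it))) {
      crits <- feasibilityCriteria(it$modality[i])
      p <- rep(baseRate, length(crits))
      names(p) <- crits
      if (it$modality[i] == "direct_admin" && it$material_tag[i] != "none") {
        p["materials"] <- 0.15
      }
      if (it$domain[i] == "socioemotional" && "caregiver_knowledge" %in% crits) {
        p["caregiver_knowledge"] <- 0.10
      }
      for (j in seq_len(nJudges)) {
        hit <- crits[runif(length(crits)) < p]
        if (length(hit)) {
          rows[[length(rows) + 1L]] <- data.frame(
            judge_id = sprintf("judge%02d", j), item_id = it$item_id[i],
            criterion = hit,
            comment = sprintf("concern about %s for %s", hit, it$item_id[i]),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    if (!length(rows)) {
      return(data.frame(judge_id = character(), item_id = character(),
                        criterion = character(), comment = character(),
                        stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate Rasch-conforming child responses
#'
#' Children are sampled with ages uniform over the curve span (or given
#' `ages`); child ability is `beta = mu(age) + sigma(age) * z` with standard
#' normal `z`, and responses are independent Bernoulli draws with
#' `P(pass) = plogis(beta - delta)` under the dichotomous Rasch model.
#'
#' @param bank an [ItemBank-class]; `difficulties(bank)` supplies delta.
#' @param curve a [ReferenceCurve-class] giving the age-ability distribution.
#' @param nChildren number of children (>= 1).
#' @param ages optional fixed ages in months (recycled to `nChildren`).
#' @param seed integer seed.
#' @return A [ResponseSet-class]; colData carries `age`, the latent `true_beta`
#'   and `true_z` (simulation ground truth for parameter-recovery checks).
#' @export
simulateResponses <- function(bank, curve = defaultReferenceCurve(),
                              nChildren = 500L, ages = NULL, seed = NULL) {
  nChildren <- as.integer(nChildren)
  stopIfNot(nChildren >= 1L, "nChildren must be positive")
  delta <- difficulties(bank)
  withSeed(seed, {
    span <- ageSpan(curve)
    if (is.null(ages)) {
      ages <- runif(nChildren, max(span[1], 0.5), span[2])
    } else {
      ages <- rep_len(as.numeric(ages), nChildren)
      checkAges(curve, ages)
    }
    z <- rnorm(nChildren)
    beta <- curveMedian(curve, ages) + curveSD(curve, ages) * z
    p <- plogis(outer(delta, beta, function(d, b) b - d))
    status <- matrix(
      as.integer(runif(length(p)) < p),
      nrow = length(delta),
      dimnames = list(names(delta), sprintf("child%05d", seq_len(nChildren)))
    )
    ResponseSet(status, ages,
      rowData = itemData(bank),
      colData = S4Vectors::DataFrame(true_beta = beta, true_z = z)
    )
  })
}
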