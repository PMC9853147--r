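bracketStart <- function(form, age) {
  sr <- startRule(form)
  if (is.null(sr)) return(rep(1L, length(age)))
  idx <- findInterval(age, sr$bracket_lower)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(sr)] <- nrow(sr)
  sr$start_index[idx]
}

#' Simulate administration of a form
#'
#' Draws Rasch-model responses for a cohort of children on the form's items, in
#' form order, optionally applying the form's start and stop rules: a child
#' begins at their age bracket's start index and halts after `stopRuleK(form)`
#' contiguous failures.  Items before the start index and after the stop are
#' not administered (`NA` in the returned matrix) unless
#' `implicitPass = TRUE`, in which case skipped leading items are recorded as
#' passes (the common basal convention).
#'
#' @param form a [Form-class] (needs a start rule when `useRules = TRUE`).
#' @param bank an [ItemBank-class] covering the form items.
#' @param children data.frame with `child_id`, `age`, and optionally
#'   `true_beta` (drawn from the curve when absent).
#' @param curve a [ReferenceCurve-class].
#' @param useRules apply start/stop rules (default TRUE).
#' @param implicitPass score skipped leading items as passes (default FALSE).
#' @param seed integer seed.
#' @return list: `responses` (a [ResponseSet-class] over administered items),
#'   `abilities` (EAP [estimateAbility()] table), `admin_length` (items
#'   administered per child).
#' @export
simulateAdministration <- function(form, bank, children, curve,
                                   useRules = TRUE, implicitPass = FALSE,
                                   seed = NULL) {
  ids <- formItems(form)
  delta <- difficulties(bank)[ids]
  stopIfNot(!any(is.na(delta)), "every form item needs a difficulty")
  if (useRules && is.null(startRule(form))) {
    stop("form has no start rule; derive one or set useRules = FALSE", call. = FALSE)
  }
  k <- stopRuleK(form)
  n <- nrow(children)

  withSeed(seed, {
    beta <- children$true_beta
    if (is.null(beta)) {
      beta <- curveMedian(curve, children$age) +
        curveSD(curve, children$age) * rnorm(n)
    }
    starts <- if (useRules) bracketStart(form, children$age) else rep(1L, n)
    X <- matrix(NA_real_, length(ids), n, dimnames = list(ids, children$child_id))
    for (c in seq_len(n)) {
      run <- 0L
      for (i in seq(starts[c], length(ids))) {
        x <- as.integer(runif(1) < plogis(beta[c] - delta[i]))
        X[i, c] <- x
        run <- if (x == 0) run + 1L else 0L
        if (useRules && run >= k) break
      }
      if (implicitPass && starts[c] > 1L) X[seq_len(starts[c] - 1L), c] <- 1
    }
    rs <- ResponseSet(X, children$age,
      rowData = itemData(bank)[match(ids, itemIds(bank)), , drop = FALSE],
      colData = S4Vectors::DataFrame(true_beta = beta)
    )
    ab <- estimateAbility(rs, difficulties(bank), method = "eap", curve = curve)
    list(
      responses = rs,
      abilities = ab,
      admin_length = data.frame(
        child_id = children$child_id, age = children$age,
        n_administered = colSums(!is.na(X)), start_index = starts
      )
    )
  })
}

#' DAZ correlation of a form against the full bank
#'
#' Simulates one cohort, scores each child twice - once on the form's items
#' only and once on the whole bank - and returns the product-moment correlation
#' of the two DAZ vectors.  A form that retains the bank's information orders
#' children the same way the full bank does.
#'
#' @param form a [Form-class] (must contain at least one bank item).
#' @param bank an [ItemBank-class].
#' @param curve a [ReferenceCurve-class].
#' @param nChildren cohort size (default 1000).
#' @param seed integer seed.
#' @param responses optional pre-simulated full-bank [ResponseSet-class]
#'   (overrides `nChildren`/`seed`).
#' @return numeric scalar correlation.
#' @export
dazCorrelation <- function(form, bank, curve, nChildren = 1000L, seed = NULL,
                           responses = NULL) {
  ids <- formItems(form)
  stopIfNot(length(ids) >= 1L, "form is empty")
  stopIfNot(all(ids %in% itemIds(bank)), "form items missing from the bank")
  if (is.null(responses)) {
    responses <- simulateResponses(bank, curve, nChildren = nChildren, seed = seed)
  }
  full <- estimateAbility(responses, bank, method = "eap", curve = curve)
  sub <- estimateAbility(responses[ids, ], bank, method = "eap", curve = curve)
  if (var(full$daz) <= 0 || var(sub$daz) <= 0) {
    stop("degenerate DAZ variance; cannot correlate", call. = FALSE)
  }
  cor(full$daz, sub$daz)
}

#' Domain information profile across age
#'
#' At each age on the grid, each form item contributes Rasch information
#' `P(1 - P)` evaluated at the median ability `mu(age)`; that information is
#' apportioned to developmental domains in proportion to the item's domain
#' weights and the per-age totals are normalised to shares.  The profile shows
#' which domains the instrument actually measures at each age.
#'
#' @param form a [Form-class].
#' @param bank an [ItemBank-class]; domain weights come from `weights`
#'   when given, else each item loads fully on its own domain.
#' @param curve a [ReferenceCurve-class].
#' @param ages age grid (default 3-month bin midpoints over 0-36).
#' @param weights optional domain-profile data.frame from
#'   [buildDomainProfiles()].
#' @return data.frame: `age`, one share column per primary domain; shares with
#'   non-zero information sum to 1 per age.
#' @export
domainInformationProfile <- function(form, bank, curve,
                                     ages = seq(1.5, 34.5, by = 3),
                                     weights = NULL) {
  ids <- formItems(form)
  delta <- difficulties(bank)[ids]
  it <- itemData(bank)
  doms <- sort(unique(primaryDomain(SUBDOMAINS)))
  W <- matrix(0, length(ids), length(doms), dimnames = list(ids, doms))
  if (is.null(weights)) {
    W[cbind(seq_along(ids), match(primaryDomain(it$domain[match(ids, it$item_id)]), doms))] <- 1
  } else {
    sub_w <- as.matrix(weights[match(ids, weights$item_id), SUBDOMAINS, drop = FALSE])
    sub_w[is.na(sub_w)] <- 0
    for (d in doms) {
      cols <- SUBDOMAINS[primaryDomain(SUBDOMAINS) == d]
      W[, d] <- rowSums(sub_w[, cols, drop = FALSE])
    }
    tot <- rowSums(W)
    zero <- tot == 0 # no votes: fall back to the bank's own domain
    W[zero, ] <- 0
    W[cbind(which(zero), match(primaryDomain(it$domain[match(ids[zero], it$item_id)]), doms))] <- 1
    tot <- rowSums(W)
    W <- W / tot
  }
  checkAges(curve, ages)
  out <- matrix(0, length(ages), length(doms), dimnames = list(NULL, doms))
  for (i in seq_along(ages)) {
    b <- curveMedian(curve, ages[i])
    info <- plogis(b - delta) * (1 - plogis(b - delta))
    shares <- colSums(info * W)
    s <- sum(shares)
    out[i, ] <- if (s > 0) shares / s else NA_real_
  }
  data.frame(age = ages, out, check.names = FALSE)
}

#' Evaluate an assembled form
#'
#' Full psychometric evaluation on a simulated cohort: DAZ correlation of the
#' form against the whole bank, separation reliability, mean SEM by 3-month age
#' bin, the domain information profile, and administration-length statistics
#' under the form's start/stop rules.
#'
#' @param form a [Form-class].
#' @param bank an [ItemBank-class].
#' @param curve a [ReferenceCurve-class].
#' @param nChildren cohort size (default 1000).
#' @param useRules simulate administration under start/stop rules when the form
#'   has a start rule (default TRUE when available).
#' @param weights optional domain-profile table for information apportioning.
#' @param seed integer seed.
#' @return An [EvaluationReport-class].
#' @export
evaluateForm <- function(form, bank, curve, nChildren = 1000L,
                         useRules = !is.null(startRule(form)),
                         weights = NULL, seed = NULL) {
  responses <- simulateResponses(bank, curve, nChildren = nChildren,
                                 seed = subSeed(seed, 1L))
  dazcor <- dazCorrelation(form, bank, curve, responses = responses)

  children <- data.frame(
    child_id = colnames(responseMatrix(responses)),
    age = colData(responses)$age,
    true_beta = colData(responses)$true_beta
  )
  adm <- simulateAdministration(form, bank, children, curve,
                                useRules = useRules, seed = subSeed(seed, 2L))
  ab <- adm$abilities
  rel <- separationReliability(ab)

  bins <- seq(0, 36, by = 3)
  bin_id <- cut(ab$age, bins, include.lowest = TRUE, right = FALSE)
  sem_by_age <- data.frame(
    age_bin = levels(bin_id),
    mean_sem = as.numeric(tapply(ab$sem, bin_id, mean, na.rm = TRUE))
  )
  info <- domainInformationProfile(form, bank, curve, weights = weights)
  al <- adm$admin_length$n_administered
  admin_stats <- data.frame(
    n_items_form = length(formItems(form)),
    mean_administered = mean(al), median_administered = stats::median(al),
    min_administered = min(al), max_administered = max(al)
  )
  new("EvaluationReport",
    form_id = form@form_id, daz_correlation = dazcor,
    reliability = if (is.na(rel)) NA_real_ else rel,
    sem_by_age = sem_by_age, info_by_domain_age = info,
    admin_length = admin_stats
  )
}

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport for", object@form_id, "\n")
  cat(sprintf("  DAZ correlation vs full bank: %.4f\n", object@daz_correlation))
  cat(sprintf("  separation reliability:       %.4f\n", object@reliability))
  if (!is.null(object@admin_length)) {
    cat(sprintf("  mean items administered:      %.1f of %d\n",
                object@admin_length$mean_administered,
                object@admin_length$n_items_form))
  }
  invisible(object)
})

#' Plot the domain information profile
#'
#' Stacked line display of the share of test information contributed by each
#' primary domain across age.
#'
#' @param report an [EvaluationReport-class] or the data.frame from
#'   [domainInformationProfile()].
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the plotted matrix.
#' @export
plotDomainInformation <- function(report, ...) {
  df <- if (is(report, "EvaluationReport")) report@info_by_domain_age else report
  m <- as.matrix(df[, setdiff(names(df), "age"), drop = FALSE])
  graphics::matplot(df$age, m, type = "l", lty = 1, lwd = 2,
                    xlab = "age (months)", ylab = "share of information", ...)
  graphics::legend("topright", colnames(m), col = seq_len(ncol(m)), lty = 1, lwd = 2,
                   cex = 0.8, bty = "n")
  invisible(m)
}
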