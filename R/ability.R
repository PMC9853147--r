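paramVector <- function(itemParams) {
  if (is.numeric(itemParams)) {
    stopIfNot(!is.null(names(itemParams)), "item parameters need item ids as names")
    return(itemParams)
  }
  if (is(itemParams, "ItemBank")) {
    return(difficulties(itemParams))
  }
  stopIfNot(all(c("item_id", "difficulty") %in% names(itemParams)),
            "itemParams needs item_id and difficulty columns")
  setNames(itemParams$difficulty, itemParams$item_id)
}

#' Estimate child D-scores (ability)
#'
#' Scores children on the D-score scale from their dichotomous responses and
#' fitted item difficulties.  `method = "ml"` solves the Rasch score equation
#' `sum(x_i - P_i) = 0` per child; perfect and zero raw scores have no finite
#' ML solution and are flagged (`+/-Inf`).  `method = "eap"` (default) uses the
#' age-conditional reference curve as a normal prior `N(mu(age), sigma(age)^2)`
#' and returns the posterior mean by Gauss-Hermite quadrature, which stays
#' finite at extreme scores.  The standard error of measurement is
#' `1 / sqrt(test information at the estimate)`; the DAZ column standardises
#' the D-score against the curve at the child's age.
#'
#' @param responses a [ResponseSet-class], a 0/1/NA matrix (items x children),
#'   or a named 0/1 vector for a single child.
#' @param itemParams data.frame from [fitDifficulties()], a named numeric of
#'   difficulties, or an `ItemBank`.  Items with `NA` difficulty are ignored.
#' @param method `"eap"` or `"ml"`.
#' @param curve [ReferenceCurve-class]; required for `"eap"` and for DAZ.
#' @param ages child ages in months (taken from the `ResponseSet` when absent).
#' @param nodes Gauss-Hermite node count for EAP (default 31).
#' @return data.frame (`AbilityEstimate`): `child_id`, `age`, `raw_score`,
#'   `n_items_used`, `dscore`, `sem`, `daz`, `extreme` flag.
#' @export
estimateAbility <- function(responses, itemParams, method = c("eap", "ml"),
                            curve = NULL, ages = NULL, nodes = 31L) {
  method <- match.arg(method)
  if (is.vector(responses) && !is.list(responses)) {
    responses <- matrix(responses, ncol = 1,
                        dimnames = list(names(responses), "child1"))
  }
  if (is(responses, "ResponseSet") && is.null(ages)) {
    ages <- colData(responses)$age
  }
  X <- responseMatrix(responses)
  delta <- paramVector(itemParams)
  delta <- delta[!is.na(delta)]
  common <- intersect(rownames(X), names(delta))
  stopIfNot(length(common) >= 1L, "no administered items with known difficulty")
  X <- X[common, , drop = FALSE]
  delta <- delta[common]
  nch <- ncol(X)

  M <- !is.na(X)
  n_used <- colSums(M)
  stopIfNot(all(n_used >= 1L), "every child needs at least one administered item")
  R <- X
  R[!M] <- 0
  raw <- colSums(R)
  extreme <- raw == 0 | raw == n_used

  if (method == "ml") {
    beta <- rep(0, nch)
    for (iter in 1:100) {
      P <- plogis(outer(-delta, beta, `+`))
      P[!M] <- 0
      score <- raw - colSums(P)
      info <- colSums(P * (1 - P))
      step <- score / pmax(info, 1e-8)
      step <- pmin(pmax(step, -5), 5)
      beta <- beta + step
      if (all(extreme) || max(abs(step[!extreme])) < 1e-10) break
    }
    beta[raw == 0] <- -Inf
    beta[raw == n_used & n_used > 0] <- Inf
  } else {
    stopIfNot(!is.null(curve), "EAP scoring needs a reference curve")
    stopIfNot(!is.null(ages), "EAP scoring needs child ages")
    ages <- rep_len(ages, nch)
    gh <- pracma::gaussHermite(nodes)
    mu <- curveMedian(curve, ages)
    sg <- curveSD(curve, ages)
    # adaptive quadrature: centre nodes at each child's posterior mode so the
    # grid resolves a posterior that is much narrower than the prior
    mode <- mu
    for (i in 1:10) {
      P <- plogis(outer(-delta, mode, `+`))
      g <- colSums(M * (R - P)) - (mode - mu) / sg^2
      h <- colSums(M * P * (1 - P)) + 1 / sg^2
      mode <- mode + pmin(pmax(g / h, -3), 3)
    }
    P <- plogis(outer(-delta, mode, `+`))
    psd <- 1 / sqrt(colSums(M * P * (1 - P)) + 1 / sg^2)
    LQ <- matrix(0, nch, length(gh$x))
    B <- matrix(0, nch, length(gh$x))
    for (q in seq_along(gh$x)) {
      bq <- mode + sqrt(2) * psd * gh$x[q]
      B[, q] <- bq
      P <- plogis(outer(-delta, bq, `+`))
      ll <- colSums(M * (R * log(pmax(P, 1e-300)) +
                           (1 - R) * log(pmax(1 - P, 1e-300))))
      LQ[, q] <- ll + log(gh$w[q]) + gh$x[q]^2 +
        stats::dnorm(bq, mu, sg, log = TRUE)
    }
    LQ <- LQ - apply(LQ, 1, max)
    W <- exp(LQ)
    W <- W / rowSums(W)
    beta <- rowSums(W * B)
  }

  sem <- rep(NA_real_, nch)
  finite <- is.finite(beta)
  if (any(finite)) {
    info <- testInformation(delta, beta[finite], mask = M[, finite, drop = FALSE])
    sem[finite] <- 1 / sqrt(info)
  }
  dazv <- rep(NA_real_, nch)
  if (!is.null(curve) && !is.null(ages)) {
    ages <- rep_len(ages, nch)
    dazv[finite] <- daz(beta[finite], ages[finite], curve)
  }
  data.frame(
    child_id = colnames(X) %||% sprintf("child%05d", seq_len(nch)),
    age = if (is.null(ages)) NA_real_ else rep_len(ages, nch),
    raw_score = as.integer(raw), n_items_used = as.integer(n_used),
    dscore = beta, sem = sem, daz = dazv, extreme = extreme,
    stringsAsFactors = FALSE
  )
}

#' Rasch test information
#'
#' Information of an item set at ability `beta`: `sum_i P_i (1 - P_i)` with
#' `P_i = plogis(beta - delta_i)`.  The measurement SE is its inverse square
#' root.
#'
#' @param delta item difficulties.
#' @param beta ability value(s).
#' @param mask optional logical matrix (items x length(beta)) restricting which
#'   items count for each ability (administered items).
#' @return numeric vector, one information value per `beta`.
#' @export
testInformation <- function(delta, beta, mask = NULL) {
  stopIfNot(length(delta) >= 1L, "empty item set")
  P <- plogis(outer(-delta, beta, `+`))
  V <- P * (1 - P)
  if (!is.null(mask)) V <- V * mask
  colSums(V)
}

#' Separation reliability
#'
#' Person-separation reliability of a scored cohort: the share of observed
#' D-score variance not attributable to measurement error,
#' `(var(dscore) - mean(sem^2)) / var(dscore)`, floored at 0.  Degenerate
#' cohorts (fewer than two finite scores, or zero variance) give `NA`.
#'
#' @param abilities data.frame with `dscore` and `sem` (see
#'   [estimateAbility()]).
#' @return numeric scalar in \[0, 1\] or `NA`.
#' @export
separationReliability <- function(abilities) {
  ok <- is.finite(abilities$dscore) & is.finite(abilities$sem)
  if (sum(ok) < 2L) return(NA_real_)
  v <- var(abilities$dscore[ok])
  if (!is.finite(v) || v <= 0) return(NA_real_)
  max(0, (v - mean(abilities$sem[ok]^2)) / v)
}

#' Development-for-age z-score (DAZ)
#'
#' Standardises a D-score against the age-conditional reference distribution:
#' `(beta - mu(age)) / sigma(age)`.
#'
#' @param beta D-score(s).
#' @param age age(s) in months, within the curve span.
#' @param curve a [ReferenceCurve-class].
#' @return numeric vector of z-scores.
#' @export
daz <- function(beta, age, curve) {
  (beta - curveMedian(curve, age)) / curveSD(curve, age)
}

#' Expected pass-age quantiles of an item
#'
#' The age at which a given share `p` of children passes an item of difficulty
#' `delta`, under the reference curve.  In the default `"marginal"` mode the
#' pass rate at age `a` averages over the ability distribution,
#' `E_z[plogis(mu(a) + sigma(a) z - delta)]` (Gauss-Hermite quadrature), and the
#' quantile solves pass rate = p by root finding.  In `"median"` mode the
#' median child is used instead, which reduces to the closed form
#' `a = mu^{-1}(delta + qlogis(p))` and equals the sigma -> 0 limit of the
#' marginal mode.  Ages where no root exists inside the curve span are censored
#' at the span boundary and flagged.
#'
#' @param delta item difficulty (scalar).
#' @param curve a [ReferenceCurve-class].
#' @param p pass probabilities (default 10/50/90%).
#' @param mode `"marginal"` or `"median"`.
#' @param nodes Gauss-Hermite nodes for the marginal mode (default 31).
#' @return data.frame: `p`, `age` (months), `censored`.
#' @export
passAgeQuantiles <- function(delta, curve, p = c(0.10, 0.50, 0.90),
                             mode = c("marginal", "median"), nodes = 31L) {
  mode <- match.arg(mode)
  stopIfNot(length(delta) == 1L && is.finite(delta), "delta must be a finite scalar")
  stopIfNot(all(p > 0 & p < 1), "p must lie strictly between 0 and 1")
  span <- ageSpan(curve)
  gh <- if (mode == "marginal") gaussHermiteNormal(nodes) else NULL
  rate <- function(a) {
    if (mode == "median") {
      plogis(curveMedian(curve, a) - delta)
    } else {
      mu <- curveMedian(curve, a)
      sg <- curveSD(curve, a)
      sum(gh$w * plogis(mu + sg * gh$z - delta))
    }
  }
  out <- data.frame(p = p, age = NA_real_, censored = FALSE)
  for (i in seq_along(p)) {
    flo <- rate(span[1]) - p[i]
    fhi <- rate(span[2]) - p[i]
    if (flo >= 0) {
      out$age[i] <- span[1]; out$censored[i] <- flo > 0
    } else if (fhi <= 0) {
      out$age[i] <- span[2]; out$censored[i] <- fhi < 0
    } else {
      out$age[i] <- uniroot(function(a) rate(a) - p[i], span, tol = 1e-10)$root
    }
  }
  out
}

# Convenience: median pass age (a50-style quantile) for many items at once.
medianPassAges <- function(delta, curve, mode = "marginal") {
  vapply(delta, function(d) passAgeQuantiles(d, curve, p = 0.5, mode = mode)$age,
         numeric(1))
}
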