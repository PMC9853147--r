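responseMatrix <- function(responses) {
  if (is(responses, "ResponseSet")) {
    assay(responses, "status")
  } else {
    as.matrix(responses)
  }
}

# Connectivity of the linking design: two items are linked when some child has
# differing observed responses on them (only pass/fail contrasts identify a
# difficulty difference).  Returns a list of item-id components (length 1 when
# connected).
linkComponents <- function(X) {
  k <- nrow(X)
  ids <- rownames(X)
  edges <- list()
  for (c in seq_len(ncol(X))) {
    x <- X[, c]
    p <- which(!is.na(x) & x == 1)
    f <- which(!is.na(x) & x == 0)
    if (length(p) && length(f)) {
      # first-fail to all passes and first-pass to all fails reach the same
      # components as the full pass x fail bipartite clique
      edges[[length(edges) + 1L]] <- cbind(rep(f[1], length(p)), p)
      edges[[length(edges) + 1L]] <- cbind(rep(p[1], length(f)), f)
    }
  }
  if (!length(edges)) {
    return(as.list(ids))
  }
  em <- unique(do.call(rbind, edges))
  g <- igraph::graph_from_edgelist(
    matrix(ids[em], ncol = 2), directed = FALSE
  )
  g <- g + igraph::vertices(setdiff(ids, igraph::V(g)$name))
  comp <- igraph::components(g)
  unname(split(names(comp$membership), comp$membership))
}

#' Fit dichotomous Rasch item difficulties
#'
#' Estimates item difficulties for the dichotomous Rasch model
#' `P(pass) = plogis(beta - delta)`.  The default method, `"mml"`, is marginal
#' maximum likelihood with the age-conditional reference curve as the ability
#' prior, integrated by adaptive Gauss-Hermite quadrature (nodes centred and
#' scaled at each child's posterior mode).  Marginal ML is the only estimator
#' here that keeps the raw-score information identifying the global spacing of
#' a bank whose difficulties span many logits; see the methods vignette.
#'
#' Two conditional estimators are provided as distribution-free cross-checks:
#' `"cml"`, classical conditional maximum likelihood via log-space elementary
#' symmetric functions (exact but nearly uninformative about the global
#' stretch of very wide banks, where it is best used locally or with
#' anchoring), and `"pairwise"`, conditional logistic estimation over item
#' pairs with exactly one pass (robust to missingness).
#'
#' Items that no child failed or no child passed carry no information about
#' their location and are flagged non-estimable (`NA` difficulty); the data are
#' iteratively trimmed of extreme-score children and unmixed items before
#' fitting.  A disconnected linking design (two item subsets with no pass/fail
#' contrast joining them) is an error naming the components.
#'
#' MML difficulties live on the reference-curve scale already; conditional
#' estimates are identified up to location, returned sum-zero.  `anchors`
#' applies an anchoring map for any method: one anchor gives a location shift,
#' two or more an affine map fitted by least squares (exact for two anchors).
#'
#' @param responses a [ResponseSet-class] or 0/1 matrix (items x children).
#' @param method `"mml"` (default), `"cml"` or `"pairwise"`.
#' @param curve a [ReferenceCurve-class]; required for `"mml"`.
#' @param ages child ages in months (taken from the `ResponseSet` when absent).
#' @param anchors optional named numeric: reporting-scale values for anchor
#'   items.
#' @param control list: `reltol` for the conditional optimizers (default
#'   1e-10), `maxit` (default 500), `nodes` adaptive quadrature size (default
#'   9), `tol` MML convergence tolerance on difficulties (default 1e-4).
#' @return data.frame (`ItemParams`): `item_id`, `difficulty`, `se_difficulty`,
#'   `estimable`, `n_pass`, `n_obs`; attribute `method`.
#' @export
fitDifficulties <- function(responses, method = c("mml", "cml", "pairwise"),
                            curve = NULL, ages = NULL,
                            anchors = NULL, control = list()) {
  method <- match.arg(method)
  if (is(responses, "ResponseSet") && is.null(ages)) {
    ages <- colData(responses)$age
  }
  X <- responseMatrix(responses)
  stopIfNot(!is.null(rownames(X)), "response matrix needs item ids as rownames")
  reltol <- control$reltol %||% 1e-10
  maxit <- control$maxit %||% 500L

  n_pass <- rowSums(X == 1, na.rm = TRUE)
  n_obs <- rowSums(!is.na(X))

  if (method == "mml") {
    # extreme-score children stay in: the marginal likelihood uses them, and
    # removing them truncates both tails of the ability distribution (which
    # stretches the recovered scale); only boundary items are flagged
    keep_i <- n_pass > 0 & n_pass < n_obs
    keep_c <- colSums(!is.na(X[keep_i, , drop = FALSE])) > 0
  } else {
    # Iteratively trim to the informative core: children with extreme raw
    # scores over the retained items carry no conditional information, and
    # items that are all-pass/all-fail over the retained children sit on the
    # likelihood boundary.  Repeat until stable (standard Rasch cleaning).
    keep_i <- rep(TRUE, nrow(X))
    keep_c <- rep(TRUE, ncol(X))
    repeat {
      Xi <- X[keep_i, keep_c, drop = FALSE]
      r <- colSums(Xi == 1, na.rm = TRUE)
      m <- colSums(!is.na(Xi))
      ok_c <- r > 0 & r < m
      s <- rowSums(Xi[, ok_c, drop = FALSE] == 1, na.rm = TRUE)
      t <- rowSums(!is.na(Xi[, ok_c, drop = FALSE]))
      ok_i <- s > 0 & s < t
      changed <- !all(ok_c) || !all(ok_i)
      keep_c[keep_c] <- ok_c
      keep_i[keep_i] <- ok_i
      if (!changed) break
    }
  }
  estimable <- keep_i
  Xe <- X[estimable, keep_c, drop = FALSE]
  stopIfNot(nrow(Xe) >= 2L, "fewer than two estimable items")

  comps <- linkComponents(Xe)
  if (length(comps) > 1L) {
    desc <- vapply(comps, function(cp) {
      paste0("{", paste(head(cp, 4), collapse = ", "),
             if (length(cp) > 4) ", ..." else "", "}")
    }, character(1))
    stop("disconnected response design; unlinked item components: ",
         paste(desc, collapse = " / "), call. = FALSE)
  }

  if (method == "mml") {
    stopIfNot(!is.null(curve), "marginal ML needs a reference curve")
    stopIfNot(!is.null(ages), "marginal ML needs child ages")
    agese <- rep_len(ages, ncol(X))[keep_c]
    complete <- colSums(is.na(Xe)) == 0L
    if (!all(complete)) {
      warning("marginal ML uses complete response vectors only; ",
              sum(!complete), " children with missing responses dropped")
      Xe <- Xe[, complete, drop = FALSE]
      agese <- agese[complete]
    }
    est <- mmlFit(Xe, agese, curve,
                  nodes = control$nodes %||% 9L,
                  tol = control$tol %||% 1e-4,
                  maxit = control$maxit %||% 500L)
  } else if (method == "cml") {
    complete <- colSums(is.na(Xe)) == 0L
    if (!all(complete)) {
      warning("conditional ML uses complete response vectors only; ",
              sum(!complete), " children with missing responses dropped")
      Xe <- Xe[, complete, drop = FALSE]
    }
    est <- cmlFit(Xe, reltol = reltol, maxit = maxit)
  } else {
    est <- pairwiseFit(Xe, reltol = reltol, maxit = maxit)
  }

  delta <- est$delta
  if (method != "mml") delta <- delta - mean(delta) # location fixed by sum-zero
  if (!is.null(anchors)) {
    stopIfNot(!is.null(names(anchors)) && all(names(anchors) %in% rownames(Xe)),
              "anchors must be named with estimable item ids")
    at <- delta[names(anchors)]
    if (length(anchors) == 1L) {
      delta <- delta + (anchors - at)
    } else {
      fit <- stats::lm.fit(cbind(1, at), as.numeric(anchors))
      delta <- fit$coefficients[1] + fit$coefficients[2] * delta
      est$se <- est$se * abs(fit$coefficients[2])
    }
  }

  out <- data.frame(
    item_id = rownames(X),
    difficulty = NA_real_, se_difficulty = NA_real_,
    estimable = estimable, n_pass = as.integer(n_pass), n_obs = as.integer(n_obs),
    stringsAsFactors = FALSE
  )
  out$difficulty[match(rownames(Xe), out$item_id)] <- unname(delta)
  out$se_difficulty[match(rownames(Xe), out$item_id)] <- unname(est$se)
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Conditional ML via log-space elementary symmetric functions (Rcpp kernel).
# X: complete 0/1 matrix, items x children, every item mixed.
cmlFit <- function(X, reltol = 1e-10, maxit = 500L) {
  k <- nrow(X)
  r <- colSums(X)
  keep <- r > 0 & r < k
  X <- X[, keep, drop = FALSE]
  stopIfNot(ncol(X) > 0L, "no children with non-extreme raw scores")
  s <- rowSums(X) # item totals over non-extreme children
  nr <- tabulate(colSums(X), nbins = k - 1L) # counts by raw score 1..k-1

  # sum-zero parameterisation: theta in R^{k-1}, delta_k = -sum(theta)
  expand <- function(theta) c(theta, -sum(theta))
  nll <- function(theta) {
    d <- expand(theta)
    lg <- esf_log(-d)
    sum(s * d) + sum(nr * lg[2:k])
  }
  grad <- function(theta) {
    d <- expand(theta)
    q <- cml_pi(-d)
    g <- s - as.numeric(q$pi %*% nr)
    g[seq_len(k - 1L)] - g[k]
  }
  start <- qlogis((ncol(X) - s + 0.5) / (ncol(X) + 1))
  start <- start - mean(start)
  opt <- stats::optim(start[seq_len(k - 1L)], nll, grad,
                      method = "BFGS",
                      control = list(reltol = reltol, maxit = maxit))
  d <- expand(opt$par)
  q <- cml_pi(-d)
  info <- as.numeric((q$pi * (1 - q$pi)) %*% nr) # diagonal conditional information
  list(delta = setNames(d, rownames(X)), se = setNames(1 / sqrt(info), rownames(X)),
       convergence = opt$convergence)
}

# Pairwise conditional estimator: for each ordered item pair (i, j), count
# children passing i and failing j; conditional on one pass within the pair,
# P(i passes) = plogis(delta_j - delta_i).  Maximising this pairwise likelihood
# gives a consistent estimator that tolerates missingness.
pairwiseFit <- function(X, reltol = 1e-10, maxit = 500L) {
  k <- nrow(X)
  P1 <- X == 1 & !is.na(X)
  P0 <- X == 0 & !is.na(X)
  N <- P1 %*% t(P0) # N[i, j] = # children with i pass, j fail
  mode(N) <- "double"
  expand <- function(theta) c(theta, -sum(theta))
  nll <- function(theta) {
    d <- expand(theta)
    D <- outer(d, d, function(a, b) b - a) # delta_j - delta_i
    lp <- plogis(D, log.p = TRUE)
    -sum(N * lp)
  }
  grad <- function(theta) {
    d <- expand(theta)
    D <- outer(d, d, function(a, b) b - a)
    G <- N * plogis(-D) # N_ij * (1 - P_ij)
    g <- rowSums(G) - colSums(G)
    g[seq_len(k - 1L)] - g[k]
  }
  s <- rowSums(P1)
  nobs <- rowSums(P1 | P0)
  start <- qlogis((nobs - s + 0.5) / (nobs + 1))
  start <- start - mean(start)
  opt <- stats::optim(start[seq_len(k - 1L)], nll, grad,
                      method = "BFGS",
                      control = list(reltol = reltol, maxit = maxit))
  d <- expand(opt$par)
  # SE from the curvature of the pairwise objective (diagonal approximation)
  D <- outer(d, d, function(a, b) b - a)
  W <- (N + t(N)) * plogis(D) * plogis(-D)
  info <- rowSums(W)
  list(delta = setNames(d, rownames(X)), se = setNames(1 / sqrt(info), rownames(X)),
       convergence = opt$convergence)
}

# Per-child posterior mode and Laplace sd of ability under prior N(mu, sg^2),
# given current difficulties.  Vectorised Newton over children.
posteriorMode <- function(X, delta, mu, sg, steps = 8L) {
  beta <- mu
  for (i in seq_len(steps)) {
    P <- plogis(outer(-delta, beta, `+`))
    g <- colSums(X - P) - (beta - mu) / sg^2
    h <- colSums(P * (1 - P)) + 1 / sg^2
    beta <- beta + pmin(pmax(g / h, -3), 3)
  }
  P <- plogis(outer(-delta, beta, `+`))
  list(mode = beta, sd = 1 / sqrt(colSums(P * (1 - P)) + 1 / sg^2))
}

# One EM update of the marginal likelihood: E-step with adaptive Gauss-Hermite
# nodes centred at each child's posterior mode, M-step one Newton step per
# item.  Returns the updated difficulties and the diagonal complete-data
# information (SE approximation).
mmlStep <- function(delta, X, s, mu, sg, gh) {
  n <- ncol(X)
  pm <- posteriorMode(X, delta, mu, sg)
  q <- length(gh$x)
  LQ <- matrix(0, n, q)
  Plist <- vector("list", q)
  for (j in seq_len(q)) {
    b <- pm$mode + sqrt(2) * pm$sd * gh$x[j]
    P <- plogis(outer(-delta, b, `+`))
    Plist[[j]] <- P
    ll <- colSums(X * log(pmax(P, 1e-300)) + (1 - X) * log(pmax(1 - P, 1e-300)))
    LQ[, j] <- ll + log(gh$w[j]) + gh$x[j]^2 +
      stats::dnorm(b, mu, sg, log = TRUE)
  }
  LQ <- LQ - apply(LQ, 1, max)
  W <- exp(LQ)
  W <- W / rowSums(W)
  g <- s
  h <- numeric(nrow(X))
  for (j in seq_len(q)) {
    g <- g - as.numeric(Plist[[j]] %*% W[, j])
    h <- h + as.numeric((Plist[[j]] * (1 - Plist[[j]])) %*% W[, j])
  }
  list(delta = delta - pmin(pmax(g / pmax(h, 1e-10), -2), 2), info = h)
}

# Marginal ML with the reference curve as ability prior; EM with SQUAREM
# extrapolation to tame the slowly converging global-stretch mode.
mmlFit <- function(X, ages, curve, nodes = 9L, tol = 1e-4, maxit = 500L) {
  k <- nrow(X)
  n <- ncol(X)
  s <- rowSums(X)
  mu <- curveMedian(curve, ages)
  sg <- curveSD(curve, ages)
  gh <- pracma::gaussHermite(nodes)
  delta <- qlogis((n - s + 0.5) / (n + 1))
  delta <- delta - mean(delta) + mean(mu)

  info <- NULL
  it <- 0L
  repeat {
    st1 <- mmlStep(delta, X, s, mu, sg, gh)
    r1 <- st1$delta - delta
    if (max(abs(r1)) < tol || it >= maxit) {
      delta <- st1$delta
      info <- st1$info
      break
    }
    st2 <- mmlStep(st1$delta, X, s, mu, sg, gh)
    r2 <- st2$delta - st1$delta
    v <- r2 - r1
    alpha <- -sqrt(sum(r1^2)) / max(sqrt(sum(v^2)), 1e-12)
    alpha <- min(-1, max(alpha, -30))
    cand <- delta - 2 * alpha * r1 + alpha^2 * v
    st3 <- mmlStep(cand, X, s, mu, sg, gh) # stabilisation step
    if (all(is.finite(st3$delta))) {
      delta <- st3$delta
      info <- st3$info
    } else {
      delta <- st2$delta
      info <- st2$info
    }
    it <- it + 3L
  }
  list(delta = setNames(delta, rownames(X)),
       se = setNames(1 / sqrt(info), rownames(X)),
       convergence = as.integer(it >= maxit))
}
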