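simRasch <- function(delta, beta, seed = 1) {
  set.seed(seed)
  P <- plogis(outer(-delta, beta, `+`))
  matrix(as.integer(runif(length(P)) < P), length(delta), length(beta),
         dimnames = list(names(delta) %||2% sprintf("i%02d", seq_along(delta)),
                         sprintf("c%04d", seq_along(beta))))
}
`%||2%` <- function(a, b) if (is.null(a)) b else a

test_that("a two-item difficulty gap is recovered by the conditional fit", {
  d <- 1.2
  X <- simRasch(c(0, d), rnorm(4000, 0.6, 1.5), seed = 2)
  fit <- fitDifficulties(X, method = "cml")
  gap <- diff(fit$difficulty)
  se <- sqrt(sum(fit$se_difficulty^2))
  expect_lt(abs(gap - d), 3 * se)
  # pairwise cross-check agrees with CML
  fitp <- fitDifficulties(X, method = "pairwise")
  expect_lt(abs(diff(fitp$difficulty) - gap), 3 * se)
})

test_that("permuting item rows permutes the estimates identically", {
  X <- simRasch(seq(-2, 2, length.out = 12), rnorm(400, 0, 2), seed = 3)
  fit <- fitDifficulties(X, method = "pairwise")
  perm <- sample(nrow(X))
  fit2 <- fitDifficulties(X[perm, ], method = "pairwise")
  expect_equal(fit2$difficulty[match(fit$item_id, fit2$item_id)],
               fit$difficulty, tolerance = 1e-6)
})

test_that("all-pass and all-fail items are flagged non-estimable", {
  X <- simRasch(c(0, 0.5, 1), rnorm(200, 0, 1), seed = 4)
  X[1, ] <- 1L
  fit <- fitDifficulties(X, method = "cml")
  expect_false(fit$estimable[1])
  expect_true(is.na(fit$difficulty[1]))
  expect_true(all(fit$estimable[2:3]))
})

test_that("a disconnected linking design raises a component-naming error", {
  X <- matrix(NA_real_, 4, 40, dimnames = list(paste0("i", 1:4), paste0("c", 1:40)))
  set.seed(5)
  X[1:2, 1:20] <- rbinom(40, 1, 0.5)
  X[3:4, 21:40] <- rbinom(40, 1, 0.5)
  expect_error(fitDifficulties(X, method = "pairwise"), "disconnected")
})

test_that("anchoring maps the conditional solution onto the reporting scale", {
  delta <- c(a = -1, b = 0, c = 1, d = 2) * 2
  X <- simRasch(delta, rnorm(3000, 1, 2.5), seed = 6)
  fit <- fitDifficulties(X, method = "cml", anchors = c(a = -2, d = 4))
  expect_equal(fit$difficulty[fit$item_id == "a"], -2, tolerance = 1e-8)
  expect_equal(fit$difficulty[fit$item_id == "d"], 4, tolerance = 1e-8)
  expect_equal(fit$difficulty, unname(delta), tolerance = 0.5)
})

test_that("ML ability solves the score equation and flags extreme scores", {
  delta <- c(i1 = -1, i2 = 0, i3 = 1)
  ab <- estimateAbility(c(i1 = 1, i2 = 1, i3 = 0), delta, method = "ml")
  # score equation sum(x - P) = 0 at the estimate
  expect_equal(sum(c(1, 1, 0) - plogis(ab$dscore - delta)), 0, tolerance = 1e-6)
  expect_false(ab$extreme)

  perfect <- estimateAbility(c(i1 = 1, i2 = 1, i3 = 1), delta, method = "ml")
  expect_true(perfect$extreme)
  expect_identical(perfect$dscore, Inf)
  zero <- estimateAbility(c(i1 = 0, i2 = 0, i3 = 0), delta, method = "ml")
  expect_identical(zero$dscore, -Inf)

  # under EAP the same responses give a finite score
  curve <- defaultReferenceCurve()
  eap <- estimateAbility(matrix(c(1, 1, 1), 3, dimnames = list(names(delta), "k1")),
                         delta + 50, method = "eap", curve = curve, ages = 12)
  expect_true(is.finite(eap$dscore))

  expect_error(estimateAbility(matrix(NA_real_, 3, 1,
                                      dimnames = list(names(delta), "k")),
                               delta, method = "ml"),
               "at least one administered item")
})

test_that("ML ability is strictly increasing in raw score", {
  delta <- setNames(seq(-2, 2, length.out = 8), paste0("i", 1:8))
  scores <- t(sapply(1:7, function(r) c(rep(1, r), rep(0, 8 - r))))
  X <- t(scores)
  rownames(X) <- names(delta)
  colnames(X) <- paste0("c", 1:7)
  ab <- estimateAbility(X, delta, method = "ml")
  expect_true(all(diff(ab$dscore[order(ab$raw_score)]) > 0))
})

test_that("translation invariance: shifting items and abilities cancels", {
  delta <- setNames(seq(-1, 1, length.out = 5), paste0("i", 1:5))
  x <- setNames(c(1, 1, 0, 1, 0), names(delta))
  b0 <- estimateAbility(x, delta, method = "ml")$dscore
  b1 <- estimateAbility(x, delta + 7, method = "ml")$dscore
  expect_equal(b1, b0 + 7, tolerance = 1e-6)
  expect_equal(testInformation(delta, b0), testInformation(delta + 7, b0 + 7))
})

test_that("pass-age quantiles match the closed form when sigma vanishes", {
  curve <- linearCurve(sigma = 1e-9) # mu(a) = a
  q <- passAgeQuantiles(20, curve, p = c(0.1, 0.5, 0.9))
  expect_equal(q$age[q$p == 0.5], 20, tolerance = 1e-6)
  expect_equal(q$age[q$p == 0.9], 20 + qlogis(0.9), tolerance = 1e-6)
  expect_equal(q$age[q$p == 0.1], 20 + qlogis(0.1), tolerance = 1e-6)
  expect_true(all(diff(q$age) > 0))
  expect_false(any(q$censored))

  # median-child mode is the closed form by construction
  qm <- passAgeQuantiles(20, linearCurve(sigma = 2), p = 0.9, mode = "median")
  expect_equal(qm$age, 20 + qlogis(0.9), tolerance = 1e-8)

  # quantile ordering holds for any difficulty within span (marginal mode)
  curve2 <- defaultReferenceCurve()
  for (d in c(30, 60, 90, 110)) {
    qq <- passAgeQuantiles(d, curve2)
    expect_true(all(diff(qq$age) >= 0))
  }

  # out-of-span roots are censored at the boundary
  qc <- passAgeQuantiles(200, defaultReferenceCurve(), p = 0.9)
  expect_true(qc$censored)
  expect_equal(qc$age, 36)
})

test_that("DAZ standardises against the curve", {
  curve <- defaultReferenceCurve()
  expect_equal(daz(curveMedian(curve, 10), 10, curve), 0)
  expect_equal(daz(curveMedian(curve, 10) + curveSD(curve, 10), 10, curve), 1)
  expect_error(daz(50, 45, curve), "outside the reference curve span")

  # children simulated from the curve have DAZ ~ N(0, 1)
  bank <- simulateItemBank(20, 20, seed = 40)
  rs <- simulateResponses(bank, curve, nChildren = 2000, seed = 41)
  z <- daz(colData(rs)$true_beta, colData(rs)$age, curve)
  expect_lt(abs(mean(z)), 0.05)
  expect_true(sd(z) > 0.95 && sd(z) < 1.05)
})

test_that("test information is additive with the expected point values", {
  expect_equal(testInformation(0, 0), 0.25) # single item at beta = delta
  expect_equal(testInformation(c(0, 0), 0), 0.5) # doubling identical items
  delta <- seq(-2, 2, 0.5)
  expect_equal(testInformation(c(delta, delta), 1),
               2 * testInformation(delta, 1))
  expect_error(testInformation(numeric(0), 0), "empty item set")
})

test_that("separation reliability matches an independent split-half estimate", {
  bank <- simulateItemBank(80, 80, seed = 42)
  curve <- defaultReferenceCurve()
  rs <- simulateResponses(bank, curve, nChildren = 600, seed = 43)
  ab <- estimateAbility(rs, bank, method = "ml")
  keep <- !ab$extreme
  rel <- separationReliability(ab[keep, ])

  # split-half oracle: score odd and even items separately, correlate, then
  # Spearman-Brown up to full length
  ids <- itemIds(bank)
  half1 <- estimateAbility(rs[ids[c(TRUE, FALSE)], ], bank, method = "ml")
  half2 <- estimateAbility(rs[ids[c(FALSE, TRUE)], ], bank, method = "ml")
  ok <- keep & !half1$extreme & !half2$extreme
  r <- cor(half1$dscore[ok], half2$dscore[ok])
  sb <- 2 * r / (1 + r)
  expect_lt(abs(rel - sb), 0.05)

  # degenerate cohorts report missing
  expect_true(is.na(separationReliability(data.frame(dscore = 1, sem = 0.1))))
  expect_true(is.na(separationReliability(
    data.frame(dscore = c(2, 2), sem = c(0.1, 0.1)))))
})

test_that("difficulty recovery improves with sample size", {
  bank <- simulateItemBank(40, 40, seed = 44)
  curve <- defaultReferenceCurve()
  truth <- difficulties(bank, use = "true")
  rmse <- sapply(c(200, 2000), function(n) {
    rs <- simulateResponses(bank, curve, nChildren = n, seed = 45)
    fit <- fitDifficulties(rs, curve = curve)
    ok <- fit$estimable
    sqrt(mean((fit$difficulty[ok] - truth[ok])^2))
  })
  expect_lt(rmse[2], rmse[1])
})

test_that("EAP recovery of ability has slope near one and unbiased DAZ", {
  bank <- simulateItemBank(60, 60, seed = 46)
  curve <- defaultReferenceCurve()
  rs <- simulateResponses(bank, curve, nChildren = 800, seed = 47)
  ab <- estimateAbility(rs, bank, method = "eap", curve = curve)
  slope <- coef(lm(ab$dscore ~ colData(rs)$true_beta))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
  expect_lt(abs(mean(ab$daz - daz(colData(rs)$true_beta, ab$age, curve))), 0.1)
})
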