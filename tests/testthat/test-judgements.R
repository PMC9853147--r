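test_that("matching coefficients hit the published endpoints exactly", {
  expect_identical(aggregateMatching(makeRatings(rep("very_strong", 6)))$value, 1)
  expect_identical(aggregateMatching(makeRatings(rep("none", 6)))$value, 0)
})

test_that("coefficients average the mapped levels over judges", {
  mixed <- aggregateMatching(makeRatings(c(rep("very_strong", 3), rep("strong", 3))))
  expect_equal(mixed$value, (3 * 1 + 3 * 2 / 3) / 6, tolerance = 1e-12)
  expect_equal(mixed$n_judges, 6L)

  # symmetric under pair order
  fwd <- makeRatings(c("strong", "partial"), "A", "B")
  rev <- fwd
  rev$item_a <- "B"; rev$item_b <- "A"
  expect_equal(aggregateMatching(fwd)$value, aggregateMatching(rev)$value)

  # custom mapping is honoured
  m <- c(none = 0, partial = 0.25, strong = 0.75, very_strong = 1)
  expect_equal(aggregateMatching(makeRatings(c("partial", "strong")), mapping = m)$value,
               0.5)
})

test_that("raising any single rating never lowers the coefficient", {
  set.seed(20)
  lv <- raschform:::MATCH_LEVELS
  for (rep in 1:25) {
    levels <- sample(lv, sample(2:8, 1), replace = TRUE)
    base <- aggregateMatching(makeRatings(levels))$value
    i <- sample(seq_along(levels), 1)
    pos <- match(levels[i], lv)
    if (pos == 4) next
    raised <- levels
    raised[i] <- lv[pos + 1]
    expect_gte(aggregateMatching(makeRatings(raised))$value, base)
  }
})

test_that("second-pass ratings override only the re-rated judge and pair", {
  r <- rbind(
    makeRatings(c("none", "none"), "A", "B"),
    makeRatings(c("strong", "strong"), "A", "C")
  )
  r2 <- rbind(r, data.frame(
    judge_id = "judge01", item_a = "A", item_b = "B",
    level = "very_strong", pass_number = 2L
  ))
  before <- aggregateMatching(r)
  after <- aggregateMatching(r2)
  ab <- after$item_a == "A" & after$item_b == "B"
  expect_equal(after$value[ab], 0.5)        # (1 + 0)/2 after the correction
  expect_equal(after$value[!ab], before$value[!ab]) # other pair untouched
  expect_error(
    aggregateMatching(rbind(r2, r2[nrow(r2), ])), "multiple pass-2"
  )
})

test_that("degenerate rating inputs error clearly", {
  expect_error(aggregateMatching(makeRatings("strong", "A", "A")), "self-pair")
  bad <- makeRatings("strong"); bad$level <- "superb"
  expect_error(aggregateMatching(bad), "unknown rating level")
})

test_that("equate groups are connected components over strong-or-better edges", {
  coef <- data.frame(
    item_a = c("A", "B", "A", "D"), item_b = c("B", "C", "C", "E"),
    value = c(0.8, 2 / 3, 0.2, 0.5), n_judges = 6
  )
  g <- extractEquateGroups(coef)
  # chain A-B, B-C above threshold, A-C below: one component of three
  expect_setequal(g$item_id[g$group_id == g$group_id[g$item_id == "A"]],
                  c("A", "B", "C"))
  expect_false("D" %in% g$item_id) # 0.5 edge is below strong

  expect_equal(nrow(extractEquateGroups(coef[coef$value < 0.6, ])), 0)
  expect_equal(nrow(extractEquateGroups(coef[0, ])), 0)

  # four items pairwise strong form a single group of four
  quad <- expand.grid(a = 1:4, b = 1:4)
  quad <- quad[quad$a < quad$b, ]
  coef4 <- data.frame(
    item_a = paste0("roll", quad$a), item_b = paste0("roll", quad$b),
    value = 0.9, n_judges = 6
  )
  g4 <- extractEquateGroups(coef4)
  expect_equal(length(unique(g4$group_id)), 1L)
  expect_equal(nrow(g4), 4L)
})

test_that("component extraction agrees with a brute-force closure oracle", {
  set.seed(30)
  for (i in 1:60) {
    n <- sample(4:20, 1)
    ids <- sprintf("i%02d", seq_len(n))
    pair <- t(combn(n, 2))
    keep <- runif(nrow(pair)) < 0.15
    if (!any(keep)) next
    coef <- data.frame(
      item_a = ids[pair[keep, 1]], item_b = ids[pair[keep, 2]],
      value = round(runif(sum(keep)), 2), n_judges = 6
    )
    got <- canonicalPartition(extractEquateGroups(coef))
    want <- bruteGroups(coef)
    want <- sort(vapply(Filter(function(s) length(s) >= 2, want),
                        function(s) paste(s, collapse = "+"), character(1)))
    expect_identical(got, unname(want))
  }
})

test_that("noiseless judges let the pipeline recover the concept partition", {
  bank <- simulateItemBank(60, 25, seed = 31)
  ratings <- simulateJudgeMatchings(bank, nJudges = 6, errorRate = 0, seed = 32)
  groups <- extractEquateGroups(aggregateMatching(ratings))
  it <- itemData(bank)
  truth <- split(it$item_id, it$latent_concept_id)
  truth <- Filter(function(s) length(s) >= 2, truth)
  want <- sort(vapply(truth, function(s) paste(sort(s), collapse = "+"), character(1)))
  expect_identical(canonicalPartition(groups), unname(want))
})

test_that("noisy judges still recover most of the partition (adjusted Rand)", {
  bank <- simulateItemBank(60, 25, seed = 33)
  ratings <- simulateJudgeMatchings(bank, nJudges = 6, errorRate = 0.1, seed = 7)
  groups <- extractEquateGroups(aggregateMatching(ratings))
  it <- itemData(bank)
  lab_true <- it$latent_concept_id
  lab_est <- groups$group_id[match(it$item_id, groups$item_id)]
  lab_est[is.na(lab_est)] <- paste0("single", seq_len(sum(is.na(lab_est))))
  expect_gt(adjustedRand(as.character(lab_true), lab_est), 0.7)
})

test_that("single rater coefficients take only the four mapped values", {
  bank <- simulateItemBank(20, 8, seed = 34)
  ratings <- simulateJudgeMatchings(bank, nJudges = 1, errorRate = 0, seed = 35)
  coef <- aggregateMatching(ratings)
  expect_true(all(coef$value %in% c(0, 1 / 3, 2 / 3, 1)))
})

test_that("domain profiles rescale votes by the panel size", {
  votes <- data.frame(
    item_id = c("a", "a", "b"),
    subdomain = c("motor.fine", "adaptive.life_skills", "motor.gross"),
    votes = c(5L, 4L, 9L)
  )
  prof <- buildDomainProfiles(votes, nJudges = 9)
  a <- prof[prof$item_id == "a", ]
  expect_equal(a$motor.fine, 5 / 9)
  expect_equal(a$adaptive.life_skills, 4 / 9)
  expect_equal(sum(a[raschform:::SUBDOMAINS] > 0), 2) # multi-domain item
  b <- prof[prof$item_id == "b", ]
  expect_equal(b$motor.gross, 1)
  expect_equal(b$primary_domain, "motor.gross")
  expect_false(b$primary_tie)

  tie <- buildDomainProfiles(data.frame(
    item_id = "t", subdomain = c("motor.fine", "cognition.reasoning"), votes = c(4L, 4L)
  ), nJudges = 9)
  expect_true(tie$primary_tie)
  expect_equal(tie$primary_domain, "cognition.reasoning") # lexicographic tie-break

  expect_error(buildDomainProfiles(votes, nJudges = 4), "exceed")
})

test_that("subdomain correlations are rank-based with missing for constants", {
  votes <- data.frame(
    item_id = rep(sprintf("i%d", 1:4), each = 2),
    subdomain = rep(c("motor.fine", "cognition.reasoning"), 4),
    votes = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 9L)
  )
  rho <- subdomainCorrelations(votes)
  m <- raschform:::voteMatrix(votes)
  # independent rank-then-Pearson computation
  hand <- cor(rank(m[, "motor.fine"]), rank(m[, "cognition.reasoning"]))
  expect_equal(rho["motor.fine", "cognition.reasoning"], hand)
  expect_equal(rho["motor.fine", "motor.fine"], 1)
  expect_true(is.na(rho["motor.gross", "motor.fine"])) # constant (all-zero) column
  expect_true(isSymmetric(rho))

  # a column duplicating another correlates exactly 1
  rho2 <- subdomainCorrelations(data.frame(
    item_id = rep(sprintf("i%d", 1:4), each = 2),
    subdomain = rep(c("motor.fine", "language.receptive"), 4),
    votes = rep(c(2L, 2L, 4L, 4L, 6L, 6L, 8L, 8L), 1)
  ))
  expect_equal(rho2["motor.fine", "language.receptive"], 1)
})

test_that("gross-motor-only voting yields negative correlations with the rest", {
  set.seed(36)
  n <- 60
  gm <- rbinom(n, 9, 0.5)
  other <- ifelse(gm > 4, 0L, rbinom(n, 5, 0.6)) # votes only when gross motor absent
  votes <- rbind(
    data.frame(item_id = sprintf("i%02d", 1:n), subdomain = "motor.gross", votes = gm),
    data.frame(item_id = sprintf("i%02d", 1:n), subdomain = "motor.fine", votes = other)
  )
  votes <- votes[votes$votes > 0, ]
  rho <- subdomainCorrelations(votes)
  expect_lt(rho["motor.gross", "motor.fine"], 0)
})

test_that("feasibility tabulation counts, totals and percentages are coherent", {
  flags <- data.frame(
    judge_id = sprintf("judge%02d", c(1:9, 1:3, 5)),
    item_id = c(rep("pic5", 9), rep("cup", 3), "walk"),
    criterion = c(rep("materials", 9), rep("adaptation", 3), "translation"),
    comment = "context-specific concern"
  )
  tab <- tabulateFeasibility(flags, "direct_admin")
  expect_equal(tab$items$item_id[1], "pic5") # most flagged first
  expect_equal(tab$items$total_concerns[1], 9)
  expect_equal(sum(tab$items$total_concerns), sum(tab$totals$n_comments))
  expect_equal(sum(tab$totals$n_comments), nrow(flags))
  expect_equal(tab$totals$percent[tab$totals$criterion == "materials"],
               round(100 * 9 / 13, 1))
  expect_true(all(tab$items$total_concerns ==
                    rowSums(tab$items[, feasibilityCriteria("direct_admin")])))

  empty <- tabulateFeasibility(flags[0, ], "caregiver_report")
  expect_equal(nrow(empty$items), 0)
  expect_true(all(empty$totals$n_comments == 0))

  expect_error(tabulateFeasibility(flags, "caregiver_report"), "materials")
})
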