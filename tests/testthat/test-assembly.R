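test_that("representative selection minimises concerns with documented tie-breaks", {
  bank <- tinyBank()
  groups <- data.frame(item_id = c("t01", "t02", "t03", "t04"),
                       group_id = c("g1", "g1", "g2", "g2"))
  feas <- data.frame(item_id = c("t01", "t02", "t03", "t04"),
                     total_concerns = c(0L, 2L, 1L, 1L))
  reps <- selectRepresentatives(groups, bank, feasibility = feas)
  expect_equal(reps$item_id[reps$group_id == "g1"], "t01") # fewest concerns
  # equal concerns in g2: shortest descriptor wins
  expect_equal(reps$item_id[reps$group_id == "g2"], "t03")

  # seven equally flagged variants: the shortest descriptor is retained
  circ <- ItemBank(data.frame(
    item_id = sprintf("c%d", 1:7),
    descriptor = c(strrep("describe the circle task ", 1:6), "copies a circle"),
    modality = "direct_admin", domain = "motor.fine",
    true_difficulty = 90
  ))
  g7 <- data.frame(item_id = sprintf("c%d", 1:7), group_id = "circle")
  r7 <- selectRepresentatives(g7, circ)
  expect_equal(r7$item_id, "c7")

  # singleton group returns its only member
  single <- selectRepresentatives(data.frame(item_id = "t05", group_id = "g3"), bank)
  expect_equal(single$item_id, "t05")
  expect_match(single$reason, "singleton")

  # modality filter can empty a group
  expect_warning(
    selectRepresentatives(groups[1:2, ], bank[c("t01", "t02")],
                          modality = "direct_admin") -> rm_,
    NA # t02 is direct, so no warning here
  )
  expect_warning(
    selectRepresentatives(data.frame(item_id = "t01", group_id = "gx"), bank,
                          modality = "direct_admin"),
    "skipped"
  )
})

uniformBank <- function(n, curve, modality = "caregiver_report") {
  ages <- seq(1, 35, length.out = n)
  ItemBank(data.frame(
    item_id = sprintf("u%03d", seq_len(n)),
    descriptor = "uniform probe", modality = modality,
    domain = "motor.gross",
    true_difficulty = curveMedian(curve, ages)
  ))
}

test_that("difficulty-uniform selection tracks the age grid", {
  curve <- defaultReferenceCurve()
  bank <- uniformBank(40, curve)
  form <- assembleForm(bank, "short_form", 18, curve,
                       domainTargets = c(motor = 1), passAgeMode = "median")
  prov <- provenance(form)
  step <- diff(prov$slot_age[1:2])
  expect_true(all(abs(prov$a50 - prov$slot_age) < step))
  expect_equal(length(formItems(form)), 18)
  expect_equal(nrow(attr(form, "gaps")), 0)
})

test_that("equate-group duplication is impossible by construction", {
  bank <- simulateItemBank(120, 50, seed = 50)
  ratings <- simulateJudgeMatchings(bank, 6, errorRate = 0, seed = 51)
  groups <- extractEquateGroups(aggregateMatching(ratings))
  bank <- setEquateGroups(bank, groups)
  reps <- selectRepresentatives(groups, bank, modality = "caregiver_report") |>
    suppressWarnings()
  form <- assembleForm(bank, "short_form", 25, representatives = reps)
  g <- itemData(bank)$equate_group[match(formItems(form), itemIds(bank))]
  g <- g[!is.na(g)]
  expect_false(anyDuplicated(g) > 0)
  expect_true(all(modality(bank)[formItems(form)] == "caregiver_report"))
  # provenance traces every item to a group or "ungrouped"
  expect_true(all(provenance(form)$equate_group != ""))
})

test_that("domain quotas steer selection before spilling over", {
  curve <- defaultReferenceCurve()
  ages <- rep(seq(2, 34, length.out = 10), 2)
  bank <- ItemBank(data.frame(
    item_id = sprintf("q%02d", 1:20),
    descriptor = "quota probe", modality = "caregiver_report",
    domain = rep(c("motor.gross", "language.expressive"), each = 10),
    true_difficulty = curveMedian(curve, ages)
  ))
  form <- assembleForm(bank, "short_form", 10, curve,
                       domainTargets = c(motor = 1))
  dom <- itemData(bank)$domain[match(formItems(form), itemIds(bank))]
  expect_true(all(dom == "motor.gross")) # language only if motor exhausted
})

test_that("ordering respects facility precedence with minimal adjustment", {
  # modelled difficulty says the 15-word item is easier; facility wins anyway
  dd <- c(w5 = 61, w15 = 60, other = 59)
  form <- Form(names(dd), "short_form")
  ord <- orderItems(form, dd,
                    precedence = data.frame(earlier = "w5", later = "w15"))
  expect_lt(match("w5", formItems(ord)), match("w15", formItems(ord)))
  expect_equal(formItems(ord)[1], "other") # untouched elsewhere

  # no precedence: pure difficulty order
  ord0 <- orderItems(form, dd)
  expect_equal(formItems(ord0), names(sort(dd)))

  # cyclic precedence is an error naming the cycle
  expect_error(
    orderItems(form, dd, precedence = data.frame(
      earlier = c("w5", "w15"), later = c("w15", "w5"))),
    "cyclic.*w5"
  )
})

test_that("ordering repair is Kendall-minimal on chain fixtures", {
  set.seed(52)
  for (trial in 1:20) {
    n <- sample(4:6, 1)
    ids <- letters[1:n]
    dd <- setNames(sample(100, n), ids)
    # random disjoint chains as precedence
    chain_of <- sample(1:2, n, replace = TRUE)
    pre <- do.call(rbind, lapply(split(ids, chain_of), function(ch) {
      if (length(ch) < 2) return(NULL)
      data.frame(earlier = head(ch, -1), later = tail(ch, -1))
    }))
    form <- Form(ids, "short_form")
    got <- formItems(orderItems(form, dd, precedence = pre))
    # exhaustive oracle: all linear extensions, minimal Kendall distance to
    # the difficulty sort
    ref <- names(sort(dd))
    perms <- allPerms(n)
    best <- Inf
    for (r in seq_len(nrow(perms))) {
      cand <- ids[perms[r, ]]
      ok <- is.null(pre) ||
        all(match(pre$earlier, cand) < match(pre$later, cand))
      if (ok) best <- min(best, kendallDist(cand, ref))
    }
    if (!is.null(pre)) {
      expect_true(all(match(pre$earlier, got) < match(pre$later, got)))
    }
    expect_equal(kendallDist(got, ref), best)
  }
})

test_that("string breaking removes long same-domain runs and is idempotent", {
  doms <- c(l1 = "language", m1 = "motor", m2 = "motor", m3 = "motor",
            m4 = "motor", m5 = "motor", l2 = "language")
  form <- Form(names(doms), "short_form")
  out <- breakStrings(form, doms)
  rl <- rle(unname(doms[formItems(out)]))
  expect_true(all(rl$lengths <= 3))
  expect_setequal(formItems(out), names(doms))
  moves <- attr(out, "moves")
  expect_gt(nrow(moves), 0)

  # idempotence
  again <- breakStrings(out, doms)
  expect_identical(formItems(again), formItems(out))
  expect_equal(nrow(attr(again, "moves")), 0)

  # nothing to break: identity
  ok_form <- Form(c("a", "b", "c", "d"), "short_form")
  ok_dom <- c(a = "motor", b = "language", c = "motor", d = "language")
  expect_identical(formItems(breakStrings(ok_form, ok_dom)), c("a", "b", "c", "d"))

  # single-domain forms cannot be broken
  expect_error(breakStrings(Form(c("a", "b"), "short_form"),
                            c(a = "motor", b = "motor")),
               "single domain")
})

test_that("string breaking on assembled forms leaves no run over the cap", {
  curve <- defaultReferenceCurve()
  for (seed in c(53, 54)) {
    bank <- simulateItemBank(150, 90, seed = seed)
    form <- assembleForm(bank, "short_form", 40, curve)
    it <- itemData(bank)
    doms <- setNames(sub("\\..*", "", it$domain), it$item_id)
    form <- orderItems(form, difficulties(bank))
    broken <- breakStrings(form, doms)
    expect_true(all(rle(unname(doms[formItems(broken)]))$lengths <= 3))
  }
})

test_that("long-form partition groups materials and balances sizes", {
  # 3 materials x 3 items: each material's items land in a single group
  bank9 <- ItemBank(data.frame(
    item_id = sprintf("p%d", 1:9),
    descriptor = "partition probe", modality = "direct_admin",
    domain = "motor.fine",
    true_difficulty = seq(40, 80, length.out = 9),
    material_tag = rep(c("block", "cup", "ball"), each = 3),
    energy_level = "seated"
  ))
  form9 <- partitionLongForm(Form(sprintf("p%d", 1:9), "long_form"), bank9)
  grp <- formGroups(form9)
  mat <- setNames(itemData(bank9)$material_tag, itemIds(bank9))
  per_mat <- tapply(grp, mat[names(grp)], function(g) length(unique(g)))
  expect_true(all(per_mat == 1))
  expect_lte(diff(range(table(grp))), 5)

  # exhaustive oracle on the 9-item fixture: our cost equals the optimum
  cost <- function(assign) {
    sum(sapply(split(names(assign), assign), function(ids) {
      length(unique(mat[ids])) + (length(unique("seated")) - 1)
    }))
  }
  expect_equal(cost(grp), 3) # one material per group is the attainable minimum

  # 157 directly administered items: sizes within the balance tolerance
  big <- simulateItemBank(157, 157, seed = 55)
  it <- itemData(big)
  it$modality <- "direct_admin"
  big <- ItemBank(it)
  ord <- itemIds(big)[order(difficulties(big))]
  f157 <- partitionLongForm(Form(ord, "long_form"), big)
  sizes <- table(formGroups(f157))
  expect_equal(sum(sizes), 157)
  expect_lte(diff(range(sizes)), 5)

  # degenerate objective: single material, all active
  flat <- ItemBank(data.frame(
    item_id = sprintf("f%d", 1:12), descriptor = "x", modality = "direct_admin",
    domain = "motor.gross", true_difficulty = 1:12,
    material_tag = "none", energy_level = "active"
  ))
  fflat <- partitionLongForm(Form(sprintf("f%d", 1:12), "long_form"), flat)
  expect_lte(diff(range(table(formGroups(fflat)))), 5)

  expect_error(partitionLongForm(Form("a", "short_form"), bank9), "long form")
})

test_that("start rules find the deepest safe entry point", {
  # constructed responses: 3 items, children at one bracket's lower edge
  X <- rbind(
    i1 = rep(1, 100),
    i2 = c(rep(1, 89), rep(0, 11)), # 89% pass: below threshold
    i3 = rep(1, 100)
  )
  colnames(X) <- sprintf("c%d", 1:100)
  rs <- ResponseSet(X, age = rep(6.2, 100))
  form <- Form(c("i1", "i2", "i3"), "short_form")
  sr <- startRule(deriveStartRules(form, rs, ageRange = c(6, 12)))
  expect_equal(sr$start_index, 1L) # i2 at 0.89 blocks the prefix

  X2 <- X
  X2["i2", ] <- c(rep(1, 90), rep(0, 10)) # exactly 90%: eligible
  rs2 <- ResponseSet(X2, age = rep(6.2, 100))
  sr2 <- startRule(deriveStartRules(form, rs2, ageRange = c(6, 12)))
  expect_equal(sr2$start_index, 3L)
})

test_that("derived start rules match the analytic prediction on noiseless data", {
  curve <- ReferenceCurve(seq(0, 36, 0.5), 20 * log2(seq(0, 36, 0.5) + 1) + 10, 0.01)
  delta <- curveMedian(curve, seq(2, 34, length.out = 12)) # well-separated items
  bank <- ItemBank(data.frame(
    item_id = sprintf("s%02d", 1:12), descriptor = "start probe",
    modality = "caregiver_report", domain = "motor.gross",
    true_difficulty = delta
  ))
  lowers <- seq(0, 30, by = 6)
  ages <- rep(lowers + 0.05, each = 400)
  rs <- simulateResponses(bank, curve, nChildren = length(ages), ages = ages, seed = 56)
  form <- Form(itemIds(bank), "short_form")
  sr <- startRule(deriveStartRules(form, rs))
  analytic <- vapply(lowers, function(lo) {
    ok <- plogis(curveMedian(curve, lo) - delta) >= 0.9
    m <- match(FALSE, ok, nomatch = length(ok) + 1L) - 1L
    max(1L, m)
  }, integer(1))
  expect_equal(sr$start_index, cummax(analytic))
  expect_true(all(diff(sr$start_index) >= 0))

  # a very easy first item alone keeps the earliest bracket at position one
  expect_gte(sr$start_index[1], 1L)
})

test_that("the stop rule fires at the k-th contiguous failure", {
  expect_equal(stopRuleCheck(c(1, 1, 0, 0, 0, 0, 0)), 7L)
  expect_true(is.na(stopRuleCheck(rep(1, 10))))
  expect_equal(stopRuleCheck(c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0)), 10L)

  # exhaustive agreement with a brute-force window scan, all strings <= 12
  for (len in 1:12) {
    grid <- as.matrix(expand.grid(rep(list(0:1), len)))
    got <- apply(grid, 1, stopRuleCheck, k = 5L)
    want <- apply(grid, 1, bruteStop, k = 5L)
    expect_identical(got, want)
  }
  # other run lengths
  expect_equal(stopRuleCheck(c(1, 0, 0, 1), k = 2L), 3L)
})
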