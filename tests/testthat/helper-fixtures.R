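suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# Small hand-built bank: two multi-item concepts plus singletons, both
# modalities, difficulties on the D-score scale.
tinyBank <- function() {
  ItemBank(data.frame(
    item_id = sprintf("t%02d", 1:8),
    descriptor = c(
      "walks with support", "walks without support",
      "says one word", "says ten words",
      "stacks two blocks", "draws a circle when shown one",
      "waves bye-bye", "drinks from a cup"
    ),
    instrument = rep(c("bankA", "bankB"), 4),
    modality = c(
      "caregiver_report", "direct_admin",
      "caregiver_report", "caregiver_report",
      "direct_admin", "direct_admin",
      "caregiver_report", "direct_admin"
    ),
    domain = c(
      "motor.gross", "motor.gross",
      "language.expressive", "language.expressive",
      "motor.fine", "motor.fine",
      "socioemotional", "adaptive.life_skills"
    ),
    true_difficulty = c(40, 55, 50, 70, 62, 95, 48, 66),
    latent_concept_id = c(1, 1, 2, 2, 3, 4, 5, 6),
    facility_rank = c(1, 2, 1, 2, 1, 1, 1, 1),
    material_tag = c("none", "none", "none", "none", "block", "pencil_paper",
                     "none", "cup"),
    energy_level = c("active", "active", "seated", "seated", "seated",
                     "seated", "seated", "seated"),
    stringsAsFactors = FALSE
  ))
}

# Rating-table builder: one row per judge for a single pair.
makeRatings <- function(levels, item_a = "A", item_b = "B", pass = 1L) {
  data.frame(
    judge_id = sprintf("judge%02d", seq_along(levels)),
    item_a = item_a, item_b = item_b,
    level = levels, pass_number = pass,
    stringsAsFactors = FALSE
  )
}

# Brute-force transitive closure over threshold edges: repeatedly merge sets
# sharing a member.  Independent of the igraph-based implementation.
bruteGroups <- function(coefficients, threshold = 2 / 3) {
  edges <- coefficients[coefficients$value >= threshold - 1e-9, , drop = FALSE]
  sets <- lapply(seq_len(nrow(edges)), function(i) c(edges$item_a[i], edges$item_b[i]))
  changed <- TRUE
  while (changed && length(sets) > 1L) {
    changed <- FALSE
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (j <= i) next
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- character(0)
          changed <- TRUE
        }
      }
    }
    sets <- Filter(length, sets)
  }
  lapply(sets, sort)
}

# Canonical representation of a partition (set of sorted member vectors) for
# comparing groupings irrespective of labels.
canonicalPartition <- function(groups_df) {
  if (nrow(groups_df) == 0L) return(character(0))
  parts <- split(groups_df$item_id, groups_df$group_id)
  unname(sort(vapply(parts, function(p) paste(sort(p), collapse = "+"), character(1))))
}

# Adjusted Rand index by brute-force pair counting.
adjustedRand <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  same_a <- outer(labels_a, labels_a, "==")[upper.tri(diag(n))]
  same_b <- outer(labels_b, labels_b, "==")[upper.tri(diag(n))]
  a <- sum(same_a & same_b); b <- sum(same_a & !same_b)
  c <- sum(!same_a & same_b); d <- sum(!same_a & !same_b)
  tot <- a + b + c + d
  exp_idx <- (a + b) * (a + c) / tot
  max_idx <- ((a + b) + (a + c)) / 2
  (a - exp_idx) / (max_idx - exp_idx)
}

# Brute-force stop-rule scan over every window.
bruteStop <- function(x, k = 5L) {
  if (length(x) < k) return(NA_integer_)
  for (i in k:length(x)) {
    if (all(x[(i - k + 1L):i] == 0)) return(i)
  }
  NA_integer_
}

# Kendall (adjacent-transposition) distance between two orderings of the same
# ids.
kendallDist <- function(ord, ref) {
  pos <- match(ord, ref)
  inv <- 0L
  for (i in seq_along(pos)) {
    inv <- inv + sum(pos[seq_len(i - 1L)] > pos[i])
  }
  inv
}

# All permutations of 1..n (n <= 7 in tests).
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  out
}

linearCurve <- function(sigma = 1e-6) {
  ReferenceCurve(seq(0, 40, by = 1), seq(0, 40, by = 1), sigma)
}
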