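make_universe_df <- function(n) {
  data.frame(sender_type = "S", receiver_type = "R",
             ligand = paste0("L", seq_len(n)), receptor = paste0("R", seq_len(n)),
             stringsAsFactors = FALSE)
}

test_that("confusion counts match set algebra on simple constructed cases", {
  uni <- make_universe_df(10)
  pos <- uni[1:3, ]
  pos$label <- "positive"
  pos$mode <- "proximal"
  truth <- truth_set(pos, uni)
  # perfect caller
  calls <- interaction_call_set(cbind(uni[1:3, ], p_value = 0.001), "perfect")
  cc <- confusion_counts(calls, truth)
  expect_equal(unclass(cc)[c("TP", "FP", "FN", "TN")],
               list(TP = 3L, FP = 0L, FN = 0L, TN = 7L))
  # null caller
  null <- interaction_call_set(cbind(uni[0, ], p_value = numeric(0)), "null")
  cc0 <- confusion_counts(null, truth)
  expect_equal(unclass(cc0)[c("TP", "FP", "FN", "TN")],
               list(TP = 0L, FP = 0L, FN = 3L, TN = 7L))
  # strict threshold: p exactly at alpha is not called
  edge <- interaction_call_set(cbind(uni[1:2, ], p_value = c(0.05, 0.049)),
                               "edge")
  expect_equal(confusion_counts(edge, truth, alpha = 0.05)$TP, 1L)
  # calls outside the universe are dropped and reported
  out <- rbind(uni[1, ], data.frame(sender_type = "Z", receiver_type = "Z",
                                    ligand = "LX", receptor = "RX"))
  oc <- confusion_counts(interaction_call_set(cbind(out, p_value = 0.01), "o"),
                         truth)
  expect_equal(attr(oc, "n_dropped"), 1L)
  expect_equal(oc$TP, 1L)
})

test_that("confusion counts equal the exhaustive oracle on random instances", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    uni <- make_universe_df(n)
    npos <- sample(0:n, 1)
    pos <- uni[seq_len(npos), , drop = FALSE]
    if (npos) { pos$label <- "positive"; pos$mode <- "proximal" }
    truth <- truth_set(pos, uni)
    ncall <- sample(0:n, 1)
    idx <- sample(n, ncall)
    calls_df <- cbind(uni[idx, , drop = FALSE],
                      p_value = runif(ncall, 0, 0.2))
    cc <- confusion_counts(interaction_call_set(calls_df, "m"), truth,
                           alpha = 0.1)
    called_keys <- with(calls_df[calls_df$p_value < 0.1, , drop = FALSE],
                        paste(sender_type, receiver_type, ligand, receptor))
    pos_keys <- if (npos) with(pos, paste(sender_type, receiver_type,
                                          ligand, receptor)) else character(0)
    uni_keys <- with(uni, paste(sender_type, receiver_type, ligand, receptor))
    orc <- oracle_confusion(called_keys, pos_keys, uni_keys)
    expect_identical(unclass(cc)[c("TP", "FP", "FN", "TN")], orc)
    expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, n)
  }
})

test_that("rank-fraction thresholding supports score-only callers", {
  uni <- make_universe_df(5)
  pos <- uni[1:2, ]; pos$label <- "positive"; pos$mode <- "proximal"
  truth <- truth_set(pos, uni)
  calls <- interaction_call_set(
    cbind(uni[1:4, ], score = c(9, 7, 2, 1),
          rank_fraction = c(0.1, 0.2, 0.5, 0.9)), "ranked")
  cc <- confusion_counts(calls, truth, alpha = 0.2, use = "rank")
  expect_equal(cc$TP, 2L)   # top 20% inclusive cutoff
  expect_equal(cc$FP, 0L)
  bad <- interaction_call_set(cbind(uni[1:2, ], score = c(1, 2)), "s")
  expect_error(confusion_counts(bad, truth), "neither")
})

test_that("precision/recall/F1/specificity follow their definitions", {
  m <- prf_metrics(list(TP = 2, FP = 1, FN = 1, TN = 6))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
  expect_length(m$degenerate_flags, 0)
  # degenerate zero-denominator cases flag and return 0
  z <- prf_metrics(list(TP = 0, FP = 0, FN = 3, TN = 7))
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
  expect_true(all(c("precision", "f1") %in% z$degenerate_flags))
  one <- prf_metrics(list(TP = 1, FP = 0, FN = 0, TN = 0))
  expect_equal(c(one$precision, one$recall, one$f1), c(1, 1, 1))
  expect_true("specificity" %in% one$degenerate_flags)
})

test_that("prf is monotone in the expected directions", {
  set.seed(3)
  for (i in 1:50) {
    cc <- as.list(setNames(sample(0:20, 4, replace = TRUE),
                           c("TP", "FP", "FN", "TN")))
    base <- prf_metrics(cc)
    if (cc$FN > 0) {
      up <- prf_metrics(modifyList(cc, list(TP = cc$TP + 1, FN = cc$FN - 1)))
      expect_gte(up$recall, base$recall)
    }
    if (cc$TN > 0) {
      fp <- prf_metrics(modifyList(cc, list(FP = cc$FP + 1, TN = cc$TN - 1)))
      expect_lte(fp$precision, base$precision)
    }
  }
})

test_that("score normalization implements per-scenario min-max and mean summary", {
  tab <- rbind(m1 = c(0.2, 0.3), m2 = c(0.5, 0.3), m3 = c(0.5, 0.3))
  res <- normalize_scores(tab)
  expect_equal(unname(res$normalized[, 1]), c(0, 1, 1))
  expect_equal(unname(res$normalized[, 2]), c(1, 1, 1))  # all-equal column
  expect_equal(res$summary[["m1"]], 0.5)
  expect_error(normalize_scores(tab[1, , drop = FALSE]), "two methods")
  # random table vs hand-computed min-max
  set.seed(5)
  r <- matrix(runif(9), 3, 3)
  nr <- normalize_scores(r)$normalized
  for (j in 1:3)
    expect_equal(nr[, j], (r[, j] - min(r[, j])) / diff(range(r[, j])))
  # max-scaling variant
  mx <- normalize_scores(r, scheme = "max")$normalized
  for (j in 1:3) expect_equal(mx[, j], r[, j] / max(r[, j]))
  expect_equal(unname(normalize_scores(tab, percent = TRUE)$normalized[2, 1]),
               100)
})

test_that("jaccard index and its mean satisfy the set definitions", {
  expect_equal(jaccard_index(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(as.numeric(jaccard_index(c("a"), c("a"))), 1)
  expect_equal(as.numeric(jaccard_index(c("a"), c("b"))), 0)
  ee <- jaccard_index(character(0), character(0))
  expect_equal(as.numeric(ee), 0)
  expect_true(attr(ee, "degenerate"))
  # symmetry and boundedness on random sets
  set.seed(8)
  for (i in 1:100) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    j1 <- as.numeric(jaccard_index(a, b))
    expect_equal(j1, as.numeric(jaccard_index(b, a)))
    expect_gte(j1, 0); expect_lte(j1, 1)
    orc <- if (!length(union(a, b))) 0 else
      length(intersect(a, b)) / length(union(a, b))
    expect_equal(j1, orc)
  }
  # mean over pairs: {a,b},{b,c},{b} -> (1/3 + 1/2 + 1/2) / 3
  expect_equal(mean_jaccard(list(c("a", "b"), c("b", "c"), "b")),
               (1/3 + 1/2 + 1/2) / 3)
  # data.frame tuple interface
  df1 <- make_universe_df(3); df2 <- make_universe_df(4)
  expect_equal(as.numeric(jaccard_index(df1, df2)), 3 / 4)
})

test_that("distance ranks order type pairs by mean cross-type distance", {
  # three clusters on a line at 0, 1, 5
  coords <- rbind(cbind(rnorm(20, 0, 0.01), 0), cbind(rnorm(20, 1, 0.01), 0),
                  cbind(rnorm(20, 5, 0.01), 0))
  map <- cell_map(coords, rep(c("A", "B", "C"), each = 20))
  calls <- interaction_call_set(data.frame(
    ligand = "L", receptor = "R", sender_type = c("A", "A"),
    receiver_type = c("B", "C"), p_value = 0.01), "m")
  prof <- distance_rank_profile(map, calls, seed = 1)
  pr <- prof$pair_ranks
  rank_ab <- pr$rank[pr$sender_type == "A" & pr$receiver_type == "B"]
  rank_ac <- pr$rank[pr$sender_type == "A" & pr$receiver_type == "C"]
  expect_lt(rank_ab, rank_ac)
  expect_equal(prof$call_ranks$rank, c(rank_ab, rank_ac))
  # two types only: both ordered pairs share rank 1
  map2 <- cell_map(coords[1:40, ], rep(c("A", "B"), each = 20))
  calls2 <- interaction_call_set(data.frame(
    ligand = "L", receptor = "R", sender_type = "A", receiver_type = "B",
    p_value = 0.01), "m")
  pr2 <- distance_rank_profile(map2, calls2)$pair_ranks
  expect_equal(pr2$rank, c(1L, 1L))
  expect_error(distance_rank_profile(map2, calls), "absent")
})

test_that("inactive subsample cap reproduces the exhaustive computation", {
  set.seed(13)
  coords <- matrix(runif(60), 30, 2)
  types <- rep(c("A", "B", "C"), each = 10)
  map <- cell_map(coords, types)
  calls <- interaction_call_set(data.frame(
    ligand = "L", receptor = "R", sender_type = "A", receiver_type = "B",
    p_value = 0.01), "m")
  full <- distance_rank_profile(map, calls, subsample_cap = 1000)$pair_ranks
  # independent loop-based oracle for the mean cross-type distance
  for (r in seq_len(nrow(full))) {
    a <- which(types == full$sender_type[r])
    b <- which(types == full$receiver_type[r])
    tot <- 0
    for (i in a) for (j in b)
      tot <- tot + sqrt(sum((coords[i, ] - coords[j, ])^2))
    expect_equal(full$proximity[r], tot / (length(a) * length(b)))
  }
})

test_that("rank profile is invariant to translation, rotation and scaling", {
  set.seed(17)
  coords <- matrix(runif(80), 40, 2)
  types <- rep(c("A", "B", "C", "D"), each = 10)
  calls <- interaction_call_set(data.frame(
    ligand = "L", receptor = "R", sender_type = "A", receiver_type = "C",
    p_value = 0.01), "m")
  base <- distance_rank_profile(cell_map(coords, types), calls)$pair_ranks
  th <- 0.7
  rot <- coords %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- sweep(rot * 3.5, 2, c(10, -4), "+")
  trans <- distance_rank_profile(cell_map(moved, types), calls)$pair_ranks
  expect_equal(base$rank, trans$rank)
})
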