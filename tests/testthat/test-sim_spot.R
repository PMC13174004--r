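test_that("default hex scaffold has 782 spots with hexagonal adjacency", {
  sc <- build_scaffold()
  expect_equal(nrow(sc$coordinates), 782L)
  deg <- lengths(sc$adjacency)
  # interior spots have exactly 6 neighbors, corners 2 or 3
  interior <- sc$coordinates[, 1] > 2 & sc$coordinates[, 1] < 32 &
    sc$coordinates[, 2] > 2 & sc$coordinates[, 2] < 17
  expect_true(all(deg[interior] == 6))
  corner <- which(sc$coordinates[, 1] == 0 & sc$coordinates[, 2] == 0)
  expect_true(deg[corner] %in% c(2L, 3L))
  # adjacency is symmetric with no self loops
  for (i in sample(782, 30)) {
    expect_false(i %in% sc$adjacency[[i]])
    for (j in sc$adjacency[[i]]) expect_true(i %in% sc$adjacency[[j]])
  }
})

test_that("scaffold accepts coordinates, rejects duplicates, handles one spot", {
  one <- build_scaffold(coordinates = cbind(0, 0))
  expect_equal(one$adjacency[[1]], integer(0))
  expect_error(build_scaffold(coordinates = rbind(c(0, 0), c(0, 0))),
               "duplicate")
  path <- write_tsv_tmp(data.frame(x = c(0, 1, 2), y = 0))
  sc <- build_scaffold(coordinates = path)
  expect_equal(sc$adjacency[[2]], c(1L, 3L))
})

test_that("central region has the requested size and a valid adjacent ring", {
  sc <- build_scaffold()
  reg <- select_central_region(sc, 130)
  expect_equal(length(reg$central), 130L)
  expect_length(intersect(reg$central, reg$adjacent), 0L)
  # every adjacent spot borders the region; no excluded spot does
  in_central <- seq_len(782) %in% reg$central
  borders <- vapply(seq_len(782), function(i)
    any(in_central[sc$adjacency[[i]]]), logical(1))
  expect_setequal(reg$adjacent, which(borders & !in_central))
  # central spots are the nearest to the centroid
  ctr <- colMeans(sc$coordinates)
  d <- sqrt(rowSums(sweep(sc$coordinates, 2, ctr)^2))
  expect_lte(max(d[reg$central]), min(d[-reg$central]) + 1e-9)
  expect_error(select_central_region(sc, 782), "smaller")
})

test_that("spot compositions sum to 12 cells and match proportions in bulk", {
  sc <- build_scaffold(rows = 10, cols = 10)
  comp <- compose_spots(sc, spot_default_proportions(), seed = 6)
  expect_true(all(rowSums(comp$counts) == 12))
  expect_equal(ncol(comp$counts), 7L)
  # pooled frequencies within 3 SEs of the generating proportions
  tot <- colSums(comp$counts)
  n <- sum(tot)
  p <- spot_default_proportions()[colnames(comp$counts)]
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(tot / n - p) < 3.5 * se))
})

test_that("purity regimes enforce their strict 0.8 bounds in the region", {
  sc <- build_scaffold(rows = 8, cols = 8)
  region <- 1:20
  high <- compose_spots(sc, spot_default_proportions(), purity_regime = "high",
                        region = region, dominant_type = "ductal", seed = 2)
  expect_true(all(high$counts[region, "ductal"] >= 10))
  expect_true(all(high$purity[region] > 0.8))
  expect_true(all(high$dominant_type[region] == "ductal"))
  mixed <- compose_spots(sc, spot_default_proportions(),
                         purity_regime = "mixed", region = region, seed = 2)
  expect_true(all(mixed$purity[region] < 0.8))
})

test_that("cell-level embedding arithmetic and spot aggregation are exact", {
  # one spot with 4 sender cells, baseline ligand counts {1,2,0,1}, fold 5
  genes <- c("LIG", "REC", "BG")
  cellm <- matrix(0L, 6, 3, dimnames = list(NULL, genes))
  cellm[, "LIG"] <- c(1L, 2L, 0L, 1L, 3L, 3L)
  cellm[, "BG"] <- 2L
  spot_of <- c(1L, 1L, 1L, 1L, 2L, 2L)
  type_of <- c("S", "S", "S", "S", "S", "X")
  pairs <- data.frame(ligand = "LIG", receptor = "REC")
  emb <- ccibench:::embed_spot_cells(cellm, spot_of, type_of,
                                     central = 1L, adjacent = integer(0),
                                     pairs, "S", "R", fold = 5)
  agg <- ccibench:::aggregate_spots(emb, spot_of, 2L)
  expect_equal(unname(agg[1, "LIG"]), 5L + 10L + 0L + 5L)
  expect_equal(unname(agg[1, "BG"]), 8L)   # untouched gene = plain sum
  expect_equal(unname(agg[2, "LIG"]), 6L)  # peripheral spot untouched
})

test_that("peripheral spot rows are invariant to the embedding fold", {
  sc <- build_scaffold(rows = 8, cols = 10)
  reg <- select_central_region(sc, 12)
  comp <- compose_spots(sc, spot_default_proportions(), seed = 14)
  m1 <- simulate_and_embed_spot(fix_models, comp, reg$central, reg$adjacent,
                                fix_pairs, "beta", "ductal", fold = 5,
                                seed = 77)
  m2 <- simulate_and_embed_spot(fix_models, comp, reg$central, reg$adjacent,
                                fix_pairs, "beta", "ductal", fold = 15,
                                seed = 77)
  periph <- setdiff(seq_len(80), c(reg$central, reg$adjacent))
  expect_identical(m1[periph, ], m2[periph, ])
  expect_false(identical(m1[reg$central, ], m2[reg$central, ]))
})

test_that("aggregation conserves column sums of the cell-level matrix", {
  sc <- build_scaffold(rows = 5, cols = 6)
  comp <- compose_spots(sc, spot_default_proportions(), seed = 4)
  roster <- ccibench:::expand_roster(comp)
  cells <- sample_counts(fix_models, roster$type_of, seed = 8)
  agg <- ccibench:::aggregate_spots(cells, roster$spot_of, 30L)
  expect_equal(colSums(agg), colSums(cells))
})

test_that("quantile truth labeling follows the constructed toy exactly", {
  # 10 spots: central {1,2}, adjacent {3,4}; LIG central mean 8 vs global
  # median 3; REC adjacent mean 6 vs global median 2 -> positive at q = 0.5
  m <- cbind(LIG = c(8, 8, 3, 3, 3, 3, 2, 4, 3, 3),
             REC = c(2, 2, 6, 6, 2, 2, 1, 2, 3, 2))
  pairs <- data.frame(ligand = "LIG", receptor = "REC")
  t50 <- label_spot_truth(m, central = 1:2, adjacent = 3:4, pairs,
                          "S", "R", q = 0.5, types = c("S", "R"))
  expect_equal(t50$interactions$label, "positive")
  # at q = 0.75 the ligand threshold rises above the central mean
  m2 <- m; m2[5:10, "LIG"] <- c(9, 9, 9, 9, 9, 9)
  t75 <- label_spot_truth(m2, 1:2, 3:4, pairs, "S", "R", q = 0.75,
                          types = c("S", "R"))
  expect_equal(t75$interactions$label, "negative")
  # all-zero global expression: quantile 0, any positive central mean passes
  m3 <- cbind(LIG = c(1, 1, rep(0, 8)), REC = c(0, 0, 1, 1, rep(0, 6)))
  t0 <- label_spot_truth(m3, 1:2, 3:4, pairs, "S", "R", q = 0.25,
                         types = c("S", "R"))
  expect_equal(t0$interactions$label, "positive")
  expect_warning(
    label_spot_truth(m, 1:2, integer(0), pairs, "S", "R", q = 0.5,
                     types = c("S", "R")), "adjacent")
})

test_that("default spot scenario: 782 spots, 7 types, 12 cells, reproducible", {
  b <- simulate_spot_dataset(fix_models, fix_pairs, "beta", "ductal", seed = 3)
  expect_equal(nrow(b$counts), 782L)
  expect_equal(ncol(b$composition$counts), 7L)
  expect_true(all(rowSums(b$composition$counts) == 12))
  expect_equal(length(b$regions$central), 130L)
  b2 <- simulate_spot_dataset(fix_models, fix_pairs, "beta", "ductal",
                              seed = 3)
  expect_identical(b$counts, b2$counts)
  expect_identical(b$truth$interactions, b2$truth$interactions)
  expect_equal(nrow(b$truth$universe), 49L * nrow(fix_pairs))
})

test_that("raising the truth quantile never flips negatives to positive", {
  sc <- build_scaffold(rows = 8, cols = 10)
  reg <- select_central_region(sc, 12)
  comp <- compose_spots(sc, spot_default_proportions(), seed = 21)
  m <- simulate_and_embed_spot(fix_models, comp, reg$central, reg$adjacent,
                               fix_pairs, "beta", "ductal", fold = 5,
                               seed = 21)
  labels <- lapply(c(0.25, 0.5, 0.75), function(q)
    label_spot_truth(m, reg$central, reg$adjacent, fix_pairs, "beta",
                     "ductal", q = q,
                     types = names(spot_default_proportions()))$
      interactions$label)
  pos <- lapply(labels, function(l) l == "positive")
  expect_true(all(pos[[2]] <= pos[[1]]))
  expect_true(all(pos[[3]] <= pos[[2]]))
})
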