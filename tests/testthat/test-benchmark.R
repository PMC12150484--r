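make_grid_fixture <- function(xy, types = NULL) {
  n <- nrow(xy)
  ids <- sprintf("c%02d", seq_len(n))
  coords <- cbind(x = xy[, 1], y = xy[, 2])
  rownames(coords) <- ids
  if (is.null(types)) types <- rep("a", n)
  expr <- rand_counts(5, n, seed = 99)
  colnames(expr) <- ids
  list(coords = coords, labels = setNames(types, ids), expr = expr)
}

test_that("grid assignment follows floor(coord/g) half-open binning", {
  # boundary lattice: exact multiples of g, just-below values, negatives
  xy <- rbind(c(250, 130), c(100, 0), c(99.999, 0), c(0, 0),
              c(-1, -1), c(-100, 50), c(200, 200), c(199.999, 199.999))
  fx <- make_grid_fixture(xy)
  ps <- gridify(fx$coords, fx$labels, fx$expr, grid_size = 100)
  got <- vapply(rownames(fx$coords), function(id) {
    names(Filter(function(m) id %in% m, ps$members))
  }, character(1))
  expect_equal(unname(got),
               c("1_2", "0_1", "0_0", "0_0", "-1_-1", "0_-1", "2_2", "1_1"))
})

test_that("pseudo-bulk is the member mean and truth the modal type", {
  xy <- rbind(c(10, 10), c(20, 20), c(30, 30), c(150, 10))
  fx <- make_grid_fixture(xy, types = c("b", "a", "b", "a"))
  fx$expr[, 1] <- c(2, 4, 0, 1, 3)
  fx$expr[, 2] <- c(4, 8, 2, 1, 3)
  fx$expr[, 3] <- c(3, 6, 1, 1, 3)
  ps <- gridify(fx$coords, fx$labels, fx$expr, grid_size = 100)
  expect_equal(ps$pseudo_bulk[1:2, "0_0"], c(g1 = 3, g2 = 6))
  expect_equal(ps$spots$truth_label[ps$spots$spot_id == "0_0"], "b")
  expect_equal(ps$spots$member_count, c(3L, 1L))
  expect_equal(ps$spots$centroid_x[1], 20)
  # modal tie resolves lexicographically
  fx2 <- make_grid_fixture(rbind(c(1, 1), c(2, 2)), types = c("b", "a"))
  ps2 <- gridify(fx2$coords, fx2$labels, fx2$expr, grid_size = 100)
  expect_equal(ps2$spots$truth_label, "a")
})

test_that("gridify conserves cells across kept and dropped grids", {
  tis <- generate_tissue(tissue_config(n_cells = 300, n_genes = 20, seed = 5))
  for (mc in c(1, 3)) {
    ps <- gridify(tis$coords, tis$type_label, tis$expr, grid_size = 150,
                  min_cells = mc)
    expect_equal(sum(ps$spots$member_count) + ps$n_dropped_cells, 300)
    expect_true(all(ps$spots$member_count >= mc))
  }
  bad <- tis$type_label[-1]
  expect_error(gridify(tis$coords, bad, tis$expr, 150), names(tis$type_label)[1])
})

test_that("downsampling is seeded, order-preserving and uniform", {
  m <- rand_counts(4, 10, seed = 1)
  expect_identical(downsample(m, 12, seed = 1), m)
  s1 <- downsample(m, 4, seed = 9)
  expect_identical(s1, downsample(m, 4, seed = 9))
  expect_equal(ncol(s1), 4)
  expect_identical(colnames(s1), sort(colnames(s1)))  # original order kept
  m3 <- m[, 1:3]
  picks <- vapply(1:3000, function(s) colnames(downsample(m3, 1, seed = s)),
                  character(1))
  freq <- table(picks) / 3000
  expect_true(all(abs(freq - 1/3) < 0.05))
})

# independent metric oracle: explicit loops and pair counting
oracle_metrics <- function(pred, truth) {
  classes <- sort(unique(truth))
  sens <- spec <- f1 <- numeric(0)
  for (cl in classes) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(truth)) {
      if (pred[i] == cl && truth[i] == cl) tp <- tp + 1
      if (pred[i] == cl && truth[i] != cl) fp <- fp + 1
      if (pred[i] != cl && truth[i] == cl) fn <- fn + 1
      if (pred[i] != cl && truth[i] != cl) tn <- tn + 1
    }
    sens <- c(sens, if (tp + fn > 0) tp / (tp + fn) else NA)
    spec <- c(spec, if (tn + fp > 0) tn / (tn + fp) else NA)
    f1 <- c(f1, if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA)
  }
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_along(truth)) for (j in seq_along(truth)) {
    if (i < j) {
      sp <- pred[i] == pred[j]; st <- truth[i] == truth[j]
      if (sp && st) n11 <- n11 + 1
      if (sp && !st) n10 <- n10 + 1
      if (!sp && st) n01 <- n01 + 1
      if (!sp && !st) n00 <- n00 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  ari <- if (den == 0) as.numeric(n10 + n01 == 0) else
    2 * (n11 * n00 - n10 * n01) / den
  list(acc = mean(pred == truth), f1_macro = mean(f1, na.rm = TRUE),
       sensitivity_macro = mean(sens, na.rm = TRUE),
       specificity_macro = mean(spec, na.rm = TRUE), ari = ari)
}

test_that("metric battery matches the brute-force oracle on exhaustive labelings", {
  n <- 5
  spots <- paste0("s", 1:n)
  labelings <- expand.grid(rep(list(c("a", "b")), n), stringsAsFactors = FALSE)
  for (ti in seq_len(nrow(labelings))) {
    truth <- setNames(unlist(labelings[ti, ]), spots)
    for (pi in seq(1, nrow(labelings), by = 7)) {
      pred <- setNames(unlist(labelings[pi, ]), spots)
      got <- classification_metrics(pred, truth)
      want <- oracle_metrics(pred, truth)
      for (f in names(want)) expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
    }
  }
})

test_that("unassigned predictions count as wrong without forming a class", {
  truth <- c(s1 = "a", s2 = "a", s3 = "b", s4 = "b")
  pred <- c(s1 = "a", s2 = "unassigned", s3 = "b", s4 = "unassigned")
  m <- classification_metrics(pred, truth)
  expect_equal(m$acc, 0.5)
  expect_equal(sort(m$per_class$class), c("a", "b"))
  o <- oracle_metrics(pred, truth)
  expect_equal(m$f1_macro, o$f1_macro)
  expect_equal(m$sensitivity_macro, o$sensitivity_macro)
  expect_error(classification_metrics(pred[-1], truth), "differ")
})

test_that("perfect agreement scores 1 on every metric; constant prediction has ARI 0", {
  truth <- c(s1 = "a", s2 = "b", s3 = "a", s4 = "b")
  m <- classification_metrics(truth, truth)
  expect_equal(unlist(m[c("acc", "f1_macro", "sensitivity_macro",
                          "specificity_macro", "ari")]),
               c(acc = 1, f1_macro = 1, sensitivity_macro = 1,
                 specificity_macro = 1, ari = 1))
  const <- setNames(rep("a", 4), names(truth))
  expect_equal(classification_metrics(const, truth)$ari, 0)
})

test_that("adjusted Rand index is symmetric, rename-invariant, and matches mclust", {
  a <- c("x", "x", "y", "z", "z", "y", "x")
  b <- c("1", "2", "2", "1", "1", "2", "1")
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  renamed <- c(x = "q", y = "r", z = "s")[a]
  expect_equal(adjusted_rand_index(renamed, b), adjusted_rand_index(a, b))
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
})

test_that("pcc summary follows the normal-approximation closed form", {
  expect_equal(pcc_summary(rep(0.4, 5)),
               list(mean = 0.4, ci_low = 0.4, ci_high = 0.4, n = 5L))
  s <- pcc_summary(c(0, 1))
  expect_equal(s$mean, 0.5)
  expect_equal(s$ci_high - s$mean, 1.96 * sqrt(0.5) / sqrt(2))
  expect_lte(s$ci_low, s$mean)
  expect_gte(s$ci_high, s$mean)
  expect_error(pcc_summary(0.3), "at least 2")
})

test_that("pairwise method comparison uses Welch tests with joint BH adjustment", {
  pcc <- list(m1 = c(0.8, 0.82, 0.79, 0.81), m2 = c(0.6, 0.62, 0.59, 0.61),
              m3 = c(0.8, 0.82, 0.79, 0.81))
  tab <- compare_methods(pcc)
  expect_equal(nrow(tab), 3)
  ht <- t.test(pcc$m1, pcc$m2)
  row12 <- tab[tab$method_a == "m1" & tab$method_b == "m2", ]
  expect_equal(row12$t, unname(ht$statistic))
  expect_equal(row12$p, ht$p.value)
  expect_true(all(tab$p_adj >= tab$p))
  expect_equal(tab$p_adj, p.adjust(tab$p, "BH"))
  # identical copies: t = 0, p = 1
  row13 <- tab[tab$method_a == "m1" & tab$method_b == "m3", ]
  expect_equal(row13$t, 0)
  expect_equal(row13$p, 1)
})

test_that("zero-variance degenerate comparisons follow the stated conventions", {
  same <- compare_methods(list(a = c(0.5, 0.5), b = c(0.5, 0.5)))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  diff_means <- compare_methods(list(a = c(0.5, 0.5), b = c(0.7, 0.7)))
  expect_equal(diff_means$p, 0)
  expect_true(is.infinite(diff_means$t))
  expect_error(compare_methods(list(a = c(1, 2))), "at least 2 methods")
  expect_error(compare_methods(list(a = c(1, 2), b = 3)), "at least 2 values")
})

test_that("synthetic pipeline recovers dominant types across seeds", {
  res <- recovery_benchmark(seeds = 1:2, n_cells = 800, grid_size = 170)
  expect_true(all(res$n_spots >= 30))
  expect_true(all(res$ari > 0.5))
  # matched pairs must show clear positive expression-space association
  expect_true(all(res$pcc_mean > 0.1))
})
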