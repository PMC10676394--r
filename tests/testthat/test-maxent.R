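test_that("no-update and penalty-dominated limits give the uniform model", {
  sc <- small_scene(seed = 2, nrows = 30, ncols = 30, n_points = 60)
  tb <- scene_tables(sc, n_background = 500)
  m0 <- fit_maxent(tb$pres, tb$bg, kinds = tb$kinds, max_iter = 0)
  expect_true(all(m0$lambda == 0))
  raw <- predict(m0, tb$bg, type = "raw")
  N <- nrow(tb$pres) + nrow(tb$bg)
  expect_equal(raw, rep(1 / N, nrow(tb$bg)), tolerance = 1e-12)
  mBig <- fit_maxent(tb$pres, tb$bg, kinds = tb$kinds, reg_multiplier = 1e6)
  expect_lt(max(abs(mBig$lambda)), 1e-6)
})

test_that("the fit recovers the sign of a strong generating weight", {
  g <- gen_env_stack(40, 40, 4, 0, smoothness = 5, collinear_pairs = 0, seed = 3)
  tr <- g$truth; tr$true_weights <- c(env01 = 2)
  occ <- gen_occurrences(g$stack, tr, n_points = 150, seed = 3)$occurrences
  env <- extract_values(g$stack, occ)
  pres <- env[env$valid, names(g$stack$layers)]
  set.seed(3)
  cells <- sample(which(valid_mask(g$stack)), 1000)
  bg <- as.data.frame(lapply(g$stack$layers, function(l) l$values[cells]))
  m <- fit_maxent(pres, bg)
  expect_gt(m$lambda[["env01:linear"]], 0)
})

test_that("fitted raw distribution is normalized with non-negative entropy", {
  sc <- small_scene(seed = 4, nrows = 30, ncols = 30, n_points = 60)
  tb <- scene_tables(sc, n_background = 600)
  m <- fit_maxent(tb$pres, tb$bg, kinds = tb$kinds)
  raw_all <- predict(m, rbind(tb$pres, tb$bg), type = "raw")
  expect_equal(sum(raw_all), 1, tolerance = 1e-8)
  expect_gte(m$entropy_H, 0)
  expect_true(m$converged)
})

test_that("output transforms behave as stated", {
  sc <- small_scene(seed = 5, nrows = 30, ncols = 30, n_points = 60)
  tb <- scene_tables(sc, n_background = 500)
  m <- fit_maxent(tb$pres, tb$bg, kinds = tb$kinds)
  raw <- predict(m, tb$bg, type = "raw")
  cll <- predict(m, tb$bg, type = "cloglog")
  lgs <- predict(m, tb$bg, type = "logistic")
  expect_true(all(cll >= 0 & cll <= 1))
  expect_true(all(lgs >= 0 & lgs <= 1))
  # cloglog is monotone in raw
  o <- order(raw)
  expect_true(all(diff(cll[o]) >= 0))
  # logistic fixed point: q e^H = 1 -> 0.5
  q_star <- exp(-m$entropy_H)
  lgs_star <- q_star * exp(m$entropy_H) / (1 + q_star * exp(m$entropy_H))
  expect_equal(lgs_star, 0.5)
  # raster prediction masks what the stack masks
  sc$stack$layers[[1]]$values[2, 2] <- NA
  map <- predict_suitability(m, sc$stack)
  expect_true(is.na(map$values[2, 2]))
  expect_error(predict_suitability(m, tiny_stack(8, 2)), "missing layer")
})

test_that("AUC equals the pairwise Mann-Whitney fraction", {
  expect_equal(auc(c(1, 1), c(0, 0)), 1)
  expect_equal(auc(c(0.3, 0.7), c(0.3, 0.7)), 0.5)
  expect_equal(auc(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  # cross-checked against explicit pair counting on random instances
  set.seed(8)
  for (i in 1:200) {
    a <- round(runif(sample(2:8, 1)), 2)
    b <- round(runif(sample(2:8, 1)), 2)
    pairs <- (sum(outer(a, b, `>`)) + 0.5 * sum(outer(a, b, `==`))) /
      (length(a) * length(b))
    expect_equal(auc(a, b), pairs)
  }
})

test_that("AUC grades follow the published quality gates", {
  expect_equal(auc_grade(c(0.55, 0.65, 0.8, 0.95)),
               c("fails", "poor", "good", "excellent"))
})

test_that("train/test splits are disjoint, exhaustive and seeded", {
  pres <- tibble::tibble(x = 1:207)
  sp <- train_test_split(pres, 0.25, seed = 1)
  expect_equal(nrow(sp$test), 52)   # round(207 * 0.25)
  expect_equal(nrow(sp$train), 155)
  expect_setequal(c(sp$train$x, sp$test$x), 1:207)
  sp2 <- train_test_split(pres, 0.25, seed = 1)
  expect_identical(sp$test$x, sp2$test$x)
  expect_error(train_test_split(tibble::tibble(x = 1), 0.25, seed = 1),
               "empty")
})

test_that("percent contribution sums to 100 and credits single-layer models fully", {
  sc <- small_scene(seed = 6, nrows = 30, ncols = 30, n_points = 80)
  tb <- scene_tables(sc, n_background = 600)
  m <- fit_maxent(tb$pres, tb$bg, kinds = tb$kinds)
  pc <- percent_contribution(m)
  expect_equal(sum(pc$percent_contribution), 100, tolerance = 0.1)
  m1 <- fit_maxent(tb$pres["env01"], tb$bg["env01"])
  pc1 <- percent_contribution(m1)
  expect_equal(pc1$percent_contribution, 100)
})

test_that("dominant generating layer tops the contribution ranking", {
  wins <- 0
  for (s in 1:10) {
    g <- gen_env_stack(30, 30, 4, 0, smoothness = 5, collinear_pairs = 0,
                       seed = s)
    tr <- g$truth; tr$true_weights <- c(env02 = 2.5, env04 = 0.3)
    occ <- gen_occurrences(g$stack, tr, 120, seed = s)$occurrences
    env <- extract_values(g$stack, occ)
    pres <- env[env$valid, names(g$stack$layers)]
    set.seed(s); cells <- sample(which(valid_mask(g$stack)), 700)
    bg <- as.data.frame(lapply(g$stack$layers, function(l) l$values[cells]))
    pc <- percent_contribution(fit_maxent(pres, bg))
    if (pc$layer[1] == "env02") wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("permutation importance is zero for unused layers and sums to 100", {
  sc <- small_scene(seed = 7, nrows = 30, ncols = 30, n_points = 80)
  tb <- scene_tables(sc, n_background = 600)
  m <- fit_maxent(tb$pres, tb$bg, kinds = tb$kinds)
  pi_ <- permutation_importance(m, tb$pres, tb$bg, seed = 1)
  expect_equal(sum(pi_$permutation_importance), 100, tolerance = 0.1)
  # a layer whose features all have lambda 0 cannot matter
  unused <- unique(m$features$defs$layer[
    vapply(seq_along(m$lambda), function(j) m$lambda[j] == 0, logical(1))])
  fully_unused <- unused[!unused %in%
    m$features$defs$layer[m$lambda != 0]]
  if (length(fully_unused)) {
    imp <- pi_$permutation_importance[pi_$layer %in% fully_unused]
    expect_true(all(imp == 0))
  }
})

test_that("jackknife gains respect redundancy and noise bounds", {
  g <- gen_env_stack(30, 30, 3, 0, smoothness = 5, collinear_pairs = 0, seed = 8)
  tr <- g$truth; tr$true_weights <- c(env01 = 2)
  occ <- gen_occurrences(g$stack, tr, 120, seed = 8)$occurrences
  env <- extract_values(g$stack, occ)
  pres <- env[env$valid, names(g$stack$layers)]
  set.seed(8); cells <- sample(which(valid_mask(g$stack)), 600)
  bg <- as.data.frame(lapply(g$stack$layers, function(l) l$values[cells]))
  # duplicate the informative layer and add an i.i.d. noise column
  pres$dup <- pres$env01; bg$dup <- bg$env01
  set.seed(99)
  pres$white <- rnorm(nrow(pres)); bg$white <- rnorm(nrow(bg))
  # tight optimizer tolerance so the submodel bound is resolved numerically
  jk <- jackknife_gains(pres, bg, tol = 1e-8)
  full <- attr(jk, "gain_full")
  expect_true(all(jk$gain_with_only >= 0))
  expect_true(all(jk$gain_without <= full + 1e-6))
  # removing one copy of a duplicated layer barely changes the gain
  expect_lt(full - jk$gain_without[jk$layer == "dup"], 0.05)
  # an i.i.d. noise layer alone explains nearly nothing
  expect_lt(jk$gain_with_only[jk$layer == "white"], 0.05)
})

test_that("response curves are flat for null models and agree with a dense scan", {
  sc <- small_scene(seed = 9, nrows = 30, ncols = 30, n_points = 80)
  tb <- scene_tables(sc, n_background = 500)
  m0 <- fit_maxent(tb$pres, tb$bg, kinds = tb$kinds, max_iter = 0)
  rc0 <- response_curve(m0, "env01")
  expect_lt(diff(range(rc0$curve$suitability)), 1e-12)
  m <- fit_maxent(tb$pres, tb$bg, kinds = tb$kinds)
  rc <- response_curve(m, "env01", n_grid = 200)
  expect_true(all(rc$curve$suitability >= 0 & rc$curve$suitability <= 1))
  # brute-force scan oracle for the threshold ranges
  above <- rc$curve$suitability > 0.30
  if (any(above) && !all(above)) {
    r <- rle(above); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    expect_equal(nrow(rc$suitable_range_030), sum(r$values))
    expect_equal(rc$suitable_range_030[, "lower"],
                 rc$curve$value[starts[r$values]], ignore_attr = TRUE)
  }
  expect_error(response_curve(m, "soil01"), "continuous")
})

test_that("replicate fits average cell-wise and reproduce under one master seed", {
  sc <- small_scene(seed = 10, nrows = 30, ncols = 30, n_points = 80)
  r1 <- fit_replicates(sc$occ, sc$stack, n_replicates = 2, seed = 5,
                       n_background = 500)
  r2 <- fit_replicates(sc$occ, sc$stack, n_replicates = 2, seed = 5,
                       n_background = 500)
  expect_identical(r1$mean_map$values, r2$mean_map$values)
  lo <- pmin(r1$maps[[1]]$values, r1$maps[[2]]$values)
  hi <- pmax(r1$maps[[1]]$values, r1$maps[[2]]$values)
  ok <- is.finite(lo)
  expect_true(all(r1$mean_map$values[ok] >= lo[ok] - 1e-12))
  expect_true(all(r1$mean_map$values[ok] <= hi[ok] + 1e-12))
  single <- fit_replicates(sc$occ, sc$stack, n_replicates = 1, seed = 5,
                           n_background = 500)
  expect_identical(single$mean_map$values, single$maps[[1]]$values)
})

test_that("tidy and glance summarize fitted models", {
  sc <- small_scene(seed = 11, nrows = 25, ncols = 25, n_points = 60)
  tb <- scene_tables(sc, n_background = 400)
  m <- fit_maxent(tb$pres, tb$bg, kinds = tb$kinds)
  td <- generics::tidy(m)
  expect_named(td, c("feature", "layer", "kind", "lambda", "beta"))
  expect_equal(nrow(td), length(m$lambda))
  gl <- generics::glance(m)
  expect_equal(gl$n_presence, nrow(tb$pres))
  expect_true(gl$converged)
})
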