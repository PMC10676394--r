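test_that("Mann-Whitney exact path matches full enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)    # 2 / choose(6, 3)
  expect_equal(res$method, "exact")
  set.seed(51)
  for (i in 1:30) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- sample(100, n1 + n2)   # distinct -> untied
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    res <- mann_whitney_u(a, b)
    expect_equal(res$p, mw_enumeration_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical samples give central U and p near 1", {
  a <- c(2, 4, 6, 8)
  res <- mann_whitney_u(a, a)
  expect_equal(res$U, length(a)^2 / 2)
  expect_gte(res$p, 0.99)
})

test_that("Mann-Whitney agrees with the standard test implementation", {
  set.seed(52)
  for (i in 1:20) {
    a <- rnorm(sample(5:12, 1)); b <- rnorm(sample(5:12, 1), mean = runif(1, 0, 2))
    ours <- mann_whitney_u(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = (ours$method == "exact"),
                                        correct = TRUE))
    expect_equal(min(ref$statistic, length(a) * length(b) - ref$statistic),
                 ours$U, ignore_attr = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 0.02)
  }
})

test_that("exact and normal paths agree within 0.02 at n = 15 per group", {
  set.seed(53)
  for (i in 1:10) {
    x <- sample(10000, 30)
    a <- x[1:15]; b <- x[16:30]
    exact <- mann_whitney_u(a, b)      # 225 <= 400, untied -> exact
    expect_equal(exact$method, "exact")
    big <- mann_whitney_u(c(a, max(x) + 1:6), c(b, max(x) + 7:12))
    expect_equal(big$method, "normal")
    # compare the two formulas on the same data via the normal z directly
    M <- 225
    sigma <- sqrt(M * 31 / 12)
    p_norm <- min(1, 2 * pnorm((exact$U - M / 2 + 0.5) / sigma))
    expect_lt(abs(exact$p - p_norm), 0.02)
  }
})

test_that("shifted normal groups are detected with high power", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s + 500)
    a <- rnorm(30, 2); b <- rnorm(30, 0)
    if (mann_whitney_u(a, b)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("stepwise regression recovers a single strong predictor", {
  set.seed(54)
  X <- as.data.frame(matrix(rnorm(100 * 5), 100))
  names(X) <- paste0("x", 1:5)
  y <- 3 + 2 * X$x1 + rnorm(100, sd = 0.1)
  m <- stepwise_ols(y, X)
  expect_equal(names(m$coefficients), "x1")
  expect_gte(m$coefficients[["x1"]], 1.9)
  expect_lte(m$coefficients[["x1"]], 2.1)
  expect_lt(m$stats$f_p, 0.05)
})

test_that("stepwise on pure noise usually selects nothing", {
  # with 10 candidates and per-step alpha 0.05 the familywise entry chance
  # is about 1 - 0.95^10 ~ 40%, so the empty model arises in ~60% of runs
  empty <- 0
  for (s in 1:50) {
    set.seed(s + 600)
    X <- as.data.frame(matrix(rnorm(100 * 10), 100))
    names(X) <- paste0("x", 1:10)
    y <- rnorm(100)
    if (length(stepwise_ols(y, X)$coefficients) == 0) empty <- empty + 1
  }
  expect_gte(empty, 25)
})

test_that("duplicated candidates never enter together", {
  set.seed(55)
  X <- data.frame(x1 = rnorm(80))
  X$x2 <- X$x1
  y <- 1 + 3 * X$x1 + rnorm(80, sd = 0.2)
  m <- stepwise_ols(y, X)
  expect_equal(length(m$coefficients), 1)
})

test_that("degenerate thresholds reduce to full OLS and the empty model", {
  set.seed(56)
  X <- as.data.frame(matrix(rnorm(60 * 3), 60)); names(X) <- paste0("x", 1:3)
  y <- 1 + X$x1 - 2 * X$x2 + rnorm(60)
  full <- stepwise_ols(y, X, p_enter = 1, p_remove = 1)
  expect_setequal(names(full$coefficients), names(X))
  ols <- coef(lm(y ~ ., data = cbind(y = y, X)))
  expect_equal(full$coefficients[names(X)], ols[names(X)], tolerance = 1e-9)
  none <- stepwise_ols(y, X, p_enter = 1e-300)
  expect_length(none$coefficients, 0)
  expect_equal(none$intercept, mean(y))
})

test_that("published equations evaluate exactly", {
  fx <- read_regression_models()
  zero <- setNames(rep(0, 10), fx$covariates)
  expect_equal(evaluate_regression(fx$models$lobetyolin, zero), 16.969)
  ones <- setNames(rep(1, 10), fx$covariates)
  expect_equal(evaluate_regression(fx$models$fat, ones), -2.685, tolerance = 1e-9)
  expect_error(evaluate_regression(fx$models$fat, c(X1 = 1)), "missing from x")
  m0 <- regression_model("c", 5)
  expect_equal(evaluate_regression(m0, c(a = 99)), 5)
})

test_that("tidy and glance expose regression terms", {
  set.seed(57)
  X <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
  y <- 2 + X$x1 + rnorm(50, sd = 0.1)
  m <- stepwise_ols(y, X)
  td <- generics::tidy(m)
  expect_equal(td$term[1], "(Intercept)")
  expect_true("x1" %in% td$term)
  gl <- generics::glance(m)
  expect_equal(gl$n, 50)
  expect_gt(gl$r.squared, 0.9)
})

test_that("Spearman matrices match the rank formula and flag significance", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  mono <- x^3 + 2
  r <- spearman_matrix(data.frame(a = x, b = -x),
                       data.frame(f = mono, g = rnorm(6)))
  expect_equal(r$rho["a", "f"], 1)
  expect_equal(r$rho["b", "f"], -1)
  expect_true(all(abs(r$rho) <= 1))
  # six-point instance vs the exhaustive rank formula oracle
  set.seed(58)
  u <- rnorm(6); v <- rnorm(6)
  rr <- spearman_matrix(data.frame(u = u, a2 = rnorm(6)),
                        data.frame(v = v))$rho["u", "v"]
  d <- rank(u) - rank(v)
  expect_equal(rr, 1 - 6 * sum(d^2) / (6 * 35), tolerance = 1e-12)
  expect_identical(r$sig["a", "f"], "**")
})

test_that("factor clustering recovers planted correlation blocks", {
  set.seed(59)
  n <- 200
  g1 <- rnorm(n); g2 <- rnorm(n); g3 <- rnorm(n)
  eco <- data.frame(a1 = g1 + rnorm(n, sd = 0.1), a2 = g1 + rnorm(n, sd = 0.1),
                    b1 = g2 + rnorm(n, sd = 0.1), b2 = g2 + rnorm(n, sd = 0.1),
                    c1 = g3 + rnorm(n, sd = 0.1))
  cl <- cluster_factors(cor(eco), k = 3)
  expect_equal(cl[["a1"]], cl[["a2"]])
  expect_equal(cl[["b1"]], cl[["b2"]])
  expect_equal(length(unique(cl)), 3)
  expect_false(cl[["a1"]] == cl[["b1"]])
  # k = n gives singletons; permutation only relabels
  expect_equal(length(unique(cluster_factors(cor(eco), k = 5))), 5)
  perm <- c(3, 1, 5, 2, 4)
  cl_p <- cluster_factors(cor(eco)[perm, perm], k = 3)
  expect_equal(cl_p[["a1"]], cl_p[["a2"]])
})

test_that("group comparison summarizes one functional factor", {
  set.seed(60)
  tab <- tibble::tibble(class = rep(c("high", "moderate"), each = 20),
                        lob = c(rnorm(20, 10), rnorm(20, 8)))
  cmp <- compare_groups(tab, "lob")
  expect_equal(cmp$n_1, 20)
  expect_lt(cmp$p, 0.05)
  expect_equal(cmp$direction, 1)
})

test_that("stepwise recovers generator coefficients at sample points", {
  # strong signals (|coef|/sd >= 5): the truth terms always enter; at
  # per-step alpha 0.05 a single spurious extra term enters in a minority
  # of runs, so the exact set is recovered in most but not all seeds
  sup_ok <- 0; exact <- 0
  truth_sup <- c("env02", "env05", "env07")
  for (s in 1:10) {
    g <- gen_env_stack(60, 60, 8, 0, smoothness = 5, collinear_pairs = 0,
                       seed = s + 900)
    set.seed(s)
    sp <- g$stack$spec
    occ <- tibble::tibble(
      longitude = runif(200, sp$xllcorner, sp$xllcorner + 60 * sp$cellsize),
      latitude = runif(200, sp$yllcorner, sp$yllcorner + 60 * sp$cellsize))
    tr <- g$truth
    tr$factor_models <- list(f = list(
      intercept = 10, coefficients = c(env02 = 2, env05 = -1.5, env07 = 1),
      sd = 0.2))
    ff <- gen_functional_factor_table(g$stack, occ, tr, seed = s)
    env <- extract_values(g$stack, occ)
    env <- env[env$valid, , drop = FALSE]
    sel <- names(stepwise_ols(ff$table$f,
                              env[names(g$stack$layers)])$coefficients)
    if (all(truth_sup %in% sel)) sup_ok <- sup_ok + 1
    if (setequal(sel, truth_sup)) exact <- exact + 1
  }
  expect_gte(sup_ok, 8)
  expect_gte(exact, 5)
})
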