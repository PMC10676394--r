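#' Feature expansion for maximum-entropy fitting
#'
#' Continuous covariates contribute a linear and a quadratic feature;
#' categorical covariates one indicator per category observed in the
#' training sample. Every feature is min-max scaled to [0, 1] on the
#' training data and the scaling is recorded so new data are expanded
#' identically. All-constant features are dropped with a warning.
#'
#' @param train Data frame of covariates (training sample).
#' @param kinds Named character vector, `"continuous"` or `"categorical"`
#'   per column; columns absent from `kinds` are treated as continuous.
#' @return Object of class `feature_expansion` with `defs` (tibble:
#'   feature, layer, kind, category), `fmin`, `fmax`.
#' @export
feature_expansion <- function(train, kinds = NULL) {
  layers <- names(train)
  kind_of <- function(l) {
    if (!is.null(kinds) && l %in% names(kinds)) kinds[[l]] else "continuous"
  }
  defs <- list()
  for (l in layers) {
    if (kind_of(l) == "categorical") {
      for (cat in sort(unique(train[[l]])))
        defs[[length(defs) + 1]] <- tibble::tibble(
          feature = paste0(l, "==", cat), layer = l,
          kind = "categorical-indicator", category = cat)
    } else {
      defs[[length(defs) + 1]] <- tibble::tibble(
        feature = paste0(l, ":linear"), layer = l,
        kind = "linear", category = NA_real_)
      defs[[length(defs) + 1]] <- tibble::tibble(
        feature = paste0(l, ":quadratic"), layer = l,
        kind = "quadratic", category = NA_real_)
    }
  }
  defs <- dplyr::bind_rows(defs)
  fe <- structure(list(defs = defs, fmin = NULL, fmax = NULL),
                  class = "feature_expansion")
  raw <- expand_features(fe, train, scale = FALSE)
  fmin <- apply(raw, 2, min); fmax <- apply(raw, 2, max)
  const <- fmax - fmin <= 0
  if (any(const)) {
    warning("dropping all-constant feature(s): ",
            paste(defs$feature[const], collapse = ", "))
    defs <- defs[!const, , drop = FALSE]
    fmin <- fmin[!const]; fmax <- fmax[!const]
  }
  if (!nrow(defs)) stop("no non-constant features")
  structure(list(defs = defs, fmin = fmin, fmax = fmax),
            class = "feature_expansion")
}

#' Expand covariates into the (scaled) feature matrix
#'
#' @param fe A [feature_expansion()].
#' @param data Data frame supplying every source layer.
#' @param scale Apply the recorded min-max scaling (default `TRUE`).
#' @return Numeric matrix, rows = observations, columns = features.
#' @export
expand_features <- function(fe, data, scale = TRUE) {
  d <- fe$defs
  n <- nrow(data)
  F_ <- matrix(0, n, nrow(d), dimnames = list(NULL, d$feature))
  for (j in seq_len(nrow(d))) {
    x <- data[[d$layer[j]]]
    if (is.null(x)) stop("data is missing layer '", d$layer[j], "'")
    if (any(!is.finite(x))) stop("non-finite covariate values in layer '",
                                 d$layer[j], "'")
    F_[, j] <- switch(d$kind[j],
      linear = x,
      quadratic = x^2,
      `categorical-indicator` = as.numeric(x == d$category[j]))
  }
  if (scale && !is.null(fe$fmin)) {
    rng <- pmax(fe$fmax - fe$fmin, .Machine$double.eps)
    F_ <- sweep(sweep(F_, 2, fe$fmin), 2, rng, "/")
  }
  F_
}

#' Fit a maximum-entropy species distribution model
#'
#' Models the relative occurrence rate as the Gibbs distribution
#' q(x) proportional to exp(lambda . f(x)) over the fitting sample
#' (presences plus background), minimizing the L1-regularized negative
#' mean log-likelihood of the presences by cyclic coordinate descent with
#' soft-thresholding. The per-feature penalty is
#' beta_j = reg_multiplier * sd_background(f_j) / sqrt(n_presences).
#' The gain improvement of each accepted coordinate update is credited to
#' the updated feature's source layer, which is what
#' [percent_contribution()] reports.
#'
#' @param presences Data frame of covariates at presence points.
#' @param background Data frame of covariates at background points.
#' @param kinds Named character vector of layer kinds (see
#'   [feature_expansion()]).
#' @param reg_multiplier Regularization multiplier (default 1).
#' @param max_iter Maximum coordinate-descent cycles (default 10000; the
#'   gain tolerance normally stops it within a few hundred).
#' @param tol Convergence tolerance on the penalized gain change per full
#'   cycle (default 1e-5).
#' @param seed Unused by the deterministic optimizer; accepted so callers
#'   can treat all fitting functions uniformly.
#' @return Object of class `maxent_model`: `features`, `lambda`, `beta`,
#'   `log_Z`, `entropy_H`, `gain`, `gain_credit` (per-layer), `bg_feature_mean`,
#'   `train_range` (per-layer min/max), `n_presence`, `n_background`,
#'   `iterations`, `converged`.
#' @export
fit_maxent <- function(presences, background, kinds = NULL,
                       reg_multiplier = 1.0, max_iter = 10000,
                       tol = 1e-5, seed = NULL) {
  presences <- as.data.frame(presences)
  background <- as.data.frame(background)
  stopifnot(nrow(presences) >= 5)
  common <- intersect(names(presences), names(background))
  presences <- presences[common]; background <- background[common]
  fe <- feature_expansion(rbind(presences, background), kinds)
  Fp <- expand_features(fe, presences)
  Fb <- expand_features(fe, background)
  F_ <- rbind(Fp, Fb)
  N <- nrow(F_); n1 <- nrow(Fp); p <- ncol(F_)
  fbar <- colMeans(Fp)
  sd_bg <- apply(Fb, 2, stats::sd)
  beta <- reg_multiplier * pmax(sd_bg, 1e-6) / sqrt(n1)
  lambda <- rep(0, p)
  u <- rep(0, N)
  credit <- stats::setNames(rep(0, length(unique(fe$defs$layer))),
                            unique(fe$defs$layer))
  # penalized gain: mean log q(presence) - log(1/N) - penalty
  gain_of <- function(u, lambda) {
    lse <- log_sum_exp(u)
    mean(u[seq_len(n1)]) - lse + log(N) - sum(beta * abs(lambda))
  }
  gain <- gain_of(u, lambda)   # 0 at lambda = 0
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    cycle_start <- gain
    for (j in seq_len(p)) {
      q <- exp(u - log_sum_exp(u))
      Eq <- sum(q * F_[, j])
      Vq <- sum(q * (F_[, j] - Eq)^2)
      if (Vq < 1e-12) next
      g <- fbar[j] - Eq
      z <- lambda[j] + g / Vq
      lam_new <- sign(z) * max(0, abs(z) - beta[j] / Vq)
      step <- lam_new - lambda[j]
      if (abs(step) < 1e-12) next
      # backtracking keeps the penalized gain non-decreasing
      for (bt in 1:30) {
        u_try <- u + step * F_[, j]
        lam_try <- lambda; lam_try[j] <- lambda[j] + step
        g_try <- gain_of(u_try, lam_try)
        if (g_try >= gain - 1e-12) break
        step <- step / 2
      }
      if (g_try >= gain - 1e-12) {
        credit[fe$defs$layer[j]] <- credit[fe$defs$layer[j]] +
          max(0, g_try - gain)
        u <- u_try; lambda <- lam_try; gain <- g_try
      }
    }
    if (gain - cycle_start < tol) { converged <- TRUE; break }
  }
  lse <- log_sum_exp(u)
  q <- exp(u - lse)
  H <- -sum(q * ifelse(q > 0, log(q), 0))
  structure(list(
    features = fe, lambda = stats::setNames(lambda, fe$defs$feature),
    beta = stats::setNames(beta, fe$defs$feature),
    log_Z = lse, entropy_H = H, gain = gain, gain_credit = credit,
    bg_feature_mean = colMeans(Fb),
    train_range = lapply(stats::setNames(common, common), function(l)
      range(c(presences[[l]], background[[l]]))),
    kinds = kinds,
    n_presence = n1, n_background = nrow(Fb),
    iterations = iter, converged = converged),
    class = "maxent_model")
}

log_sum_exp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features over %d layers; gain %.4f; %d/%d nonzero lambda; %s after %d cycles\n",
              length(x$lambda), length(unique(x$features$defs$layer)),
              x$gain, sum(x$lambda != 0), length(x$lambda),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Predict maxent scores for a covariate table
#'
#' @param object A `maxent_model`.
#' @param newdata Data frame supplying every source layer.
#' @param type `"cloglog"` (default), `"logistic"` or `"raw"`. Raw values
#'   are exp(lambda . f(x)) / Z with Z from the training sample (so they
#'   sum to 1 over the fitting sample); cloglog = 1 - exp(-exp(H) * raw);
#'   logistic = raw exp(H) / (1 + raw exp(H)).
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("cloglog", "logistic", "raw"), ...) {
  type <- match.arg(type)
  F_ <- expand_features(object$features, as.data.frame(newdata))
  raw <- exp(drop(F_ %*% object$lambda) - object$log_Z)
  transform_raw(raw, object$entropy_H, type)
}

transform_raw <- function(raw, H, type) {
  switch(type,
         raw = raw,
         cloglog = 1 - exp(-exp(H) * raw),
         logistic = { r <- raw * exp(H); r / (1 + r) })
}

#' Predict a suitability raster from a fitted model
#'
#' @param model A `maxent_model`.
#' @param stack An [env_stack()] supplying every source layer.
#' @param type Output scale, as in [predict.maxent_model()].
#' @return A [raster_layer()] named `"suitability"`; cells masked in any
#'   source layer stay masked.
#' @export
predict_suitability <- function(model, stack,
                                type = c("cloglog", "logistic", "raw")) {
  type <- match.arg(type)
  need <- unique(model$features$defs$layer)
  miss <- setdiff(need, names(stack$layers))
  if (length(miss)) stop("stack is missing layer(s): ",
                         paste(miss, collapse = ", "))
  mask <- valid_mask(stack)
  idx <- which(mask)
  df <- as.data.frame(lapply(stack$layers[need], function(l) l$values[idx]))
  names(df) <- need
  sc <- predict.maxent_model(model, df, type = type)
  v <- matrix(NA_real_, stack$spec$nrows, stack$spec$ncols)
  v[idx] <- sc
  raster_layer("suitability", stack$spec, v, "continuous")
}

#' Area under the ROC curve for presence vs background scores
#'
#' Mann-Whitney form: the fraction of (presence, background) pairs where
#' the presence scores higher, ties counted one half.
#'
#' @param scores_presence,scores_background Non-empty numeric vectors.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores_presence, scores_background) {
  n1 <- length(scores_presence); n2 <- length(scores_background)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Verbal model-quality grade for an AUC value
#'
#' @param x AUC value(s).
#' @return Character: `"fails"` (< 0.6), `"poor"` (< 0.7), `"good"`
#'   (0.7-0.9), `"excellent"` (> 0.9).
#' @export
auc_grade <- function(x) {
  cut(x, c(-Inf, 0.6, 0.7, 0.9, Inf),
      labels = c("fails", "poor", "good", "excellent"),
      right = FALSE) |> as.character()
}

#' Split presence records into training and testing sets
#'
#' @param presences Data frame or tibble of presence records.
#' @param test_fraction Fraction held out (0 < f < 1); test size is
#'   `round(n * f)` and must be >= 1.
#' @param seed Integer seed.
#' @return List with `train` and `test` (disjoint, union = input).
#' @export
train_test_split <- function(presences, test_fraction = 0.25, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- nrow(presences)
  n_test <- round(n * test_fraction)
  if (n_test < 1) stop("test set would be empty (n = ", n, ", fraction = ",
                       test_fraction, ")")
  set.seed(seed)
  test_idx <- sample.int(n, n_test)
  list(train = presences[-test_idx, , drop = FALSE],
       test = presences[test_idx, , drop = FALSE])
}

#' Percent contribution of each source layer
#'
#' Shares of the total penalized-gain improvement credited to each layer
#' during coordinate descent, normalized to sum 100.
#'
#' @param model A fitted `maxent_model`.
#' @return Tibble: `layer`, `percent_contribution`, sorted descending.
#' @export
percent_contribution <- function(model) {
  cr <- model$gain_credit
  tot <- sum(cr)
  if (tot <= 0) {
    warning("zero total gain; all contributions 0")
    pc <- cr * 0
  } else pc <- 100 * cr / tot
  tibble::tibble(layer = names(pc), percent_contribution = unname(pc)) |>
    dplyr::arrange(dplyr::desc(.data$percent_contribution))
}

#' Permutation importance of each source layer
#'
#' For each layer, its values are permuted jointly across presences and
#' background, model scores recomputed and the AUC drop recorded; the
#' mean drop over `n_perm` permutations, floored at zero, is normalized
#' across layers to sum 100.
#'
#' @param model A fitted `maxent_model`.
#' @param presences,background Covariate data frames (as used in fitting).
#' @param n_perm Permutations per layer (default 3).
#' @param seed Integer seed.
#' @return Tibble: `layer`, `permutation_importance`.
#' @export
permutation_importance <- function(model, presences, background,
                                   n_perm = 3, seed = 1) {
  set.seed(seed)
  layers <- unique(model$features$defs$layer)
  all_df <- rbind(as.data.frame(presences)[layers],
                  as.data.frame(background)[layers])
  n1 <- nrow(presences)
  base_scores <- predict.maxent_model(model, all_df, type = "raw")
  base_auc <- auc(base_scores[seq_len(n1)], base_scores[-seq_len(n1)])
  drops <- vapply(layers, function(l) {
    mean(vapply(seq_len(n_perm), function(k) {
      d <- all_df
      d[[l]] <- sample(d[[l]])
      s <- predict.maxent_model(model, d, type = "raw")
      base_auc - auc(s[seq_len(n1)], s[-seq_len(n1)])
    }, numeric(1)))
  }, numeric(1))
  drops <- pmax(drops, 0)
  tot <- sum(drops)
  imp <- if (tot > 0) 100 * drops / tot else drops
  tibble::tibble(layer = layers, permutation_importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$permutation_importance))
}

#' Jackknife test of variable importance
#'
#' Refits the model with only, and without, each layer, reporting the
#' regularized training gain of each reduced model next to the full
#' model's gain. On the regularized scale every submodel optimum is
#' bounded by the full-model optimum (a submodel is the full problem with
#' the removed features pinned at zero), so `gain_without <= gain_full`
#' holds by construction.
#'
#' @param presences,background Covariate data frames (>= 2 layers).
#' @param kinds Layer kinds (see [feature_expansion()]).
#' @param ... Passed to [fit_maxent()].
#' @return Tibble: `layer`, `gain_with_only`, `gain_without`, plus
#'   attribute `gain_full`.
#' @export
jackknife_gains <- function(presences, background, kinds = NULL, ...) {
  layers <- intersect(names(presences), names(background))
  stopifnot(length(layers) >= 2)
  train_gain <- function(cols) {
    m <- fit_maxent(presences[cols], background[cols],
                    kinds = kinds[intersect(names(kinds), cols)], ...)
    max(0, m$gain)
  }
  full <- train_gain(layers)
  res <- tibble::tibble(
    layer = layers,
    gain_with_only = vapply(layers, function(l) train_gain(l), numeric(1)),
    gain_without = vapply(layers, function(l)
      train_gain(setdiff(layers, l)), numeric(1)))
  attr(res, "gain_full") <- full
  res
}

#' Univariate response curve of a fitted model
#'
#' Varies one continuous layer over its training range on a grid while
#' every other feature is held at its background mean, and reports the
#' cloglog response plus the sub-ranges where it exceeds 0.30 (suitable)
#' and 0.50 (optimal).
#'
#' @param model A fitted `maxent_model`.
#' @param layer Continuous source-layer name.
#' @param n_grid Grid resolution (default 100).
#' @return Object of class `response_curve`: tibble `curve` (`value`,
#'   `suitability`), `suitable_range_030`, `optimal_range_050` (two-column
#'   matrices of interval endpoints).
#' @export
response_curve <- function(model, layer, n_grid = 100) {
  d <- model$features$defs
  if (!layer %in% d$layer) stop("model has no layer '", layer, "'")
  if (any(d$kind[d$layer == layer] == "categorical-indicator"))
    stop("response curves require a continuous layer")
  rng <- model$train_range[[layer]]
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  own <- which(d$layer == layer)
  fixed <- sum(model$lambda[-own] * model$bg_feature_mean[-own])
  scale_j <- function(j, x)
    (x - model$features$fmin[j]) /
      max(model$features$fmax[j] - model$features$fmin[j], .Machine$double.eps)
  u <- rep(fixed, n_grid)
  for (j in own) {
    raw_f <- switch(d$kind[j], linear = grid, quadratic = grid^2)
    u <- u + model$lambda[j] * scale_j(j, raw_f)
  }
  suit <- transform_raw(exp(u - model$log_Z), model$entropy_H, "cloglog")
  runs_above <- function(th) {
    above <- suit > th
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- r$values
    cbind(lower = grid[starts[keep]], upper = grid[ends[keep]])
  }
  structure(list(layer = layer,
                 curve = tibble::tibble(value = grid, suitability = suit),
                 suitable_range_030 = runs_above(0.30),
                 optimal_range_050 = runs_above(0.50)),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> layer '%s', %d grid points, %d suitable (>0.30) interval(s)\n",
              x$layer, nrow(x$curve), nrow(x$suitable_range_030)))
  invisible(x)
}

#' Plot a response curve
#'
#' @param object A `response_curve`.
#' @param ... Unused.
#' @return A ggplot object with the 0.30 and 0.50 thresholds marked.
#' @method autoplot response_curve
#' @export
autoplot.response_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$value, y = .data$suitability)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0.30, 0.50), linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = object$layer, y = "suitability (cloglog)")
}

#' Fit replicate maxent models and average their suitability maps
#'
#' Each replicate draws a fresh 75/25 presence split and a fresh uniform
#' background sample of valid cells, fits, predicts a cloglog map and
#' records train/test AUC; the returned raster is the cell-wise mean map.
#'
#' @param occ Occurrence tibble (`longitude`, `latitude`).
#' @param stack An [env_stack()].
#' @param n_replicates Number of replicates (default 10).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param n_background Background sample size (default 10000, capped at
#'   the number of valid cells).
#' @param test_fraction Held-out fraction per replicate (default 0.25).
#' @param ... Passed to [fit_maxent()].
#' @return Object of class `maxent_replicates`: `mean_map`
#'   ([raster_layer()]), `metrics` (tibble: replicate, auc_train,
#'   auc_test), `models` (list), `maps` (list).
#' @export
fit_replicates <- function(occ, stack, n_replicates = 10, seed = 1,
                           n_background = 10000, test_fraction = 0.25, ...) {
  stopifnot(n_replicates >= 1)
  kinds <- vapply(stack$layers, `[[`, character(1), "kind")
  mask <- valid_mask(stack)
  valid_cells <- which(mask)
  env_at <- function(pts) {
    e <- extract_values(stack, pts)
    e[e$valid, names(stack$layers), drop = FALSE]
  }
  pres_env <- env_at(occ)
  maps <- vector("list", n_replicates)
  models <- vector("list", n_replicates)
  metrics <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rseed <- (seed * 1000L + r) %% .Machine$integer.max
    sp <- train_test_split(pres_env, test_fraction, seed = rseed)
    set.seed(rseed + 1L)
    bg_cells <- sample(valid_cells, min(n_background, length(valid_cells)))
    bg <- as.data.frame(lapply(stack$layers, function(l) l$values[bg_cells]))
    m <- fit_maxent(sp$train, bg, kinds = kinds, ...)
    map <- predict_suitability(m, stack, type = "cloglog")
    s_train <- predict.maxent_model(m, sp$train, type = "raw")
    s_test <- predict.maxent_model(m, sp$test, type = "raw")
    s_bg <- predict.maxent_model(m, bg, type = "raw")
    maps[[r]] <- map; models[[r]] <- m
    metrics[[r]] <- tibble::tibble(replicate = r,
                                   auc_train = auc(s_train, s_bg),
                                   auc_test = auc(s_test, s_bg))
  }
  mv <- Reduce(`+`, lapply(maps, function(m) m$values)) / n_replicates
  structure(list(
    mean_map = raster_layer("suitability", stack$spec, mv, "continuous"),
    metrics = dplyr::bind_rows(metrics),
    models = models, maps = maps),
    class = "maxent_replicates")
}

#' @export
print.maxent_replicates <- function(x, ...) {
  cat(sprintf("<maxent_replicates> %d replicates; mean train AUC %.3f, mean test AUC %.3f (%s)\n",
              nrow(x$metrics), mean(x$metrics$auc_train),
              mean(x$metrics$auc_test), auc_grade(mean(x$metrics$auc_test))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted maxent model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return Tibble: `feature`, `layer`, `kind`, `lambda`, `beta`.
#' @method tidy maxent_model
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(feature = x$features$defs$feature,
                 layer = x$features$defs$layer,
                 kind = x$features$defs$kind,
                 lambda = unname(x$lambda),
                 beta = unname(x$beta))
}

#' One-row summary of a fitted maxent model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return Tibble with gain, entropy, normalizer, counts and convergence.
#' @method glance maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(gain = x$gain, entropy_H = x$entropy_H, log_Z = x$log_Z,
                 n_presence = x$n_presence, n_background = x$n_background,
                 n_features = length(x$lambda),
                 n_nonzero = sum(x$lambda != 0),
                 iterations = x$iterations, converged = x$converged)
}
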