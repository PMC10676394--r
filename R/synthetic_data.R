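#' Synthetic ground truth
#'
#' Records everything the generators decided so downstream stages can be
#' tested as recovery problems: the coefficients of the suitability
#' surface that produced the occurrences, the collinear layer pairs that
#' were planted, the chromatographic peak templates, and the sparse linear
#' models behind the functional-factor table.
#'
#' @param true_weights Named numeric: layer name -> coefficient of the
#'   generating log-linear suitability surface.
#' @param collinear_pairs List of 2-element character vectors (planted
#'   |r| > 0.8 pairs).
#' @param peak_templates Tibble with columns `rt` (min), `area`, `cv`
#'   (per-sample area coefficient of variation).
#' @param factor_models Named list: factor name -> list(intercept,
#'   coefficients (named numeric), sd).
#' @param seed Integer seed the generators were called with.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(true_weights = numeric(), collinear_pairs = list(),
                            peak_templates = default_peak_templates(),
                            factor_models = list(), seed = NA_integer_) {
  structure(list(true_weights = true_weights,
                 collinear_pairs = collinear_pairs,
                 peak_templates = peak_templates,
                 factor_models = factor_models,
                 seed = seed),
            class = "synthetic_truth")
}

#' Default chromatographic peak templates
#'
#' Twenty Gaussian peaks spread over a 0-50 min gradient, mimicking a
#' standardized herbal-extract fingerprint: right-skewed areas, a handful
#' of dominant peaks among many minor ones, area CV 20 percent.
#'
#' @return Tibble with columns `rt`, `area`, `cv`.
#' @export
default_peak_templates <- function() {
  rt <- c(3.1, 5.4, 7.2, 9.0, 11.3, 13.6, 15.2, 17.8, 19.5, 21.9,
          24.3, 26.6, 28.4, 31.0, 33.7, 36.1, 38.9, 41.5, 44.2, 47.3)
  area <- c(12, 4, 7, 25, 3, 9, 5, 14, 6, 40,
            8, 18, 3.5, 11, 5.5, 22, 4.5, 7.5, 16, 6.5)
  tibble::tibble(rt = rt, area = area, cv = rep(0.2, 20))
}

# Separable Gaussian smoothing of a matrix, reflecting at edges.
smooth_matrix <- function(m, length_scale) {
  if (length_scale <= 1) return(m)
  half <- max(1L, ceiling(3 * length_scale))
  k <- stats::dnorm(-half:half, sd = length_scale)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    pad <- c(v[pmin(half:1, n)], v, v[pmax(n - (1:half) + 1, 1)])
    stats::filter(pad, k, sides = 2)[(half + 1):(half + n)]
  }
  m2 <- apply(m, 2, smooth_vec)
  t(apply(t(m2), 2, smooth_vec))
}

#' Generate a synthetic environmental stack
#'
#' Continuous layers are spatially autocorrelated Gaussian random fields
#' (white noise smoothed with a Gaussian kernel at the requested length
#' scale), standardized to mean 0, sd 1 over valid cells. Each requested
#' collinear pair is planted as y = 0.95 x + small noise, guaranteeing
#' empirical |r| >= 0.8. Categorical layers are integer-coded Voronoi
#' patches (nearest of a handful of random seed cells).
#'
#' @param nrows,ncols Grid dimensions (>= 8).
#' @param n_continuous Number of continuous layers (>= 2).
#' @param n_categorical Number of categorical layers.
#' @param smoothness Smoothing length scale in cells (1 = white noise).
#' @param collinear_pairs Number of planted collinear pairs (each consumes
#'   two of the continuous layers; must be <= n_continuous / 2).
#' @param seed Integer seed.
#' @param xllcorner,yllcorner,cellsize Grid georeferencing; defaults place
#'   a ~1 km degree grid at mid latitudes.
#' @return List with elements `stack` ([env_stack()]) and `truth`
#'   ([synthetic_truth()], with `collinear_pairs` filled in).
#' @export
gen_env_stack <- function(nrows = 100, ncols = 100, n_continuous = 12,
                          n_categorical = 1, smoothness = 8,
                          collinear_pairs = 2, seed = 1,
                          xllcorner = 103, yllcorner = 34,
                          cellsize = 0.00898) {
  stopifnot(nrows >= 8, ncols >= 8, n_continuous >= 2)
  if (collinear_pairs > n_continuous / 2)
    stop("collinear_pairs (", collinear_pairs, ") exceeds n_continuous/2")
  set.seed(seed)
  spec <- grid_spec(ncols, nrows, xllcorner, yllcorner, cellsize)
  standardize <- function(m) (m - mean(m)) / stats::sd(as.vector(m))
  n_free <- n_continuous - collinear_pairs
  layers <- vector("list", n_continuous + n_categorical)
  cont_names <- paste0("env", sprintf("%02d", seq_len(n_continuous)))
  # independent fields first, then planted collinear partners
  for (i in seq_len(n_free)) {
    f <- standardize(smooth_matrix(matrix(stats::rnorm(nrows * ncols), nrows),
                                   smoothness))
    layers[[i]] <- raster_layer(cont_names[i], spec, f, "continuous")
  }
  pairs <- list()
  for (p in seq_len(collinear_pairs)) {
    base <- layers[[p]]$values
    nz <- standardize(smooth_matrix(matrix(stats::rnorm(nrows * ncols), nrows),
                                    smoothness))
    partner <- standardize(0.95 * base + 0.1 * nz)
    j <- n_free + p
    layers[[j]] <- raster_layer(cont_names[j], spec, partner, "continuous")
    pairs[[p]] <- c(cont_names[p], cont_names[j])
  }
  for (c_ in seq_len(n_categorical)) {
    n_patch <- 5L
    sr <- stats::runif(n_patch, 1, nrows)
    sc <- stats::runif(n_patch, 1, ncols)
    rows <- matrix(rep(seq_len(nrows), ncols), nrows)
    cols <- matrix(rep(seq_len(ncols), each = nrows), nrows)
    d <- lapply(seq_len(n_patch),
                function(k) (rows - sr[k])^2 + (cols - sc[k])^2)
    code <- matrix(max.col(-do.call(cbind, lapply(d, as.vector))), nrows)
    layers[[n_continuous + c_]] <-
      raster_layer(paste0("soil", sprintf("%02d", c_)), spec,
                   matrix(as.numeric(code), nrows), "categorical")
  }
  list(stack = env_stack(layers),
       truth = synthetic_truth(collinear_pairs = pairs, seed = seed))
}

#' Default generating weights for the synthetic suitability surface
#'
#' Three informative layers (one strongly positive, one negative, one
#' moderate) out of the stack's continuous layers; all others zero. The
#' weights define log-suitability Sum(w x) used by [gen_occurrences()].
#'
#' @param stack An `env_stack`.
#' @return Named numeric vector over the stack's continuous layers.
#' @export
default_true_weights <- function(stack) {
  cont <- names(stack$layers)[vapply(stack$layers, function(l)
    l$kind == "continuous", logical(1))]
  w <- stats::setNames(rep(0, length(cont)), cont)
  w[cont[1]] <- 2
  if (length(cont) >= 3) w[cont[3]] <- -1.5
  if (length(cont) >= 5) w[cont[5]] <- 1
  w
}

#' Sample presence points from a known suitability surface
#'
#' Cells are sampled without replacement with probability proportional to
#' exp(Sum w_l x_l) (the Gibbs form, so a maximum-entropy fit is correctly
#' specified); one point is then placed uniformly inside each sampled
#' cell.
#'
#' @param stack An [env_stack()].
#' @param truth A [synthetic_truth()] whose `true_weights` reference stack
#'   layers; if empty, [default_true_weights()] are filled in.
#' @param n_points Number of presences (<= number of valid cells).
#' @param seed Integer seed.
#' @param species Species label for the output tibble.
#' @return List with `occurrences` (tibble: species, longitude, latitude)
#'   and `truth` (with `true_weights` recorded).
#' @export
gen_occurrences <- function(stack, truth, n_points = 200, seed = 1,
                            species = "synthetic_sp") {
  if (!length(truth$true_weights))
    truth$true_weights <- default_true_weights(stack)
  w <- truth$true_weights
  miss <- setdiff(names(w), names(stack$layers))
  if (length(miss)) stop("true_weights reference missing layers: ",
                         paste(miss, collapse = ", "))
  set.seed(seed)
  mask <- valid_mask(stack)
  valid_cells <- which(mask)
  if (n_points > length(valid_cells))
    stop("n_points (", n_points, ") exceeds valid cells (", length(valid_cells), ")")
  eta <- rep(0, length(valid_cells))
  for (nm in names(w))
    eta <- eta + w[[nm]] * stack$layers[[nm]]$values[valid_cells]
  prob <- exp(eta - max(eta))
  picked <- sample(valid_cells, n_points, prob = prob)
  s <- stack$spec
  row <- ((picked - 1) %% s$nrows) + 1
  col <- ((picked - 1) %/% s$nrows) + 1
  lat_top <- s$yllcorner + s$nrows * s$cellsize
  lon <- s$xllcorner + (col - 1) * s$cellsize + stats::runif(n_points) * s$cellsize
  lat <- lat_top - row * s$cellsize + stats::runif(n_points) * s$cellsize
  list(occurrences = tibble::tibble(species = species, longitude = lon,
                                    latitude = lat),
       truth = truth)
}

#' Shift layers of a stack to emulate a future climate scenario
#'
#' @param stack An [env_stack()].
#' @param deltas Named numeric: additive shift per layer (names must be
#'   layer names); untouched layers are returned identical.
#' @param seed Unused (reserved for stochastic scenario generators);
#'   present so every generator shares one signature.
#' @return A shifted `env_stack`; masked cells stay masked.
#' @export
gen_future_stack <- function(stack, deltas, seed = 1) {
  miss <- setdiff(names(deltas), names(stack$layers))
  if (length(miss)) stop("deltas reference missing layers: ",
                         paste(miss, collapse = ", "))
  layers <- lapply(stack$layers, function(l) {
    if (l$name %in% names(deltas)) {
      v <- l$values + deltas[[l$name]]
      v[!is.finite(l$values)] <- NA_real_
      raster_layer(l$name, l$spec, v, l$kind)
    } else l
  })
  env_stack(layers)
}

#' Generate synthetic chromatograms
#'
#' Each chromatogram is a sum of Gaussian peaks on a uniform time grid:
#' template areas scaled by log-normal per-sample multipliers (CV from the
#' template), retention times jittered with Gaussian noise, plus white
#' baseline noise.
#'
#' @param n_samples Number of samples.
#' @param truth A [synthetic_truth()] supplying `peak_templates`.
#' @param rt_jitter_sd Retention-time jitter sd in minutes (>= 0).
#' @param baseline_noise_sd Baseline noise sd in signal units (>= 0).
#' @param seed Integer seed.
#' @param t_max Run length in minutes (default 50).
#' @param dt Sampling interval in minutes (default 0.02).
#' @param peak_sd Gaussian peak width sd in minutes (default 0.12).
#' @return Long tibble: `sample_id`, `time`, `signal`.
#' @export
gen_chromatograms <- function(n_samples, truth, rt_jitter_sd = 0.05,
                              baseline_noise_sd = 0.05, seed = 1,
                              t_max = 50, dt = 0.02, peak_sd = 0.12) {
  if (rt_jitter_sd < 0 || baseline_noise_sd < 0)
    stop("rt_jitter_sd and baseline_noise_sd must be non-negative")
  tpl <- truth$peak_templates
  stopifnot(nrow(tpl) > 0, all(tpl$rt >= 0), all(tpl$rt <= t_max))
  set.seed(seed)
  time <- seq(0, t_max, by = dt)
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    sig <- rep(0, length(time))
    # log-normal multiplier with the template CV: sdlog^2 = log(1 + cv^2)
    sdlog <- sqrt(log(1 + tpl$cv^2))
    mult <- stats::rlnorm(nrow(tpl), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    rts <- tpl$rt + stats::rnorm(nrow(tpl), sd = rt_jitter_sd)
    for (p in seq_len(nrow(tpl))) {
      a <- tpl$area[p] * mult[p]
      sig <- sig + a * stats::dnorm(time, mean = rts[p], sd = peak_sd)
    }
    if (baseline_noise_sd > 0)
      sig <- sig + stats::rnorm(length(time), sd = baseline_noise_sd)
    out[[s]] <- tibble::tibble(sample_id = sprintf("S%02d", s),
                               time = time, signal = sig)
  }
  dplyr::bind_rows(out)
}

#' Default sparse linear models for the functional-factor table
#'
#' Each factor depends on at most three layers of the stack, with
#' coefficients large relative to the noise sd so that stepwise selection
#' can recover the support.
#'
#' @param stack An `env_stack`.
#' @param n_factors Number of functional factors (default 6).
#' @param seed Integer seed for drawing supports and coefficients.
#' @return Named list of `list(intercept, coefficients, sd)` models.
#' @export
default_factor_models <- function(stack, n_factors = 6, seed = 1) {
  set.seed(seed)
  cont <- names(stack$layers)[vapply(stack$layers, function(l)
    l$kind == "continuous", logical(1))]
  models <- list()
  for (i in seq_len(n_factors)) {
    k <- sample(1:3, 1)
    sup <- sample(cont, k)
    coefs <- stats::setNames(sample(c(-1, 1), k, TRUE) * stats::runif(k, 1, 3), sup)
    models[[sprintf("factor%02d", i)]] <-
      list(intercept = stats::runif(1, 5, 50), coefficients = coefs, sd = 0.2)
  }
  models
}

#' Generate a functional-factor concentration table at sample points
#'
#' Per sample, each factor equals intercept + Sum coef * (layer value at
#' the sample's cell) + Gaussian noise, with coefficients taken from
#' `truth$factor_models` (filled with [default_factor_models()] when
#' empty).
#'
#' @param stack An [env_stack()].
#' @param occ Occurrence tibble (`longitude`, `latitude`).
#' @param truth A [synthetic_truth()].
#' @param seed Integer seed.
#' @return List with `table` (tibble: longitude, latitude, one column per
#'   factor) and `truth` (with `factor_models` recorded).
#' @export
gen_functional_factor_table <- function(stack, occ, truth, seed = 1) {
  if (!length(truth$factor_models))
    truth$factor_models <- default_factor_models(stack, seed = seed)
  for (m in truth$factor_models) {
    miss <- setdiff(names(m$coefficients), names(stack$layers))
    if (length(miss)) stop("factor_models reference missing layers: ",
                           paste(miss, collapse = ", "))
  }
  set.seed(seed)
  env <- extract_values(stack, occ)
  env <- env[env$valid, , drop = FALSE]
  out <- tibble::tibble(longitude = env$longitude, latitude = env$latitude)
  for (nm in names(truth$factor_models)) {
    m <- truth$factor_models[[nm]]
    y <- rep(m$intercept, nrow(env))
    for (l in names(m$coefficients)) y <- y + m$coefficients[[l]] * env[[l]]
    if (m$sd > 0) y <- y + stats::rnorm(nrow(env), sd = m$sd)
    out[[nm]] <- y
  }
  list(table = out, truth = truth)
}
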