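# Small fixtures built in code, shared across test files.

# 2x2 layer on a unit degree grid
tiny_layer <- function(values = matrix(c(1, 2, 3, 4), 2),
                       name = "t", kind = "continuous") {
  raster_layer(name, grid_spec(2, 2, 0, 0, 1), values, kind)
}

# n x n stack of k deterministic layers (no randomness)
tiny_stack <- function(n = 5, k = 2) {
  spec <- grid_spec(n, n, 0, 0, 1)
  layers <- lapply(seq_len(k), function(i) {
    v <- matrix(seq_len(n * n) * i / (n * n), n)
    raster_layer(paste0("L", i), spec, v, "continuous")
  })
  env_stack(layers)
}

# default synthetic scene at reduced size for speed
small_scene <- function(seed = 1, nrows = 50, ncols = 50, n_points = 120) {
  g <- gen_env_stack(nrows = nrows, ncols = ncols, n_continuous = 6,
                     n_categorical = 1, smoothness = 5,
                     collinear_pairs = 1, seed = seed)
  o <- gen_occurrences(g$stack, g$truth, n_points = n_points, seed = seed)
  list(stack = g$stack, truth = o$truth, occ = o$occurrences)
}

# presence/background covariate tables from a scene
scene_tables <- function(scene, n_background = 1500, seed = 1) {
  env <- extract_values(scene$stack, scene$occ)
  pres <- env[env$valid, names(scene$stack$layers), drop = FALSE]
  set.seed(seed)
  cells <- sample(which(valid_mask(scene$stack)),
                  min(n_background, sum(valid_mask(scene$stack))))
  bg <- as.data.frame(lapply(scene$stack$layers, function(l) l$values[cells]))
  kinds <- vapply(scene$stack$layers, `[[`, character(1), "kind")
  list(pres = pres, bg = bg, kinds = kinds)
}

# exhaustive Fisher-Jenks oracle: enumerate all contiguous partitions
jenks_oracle_sse <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  sse_of <- function(g) sum((g - mean(g))^2)
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  for (c_ in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, c_], n)
    s <- sum(vapply(seq_len(k), function(i)
      sse_of(x[(bounds[i] + 1):bounds[i + 1]]), numeric(1)))
    if (s < best) best <- s
  }
  best
}

# exact Mann-Whitney two-sided p by full enumeration of arrangements
mw_enumeration_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  u_of <- function(idx) {
    aa <- pool[idx]; bb <- pool[-idx]
    sum(outer(aa, bb, `>`)) + 0.5 * sum(outer(aa, bb, `==`))
  }
  u_obs <- min(u_of(seq_len(n1)), n1 * n2 - u_of(seq_len(n1)))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  us_min <- pmin(us, n1 * n2 - us)
  mean(us_min <= u_obs + 1e-9)
}
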