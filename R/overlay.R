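#' Predict a functional-factor raster from a regression model
#'
#' Cell-wise evaluation of `intercept + sum(coef * layer)`; a cell is
#' masked as soon as any covariate layer is masked there.
#'
#' @param model A [regression_model()].
#' @param stack An [env_stack()] supplying every model covariate as a
#'   layer.
#' @return A [raster_layer()] named after the model response.
#' @export
predict_factor_raster <- function(model, stack) {
  need <- names(model$coefficients)
  miss <- setdiff(need, names(stack$layers))
  if (length(miss)) stop("stack is missing covariate layer(s): ",
                         paste(miss, collapse = ", "))
  s <- stack$spec
  v <- matrix(model$intercept, s$nrows, s$ncols)
  for (nm in need) v <- v + model$coefficients[[nm]] * stack$layers[[nm]]$values
  raster_layer(model$response, s, v, "continuous")
}

#' Min-max normalize a raster layer to [0, 1]
#'
#' Linear rescale over valid cells: the minimum maps to 0, the maximum
#' to 1; invariant to positive affine pre-transforms.
#'
#' @param layer A [raster_layer()] with >= 2 distinct valid values.
#' @param constant_value Substitute for a constant layer; the default
#'   `NULL` makes a constant layer an error.
#' @return The normalized [raster_layer()].
#' @export
minmax_normalize <- function(layer, constant_value = NULL) {
  v <- layer$values
  fin <- v[is.finite(v)]
  rng <- range(fin)
  if (diff(rng) == 0) {
    if (is.null(constant_value))
      stop("layer '", layer$name, "' is constant; cannot min-max normalize")
    v[is.finite(v)] <- constant_value
  } else {
    v <- (v - rng[1]) / diff(rng)
  }
  raster_layer(layer$name, layer$spec, v, "continuous")
}

#' Fuzzy overlay of membership rasters
#'
#' Cell-wise combination of aligned [0, 1] layers: AND = min, OR = max,
#' SUM = 1 - prod(1 - v), PRODUCT = prod(v), GAMMA = SUM^gamma *
#' PRODUCT^(1 - gamma). For every cell PRODUCT <= AND <= each input <=
#' OR <= SUM, and GAMMA lies between PRODUCT and SUM.
#'
#' @param layers List of >= 2 aligned [raster_layer()] objects with
#'   values in [0, 1].
#' @param method One of `"fuzzy_gamma"` (default), `"fuzzy_and"`,
#'   `"fuzzy_or"`, `"fuzzy_sum"`, `"fuzzy_product"`.
#' @param gamma Gamma exponent in [0, 1] (default 0.9); used only by
#'   `fuzzy_gamma`.
#' @return Object of class `quality_map`: a [raster_layer()] named
#'   `"quality"` plus a `provenance` attribute recording inputs, method
#'   and gamma.
#' @export
fuzzy_overlay <- function(layers, method = c("fuzzy_gamma", "fuzzy_and",
                                             "fuzzy_or", "fuzzy_sum",
                                             "fuzzy_product"),
                          gamma = 0.9) {
  method <- match.arg(method)
  stopifnot(length(layers) >= 2,
            all(vapply(layers, inherits, logical(1), "raster_layer")))
  spec <- layers[[1]]$spec
  for (l in layers) {
    stopifnot(specs_aligned(l$spec, spec))
    fin <- l$values[is.finite(l$values)]
    if (any(fin < 0 | fin > 1))
      stop("layer '", l$name, "' has values outside [0, 1]")
  }
  if (method == "fuzzy_gamma") stopifnot(gamma >= 0, gamma <= 1)
  mats <- lapply(layers, `[[`, "values")
  v <- switch(method,
    fuzzy_and = Reduce(pmin, mats),
    fuzzy_or = Reduce(pmax, mats),
    fuzzy_sum = 1 - Reduce(`*`, lapply(mats, function(m) 1 - m)),
    fuzzy_product = Reduce(`*`, mats),
    fuzzy_gamma = {
      s <- 1 - Reduce(`*`, lapply(mats, function(m) 1 - m))
      p <- Reduce(`*`, mats)
      s^gamma * p^(1 - gamma)
    })
  out <- raster_layer("quality", spec, v, "continuous")
  structure(out,
            class = c("quality_map", "raster_layer"),
            provenance = list(
              inputs = vapply(layers, `[[`, character(1), "name"),
              method = method,
              gamma = if (method == "fuzzy_gamma") gamma else NA_real_))
}

#' Mask a quality map by suitability class
#'
#' @param q A `quality_map` (or any [raster_layer()]).
#' @param cmap An aligned `class_map`.
#' @param excluded Class labels to mask (default `"unsuitable"`).
#' @return The map with cells of the excluded classes masked.
#' @export
mask_by_class <- function(q, cmap, excluded = "unsuitable") {
  stopifnot(inherits(cmap, "class_map"), specs_aligned(q$spec, cmap$spec))
  codes <- match(excluded, cmap$labels) - 1
  if (anyNA(codes)) stop("unknown class label(s): ",
                         paste(excluded[is.na(codes)], collapse = ", "))
  v <- q$values
  v[cmap$classes %in% codes] <- NA_real_
  out <- raster_layer(q$name, q$spec, v, q$kind)
  attributes_keep <- attr(q, "provenance")
  structure(out, class = class(q),
            provenance = c(attributes_keep,
                           list(masked_classes = excluded)))
}

#' Functional-factor subsets for quality zoning
#'
#' @param categories Named character vector: factor name -> category
#'   (`"index"`, `"effective"`, `"peak"`, `"nutritional"`).
#' @param subset `"medicinal"` (fingerprint peaks + index components +
#'   effective compound groups), `"edible"` (nutritional components and
#'   elements) or `"comprehensive"` (all).
#' @return Character vector of factor names.
#' @export
factor_subset <- function(categories,
                          subset = c("comprehensive", "medicinal", "edible")) {
  subset <- match.arg(subset)
  keep <- switch(subset,
                 comprehensive = unique(categories),
                 medicinal = c("peak", "index", "effective"),
                 edible = "nutritional")
  names(categories)[categories %in% keep]
}

#' Compose a quality-zoning map
#'
#' Predicts each subset factor's concentration raster from its regression
#' model, min-max normalizes every prediction to [0, 1], fuzzily overlays
#' them together with the (already [0, 1]) suitability layer, and masks
#' the unsuitable class. Permutation-invariant in the factor list.
#'
#' @param models Named list of [regression_model()] objects.
#' @param stack An [env_stack()] supplying the model covariates.
#' @param suitability Suitability [raster_layer()] in [0, 1].
#' @param cmap A `class_map` of the suitability raster.
#' @param subset Factor subset (see [factor_subset()]); either a subset
#'   name resolved against `categories`, or a character vector of model
#'   names.
#' @param categories Factor categories (required when `subset` is a
#'   subset name).
#' @param method,gamma Overlay parameters (see [fuzzy_overlay()]).
#' @param excluded Classes masked from the final map.
#' @return A `quality_map` with full provenance.
#' @export
compose_zoning <- function(models, stack, suitability, cmap,
                           subset = "comprehensive", categories = NULL,
                           method = "fuzzy_gamma", gamma = 0.9,
                           excluded = "unsuitable") {
  if (length(subset) == 1 &&
      subset %in% c("comprehensive", "medicinal", "edible")) {
    if (is.null(categories)) stop("categories required to resolve subset '",
                                  subset, "'")
    wanted <- factor_subset(categories, subset)
  } else wanted <- subset
  wanted <- intersect(names(models), wanted)
  if (!length(wanted)) stop("empty factor subset")
  layers <- lapply(models[wanted], function(m)
    minmax_normalize(predict_factor_raster(m, stack)))
  q <- fuzzy_overlay(c(layers, list(suitability)), method = method,
                     gamma = gamma)
  mask_by_class(q, cmap, excluded = excluded)
}
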