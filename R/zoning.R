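#' Classify a suitability raster with fixed breaks
#'
#' The four habitat classes are cut at the given thresholds with
#' half-open intervals, upper class closed at 1: unsuitable [0, b1),
#' low [b1, b2), moderate [b2, b3), high [b3, 1]. Masked cells stay
#' masked.
#'
#' @param suitability A [raster_layer()] with values in [0, 1].
#' @param breaks Ascending thresholds strictly inside (0, 1); default
#'   `c(0.1, 0.3, 0.6)`.
#' @return Object of class `class_map`: `spec`, `classes` (integer matrix,
#'   codes 0-3, NA masked), `breaks`, `labels`.
#' @export
classify_fixed_breaks <- function(suitability, breaks = c(0.1, 0.3, 0.6)) {
  stopifnot(inherits(suitability, "raster_layer"),
            all(diff(breaks) > 0), all(breaks > 0), all(breaks < 1))
  v <- suitability$values
  fin <- is.finite(v)
  if (any(v[fin] < 0 | v[fin] > 1))
    stop("suitability values outside [0, 1]")
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  cls[fin] <- rowSums(outer(v[fin], breaks, `>=`))
  n_cls <- length(breaks) + 1
  labels <- if (n_cls == 4) c("unsuitable", "low", "moderate", "high")
            else paste0("class", seq_len(n_cls) - 1)
  structure(list(spec = suitability$spec, classes = cls, breaks = breaks,
                 labels = labels),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(x$classes, levels = seq_along(x$labels) - 1,
                      labels = x$labels))
  cat("<class_map> breaks", paste(x$breaks, collapse = "/"), "cells:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Fisher-Jenks natural breaks
#'
#' Exact dynamic program minimizing the total within-class sum of squared
#' deviations of a 1-D partition into `n_classes` contiguous classes of
#' the sorted values.
#'
#' @param values Numeric vector with at least `n_classes` distinct values.
#' @param n_classes Number of classes (k >= 1).
#' @return Ascending numeric vector of `n_classes - 1` thresholds; a value
#'   v belongs to class i when `breaks[i-1] <= v < breaks[i]` with the
#'   thresholds placed at the lower edge of each upper class.
#' @export
jenks_breaks <- function(values, n_classes) {
  x <- sort(values[is.finite(values)])
  n <- length(x)
  k <- as.integer(n_classes)
  stopifnot(k >= 1)
  if (length(unique(x)) < k)
    stop("need at least ", k, " distinct values, got ", length(unique(x)))
  if (k == 1) return(numeric(0))
  # prefix sums give O(1) within-class SSE of x[i..j]
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)     # cost[c, j]: best SSE of x[1..j] in c classes
  back <- matrix(0L, k, n)      # start index of the last class
  for (j in seq_len(n)) { cost[1, j] <- sse(1, j); back[1, j] <- 1L }
  for (c_ in 2:k) {
    for (j in c_:n) {
      best <- Inf; bi <- c_
      for (i in c_:j) {
        v <- cost[c_ - 1, i - 1] + sse(i, j)
        if (v < best) { best <- v; bi <- i }
      }
      cost[c_, j] <- best; back[c_, j] <- as.integer(bi)
    }
  }
  starts <- integer(k)
  j <- n
  for (c_ in k:1) { starts[c_] <- back[c_, j]; j <- starts[c_] - 1L }
  x[starts[-1]]
}

#' Within-class sum of squared deviations of a break set
#'
#' @param values Numeric vector.
#' @param breaks Ascending thresholds (lower edges of the upper classes).
#' @return Total within-class SSE.
#' @export
breaks_sse <- function(values, breaks) {
  cls <- rowSums(outer(values, breaks, `>=`))
  sum(unlist(lapply(split(values, cls), function(g) sum((g - mean(g))^2))))
}

#' Zonal areas of a class map
#'
#' Cell areas are latitude-corrected for degree grids (cosine of the
#' row-centre latitude) and flat for metre grids.
#'
#' @param cmap A `class_map`.
#' @param units `"degrees"` (default) or `"metres"`.
#' @return Tibble: `class` (label), `cells`, `area_km2`, `fraction_pct`
#'   (of total valid area, summing to 100).
#' @export
class_areas <- function(cmap, units = c("degrees", "metres")) {
  units <- match.arg(units)
  row_area <- cell_area_km2(cmap$spec, units)
  area_of <- function(code) {
    hit <- cmap$classes == code
    hit[is.na(hit)] <- FALSE
    sum(rowSums(hit) * row_area)
  }
  codes <- seq_along(cmap$labels) - 1
  areas <- vapply(codes, area_of, numeric(1))
  cells <- vapply(codes, function(c_) sum(cmap$classes == c_, na.rm = TRUE),
                  numeric(1))
  tibble::tibble(class = cmap$labels, cells = as.integer(cells),
                 area_km2 = areas,
                 fraction_pct = 100 * areas / sum(areas))
}

#' Percent change rate between current and future zonal areas
#'
#' @param current_area Current area (> 0).
#' @param future_area Future area.
#' @return `100 * (future - current) / current`.
#' @export
change_rate <- function(current_area, future_area) {
  if (any(current_area <= 0)) stop("current_area must be positive")
  100 * (future_area - current_area) / current_area
}

#' Compare current and future class maps
#'
#' @param current,future Aligned `class_map` objects.
#' @param units Area units (see [class_areas()]).
#' @return Object of class `scenario_comparison`: `areas` (tibble: class,
#'   current_area_km2, future_area_km2, change_rate_pct) and `transitions`
#'   (square matrix of cell counts, rows = current class, cols = future
#'   class; row sums equal current class cell counts).
#' @export
scenario_compare <- function(current, future, units = "degrees") {
  stopifnot(inherits(current, "class_map"), inherits(future, "class_map"),
            specs_aligned(current$spec, future$spec))
  a_cur <- class_areas(current, units)
  a_fut <- class_areas(future, units)
  areas <- tibble::tibble(
    class = a_cur$class,
    current_area_km2 = a_cur$area_km2,
    future_area_km2 = a_fut$area_km2,
    change_rate_pct = ifelse(a_cur$area_km2 > 0,
                             100 * (a_fut$area_km2 - a_cur$area_km2) / a_cur$area_km2,
                             NA_real_))
  both <- is.finite(current$classes) & is.finite(future$classes)
  lv <- seq_along(current$labels) - 1
  trans <- table(factor(current$classes[both], levels = lv),
                 factor(future$classes[both], levels = lv))
  dimnames(trans) <- list(current = current$labels, future = future$labels)
  structure(list(areas = areas, transitions = unclass(trans)),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison>\n")
  print(as.data.frame(x$areas))
  invisible(x)
}

#' Plot a class map
#'
#' @param object A `class_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot class_map
#' @export
autoplot.class_map <- function(object, ...) {
  lyr <- raster_layer("class", object$spec,
                      matrix(as.numeric(object$classes),
                             object$spec$nrows), "continuous")
  df <- as_tibble.raster_layer(lyr)
  df$class <- factor(df$value, levels = seq_along(object$labels) - 1,
                     labels = object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$longitude, y = .data$latitude,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_d(na.value = "grey90", drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "suitability class")
}
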