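#' Detect peaks in a chromatogram
#'
#' Finds local maxima above a height threshold whose topographic
#' prominence exceeds `min_prominence`. Peak bounds are placed at the
#' enclosing prominence minima; the area is the trapezoidal integral of
#' the baseline-subtracted signal between the bounds, the baseline being
#' the straight segment joining the bound points.
#'
#' @param time Strictly increasing time grid (minutes), >= 3 points.
#' @param signal Detector signal, same length, finite.
#' @param min_height Minimum apex height above zero.
#' @param min_prominence Minimum prominence (default `min_height / 2`).
#' @return Tibble (possibly empty): `rt`, `height`, `area`, `left`,
#'   `right`, sorted by `rt`; areas are positive.
#' @export
detect_peaks <- function(time, signal, min_height = 0.5,
                         min_prominence = min_height / 2) {
  stopifnot(length(time) >= 3, length(time) == length(signal),
            all(diff(time) > 0), all(is.finite(signal)))
  n <- length(signal)
  apex <- which(signal[2:(n - 1)] > signal[1:(n - 2)] &
                  signal[2:(n - 1)] >= signal[3:n]) + 1L
  apex <- apex[signal[apex] >= min_height]
  out <- list()
  for (i in apex) {
    # walk out to the nearest higher point on each side; the prominence
    # saddle is the minimum along each walk
    l <- i; lmin <- i
    while (l > 1 && signal[l - 1] <= signal[i]) {
      l <- l - 1L
      if (signal[l] < signal[lmin]) lmin <- l
    }
    r <- i; rmin <- i
    while (r < n && signal[r + 1] <= signal[i]) {
      r <- r + 1L
      if (signal[r] < signal[rmin]) rmin <- r
    }
    saddle <- max(signal[lmin], signal[rmin])
    if (l == 1 && r == n) saddle <- min(signal[lmin], signal[rmin])
    prom <- signal[i] - saddle
    if (prom < min_prominence) next
    lb <- lmin; rb <- rmin
    seg <- lb:rb
    base <- signal[lb] + (signal[rb] - signal[lb]) *
      (time[seg] - time[lb]) / (time[rb] - time[lb])
    y <- pmax(signal[seg] - base, 0)
    area <- sum(diff(time[seg]) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    if (area <= 0) next
    out[[length(out) + 1]] <- tibble::tibble(
      rt = time[i], height = signal[i], area = area,
      left = time[lb], right = time[rb])
  }
  if (!length(out))
    return(tibble::tibble(rt = numeric(), height = numeric(),
                          area = numeric(), left = numeric(),
                          right = numeric()))
  dplyr::arrange(dplyr::bind_rows(out), .data$rt)
}

#' Detect peaks for every sample of a long chromatogram table
#'
#' @param chrom Long tibble: `sample_id`, `time`, `signal`.
#' @param ... Passed to [detect_peaks()].
#' @return Tibble of peaks with a `sample_id` column.
#' @export
detect_peaks_all <- function(chrom, ...) {
  parts <- split(chrom, chrom$sample_id)
  dplyr::bind_rows(lapply(names(parts), function(id) {
    p <- detect_peaks(parts[[id]]$time, parts[[id]]$signal, ...)
    if (nrow(p)) dplyr::bind_cols(tibble::tibble(sample_id = id), p) else NULL
  }))
}

#' Multi-point retention-time correction
#'
#' For each sample, its peaks nearest to each anchor time (within
#' `window`) are matched and a piecewise-linear monotone time warp is fit
#' through the matched (sample, anchor) pairs and applied to all of the
#' sample's retention times. Samples matching fewer than two anchors are
#' left uncorrected with a warning.
#'
#' @param peaks Peak tibble with `sample_id`, `rt` columns (other columns
#'   carried through).
#' @param anchors Ascending reference retention times (>= 2, spanning the
#'   run).
#' @param window Matching half-window in minutes (default 0.5).
#' @return The peak tibble with corrected `rt` (original kept as
#'   `rt_raw`).
#' @export
rt_correct <- function(peaks, anchors, window = 0.5) {
  stopifnot(length(anchors) >= 2, all(diff(anchors) > 0))
  fix_one <- function(df, key) {
    obs <- vapply(anchors, function(a) {
      d <- abs(df$rt - a)
      if (min(d) <= window) df$rt[which.min(d)] else NA_real_
    }, numeric(1))
    ok <- !is.na(obs)
    df$rt_raw <- df$rt
    if (sum(ok) < 2) {
      warning("sample ", key$sample_id[1],
              ": fewer than 2 anchors matched; left uncorrected")
      return(df)
    }
    # monotone piecewise-linear map observed -> reference, extrapolating
    # with the end slopes
    warp <- stats::approxfun(obs[ok], anchors[ok], rule = 2)
    rt_new <- warp(df$rt)
    # rule = 2 clamps outside the anchor span; extend linearly instead
    o <- obs[ok]; a <- anchors[ok]
    sl_lo <- (a[2] - a[1]) / (o[2] - o[1])
    kk <- length(o)
    sl_hi <- (a[kk] - a[kk - 1]) / (o[kk] - o[kk - 1])
    lo <- df$rt < o[1]; hi <- df$rt > o[kk]
    rt_new[lo] <- a[1] + sl_lo * (df$rt[lo] - o[1])
    rt_new[hi] <- a[kk] + sl_hi * (df$rt[hi] - o[kk])
    df$rt <- rt_new
    df
  }
  peaks |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(fix_one) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, .data$rt)
}

#' Match common peaks across samples
#'
#' Greedy single-pass clustering of all peaks by corrected retention
#' time: peaks sorted by rt are grouped while the running cluster span
#' stays within `rt_window`. A cluster is a *common peak* iff it contains
#' exactly one peak from every sample (the standard fingerprint
#' convention: present in 100 percent of samples).
#'
#' @param peaks Peak tibble: `sample_id`, `rt`, `area`.
#' @param rt_window Maximum cluster width in minutes (default 0.3).
#' @return Object of class `common_peak_matrix`: `areas` (matrix, rows =
#'   samples, cols = common peaks, all entries > 0), `consensus_rt`
#'   (mean rt per column, ascending), `samples`.
#' @export
match_common_peaks <- function(peaks, rt_window = 0.3) {
  samples <- sort(unique(peaks$sample_id))
  stopifnot(length(samples) >= 2)
  p <- peaks[order(peaks$rt), ]
  cluster <- integer(nrow(p))
  cid <- 0L; start_rt <- -Inf
  for (i in seq_len(nrow(p))) {
    if (p$rt[i] - start_rt > rt_window) { cid <- cid + 1L; start_rt <- p$rt[i] }
    cluster[i] <- cid
  }
  p$cluster <- cluster
  common <- p |>
    dplyr::group_by(.data$cluster) |>
    dplyr::filter(dplyr::n() == length(samples),
                  dplyr::n_distinct(.data$sample_id) == length(samples)) |>
    dplyr::ungroup()
  if (!nrow(common))
    stop("no common peaks found; try a larger rt_window")
  wide <- common |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(consensus_rt = mean(.data$rt)) |>
    dplyr::ungroup()
  rts <- sort(unique(wide$consensus_rt))
  m <- matrix(NA_real_, length(samples), length(rts),
              dimnames = list(samples, sprintf("P%02d", seq_along(rts))))
  for (k in seq_along(rts)) {
    sub <- wide[wide$consensus_rt == rts[k], ]
    m[sub$sample_id, k] <- sub$area
  }
  stopifnot(all(is.finite(m)), all(m > 0))
  structure(list(areas = m, consensus_rt = rts, samples = samples),
            class = "common_peak_matrix")
}

#' @export
print.common_peak_matrix <- function(x, ...) {
  cat(sprintf("<common_peak_matrix> %d samples x %d common peaks (rt %.1f-%.1f min)\n",
              nrow(x$areas), ncol(x$areas), min(x$consensus_rt),
              max(x$consensus_rt)))
  invisible(x)
}

#' Reference (control) fingerprint vector
#'
#' @param m A `common_peak_matrix`.
#' @param method `"median"` (robust default) or `"mean"`.
#' @return Named numeric vector of consensus areas, one per common peak.
#' @export
reference_vector <- function(m, method = c("median", "mean")) {
  method <- match.arg(method)
  apply(m$areas, 2, method)
}

#' Included-angle cosine similarity of two fingerprint vectors
#'
#' @param a,b Same-length nonzero numeric vectors.
#' @return `a . b / (|a| |b|)`; in [0, 1] for nonnegative vectors.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Pairwise similarity matrix with the reference fingerprint
#'
#' @param m A `common_peak_matrix`.
#' @param method Similarity: `"cosine"` (default, the included-angle
#'   measure) or `"correlation"` (Pearson on the area vectors).
#' @param reference Reference aggregation passed to [reference_vector()].
#' @return Symmetric matrix over samples plus a final row/column `R` for
#'   the reference; unit diagonal.
#' @export
similarity_matrix <- function(m, method = c("cosine", "correlation"),
                              reference = "median") {
  method <- match.arg(method)
  vecs <- rbind(m$areas, R = reference_vector(m, reference))
  simfun <- if (method == "cosine") cosine_similarity
            else function(a, b) stats::cor(a, b)
  n <- nrow(vecs)
  S <- matrix(1, n, n, dimnames = list(rownames(vecs), rownames(vecs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    S[i, j] <- S[j, i] <- simfun(vecs[i, ], vecs[j, ])
  }
  S
}

#' PCA marker-peak selection from a common-peak matrix
#'
#' Columns are standardized and the correlation matrix
#' eigen-decomposed; components with eigenvalue >= `eig_min` are
#' retained, loadings are eigenvectors scaled by the square root of their
#' eigenvalue, and a peak is selected when the absolute loading on any
#' retained component exceeds `loading_min`.
#'
#' @param m A `common_peak_matrix` (>= 3 samples, >= 2 peaks).
#' @param eig_min Eigenvalue retention threshold (default 1).
#' @param loading_min Absolute-loading selection threshold (default 0.8).
#' @return Object of class `pca_selection`: `eigenvalues`,
#'   `cumulative_variance_pct`, `n_retained`, `loadings` (peaks x
#'   retained components), `selected_peaks`.
#' @export
pca_select_peaks <- function(m, eig_min = 1.0, loading_min = 0.8) {
  A <- m$areas
  stopifnot(nrow(A) >= 3, ncol(A) >= 2)
  sds <- apply(A, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant peak column(s): ",
            paste(colnames(A)[sds == 0], collapse = ", "))
    A <- A[, sds > 0, drop = FALSE]
  }
  R <- stats::cor(A)
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  keep <- which(ev >= eig_min)
  if (!length(keep)) keep <- 1L
  load <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]),
                                                   length(keep))
  dimnames(load) <- list(colnames(A), paste0("PC", keep))
  sel <- rownames(load)[apply(abs(load) > loading_min, 1, any)]
  structure(list(eigenvalues = ev,
                 cumulative_variance_pct = 100 * cumsum(ev) / sum(ev),
                 n_retained = length(keep),
                 loadings = load, selected_peaks = sel),
            class = "pca_selection")
}

#' @export
print.pca_selection <- function(x, ...) {
  cat(sprintf("<pca_selection> %d component(s) retained (cumulative %.1f%%); %d peak(s) selected: %s\n",
              x$n_retained, x$cumulative_variance_pct[x$n_retained],
              length(x$selected_peaks),
              paste(x$selected_peaks, collapse = ", ")))
  invisible(x)
}
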