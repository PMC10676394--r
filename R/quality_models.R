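#' Mann-Whitney U test
#'
#' U counts the (a, b) pairs where a exceeds b, ties half-weighted; the
#' reported statistic is `min(U, n1*n2 - U)`. The p value is exact (full
#' null distribution of U computed by dynamic programming) when
#' `n1 * n2 <= 400` and there are no ties, and a normal approximation
#' with tie and continuity correction otherwise. Two-sided.
#'
#' @param a,b Non-empty numeric vectors.
#' @return Tibble: `U`, `p`, `method` ("exact" or "normal"), `direction`
#'   (+1 when a tends larger, -1 smaller, 0 tied).
#' @export
mann_whitney_u <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(a, b))
  U_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # pairs where a > b (+ half ties)
  M <- n1 * n2
  U <- min(U_a, M - U_a)
  ties <- any(duplicated(c(a, b)))
  if (!ties && M <= 400) {
    counts <- u_null_counts(n1, n2)
    tot <- choose(n1 + n2, n1)
    p <- min(1, 2 * sum(counts[seq_len(U + 1)]) / tot)
    method <- "exact"
  } else {
    nt <- n1 + n2
    tie_tab <- table(c(a, b))
    sigma2 <- M / 12 * ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - M / 2 + 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z))
    }
    method <- "normal"
  }
  tibble::tibble(U = U, p = p, method = method,
                 direction = sign(U_a - M / 2))
}

# Null distribution of U for sample sizes (m, n): counts[u + 1] = number
# of rank arrangements with statistic u, u = 0..m*n. Recurrence
# c(m, n, u) = c(m - 1, n, u - n) + c(m, n - 1, u).
u_null_counts <- function(m, n) {
  prev <- lapply(0:n, function(j) 1)           # m = 0: mass at u = 0
  for (i in seq_len(m)) {
    cur <- vector("list", n + 1)
    cur[[1]] <- 1
    for (j in seq_len(n)) {
      shifted <- c(rep(0, j), prev[[j + 1]])   # length (i-1)*j + 1 + j
      grown <- c(cur[[j]], rep(0, i))          # length i*(j-1) + 1 + i
      cur[[j + 1]] <- shifted + grown          # both length i*j + 1
    }
    prev <- cur
  }
  prev[[n + 1]]
}

#' Compare a functional factor between suitability groups
#'
#' @param table Data frame with a factor column and a `class` column.
#' @param factor_name Column to compare.
#' @param classes Two class labels, default `c("high", "moderate")`.
#' @return One-row tibble: factor, group sizes, U, p, direction.
#' @export
compare_groups <- function(table, factor_name,
                           classes = c("high", "moderate")) {
  a <- table[[factor_name]][table$class == classes[1]]
  b <- table[[factor_name]][table$class == classes[2]]
  res <- mann_whitney_u(a, b)
  tibble::tibble(factor = factor_name, n_1 = length(a), n_2 = length(b),
                 U = res$U, p = res$p, direction = res$direction)
}

#' Construct a linear regression model object
#'
#' The exact-arithmetic container behind both stepwise fits and printed
#' published equations: an intercept plus named coefficients.
#'
#' @param response Response name.
#' @param intercept Numeric intercept.
#' @param coefficients Named numeric vector (possibly empty).
#' @param stats Optional list of fit statistics (r.squared, f_p,
#'   coef_p, n).
#' @return Object of class `regression_model`.
#' @export
regression_model <- function(response, intercept, coefficients = numeric(),
                             stats = NULL) {
  if (anyDuplicated(names(coefficients)))
    stop("duplicate covariate names")
  structure(list(response = response, intercept = as.numeric(intercept),
                 coefficients = coefficients, stats = stats),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  terms <- if (length(x$coefficients))
    paste(sprintf("%+.3f*%s", x$coefficients, names(x$coefficients)),
          collapse = " ")
  else ""
  cat(sprintf("<regression_model> %s = %.3f %s\n", x$response, x$intercept,
              terms))
  invisible(x)
}

#' Evaluate a regression model at a covariate vector
#'
#' @param model A [regression_model()].
#' @param x Named numeric vector or one-row data frame supplying every
#'   model covariate.
#' @return `intercept + sum(coef * x)`.
#' @export
evaluate_regression <- function(model, x) {
  x <- unlist(x)
  miss <- setdiff(names(model$coefficients), names(x))
  if (length(miss)) stop("covariate(s) missing from x: ",
                         paste(miss, collapse = ", "))
  model$intercept + sum(model$coefficients * x[names(model$coefficients)])
}

#' SPSS-style stepwise ordinary least squares
#'
#' Forward step: among candidates not yet included, add the one with the
#' smallest partial-F p value if below `p_enter`. Backward step after
#' every addition: remove any included covariate whose p value exceeds
#' `p_remove`. Repeats to a fixed point; the final model is refit by OLS.
#' A candidate perfectly collinear with the included set never enters
#' (its partial F is undefined and it is skipped).
#'
#' @param y Response vector.
#' @param X Data frame of candidate covariates (syntactic names).
#' @param p_enter Probability-of-F-to-enter (default 0.05).
#' @param p_remove Probability-of-F-to-remove (default 0.10).
#' @return A [regression_model()] with fit statistics (`r.squared`,
#'   `f_p`, `coef_p`, `n`); empty model (intercept = mean(y)) when
#'   nothing enters.
#' @export
stepwise_ols <- function(y, X, p_enter = 0.05, p_remove = 0.10) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  included <- character()
  coef_p <- function(vars) {
    d <- data.frame(.y = y, X[vars])
    fit <- stats::lm(.y ~ ., data = d)
    ct <- stats::summary.lm(fit)$coefficients
    list(fit = fit, ct = ct)
  }
  repeat {
    changed <- FALSE
    cand <- setdiff(names(X), included)
    if (length(cand)) {
      pv <- vapply(cand, function(v) {
        ct <- coef_p(c(included, v))$ct
        if (!(v %in% rownames(ct))) NA_real_ else ct[v, 4]
      }, numeric(1))
      pv <- pv[!is.na(pv)]
      if (length(pv) && min(pv) < p_enter) {
        included <- c(included, names(pv)[which.min(pv)])
        changed <- TRUE
        repeat {     # backward sweep after each entry
          if (!length(included)) break
          ct <- coef_p(included)$ct
          pv_in <- ct[intersect(included, rownames(ct)), 4, drop = TRUE]
          pv_in <- stats::setNames(as.numeric(pv_in),
                                   intersect(included, rownames(ct)))
          if (length(pv_in) && max(pv_in) > p_remove) {
            included <- setdiff(included, names(pv_in)[which.max(pv_in)])
          } else break
        }
      }
    }
    if (!changed) break
  }
  if (!length(included)) {
    return(regression_model(".y", mean(y),
                            stats = list(r.squared = 0, f_p = NA_real_,
                                         coef_p = numeric(), n = length(y))))
  }
  res <- coef_p(included)
  sm <- stats::summary.lm(res$fit)
  f_p <- if (!is.null(sm$fstatistic))
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE) else NA_real_
  cf <- stats::coef(res$fit)
  regression_model(".y", cf[["(Intercept)"]], cf[included],
                   stats = list(r.squared = sm$r.squared,
                                f_p = unname(f_p),
                                coef_p = res$ct[included, 4],
                                n = length(y)))
}

#' Tidy a regression model
#'
#' @param x A `regression_model`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (intercept first), `p.value` when
#'   fitted.
#' @method tidy regression_model
#' @export
tidy.regression_model <- function(x, ...) {
  out <- tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                        estimate = c(x$intercept, unname(x$coefficients)))
  if (!is.null(x$stats$coef_p))
    out$p.value <- c(NA_real_, unname(x$stats$coef_p[names(x$coefficients)]))
  out
}

#' One-row summary of a regression model
#'
#' @param x A `regression_model`.
#' @param ... Unused.
#' @return Tibble: `r.squared`, `f_p`, `n_terms`, `n`.
#' @method glance regression_model
#' @export
glance.regression_model <- function(x, ...) {
  tibble::tibble(r.squared = x$stats$r.squared %||% NA_real_,
                 f_p = x$stats$f_p %||% NA_real_,
                 n_terms = length(x$coefficients),
                 n = x$stats$n %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read regression models from a JSON file
#'
#' The JSON format is a list with `covariates` (ordered names mapped to
#' the generic X1..Xk symbols), optional `categories` (factor -> subset
#' label), and `models`, each with `response`, `intercept` and a
#' `coefficients` array aligned with `covariates`.
#'
#' @param path JSON path; default the packaged table of published
#'   ecology-to-functional-factor equations.
#' @return List: `covariates`, `categories`, `models` (named list of
#'   [regression_model()]).
#' @export
read_regression_models <- function(path = system.file(
  "extdata", "table4_models.json", package = "pharmaniche")) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(seq_len(nrow(j$models)), function(i) {
    co <- stats::setNames(as.numeric(j$models$coefficients[[i]]),
                          j$covariates)
    regression_model(j$models$response[i], j$models$intercept[i], co)
  })
  names(models) <- j$models$response
  list(covariates = j$covariates,
       categories = unlist(j$categories),
       models = models)
}

#' Spearman correlation of ecological vs functional factors
#'
#' Rank-transform (average ranks for ties) then Pearson on the ranks;
#' p values from the t approximation; significance flags at 0.05 and
#' 0.01. Also returns the ecological-factor self-correlation used by
#' [cluster_factors()].
#'
#' @param eco Data frame of ecological covariates at the samples.
#' @param func Data frame of functional factors (same rows).
#' @return Object of class `correlation_cluster_report`: `rho` (eco x
#'   func), `p`, `sig` (character matrix: "", "*", "**"), `eco_rho`
#'   (eco x eco).
#' @export
spearman_matrix <- function(eco, func) {
  eco <- as.data.frame(eco); func <- as.data.frame(func)
  n <- nrow(eco)
  stopifnot(n >= 5, nrow(func) == n)
  rho <- stats::cor(apply(eco, 2, rank), apply(func, 2, rank))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  sig <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  sig[p < 0.05] <- "*"; sig[p < 0.01] <- "**"
  structure(list(rho = rho, p = p, sig = sig,
                 eco_rho = stats::cor(apply(eco, 2, rank))),
            class = "correlation_cluster_report")
}

#' @export
print.correlation_cluster_report <- function(x, ...) {
  cat(sprintf("<correlation_cluster_report> %d ecological x %d functional factors; %d significant at 0.05\n",
              nrow(x$rho), ncol(x$rho), sum(x$p < 0.05)))
  invisible(x)
}

#' Cluster factors by correlation structure
#'
#' Average-linkage hierarchical clustering on the distance `1 - |rho|`,
#' cut at `k` clusters.
#'
#' @param corr Symmetric correlation matrix with dimnames.
#' @param k Number of clusters (default 3).
#' @return Named integer vector of cluster assignments.
#' @export
cluster_factors <- function(corr, k = 3) {
  stopifnot(isSymmetric(unname(corr)), k >= 1, k <= nrow(corr))
  d <- stats::as.dist(1 - abs(corr))
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}

#' Plot a Spearman correlation report as a heat map
#'
#' @param object A `correlation_cluster_report`.
#' @param ... Unused.
#' @return A ggplot tile map with significance stars.
#' @method autoplot correlation_cluster_report
#' @export
autoplot.correlation_cluster_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$rho))
  names(df) <- c("eco", "func", "rho")
  df$sig <- as.vector(object$sig)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$func, y = .data$eco,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
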