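#' Iteratively drop zero-contribution factors
#'
#' Repeats {fit a maxent model; drop every layer whose percent
#' contribution falls below `eps`} until no layer is dropped or a single
#' layer remains. The surviving set shrinks monotonically, so the loop
#' always terminates.
#'
#' @param presences,background Covariate data frames over the candidate
#'   layers.
#' @param kinds Layer kinds (see [feature_expansion()]).
#' @param eps Contribution threshold in percent (default 0.05).
#' @param ... Passed to [fit_maxent()].
#' @return List: `surviving` (character), `dropped_zero` (tibble: layer,
#'   iteration), `model` (final fit), `contributions` (final tibble).
#' @export
iterate_drop_zero <- function(presences, background, kinds = NULL,
                              eps = 0.05, ...) {
  layers <- intersect(names(presences), names(background))
  stopifnot(length(layers) >= 2)
  dropped <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    m <- fit_maxent(presences[layers], background[layers],
                    kinds = kinds[intersect(names(kinds), layers)], ...)
    pc <- percent_contribution(m)
    zero <- pc$layer[pc$percent_contribution < eps]
    zero <- zero[seq_len(min(length(zero), length(layers) - 1))]
    if (!length(zero)) break
    dropped[[it]] <- tibble::tibble(layer = zero, iteration = it)
    layers <- setdiff(layers, zero)
    if (length(layers) == 1) break
  }
  list(surviving = layers,
       dropped_zero = if (length(dropped)) dplyr::bind_rows(dropped)
                      else tibble::tibble(layer = character(), iteration = integer()),
       model = m, contributions = pc)
}

#' Prune collinear factors, keeping the larger contributor
#'
#' Computes pairwise Pearson correlations among continuous factors and
#' processes every pair with |r| above the threshold in decreasing |r|
#' order; in each pair the member with the smaller percent contribution
#' is dropped (unless one member is already gone). Categorical factors
#' are exempt. The result is independent of input column order.
#'
#' @param values Data frame of factor values (e.g. at presence points).
#' @param contributions Tibble with `layer`, `percent_contribution`.
#' @param r_threshold Correlation threshold in (0, 1), default 0.8.
#' @param categorical Character vector of categorical factor names to
#'   exempt.
#' @return List: `surviving` (character), `dropped_collinear` (tibble:
#'   dropped, kept, r).
#' @export
pearson_prune <- function(values, contributions, r_threshold = 0.8,
                          categorical = character()) {
  stopifnot(r_threshold > 0, r_threshold < 1)
  cont <- setdiff(names(values), categorical)
  pc <- stats::setNames(contributions$percent_contribution, contributions$layer)
  consts <- vapply(values[cont], function(v) stats::sd(v) == 0, logical(1))
  if (any(consts))
    warning("constant column(s) treated as uncorrelated: ",
            paste(cont[consts], collapse = ", "))
  R <- suppressWarnings(stats::cor(values[cont]))
  R[!is.finite(R)] <- 0
  pairs <- which(upper.tri(R) & abs(R) > r_threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-abs(R[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
  }
  alive <- stats::setNames(rep(TRUE, length(names(values))), names(values))
  log <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- cont[pairs[k, 1]]; b <- cont[pairs[k, 2]]
    if (!alive[a] || !alive[b]) next
    drop <- if (pc[a] < pc[b] ||
                (pc[a] == pc[b] && a > b)) a else b   # name order breaks exact ties
    keep <- setdiff(c(a, b), drop)
    alive[drop] <- FALSE
    log[[length(log) + 1]] <- tibble::tibble(
      dropped = drop, kept = keep, r = R[pairs[k, 1], pairs[k, 2]])
  }
  list(surviving = names(alive)[alive],
       dropped_collinear = if (length(log)) dplyr::bind_rows(log)
       else tibble::tibble(dropped = character(), kept = character(),
                           r = numeric()))
}

#' Consensus main factors across three importance rankings
#'
#' Takes the intersection of the top-k factors under percent contribution,
#' permutation importance and jackknife with-only gain, and reports their
#' cumulative percent contribution.
#'
#' @param contribution Tibble with `layer`, `percent_contribution`.
#' @param permutation Tibble with `layer`, `permutation_importance`.
#' @param jackknife Tibble with `layer`, `gain_with_only`.
#' @param top_k Rank depth (default 10).
#' @return List: `main_factors` (character, ordered by contribution),
#'   `cumulative_contribution` (percent).
#' @export
consensus_main_factors <- function(contribution, permutation, jackknife,
                                   top_k = 10) {
  top <- function(tbl, col) {
    tbl <- tbl[order(-tbl[[col]]), ]
    utils::head(tbl$layer, top_k)
  }
  common <- Reduce(intersect, list(top(contribution, "percent_contribution"),
                                   top(permutation, "permutation_importance"),
                                   top(jackknife, "gain_with_only")))
  if (!length(common))
    stop("no common factors among the three top-", top_k,
         " rankings; increase top_k")
  ord <- contribution[order(-contribution$percent_contribution), ]
  main <- ord$layer[ord$layer %in% common]
  list(main_factors = main,
       cumulative_contribution = cumulative_contribution(main, contribution))
}

#' Cumulative percent contribution of a factor set
#'
#' @param factors Character vector of layer names (must appear in
#'   `table`).
#' @param table Tibble with `layer`, `percent_contribution`.
#' @return Sum of the factors' percent contributions.
#' @export
cumulative_contribution <- function(factors, table) {
  if (!length(factors)) return(0)
  miss <- setdiff(factors, table$layer)
  if (length(miss)) stop("factor(s) absent from contribution table: ",
                         paste(miss, collapse = ", "))
  sum(table$percent_contribution[table$layer %in% factors])
}

#' Full variable-selection pipeline
#'
#' Chains the three stages the selection procedure consists of: iterative
#' zero-contribution dropping, collinearity pruning at presence points,
#' and a refit on the survivors whose contribution / permutation /
#' jackknife rankings define the consensus main factors.
#'
#' @param occ Occurrence tibble.
#' @param stack An [env_stack()].
#' @param r_threshold Pearson threshold (default 0.8).
#' @param top_k Consensus rank depth (default 10).
#' @param seed Integer seed (background sampling).
#' @param n_background Background sample size (default 10000).
#' @param eps Zero-contribution threshold in percent.
#' @param ... Passed to [fit_maxent()].
#' @return Object of class `selection_result`: `surviving`,
#'   `dropped_zero`, `dropped_collinear`, `main_factors`,
#'   `cumulative_contribution`, `contributions`, `permutation`,
#'   `jackknife`, `model`.
#' @export
select_factors <- function(occ, stack, r_threshold = 0.8, top_k = 10,
                           seed = 1, n_background = 10000, eps = 0.05, ...) {
  kinds <- vapply(stack$layers, `[[`, character(1), "kind")
  env <- extract_values(stack, occ)
  pres <- env[env$valid, names(stack$layers), drop = FALSE]
  set.seed(seed)
  cells <- which(valid_mask(stack))
  bg_cells <- sample(cells, min(n_background, length(cells)))
  bg <- as.data.frame(lapply(stack$layers, function(l) l$values[bg_cells]))
  st1 <- iterate_drop_zero(pres, bg, kinds = kinds, eps = eps, ...)
  st2 <- pearson_prune(pres[st1$surviving],
                       st1$contributions[st1$contributions$layer %in% st1$surviving, ],
                       r_threshold = r_threshold,
                       categorical = names(kinds)[kinds == "categorical"])
  surv <- st2$surviving
  m <- fit_maxent(pres[surv], bg[surv],
                  kinds = kinds[intersect(names(kinds), surv)], ...)
  pc <- percent_contribution(m)
  pi_ <- permutation_importance(m, pres[surv], bg[surv], seed = seed)
  jk <- if (length(surv) >= 2)
    jackknife_gains(pres[surv], bg[surv],
                    kinds = kinds[intersect(names(kinds), surv)], ...)
  else tibble::tibble(layer = surv, gain_with_only = m$gain, gain_without = 0)
  cons <- consensus_main_factors(pc, pi_, jk, top_k = min(top_k, length(surv)))
  structure(list(surviving = surv,
                 dropped_zero = st1$dropped_zero,
                 dropped_collinear = st2$dropped_collinear,
                 main_factors = cons$main_factors,
                 cumulative_contribution = cons$cumulative_contribution,
                 contributions = pc, permutation = pi_, jackknife = jk,
                 model = m),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d surviving factor(s); %d dropped at zero contribution, %d collinear; %d main factor(s) (cumulative %.1f%%)\n",
              length(x$surviving), nrow(x$dropped_zero),
              nrow(x$dropped_collinear), length(x$main_factors),
              x$cumulative_contribution))
  invisible(x)
}
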