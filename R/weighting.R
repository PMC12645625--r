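#' Post-stratification weights by capped raking
#'
#' Iterative proportional fitting (raking) of respondent weights so that
#' the weighted marginal distribution of each weighting variable matches a
#' target distribution, with a hard cap on the final weight (default 2) to
#' limit variance inflation. The cap is applied after every full IPF cycle
#' and iteration continues (rake-trim-rerake), so margins are matched as
#' closely as the cap allows; a binding cap can leave residual deviations,
#' which are reported rather than hidden. Weights are normalised to mean 1.
#'
#' @param respondents Data.frame holding one column per weighting variable.
#' @param targets Named list: for each weighting variable, a named numeric
#'   vector of target category proportions (each summing to 1).
#' @param cap Maximum weight after normalisation (use `Inf` to disable).
#' @param tol Convergence tolerance on the maximum absolute deviation
#'   between weighted category shares and targets.
#' @param max_iter Maximum number of full IPF cycles.
#' @param initial Starting weights; defaults to the `design_weight` column
#'   when present, else 1.
#' @return An object of class `rake_result`: list with `weights`,
#'   `iterations`, `max_dev`, `n_capped`, `converged`.
#' @examples
#' d <- data.frame(residence = rep(c("urban", "rural"), c(70, 30)))
#' w <- rake(d, list(residence = c(urban = 0.5, rural = 0.5)))
#' tapply(w$weights, d$residence, sum) / sum(w$weights)
#' @export
rake <- function(respondents, targets, cap = 2, tol = 1e-6, max_iter = 100,
                 initial = NULL) {
  stopifnot(is.list(targets), length(targets) >= 1)
  n <- nrow(respondents)
  for (v in names(targets)) {
    if (is.null(respondents[[v]])) stop("missing weighting variable: ", v)
    tg <- targets[[v]]
    if (abs(sum(tg) - 1) > 1e-9) stop("targets for ", v, " must sum to 1")
    seen <- unique(respondents[[v]])
    if (!all(seen %in% names(tg))) {
      stop("no target for category ", paste(setdiff(seen, names(tg)),
                                            collapse = ", "), " of ", v)
    }
    empty <- setdiff(names(tg)[tg > 0], seen)
    if (length(empty)) {
      stop("empty sample category with nonzero target: ",
           paste(paste0(v, "=", empty), collapse = ", "))
    }
  }
  if (cap < 1) stop("cap must be >= 1 (weights are normalised to mean 1)")
  w <- if (!is.null(initial)) initial else
    if (!is.null(respondents$design_weight)) respondents$design_weight else
      rep(1, n)
  if (any(w <= 0)) stop("initial weights must be positive")
  w <- w / mean(w)

  max_dev <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (v in names(targets)) {
      tg <- targets[[v]]
      share <- tapply(w, respondents[[v]], sum) / sum(w)
      f <- tg[names(share)] / share
      f[!is.finite(f)] <- 1
      w <- w * f[match(respondents[[v]], names(share))]
    }
    w <- cap_normalise(w, cap)
    max_dev <- max(vapply(names(targets), function(v) {
      share <- tapply(w, respondents[[v]], sum) / sum(w)
      tg <- targets[[v]]
      max(abs(share - tg[names(share)]))
    }, numeric(1)))
    if (max_dev < tol) break
  }
  converged <- max_dev < tol
  if (!converged) {
    warning(sprintf(
      "raking stopped after %d cycles with residual deviation %.2e (cap = %g)",
      iter, max_dev, cap))
  }
  structure(list(weights = as.numeric(w), iterations = iter, max_dev = max_dev,
                 n_capped = sum(w >= cap - 1e-12), converged = converged,
                 cap = cap),
            class = "rake_result")
}

# scale then clip so that mean(pmin(s * w, cap)) = 1 and max <= cap
cap_normalise <- function(w, cap) {
  if (!is.finite(cap)) return(w / mean(w))
  f <- function(s) mean(pmin(s * w, cap)) - 1
  if (f(cap / min(w)) < 0) stop("cap infeasible: cannot reach mean weight 1")
  s <- stats::uniroot(f, c(1e-12, cap / min(w)), tol = 1e-12)$root
  pmin(s * w, cap)
}

#' @export
print.rake_result <- function(x, ...) {
  cat(sprintf(
    "rake_result: %d weights, %d cycles, max deviation %.3g, %d at cap %g%s\n",
    length(x$weights), x$iterations, x$max_dev, x$n_capped, x$cap,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Combine per-stratum weights into national weights
#'
#' Rescales independently raked within-stratum weights so that each
#' stratum's share of the total weight equals its population share, then
#' normalises to mean 1 overall (as when separate provincial weight sets
#' are merged in proportion to provincial population).
#'
#' @param weights Named list of per-stratum weight vectors.
#' @param shares Named numeric of population shares, summing to 1, with the
#'   same names as `weights`.
#' @param strata Optional factor of stratum membership; when supplied the
#'   return is a single vector in the original respondent order, with
#'   `weights` entries matching `split(seq_along(strata), strata)`.
#' @return List of rescaled weight vectors (or one vector when `strata`
#'   is given).
#' @export
combine_strata <- function(weights, shares, strata = NULL) {
  if (abs(sum(shares) - 1) > 1e-9) stop("stratum shares must sum to 1")
  miss <- setdiff(names(shares), names(weights))
  if (length(miss)) stop("missing stratum: ", paste(miss, collapse = ", "))
  n_tot <- sum(lengths(weights[names(shares)]))
  out <- lapply(names(shares), function(s) {
    w <- weights[[s]]
    w * shares[[s]] * n_tot / sum(w)
  })
  names(out) <- names(shares)
  if (is.null(strata)) return(out)
  idx <- split(seq_along(strata), strata)
  res <- numeric(length(strata))
  for (s in names(shares)) res[idx[[s]]] <- out[[s]]
  res
}

#' Sample composition before and after weighting
#'
#' Compares unweighted and weighted category shares with the raking
#' targets, flagging categories whose weighted share still deviates from
#' target by more than `flag_tol` (as happens when the weight cap binds).
#'
#' @inheritParams rake
#' @param weights Optional weight vector (e.g. `rake(...)$weights`).
#' @param flag_tol Deviation above which a residual gap is flagged.
#' @return Data.frame with columns `variable`, `category`, `target`,
#'   `unweighted`, `weighted`, `gap`, `flagged`.
#' @export
composition_report <- function(respondents, targets, weights = NULL,
                               flag_tol = 1e-6) {
  if (is.null(weights)) weights <- rep(1, nrow(respondents))
  rows <- lapply(names(targets), function(v) {
    tg <- targets[[v]]
    x <- factor(respondents[[v]], levels = names(tg))
    unw <- as.numeric(table(x)) / length(x)
    wtd <- as.numeric(tapply(weights, x, sum, default = 0)) / sum(weights)
    data.frame(variable = v, category = names(tg), target = as.numeric(tg),
               unweighted = unw, weighted = wtd, gap = wtd - as.numeric(tg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- abs(out$gap) > flag_tol
  rownames(out) <- NULL
  out
}
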