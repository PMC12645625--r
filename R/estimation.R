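#' Tabulate deaths and person-years by 5-year age group
#'
#' Accumulates, at month resolution, each sibling's exposure inside a
#' half-open calendar window `[start_cmc, end_cmc)` into the seven adult
#' age groups 15-19 ... 45-49, together with weighted death counts. A
#' month `t` contributes `weight/12` person-years to the group containing
#' the completed age `(t - birth_cmc) %/% 12` whenever
#' `birth <= t < min(death, end)` and `start <= t`; a death inside the
#' window adds `weight` to its age-at-death group. Ages outside 15-49 are
#' ignored. Respondents themselves never appear: only sibling rows are
#' tabulated.
#'
#' @param siblings Full-history rows with `birth_cmc` set (and `death_cmc`
#'   for the deceased).
#' @param respondents Respondent roster (supplies weights).
#' @param window Integer vector `c(start_cmc, end_cmc)`, half-open.
#' @param weights Optional respondent-level weight vector aligned with
#'   `respondents`; defaults to `ps_weight`, then `design_weight`, then 1.
#' @return Data.frame of class `exposure_table`: `age_group`, `x` (lower
#'   age bound), `deaths`, `person_years`, `deaths_unw`, `person_years_unw`.
#' @export
tabulate_exposure <- function(siblings, respondents, window, weights = NULL) {
  acc <- exposure_matrices(siblings, respondents, window, weights)
  out <- data.frame(
    age_group = age_group_labels(), x = seq(15L, 45L, 5L),
    deaths = colSums(acc$D), person_years = colSums(acc$PY),
    deaths_unw = colSums(acc$D / acc$w_row)[seq_len(7)],
    person_years_unw = colSums(acc$PY / acc$w_row),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("exposure_table", "data.frame")
  out
}

age_group_labels <- function() sprintf("%d-%d", seq(15L, 45L, 5L),
                                       seq(19L, 49L, 5L))

# per-sibling exposure, summed to per-respondent matrices (n x 7) so the
# delete-one-respondent jackknife is a vectorised subtraction
exposure_matrices <- function(siblings, respondents, window, weights = NULL) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (is.null(weights)) {
    weights <- if (!is.null(respondents$ps_weight)) respondents$ps_weight else
      if (!is.null(respondents$design_weight)) respondents$design_weight else
        rep(1, nrow(respondents))
  }
  if (anyNA(siblings$birth_cmc)) {
    stop("siblings without birth_cmc: impute or derive dates first")
  }
  dead <- siblings$alive == 0L
  if (any(dead & is.na(siblings$death_cmc))) {
    stop("deceased siblings without death_cmc: impute dates first")
  }
  ri <- match(siblings$respondent_id, respondents$respondent_id)
  if (anyNA(ri)) stop("siblings reference unknown respondents")
  w <- weights[ri]
  n <- nrow(respondents)
  birth <- siblings$birth_cmc
  stop_cmc <- ifelse(dead, siblings$death_cmc, window[2])

  xs <- seq(15L, 45L, 5L)
  PY <- matrix(0, n, 7L)
  D <- matrix(0, n, 7L)
  add_into <- function(M, k, vals, rows) {
    rs <- rowsum(vals, rows)
    j <- as.integer(rownames(rs))
    M[j, k] <- M[j, k] + rs[, 1]
    M
  }
  for (k in seq_along(xs)) {
    lo <- pmax(window[1], birth + 12L * xs[k])
    hi <- pmin(window[2], stop_cmc, birth + 12L * (xs[k] + 5L))
    months <- pmax(0L, hi - lo)
    py <- w * months / 12
    nz <- py > 0
    if (any(nz)) PY <- add_into(PY, k, py[nz], ri[nz])
  }
  dth <- dead & !is.na(siblings$death_cmc) &
    siblings$death_cmc >= window[1] & siblings$death_cmc < window[2]
  if (any(dth)) {
    aad <- (siblings$death_cmc[dth] - birth[dth]) %/% 12L
    grp <- aad %/% 5L - 2L  # 15-19 -> 1
    keep <- grp >= 1L & grp <= 7L
    if (any(keep)) {
      i <- ri[dth][keep]
      g <- grp[keep]
      ww <- w[dth][keep]
      for (k in 1:7) {
        sel <- g == k
        if (any(sel)) D <- add_into(D, k, ww[sel], i[sel])
      }
    }
  }
  list(D = D, PY = PY, w_row = ifelse(weights == 0, 1, weights))
}

#' Age-specific mortality rates from an exposure table
#'
#' `m_a = deaths_a / person_years_a`; groups without exposure are flagged
#' unestimable (`NA`).
#'
#' @param exposure An `exposure_table` from [tabulate_exposure()].
#' @return Data.frame `age_group`, `x`, `m`, `estimable`.
#' @export
rates_from_exposure <- function(exposure) {
  if (all(exposure$person_years == 0)) stop("no exposure in any age group")
  m <- ifelse(exposure$person_years > 0,
              exposure$deaths / exposure$person_years, NA_real_)
  data.frame(age_group = exposure$age_group, x = exposure$x, m = m,
             estimable = exposure$person_years > 0, stringsAsFactors = FALSE)
}

#' Convert a mortality rate to a probability of dying
#'
#' Actuarial conversion for an `n`-year interval assuming deaths fall on
#' average halfway through the interval:
#' \eqn{q = n m / (1 + (n/2) m)}. Monotone increasing in `m`, and in
#' `[0, 1)` for the rates encountered in practice (clamped at 1 beyond).
#'
#' @param m Mortality rate(s), deaths per person-year (>= 0).
#' @param n Interval width in years.
#' @export
q_from_m <- function(m, n = 5) {
  if (any(m < 0, na.rm = TRUE)) stop("rates must be non-negative")
  pmin(n * m / (1 + (n / 2) * m), 1)
}

#' Chain 5-year probabilities into the adult mortality probability
#'
#' The probability that a 15-year-old dies before exact age 50, obtained
#' by chaining survival across the seven 5-year groups:
#' \eqn{{}_{35}q_{15} = 1 - \prod_a (1 - {}_5q_a)}.
#'
#' @param rates Data.frame from [rates_from_exposure()] (or a bare numeric
#'   vector of seven age-specific rates `m`).
#' @export
chain_35q15 <- function(rates) {
  m <- if (is.data.frame(rates)) rates$m else rates
  if (length(m) != 7L) stop("need seven 5-year age groups spanning 15-49")
  if (anyNA(m)) {
    miss <- age_group_labels()[is.na(m)]
    stop("unestimable age group(s): ", paste(miss, collapse = ", "))
  }
  1 - prod(1 - q_from_m(m, 5))
}

#' Delete-one jackknife standard error and confidence interval
#'
#' Leave-one-unit-out jackknife at the respondent level:
#' `var = (n-1)/n * sum((theta_i - mean(theta_i))^2)`, with a
#' normal-approximation interval truncated to `[0, 1]` when the estimate
#' is a probability.
#'
#' @param data List or data.frame of units (rows are deleted one at a
#'   time; a list is treated as a list of units).
#' @param estimator Function mapping a subset of `data` to a scalar.
#' @param level Confidence level.
#' @param truncate01 Truncate the interval to `[0, 1]`.
#' @return List `estimate`, `se`, `ci` (length 2), `n_used`.
#' @export
jackknife_ci <- function(data, estimator, level = 0.95, truncate01 = FALSE) {
  idx <- if (is.data.frame(data)) seq_len(nrow(data)) else seq_along(data)
  n <- length(idx)
  if (n < 2) stop("jackknife needs at least 2 units")
  take <- function(i) if (is.data.frame(data)) data[i, , drop = FALSE] else data[i]
  est <- estimator(data)
  theta <- vapply(idx, function(i) {
    tryCatch(estimator(take(setdiff(idx, i))), error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(theta)) {
    warning(sum(is.na(theta)), " jackknife replicate(s) failed and were skipped")
    theta <- theta[!is.na(theta)]
  }
  k <- length(theta)
  se <- sqrt((k - 1) / k * sum((theta - mean(theta))^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- est + c(-1, 1) * z * se
  if (truncate01) ci <- pmin(pmax(ci, 0), 1)
  list(estimate = est, se = se, ci = ci, n_used = k)
}

#' Estimate adult mortality (35q15) from a full sibling history
#'
#' The direct sibling method: tabulate weighted deaths and person-years by
#' 5-year age group over an observation window, convert rates to
#' probabilities (deaths assumed halfway through each interval), chain the
#' seven groups into the probability of dying between ages 15 and 50, and
#' attach a respondent-level delete-one jackknife standard error.
#'
#' @inheritParams tabulate_exposure
#' @param sex Sibling sex filter: `"both"`, `"male"` or `"female"`
#'   (siblings of unknown sex count under `"both"` only).
#' @param se_method `"jackknife"` or `"none"` (point estimate only; much
#'   faster in simulation studies).
#' @param level Confidence level for the jackknife interval.
#' @return Object of class `mort_est`: list with `q35_15`, `se`, `ci`,
#'   `rates`, `exposure`, `sex`, `window`, `n_respondents`, `n_deaths`,
#'   `person_years`.
#' @export
estimate_35q15 <- function(siblings, respondents, window,
                           sex = c("both", "male", "female"),
                           weights = NULL, se_method = c("jackknife", "none"),
                           level = 0.95) {
  sex <- match.arg(sex)
  se_method <- match.arg(se_method)
  keep <- switch(sex, both = rep(TRUE, nrow(siblings)),
                 male = siblings$sex == "m", female = siblings$sex == "f")
  sib <- siblings[keep, , drop = FALSE]
  acc <- exposure_matrices(sib, respondents, window, weights)
  D <- colSums(acc$D)
  PY <- colSums(acc$PY)
  if (any(PY == 0)) {
    stop("no exposure in age group(s): ",
         paste(age_group_labels()[PY == 0], collapse = ", "))
  }
  q <- chain_from_DP(D, PY)
  se <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (se_method == "jackknife") {
    n <- nrow(acc$D)
    Dl <- sweep(-acc$D, 2, D, "+")   # leave-one-out totals
    PYl <- sweep(-acc$PY, 2, PY, "+")
    ok <- rowSums(PYl <= 0) == 0
    if (!all(ok)) {
      warning(sum(!ok), " jackknife replicate(s) with empty age groups skipped")
    }
    qa <- pmin(5 * (Dl[ok, ] / PYl[ok, ]) / (1 + 2.5 * Dl[ok, ] / PYl[ok, ]), 1)
    theta <- 1 - apply(1 - qa, 1, prod)
    k <- length(theta)
    se <- sqrt((k - 1) / k * sum((theta - mean(theta))^2))
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- pmin(pmax(q + c(-1, 1) * z * se, 0), 1)
  }
  exposure <- data.frame(age_group = age_group_labels(),
                         x = seq(15L, 45L, 5L), deaths = D, person_years = PY,
                         stringsAsFactors = FALSE)
  class(exposure) <- c("exposure_table", "data.frame")
  structure(list(q35_15 = q, se = se, ci = ci,
                 rates = rates_from_exposure(exposure), exposure = exposure,
                 sex = sex, window = window,
                 n_respondents = nrow(respondents),
                 n_deaths = sum(D), person_years = sum(PY)),
            class = "mort_est")
}

chain_from_DP <- function(D, PY) {
  m <- D / PY
  1 - prod(1 - pmin(5 * m / (1 + 2.5 * m), 1))
}

#' @export
print.mort_est <- function(x, ...) {
  cat(sprintf("35q15 (%s, window [%d, %d)): %.4f", x$sex,
              x$window[1], x$window[2], x$q35_15))
  if (!is.na(x$se)) {
    cat(sprintf("  se %.4f  95%% CI [%.4f, %.4f]", x$se, x$ci[1], x$ci[2]))
  }
  cat(sprintf("\n  deaths %.1f, person-years %.1f, respondents %d\n",
              x$n_deaths, x$person_years, x$n_respondents))
  invisible(x)
}

#' Annual series of adult mortality estimates
#'
#' One [estimate_35q15()] per calendar year, over the window
#' `[to_cmc(y, 1), to_cmc(y + 1, 1))`. Years whose estimation fails (e.g.
#' an empty age group) are flagged rather than aborting the series.
#'
#' @inheritParams estimate_35q15
#' @param years Integer vector of calendar years.
#' @return Data.frame `year`, `q35_15`, `se`, `ci_low`, `ci_high`,
#'   `deaths`, `person_years`, `estimable`.
#' @export
annual_series <- function(siblings, respondents, years, sex = "both",
                          weights = NULL, se_method = "jackknife") {
  rows <- lapply(years, function(y) {
    win <- c(to_cmc(y, 1), to_cmc(y + 1, 1))
    est <- tryCatch(
      estimate_35q15(siblings, respondents, win, sex = sex,
                     weights = weights, se_method = se_method),
      error = function(e) NULL)
    if (is.null(est)) {
      data.frame(year = y, q35_15 = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, deaths = NA_real_,
                 person_years = NA_real_, estimable = FALSE)
    } else {
      data.frame(year = y, q35_15 = est$q35_15, se = est$se,
                 ci_low = est$ci[1], ci_high = est$ci[2],
                 deaths = est$n_deaths, person_years = est$person_years,
                 estimable = TRUE)
    }
  })
  do.call(rbind, rows)
}

#' Scale a national mortality schedule to a province
#'
#' Rescales national age-specific adult mortality rates by the ratio of
#' province to national under-five mortality and re-chains the scaled
#' schedule into a provincial 35q15 (the approximation used when national
#' reference estimates must be carried to subnational areas).
#'
#' @param national Either a numeric vector of seven age-specific rates, or
#'   a single national 35q15 probability in `(0, 1)` (converted to a flat
#'   schedule before scaling).
#' @param province_u5mr,national_u5mr Under-five mortality in the province
#'   and nationally (any common scale).
#' @return Provincial 35q15 probability.
#' @export
scale_subnational <- function(national, province_u5mr, national_u5mr) {
  if (national_u5mr <= 0) stop("national_u5mr must be positive")
  if (province_u5mr < 0) stop("province_u5mr must be non-negative")
  m <- if (length(national) == 7L) national else {
    if (national <= 0 || national >= 1) stop("national 35q15 must be in (0,1)")
    # invert a flat schedule: q5 per group, then m from q = 5m/(1+2.5m)
    q5 <- 1 - (1 - national)^(1 / 7)
    rep(q5 / (5 - 2.5 * q5), 7L)
  }
  ratio <- province_u5mr / national_u5mr
  chain_35q15(m * ratio)
}
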