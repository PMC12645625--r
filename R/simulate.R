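#' Calibrate a stationary life-table regime
#'
#' Builds the mortality regime used by the sibship simulator: a
#' piecewise-constant hazard per single year of age (0--95) and per sex,
#' with the adult segment (ages 15--49) rescaled so that the implied
#' probability of dying between exact ages 15 and 50 equals
#' `target_35q15`. With constant hazards the implied probability has the
#' closed form \eqn{1 - \exp(-k \sum_{a=15}^{49} h_a)}, so the scaling
#' factor solves the target exactly.
#'
#' The default hazard template has a Sahelian-like shape: elevated infant
#' and early-childhood mortality, a mortality trough around age 10, and a
#' Gompertz-type rise through adulthood.
#'
#' @param target_35q15 Named numeric, probabilities in `[0, 1)` for sexes
#'   `m` and `f` (a single unnamed value is applied to both).
#' @param fertility_mean,fertility_size Negative-binomial sibship-size
#'   distribution (number of maternal siblings per respondent).
#' @param gap_sd_months SD of the respondent-sibling birth-gap law (months).
#' @param template Optional length-96 base hazard vector.
#' @return An object of class `lt_regime`.
#' @examples
#' reg <- calibrate_regime(c(m = 0.178, f = 0.138))
#' regime_35q15(reg, "m")  # 0.178
#' @export
calibrate_regime <- function(target_35q15 = c(m = 0.15, f = 0.15),
                             fertility_mean = 6, fertility_size = 5,
                             gap_sd_months = 60, template = NULL) {
  if (is.null(names(target_35q15))) {
    target_35q15 <- c(m = unname(target_35q15[1]), f = unname(target_35q15[1]))
  }
  if (any(target_35q15 < 0) || any(target_35q15 >= 1)) {
    stop("target_35q15 must lie in [0, 1)")
  }
  if (is.null(template)) template <- default_hazard_template()
  stopifnot(length(template) == 96L, all(template >= 0))
  adult <- 16:50  # ages 15..49
  H <- sum(template[adult])
  hz <- lapply(c(m = "m", f = "f"), function(s) {
    k <- -log(1 - target_35q15[[s]]) / H
    h <- template
    h[adult] <- h[adult] * k
    h
  })
  structure(list(hazard = hz, target_35q15 = target_35q15,
                 fertility_mean = fertility_mean,
                 fertility_size = fertility_size,
                 gap_sd_months = gap_sd_months),
            class = "lt_regime")
}

default_hazard_template <- function() {
  ages <- 0:95
  child <- ifelse(ages == 0, 0.060,
            ifelse(ages <= 4, 0.012 * exp(-0.5 * (ages - 1)),
              ifelse(ages <= 14, 0.0015, 0)))
  adult <- ifelse(ages >= 15, 0.003 * exp(0.05 * (ages - 15)), 0)
  child + adult
}

#' Closed-form adult mortality of a regime
#'
#' The probability that a 15-year-old dies before age 50 implied by the
#' regime's single-year hazards, `1 - exp(-sum(h[15..49]))`.
#'
#' @param regime An `lt_regime`.
#' @param sex `"m"` or `"f"`.
#' @export
regime_35q15 <- function(regime, sex = "m") {
  1 - exp(-sum(regime$hazard[[sex]][16:50]))
}

#' Simulate sibships under a stationary regime
#'
#' Draws a roster of survey respondents (alive at interview by
#' construction) together with the full survival history of each
#' respondent's maternal siblings. Sibship sizes are negative-binomial,
#' birth gaps are discretised-normal in months, sibling lifetimes are drawn
#' from the regime's single-year hazards, and everything is censored at the
#' interview date. Respondent covariates (residence, education, household
#' size) are drawn from fixed category probabilities and are available for
#' the selection and weighting stages.
#'
#' @param regime An `lt_regime` from [calibrate_regime()].
#' @param n_respondents Number of respondents.
#' @param interview_cmc Interview date (single CMC applied to all).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return `list(respondents = data.frame, siblings = data.frame)` in the
#'   full sibling-history layout.
#' @export
simulate_sibships <- function(regime, n_respondents, interview_cmc,
                              seed = NULL) {
  stopifnot(inherits(regime, "lt_regime"), n_respondents >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_respondents
  resp <- data.frame(
    respondent_id = sprintf("r%06d", seq_len(n)),
    sex = sample(c("m", "f"), n, replace = TRUE),
    age_years = sample(15:64, n, replace = TRUE, prob = exp(-0.03 * (0:49))),
    interview_cmc = as.integer(interview_cmc),
    residence = sample(c("urban", "rural"), n, replace = TRUE, prob = c(0.35, 0.65)),
    education = sample(c("none", "primary", "secondary+"), n, replace = TRUE,
                       prob = c(0.40, 0.35, 0.25)),
    hh_size_class = sample(c("1-4", "5+"), n, replace = TRUE),
    design_weight = 1,
    stringsAsFactors = FALSE
  )
  resp$age_group <- age_group_5(resp$age_years)
  resp_birth <- as.integer(interview_cmc - 12L * resp$age_years -
                             sample(0:11, n, replace = TRUE))

  n_sib <- stats::rnbinom(n, size = regime$fertility_size,
                          mu = regime$fertility_mean)
  owner <- rep(seq_len(n), n_sib)
  m <- length(owner)
  if (m == 0L) stop("no siblings simulated; increase fertility or n")
  sib_sex <- sample(c("m", "f"), m, replace = TRUE)

  # birth gap in months, redrawn while the sibling would be born after the
  # interview (respondents can have younger siblings only up to "today")
  gap <- as.integer(round(stats::rnorm(m, 0, regime$gap_sd_months)))
  birth <- resp_birth[owner] + gap
  for (it in 1:20) {
    bad <- birth >= interview_cmc
    if (!any(bad)) break
    gap[bad] <- as.integer(round(stats::rnorm(sum(bad), 0, regime$gap_sd_months)))
    birth[bad] <- resp_birth[owner[bad]] + gap[bad]
  }
  birth <- pmin(birth, as.integer(interview_cmc) - 1L)

  death_age <- draw_death_age(regime, sib_sex)
  death_cmc <- ifelse(death_age > 95L, NA_integer_,
                      birth + 12L * death_age + sample(0:11, m, replace = TRUE))
  alive <- is.na(death_cmc) | death_cmc >= interview_cmc
  death_cmc[alive] <- NA_integer_

  sib <- data.frame(
    respondent_id = resp$respondent_id[owner],
    line_no = stats::ave(owner, owner, FUN = seq_along),
    sex = sib_sex,
    alive = as.integer(alive),
    age_now = ifelse(alive, (as.integer(interview_cmc) - birth) %/% 12L, NA_integer_),
    age_at_death = ifelse(alive, NA_integer_, death_age),
    years_since_death = ifelse(alive, NA_integer_,
                               (as.integer(interview_cmc) - death_cmc) %/% 12L),
    death_cmc = as.integer(death_cmc),
    birth_cmc = as.integer(birth),
    imputed_fields = "",
    stringsAsFactors = FALSE
  )
  list(respondents = resp, siblings = sib)
}

# inverse-CDF draw of the completed age at death (96 = survives past 95)
draw_death_age <- function(regime, sex) {
  m <- length(sex)
  out <- integer(m)
  for (s in c("m", "f")) {
    i <- sex == s
    if (!any(i)) next
    S <- exp(-cumsum(regime$hazard[[s]]))  # survival to exact ages 1..96
    u <- stats::runif(sum(i))
    out[i] <- 96L - findInterval(u, rev(S))
  }
  out
}

#' Overlay a recent mortality shock on simulated histories
#'
#' Multiplies the regime's hazards by `factor` during a calendar window
#' (e.g. the three years before the interview), breaking stationarity.
#' Implemented as a competing exposure: each sibling alive in the window
#' is exposed month by month to the additional hazard
#' `(factor - 1) * h_age / 12`, and dies at the first month where an
#' independent exponential draw is exceeded, if that precedes their
#' originally simulated death. With `factor = 1` the histories are
#' returned unchanged; this construction is exact for piecewise-constant
#' hazards.
#'
#' @param siblings,respondents Simulator output.
#' @param regime The `lt_regime` the histories were drawn from.
#' @param factor Hazard multiplier during the window (>= 1).
#' @param window `c(start_cmc, end_cmc)`, half-open.
#' @param seed Optional seed.
#' @return The sibling data.frame with shock deaths applied.
#' @export
apply_mortality_shock <- function(siblings, respondents, regime, factor,
                                  window, seed = NULL) {
  stopifnot(factor >= 1, length(window) == 2L, window[1] < window[2])
  if (factor == 1) return(siblings)
  if (!is.null(seed)) set.seed(seed)
  iv <- respondents$interview_cmc[match(siblings$respondent_id,
                                        respondents$respondent_id)]
  m <- nrow(siblings)
  stop_cmc <- ifelse(siblings$alive == 1L, iv, siblings$death_cmc)
  E <- stats::rexp(m)
  cum <- numeric(m)
  hit_month <- rep(NA_integer_, m)
  hz <- regime$hazard
  for (t in window[1]:(window[2] - 1L)) {
    active <- is.na(hit_month) & siblings$birth_cmc <= t & t < stop_cmc
    if (!any(active)) next
    a <- pmin((t - siblings$birth_cmc[active]) %/% 12L, 95L)
    h <- ifelse(siblings$sex[active] == "f", hz$f[a + 1L], hz$m[a + 1L])
    cum[active] <- cum[active] + (factor - 1) * h / 12
    crossed <- active & cum >= E
    hit_month[crossed & is.na(hit_month)] <- t
  }
  hit <- which(!is.na(hit_month))
  if (length(hit)) {
    t <- hit_month[hit]
    siblings$alive[hit] <- 0L
    siblings$death_cmc[hit] <- t
    siblings$age_at_death[hit] <- (t - siblings$birth_cmc[hit]) %/% 12L
    siblings$years_since_death[hit] <- (iv[hit] - t) %/% 12L
    siblings$age_now[hit] <- NA_integer_
  }
  siblings
}

#' Reporting-error model
#'
#' Parameters of the reporting-error injector: `heap_prob` rounds a
#' recorded age to the nearest multiple of five; `displace_prob` shifts a
#' death date backwards in time by a geometric number of months with mean
#' `displace_mean_months` (the recorded age at death is preserved, only the
#' date moves); `omit_death_prob` deletes a deceased sibling's row
#' entirely.
#'
#' @param heap_prob,displace_prob,omit_death_prob Probabilities in `[0,1]`.
#' @param displace_mean_months Mean backward shift, months (>= 1).
#' @export
error_model <- function(heap_prob = 0, displace_prob = 0,
                        displace_mean_months = 6, omit_death_prob = 0) {
  p <- c(heap_prob, displace_prob, omit_death_prob)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (displace_mean_months < 1) stop("displace_mean_months must be >= 1")
  structure(list(heap_prob = heap_prob, displace_prob = displace_prob,
                 displace_mean_months = displace_mean_months,
                 omit_death_prob = omit_death_prob), class = "error_model")
}

#' Inject reporting errors into a full sibling history
#'
#' Applies age heaping, backward displacement of death dates and omission
#' of deceased siblings (see [error_model()]). Birth dates are re-derived
#' where an age or date changed so that rows remain internally consistent.
#'
#' @param siblings,respondents Full-history tables.
#' @param model An [error_model()].
#' @param seed Optional seed.
#' @return The perturbed sibling data.frame.
#' @export
inject_errors <- function(siblings, respondents, model, seed = NULL) {
  stopifnot(inherits(model, "error_model"))
  if (!is.null(seed)) set.seed(seed)
  iv <- respondents$interview_cmc[match(siblings$respondent_id,
                                        respondents$respondent_id)]
  h5 <- function(x) as.integer(5L * floor(x / 5 + 0.5))

  if (model$heap_prob > 0) {
    al <- which(siblings$alive == 1L & !is.na(siblings$age_now))
    hit <- al[stats::runif(length(al)) < model$heap_prob]
    siblings$age_now[hit] <- h5(siblings$age_now[hit])
    siblings$birth_cmc[hit] <- iv[hit] - 12L * siblings$age_now[hit] - 6L
    dd <- which(siblings$alive == 0L & !is.na(siblings$age_at_death))
    hit <- dd[stats::runif(length(dd)) < model$heap_prob]
    siblings$age_at_death[hit] <- h5(siblings$age_at_death[hit])
    siblings$birth_cmc[hit] <- siblings$death_cmc[hit] -
      12L * siblings$age_at_death[hit] - 6L
  }
  if (model$displace_prob > 0) {
    dd <- which(siblings$alive == 0L & !is.na(siblings$death_cmc))
    hit <- dd[stats::runif(length(dd)) < model$displace_prob]
    if (length(hit)) {
      mm <- model$displace_mean_months
      shift <- 1L + if (mm > 1) stats::rgeom(length(hit), 1 / mm) else 0L
      siblings$death_cmc[hit] <- siblings$death_cmc[hit] - shift
      siblings$birth_cmc[hit] <- siblings$death_cmc[hit] -
        12L * siblings$age_at_death[hit] - 6L
      siblings$years_since_death[hit] <-
        (iv[hit] - siblings$death_cmc[hit]) %/% 12L
    }
  }
  if (model$omit_death_prob > 0) {
    dd <- which(siblings$alive == 0L)
    drop <- dd[stats::runif(length(dd)) < model$omit_death_prob]
    if (length(drop)) siblings <- siblings[-drop, , drop = FALSE]
  }
  siblings
}

#' Phone-ownership selection model
#'
#' Logistic selection of respondents on categorical covariates:
#' `P(selected) = plogis(intercept + sum of category coefficients)`.
#' `coefs` is a named list (one element per covariate column) of named
#' numeric vectors (one element per category).
#'
#' @param intercept Baseline log-odds (may be `Inf` for certain inclusion).
#' @param coefs Named list of named coefficient vectors.
#' @export
selection_model <- function(intercept = 0, coefs = list()) {
  structure(list(intercept = intercept, coefs = coefs),
            class = "selection_model")
}

#' Thin a simulated survey by phone-ownership selection
#'
#' Bernoulli-selects respondents with the logistic probability of a
#' [selection_model()]; sibling rows of dropped respondents are removed.
#'
#' @param respondents,siblings Simulator output.
#' @param model A [selection_model()].
#' @param seed Optional seed.
#' @return `list(respondents, siblings)` for the selected subsample.
#' @export
apply_selection <- function(respondents, siblings, model, seed = NULL) {
  stopifnot(inherits(model, "selection_model"))
  if (!is.null(seed)) set.seed(seed)
  lp <- rep(model$intercept, nrow(respondents))
  for (v in names(model$coefs)) {
    if (is.null(respondents[[v]])) stop("unknown selection covariate: ", v)
    co <- model$coefs[[v]]
    lp <- lp + ifelse(respondents[[v]] %in% names(co),
                      co[respondents[[v]]], 0)
  }
  keep <- stats::runif(nrow(respondents)) < stats::plogis(lp)
  if (!any(keep)) stop("selection removed every respondent; relax the model")
  resp <- respondents[keep, , drop = FALSE]
  sib <- siblings[siblings$respondent_id %in% resp$respondent_id, , drop = FALSE]
  list(respondents = resp, siblings = sib)
}

#' Collapse a full history to the shortened summary instrument
#'
#' Reduces a full sibling history to per-respondent counts (siblings ever
#' born, alive, dead) plus detail rows for deaths on or after
#' `cutoff_cmc`, mimicking the shortened phone-survey module. Country
#' variants mask fields: `"burkina"` keeps sibling sex and ages at death,
#' `"drc"` keeps sex but drops ages at death, `"malawi"` combines the
#' sexes (and keeps ages at death).
#'
#' @param siblings,respondents Full-history tables.
#' @param cutoff_cmc Recency cutoff (deaths at or after it get detail rows).
#' @param variant `"burkina"`, `"drc"` or `"malawi"`.
#' @return `list(summary = data.frame, details = data.frame)`.
#' @export
collapse_to_summary <- function(siblings, respondents, cutoff_cmc,
                                variant = c("burkina", "drc", "malawi")) {
  variant <- match.arg(variant)
  by_sex <- variant %in% c("burkina", "drc")
  sexv <- if (by_sex) siblings$sex else rep("u", nrow(siblings))
  rid <- factor(siblings$respondent_id, levels = unique(respondents$respondent_id))
  sx <- factor(sexv, levels = if (by_sex) c("m", "f", "u") else "u")
  tab_all <- table(rid, sx)
  alv <- siblings$alive == 1L
  tab_alive <- table(rid[alv], sx[alv])
  grid <- expand.grid(respondent_id = levels(rid), sex = levels(sx),
                      stringsAsFactors = FALSE)
  grid$n_ever <- as.integer(tab_all[cbind(grid$respondent_id, grid$sex)])
  grid$n_alive <- as.integer(tab_alive[cbind(grid$respondent_id, grid$sex)])
  grid$n_dead <- grid$n_ever - grid$n_alive
  smry <- grid[grid$n_ever > 0 | !by_sex, , drop = FALSE]
  smry <- smry[order(smry$respondent_id, smry$sex), , drop = FALSE]
  rownames(smry) <- NULL

  rec <- siblings[siblings$alive == 0L & !is.na(siblings$death_cmc) &
                    siblings$death_cmc >= cutoff_cmc, , drop = FALSE]
  ym <- if (nrow(rec)) from_cmc(rec$death_cmc) else
    data.frame(year = integer(), month = integer())
  details <- data.frame(
    respondent_id = rec$respondent_id,
    sex = if (by_sex) rec$sex else rep("u", nrow(rec)),
    age_at_death = if (variant == "drc") rep(NA_integer_, nrow(rec)) else
      rec$age_at_death,
    death_year = ym$year,
    death_month = ym$month,
    stringsAsFactors = FALSE
  )
  list(summary = smry, details = details)
}
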