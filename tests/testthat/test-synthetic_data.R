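test_that("regime calibration hits the target adult mortality in closed form", {
  expect_equal(regime_35q15(calibrate_regime(c(m = 0.178, f = 0.138)), "m"),
               0.178, tolerance = 1e-9)
  expect_equal(regime_35q15(calibrate_regime(c(m = 0.178, f = 0.138)), "f"),
               0.138, tolerance = 1e-9)

  z <- calibrate_regime(c(m = 0, f = 0))
  expect_true(all(z$hazard$m[16:50] == 0))

  lo <- calibrate_regime(c(m = 0.1, f = 0.1))
  hi <- calibrate_regime(c(m = 0.2, f = 0.2))
  expect_true(all(hi$hazard$m[16:50] > lo$hazard$m[16:50]))
  expect_error(calibrate_regime(c(m = 1, f = 0.1)), "target")
})

test_that("simulated sibships are deterministic under a seed and censor correctly", {
  reg <- calibrate_regime(c(m = 0.15, f = 0.12))
  a <- simulate_sibships(reg, 300, to_cmc(2022, 1), seed = 5)
  b <- simulate_sibships(reg, 300, to_cmc(2022, 1), seed = 5)
  expect_identical(a, b)
  c <- simulate_sibships(reg, 300, to_cmc(2022, 1), seed = 6)
  expect_false(identical(a$siblings, c$siblings))

  expect_length(validate_full_ssh(a$siblings, a$respondents), 0L)
  expect_true(all(a$siblings$birth_cmc < to_cmc(2022, 1)))

  # a regime with no mortality at all leaves every sibling alive
  reg0 <- reg
  reg0$hazard$m[] <- 0
  reg0$hazard$f[] <- 0
  s0 <- simulate_sibships(reg0, 200, to_cmc(2022, 1), seed = 9)
  expect_true(all(s0$siblings$alive == 1L))
})

test_that("direct estimation recovers the simulated adult mortality level", {
  # parameter-recovery oracle across low/mid/high regimes; n scaled to
  # 12000 respondents per regime to keep the default run quick (the
  # n = 50000 case runs in the acceptance suite)
  for (tgt in c(0.05, 0.15, 0.30)) {
    reg <- calibrate_regime(c(m = tgt, f = tgt))
    sim <- simulate_sibships(reg, 12000, to_cmc(2022, 1), seed = round(100 * tgt))
    est <- estimate_35q15(sim$siblings, sim$respondents,
                          c(to_cmc(2019, 1), to_cmc(2022, 1)))
    expect_lt(abs(est$q35_15 - tgt), 3 * est$se)
  }
})

test_that("error injectors perturb histories as specified", {
  reg <- calibrate_regime(c(m = 0.2, f = 0.2))
  sim <- simulate_sibships(reg, 1500, to_cmc(2022, 1), seed = 21)

  ident <- inject_errors(sim$siblings, sim$respondents, error_model(), seed = 1)
  expect_identical(ident, sim$siblings)

  heaped <- inject_errors(sim$siblings, sim$respondents,
                          error_model(heap_prob = 1), seed = 2)
  expect_true(all(heaped$age_now[heaped$alive == 1L] %% 5L == 0L))
  expect_true(all(heaped$age_at_death[heaped$alive == 0L] %% 5L == 0L))
  expect_length(validate_full_ssh(heaped, sim$respondents), 0L)

  disp <- inject_errors(sim$siblings, sim$respondents,
                        error_model(displace_prob = 1,
                                    displace_mean_months = 12), seed = 3)
  dd <- sim$siblings$alive == 0L
  expect_true(all(disp$death_cmc[dd] < sim$siblings$death_cmc[dd]))
  expect_identical(disp$age_at_death[dd], sim$siblings$age_at_death[dd])
  expect_length(validate_full_ssh(disp, sim$respondents), 0L)

  omitted <- inject_errors(sim$siblings, sim$respondents,
                           error_model(omit_death_prob = 1), seed = 4)
  expect_true(all(omitted$alive == 1L))
  qt <- quality_table(omitted, sim$respondents)
  expect_true(all(qt$prop_surviving == 1))
})

test_that("backward displacement lowers the recent-death proportion", {
  reg <- calibrate_regime(c(m = 0.2, f = 0.2))
  sim <- simulate_sibships(reg, 8000, to_cmc(2022, 1), seed = 31)
  disp <- inject_errors(sim$siblings, sim$respondents,
                        error_model(displace_prob = 0.5,
                                    displace_mean_months = 12), seed = 32)
  # pooled recent-death share must drop when dates shift backwards
  agg <- function(sib, resp) {
    dd <- sib$alive == 0L
    rec <- dd & sib$death_cmc >= to_cmc(2022, 1) - 36L
    sum(rec) / sum(dd)
  }
  expect_lt(agg(disp, sim$respondents), agg(sim$siblings, sim$respondents))
})

test_that("phone-ownership selection skews composition as modelled", {
  reg <- calibrate_regime(c(m = 0.15, f = 0.15))
  sim <- simulate_sibships(reg, 8000, to_cmc(2022, 1), seed = 41)

  ident <- apply_selection(sim$respondents, sim$siblings,
                           selection_model(intercept = Inf), seed = 1)
  expect_identical(ident$respondents, sim$respondents)

  sel <- apply_selection(sim$respondents, sim$siblings,
                         selection_model(intercept = -1, coefs = list(
                           residence = c(urban = 2, rural = 0),
                           education = c("secondary+" = 1.5))), seed = 2)
  share <- function(d) mean(d$residence == "urban")
  expect_gt(share(sel$respondents), share(sim$respondents))
  expect_true(all(sel$siblings$respondent_id %in% sel$respondents$respondent_id))

  expect_error(apply_selection(sim$respondents, sim$siblings,
                               selection_model(intercept = -Inf)), "relax")
})

test_that("collapsing to the summary instrument counts and masks correctly", {
  iv <- to_cmc(2022, 1)
  resp <- make_respondents(1, interview_cmc = iv)
  sib <- rbind(
    make_sibling("p001", sex = "m", alive = 1L, age_now = 20L,
                 birth_cmc = iv - 246L),
    make_sibling("p001", sex = "m", alive = 1L, age_now = 25L,
                 birth_cmc = iv - 306L),
    make_sibling("p001", sex = "f", alive = 1L, age_now = 28L,
                 birth_cmc = iv - 342L),
    make_sibling("p001", sex = "f", alive = 1L, age_now = 35L,
                 birth_cmc = iv - 426L),
    make_sibling("p001", sex = "f", alive = 0L, age_at_death = 30L,
                 death_cmc = 1435L, years_since_death = 2L,
                 birth_cmc = 1435L - 366L))
  got <- collapse_to_summary(sib, resp, cutoff_cmc = 1429L, "burkina")
  f <- got$summary[got$summary$sex == "f", ]
  expect_equal(f[c("n_ever", "n_alive", "n_dead")],
               data.frame(n_ever = 3L, n_alive = 2L, n_dead = 1L),
               ignore_attr = TRUE)
  expect_equal(sum(got$summary$n_ever), 5L)
  expect_equal(nrow(got$details), 1L)
  expect_equal(got$details$death_year, 2019L)

  # boundary: a death one month before the cutoff is counted but yields
  # no detail row (half-open recency convention)
  sib$death_cmc[5] <- 1428L
  got <- collapse_to_summary(sib, resp, cutoff_cmc = 1429L, "burkina")
  expect_equal(got$summary$n_dead[got$summary$sex == "f"], 1L)
  expect_equal(nrow(got$details), 0L)

  sib$death_cmc[5] <- 1435L
  drc <- collapse_to_summary(sib, resp, 1429L, "drc")
  expect_true(is.na(drc$details$age_at_death))
  mal <- collapse_to_summary(sib, resp, 1429L, "malawi")
  expect_equal(mal$summary$sex, "u")
  expect_equal(mal$details$sex, "u")
  expect_equal(mal$summary$n_ever, 5L)
  expect_false(is.na(mal$details$age_at_death))

  # detail rows can never outnumber the dead
  reg <- calibrate_regime(c(m = 0.25, f = 0.25))
  sim <- simulate_sibships(reg, 500, iv, seed = 51)
  cs <- collapse_to_summary(sim$siblings, sim$respondents, 1429L, "burkina")
  nd <- table(paste(cs$details$respondent_id, cs$details$sex))
  lim <- cs$summary$n_dead[match(names(nd), paste(cs$summary$respondent_id,
                                                  cs$summary$sex))]
  expect_true(all(as.integer(nd) <= lim))
})

test_that("a recent mortality shock raises deaths only inside its window", {
  reg <- calibrate_regime(c(m = 0.1, f = 0.1))
  sim <- simulate_sibships(reg, 6000, to_cmc(2022, 1), seed = 61)
  win <- c(to_cmc(2019, 1), to_cmc(2022, 1))
  shocked <- apply_mortality_shock(sim$siblings, sim$respondents, reg,
                                   factor = 3, window = win, seed = 62)
  expect_identical(apply_mortality_shock(sim$siblings, sim$respondents, reg,
                                         factor = 1, window = win),
                   sim$siblings)
  in_win <- function(s) sum(s$alive == 0L & s$death_cmc >= win[1] &
                              s$death_cmc < win[2], na.rm = TRUE)
  pre_win <- function(s) sum(s$alive == 0L & s$death_cmc < win[1], na.rm = TRUE)
  expect_gt(in_win(shocked), in_win(sim$siblings))
  expect_equal(pre_win(shocked), pre_win(sim$siblings))
  expect_length(validate_full_ssh(shocked, sim$respondents), 0L)
})
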