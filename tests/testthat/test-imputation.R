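test_that("reference tables tabulate weighted histograms per key", {
  ref <- degenerate_reference(gap = 2L)
  tab <- build_reference_tables(ref$siblings, ref$respondents)
  expect_true(all(tab$ad$diff == 2L))
  # normalised mass is 1 within every key
  for (k in unique(paste(tab$ad$agegrp, tab$ad$sex))) {
    w <- tab$ad$w[paste(tab$ad$agegrp, tab$ad$sex) == k]
    expect_equal(sum(w / sum(w)), 1)
  }

  # weighted vs unweighted tables differ when weights track the gaps
  iv <- to_cmc(2022, 1)
  resp <- make_respondents(2, age = 30L, interview_cmc = iv)
  sib <- rbind(
    make_sibling("p001", alive = 1L, age_now = 28L, birth_cmc = iv - 342L),
    make_sibling("p002", alive = 1L, age_now = 25L, birth_cmc = iv - 306L))
  tw <- build_reference_tables(sib, resp, weights = c(3, 1))
  expect_equal(tw$ad$w[tw$ad$diff == 2L] / sum(tw$ad$w), 0.75)
  tu <- build_reference_tables(sib, resp)
  expect_equal(tu$ad$w[tu$ad$diff == 2L] / sum(tu$ad$w), 0.5)
})

test_that("the key fallback chain resolves in the documented order", {
  iv <- to_cmc(2022, 1)
  resp <- make_respondents(4, age = c(30L, 30L, 30L, 40L), interview_cmc = iv)
  sib <- rbind(
    make_sibling("p001", sex = "m", alive = 1L, age_now = 28L,
                 birth_cmc = iv - 342L),
    make_sibling("p002", sex = "f", alive = 1L, age_now = 27L,
                 birth_cmc = iv - 330L),
    make_sibling("p004", sex = "f", alive = 1L, age_now = 38L,
                 birth_cmc = iv - 462L))
  tab <- build_reference_tables(sib, resp)

  k <- fallback_key(tab, "age_diff", "30-34", "m")
  expect_equal(k$level, "exact")
  expect_equal(k$sex, "m")
  # sex cell present only for the other sex at 40-44: collapse sex
  k <- fallback_key(tab, "age_diff", "40-44", "m")
  expect_equal(k$level, "sex_collapsed")
  # absent age group: walk to the nearest populated neighbour
  k <- fallback_key(tab, "age_diff", "35-39", "f")
  expect_equal(k$level, "adjacent")
  expect_true(k$agegrp %in% c("30-34", "40-44"))

  # a single populated key serves every other request globally
  one <- degenerate_reference(gap = 2L, n = 4L, resp_age = 52L)
  tab1 <- build_reference_tables(one$siblings, one$respondents)
  expect_warning(k <- fallback_key(tab1, "age_diff", "20-24", "m"), "pooled")
  expect_equal(k$level, "global")
})

test_that("degenerate tables impute deterministically", {
  iv <- to_cmc(2022, 1)
  ref <- degenerate_reference(gap = 2L, resp_age = 30L)
  tab <- build_reference_tables(ref$siblings, ref$respondents)
  resp <- make_respondents(5, age = 30L, interview_cmc = iv)
  smry <- data.frame(respondent_id = resp$respondent_id, sex = "f",
                     n_ever = 3L, n_alive = 3L, n_dead = 0L)
  out <- impute_partial(smry, NULL, resp, tab, to_cmc(2019, 1), seed = 1)
  expect_equal(nrow(out), 15L)
  expect_true(all(out$alive == 1L))
  expect_true(all(out$age_now == 28L))
  expect_true(all(grepl("age_now", out$imputed_fields)))
  expect_length(validate_full_ssh(out, resp), 0L)

  # degenerate joint death schedule: all deaths at age 40, 2 years ago
  dref <- make_respondents(20, age = 30L, interview_cmc = iv)
  dsib <- make_sibling(dref$respondent_id, sex = "f", alive = 0L,
                       age_at_death = 40L, death_cmc = iv - 30L,
                       years_since_death = 2L,
                       birth_cmc = iv - 30L - 486L)
  dtab <- build_reference_tables(dsib, dref)
  smry2 <- data.frame(respondent_id = resp$respondent_id[1], sex = "f",
                      n_ever = 2L, n_alive = 0L, n_dead = 2L)
  outc <- impute_complete(smry2, NULL, resp, dtab, to_cmc(2019, 1), seed = 2)
  expect_true(all(outc$age_at_death == 40L))
  expect_true(all(outc$years_since_death == 2L))
  expect_true(all(outc$death_cmc >= iv - 35L & outc$death_cmc <= iv - 24L))
  expect_true(all(grepl("age_at_death;death_cmc", outc$imputed_fields)))
})

test_that("imputation draws reproduce the reference distributions", {
  # sampling-consistency oracle: total-variation distance at 100000 draws
  iv <- to_cmc(2022, 1)
  gaps <- c(-2L, 0L, 3L)
  probs <- c(0.2, 0.5, 0.3)
  resp_ref <- make_respondents(10, age = 30L, interview_cmc = iv)
  sib_ref <- do.call(rbind, lapply(1:10, function(i) {
    make_sibling(resp_ref$respondent_id[i], sex = "f", alive = 1L,
                 age_now = 30L - rep(gaps, round(probs * 10))[i],
                 birth_cmc = iv - 360L)
  }))
  sib_ref$birth_cmc <- iv - 12L * sib_ref$age_now - 6L
  tab <- build_reference_tables(sib_ref, resp_ref)

  resp <- make_respondents(1, age = 32L, interview_cmc = iv)
  smry <- data.frame(respondent_id = "p001", sex = "f",
                     n_ever = 100000L, n_alive = 100000L, n_dead = 0L)
  out <- impute_partial(smry, NULL, resp, tab, to_cmc(2019, 1), seed = 3)
  emp <- table(factor(32L - out$age_now, levels = gaps)) / nrow(out)
  expect_lt(0.5 * sum(abs(as.numeric(emp) - probs)), 0.01)

  # joint (age at death, time since death) draws in complete mode
  cells <- data.frame(aad = c(40L, 30L), tsd = c(2L, 5L))
  pr <- c(0.25, 0.75)
  resp_d <- make_respondents(8, age = 30L, interview_cmc = iv)
  sib_d <- do.call(rbind, lapply(1:8, function(i) {
    k <- rep(1:2, round(pr * 8))[i]
    dc <- iv - 12L * cells$tsd[k] - 6L
    make_sibling(resp_d$respondent_id[i], sex = "f", alive = 0L,
                 age_at_death = cells$aad[k], death_cmc = dc,
                 years_since_death = cells$tsd[k],
                 birth_cmc = dc - 12L * cells$aad[k] - 6L)
  }))
  dtab <- build_reference_tables(sib_d, resp_d)
  smry2 <- data.frame(respondent_id = "p001", sex = "f",
                      n_ever = 100000L, n_alive = 0L, n_dead = 100000L)
  outc <- impute_complete(smry2, NULL, resp, dtab, to_cmc(2019, 1), seed = 4)
  emp2 <- table(factor(paste(outc$age_at_death, outc$years_since_death),
                       levels = paste(cells$aad, cells$tsd))) / nrow(outc)
  expect_lt(0.5 * sum(abs(as.numeric(emp2) - pr)), 0.01)
})

test_that("imputation conserves counts and reported recent-death details", {
  reg <- calibrate_regime(c(m = 0.2, f = 0.2))
  iv <- to_cmc(2022, 1)
  cutoff <- to_cmc(2019, 1)
  ref <- simulate_sibships(reg, 2500, iv, seed = 5)
  tgt <- simulate_sibships(reg, 2500, iv, seed = 6)
  tab <- build_reference_tables(ref$siblings, ref$respondents)

  for (variant in c("burkina", "drc", "malawi")) {
    coll <- collapse_to_summary(tgt$siblings, tgt$respondents, cutoff, variant)
    for (mode in c("partial", "complete")) {
      fn <- if (mode == "partial") impute_partial else impute_complete
      out <- fn(coll$summary, coll$details, tgt$respondents, tab, cutoff,
                seed = 7)
      got <- collapse_to_summary(out, tgt$respondents, cutoff, variant)
      key <- paste(coll$summary$respondent_id, coll$summary$sex)
      i <- match(key, paste(got$summary$respondent_id, got$summary$sex))
      expect_equal(got$summary$n_ever[i], coll$summary$n_ever,
                   info = paste(variant, mode))
      expect_equal(got$summary$n_alive[i], coll$summary$n_alive,
                   info = paste(variant, mode))
      expect_length(validate_full_ssh(out, tgt$respondents), 0L)
    }
  }

  # partial mode keeps every reported recent-death age and date
  coll <- collapse_to_summary(tgt$siblings, tgt$respondents, cutoff, "burkina")
  out <- impute_partial(coll$summary, coll$details, tgt$respondents, tab,
                        cutoff, seed = 8)
  rec <- out[out$alive == 0L & out$death_cmc >= cutoff, ]
  rec$death_ym <- paste(from_cmc(rec$death_cmc)$year,
                        from_cmc(rec$death_cmc)$month)
  want <- coll$details
  want$death_ym <- paste(want$death_year, want$death_month)
  expect_equal(
    sort(paste(rec$respondent_id, rec$sex, rec$age_at_death, rec$death_ym)),
    sort(paste(want$respondent_id, want$sex, want$age_at_death, want$death_ym)))
  expect_false(any(grepl("age_at_death", rec$imputed_fields)))

  # complete mode flags every death field as imputed instead
  outc <- impute_complete(coll$summary, coll$details, tgt$respondents, tab,
                          cutoff, seed = 9)
  dead <- outc[outc$alive == 0L, ]
  expect_true(all(grepl("age_at_death", dead$imputed_fields)))
  expect_true(all(grepl("death_cmc", dead$imputed_fields)))

  # partial mode places undetailed deaths strictly before the cutoff
  nonrec <- out[out$alive == 0L & grepl("death_cmc", out$imputed_fields), ]
  expect_true(all(nonrec$death_cmc < cutoff))
})

test_that("drc-variant recent deaths get ages conditioned on timing", {
  reg <- calibrate_regime(c(m = 0.25, f = 0.25))
  iv <- to_cmc(2022, 1)
  cutoff <- to_cmc(2019, 1)
  ref <- simulate_sibships(reg, 2000, iv, seed = 10)
  tgt <- simulate_sibships(reg, 800, iv, seed = 11)
  tab <- build_reference_tables(ref$siblings, ref$respondents)
  coll <- collapse_to_summary(tgt$siblings, tgt$respondents, cutoff, "drc")
  expect_true(all(is.na(coll$details$age_at_death)))
  out <- impute_partial(coll$summary, coll$details, tgt$respondents, tab,
                        cutoff, seed = 12)
  rec <- out[out$alive == 0L & out$death_cmc >= cutoff, ]
  expect_equal(nrow(rec), nrow(coll$details))
  expect_true(all(!is.na(rec$age_at_death)))
  expect_true(all(grepl("age_at_death", rec$imputed_fields)))
  # reported dates still honoured
  expect_equal(sort(from_cmc(rec$death_cmc)$year), sort(coll$details$death_year))
})
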