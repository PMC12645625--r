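# shared fixture builders and independent oracles

make_respondents <- function(n, age = 30L, interview_cmc = to_cmc(2022, 1),
                             weight = 1) {
  data.frame(respondent_id = sprintf("p%03d", seq_len(n)),
             sex = rep(c("f", "m"), length.out = n),
             age_years = rep_len(age, n),
             interview_cmc = interview_cmc,
             residence = rep(c("urban", "rural"), length.out = n),
             education = "primary", hh_size_class = "1-4",
             design_weight = rep_len(weight, n),
             stringsAsFactors = FALSE)
}

make_sibling <- function(respondent_id, sex = "f", alive = 1L,
                         age_now = NA, age_at_death = NA,
                         years_since_death = NA, death_cmc = NA,
                         birth_cmc = NA, line_no = 1L) {
  data.frame(respondent_id = respondent_id, line_no = line_no, sex = sex,
             alive = as.integer(alive), age_now = as.integer(age_now),
             age_at_death = as.integer(age_at_death),
             years_since_death = as.integer(years_since_death),
             death_cmc = as.integer(death_cmc),
             birth_cmc = as.integer(birth_cmc),
             imputed_fields = "", stringsAsFactors = FALSE)
}

# random sibling rows with consistent dates, attached to `resp`
random_siblings <- function(n, resp, seed) {
  set.seed(seed)
  iv <- resp$interview_cmc[1]
  birth <- sample((iv - 700L):(iv + 50L), n, replace = TRUE)
  lived <- sample(0:800, n, replace = TRUE)
  dead <- runif(n) < 0.4 & birth + lived < iv
  death <- ifelse(dead, birth + lived, NA_integer_)
  data.frame(
    respondent_id = sample(resp$respondent_id, n, replace = TRUE),
    line_no = 1L, sex = sample(c("m", "f"), n, replace = TRUE),
    alive = as.integer(!dead),
    age_now = ifelse(!dead, pmax((iv - birth) %/% 12L, 0L), NA_integer_),
    age_at_death = ifelse(dead, (death - birth) %/% 12L, NA_integer_),
    years_since_death = ifelse(dead, (iv - death) %/% 12L, NA_integer_),
    death_cmc = as.integer(death), birth_cmc = as.integer(birth),
    imputed_fields = "", stringsAsFactors = FALSE)
}

# month-by-month event-loop oracle for deaths/person-years by age group
oracle_exposure <- function(siblings, respondents, window, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(respondents))
  w <- weights[match(siblings$respondent_id, respondents$respondent_id)]
  D <- PY <- numeric(7)
  for (i in seq_len(nrow(siblings))) {
    b <- siblings$birth_cmc[i]
    stp <- if (siblings$alive[i] == 1L) window[2] else
      min(siblings$death_cmc[i], window[2])
    for (t in window[1]:(window[2] - 1L)) {
      if (t < b || t >= stp) next
      age <- (t - b) %/% 12L
      if (age >= 15L && age < 50L) {
        g <- (age - 15L) %/% 5L + 1L
        PY[g] <- PY[g] + w[i] / 12
      }
    }
    if (siblings$alive[i] == 0L && !is.na(siblings$death_cmc[i]) &&
        siblings$death_cmc[i] >= window[1] && siblings$death_cmc[i] < window[2]) {
      age <- (siblings$death_cmc[i] - b) %/% 12L
      if (age >= 15L && age < 50L) {
        g <- (age - 15L) %/% 5L + 1L
        D[g] <- D[g] + w[i]
      }
    }
  }
  list(D = D, PY = PY)
}

# independent brute-force IPF (no cap), iterated to a fixed point
oracle_ipf <- function(d, targets, iters = 10000) {
  w <- rep(1, nrow(d))
  for (it in seq_len(iters)) {
    for (v in names(targets)) {
      share <- tapply(w, d[[v]], sum) / sum(w)
      f <- targets[[v]][names(share)] / share
      w <- w * f[match(d[[v]], names(share))]
    }
  }
  w / mean(w)
}

# reference fixture with a known degenerate age-difference law: every
# surviving sibling is exactly `gap` years younger than the respondent
degenerate_reference <- function(gap = 2L, n = 40L, resp_age = 30L,
                                 iv = to_cmc(2022, 1)) {
  resp <- make_respondents(n, age = resp_age, interview_cmc = iv)
  sib <- make_sibling(resp$respondent_id, sex = rep(c("m", "f"), n / 2),
                      alive = 1L, age_now = resp_age - gap,
                      birth_cmc = iv - 12L * (resp_age - gap) - 6L)
  list(respondents = resp, siblings = sib)
}
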