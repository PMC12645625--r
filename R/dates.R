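#' Century-month codes
#'
#' Dates are carried internally as century-month codes (CMC), the survey
#' convention in which January 1900 is month 1. `to_cmc()` converts a
#' calendar (year, month) pair to a CMC and `from_cmc()` inverts it exactly.
#'
#' @param year Calendar year (>= 1900). Vectorised.
#' @param month Month 1--12. Vectorised, recycled against `year`.
#' @return `to_cmc()`: integer CMC. `from_cmc()`: a data.frame with columns
#'   `year` and `month`.
#' @examples
#' to_cmc(2019, 1)   # 1429
#' from_cmc(1476)    # December 2022
#' @export
to_cmc <- function(year, month) {
  if (any(year < 1900)) stop("year must be >= 1900")
  if (any(month < 1 | month > 12)) stop("month must be in 1..12")
  as.integer((year - 1900L) * 12L + month)
}

#' @param cmc Integer century-month code (>= 1).
#' @rdname to_cmc
#' @export
from_cmc <- function(cmc) {
  if (any(cmc < 1)) stop("cmc must be >= 1")
  cmc <- as.integer(cmc)
  data.frame(year = 1900L + (cmc - 1L) %/% 12L, month = (cmc - 1L) %% 12L + 1L)
}

#' Derive birth dates for sibling records
#'
#' Fills `birth_cmc` from the recorded age: for surviving siblings from the
#' current age and the interview date, for deceased siblings from the age at
#' death and the date of death. A within-year month offset `j` places the
#' birth inside the 12-month band consistent with the reported completed
#' age; the default `j = 6` (mid-year) is deterministic, `j = "random"`
#' draws uniformly on 0..11 per record from the current RNG stream.
#'
#' @param siblings Full-history sibling data.frame (see [load_full_ssh()]).
#' @param respondents Respondent data.frame supplying `interview_cmc`.
#' @param j Either an integer offset in 0..11 applied to every record, or
#'   `"random"`.
#' @param overwrite Recompute `birth_cmc` even where already set.
#' @return `siblings` with `birth_cmc` filled and flagged in
#'   `imputed_fields`.
#' @export
derive_birth_cmc <- function(siblings, respondents, j = 6L, overwrite = FALSE) {
  iv <- respondents$interview_cmc[match(siblings$respondent_id, respondents$respondent_id)]
  if (anyNA(iv)) stop("some siblings reference unknown respondents")
  n <- nrow(siblings)
  jj <- if (identical(j, "random")) sample.int(12L, n, replace = TRUE) - 1L else {
    stopifnot(j %in% 0:11); rep(as.integer(j), n)
  }
  todo <- if (overwrite) rep(TRUE, n) else is.na(siblings$birth_cmc)
  alive <- siblings$alive == 1L
  b <- siblings$birth_cmc
  can_alive <- alive & !is.na(siblings$age_now)
  can_dead <- !alive & !is.na(siblings$age_at_death) & !is.na(siblings$death_cmc)
  if (any(todo & !(can_alive | can_dead))) {
    stop("cannot derive birth_cmc: age or death date missing; impute first")
  }
  i <- todo & can_alive
  b[i] <- iv[i] - 12L * siblings$age_now[i] - jj[i]
  i <- todo & can_dead
  b[i] <- siblings$death_cmc[i] - 12L * siblings$age_at_death[i] - jj[i]
  siblings$birth_cmc <- as.integer(b)
  siblings$imputed_fields <- ifelse(todo & (can_alive | can_dead),
    add_imputed_flag(siblings$imputed_fields, "birth_cmc"),
    siblings$imputed_fields)
  siblings
}

# append a field name to the semicolon-separated provenance flag
add_imputed_flag <- function(flags, field) {
  flags[is.na(flags)] <- ""
  ifelse(flags == "", field,
    ifelse(grepl(paste0("(^|;)", field, "($|;)"), flags), flags,
      paste(flags, field, sep = ";")))
}

# 5-year age-group label factory used across modules
age_group_5 <- function(age, lo = 15L, hi = 64L) {
  x <- pmin(pmax(age, lo), hi)
  g <- lo + 5L * ((x - lo) %/% 5L)
  sprintf("%d-%d", g, g + 4L)
}
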