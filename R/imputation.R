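#' Build hot-deck reference tables from a full sibling history
#'
#' Tabulates, from a reference survey with observed (non-imputed) ages and
#' dates, the two empirical distributions used to reconstruct full
#' histories from summary ones:
#' * an age-difference table: weighted histogram of respondent age minus
#'   sibling current age for surviving siblings, keyed by the respondent's
#'   5-year age group and the sibling's sex;
#' * a death-schedule table: weighted joint histogram of (age at death,
#'   time since death in completed years) for deceased siblings, under the
#'   same keys.
#'
#' Empty keys are not an error: draws resolve them later through the
#' fallback chain (see [fallback_key()]).
#'
#' @param siblings,respondents Reference full-history tables.
#' @param weights Optional respondent-level weights (defaults to the
#'   `design_weight` column, else 1).
#' @param max_gap Age differences outside `[-max_gap, max_gap]` are dropped.
#' @return An object of class `ref_tables` with data.frame components `ad`
#'   (`agegrp, sex, diff, w`) and `ds` (`agegrp, sex, aad, tsd, w`).
#' @export
build_reference_tables <- function(siblings, respondents, weights = NULL,
                                   max_gap = 40L) {
  if (is.null(weights)) {
    weights <- if (!is.null(respondents$ps_weight)) respondents$ps_weight else
      if (!is.null(respondents$design_weight)) respondents$design_weight else
        rep(1, nrow(respondents))
  }
  ri <- match(siblings$respondent_id, respondents$respondent_id)
  if (anyNA(ri)) stop("siblings reference unknown respondents")
  g <- age_group_5(respondents$age_years)[ri]
  iv <- respondents$interview_cmc[ri]
  w <- weights[ri]
  resp_age <- respondents$age_years[ri]

  agg <- function(w, by) {
    if (!length(w)) {
      return(cbind(as.data.frame(lapply(by, function(x) x[0])),
                   data.frame(w = numeric())))
    }
    stats::aggregate(list(w = w), by = by, FUN = sum)
  }
  al <- siblings$alive == 1L & !is.na(siblings$age_now)
  diff <- resp_age - siblings$age_now
  al <- al & !is.na(diff) & abs(diff) <= max_gap
  ad <- agg(w[al], list(agegrp = g[al], sex = siblings$sex[al],
                        diff = diff[al]))

  dd <- siblings$alive == 0L & !is.na(siblings$age_at_death) &
    !is.na(siblings$death_cmc)
  tsd <- (iv - siblings$death_cmc) %/% 12L
  dd <- dd & siblings$age_at_death >= 0L & siblings$age_at_death <= 94L &
    !is.na(tsd) & tsd >= 0L & tsd <= 49L
  ds <- agg(w[dd], list(agegrp = g[dd], sex = siblings$sex[dd],
                        aad = siblings$age_at_death[dd], tsd = tsd[dd]))

  structure(list(ad = ad, ds = ds, age_levels = unique(age_group_5(15:95))),
            class = "ref_tables")
}

#' Resolve a reference-table key through the fallback chain
#'
#' When the exact (respondent age group, sibling sex) cell of a reference
#' table is empty, draws fall back in order: collapse the sibling sex;
#' move to the nearest adjacent respondent age group (sex-specific, then
#' collapsed); finally pool the whole table. The resolved key is returned
#' so callers can log it.
#'
#' @param tables A `ref_tables` object.
#' @param table `"age_diff"` or `"death_schedule"`.
#' @param agegrp Respondent 5-year age-group label, e.g. `"25-29"`.
#' @param sex Sibling sex `"m"`, `"f"` or `"u"` (combined).
#' @return List with the resolved `agegrp` (possibly `"all"`), `sex`
#'   (possibly `"all"`) and the fallback `level` used
#'   (`"exact"`, `"sex_collapsed"`, `"adjacent"`, `"adjacent_collapsed"`,
#'   `"global"`).
#' @export
fallback_key <- function(tables, table = c("age_diff", "death_schedule"),
                         agegrp, sex) {
  table <- match.arg(table)
  tab <- if (table == "age_diff") tables$ad else tables$ds
  sel <- resolve_cells(tab, agegrp, sex, tables$age_levels)
  sel$key
}

# returns list(rows = df subset, key = list(agegrp, sex, level))
resolve_cells <- function(tab, agegrp, sex, age_levels) {
  if (nrow(tab) == 0L) stop("reference table is empty")
  pick <- function(g, s) {
    r <- tab[(is.na(g) | tab$agegrp == g) & (is.na(s) | tab$sex == s), ,
             drop = FALSE]
    if (nrow(r)) r else NULL
  }
  hit <- function(rows, g, s, level) {
    list(rows = rows, key = list(agegrp = g, sex = s, level = level))
  }
  if (sex != "u") {
    r <- pick(agegrp, sex)
    if (!is.null(r)) return(hit(r, agegrp, sex, "exact"))
  }
  r <- pick(agegrp, NA)
  if (!is.null(r)) {
    return(hit(r, agegrp, "all",
               if (sex == "u") "exact" else "sex_collapsed"))
  }
  i0 <- match(agegrp, age_levels)
  if (!is.na(i0)) {
    for (d in 1L) {
      for (g in age_levels[c(i0 - d, i0 + d)[c(i0 - d, i0 + d) >= 1]]) {
        if (is.na(g)) next
        if (sex != "u") {
          r <- pick(g, sex)
          if (!is.null(r)) return(hit(r, g, sex, "adjacent"))
        }
        r <- pick(g, NA)
        if (!is.null(r)) return(hit(r, g, "all", "adjacent_collapsed"))
      }
    }
  }
  warning("falling back to globally pooled reference table for key (",
          agegrp, ", ", sex, ")")
  hit(tab, "all", "all", "global")
}

#' Reconstruct full sibling histories from summary histories
#'
#' Hot-deck imputation of the ages and dates a shortened sibling module
#' does not collect, drawing from the empirical distributions of a
#' reference survey ([build_reference_tables()]).
#'
#' `impute_partial()` keeps everything the respondent reported: surviving
#' siblings get a current age via a drawn respondent-sibling age
#' difference; recent deaths keep their reported sex, age at death and
#' death date (only genuinely missing fields, such as the death month or
#' the age at death in the DRC variant, are filled, conditioning on the
#' reported time since death where possible); deaths predating the recency
#' cutoff get an (age at death, time since death) pair drawn from the
#' death schedule restricted to times consistent with the death being
#' non-recent.
#'
#' `impute_complete()` discards all reported death detail and draws (age
#' at death, time since death) jointly from the death schedule for every
#' deceased sibling; surviving siblings are treated as in partial mode.
#'
#' @param summary_ssh Summary table (`respondent_id, sex, n_ever, n_alive,
#'   n_dead`), one row per respondent (per sibling sex where collected).
#' @param details Recent-death detail rows (`respondent_id, sex,
#'   age_at_death, death_year, death_month`); ignored by complete mode.
#' @param respondents Respondent roster with `age_years`, `interview_cmc`.
#' @param tables A `ref_tables` object from the reference survey.
#' @param cutoff_cmc Recency cutoff used by the summary instrument.
#' @param seed Optional seed.
#' @return A full sibling-history data.frame; imputed fields are flagged
#'   in `imputed_fields`.
#' @export
impute_partial <- function(summary_ssh, details, respondents, tables,
                           cutoff_cmc, seed = NULL) {
  impute_ssh(summary_ssh, details, respondents, tables, cutoff_cmc,
             mode = "partial", seed = seed)
}

#' @rdname impute_partial
#' @export
impute_complete <- function(summary_ssh, details, respondents, tables,
                            cutoff_cmc, seed = NULL) {
  impute_ssh(summary_ssh, details, respondents, tables, cutoff_cmc,
             mode = "complete", seed = seed)
}

impute_ssh <- function(summary_ssh, details, respondents, tables, cutoff_cmc,
                       mode = c("partial", "complete"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tables, "ref_tables"))
  if (!is.null(seed)) set.seed(seed)
  ri <- match(summary_ssh$respondent_id, respondents$respondent_id)
  if (anyNA(ri)) stop("summary rows reference unknown respondents")
  if (is.null(summary_ssh$sex)) summary_ssh$sex <- "u"
  smry <- summary_ssh
  smry$agegrp <- age_group_5(respondents$age_years)[ri]
  smry$resp_age <- respondents$age_years[ri]
  smry$iv <- respondents$interview_cmc[ri]

  out <- list(
    alive_rows(smry, tables),
    if (mode == "partial") recent_rows(smry, details, tables, cutoff_cmc),
    nonrecent_rows(smry, details, tables, cutoff_cmc, mode)
  )
  sib <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(sib) || nrow(sib) == 0L) {
    sib <- empty_full_ssh()
  }
  sib <- sib[order(match(sib$respondent_id, respondents$respondent_id)), ,
             drop = FALSE]
  sib$line_no <- stats::ave(seq_len(nrow(sib)),
                            sib$respondent_id, FUN = seq_along)
  rownames(sib) <- NULL
  sib[FULL_SSH_COLS]
}

empty_full_ssh <- function() {
  data.frame(respondent_id = character(), line_no = integer(),
             sex = character(), alive = integer(), age_now = integer(),
             age_at_death = integer(), years_since_death = integer(),
             death_cmc = integer(), birth_cmc = integer(),
             imputed_fields = character(), stringsAsFactors = FALSE)
}

# surviving siblings: age from a drawn respondent-sibling age difference
alive_rows <- function(smry, tables) {
  src <- smry[smry$n_alive > 0, , drop = FALSE]
  if (!nrow(src)) return(NULL)
  idx <- rep(seq_len(nrow(src)), src$n_alive)
  d <- src[idx, c("respondent_id", "sex", "agegrp", "resp_age", "iv")]
  d$age_now <- NA_integer_
  for (key in unique(paste(d$agegrp, d$sex))) {
    i <- which(paste(d$agegrp, d$sex) == key)
    cells <- resolve_cells(tables$ad, d$agegrp[i[1]], d$sex[i[1]],
                           tables$age_levels)$rows
    age <- d$resp_age[i] - draw_from(cells, length(i))$diff
    # redraw implausible ages, then clamp: keeps sibling counts conserved
    for (t in 1:10) {
      bad <- age < 0 | age > 95
      if (!any(bad)) break
      age[bad] <- d$resp_age[i][bad] - draw_from(cells, sum(bad))$diff
    }
    d$age_now[i] <- pmin(pmax(age, 0L), 95L)
  }
  n <- nrow(d)
  data.frame(respondent_id = d$respondent_id, line_no = NA_integer_,
             sex = d$sex, alive = 1L, age_now = as.integer(d$age_now),
             age_at_death = NA_integer_, years_since_death = NA_integer_,
             death_cmc = NA_integer_,
             birth_cmc = as.integer(d$iv - 12L * d$age_now -
                                      sample(0:11, n, replace = TRUE)),
             imputed_fields = "age_now;birth_cmc",
             stringsAsFactors = FALSE)
}

# recent deaths in partial mode: keep reported fields, fill only gaps
recent_rows <- function(smry, details, tables, cutoff_cmc) {
  if (is.null(details) || nrow(details) == 0L) return(NULL)
  key <- paste(smry$respondent_id, smry$sex)
  di <- match(paste(details$respondent_id, details$sex), key)
  if (anyNA(di)) di <- match(details$respondent_id, smry$respondent_id)
  if (anyNA(di)) stop("recent-death details reference unknown respondents")
  d <- details
  d$agegrp <- smry$agegrp[di]
  d$resp_age <- smry$resp_age[di]
  d$iv <- smry$iv[di]
  n <- nrow(d)
  flags <- rep("birth_cmc", n)

  cm <- from_cmc(cutoff_cmc)
  miss_m <- is.na(d$death_month)
  if (any(miss_m)) {
    lo <- ifelse(d$death_year[miss_m] == cm$year, cm$month, 1L)
    d$death_month[miss_m] <- lo +
      floor(stats::runif(sum(miss_m)) * (12L - lo + 1L))
    flags[miss_m] <- add_imputed_flag(flags[miss_m], "death_month")
  }
  death_cmc <- pmin(to_cmc(d$death_year, d$death_month), d$iv)

  miss_a <- is.na(d$age_at_death)
  if (any(miss_a)) {
    for (i in which(miss_a)) {
      cells <- resolve_cells(tables$ds, d$agegrp[i], d$sex[i],
                             tables$age_levels)$rows
      tsd_i <- (d$iv[i] - death_cmc[i]) %/% 12L
      for (wd in 0:49) {
        sub <- cells[abs(cells$tsd - tsd_i) <= wd, , drop = FALSE]
        if (nrow(sub)) break
      }
      d$age_at_death[i] <- draw_from(sub, 1L)$aad
    }
    flags[miss_a] <- add_imputed_flag(flags[miss_a], "age_at_death")
  }
  data.frame(respondent_id = d$respondent_id, line_no = NA_integer_,
             sex = d$sex, alive = 0L, age_now = NA_integer_,
             age_at_death = as.integer(d$age_at_death),
             years_since_death = as.integer((d$iv - death_cmc) %/% 12L),
             death_cmc = as.integer(death_cmc),
             birth_cmc = as.integer(death_cmc - 12L * d$age_at_death -
                                      sample(0:11, n, replace = TRUE)),
             imputed_fields = flags, stringsAsFactors = FALSE)
}

# deaths drawn from the joint (age at death, time since death) schedule:
# all deaths in complete mode, only pre-cutoff deaths in partial mode
nonrecent_rows <- function(smry, details, tables, cutoff_cmc, mode) {
  n_detail <- if (mode == "partial" && !is.null(details) && nrow(details)) {
    tab <- table(paste(details$respondent_id, details$sex))
    k <- paste(smry$respondent_id, smry$sex)
    got <- as.integer(tab[k])
    got[is.na(got)] <- 0L
    # combined-sex detail rows (sex masked) matched on respondent only
    if (sum(got) < nrow(details)) {
      tab2 <- table(details$respondent_id)
      got2 <- as.integer(tab2[smry$respondent_id])
      got2[is.na(got2)] <- 0L
      got <- pmax(got, ifelse(got == 0L, got2, got))
    }
    got
  } else rep(0L, nrow(smry))
  n_draw <- if (mode == "partial") smry$n_dead - n_detail else smry$n_dead
  if (any(n_draw < 0)) stop("more recent-death detail rows than n_dead")
  src <- smry[n_draw > 0, , drop = FALSE]
  n_draw <- n_draw[n_draw > 0]
  if (!nrow(src)) return(NULL)
  idx <- rep(seq_len(nrow(src)), n_draw)
  d <- src[idx, c("respondent_id", "sex", "agegrp", "resp_age", "iv")]
  d$wy <- if (mode == "partial") (d$iv - cutoff_cmc) %/% 12L else -1L
  d$aad <- NA_integer_
  d$tsd <- NA_integer_
  for (key in unique(paste(d$agegrp, d$sex, d$wy))) {
    i <- which(paste(d$agegrp, d$sex, d$wy) == key)
    cells <- resolve_cells(tables$ds, d$agegrp[i[1]], d$sex[i[1]],
                           tables$age_levels)$rows
    if (d$wy[i[1]] >= 0L) {
      # the respondent asserted these deaths predate the recency cutoff
      trunc <- cells[cells$tsd >= d$wy[i[1]], , drop = FALSE]
      if (nrow(trunc) == 0L) {
        trunc <- tables$ds[tables$ds$tsd >= d$wy[i[1]], , drop = FALSE]
      }
      if (nrow(trunc)) cells <- trunc
    }
    dr <- draw_from(cells, length(i))
    d$aad[i] <- dr$aad
    d$tsd[i] <- dr$tsd
  }
  n <- nrow(d)
  death <- d$iv - 12L * d$tsd - sample(0:11, n, replace = TRUE)
  if (mode == "partial") death <- pmin(death, cutoff_cmc - 1L)
  data.frame(respondent_id = d$respondent_id, line_no = NA_integer_,
             sex = d$sex, alive = 0L, age_now = NA_integer_,
             age_at_death = as.integer(d$aad),
             years_since_death = as.integer((d$iv - death) %/% 12L),
             death_cmc = as.integer(death),
             birth_cmc = as.integer(death - 12L * d$aad -
                                      sample(0:11, n, replace = TRUE)),
             imputed_fields = "age_at_death;death_cmc;years_since_death;birth_cmc",
             stringsAsFactors = FALSE)
}

# categorical draw of n rows from a weighted cell table
draw_from <- function(cells, n) {
  if (nrow(cells) == 0L) stop("no reference cells to draw from")
  if (nrow(cells) == 1L) return(cells[rep(1L, n), , drop = FALSE])
  cells[sample.int(nrow(cells), n, replace = TRUE, prob = cells$w), ,
        drop = FALSE]
}
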