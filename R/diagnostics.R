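#' Sibship data-quality summaries by respondent age group
#'
#' The three descriptive checks used to judge summary sibling data: mean
#' siblings ever born, proportion of siblings surviving, and the
#' proportion of deceased siblings whose death falls within the recency
#' window. Accepts either a full sibling history or a summary table (with
#' its recent-death detail rows); a full history and its own collapsed
#' summary give identical results. Proportions are ratios of (weighted)
#' sums, so respondents reporting no deceased siblings do not enter the
#' recent-death denominator.
#'
#' @param x Full sibling history data.frame, or a summary table
#'   (`respondent_id, n_ever, n_alive, n_dead`).
#' @param respondents Respondent roster.
#' @param recency_window Months before the interview counting as recent.
#' @param weights Optional respondent-level weights (default `ps_weight`,
#'   then `design_weight`, then 1).
#' @param details Recent-death detail rows (summary form only); rows per
#'   respondent are counted as recent deaths.
#' @return Data.frame per respondent 5-year age group with weighted and
#'   unweighted `mean_siblings`, `prop_surviving`, `prop_recent_deaths`
#'   (NaN where a group reports no deaths) and `n_respondents`.
#' @export
quality_table <- function(x, respondents, recency_window = 36L,
                          weights = NULL, details = NULL) {
  if (is.null(weights)) {
    weights <- if (!is.null(respondents$ps_weight)) respondents$ps_weight else
      if (!is.null(respondents$design_weight)) respondents$design_weight else
        rep(1, nrow(respondents))
  }
  rid <- respondents$respondent_id
  per <- data.frame(respondent_id = rid,
                    agegrp = age_group_5(respondents$age_years),
                    w = weights, stringsAsFactors = FALSE)
  cnt <- function(ids) {
    v <- as.integer(table(factor(ids, levels = rid)))
    v
  }
  if (!is.null(x$n_ever)) {
    agg <- stats::aggregate(x[c("n_ever", "n_alive", "n_dead")],
                            by = list(respondent_id = x$respondent_id), sum)
    i <- match(rid, agg$respondent_id)
    per$n_ever <- ifelse(is.na(i), 0L, agg$n_ever[i])
    per$n_alive <- ifelse(is.na(i), 0L, agg$n_alive[i])
    per$n_dead <- ifelse(is.na(i), 0L, agg$n_dead[i])
    per$n_recent <- if (!is.null(details) && nrow(details)) {
      cnt(details$respondent_id)
    } else 0L
  } else {
    iv <- respondents$interview_cmc[match(x$respondent_id, rid)]
    per$n_ever <- cnt(x$respondent_id)
    per$n_alive <- cnt(x$respondent_id[x$alive == 1L])
    per$n_dead <- per$n_ever - per$n_alive
    rec <- x$alive == 0L & !is.na(x$death_cmc) &
      x$death_cmc >= iv - recency_window
    per$n_recent <- cnt(x$respondent_id[rec])
  }
  groups <- split(per, per$agegrp)
  rows <- lapply(groups, function(gp) {
    data.frame(
      age_group = gp$agegrp[1],
      n_respondents = nrow(gp),
      mean_siblings = sum(gp$w * gp$n_ever) / sum(gp$w),
      prop_surviving = sum(gp$w * gp$n_alive) / sum(gp$w * gp$n_ever),
      prop_recent_deaths = sum(gp$w * gp$n_recent) / sum(gp$w * gp$n_dead),
      mean_siblings_unw = mean(gp$n_ever),
      prop_surviving_unw = sum(gp$n_alive) / sum(gp$n_ever),
      prop_recent_deaths_unw = sum(gp$n_recent) / sum(gp$n_dead),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$age_group), , drop = FALSE]
}

#' Myers' blended index of age heaping
#'
#' Measures digit preference in reported ages on the standard blended
#' 0--90 scale: 0 means every terminal digit carries 10% of the blended
#' population, 90 means all ages share one terminal digit. For digit `d`,
#' `S1_d` sums counts at ages `L+d, L+10+d, ...` over all but the last
#' decade of the range, `S2_d` the same shifted one decade up; the blended
#' count is `B_d = (d+1) S1_d + (9-d) S2_d`, and the index is half the sum
#' of absolute deviations of the blended percentages from 10.
#'
#' @param ages Integer ages (ages outside `range` are dropped).
#' @param range Length-2 decade-aligned range, default `c(10, 89)`.
#' @return Object of class `myers_index`: list with `index`, `pct`
#'   (blended percentage per terminal digit), `range`, `n`.
#' @export
myers_index <- function(ages, range = c(10L, 89L)) {
  lo <- range[1]; hi <- range[2]
  if (lo %% 10L != 0L || (hi + 1L - lo) %% 10L != 0L || hi <= lo) {
    stop("range must be decade-aligned, e.g. c(10, 89)")
  }
  ages <- ages[!is.na(ages) & ages >= lo & ages <= hi]
  if (!length(ages)) stop("no ages in range")
  ndec <- (hi + 1L - lo) %/% 10L
  counts <- tabulate(ages - lo + 1L, nbins = hi - lo + 1L)
  S1 <- S2 <- numeric(10)
  for (d in 0:9) {
    a1 <- lo + d + 10L * (0:(ndec - 2L))
    S1[d + 1] <- sum(counts[a1 - lo + 1L])
    S2[d + 1] <- sum(counts[a1 + 10L - lo + 1L])
  }
  B <- (1:10) * S1 + (9:0) * S2
  pct <- 100 * B / sum(B)
  structure(list(index = 0.5 * sum(abs(pct - 10)),
                 pct = stats::setNames(pct, 0:9),
                 range = c(lo, hi), n = length(ages)),
            class = "myers_index")
}

#' @export
print.myers_index <- function(x, ...) {
  cat(sprintf("Myers' blended index: %.1f (ages %d-%d, n = %d)\n",
              x$index, x$range[1], x$range[2], x$n))
  invisible(x)
}

#' Relative bias of an estimate against a reference
#'
#' Signed percentage difference `100 * (estimate - reference) / reference`.
#' Reported values are conventionally rounded to the nearest integer
#' percent; full precision is returned.
#'
#' @param estimate,reference Numeric; `reference` must be positive.
#' @export
relative_bias <- function(estimate, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (estimate - reference) / reference
}
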