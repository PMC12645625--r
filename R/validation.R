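#' Paired-survey validation of the imputation approaches
#'
#' Replays the imputation validation design on synthetic data: for each
#' replicate, two independent surveys are simulated from the same regime;
#' the first ("reference", standing in for an earlier face-to-face survey
#' with full histories) supplies the hot-deck tables, the second
#' ("target") is collapsed to the shortened summary instrument and
#' reconstructed by partial and complete imputation. Adult mortality over
#' the window preceding the interview is then estimated three ways —
#' directly from the target's full histories, and from each imputed
#' reconstruction — and compared by mean absolute percentage deviation
#' (MAPE) and the median imputed/direct ratio, per sex.
#'
#' @param regime `lt_regime` for both surveys.
#' @param n_respondents Respondents per simulated survey.
#' @param n_replicates Number of paired replicates.
#' @param errors [error_model()] applied to the target survey before
#'   collapsing (default: no reporting errors).
#' @param variant Summary-instrument variant (see [collapse_to_summary()]).
#' @param interview_cmc,cutoff_cmc Interview date and recency cutoff.
#' @param window_months Estimation window before the interview.
#' @param shock_factor,shock_months Optional recent mortality shock
#'   multiplying target-survey hazards by `shock_factor` during the last
#'   `shock_months` before the interview (breaks stationarity, the setting
#'   in which complete imputation degrades).
#' @param seed Optional seed for the whole experiment.
#' @return Object of class `validation_report`: list with `replicates`
#'   (one row per replicate x sex), `summary` (MAPE and median ratio per
#'   method and sex) and `config`.
#' @export
run_paired_experiment <- function(regime, n_respondents = 4000,
                                  n_replicates = 20,
                                  errors = error_model(),
                                  variant = "burkina",
                                  interview_cmc = to_cmc(2022, 1),
                                  cutoff_cmc = to_cmc(2019, 1),
                                  window_months = 36L,
                                  shock_factor = 1, shock_months = NULL,
                                  seed = NULL) {
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(shock_months)) shock_months <- window_months
  sexes <- if (variant == "malawi") "both" else c("male", "female")
  window <- c(interview_cmc - window_months, interview_cmc)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    ref <- simulate_sibships(regime, n_respondents, interview_cmc)
    tgt <- simulate_sibships(regime, n_respondents, interview_cmc)
    if (shock_factor != 1) {
      tgt$siblings <- apply_mortality_shock(
        tgt$siblings, tgt$respondents, regime, shock_factor,
        c(interview_cmc - shock_months, interview_cmc))
    }
    tgt$siblings <- inject_errors(tgt$siblings, tgt$respondents, errors)
    tables <- build_reference_tables(ref$siblings, ref$respondents)
    coll <- collapse_to_summary(tgt$siblings, tgt$respondents, cutoff_cmc,
                                variant)
    imp_p <- impute_partial(coll$summary, coll$details, tgt$respondents,
                            tables, cutoff_cmc)
    imp_c <- impute_complete(coll$summary, coll$details, tgt$respondents,
                             tables, cutoff_cmc)
    for (sx in sexes) {
      est <- tryCatch(list(
        direct = estimate_35q15(tgt$siblings, tgt$respondents, window,
                                sex = sx, se_method = "none")$q35_15,
        partial = estimate_35q15(imp_p, tgt$respondents, window,
                                 sex = sx, se_method = "none")$q35_15,
        complete = estimate_35q15(imp_c, tgt$respondents, window,
                                  sex = sx, se_method = "none")$q35_15),
        error = function(e) NULL)
      if (is.null(est)) {
        warning("replicate ", r, " (", sx, ") dropped: estimation failed")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, sex = sx, direct = est$direct,
        partial = est$partial, complete = est$complete,
        stringsAsFactors = FALSE)
    }
  }
  rep_df <- do.call(rbind, rows)
  if (is.null(rep_df)) stop("all replicates failed")
  agg <- lapply(split(rep_df, rep_df$sex), function(d) {
    data.frame(
      sex = d$sex[1], n_replicates = nrow(d),
      mape_partial = mean(100 * abs(d$partial - d$direct) / d$direct),
      mape_complete = mean(100 * abs(d$complete - d$direct) / d$direct),
      ratio_partial = stats::median(d$partial / d$direct),
      ratio_complete = stats::median(d$complete / d$direct),
      stringsAsFactors = FALSE)
  })
  smry <- do.call(rbind, agg)
  rownames(smry) <- NULL
  structure(list(replicates = rep_df, summary = smry,
                 config = list(n_respondents = n_respondents,
                               n_replicates = n_replicates,
                               variant = variant,
                               interview_cmc = interview_cmc,
                               cutoff_cmc = cutoff_cmc,
                               window_months = window_months,
                               shock_factor = shock_factor,
                               shock_months = shock_months,
                               errors = unclass(errors), seed = seed)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Paired-survey imputation validation: %d replicates x %d respondents\n",
              x$config$n_replicates, x$config$n_respondents))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run the full shortened-instrument analysis pipeline
#'
#' End-to-end orchestration on simulated data: simulate a population and
#' a reference survey, apply phone-ownership selection, rake
#' post-stratification weights to the known population margins (cap 2),
#' collapse to the shortened summary instrument, impute full histories
#' (partial and complete), estimate adult mortality with jackknife
#' intervals, and compute data-quality diagnostics. Deterministic for a
#' fixed seed; optionally writes all outputs as CSV/JSON under `out_dir`.
#'
#' @param config Named list; recognised keys (all optional):
#'   `n_respondents` (default 2000), `target_35q15` (default
#'   `c(m = 0.15, f = 0.15)`), `fertility_mean` (6), `errors` (list of
#'   [error_model()] arguments), `selection` (list of [selection_model()]
#'   arguments; `NULL` for none), `rake_targets` (margin list; defaults to
#'   the simulator's population margins), `cap` (2), `variant`
#'   (`"burkina"`), `interview` (`list(year = 2022, month = 1)`),
#'   `recency_cutoff` (`list(year = 2019, month = 1)`), `window_months`
#'   (36), `seed` (1), `out_dir` (`NULL`).
#' @return List with `respondents`, `weights`, `summary`, `details`,
#'   `imputed_partial`, `imputed_complete`, `estimates` (data.frame),
#'   `quality`, `myers`, `provenance`.
#' @export
run_full_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    n_respondents = 2000L, target_35q15 = c(m = 0.15, f = 0.15),
    fertility_mean = 6, errors = list(), selection = NULL,
    rake_targets = NULL, cap = 2, variant = "burkina",
    interview = list(year = 2022, month = 1),
    recency_cutoff = list(year = 2019, month = 1),
    window_months = 36L, seed = 1L, out_dir = NULL), config)
  set.seed(cfg$seed)
  iv <- to_cmc(cfg$interview$year, cfg$interview$month)
  cutoff <- to_cmc(cfg$recency_cutoff$year, cfg$recency_cutoff$month)
  regime <- calibrate_regime(cfg$target_35q15,
                             fertility_mean = cfg$fertility_mean)

  ref <- simulate_sibships(regime, cfg$n_respondents, iv)
  pop <- simulate_sibships(regime, cfg$n_respondents, iv)
  samp <- if (!is.null(cfg$selection)) {
    apply_selection(pop$respondents, pop$siblings,
                    do.call(selection_model, cfg$selection))
  } else pop
  samp$siblings <- inject_errors(samp$siblings, samp$respondents,
                                 do.call(error_model, cfg$errors))

  targets <- cfg$rake_targets
  if (is.null(targets)) {
    targets <- list(residence = c(urban = 0.35, rural = 0.65),
                    education = c(none = 0.40, primary = 0.35,
                                  "secondary+" = 0.25),
                    hh_size_class = c("1-4" = 0.5, "5+" = 0.5))
  }
  rk <- rake(samp$respondents, targets, cap = cfg$cap)
  samp$respondents$ps_weight <- rk$weights

  tables <- build_reference_tables(ref$siblings, ref$respondents)
  coll <- collapse_to_summary(samp$siblings, samp$respondents, cutoff,
                              cfg$variant)
  imp_p <- impute_partial(coll$summary, coll$details, samp$respondents,
                          tables, cutoff)
  imp_c <- impute_complete(coll$summary, coll$details, samp$respondents,
                           tables, cutoff)

  window <- c(iv - cfg$window_months, iv)
  sexes <- if (cfg$variant == "malawi") "both" else c("both", "male", "female")
  est_rows <- list()
  for (mode in c("partial", "complete")) {
    sib <- if (mode == "partial") imp_p else imp_c
    for (sx in sexes) {
      e <- tryCatch(estimate_35q15(sib, samp$respondents, window, sex = sx),
                    error = function(err) {
                      stop("estimation stage failed (", mode, ", ", sx, "): ",
                           conditionMessage(err))
                    })
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        mode = mode, sex = sx, q35_15 = e$q35_15, se = e$se,
        ci_low = e$ci[1], ci_high = e$ci[2], deaths = e$n_deaths,
        person_years = e$person_years, stringsAsFactors = FALSE)
    }
  }
  estimates <- do.call(rbind, est_rows)
  quality <- quality_table(samp$siblings, samp$respondents,
                           recency_window = cfg$window_months,
                           weights = rk$weights)
  aad <- samp$siblings$age_at_death
  myers <- if (sum(!is.na(aad) & aad >= 10 & aad <= 89) >= 50) {
    myers_index(aad[!is.na(aad)])
  } else NULL
  prov <- list(package_version = as.character(utils::packageVersion("sibmort")),
               seed = cfg$seed,
               config = cfg[setdiff(names(cfg), "out_dir")])

  out <- list(respondents = samp$respondents, weights = rk,
              summary = coll$summary, details = coll$details,
              imputed_partial = imp_p, imputed_complete = imp_c,
              estimates = estimates, quality = quality, myers = myers,
              provenance = prov)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    op <- function(f) file.path(cfg$out_dir, f)
    write_respondents(samp$respondents, op("respondents.csv"))
    write_summary_ssh(coll$summary, coll$details, op("summary_ssh.csv"),
                      op("recent_deaths.csv"))
    write_full_ssh(imp_p, op("full_ssh_partial.csv"))
    write_full_ssh(imp_c, op("full_ssh_complete.csv"))
    utils::write.csv(estimates, op("estimates.csv"), row.names = FALSE)
    utils::write.csv(quality, op("quality_table.csv"), row.names = FALSE)
    jsonlite::write_json(prov, op("provenance.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  out
}
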