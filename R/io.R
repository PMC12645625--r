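#' Read and write sibling-history tables
#'
#' Plain-CSV readers and writers for the three tables the package works
#' with: respondent rosters, full sibling histories (one row per sibling),
#' and summary sibling histories (per-respondent counts plus detail rows
#' for recent deaths). Loading validates the row-level invariants of each
#' table and fails with a per-row report when a hard violation is found.
#'
#' Full-history columns: `respondent_id`, `line_no`, `sex` (m/f/u),
#' `alive` (0/1), `age_now`, `age_at_death`, `years_since_death`,
#' `death_cmc`, `birth_cmc`, `imputed_fields`; blank where unset.
#'
#' @param path CSV file path.
#' @param respondents Optional respondent table; when supplied, death dates
#'   are checked against the owner's interview date.
#' @return `load_full_ssh()`: the sibling data.frame.
#' @name ssh_io
NULL

FULL_SSH_COLS <- c("respondent_id", "line_no", "sex", "alive", "age_now",
                   "age_at_death", "years_since_death", "death_cmc",
                   "birth_cmc", "imputed_fields")

#' @rdname ssh_io
#' @export
load_full_ssh <- function(path, respondents = NULL) {
  d <- utils::read.csv(path, colClasses = c(respondent_id = "character"))
  need <- setdiff(c("respondent_id", "line_no", "sex", "alive"), names(d))
  if (length(need)) stop("full SSH file missing columns: ", paste(need, collapse = ", "))
  for (col in FULL_SSH_COLS) if (is.null(d[[col]])) d[[col]] <- NA
  d <- d[FULL_SSH_COLS]
  d$imputed_fields[is.na(d$imputed_fields)] <- ""
  for (col in c("line_no", "alive", "age_now", "age_at_death",
                "years_since_death", "death_cmc", "birth_cmc")) {
    d[[col]] <- as.integer(d[[col]])
  }
  msgs <- validate_full_ssh(d, respondents)
  if (length(msgs)) stop("invalid full SSH rows:\n", paste(msgs, collapse = "\n"))
  d
}

#' Validate full sibling-history rows
#'
#' @param siblings Full-history data.frame.
#' @inheritParams ssh_io
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_full_ssh <- function(siblings, respondents = NULL) {
  msgs <- character()
  bad <- function(rows, what) {
    if (any(rows, na.rm = TRUE)) {
      sprintf("row %d: %s", which(rows), what)
    } else character()
  }
  msgs <- c(msgs,
    bad(!siblings$sex %in% c("m", "f", "u"), "sex must be m/f/u"),
    bad(!siblings$alive %in% c(0L, 1L), "alive must be 0/1"),
    bad(siblings$alive == 1L &
          (!is.na(siblings$death_cmc) | !is.na(siblings$age_at_death) |
             !is.na(siblings$years_since_death)),
        "alive sibling carries death fields"),
    bad(siblings$alive == 0L & !is.na(siblings$age_now),
        "deceased sibling carries current age"))
  full <- !is.na(siblings$birth_cmc) & !is.na(siblings$death_cmc) &
    !is.na(siblings$age_at_death)
  msgs <- c(msgs, bad(full & siblings$age_at_death !=
      (siblings$death_cmc - siblings$birth_cmc) %/% 12L,
    "age_at_death inconsistent with birth/death dates"))
  if (!is.null(respondents)) {
    iv <- respondents$interview_cmc[match(siblings$respondent_id,
                                          respondents$respondent_id)]
    msgs <- c(msgs, bad(!is.na(siblings$death_cmc) & siblings$death_cmc > iv,
                        "death after owner's interview"))
  }
  msgs
}

#' @param siblings Full-history data.frame to write.
#' @rdname ssh_io
#' @export
write_full_ssh <- function(siblings, path) {
  for (col in FULL_SSH_COLS) if (is.null(siblings[[col]])) siblings[[col]] <- NA
  utils::write.csv(siblings[FULL_SSH_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname ssh_io
#' @export
load_respondents <- function(path) {
  d <- utils::read.csv(path, colClasses = c(respondent_id = "character"))
  need <- setdiff(c("respondent_id", "sex", "age_years", "interview_cmc"), names(d))
  if (length(need)) stop("respondent file missing columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$respondent_id)) stop("duplicate respondent_id")
  if (any(d$age_years < 15 | d$age_years > 95)) stop("respondent age outside 15..95")
  if (any(d$interview_cmc <= 0)) stop("interview_cmc must be positive")
  if (is.null(d$design_weight)) d$design_weight <- 1
  d
}

#' @rdname ssh_io
#' @export
write_respondents <- function(respondents, path) {
  utils::write.csv(respondents, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @param detail_path CSV of recent-death detail rows
#'   (`respondent_id`, `sex`, `age_at_death`, `death_year`, `death_month`).
#' @rdname ssh_io
#' @export
load_summary_ssh <- function(path, detail_path = NULL) {
  d <- utils::read.csv(path, colClasses = c(respondent_id = "character"))
  need <- setdiff(c("respondent_id", "n_ever", "n_alive", "n_dead"), names(d))
  if (length(need)) stop("summary SSH file missing columns: ", paste(need, collapse = ", "))
  if (is.null(d$sex)) d$sex <- "u"  # combined-sex variant
  bad <- which(d$n_alive + d$n_dead != d$n_ever |
                 d$n_ever < 0 | d$n_alive < 0 | d$n_dead < 0)
  if (length(bad)) {
    stop("invalid summary rows (n_alive + n_dead must equal n_ever): row ",
         paste(bad, collapse = ", "))
  }
  details <- if (!is.null(detail_path)) {
    rd <- utils::read.csv(detail_path, colClasses = c(respondent_id = "character"))
    if (is.null(rd$sex)) rd$sex <- "u"
    if (is.null(rd$age_at_death)) rd$age_at_death <- NA_integer_
    if (is.null(rd$death_month)) rd$death_month <- NA_integer_
    if (is.null(rd$death_year)) stop("recent-death file needs death_year")
    nd <- table(rd$respondent_id)
    tot <- tapply(d$n_dead, d$respondent_id, sum)
    lim <- as.integer(tot[names(nd)])
    if (any(is.na(lim) | nd > lim)) {
      stop("recent-death detail rows exceed n_dead for some respondents")
    }
    rd
  } else {
    data.frame(respondent_id = character(), sex = character(),
               age_at_death = integer(), death_year = integer(),
               death_month = integer())
  }
  list(summary = d, details = details)
}

#' @param summary_ssh Summary table as returned in `load_summary_ssh()$summary`.
#' @param details Recent-death detail table.
#' @rdname ssh_io
#' @export
write_summary_ssh <- function(summary_ssh, details, path, detail_path) {
  utils::write.csv(summary_ssh, path, row.names = FALSE, na = "")
  utils::write.csv(details, detail_path, row.names = FALSE, na = "")
  invisible(path)
}
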