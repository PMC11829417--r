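#' Age-band matching window
#'
#' Cases aged up to 240 months are matched within 12 months; 241-360
#' months within 24 months; older than 360 months within 48 months. The
#' boundary ages (exactly 240 or 360 months) take the younger band's
#' window.
#'
#' @param age_months numeric age(s) in months.
#' @return Matching window(s) in months.
#' @export
age_match_window <- function(age_months) {
  ifelse(age_months <= 240, 12, ifelse(age_months <= 360, 24, 48))
}

#' Greedy case-control pair matching
#'
#' Matches each case to an unused control under the hierarchy: sex is an
#' obligatory match; the age gap must fall inside the case's age-band
#' window (12/24/48 months); candidates from the case's own study are
#' preferred; among the preferred set the smallest absolute age gap wins,
#' with ties broken by racial match and then by subject id order. When a
#' cross-study pair is unavoidable, controls from studies that have so far
#' donated more controls to cross-study pairs than they have received (via
#' their own unmatched cases) are preferred, to balance the direction of
#' cross-study contributions. Cases are processed in ascending age order;
#' each subject is used at most once.
#'
#' @param subjects `data.frame` with columns `subject_id`, `group`
#'   (`"case"`/`"control"`), `age_months`, `sex`, `study_id`, `race_label`.
#' @return List with `pairs` (a `data.frame`: `case_id`, `control_id`,
#'   `age_gap_months`, `same_study`, `same_race`) and `unmatched`
#'   (subject ids).
#' @export
match_pairs <- function(subjects) {
  need <- c("subject_id", "group", "age_months", "sex", "study_id",
            "race_label")
  if (!all(need %in% names(subjects)))
    stop("subjects table must have columns: ", paste(need, collapse = ", "))
  cases <- subjects[subjects$group == "case", , drop = FALSE]
  ctrls <- subjects[subjects$group == "control", , drop = FALSE]
  if (!nrow(cases) || !nrow(ctrls)) stop("empty cohorts")
  cases <- cases[order(cases$age_months, cases$subject_id), , drop = FALSE]
  used <- rep(FALSE, nrow(ctrls))
  # net cross-study control donations per study (donated - received)
  studies <- unique(subjects$study_id)
  cross_balance <- stats::setNames(rep(0, length(studies)), studies)
  rows <- list()
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    win <- age_match_window(cs$age_months)
    cand <- which(!used & ctrls$sex == cs$sex &
                    abs(ctrls$age_months - cs$age_months) <= win)
    if (!length(cand)) next
    intra <- cand[ctrls$study_id[cand] == cs$study_id]
    pool <- if (length(intra)) intra else cand
    gap <- abs(ctrls$age_months[pool] - cs$age_months)
    race_ok <- ctrls$race_label[pool] == cs$race_label
    if (length(intra)) {
      o <- order(gap, !race_ok, ctrls$subject_id[pool])
    } else {
      # prefer donor studies that are owed a cross-study control
      owed <- cross_balance[ctrls$study_id[pool]]
      o <- order(gap, owed, !race_ok, ctrls$subject_id[pool])
    }
    j <- pool[o[1]]
    used[j] <- TRUE
    same_study <- ctrls$study_id[j] == cs$study_id
    if (!same_study) {
      cross_balance[ctrls$study_id[j]] <- cross_balance[ctrls$study_id[j]] + 1
      cross_balance[cs$study_id] <- cross_balance[cs$study_id] - 1
    }
    rows[[length(rows) + 1L]] <- data.frame(
      case_id = cs$subject_id, control_id = ctrls$subject_id[j],
      age_gap_months = abs(ctrls$age_months[j] - cs$age_months),
      same_study = same_study,
      same_race = ctrls$race_label[j] == cs$race_label)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), control_id = character(),
               age_gap_months = numeric(), same_study = logical(),
               same_race = logical())
  matched <- c(pairs$case_id, pairs$control_id)
  list(pairs = pairs,
       unmatched = setdiff(subjects$subject_id, matched))
}
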