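#' Estimate the SSRT by the integration method
#'
#' The stop-signal reaction time is estimated as the p-th quantile of the
#' go-RT distribution minus the mean stop-signal delay, where
#' p = P(respond | stop signal) over the staircase-tracked stop trials.
#' The quantile is the ceiling(p * n_go)-th order statistic (no
#' interpolation).  Omitted go trials are adjusted for by assigning them the
#' maximum observed go RT before taking the quantile, which counteracts the
#' underestimation of the go-RT quantile that omissions would otherwise
#' cause.  NoGo trials (SSD = 0) never enter the estimate.
#'
#' Wrong-side go responses keep their RT in the distribution used here (the
#' go process did finish); they are excluded from the mean go RT reported by
#' [summarize_session()].
#'
#' @param log A `session_log` tibble (see [simulate_session()]) or any tibble
#'   with columns `trial_type`, `ssd_ms`, `responded`, `rt_ms` for a single
#'   session.
#' @return A one-row tibble: `ssrt_ms`, `p_respond_stop`, `mean_ssd_ms`,
#'   `n_go`, `n_go_omitted`, `n_stop`, `flagged` (`TRUE` when
#'   `p_respond_stop` is 0 or 1 and the quantile degenerates to the
#'   min/max).
#' @examples
#' log <- simulate_session(seed = 1)
#' estimate_ssrt(log)
#' @export
estimate_ssrt <- function(log) {
  go <- log[log$trial_type == "go", ]
  stop_trials <- log[log$trial_type == "stop", ]
  if (nrow(stop_trials) < 1) abort("log contains no stop trials")
  rts <- go$rt_ms[go$responded]
  if (length(rts) == 0) abort("no responded go trials: SSRT is undefined")

  n_omit <- sum(!go$responded)
  adjusted <- sort(c(rts, rep(max(rts), n_omit)))
  n_go <- length(adjusted)

  p <- mean(stop_trials$responded)
  mean_ssd <- mean(stop_trials$ssd_ms)
  k <- min(max(ceiling(p * n_go), 1L), n_go)
  flagged <- p <= 0 || p >= 1
  if (flagged) {
    warn(sprintf("P(respond|stop) = %g: quantile degenerates to the %s",
                 p, if (p <= 0) "minimum" else "maximum"))
  }
  tibble(
    ssrt_ms = adjusted[k] - mean_ssd,
    p_respond_stop = p,
    mean_ssd_ms = mean_ssd,
    n_go = n_go,
    n_go_omitted = n_omit,
    n_stop = nrow(stop_trials),
    flagged = flagged
  )
}

#' Behavioral summary of one stop-signal session
#'
#' Computes the session's SSRT (integration method, omission-adjusted), the
#' mean RT of correct responded go trials, the go commission error rate
#' (wrong-side responses / responded go trials), the go omission rate, the
#' probability of responding on stop trials and the mean SSD.
#'
#' @param log A single-session trial tibble (see [estimate_ssrt()]).
#' @param subject_id,session_id Identifiers; default to the log's attributes
#'   or columns.
#' @return A one-row tibble with the measures above.
#' @examples
#' summarize_session(simulate_session(seed = 1))
#' @export
summarize_session <- function(log, subject_id = NULL, session_id = NULL) {
  subject_id <- subject_id %||% attr(log, "subject_id") %||%
    unique(log$subject_id)
  session_id <- session_id %||% attr(log, "session_id") %||%
    unique(log$session_id)
  go <- log[log$trial_type == "go", ]
  responded <- go[go$responded, ]
  if (nrow(responded) == 0) abort("no responded go trials in session")
  est <- estimate_ssrt(log)
  tibble(
    subject_id = as.character(subject_id),
    session_id = as.character(session_id),
    ssrt_ms = est$ssrt_ms,
    go_rt_mean_ms = mean(responded$rt_ms[responded$correct_side]),
    go_error_rate = mean(!responded$correct_side),
    go_omission_rate = 1 - nrow(responded) / nrow(go),
    p_respond_stop = est$p_respond_stop,
    mean_ssd_ms = est$mean_ssd_ms,
    ssrt_flagged = est$flagged
  )
}

#' Summarize many sessions stored in one trial table
#'
#' @param trials A tibble of trials with `subject_id` and `session_id`
#'   columns (e.g. from [read_session_log()] or [simulate_cohort_sessions()]).
#' @return A tibble with one [summarize_session()] row per
#'   subject-by-session.
#' @export
summarize_sessions <- function(trials) {
  trials |>
    dplyr::group_by(.data$subject_id, .data$session_id) |>
    dplyr::group_modify(~ summarize_session(.x, subject_id = .y$subject_id,
                                            session_id = .y$session_id) |>
                          dplyr::select(-"subject_id", -"session_id")) |>
    dplyr::ungroup()
}

#' Per-drug change in SSRT
#'
#' `delta_ssrt_ms = SSRT(placebo) - SSRT(drug)`: positive values mean the
#' drug shortened the SSRT, i.e. improved stopping efficiency.  All
#' responder labels in the package derive from this one improvement-positive
#' convention.
#'
#' @param summaries A tibble of session summaries ([summarize_sessions()])
#'   containing a `"placebo"` session and the `drug` session for each
#'   subject.
#' @param drug Session identifier of the drug condition.
#' @return A tibble `subject_id`, `drug`, `delta_ssrt_ms`.
#' @examples
#' s <- tibble::tibble(subject_id = c("a", "a"),
#'                     session_id = c("placebo", "atomoxetine"),
#'                     ssrt_ms = c(300, 280))
#' compute_deltas(s, "atomoxetine")  # +20: improvement
#' @export
compute_deltas <- function(summaries, drug) {
  wide <- summaries |>
    dplyr::filter(.data$session_id %in% c("placebo", drug)) |>
    dplyr::select("subject_id", "session_id", "ssrt_ms") |>
    tidyr::pivot_wider(names_from = "session_id", values_from = "ssrt_ms")
  if (!drug %in% names(wide)) {
    abort(sprintf("no '%s' sessions found in summaries", drug))
  }
  missing <- wide$subject_id[is.na(wide$placebo) | is.na(wide[[drug]])]
  if (length(missing) > 0) {
    abort(paste0("missing placebo or ", drug, " session for subject(s): ",
                 paste(missing, collapse = ", ")))
  }
  delta <- wide$placebo - wide[[drug]]
  tibble(subject_id = wide$subject_id, drug = drug, delta_ssrt_ms = delta)
}
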