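#' Stop-signal task design
#'
#' Describes one session of the stop-signal task: randomly interleaved go
#' trials, stop-signal trials whose stop-signal delay (SSD) is tracked online
#' by a one-up-one-down staircase targeting 50% successful inhibition, and
#' NoGo trials (stop trials with SSD fixed at 0 ms).
#'
#' The staircase step size, starting SSD and SSD bounds are not dictated by
#' the task itself; the defaults (50 ms step, 250 ms start, 0--900 ms bounds)
#' follow common practice for fixed-step tracking and are fully configurable.
#'
#' @param n_go,n_stop,n_nogo Trial counts per type (defaults 360/80/40).
#' @param ssd_initial_ms Starting stop-signal delay in ms.
#' @param ssd_step_ms Staircase step in ms (> 0).
#' @param ssd_min_ms,ssd_max_ms Clamping bounds for the SSD in ms.
#' @param response_window_ms Maximum RT; slower responses count as omissions.
#' @return A `task_design` object (a validated list).
#' @examples
#' task_design()
#' @export
task_design <- function(n_go = 360, n_stop = 80, n_nogo = 40,
                        ssd_initial_ms = 250, ssd_step_ms = 50,
                        ssd_min_ms = 0, ssd_max_ms = 900,
                        response_window_ms = 1000) {
  check_number(n_go, "n_go", min = 1)
  check_number(n_stop, "n_stop", min = 1)
  check_number(n_nogo, "n_nogo", min = 0)
  check_number(ssd_step_ms, "ssd_step_ms", min = 0, strict_min = TRUE)
  check_number(ssd_min_ms, "ssd_min_ms", min = 0)
  check_number(response_window_ms, "response_window_ms", min = 0,
               strict_min = TRUE)
  if (ssd_min_ms > ssd_initial_ms || ssd_initial_ms > ssd_max_ms) {
    stop_config("`ssd_initial_ms` must lie within [ssd_min_ms, ssd_max_ms]",
                field = "ssd_initial_ms")
  }
  structure(
    list(n_go = as.integer(n_go), n_stop = as.integer(n_stop),
         n_nogo = as.integer(n_nogo), ssd_initial_ms = ssd_initial_ms,
         ssd_step_ms = ssd_step_ms, ssd_min_ms = ssd_min_ms,
         ssd_max_ms = ssd_max_ms, response_window_ms = response_window_ms),
    class = "task_design"
  )
}

#' Race-model generative parameters for one session
#'
#' Under the independent horse-race model a go process and a stop process
#' race on every stop trial; the response is inhibited iff the stop process
#' finishes first.  Go finishing times are ex-Gaussian (Normal(mu, sigma) +
#' Exponential(tau)); the stop process latency is a known constant
#' `ssrt_true_ms`, which makes the true SSRT exactly defined and recoverable
#' by the integration-method estimator.
#'
#' @param go_mu_ms,go_sigma_ms,go_tau_ms Ex-Gaussian go-RT parameters (ms).
#'   `go_sigma_ms` and `go_tau_ms` may be 0 to obtain a degenerate
#'   (deterministic) go process, useful for exact race arithmetic.
#' @param ssrt_true_ms True stop-process latency in ms (> 0).
#' @param go_omission_rate Probability of an attentional lapse (no go process
#'   started; on stop trials a lapse yields a successful stop).
#' @param go_error_rate Probability that a response is on the wrong side.
#' @return A `race_params` object.
#' @examples
#' race_params(ssrt_true_ms = 220)
#' @export
race_params <- function(go_mu_ms = 400, go_sigma_ms = 50, go_tau_ms = 60,
                        ssrt_true_ms = 200, go_omission_rate = 0.02,
                        go_error_rate = 0.03) {
  check_number(go_mu_ms, "go_mu_ms", min = 0, strict_min = TRUE)
  check_number(go_sigma_ms, "go_sigma_ms", min = 0)
  check_number(go_tau_ms, "go_tau_ms", min = 0)
  check_number(ssrt_true_ms, "ssrt_true_ms", min = 0, strict_min = TRUE)
  check_number(go_omission_rate, "go_omission_rate", min = 0, max = 1)
  check_number(go_error_rate, "go_error_rate", min = 0, max = 1)
  structure(
    list(go_mu_ms = go_mu_ms, go_sigma_ms = go_sigma_ms,
         go_tau_ms = go_tau_ms, ssrt_true_ms = ssrt_true_ms,
         go_omission_rate = go_omission_rate, go_error_rate = go_error_rate),
    class = "race_params"
  )
}

#' One-up-one-down staircase update of the stop-signal delay
#'
#' A successful stop makes inhibition harder next time (SSD + step); a failed
#' stop makes it easier (SSD - step).  The result is clamped to the design's
#' SSD bounds.  This fixed-step rule converges on the delay at which stopping
#' succeeds 50% of the time.
#'
#' @param ssd_ms Current stop-signal delay (ms).
#' @param stop_succeeded Logical, was the stop successful (no response)?
#' @param design A [task_design()].
#' @return The next stop-signal delay (ms).
#' @examples
#' staircase_update(200, TRUE, task_design())  # 250
#' @export
staircase_update <- function(ssd_ms, stop_succeeded, design = task_design()) {
  step <- if (isTRUE(stop_succeeded)) design$ssd_step_ms else -design$ssd_step_ms
  min(max(ssd_ms + step, design$ssd_min_ms), design$ssd_max_ms)
}

# ex-Gaussian draw; degenerate components (sigma or tau == 0) collapse to
# their means so exact race arithmetic is possible in tests
rexgauss <- function(n, mu, sigma, tau) {
  g <- if (sigma > 0) rnorm(n, mu, sigma) else rep(mu, n)
  e <- if (tau > 0) rexp(n, rate = 1 / tau) else 0
  g + e
}

#' Simulate a single trial of the stop-signal task
#'
#' Go trials draw an ex-Gaussian finishing time; the trial is an omission on
#' an attentional lapse or when the finishing time exceeds the response
#' window, and a commission error (wrong side) with probability
#' `go_error_rate`.  On stop and NoGo trials the go process races a constant
#' stop process: the subject responds iff the go finishing time is smaller
#' than `ssd_ms + ssrt_true_ms` (and no lapse occurred); a responded stop
#' trial records the go RT.
#'
#' @param trial_type One of `"go"`, `"stop"`, `"nogo"`.
#' @param ssd_ms Stop-signal delay for this trial (ignored for go trials;
#'   0 for NoGo trials).
#' @param params A [race_params()].
#' @param design A [task_design()] (supplies the response window).
#' @return A one-row tibble with columns `trial_type`, `ssd_ms`, `responded`,
#'   `rt_ms`, `correct_side`.
#' @examples
#' p <- race_params(go_mu_ms = 400, go_sigma_ms = 0, go_tau_ms = 0,
#'                  ssrt_true_ms = 200, go_omission_rate = 0,
#'                  go_error_rate = 0)
#' simulate_trial("stop", 150, p)  # 400 >= 350: successful stop
#' @export
simulate_trial <- function(trial_type = c("go", "stop", "nogo"), ssd_ms = NA,
                           params = race_params(), design = task_design()) {
  trial_type <- match.arg(trial_type)
  lapse <- runif(1) < params$go_omission_rate
  finish <- rexgauss(1, params$go_mu_ms, params$go_sigma_ms, params$go_tau_ms)
  wrong <- runif(1) < params$go_error_rate

  if (trial_type == "go") {
    responded <- !lapse && finish <= design$response_window_ms
    return(tibble(
      trial_type = "go", ssd_ms = NA_real_, responded = responded,
      rt_ms = if (responded) finish else NA_real_,
      correct_side = if (responded) !wrong else NA
    ))
  }
  ssd <- if (trial_type == "nogo") 0 else ssd_ms
  responded <- !lapse &&
    finish < ssd + params$ssrt_true_ms &&
    finish <= design$response_window_ms
  tibble(
    trial_type = trial_type, ssd_ms = ssd, responded = responded,
    rt_ms = if (responded) finish else NA_real_,
    correct_side = if (responded) !wrong else NA
  )
}

#' Simulate a full stop-signal session
#'
#' Trial order is a seeded random permutation of the designed go, stop and
#' NoGo trials.  The staircase state threads through the stop trials in
#' presentation order; NoGo trials keep SSD = 0 and do not touch the
#' staircase.
#'
#' @param design A [task_design()].
#' @param params A [race_params()].
#' @param seed Integer seed; identical `(design, params, seed)` reproduce the
#'   session exactly.
#' @param subject_id,session_id Identifiers stored on the log.
#' @return A `session_log`: a tibble with one row per trial (columns `trial`,
#'   `trial_type`, `ssd_ms`, `responded`, `rt_ms`, `correct_side`) and
#'   attributes `subject_id`, `session_id`, `seed`, `design`.
#' @examples
#' log <- simulate_session(seed = 1)
#' table(log$trial_type)
#' @export
simulate_session <- function(design = task_design(), params = race_params(),
                             seed = NULL, subject_id = "s01",
                             session_id = "placebo") {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      simulate_session(design, params, seed = NULL, subject_id = subject_id,
                       session_id = session_id) |>
        structure(seed = as.integer(seed))
    ))
  }
  types <- sample(rep(c("go", "stop", "nogo"),
                      times = c(design$n_go, design$n_stop, design$n_nogo)))
  n <- length(types)
  # one lapse/finish/side draw per trial, exactly as simulate_trial() makes,
  # drawn up front so the staircase loop below runs on plain vectors
  lapse <- runif(n) < params$go_omission_rate
  finish <- rexgauss(n, params$go_mu_ms, params$go_sigma_ms, params$go_tau_ms)
  wrong <- runif(n) < params$go_error_rate

  ssd_col <- rep(NA_real_, n)
  responded <- logical(n)
  ssd <- design$ssd_initial_ms
  for (i in seq_len(n)) {
    tt <- types[i]
    if (tt == "go") {
      responded[i] <- !lapse[i] && finish[i] <= design$response_window_ms
    } else {
      this_ssd <- if (tt == "stop") ssd else 0
      ssd_col[i] <- this_ssd
      responded[i] <- !lapse[i] &&
        finish[i] < this_ssd + params$ssrt_true_ms &&
        finish[i] <= design$response_window_ms
      if (tt == "stop") {
        ssd <- staircase_update(ssd, stop_succeeded = !responded[i], design)
      }
    }
  }
  log <- tibble(
    trial = seq_len(n), trial_type = types, ssd_ms = ssd_col,
    responded = responded,
    rt_ms = ifelse(responded, finish, NA_real_),
    correct_side = ifelse(responded, !wrong, NA)
  )
  structure(log, subject_id = subject_id, session_id = session_id,
            seed = NA_integer_, design = design,
            class = c("session_log", class(log)))
}

#' Read/write session logs as delimited text
#'
#' One trial per row, tab-separated, with a mandatory header row
#' (`trial`, `trial_type`, `ssd_ms`, `responded`, `rt_ms`, `correct_side`);
#' `subject_id` and `session_id` are stored as ordinary columns so that logs
#' from many sessions can live in one file.
#'
#' @param log A `session_log` (or a bound tibble of several).
#' @param path File path.
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` returns a tibble of trials.
#' @export
write_session_log <- function(log, path) {
  out <- as_tibble(log)
  if (!"subject_id" %in% names(out)) {
    out <- dplyr::mutate(out,
                         subject_id = attr(log, "subject_id"),
                         session_id = attr(log, "session_id"), .before = 1)
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    session_id = readr::col_character(),
    trial = readr::col_integer(),
    trial_type = readr::col_character(),
    ssd_ms = readr::col_double(),
    responded = readr::col_logical(),
    rt_ms = readr::col_double(),
    correct_side = readr::col_logical()
  ))
}
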