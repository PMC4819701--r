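#' Group-level Parkinson's deficit in SSRT
#'
#' The magnitude of the Parkinson's deficit is the mean placebo SSRT of the
#' patient group minus the mean SSRT of the control group.  Responder
#' benchmarks are defined as fractions of this deficit.
#'
#' @param pd_placebo_ssrts Numeric vector of patient placebo SSRTs (ms).
#' @param control_ssrts Numeric vector of control SSRTs (ms).
#' @return The deficit in ms.  A non-positive deficit is returned with a
#'   warning: fraction-of-deficit benchmarks are then ill-posed.
#' @examples
#' group_deficit(c(310, 290), c(240, 260))  # 50
#' @export
group_deficit <- function(pd_placebo_ssrts, control_ssrts) {
  if (length(pd_placebo_ssrts) == 0 || length(control_ssrts) == 0) {
    abort("both SSRT vectors must be non-empty")
  }
  d <- mean(pd_placebo_ssrts) - mean(control_ssrts)
  if (d <= 0) {
    warn(sprintf(
      "group deficit is %.1f ms (<= 0): fraction-of-deficit benchmarks are ill-posed", d))
  }
  d
}

#' Label drug responders against a fraction-of-deficit benchmark
#'
#' A patient is a responder iff their SSRT improvement under drug exceeds
#' (strictly) a threshold equal to `fraction` times the Parkinson's deficit.
#' On the group scale the deficit -- and hence the threshold -- is shared by
#' all patients.  On the individual scale each patient's own deficit
#' (placebo SSRT minus the control-group mean SSRT) sets their threshold;
#' this reading of a per-patient benchmark is an implementation choice,
#' documented rather than asserted.
#'
#' Ties at the threshold are nonresponders ("larger than" is strict).
#'
#' @param deltas Tibble from [compute_deltas()] (`subject_id`, `drug`,
#'   `delta_ssrt_ms`).
#' @param deficit Group deficit in ms ([group_deficit()]); must be > 0 for
#'   the group scale.  Ignored on the individual scale.
#' @param fraction Benchmark fraction in (0, 1]; 0.30 is the principal
#'   benchmark, 0.10--0.50 the conventional sweep range.
#' @param scale `"group"` or `"individual"`.
#' @param placebo_ssrts For `scale = "individual"`: tibble `subject_id`,
#'   `ssrt_ms` of patient placebo SSRTs.
#' @param control_mean For `scale = "individual"`: control-group mean SSRT.
#' @return A tibble `subject_id`, `drug`, `delta_ssrt_ms`, `deficit_ms`,
#'   `threshold_ms`, `responder` (logical), `label` (factor
#'   nonresponder/responder), with attributes `fraction` and `scale`.
#' @examples
#' d <- tibble::tibble(subject_id = c("a", "b"), drug = "atomoxetine",
#'                     delta_ssrt_ms = c(20, 15))
#' label_responders(d, deficit = 50, fraction = 0.30)
#' @export
label_responders <- function(deltas, deficit = NULL, fraction = 0.30,
                             scale = c("group", "individual"),
                             placebo_ssrts = NULL, control_mean = NULL) {
  scale <- match.arg(scale)
  check_number(fraction, "fraction", min = 0, max = 1, strict_min = TRUE)
  if (scale == "group") {
    if (is.null(deficit)) stop_config("`deficit` is required on the group scale",
                                      field = "deficit")
    if (deficit <= 0) {
      abort(sprintf("group deficit %.1f ms <= 0: benchmark undefined", deficit))
    }
    deficit_ms <- rep(deficit, nrow(deltas))
  } else {
    if (is.null(placebo_ssrts) || is.null(control_mean)) {
      stop_config("individual scale needs `placebo_ssrts` and `control_mean`",
                  field = "placebo_ssrts")
    }
    idx <- match(deltas$subject_id, placebo_ssrts$subject_id)
    if (anyNA(idx)) {
      abort(paste0("no placebo SSRT for subject(s): ",
                   paste(deltas$subject_id[is.na(idx)], collapse = ", ")))
    }
    deficit_ms <- placebo_ssrts$ssrt_ms[idx] - control_mean
  }
  threshold <- fraction * deficit_ms
  responder <- deltas$delta_ssrt_ms > threshold  # strict
  out <- tibble(
    subject_id = deltas$subject_id,
    drug = deltas$drug,
    delta_ssrt_ms = deltas$delta_ssrt_ms,
    deficit_ms = deficit_ms,
    threshold_ms = threshold,
    responder = responder,
    label = as_responder_factor(responder)
  )
  structure(out, fraction = fraction, scale = scale)
}
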