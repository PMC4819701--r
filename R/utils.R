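#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rexp runif setNames predict
NULL

# deterministic fan-out of a single user seed into per-stage / per-unit seeds;
# kept strictly below 2^31 - 1 so set.seed() always accepts the result
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1000003) * 2053 + as.numeric(i) * 7919) %%
    2147483646L + 1L
}

stop_config <- function(msg, field = NULL) {
  abort(msg, class = "stopstrat_config_error", field = field)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_config(sprintf("`%s` must be a single number", name), field = name)
  }
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max) {
    stop_config(sprintf("`%s` = %g is outside its valid range", name, x),
                field = name)
  }
  invisible(x)
}

# responder labels are carried everywhere as a two-level factor so that class
# ordering (and hence SVM decision-value sign) is fixed once, here
responder_levels <- c("nonresponder", "responder")

as_responder_factor <- function(labels) {
  if (is.logical(labels)) {
    return(factor(responder_levels[labels + 1L], levels = responder_levels))
  }
  f <- as.factor(labels)
  if (!all(levels(f) %in% responder_levels)) {
    abort(paste0("labels must be logical or use levels ",
                 paste(responder_levels, collapse = "/")))
  }
  factor(as.character(f), levels = responder_levels)
}
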