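# Shared fixtures, all built in code.

# a degenerate race: deterministic go process, no lapses or side errors,
# so race outcomes follow from plain arithmetic
deterministic_params <- function(mu = 400, ssrt = 200) {
  race_params(go_mu_ms = mu, go_sigma_ms = 0, go_tau_ms = 0,
              ssrt_true_ms = ssrt, go_omission_rate = 0, go_error_rate = 0)
}

# hand-built single-session log: go RTs and stop trials fully specified
make_log <- function(go_rts, go_responded = rep(TRUE, length(go_rts)),
                     go_correct = rep(TRUE, length(go_rts)),
                     stop_responded, stop_ssd = rep(200, length(stop_responded))) {
  n_go <- length(go_rts)
  n_stop <- length(stop_responded)
  tibble::tibble(
    trial = seq_len(n_go + n_stop),
    trial_type = rep(c("go", "stop"), c(n_go, n_stop)),
    ssd_ms = c(rep(NA_real_, n_go), stop_ssd),
    responded = c(go_responded, stop_responded),
    rt_ms = c(ifelse(go_responded, go_rts, NA_real_),
              ifelse(stop_responded, 400, NA_real_)),
    correct_side = c(ifelse(go_responded, go_correct, NA),
                     ifelse(stop_responded, TRUE, NA))
  )
}

# two well-separated 1-D clusters plus optional noise columns:
# linearly separable, so a mid-grid RBF-SVM classifies it perfectly
make_separable <- function(n_per_class = 6, n_noise = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- tibble::tibble(signal = c(rnorm(n_per_class, -3, 0.3),
                                   rnorm(n_per_class, 3, 0.3)))
    if (n_noise > 0) {
      for (j in seq_len(n_noise)) {
        x[[paste0("noise", j)]] <- rnorm(2 * n_per_class)
      }
    }
    list(features = x, labels = rep(c(FALSE, TRUE), each = n_per_class))
  })
}

# a small coarse grid used wherever grid density is not itself under test
coarse_grid <- function() grid_spec(-4, 4, 2)
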