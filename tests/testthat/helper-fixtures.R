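# Shared fixtures and independent oracles, built in code at test time.

# canonical 20-reading cuff series for one subject from a MAP vector
make_bp_series <- function(map, subject_id = "s01", pp = 40) {
  stopifnot(length(map) == 20)
  phases <- c(rep("pre_baseline", 8), "training", rep("scenario", 5),
              rep("post_baseline", 6))
  tibble::tibble(
    subject_id = subject_id,
    phase = phases,
    scenario_domain = replace(rep(NA_character_, 20), phases == "scenario",
                              risk_domains()),
    systolic = map + (2 / 3) * pp,
    diastolic = map - (1 / 3) * pp
  )
}

# pure sinusoid sampled at fs Hz
sinusoid <- function(freq, dur_sec, fs = 200, amp = 1, phase = 0) {
  t <- seq(0, dur_sec - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}

# brute-force GLS oracle: given variance components, solve the marginal
# model (X' V^-1 X)^-1 X' V^-1 y by direct inversion
gls_oracle <- function(y, X, subj, item, var_s, var_i, var_e) {
  Zs <- outer(subj, unique(subj), `==`) * 1
  Zi <- outer(item, unique(item), `==`) * 1
  V <- var_s * tcrossprod(Zs) + var_i * tcrossprod(Zi) +
    var_e * diag(length(y))
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# minimal moderation_result stand-in for probing jn_regions/simple_slopes
# with arbitrary coefficients and covariance
fake_moderation <- function(b, vcov4, df_resid = 100, range = c(-2, 2)) {
  stopifnot(length(b) == 4, all(dim(vcov4) == c(4, 4)))
  terms <- c("b0", "b1", "b2", "b3")
  dimnames(vcov4) <- list(terms, terms)
  structure(list(
    coefficients = tibble::tibble(term = terms, estimate = unname(b),
                                  se = sqrt(diag(vcov4))),
    vcov = vcov4,
    lrt_interaction = list(chi_sq = NA_real_, df = 1L, p = NA_real_),
    moderator_range = range,
    moderator_mean = mean(range), moderator_sd = diff(range) / 4,
    df_resid = df_resid, n_obs = df_resid + 4,
    variables = c(y = "y", x_focal = "x", moderator = "w")
  ), class = "moderation_result")
}

# dense grid scan oracle for Johnson-Neyman boundaries: sign changes of
# |theta/se| - t_crit over a fine grid
jn_grid_oracle <- function(b1, b3, v11, v13, v33, t_crit, range,
                           step = 1e-4) {
  w <- seq(range[1], range[2], by = step)
  theta <- b1 + b3 * w
  se <- sqrt(v11 + 2 * w * v13 + w^2 * v33)
  f <- abs(theta / se) - t_crit
  idx <- which(f[-1] * f[-length(f)] < 0)
  (w[idx] + w[idx + 1]) / 2
}
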