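#' Moderated mixed model for risk perception x imagery intensity
#'
#' Fits, with crossed subject and risk-domain random intercepts, a step-1
#' model `y ~ x_focal + moderator` and a step-2 model adding the
#' `x_focal : moderator` interaction, and compares them with a 1-df
#' likelihood-ratio test on ML refits. Reported coefficients come from the
#' REML step-2 fit; predictors are not mean-centered (coefficients are on
#' the raw scale).
#'
#' @param data A trial table.
#' @param y Outcome column (risk taking).
#' @param x_focal Focal predictor column (risk perception).
#' @param moderator Moderator column (e.g. mean IAI).
#' @param subject,item Random-intercept grouping columns.
#' @return An object of class `"moderation_result"`: `coefficients` tibble
#'   (term, estimate, se), `vcov`, `lrt_interaction` (chi_sq, df = 1, p),
#'   `moderator_range`, `moderator_mean`, `moderator_sd`, `df_resid`,
#'   `n_obs`, `variables`, and the step fits.
#' @export
fit_interaction <- function(data, y, x_focal, moderator,
                            subject = "subject_id", item = "item_id") {
  data <- tibble::as_tibble(data)
  used <- c(y, x_focal, moderator, subject, item)
  data <- data[stats::complete.cases(data[used]), ]
  if (stats::sd(data[[moderator]]) == 0) {
    stop("design error: moderator does not vary across rows", call. = FALSE)
  }
  inter <- paste0(".xw")
  data[[inter]] <- data[[x_focal]] * data[[moderator]]
  step1 <- fit_lmm(data, y, c(x_focal, moderator), subject, item, reml = TRUE)
  step2 <- fit_lmm(data, y, c(x_focal, moderator, inter), subject, item,
                   reml = TRUE)
  ml1 <- fit_lmm(data, y, c(x_focal, moderator), subject, item, reml = FALSE)
  ml2 <- fit_lmm(data, y, c(x_focal, moderator, inter), subject, item,
                 reml = FALSE)
  chi <- max(0, 2 * (ml2$log_likelihood - ml1$log_likelihood))
  coefs <- step2$fixed_effects
  coefs$term <- c("b0", "b1", "b2", "b3")
  v <- step2$vcov_fixed
  dimnames(v) <- list(coefs$term, coefs$term)
  structure(list(
    coefficients = coefs,
    vcov = v,
    lrt_interaction = list(chi_sq = chi, df = 1L,
                           p = stats::pchisq(chi, 1, lower.tail = FALSE)),
    moderator_range = range(data[[moderator]]),
    moderator_mean = mean(data[[moderator]]),
    moderator_sd = stats::sd(data[[moderator]]),
    df_resid = step2$n_obs - nrow(coefs),
    n_obs = step2$n_obs,
    variables = c(y = y, x_focal = x_focal, moderator = moderator),
    fits = list(step1 = step1, step2 = step2, step1_ml = ml1, step2_ml = ml2)
  ), class = "moderation_result")
}

#' @export
print.moderation_result <- function(x, ...) {
  v <- x$variables
  cat(sprintf("Moderated model: %s ~ %s * %s (crossed random intercepts)\n",
              v["y"], v["x_focal"], v["moderator"]))
  print(x$coefficients)
  cat(sprintf("interaction LRT: chi^2(1) = %.3f, p = %.4g; moderator range [%.3g, %.3g]\n",
              x$lrt_interaction$chi_sq, x$lrt_interaction$p,
              x$moderator_range[1], x$moderator_range[2]))
  invisible(x)
}

#' @export
tidy.moderation_result <- function(x, ...) x$coefficients

#' @export
glance.moderation_result <- function(x, ...) {
  tibble::tibble(
    lrt_chi_sq = x$lrt_interaction$chi_sq, lrt_df = x$lrt_interaction$df,
    lrt_p = x$lrt_interaction$p, n_obs = x$n_obs,
    moderator_mean = x$moderator_mean, moderator_sd = x$moderator_sd
  )
}

mod_coef <- function(x) {
  stats::setNames(x$coefficients$estimate, x$coefficients$term)
}

# conditional effect of the focal predictor at moderator value w
theta_at <- function(x, w) {
  b <- mod_coef(x)
  v <- x$vcov
  list(theta = b["b1"] + b["b3"] * w,
       se = sqrt(v["b1", "b1"] + 2 * w * v["b1", "b3"] + w^2 * v["b3", "b3"]))
}

crit_value <- function(x, alpha, df_method) {
  if (df_method == "residual") stats::qt(1 - alpha / 2, x$df_resid)
  else stats::qnorm(1 - alpha / 2)
}

#' Simple slopes of the focal predictor at chosen moderator values
#'
#' Conditional effect \eqn{\theta(w) = b_1 + b_3 w} with standard error
#' \eqn{\sqrt{v_{11} + 2 w v_{13} + w^2 v_{33}}} and a t test on the model's
#' residual degrees of freedom (`n_obs` minus the number of fixed effects).
#' Default probe points are the moderator mean and one SD below/above it
#' (SD computed across analysis rows). Values outside the observed moderator
#' range trigger an extrapolation warning.
#'
#' @param result A [fit_interaction()] result.
#' @param at Moderator values to probe (default mean -1 SD, mean, mean +1 SD).
#' @param df_method `"residual"` (Student t, default) or `"normal"` (z).
#' @return A tibble: `w`, `slope`, `se`, `t`, `df`, `p`.
#' @export
simple_slopes <- function(result, at = NULL,
                          df_method = c("residual", "normal")) {
  df_method <- match.arg(df_method)
  if (is.null(at)) {
    at <- result$moderator_mean + c(-1, 0, 1) * result$moderator_sd
  }
  out_of_range <- at < result$moderator_range[1] |
    at > result$moderator_range[2]
  if (any(out_of_range)) {
    warning("extrapolation: probe value(s) outside the observed moderator range",
            call. = FALSE)
  }
  df <- if (df_method == "residual") result$df_resid else Inf
  purrr::map(at, function(w) {
    th <- theta_at(result, w)
    tstat <- unname(th$theta / th$se)
    tibble::tibble(w = w, slope = unname(th$theta), se = unname(th$se),
                   t = unname(tstat), df = df,
                   p = 2 * stats::pt(-abs(tstat), df))
  }) |> purrr::list_rbind()
}

#' Johnson-Neyman regions of significance
#'
#' Derives, over the observed moderator range, the moderator values at which
#' the pointwise confidence interval for the conditional effect
#' \eqn{\theta(w) = b_1 + b_3 w} touches zero, by solving
#' \eqn{(b_3^2 - t^2 v_{33}) w^2 + 2 (b_1 b_3 - t^2 v_{13}) w +
#' (b_1^2 - t^2 v_{11}) = 0}. Also returns a dense grid of conditional
#' estimates with pointwise bands for plotting.
#'
#' @param result A [fit_interaction()] result.
#' @param alpha Significance level (default 0.05).
#' @param df_method `"residual"` (Student t, default) or `"normal"`.
#' @param grid_n Number of grid points across the moderator range.
#' @return An object of class `"jn_regions"`: `boundaries` (possibly empty
#'   numeric vector inside the observed range), `grid` tibble (`w`, `theta`,
#'   `lower`, `upper`, `significant`), `alpha`, `t_crit`,
#'   `moderator_range`, and `uniformly_significant` when no real boundary
#'   exists.
#' @export
jn_regions <- function(result, alpha = 0.05,
                       df_method = c("residual", "normal"), grid_n = 201) {
  df_method <- match.arg(df_method)
  b <- mod_coef(result)
  v <- result$vcov
  tc <- crit_value(result, alpha, df_method)
  qa <- b["b3"]^2 - tc^2 * v["b3", "b3"]
  qb <- 2 * (b["b1"] * b["b3"] - tc^2 * v["b1", "b3"])
  qc <- b["b1"]^2 - tc^2 * v["b1", "b1"]
  roots <- numeric(0)
  if (abs(qa) < .Machine$double.eps^0.75) {
    if (abs(qb) > 0) roots <- -qc / qb
  } else {
    disc <- qb^2 - 4 * qa * qc
    if (disc >= 0) roots <- sort((-qb + c(-1, 1) * sqrt(disc)) / (2 * qa))
  }
  rng <- result$moderator_range
  boundaries <- unname(roots[roots >= rng[1] & roots <= rng[2]])
  ws <- seq(rng[1], rng[2], length.out = grid_n)
  grid <- purrr::map(ws, function(w) {
    th <- theta_at(result, w)
    tibble::tibble(w = w, theta = unname(th$theta),
                   lower = unname(th$theta - tc * th$se),
                   upper = unname(th$theta + tc * th$se))
  }) |> purrr::list_rbind()
  grid$significant <- grid$lower > 0 | grid$upper < 0
  structure(list(
    boundaries = boundaries, grid = grid, alpha = alpha, t_crit = unname(tc),
    moderator_range = rng,
    uniformly_significant = if (length(boundaries)) NA else
      all(grid$significant)
  ), class = "jn_regions")
}

#' @export
print.jn_regions <- function(x, ...) {
  if (length(x$boundaries)) {
    cat("Johnson-Neyman boundaries inside [",
        signif(x$moderator_range[1], 4), ", ",
        signif(x$moderator_range[2], 4), "]: ",
        paste(signif(x$boundaries, 4), collapse = ", "), "\n", sep = "")
  } else {
    cat("No Johnson-Neyman boundary in the observed moderator range; effect",
        if (isTRUE(x$uniformly_significant)) "significant"
        else "non-significant", "throughout\n")
  }
  invisible(x)
}

#' Plot the Johnson-Neyman conditional-effect grid
#'
#' Conditional effect of the focal predictor across the moderator range with
#' pointwise confidence bands; boundaries are marked with vertical lines.
#'
#' @param object A `"jn_regions"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jn_regions <- function(object, ...) {
  g <- object$grid
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$w, y = .data$theta)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "moderator value",
                  y = "conditional effect of focal predictor",
                  title = "Johnson-Neyman regions of significance") +
    ggplot2::theme_minimal()
  if (length(object$boundaries)) {
    p <- p + ggplot2::geom_vline(xintercept = object$boundaries,
                                 linetype = 3, colour = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
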