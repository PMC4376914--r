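# run code under a temporary RNG state so seeded helpers do not clobber the
# caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit a crossed random-intercept linear mixed model
#'
#' Fits `response ~ fixed effects + (1 | subject) + (1 | item)`: trial-level
#' ratings are modelled with additive random offsets for subjects and for
#' items (scenarios or risk domains), the standard remedy for
#' non-independence of repeated ratings. Rows with missing values in any used
#' column are dropped listwise for this model only (count reported via a
#' message). If the crossed fit fails, the model falls back to a
#' subject-only random intercept with a message.
#'
#' @param data A trial table (long format).
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect column names (may be empty
#'   for an intercept-only model).
#' @param subject,item Grouping columns for the random intercepts; set
#'   `item = NULL` for a subject-only model.
#' @param reml Fit by REML (`TRUE`, default) or maximum likelihood.
#' @return An object of class `"lmm_fit"`: `fixed_effects` tibble (term,
#'   estimate, se), `vcov_fixed`, `variance_components` (subject, item,
#'   residual), `log_likelihood`, `objective`, `n_obs`, `n_subjects`,
#'   `n_items`, and the underlying `model`.
#' @export
fit_lmm <- function(data, response, fixed = character(),
                    subject = "subject_id", item = "item_id", reml = TRUE) {
  data <- tibble::as_tibble(data)
  used <- c(response, fixed, subject, item)
  stopifnot(all(used %in% names(data)))
  cc <- stats::complete.cases(data[used])
  if (any(!cc)) {
    message("fit_lmm: dropping ", sum(!cc), " incomplete row(s) for '",
            response, "' model")
    data <- data[cc, ]
  }
  if (dplyr::n_distinct(data[[subject]]) < 2) {
    stop("design error: need >= 2 subjects", call. = FALSE)
  }
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (length(fixed)) {
    mm <- stats::model.matrix(
      stats::as.formula(paste("~", rhs)), data = data)
    if (qr(mm, tol = 1e-10)$rank < ncol(mm)) {
      stop("rank error: fixed-effect design matrix is singular", call. = FALSE)
    }
  }
  ranef_terms <- paste0("(1 | ", subject, ")")
  if (!is.null(item)) {
    if (dplyr::n_distinct(data[[item]]) < 2) {
      stop("design error: need >= 2 items for an item intercept", call. = FALSE)
    }
    ranef_terms <- paste(ranef_terms, "+", paste0("(1 | ", item, ")"))
  }
  fml <- stats::as.formula(paste(response, "~", rhs, "+", ranef_terms))
  fit <- tryCatch(
    lme4::lmer(fml, data = data, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) e
  )
  if (inherits(fit, "error") && !is.null(item)) {
    message("fit_lmm: crossed fit failed (", conditionMessage(fit),
            "); falling back to subject-only random intercept")
    return(fit_lmm(data, response, fixed, subject, item = NULL, reml = reml))
  }
  if (inherits(fit, "error")) {
    stop("convergence error: ", conditionMessage(fit), call. = FALSE)
  }
  quiet_try <- function(expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) NULL),
      warning = function(w) {
        if (grepl("variance-covariance matrix problem", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  co <- quiet_try(summary(fit)$coefficients)
  vcov_f <- quiet_try(as.matrix(stats::vcov(fit)))
  if (is.null(co) || is.null(vcov_f) || anyNA(vcov_f)) {
    # degenerate fit (residual variance numerically zero): fall back to the
    # OLS covariance sigma^2 (X'X)^-1, which tends to 0 with the noise
    beta <- lme4::fixef(fit)
    X <- stats::model.matrix(fit)
    vcov_f <- stats::sigma(fit)^2 * solve(crossprod(X))
    co <- cbind(Estimate = beta, `Std. Error` = sqrt(diag(vcov_f)))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(g) {
    i <- which(vc$grp == g)
    if (length(i)) vc$vcov[i] else NA_real_
  }
  structure(list(
    fixed_effects = tibble::tibble(term = rownames(co),
                                   estimate = unname(co[, "Estimate"]),
                                   se = unname(co[, "Std. Error"])),
    vcov_fixed = vcov_f,
    variance_components = c(subject = getvar(subject),
                            item = if (is.null(item)) NA_real_ else getvar(item),
                            residual = getvar("Residual")),
    log_likelihood = as.numeric(stats::logLik(fit)),
    objective = if (reml) "REML" else "ML",
    n_obs = nrow(data),
    n_subjects = dplyr::n_distinct(data[[subject]]),
    n_items = if (is.null(item)) NA_integer_ else
      dplyr::n_distinct(data[[item]]),
    formula = fml,
    model = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit>", deparse(x$formula), "(", x$objective, ")\n")
  print(x$fixed_effects)
  cat("variance components:",
      paste(names(x$variance_components),
            signif(x$variance_components, 4), sep = "=", collapse = ", "),
      "\nlogLik:", x$log_likelihood, " n:", x$n_obs, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.lmm_fit <- function(x, ...) x$fixed_effects

#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood, objective = x$objective,
                 n_obs = x$n_obs, n_subjects = x$n_subjects,
                 n_items = x$n_items)
}

coef_se <- function(fit, term) {
  row <- fit$fixed_effects[fit$fixed_effects$term == term, ]
  c(estimate = row$estimate, se = row$se)
}

#' Monte-Carlo confidence interval for a three-path indirect effect
#'
#' Approximates the sampling distribution of the product
#' \eqn{a_1 d_{21} b_2} by drawing each coefficient independently from a
#' normal distribution centred at its estimate with its standard error, and
#' returns the 2.5th and 97.5th percentiles of the `k` products (percentile
#' method, linear interpolation between order statistics). The indirect
#' effect is judged significant when the interval excludes zero.
#'
#' @param a1,d21,b2 Path estimates.
#' @param se_a1,se_d21,se_b2 Their standard errors (all `>= 0`).
#' @param k Number of Monte-Carlo draws (at least 1000; default 100000).
#' @param seed Integer seed (mandatory, recorded in the output).
#' @param level Confidence level (default 0.95).
#' @return A list: `lower`, `upper`, `point` (= `a1 * d21 * b2`),
#'   `significant`, `k`, `seed`, `level`.
#' @export
mc_indirect_ci <- function(a1, d21, b2, se_a1, se_d21, se_b2,
                           k = 100000, seed, level = 0.95) {
  if (missing(seed)) stop("seed is mandatory for mc_indirect_ci", call. = FALSE)
  if (k < 1000) {
    stop("precision error: k must be at least 1000 draws", call. = FALSE)
  }
  if (any(c(se_a1, se_d21, se_b2) < 0)) {
    stop("domain error: standard errors must be >= 0", call. = FALSE)
  }
  prods <- with_seed(seed, {
    stats::rnorm(k, a1, se_a1) * stats::rnorm(k, d21, se_d21) *
      stats::rnorm(k, b2, se_b2)
  })
  qs <- stats::quantile(prods, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], point = a1 * d21 * b2,
       significant = qs[1] > 0 || qs[2] < 0, k = as.integer(k),
       seed = as.integer(seed), level = level)
}

#' Likelihood-ratio test for the serially mediated model
#'
#' Refits, by maximum likelihood with identical crossed random-intercept
#' structures and on identical rows, the baseline outcome model
#' `y ~ x (+ covariates)` and the mediated model
#' `y ~ x + m1 + m2 (+ covariates)`, and compares them:
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{base})} on 2 df.
#'
#' @param data A trial table.
#' @param x,m1,m2,y Column names of predictor, both mediators, and outcome.
#' @param covariates_on_y Optional covariate columns for the outcome models.
#' @param subject,item Random-intercept grouping columns.
#' @return A list: `chi_sq`, `df` (= 2), `p`.
#' @export
lrt_mediation <- function(data, x, m1, m2, y, covariates_on_y = character(),
                          subject = "subject_id", item = "item_id") {
  data <- tibble::as_tibble(data)
  used <- c(x, m1, m2, y, covariates_on_y, subject, item)
  data <- data[stats::complete.cases(data[used]), ]
  base <- fit_lmm(data, y, c(x, covariates_on_y), subject, item, reml = FALSE)
  full <- fit_lmm(data, y, c(x, m1, m2, covariates_on_y), subject, item,
                  reml = FALSE)
  chi <- 2 * (full$log_likelihood - base$log_likelihood)
  if (chi < -1e-6) {
    stop("optimization error: full-model likelihood below baseline (chi^2 = ",
         signif(chi, 4), ")", call. = FALSE)
  }
  chi <- max(chi, 0)
  list(chi_sq = chi, df = 2L, p = stats::pchisq(chi, 2, lower.tail = FALSE))
}

#' Serial two-mediator path model with crossed random intercepts
#'
#' Estimates the serial mediation chain `x -> m1 -> m2 -> y` from trial-level
#' data. Three crossed random-intercept mixed models are fitted (REML):
#' `m1 ~ x` giving \eqn{a_1}; `m2 ~ x + m1` giving \eqn{a_2} and
#' \eqn{d_{21}}; and `y ~ x + m1 + m2 (+ covariates)` giving \eqn{c'},
#' \eqn{b_1} and \eqn{b_2}. Covariates enter only the outcome model. The
#' three-path indirect effect \eqn{a_1 d_{21} b_2} gets a Monte-Carlo
#' percentile CI ([mc_indirect_ci()]), and the mediated outcome model is
#' compared against the x-only baseline with a 2-df likelihood-ratio test on
#' ML refits ([lrt_mediation()]).
#'
#' @param data A trial table.
#' @param x,m1,m2,y Column names of predictor, mediators, outcome.
#' @param covariates_on_y Covariate columns for the outcome model (e.g.
#'   trait anxiety and risk propensity scores).
#' @param k Monte-Carlo draws for the indirect-effect CI.
#' @param seed Integer seed for the Monte-Carlo draws.
#' @param subject,item Random-intercept grouping columns.
#' @return An object of class `"mediation_result"` with path coefficients
#'   (`a1`, `a2`, `d21`, `b1`, `b2`, `c_prime`, each `estimate`/`se`),
#'   `indirect_serial`, `mc_ci`, `lrt`, and the three `fits`.
#' @examples
#' \donttest{
#' d <- gen_study1(seed = 1)
#' m <- serial_mediation(d, "x", "stress", "risk_perception", "risk_taking",
#'                       covariates_on_y = c("stai", "siri"),
#'                       k = 10000, seed = 2)
#' tidy(m)
#' }
#' @export
serial_mediation <- function(data, x, m1, m2, y,
                             covariates_on_y = character(),
                             k = 100000, seed,
                             subject = "subject_id", item = "item_id") {
  if (missing(seed)) stop("seed is mandatory for serial_mediation", call. = FALSE)
  data <- tibble::as_tibble(data)
  fit_m1 <- fit_lmm(data, m1, x, subject, item, reml = TRUE)
  fit_m2 <- fit_lmm(data, m2, c(x, m1), subject, item, reml = TRUE)
  fit_y <- fit_lmm(data, y, c(x, m1, m2, covariates_on_y), subject, item,
                   reml = TRUE)
  paths <- list(
    a1 = coef_se(fit_m1, x),
    a2 = coef_se(fit_m2, x),
    d21 = coef_se(fit_m2, m1),
    c_prime = coef_se(fit_y, x),
    b1 = coef_se(fit_y, m1),
    b2 = coef_se(fit_y, m2)
  )
  ci <- mc_indirect_ci(paths$a1["estimate"], paths$d21["estimate"],
                       paths$b2["estimate"],
                       paths$a1["se"], paths$d21["se"], paths$b2["se"],
                       k = k, seed = seed)
  lrt <- lrt_mediation(data, x, m1, m2, y, covariates_on_y, subject, item)
  structure(list(
    paths = paths,
    indirect_serial = unname(paths$a1["estimate"] * paths$d21["estimate"] *
                               paths$b2["estimate"]),
    mc_ci = ci, lrt = lrt,
    covariates_on_y = covariates_on_y,
    variables = c(x = x, m1 = m1, m2 = m2, y = y),
    fits = list(m1 = fit_m1, m2 = fit_m2, y = fit_y)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  v <- x$variables
  cat(sprintf("Serial mediation: %s -> %s -> %s -> %s\n",
              v["x"], v["m1"], v["m2"], v["y"]))
  print(tidy(x))
  cat(sprintf("indirect a1*d21*b2 = %.4f, 95%% MC CI [%.4f, %.4f] (k = %d)\n",
              x$indirect_serial, x$mc_ci$lower, x$mc_ci$upper, x$mc_ci$k))
  cat(sprintf("LRT vs baseline: chi^2(%d) = %.3f, p = %.4g\n",
              x$lrt$df, x$lrt$chi_sq, x$lrt$p))
  invisible(x)
}

#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    path = names(x$paths),
    estimate = vapply(x$paths, function(p) unname(p["estimate"]), 1.0),
    se = vapply(x$paths, function(p) unname(p["se"]), 1.0)
  )
}

#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(
    indirect_serial = x$indirect_serial,
    mc_lower = x$mc_ci$lower, mc_upper = x$mc_ci$upper,
    mc_significant = x$mc_ci$significant,
    lrt_chi_sq = x$lrt$chi_sq, lrt_df = x$lrt$df, lrt_p = x$lrt$p,
    n_obs = x$fits$y$n_obs
  )
}

#' Plot serial-mediation path coefficients
#'
#' Dot-and-whisker display of the unstandardized path coefficients with
#' approximate 95% intervals (estimate +/- 1.96 SE).
#'
#' @param object A `"mediation_result"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mediation_result <- function(object, ...) {
  td <- tidy(object)
  td$path <- factor(td$path, levels = rev(td$path))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$path)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                   xmax = .data$estimate + 1.96 * .data$se)) +
    ggplot2::labs(x = "unstandardized coefficient", y = NULL,
                  title = "Serial mediation path coefficients") +
    ggplot2::theme_minimal()
}
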