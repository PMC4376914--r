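#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fits a fully within-subject ANOVA on long-format data and reports, for
#' every main effect and interaction, the F statistic, uncorrected degrees of
#' freedom, the Greenhouse-Geisser epsilon
#' (\eqn{\epsilon = (\mathrm{tr}\,\Sigma)^2 / ((k-1)\,\mathrm{tr}\,\Sigma^2)}
#' on the double-centered covariance of the contrast variables), the
#' epsilon-corrected p value, and partial eta squared
#' \eqn{SS_{effect} / (SS_{effect} + SS_{error})}. Effects with a single
#' numerator df have epsilon fixed at 1 (sphericity holds trivially).
#'
#' @param data Long-format data frame: one row per subject x cell.
#' @param dv Name of the response column (character).
#' @param subject Name of the subject identifier column.
#' @param within Character vector of within-subject factor columns.
#' @return A tibble with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `gg_epsilon`, `p_uncorrected`, `p_gg`, `partial_eta_sq`.
#' @examples
#' d <- tidyr::expand_grid(s = factor(1:8), cond = c("a", "b", "c"))
#' d$y <- rnorm(nrow(d)) + (d$cond == "b")
#' rm_anova(d, dv = "y", subject = "s", within = "cond")
#' @export
rm_anova <- function(data, dv, subject, within) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c(dv, subject, within) %in% names(data)))
  data$.cell <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  wide <- data |>
    dplyr::select(dplyr::all_of(c(subject, dv)), ".cell") |>
    tidyr::pivot_wider(names_from = ".cell", values_from = dplyr::all_of(dv))
  y <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(y)) {
    stop("design error: unbalanced or missing within-subject cells", call. = FALSE)
  }
  if (nrow(y) < 3) {
    stop("design error: repeated-measures ANOVA needs at least 3 subjects",
         call. = FALSE)
  }
  idata <- tidyr::expand_grid(!!!purrr::map(
    stats::setNames(within, within),
    ~ unique(data[[.x]])
  ))
  idata <- as.data.frame(purrr::map(idata, factor))
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  mlm <- stats::lm(y ~ 1)
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = "III")
  # a singular contrast covariance (e.g. summaries that sum to zero by
  # construction) makes sphericity corrections unavailable; epsilon then
  # defaults to 1 below, which is also the only consistent choice there
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("non-sphericity|HF eps", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  ut <- s$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  adj <- s$pval.adjustments
  purrr::map(effects, function(ef) {
    ss_eff <- ut[ef, "Sum Sq"]
    ss_err <- ut[ef, "Error SS"]
    df1 <- ut[ef, "num Df"]
    df2 <- ut[ef, "den Df"]
    p_unc <- ut[ef, "Pr(>F)"]
    if (!is.null(adj) && ef %in% rownames(adj) &&
        is.finite(adj[ef, "GG eps"])) {
      eps <- adj[ef, "GG eps"]
      p_gg <- adj[ef, "Pr(>F[GG])"]
    } else {
      # 1-df effects (and degenerate contrast covariances) satisfy
      # sphericity trivially: epsilon = 1, corrected p = uncorrected p
      eps <- 1
      p_gg <- p_unc
    }
    tibble::tibble(
      effect = ef, F = ut[ef, "F value"], df1 = df1, df2 = df2,
      gg_epsilon = unname(eps), p_uncorrected = unname(p_unc),
      p_gg = unname(p_gg),
      partial_eta_sq = ss_eff / (ss_eff + ss_err)
    )
  }) |> purrr::list_rbind()
}

#' Holm step-down adjustment of p values
#'
#' Step-down Bonferroni-Holm correction: sort the p values ascending,
#' multiply the j-th smallest by `m - j + 1`, enforce monotonicity and cap at
#' 1, and return the adjusted values in the input order.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @param m Number of comparisons in the family (defaults to `length(p)`).
#' @return Adjusted p values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.03)) # 0.03 0.04 0.04
#' @export
holm_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("domain error: p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm", n = m)
}

#' Per-scenario tests of mean thought valence against neutral
#'
#' For each scenario, averages the (recoded) valence ratings within subject,
#' tests the subject means against 0 with a two-tailed one-sample t-test, and
#' Holm-adjusts the p values across scenarios. Scenarios with zero
#' between-subject variance are flagged as degenerate (p set to 1 when the
#' mean is exactly 0, to 0 otherwise).
#'
#' @param data Long-format trial data.
#' @param value Name of the valence column.
#' @param subject,scenario Names of the subject and scenario id columns.
#' @return A tibble per scenario: `scenario`, `mean`, `t`, `df`, `p`,
#'   `p_holm`, `degenerate`.
#' @export
posthoc_vs_neutral <- function(data, value = "x", subject = "subject_id",
                               scenario = "item_id") {
  data <- tibble::as_tibble(data)
  means <- data |>
    dplyr::group_by(.data[[subject]], .data[[scenario]]) |>
    dplyr::summarise(v = mean(.data[[value]], na.rm = TRUE), .groups = "drop")
  if (dplyr::n_distinct(means[[subject]]) < 2) {
    stop("sample-size error: need at least 2 subjects", call. = FALSE)
  }
  res <- means |>
    dplyr::group_by(scenario = .data[[scenario]]) |>
    dplyr::summarise(
      mean = mean(.data$v),
      sd = stats::sd(.data$v),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(
      degenerate = .data$sd == 0,
      t = ifelse(.data$degenerate, 0, .data$mean / (.data$sd / sqrt(.data$n))),
      df = .data$n - 1,
      p = dplyr::case_when(
        degenerate & mean == 0 ~ 1,
        degenerate ~ 0,
        TRUE ~ 2 * stats::pt(-abs(.data$mean / (.data$sd / sqrt(.data$n))),
                             .data$n - 1)
      )
    )
  res$p_holm <- holm_adjust(res$p)
  if (any(res$degenerate)) {
    warning("degenerate (zero-variance) scenario(s): ",
            paste(res$scenario[res$degenerate], collapse = ", "), call. = FALSE)
  }
  dplyr::select(res, "scenario", "mean", "t", "df", "p", "p_holm", "degenerate")
}

#' Valence ANOVA against an explicit neutral reference level
#'
#' Repeated-measures ANOVA comparing the per-scenario mean valence ratings to
#' the neutral point 0, modelled as an explicit constant reference level of
#' the within-subject factor. With 10 scenarios and the neutral level this is
#' an 11-level factor, giving F(10, 10 * (n - 1)) degrees of freedom.
#'
#' @inheritParams posthoc_vs_neutral
#' @return The [rm_anova()] tibble for the scenario factor.
#' @export
valence_anova <- function(data, value = "x", subject = "subject_id",
                          scenario = "item_id") {
  data <- tibble::as_tibble(data)
  means <- data |>
    dplyr::group_by(.data[[subject]], .data[[scenario]]) |>
    dplyr::summarise(v = mean(.data[[value]], na.rm = TRUE), .groups = "drop")
  names(means) <- c("s", "scen", "v")
  neutral <- tibble::tibble(s = unique(means$s), scen = ".neutral", v = 0)
  long <- dplyr::bind_rows(means, neutral)
  rm_anova(long, dv = "v", subject = "s", within = "scen")
}

#' Intraclass correlation for rating consistency
#'
#' Two-way mixed, consistency, average-measures intraclass correlation
#' ICC(3,k) = (MS_rows - MS_error) / MS_rows, measuring how consistently the
#' item profile is rated across subjects. ICC(2,1) and ICC(2,k)
#' (absolute-agreement variants) are available via `type`.
#'
#' @param ratings A numeric matrix (subjects x items) or a long data frame
#'   (then give `value`, `subject`, `item`).
#' @param value,subject,item Column names when `ratings` is long.
#' @param type One of `"ICC3k"` (default), `"ICC2k"`, `"ICC21"`.
#' @return The ICC as a single number.
#' @export
icc_consistency <- function(ratings, value = NULL, subject = NULL, item = NULL,
                            type = c("ICC3k", "ICC2k", "ICC21")) {
  type <- match.arg(type)
  if (is.data.frame(ratings) && !is.null(value)) {
    ratings <- ratings |>
      dplyr::group_by(.data[[subject]], .data[[item]]) |>
      dplyr::summarise(v = mean(.data[[value]], na.rm = TRUE),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = dplyr::all_of(item), values_from = "v")
    ratings <- as.matrix(ratings[, -1, drop = FALSE])
  }
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("design error: ICC needs a complete matrix", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) {
    stop("design error: ICC needs >= 2 subjects and >= 2 items", call. = FALSE)
  }
  grand <- mean(x)
  ms_r <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  ms_c <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  ss_e <- sum((x - outer(rowMeans(x), rep(1, k)) -
                 outer(rep(1, n), colMeans(x)) + grand)^2)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  if (ms_r == 0) {
    warning("ICC undefined: zero between-subject variance", call. = FALSE)
    return(NaN)
  }
  switch(type,
    ICC3k = (ms_r - ms_e) / ms_r,
    ICC2k = (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n),
    ICC21 = (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  )
}

#' PANAS pre/post change analysis
#'
#' Mean change in positive (PA) and negative (NA) affect with 95% confidence
#' intervals, plus the scale-by-time interaction F from the repeated-measures
#' model on change scores (equivalently, a one-sample F on the difference of
#' the NA and PA change scores), F(1, n - 1).
#'
#' @param records A data frame of PANAS records (see [validate_panas()]).
#' @return A list of class `"panas_change"`: `changes` tibble (scale, delta,
#'   lower, upper), `interaction` (F, df1, df2, p, partial_eta_sq), `n`.
#' @export
panas_change <- function(records) {
  records <- tibble::as_tibble(records)
  validate_panas(records)
  n <- nrow(records)
  if (n < 3) stop("sample-size error: need at least 3 subjects", call. = FALSE)
  d_pa <- records$pa_post - records$pa_pre
  d_na <- records$na_post - records$na_pre
  ci <- function(d) {
    half <- stats::qt(0.975, n - 1) * stats::sd(d) / sqrt(n)
    c(mean(d) - half, mean(d) + half)
  }
  contrast <- d_na - d_pa
  if (stats::sd(contrast) == 0) {
    f_val <- if (mean(contrast) == 0) 0 else Inf
    p_int <- if (mean(contrast) == 0) 1 else 0
  } else {
    tt <- stats::t.test(contrast)
    f_val <- unname(tt$statistic)^2
    p_int <- tt$p.value
  }
  changes <- tibble::tibble(
    scale = c("PA", "NA"),
    delta = c(mean(d_pa), mean(d_na)),
    lower = c(ci(d_pa)[1], ci(d_na)[1]),
    upper = c(ci(d_pa)[2], ci(d_na)[2])
  )
  structure(list(
    changes = changes,
    interaction = list(F = f_val, df1 = 1, df2 = n - 1, p = p_int,
                       partial_eta_sq = f_val / (f_val + n - 1)),
    n = n,
    note = "interaction = scale(PA/NA) x time contrast on change scores"
  ), class = "panas_change")
}

#' @export
print.panas_change <- function(x, ...) {
  cat(sprintf("PANAS change (n = %d): delta PA = %.2f, delta NA = %.2f; F(1, %d) = %.3f, p = %.4g\n",
              x$n, x$changes$delta[1], x$changes$delta[2],
              x$interaction$df2, x$interaction$F, x$interaction$p))
  invisible(x)
}

#' Subject-level Pearson correlation between two trial-table variables
#'
#' Averages each variable within subject (subject-level covariates are
#' unchanged by averaging) and correlates the subject-level values, two-tailed.
#'
#' @param table A trial table.
#' @param var_a,var_b Column names to correlate.
#' @param subject Subject id column.
#' @return A tibble: `var_a`, `var_b`, `r`, `df`, `p`, `n`.
#' @export
subject_level_correlation <- function(table, var_a, var_b,
                                      subject = "subject_id") {
  table <- tibble::as_tibble(table)
  agg <- table |>
    dplyr::group_by(.data[[subject]]) |>
    dplyr::summarise(a = mean(.data[[var_a]], na.rm = TRUE),
                     b = mean(.data[[var_b]], na.rm = TRUE), .groups = "drop")
  agg <- agg[stats::complete.cases(agg[c("a", "b")]), ]
  if (nrow(agg) < 3) {
    stop("sample-size error: need >= 3 subjects after aggregation",
         call. = FALSE)
  }
  if (stats::sd(agg$a) == 0 || stats::sd(agg$b) == 0) {
    warning("correlation undefined: zero variance", call. = FALSE)
    return(tibble::tibble(var_a = var_a, var_b = var_b, r = NaN,
                          df = nrow(agg) - 2, p = NaN, n = nrow(agg)))
  }
  ct <- stats::cor.test(agg$a, agg$b)
  tibble::tibble(var_a = var_a, var_b = var_b,
                 r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value, n = nrow(agg))
}
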