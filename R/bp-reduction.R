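#' Mean Arterial Pressure from a cuff reading
#'
#' MAP = 2/3 * diastolic + 1/3 * systolic, the standard weighted average that
#' downweights the brief systolic peak relative to the longer diastolic phase
#' of the cardiac cycle. Vectorized over readings.
#'
#' @param systolic Systolic pressure(s), mmHg.
#' @param diastolic Diastolic pressure(s), mmHg.
#' @return MAP in mmHg.
#' @examples
#' map_from_cuff(120, 80) # 93.33
#' @export
map_from_cuff <- function(systolic, diastolic) {
  if (any(!(systolic > diastolic & diastolic > 0))) {
    stop("domain error: need systolic > diastolic > 0", call. = FALSE)
  }
  (2 / 3) * diastolic + (1 / 3) * systolic
}

# canonical per-subject layout: 8 pre-baseline, 1 training, 5 scenario,
# 6 post-baseline readings, in acquisition order
check_canonical_layout <- function(phases) {
  expected <- c(rep("pre_baseline", 8), "training", rep("scenario", 5),
                rep("post_baseline", 6))
  if (length(phases) != 20) {
    stop("layout error: expected 20 readings, got ", length(phases),
         call. = FALSE)
  }
  bad <- which(phases != expected)
  if (length(bad)) {
    stop("layout error: reading ", bad[1], " has phase '", phases[bad[1]],
         "', expected '", expected[bad[1]], "'", call. = FALSE)
  }
  invisible(TRUE)
}

reduce_one_subject <- function(sub) {
  check_canonical_layout(sub$phase)
  map <- map_from_cuff(sub$systolic, sub$diastolic)
  # discard pre-baseline 1-3 (lab-novelty stress), the training reading, and
  # post-baseline 1 (post-stress recovery); 15 readings remain
  keep <- setdiff(seq_len(20), c(1:3, 9, 15))
  retained <- map[keep]
  if (stats::sd(retained) == 0) {
    stop("degenerate-variance error: retained readings are constant for subject ",
         sub$subject_id[1], call. = FALSE)
  }
  z <- as.numeric(scale(retained))   # sample SD (n - 1)
  phase_kept <- sub$phase[keep]
  vis_idx <- which(phase_kept == "scenario")
  vis_dom <- sub$scenario_domain[keep][vis_idx]
  if (anyDuplicated(vis_dom)) {
    stop("layout error: duplicated scenario domain(s) for subject ",
         sub$subject_id[1], ": ",
         paste(vis_dom[duplicated(vis_dom)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    subject_id = sub$subject_id[1],
    phase = c("pre_baseline", "post_baseline", rep("visualization", 5)),
    domain = c(NA_character_, NA_character_, vis_dom),
    map_z = c(mean(z[phase_kept == "pre_baseline"]),
              mean(z[phase_kept == "post_baseline"]),
              z[vis_idx]),
    retained_mean = mean(retained),
    retained_sd = stats::sd(retained)
  )
}

#' Reduce a raw cuff series to z-scored MAP stress indicators
#'
#' Applies the five-step cardiovascular data-reduction procedure per subject:
#' (1) convert all 20 readings to MAP; (2) drop the first three pre-baseline
#' readings, the training reading and the first post-baseline reading,
#' leaving 15; (3) z-score the 15 within subject (sample SD); (4) average the
#' 5 remaining pre-baseline and 5 remaining post-baseline z-scores
#' separately; (5) keep the 5 visualization z-scores keyed by risk domain.
#'
#' @param series A tibble of cuff readings as returned by [read_bp_series()]
#'   (columns `subject_id`, `phase`, `scenario_domain`, `systolic`,
#'   `diastolic`), in acquisition order, one canonical 20-reading block per
#'   subject.
#' @return A tibble with one `pre_baseline` and one `post_baseline` row
#'   (phase means) plus five `visualization` rows per subject, with the
#'   within-subject z-scored MAP in `map_z`.
#' @export
reduce_bp_series <- function(series) {
  series <- tibble::as_tibble(series)
  validate_bp_series(series)
  if (!"scenario_domain" %in% names(series)) {
    series$scenario_domain <- NA_character_
  }
  series |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_split() |>
    purrr::map(reduce_one_subject) |>
    purrr::list_rbind()
}

#' Phase contrast on reduced blood pressure
#'
#' One-way repeated-measures ANOVA over the three phase summaries
#' (pre-baseline mean, visualization mean, post-baseline mean) of the reduced
#' z-scored MAP, with uncorrected paired t follow-ups.
#'
#' @param reduced Output of [reduce_bp_series()] for at least 3 subjects.
#' @return A list of class `"phase_contrast"` with elements `anova` (tibble:
#'   effect, F, df1, df2, gg_epsilon, p_gg, partial_eta_sq), `means` (phase
#'   means with 95% CIs) and `pairwise` (paired t-tests).
#' @export
phase_contrast <- function(reduced) {
  wide <- reduced |>
    dplyr::group_by(.data$subject_id, .data$phase) |>
    dplyr::summarise(map_z = mean(.data$map_z), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "map_z")
  need <- c("pre_baseline", "visualization", "post_baseline")
  if (!all(need %in% names(wide))) {
    stop("phase_contrast needs pre_baseline, visualization and post_baseline rows",
         call. = FALSE)
  }
  if (nrow(wide) < 3) {
    stop("sample-size error: phase contrast needs at least 3 subjects",
         call. = FALSE)
  }
  long <- wide |>
    tidyr::pivot_longer(dplyr::all_of(need),
                        names_to = "phase", values_to = "map_z")
  aov_tab <- rm_anova(long, dv = "map_z", subject = "subject_id",
                      within = "phase")
  means <- long |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      mean = mean(.data$map_z),
      ci_half = stats::qt(0.975, dplyr::n() - 1) *
        stats::sd(.data$map_z) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(lower = .data$mean - .data$ci_half,
                  upper = .data$mean + .data$ci_half)
  pairs <- utils::combn(need, 2, simplify = FALSE)
  pairwise <- purrr::map(pairs, function(pr) {
    tt <- stats::t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
    tibble::tibble(phase_a = pr[1], phase_b = pr[2],
                   mean_diff = unname(tt$estimate),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  }) |> purrr::list_rbind()
  structure(list(anova = aov_tab, means = means, pairwise = pairwise,
                 n_subjects = nrow(wide)),
            class = "phase_contrast")
}

#' @export
print.phase_contrast <- function(x, ...) {
  a <- x$anova[x$anova$effect == "phase", ]
  cat(sprintf("Phase contrast on z-scored MAP (%d subjects): F(%g, %g) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$n_subjects, a$df1, a$df2, a$F, a$p_gg, a$partial_eta_sq))
  print(x$means)
  invisible(x)
}

#' Plot reduced blood pressure by phase
#'
#' Phase means of z-scored MAP with 95% confidence intervals.
#'
#' @param object A `"phase_contrast"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_contrast <- function(object, ...) {
  m <- object$means
  m$phase <- factor(m$phase,
                    levels = c("pre_baseline", "visualization", "post_baseline"))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$phase, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), width = 0.2) +
    ggplot2::labs(x = NULL, y = "z-scored MAP",
                  title = "Blood-pressure stress reactivity by phase") +
    ggplot2::theme_minimal()
}
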