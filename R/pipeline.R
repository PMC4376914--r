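new_manifest <- function(seed) {
  list(package = "riskimagery",
       version = as.character(utils::packageVersion("riskimagery")),
       r_version = as.character(getRversion()),
       seed = seed, stages = list())
}

log_stage <- function(manifest, name, note) {
  manifest$stages[[name]] <- note
  manifest
}

#' Run the full Study-1 analysis bundle
#'
#' Composes the Study-1 analyses on a trial table: the valence
#' repeated-measures ANOVA against the neutral reference, Holm-corrected
#' per-scenario tests against neutral, ICC reliability of each rating,
#' subject-level covariate correlations, and the serial mediation model with
#' its Monte-Carlo CI and likelihood-ratio test.
#'
#' @param trials A trial table (columns `subject_id`, `item_id`, `x`,
#'   `stress`, `risk_perception`, `risk_taking`, optionally `stai`, `siri`).
#' @param k Monte-Carlo draws for the indirect-effect CI.
#' @param seed Integer seed.
#' @return A list of class `"study_results"` with blocks `valence_anova`,
#'   `posthoc`, `icc`, `correlations`, `mediation`, and a `manifest`.
#' @export
run_study1 <- function(trials, k = 100000, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  trials <- tibble::as_tibble(trials)
  man <- new_manifest(seed)
  va <- valence_anova(trials)
  man <- log_stage(man, "valence_anova", list(n_rows = nrow(trials)))
  ph <- posthoc_vs_neutral(trials)
  man <- log_stage(man, "posthoc", list(n_scenarios = nrow(ph)))
  icc <- purrr::map(
    c(x = "x", stress = "stress", risk_perception = "risk_perception",
      risk_taking = "risk_taking"),
    function(v) icc_consistency(trials, value = v, subject = "subject_id",
                                item = "item_id"))
  man <- log_stage(man, "icc", list(measures = names(icc)))
  covs <- intersect(c("stai", "siri"), names(trials))
  cors <- purrr::map(covs, function(cv) {
    purrr::map(c("x", "stress", "risk_perception", "risk_taking"),
               function(v) subject_level_correlation(trials, cv, v)) |>
      purrr::list_rbind()
  }) |> purrr::list_rbind()
  man <- log_stage(man, "correlations", list(n = nrow(cors)))
  med <- serial_mediation(trials, "x", "stress", "risk_perception",
                          "risk_taking", covariates_on_y = covs,
                          k = k, seed = seed)
  man <- log_stage(man, "mediation", list(k = k))
  structure(list(valence_anova = va, posthoc = ph, icc = icc,
                 correlations = cors, mediation = med, manifest = man),
            class = "study_results")
}

#' Run the full Study-2 analysis bundle
#'
#' Composes the Study-2 analyses: PANAS change with the scale-by-time F,
#' blood-pressure reduction plus the three-phase contrast, the correlation
#' between positive-affect change and visualization blood pressure, and the
#' serial mediation model with vividness as predictor and the five risk
#' domains as items.
#'
#' @param trials Ratings trial table (vividness in `x`).
#' @param bp Raw cuff series ([read_bp_series()] layout).
#' @param panas PANAS records.
#' @param k,seed As in [run_study1()].
#' @return A list of class `"study_results"` with blocks `panas`, `bp`
#'   (reduced series + `phase_contrast`), `pa_bp_correlation`, `mediation`,
#'   and a `manifest`.
#' @export
run_study2 <- function(trials, bp, panas, k = 100000, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  man <- new_manifest(seed)
  pc_panas <- panas_change(panas)
  man <- log_stage(man, "panas", list(n = pc_panas$n))
  reduced <- reduce_bp_series(bp)
  man <- log_stage(man, "bp_reduce",
                   list(n_subjects = dplyr::n_distinct(reduced$subject_id),
                        retained_per_subject = 15))
  pc <- phase_contrast(reduced)
  man <- log_stage(man, "bp_contrast", list())
  # correlation between PA change and mean visualization blood pressure
  vis <- reduced |>
    dplyr::filter(.data$phase == "visualization") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(vis_z = mean(.data$map_z), .groups = "drop")
  pa <- tibble::tibble(subject_id = panas$subject_id,
                       d_pa = panas$pa_post - panas$pa_pre)
  joined <- dplyr::inner_join(vis, pa, by = "subject_id")
  ct <- stats::cor.test(joined$d_pa, joined$vis_z)
  pa_bp <- tibble::tibble(r = unname(ct$estimate),
                          df = unname(ct$parameter), p = ct$p.value)
  man <- log_stage(man, "pa_bp_correlation", list(n = nrow(joined)))
  covs <- intersect("siri", names(trials))
  med <- serial_mediation(trials, "x", "stress", "risk_perception",
                          "risk_taking", covariates_on_y = covs,
                          k = k, seed = seed)
  man <- log_stage(man, "mediation", list(k = k))
  structure(list(panas = pc_panas,
                 bp = list(reduced = reduced, phase_contrast = pc),
                 pa_bp_correlation = pa_bp, mediation = med, manifest = man),
            class = "study_results")
}

#' Run the full Study-3 analysis bundle
#'
#' Composes the Study-3 analyses: the EEG-to-IAI pipeline per recording, the
#' listening-versus-visualization phase ANOVA on the IAI, aggregation over
#' the parieto-occipital electrodes, and the moderated mixed model with
#' simple slopes and Johnson-Neyman regions of significance.
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param trials Risk ratings trial table (`risk_perception`,
#'   `risk_taking`, with `domain`).
#' @param filter Logical, passed to [eeg_iai_table()] (disable for
#'   synthetic narrowband signals when speed matters).
#' @param seed Integer seed.
#' @return A list of class `"study_results"` with blocks `iai_table`,
#'   `phase_anova`, `iai_mean` (per subject x domain), `moderation`,
#'   `simple_slopes`, `jn`, and a `manifest`.
#' @export
run_study3 <- function(recordings, trials, filter = TRUE, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  man <- new_manifest(seed)
  iai <- purrr::map(recordings, eeg_iai_table, filter = filter) |>
    purrr::list_rbind()
  man <- log_stage(man, "eeg_iai", list(n_rows = nrow(iai)))
  # phase effect: IAI averaged over electrodes and domains, per phase
  phase_dat <- iai |>
    dplyr::group_by(.data$subject_id, .data$phase) |>
    dplyr::summarise(iai = mean(.data$iai), .groups = "drop")
  phase_anova <- rm_anova(phase_dat, dv = "iai", subject = "subject_id",
                          within = "phase")
  man <- log_stage(man, "phase_anova", list())
  iai_mean <- aggregate_iai(iai)
  man <- log_stage(man, "aggregate_iai", list(n_rows = nrow(iai_mean)))
  analysis <- trials |>
    dplyr::inner_join(iai_mean, by = c("subject_id", "domain"))
  mod <- fit_interaction(analysis, y = "risk_taking",
                         x_focal = "risk_perception", moderator = "iai",
                         item = "domain")
  slopes <- simple_slopes(mod)
  jn <- jn_regions(mod)
  man <- log_stage(man, "moderation", list(n_rows = nrow(analysis)))
  structure(list(iai_table = iai, phase_anova = phase_anova,
                 iai_mean = iai_mean, moderation = mod,
                 simple_slopes = slopes, jn = jn, manifest = man),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat("<study_results> blocks:",
      paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  invisible(x)
}
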