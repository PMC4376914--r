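# truncated normal by rejection with inverse-cdf fallback (deterministic
# given the RNG state)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate a Study-1-style trial table with a serial mediation chain
#'
#' Simulates 60 subjects x 10 scenarios (two scenarios per risk domain) with
#' subject and item random intercepts for each response. Recoded thought
#' valence `x` is drawn from a truncated normal on `[-2, 2]`; then
#' `m1 = a1 x + effects + noise` (stress),
#' `m2 = a2 x + d21 m1 + effects + noise` (risk perception), and
#' `y = c' x + b1 m1 + b2 m2 + covariate effects + effects + noise`
#' (risk taking). Trait-anxiety (`stai`) and risk-propensity (`siri`) scores
#' are drawn with configurable correlations to the subject intercepts of
#' stress and risk taking respectively.
#'
#' @param n_subjects,n_items Design size (defaults 60 x 10).
#' @param a1,a2,d21,b1,b2,c_prime True path coefficients.
#' @param x_mean,x_sd Mean/SD of the latent valence before truncation to
#'   `[-2, 2]` (defaults to the negative mean reported for recoded valence).
#' @param sd_subject,sd_item,sd_resid Random-intercept and residual SDs,
#'   shared by the three responses.
#' @param sd_resid_y Residual SD of the outcome only (defaults to
#'   `sd_resid`); set to ~0 to make the outcome an exact linear function of
#'   `x`, `m1`, `m2` while the mediators keep their own variation.
#' @param gamma_stai,gamma_siri Covariate effects on the outcome (per
#'   centred covariate point).
#' @param cor_stai,cor_siri Correlations of the covariates with the subject
#'   intercepts of stress and risk taking.
#' @param discretize Round and clip ratings to their printed scales
#'   (1-10 mediators, 1-5 outcome). Off by default so that
#'   parameter-recovery checks see the uncoarsened model.
#' @param seed Integer seed (mandatory; generation is fully deterministic).
#' @return A trial table tibble with columns `subject_id`, `item_id`,
#'   `domain`, `x`, `stress`, `risk_perception`, `risk_taking`, `stai`,
#'   `siri`.
#' @export
gen_study1 <- function(n_subjects = 60, n_items = 10,
                       a1 = 1.0, a2 = 0.3, d21 = 0.5,
                       b1 = 0.05, b2 = -0.6, c_prime = -0.15,
                       x_mean = 0.83, x_sd = 0.98,
                       sd_subject = 0.5, sd_item = 0.3, sd_resid = 1.0,
                       sd_resid_y = sd_resid,
                       gamma_stai = 0.02, gamma_siri = 0.02,
                       cor_stai = 0.45, cor_siri = 0.35,
                       discretize = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory for gen_study1", call. = FALSE)
  stopifnot(abs(cor_stai) < 1, abs(cor_siri) < 1,
            sd_subject >= 0, sd_item >= 0, sd_resid >= 0)
  with_seed(seed, {
    doms <- rep(risk_domains(), length.out = n_items)
    u1 <- stats::rnorm(n_subjects, 0, sd_subject)  # stress intercepts
    u2 <- stats::rnorm(n_subjects, 0, sd_subject)
    u3 <- stats::rnorm(n_subjects, 0, sd_subject)  # risk-taking intercepts
    w1 <- stats::rnorm(n_items, 0, sd_item)
    w2 <- stats::rnorm(n_items, 0, sd_item)
    w3 <- stats::rnorm(n_items, 0, sd_item)
    std <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v)
      else rep(0, length(v))
    stai <- 40 + 9 * (cor_stai * std(u1) +
                        sqrt(1 - cor_stai^2) * stats::rnorm(n_subjects))
    siri <- 50 + 10 * (cor_siri * std(u3) +
                         sqrt(1 - cor_siri^2) * stats::rnorm(n_subjects))
    g <- tidyr::expand_grid(s = seq_len(n_subjects), i = seq_len(n_items))
    n <- nrow(g)
    x <- rtruncnorm(n, x_mean, x_sd, -2, 2)
    m1 <- a1 * x + u1[g$s] + w1[g$i] + stats::rnorm(n, 0, sd_resid)
    m2 <- a2 * x + d21 * m1 + u2[g$s] + w2[g$i] + stats::rnorm(n, 0, sd_resid)
    y <- c_prime * x + b1 * m1 + b2 * m2 +
      gamma_stai * (stai[g$s] - 40) + gamma_siri * (siri[g$s] - 50) +
      u3[g$s] + w3[g$i] + stats::rnorm(n, 0, sd_resid_y)
    # responses live on latent scales centred near the printed ranges
    stress <- 5 + m1
    risk_perception <- 5 + m2
    risk_taking <- 3 + y
    if (discretize) {
      stress <- clip(round(stress), 1, 10)
      risk_perception <- clip(round(risk_perception), 1, 10)
      risk_taking <- clip(round(risk_taking), 1, 5)
    }
    tibble::tibble(
      subject_id = sprintf("s%02d", g$s),
      item_id = sprintf("scen%02d", g$i),
      domain = doms[g$i],
      x = x, stress = stress, risk_perception = risk_perception,
      risk_taking = risk_taking,
      stai = stai[g$s], siri = siri[g$s]
    )
  })
}

#' Generate a Study-2-style bundle: ratings, cuff series and PANAS records
#'
#' Simulates 22 subjects, each with the canonical 20-reading cuff layout
#' (8 pre-baseline, 1 training, 5 scenario, 6 post-baseline readings).
#' Baseline readings are normal around the subject's resting MAP;
#' visualization (and training) readings are elevated by `delta` mmHg scaled
#' by the subject's relative imagery vividness. Systolic/diastolic pairs are
#' reconstructed from MAP and a drawn pulse pressure
#' (`SY = MAP + 2/3 PP`, `DY = MAP - 1/3 PP`), so [map_from_cuff()] recovers
#' the intended MAP exactly. Ratings follow the same serial chain as Study 1
#' with imagery vividness (1-10) as predictor and the five risk domains as
#' items; PANAS pre/post scores get the configured shifts.
#'
#' @param n_subjects Number of subjects (default 22).
#' @param a1,a2,d21,b1,b2,c_prime True path coefficients (defaults follow
#'   the Study-2 estimates).
#' @param viv_mean,viv_sd Vividness distribution (truncated to `[1, 10]`).
#' @param map_mean,map_sd Between-subject resting MAP distribution, mmHg.
#' @param delta Visualization MAP elevation in mmHg at average vividness
#'   (default 4.5, which yields a visualization z-score near +0.8 after
#'   reduction).
#' @param pp_mean,pp_sd Pulse-pressure distribution, mmHg.
#' @param noise_sd Reading noise SD, mmHg (default 3, the monitor's error).
#' @param pa_shift,na_shift True pre-to-post shifts of positive/negative
#'   affect (defaults -2.5 / +2.67).
#' @param panas_sd Noise SD of the PANAS change scores.
#' @param pa_bp_coupling Strength of the link between a subject's realized
#'   visualization blood-pressure response (in within-subject z units) and
#'   their positive-affect decrease, in PANAS points per z unit; the
#'   default of 7 produces a PA-change/visualization-BP correlation near
#'   -0.35.
#' @param sd_subject,sd_item,sd_resid Random-effect and residual SDs of the
#'   ratings chain.
#' @param discretize Round and clip ratings to the printed 1-10 scales.
#' @param seed Integer seed (mandatory).
#' @return A list with tibbles `trials`, `bp` (cuff series rows in
#'   acquisition order) and `panas`.
#' @export
gen_study2 <- function(n_subjects = 22,
                       a1 = 0.64, a2 = 0.3, d21 = 0.52,
                       b1 = 0.05, b2 = -0.64, c_prime = 0.10,
                       viv_mean = 6, viv_sd = 1.5,
                       map_mean = 93, map_sd = 8, delta = 4.5,
                       pp_mean = 40, pp_sd = 5, noise_sd = 3,
                       pa_shift = -2.5, na_shift = 2.67, panas_sd = 4,
                       pa_bp_coupling = 7,
                       sd_subject = 0.5, sd_item = 0.2, sd_resid = 1.0,
                       discretize = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory for gen_study2", call. = FALSE)
  with_seed(seed, {
    doms <- risk_domains()
    # --- ratings chain (items = the five risk domains) ---
    u1 <- stats::rnorm(n_subjects, 0, sd_subject)
    u2 <- stats::rnorm(n_subjects, 0, sd_subject)
    u3 <- stats::rnorm(n_subjects, 0, sd_subject)
    w1 <- stats::rnorm(5, 0, sd_item)
    w2 <- stats::rnorm(5, 0, sd_item)
    w3 <- stats::rnorm(5, 0, sd_item)
    std <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v)
      else rep(0, length(v))
    siri <- 50 + 10 * (0.35 * std(u3) + sqrt(1 - 0.35^2) *
                         stats::rnorm(n_subjects))
    g <- tidyr::expand_grid(s = seq_len(n_subjects), i = 1:5)
    n <- nrow(g)
    x <- rtruncnorm(n, viv_mean, viv_sd, 1, 10)
    m1 <- a1 * x + u1[g$s] + w1[g$i] + stats::rnorm(n, 0, sd_resid)
    m2 <- a2 * x + d21 * m1 + u2[g$s] + w2[g$i] + stats::rnorm(n, 0, sd_resid)
    y <- c_prime * x + b1 * m1 + b2 * m2 + 0.02 * (siri[g$s] - 50) +
      u3[g$s] + w3[g$i] + stats::rnorm(n, 0, sd_resid)
    stress <- 2 + m1
    risk_perception <- 2 + m2
    risk_taking <- 5 + y
    if (discretize) {
      stress <- clip(round(stress), 1, 10)
      risk_perception <- clip(round(risk_perception), 1, 10)
      risk_taking <- clip(round(risk_taking), 1, 10)
    }
    trials <- tibble::tibble(
      subject_id = sprintf("s%02d", g$s),
      item_id = doms[g$i], domain = doms[g$i],
      x = x, stress = stress, risk_perception = risk_perception,
      risk_taking = risk_taking, siri = siri[g$s]
    )
    # --- cuff series ---
    viv_subj <- tapply(x, g$s, mean)
    rel_viv <- viv_subj / mean(viv_subj)
    map0 <- stats::rnorm(n_subjects, map_mean, map_sd)
    bp <- purrr::map(seq_len(n_subjects), function(s) {
      phases <- c(rep("pre_baseline", 8), "training", rep("scenario", 5),
                  rep("post_baseline", 6))
      elev <- ifelse(phases %in% c("scenario", "training"),
                     delta * rel_viv[s], 0)
      map <- map0[s] + elev + stats::rnorm(20, 0, noise_sd)
      pp <- abs(stats::rnorm(20, pp_mean, pp_sd)) + 1
      dom_order <- sample(doms)
      tibble::tibble(
        subject_id = sprintf("s%02d", s),
        phase = phases,
        scenario_domain = replace(rep(NA_character_, 20),
                                  phases == "scenario", dom_order),
        systolic = map + (2 / 3) * pp,
        diastolic = map - (1 / 3) * pp
      )
    }) |> purrr::list_rbind()
    if (any(bp$diastolic <= 0)) {
      stop("config error: generated diastolic pressure <= 0; lower delta or noise",
           call. = FALSE)
    }
    # --- PANAS ---
    # realized visualization response in within-subject z units (same
    # reduction as the analysis applies: drop pre 1-3, training, post 1)
    vis_z <- vapply(split(bp, bp$subject_id), function(sub) {
      map <- (2 / 3) * sub$diastolic + (1 / 3) * sub$systolic
      z <- as.numeric(scale(map[setdiff(1:20, c(1:3, 9, 15))]))
      mean(z[6:10])
    }, 1.0)
    vis_z <- vis_z[sprintf("s%02d", seq_len(n_subjects))]
    pa_pre <- clip(round(stats::rnorm(n_subjects, 32, 5)), 10, 50)
    na_pre <- clip(round(stats::rnorm(n_subjects, 16, 4)), 10, 50)
    panas <- tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(n_subjects)),
      pa_pre = pa_pre,
      # subjects with a stronger imagery-driven pressor response lose more
      # positive affect
      pa_post = clip(round(pa_pre + pa_shift -
                             pa_bp_coupling * (vis_z - mean(vis_z)) +
                             stats::rnorm(n_subjects, 0, panas_sd)), 10, 50),
      na_pre = na_pre,
      na_post = clip(round(na_pre + na_shift +
                             stats::rnorm(n_subjects, 0, panas_sd)), 10, 50)
    )
    list(trials = trials, bp = bp, panas = panas)
  })
}

#' Generate Study-3-style moderated risk ratings (no EEG signals)
#'
#' The behavioural half of the Study-3 generator: a per-subject imagery
#' ability factor `g > 0` (the true IAI) and a trial table following the
#' moderated model
#' `y = b0 + b1 risk + b2 g + b3 risk * g + effects + noise`.
#' Used directly for moderation calibration simulations; [gen_study3()]
#' builds EEG signals on top of it.
#'
#' @param n_subjects Number of subjects (default 16 analyzable).
#' @param n_scenarios Risky scenarios (default 10, two per domain).
#' @param b0,b1,b2,b3 True moderation coefficients.
#' @param g_mean,g_sd,g_range Imagery-ability distribution (truncated
#'   normal; defaults span the observed IAI range of roughly 0.97-1.19).
#' @param rp_mean,rp_sd Risk-perception distribution (truncated to 1-10).
#' @param sd_subject,sd_item,sd_resid Random-effect and residual SDs.
#' @param seed Integer seed (mandatory).
#' @return A list: `trials` tibble (with `risk_perception`, `risk_taking`,
#'   `iai_true`) and `g` (named per-subject ability vector).
#' @export
gen_study3_ratings <- function(n_subjects = 16, n_scenarios = 10,
                               b0 = 31.5, b1 = -3.5, b2 = -25, b3 = 3.0,
                               g_mean = 1.06, g_sd = 0.06,
                               g_range = c(0.95, 1.25),
                               rp_mean = 6, rp_sd = 2,
                               sd_subject = 0.3, sd_item = 0.1,
                               sd_resid = 0.4, seed) {
  if (missing(seed)) stop("seed is mandatory for gen_study3_ratings",
                          call. = FALSE)
  with_seed(seed, {
    doms <- rep(risk_domains(), length.out = n_scenarios)
    g_fac <- rtruncnorm(n_subjects, g_mean, g_sd, g_range[1], g_range[2])
    names(g_fac) <- sprintf("s%02d", seq_len(n_subjects))
    u <- stats::rnorm(n_subjects, 0, sd_subject)
    w <- stats::rnorm(length(unique(doms)), 0, sd_item)
    names(w) <- unique(doms)
    grid <- tidyr::expand_grid(s = seq_len(n_subjects),
                               i = seq_len(n_scenarios))
    n <- nrow(grid)
    rp <- rtruncnorm(n, rp_mean, rp_sd, 1, 10)
    gg <- g_fac[grid$s]
    y <- b0 + b1 * rp + b2 * gg + b3 * rp * gg +
      u[grid$s] + w[doms[grid$i]] + stats::rnorm(n, 0, sd_resid)
    trials <- tibble::tibble(
      subject_id = sprintf("s%02d", grid$s),
      item_id = sprintf("scen%02d", grid$i),
      domain = doms[grid$i],
      risk_perception = rp, risk_taking = unname(y),
      iai_true = unname(gg)
    )
    list(trials = trials, g = g_fac)
  })
}

# build the sample intervals of the Study-3 session layout
study3_events <- function(fs, baseline_sec, listening_sec, visualization_sec,
                          n_scenarios, doms) {
  segs <- list()
  cursor <- 0L
  add <- function(kind, scen, dom, dur) {
    n <- as.integer(round(dur * fs))
    segs[[length(segs) + 1]] <<- tibble::tibble(
      segment_kind = kind, scenario_id = scen, domain = dom,
      start_sample = cursor, end_sample = cursor + n)
    cursor <<- cursor + n
  }
  add("baseline", "weather1", NA_character_, baseline_sec)
  for (i in seq_len(n_scenarios)) {
    scen <- sprintf("scen%02d", i)
    add("listening", scen, doms[i], listening_sec)
    add("visualization", scen, doms[i], visualization_sec)
  }
  add("baseline", "weather2", NA_character_, baseline_sec)
  purrr::list_rbind(segs)
}

#' Generate a Study-3-style bundle: EEG recordings plus risk ratings
#'
#' For each subject, draws an imagery-ability factor `g > 0` and synthesizes
#' a six-channel 200 Hz recording: every segment carries a 10 Hz alpha
#' sinusoid (baseline amplitude `alpha_amp`) plus white broadband noise;
#' during risky-scenario visualization the alpha amplitude on the
#' parieto-occipital channels (O1, O2, P3, P4) is attenuated to
#' `alpha_amp / sqrt(g)` — so the alpha-power ratio (the IAI) equals `g`
#' exactly in the noiseless case — while the frontal control channels stay
#' unmodulated. Artifact epochs (a large square pulse) are injected at the
#' configured rate on the 2-second epoch grid. The two baseline (weather)
#' segments are four times the length of a risky-scenario phase. Ratings
#' come from [gen_study3_ratings()] with `iai_true = g`.
#'
#' @inheritParams gen_study3_ratings
#' @param alpha_amp Baseline alpha amplitude, microvolts.
#' @param noise_sd Broadband white-noise SD, microvolts.
#' @param artifact_rate Fraction of epochs carrying an injected artifact
#'   (default 0.05, the reported rejection rate).
#' @param listening_attenuation Alpha attenuation factor during listening
#'   (default 1 = none).
#' @param sampling_rate Hz (canonical 200).
#' @param visualization_sec Risky-scenario visualization duration, seconds
#'   (default 30; baselines are four times as long).
#' @param listening_sec Listening duration, seconds.
#' @return A list: `recordings` (list of [eeg_recording()]), `trials`,
#'   `g` (true per-subject ability / IAI).
#' @export
gen_study3 <- function(n_subjects = 16, n_scenarios = 10,
                       b0 = 31.5, b1 = -3.5, b2 = -25, b3 = 3.0,
                       g_mean = 1.06, g_sd = 0.06, g_range = c(0.95, 1.25),
                       alpha_amp = 10, noise_sd = 1, artifact_rate = 0.05,
                       listening_attenuation = 1,
                       sampling_rate = 200, visualization_sec = 30,
                       listening_sec = 30, seed) {
  if (missing(seed)) stop("seed is mandatory for gen_study3", call. = FALSE)
  stopifnot(artifact_rate >= 0, artifact_rate < 1, alpha_amp > 0)
  ratings <- gen_study3_ratings(
    n_subjects = n_subjects, n_scenarios = n_scenarios,
    b0 = b0, b1 = b1, b2 = b2, b3 = b3,
    g_mean = g_mean, g_sd = g_sd, g_range = g_range, seed = seed)
  g_fac <- ratings$g
  doms <- rep(risk_domains(), length.out = n_scenarios)
  fs <- sampling_rate
  baseline_sec <- 4 * visualization_sec
  channels <- c("Fp1", "Fp2", "P3", "P4", "O1", "O2")
  po <- c("P3", "P4", "O1", "O2")
  events <- study3_events(fs, baseline_sec, listening_sec, visualization_sec,
                          n_scenarios, doms)
  n_samples <- max(events$end_sample)
  recordings <- with_seed(seed + 1L, purrr::map(seq_len(n_subjects), function(s) {
    g <- g_fac[s]
    sig <- matrix(0, n_samples, length(channels),
                  dimnames = list(NULL, channels))
    for (r in seq_len(nrow(events))) {
      ev <- events[r, ]
      idx <- (ev$start_sample + 1):ev$end_sample
      tt <- (idx - 1) / fs
      phase0 <- stats::runif(1, 0, 2 * pi)
      carrier <- sin(2 * pi * 10 * tt + phase0)
      for (ch in channels) {
        amp <- alpha_amp
        if (ch %in% po) {
          if (ev$segment_kind == "visualization") amp <- alpha_amp / sqrt(g)
          if (ev$segment_kind == "listening")
            amp <- alpha_amp / sqrt(listening_attenuation)
        }
        noise <- if (noise_sd > 0) stats::rnorm(length(idx), 0, noise_sd)
          else 0
        sig[idx, ch] <- amp * carrier + noise
      }
      # inject artifact epochs on the 2-s grid, all channels at once
      n_ep <- length(idx) %/% (2 * fs)
      if (artifact_rate > 0 && n_ep > 0) {
        hit <- which(stats::runif(n_ep) < artifact_rate)
        for (e in hit) {
          at <- ev$start_sample + (e - 1) * 2 * fs + seq_len(20)
          sig[at, ] <- sig[at, ] + 150
        }
      }
    }
    eeg_recording(sprintf("s%02d", s), sig, channels, events, fs)
  }))
  list(recordings = recordings, trials = ratings$trials, g = g_fac)
}
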