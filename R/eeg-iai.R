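#' Zero-phase band-pass filter for EEG amplitude series
#'
#' Band-passes a single-channel amplitude series between `low` and `high` Hz
#' with zero phase shift (forward-backward application). The default design is
#' a Butterworth cascade: an order-2 high-pass at `low` followed by an
#' order-4 low-pass at `high`, each applied with `signal::filtfilt()`. A
#' linear-phase FIR design (windowed sinc, applied zero-phase) is available
#' via `design = "fir"`; note a 0.1 Hz edge needs a very long FIR kernel.
#'
#' @param x Numeric amplitude series (microvolts).
#' @param sampling_rate Sampling rate in Hz; must exceed `2 * high`.
#' @param low High-pass cutoff in Hz (default 0.1).
#' @param high Low-pass cutoff in Hz (default 35).
#' @param design `"butterworth"` (default) or `"fir"`.
#' @return Filtered series, same length as the input.
#' @export
bandpass_filter <- function(x, sampling_rate, low = 0.1, high = 35,
                            design = c("butterworth", "fir")) {
  design <- match.arg(design)
  nyq <- sampling_rate / 2
  if (high >= nyq) {
    stop("parameter error: high cutoff must be below the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  }
  if (low <= 0 || low >= high) {
    stop("parameter error: need 0 < low < high", call. = FALSE)
  }
  if (design == "butterworth") {
    hp <- signal::butter(2, low / nyq, type = "high")
    lp <- signal::butter(4, high / nyq, type = "low")
    y <- signal::filtfilt(hp, x)
    y <- signal::filtfilt(lp, y)
  } else {
    # windowed-sinc band-pass, odd length covering ~3 cycles of the low edge
    ntaps <- min(length(x) - 1, 2 * ceiling(3 * sampling_rate / low / 2) + 1)
    fir <- signal::fir1(ntaps - 1, c(low, high) / nyq, type = "pass")
    y <- signal::filtfilt(fir, 1, x)
  }
  as.numeric(y)
}

#' Cut a segment into fixed 2-second epochs and reject artifacts
#'
#' Splits the samples of one event segment into consecutive non-overlapping
#' epochs of `epoch_sec` seconds (partial trailing windows are discarded) and
#' marks an epoch as an artifact when its amplitude exceeds the threshold:
#' by default `max(|x|) > threshold` anywhere in the epoch; a peak-to-peak
#' criterion is available via `criterion`.
#'
#' @param x Amplitude series of the segment (microvolts).
#' @param sampling_rate Sampling rate in Hz.
#' @param threshold Artifact threshold in microvolts (default 70).
#' @param epoch_sec Epoch length in seconds (default 2).
#' @param criterion `"absolute"` (default) or `"peak_to_peak"`.
#' @return A list of class `"epoch_set"`: `epochs` (matrix, one row per
#'   epoch), `kept` (logical mask), `rejection_fraction`, `epoch_length`,
#'   `sampling_rate`.
#' @export
epoch_and_reject <- function(x, sampling_rate, threshold = 70, epoch_sec = 2,
                             criterion = c("absolute", "peak_to_peak")) {
  criterion <- match.arg(criterion)
  len <- as.integer(round(epoch_sec * sampling_rate))
  n_ep <- length(x) %/% len
  if (n_ep < 1) {
    stop("segment error: segment shorter than one epoch (", len, " samples)",
         call. = FALSE)
  }
  epochs <- matrix(x[seq_len(n_ep * len)], nrow = n_ep, ncol = len,
                   byrow = TRUE)
  stat <- switch(criterion,
    absolute = apply(abs(epochs), 1, max),
    peak_to_peak = apply(epochs, 1, function(e) diff(range(e)))
  )
  kept <- stat <= threshold
  structure(list(epochs = epochs, kept = kept,
                 rejection_fraction = mean(!kept),
                 epoch_length = len, sampling_rate = sampling_rate),
            class = "epoch_set")
}

# one-sided periodogram PSD of one epoch, rectangular window.
# Density scaling: P(f_k) = 2 |X_k|^2 / (fs * N)  (uV^2/Hz), so that
# sum(P) * df equals the mean squared amplitude (Parseval).
periodogram_psd <- function(e, sampling_rate) {
  n <- length(e)
  xf <- stats::fft(e)
  half <- seq_len(floor(n / 2) + 1)
  p <- (Mod(xf[half])^2) / (sampling_rate * n)
  # double all bins except DC and (for even n) Nyquist
  dbl <- rep(2, length(half)); dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(half)] <- 1
  list(freq = (half - 1) * sampling_rate / n, psd = p * dbl)
}

#' Alpha-band power density of an epoch set
#'
#' Per kept epoch, computes the rectangular-window periodogram power spectral
#' density and averages the density over the frequency bins inside the alpha
#' band (8-13 Hz inclusive); the epoch values are then averaged across kept
#' epochs. Units are microvolts squared per Hz.
#'
#' @param epoch_set An [epoch_and_reject()] result.
#' @param band Length-2 numeric band limits in Hz (default `c(8, 13)`).
#' @return Mean alpha power density (single number).
#' @export
alpha_power <- function(epoch_set, band = c(8, 13)) {
  kept <- which(epoch_set$kept)
  if (length(kept) == 0) {
    stop("rejection error: all ", length(epoch_set$kept),
         " epochs rejected; no data for power estimate", call. = FALSE)
  }
  fs <- epoch_set$sampling_rate
  vals <- vapply(kept, function(i) {
    pg <- periodogram_psd(epoch_set$epochs[i, ], fs)
    inband <- pg$freq >= band[1] & pg$freq <= band[2]
    mean(pg$psd[inband])
  }, 1.0)
  mean(vals)
}

#' Imagery Alpha Index from baseline and task alpha power
#'
#' IAI = mean of the two baseline alpha powers divided by the mean alpha
#' power of the task (risky-scenario) segments of one risk domain. Values
#' above 1 indicate task-related alpha attenuation, i.e. stronger
#' imagery-related cortical activation relative to rest.
#'
#' @param baseline_power Numeric vector of baseline segment powers (the two
#'   baselines are weighted equally).
#' @param task_power Numeric vector of task segment powers (the scenarios of
#'   one domain are averaged).
#' @return The IAI (dimensionless positive ratio).
#' @export
compute_iai <- function(baseline_power, task_power) {
  if (length(baseline_power) == 0 || length(task_power) == 0 ||
      any(!is.finite(baseline_power)) || any(!is.finite(task_power)) ||
      any(baseline_power <= 0) || any(task_power <= 0)) {
    stop("degenerate-power error: all powers must be finite and positive",
         call. = FALSE)
  }
  mean(baseline_power) / mean(task_power)
}

#' Full IAI table for one EEG recording
#'
#' Runs the preprocessing chain on every channel of a recording: zero-phase
#' band-pass (0.1-35 Hz), 2-second epoching with 70 uV artifact rejection,
#' periodogram alpha power (8-13 Hz), then the Imagery Alpha Index per
#' electrode, risk domain, and phase. Baseline alpha uses all epochs of each
#' baseline segment, the two baseline powers weighted equally; the task power
#' of a domain averages its scenarios' segment powers.
#'
#' @param recording An [eeg_recording()] object.
#' @param low,high Band-pass edges in Hz.
#' @param threshold Artifact threshold in microvolts.
#' @param band Alpha band limits in Hz.
#' @param filter_design Passed to [bandpass_filter()].
#' @param filter Logical; set `FALSE` to skip filtering (e.g. for synthetic
#'   narrowband signals).
#' @return A tibble (the IAI table): `subject_id`, `electrode`, `domain`,
#'   `phase` (`listening`/`visualization`), `iai`, plus the overall epoch
#'   `rejection_fraction` as an attribute.
#' @export
eeg_iai_table <- function(recording, low = 0.1, high = 35, threshold = 70,
                          band = c(8, 13),
                          filter_design = c("butterworth", "fir"),
                          filter = TRUE) {
  stopifnot(inherits(recording, "eeg_recording"))
  filter_design <- match.arg(filter_design)
  fs <- recording$sampling_rate
  ev <- recording$events
  rej_n <- 0L; tot_n <- 0L

  seg_power <- function(sig, e) {
    es <- epoch_and_reject(sig[(e$start_sample + 1):e$end_sample], fs,
                           threshold = threshold)
    rej_n <<- rej_n + sum(!es$kept); tot_n <<- tot_n + length(es$kept)
    if (!any(es$kept)) return(NA_real_)
    alpha_power(es, band = band)
  }

  rows <- purrr::map(recording$channels, function(ch) {
    sig <- recording$signal[, ch]
    if (filter) sig <- bandpass_filter(sig, fs, low, high, filter_design)
    base_ev <- ev[ev$segment_kind == "baseline", ]
    if (nrow(base_ev) == 0) {
      stop("integrity error: recording has no baseline segments", call. = FALSE)
    }
    base_p <- vapply(seq_len(nrow(base_ev)),
                     function(i) seg_power(sig, base_ev[i, ]), 1.0)
    task_ev <- ev[ev$segment_kind %in% c("listening", "visualization"), ]
    purrr::map(split(task_ev, list(task_ev$domain, task_ev$segment_kind),
                     drop = TRUE), function(grp) {
      tp <- vapply(seq_len(nrow(grp)), function(i) seg_power(sig, grp[i, ]), 1.0)
      tibble::tibble(
        subject_id = recording$subject_id, electrode = ch,
        domain = grp$domain[1], phase = grp$segment_kind[1],
        iai = compute_iai(base_p[!is.na(base_p)], tp[!is.na(tp)])
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  attr(rows, "rejection_fraction") <- if (tot_n > 0) rej_n / tot_n else NA_real_
  rows
}

#' Aggregate the IAI over imagery-related electrodes
#'
#' Arithmetic mean of the visualization-phase IAI over the parieto-occipital
#' electrodes associated with mental imagery (O1, O2, P3, P4 by default),
#' per subject and risk domain.
#'
#' @param iai_table An IAI table (from [eeg_iai_table()], possibly
#'   row-bound over subjects).
#' @param electrodes Electrodes to average over; all must be present.
#' @param phase Phase to aggregate (default `"visualization"`).
#' @return A tibble: `subject_id`, `domain`, `iai`.
#' @export
aggregate_iai <- function(iai_table, electrodes = c("O1", "O2", "P3", "P4"),
                          phase = "visualization") {
  iai_table <- tibble::as_tibble(iai_table)
  missing_el <- setdiff(electrodes, unique(iai_table$electrode))
  if (length(missing_el)) {
    stop("coverage error: electrode(s) not present: ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  iai_table |>
    dplyr::filter(.data$phase == !!phase,
                  .data$electrode %in% electrodes) |>
    dplyr::group_by(.data$subject_id, .data$domain) |>
    dplyr::summarise(iai = mean(.data$iai), .groups = "drop")
}
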