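#' Gaussian-kernel firing-rate estimate
#'
#' Convolves a spike train with a unit-area Gaussian kernel (default
#' sigma 25 ms) to give an instantaneous firing rate in Hz. The integral
#' of the returned trace equals the spike count.
#'
#' @param spike_times_ms Sorted spike times (ms); may be empty.
#' @param sigma_ms Kernel standard deviation (ms, > 0).
#' @param dt_ms Output sampling step (ms).
#' @param t_range Length-2 vector giving the output window (ms); defaults
#'   to the spike range padded by 4 sigma.
#' @return A data frame with columns `time_ms`, `rate_hz`.
#' @examples
#' r <- smooth_firing_rate(100, sigma_ms = 25, dt_ms = 1)
#' max(r$rate_hz)  # 15.96 Hz: 1 / (0.025 s * sqrt(2 pi))
#' @export
smooth_firing_rate <- function(spike_times_ms, sigma_ms = 25, dt_ms = 1,
                               t_range = NULL) {
  if (sigma_ms <= 0) stop("sigma_ms must be positive")
  if (length(spike_times_ms) && is.unsorted(spike_times_ms))
    stop("spike times must be sorted")
  if (is.null(t_range)) {
    t_range <- if (length(spike_times_ms))
      range(spike_times_ms) + c(-4, 4) * sigma_ms else c(0, 1)
  }
  tt <- seq(t_range[1], t_range[2], by = dt_ms)
  rate <- numeric(length(tt))
  for (ts in spike_times_ms)
    rate <- rate + stats::dnorm(tt, mean = ts, sd = sigma_ms)
  # dnorm is per-ms density; x1000 converts spikes/ms to Hz
  data.frame(time_ms = tt, rate_hz = rate * 1000)
}

#' Build a direction-response series
#'
#' @param direction_deg Stimulus directions (degrees).
#' @param metric Non-negative responses (spike counts, peak rates, peak
#'   amplitudes or clamped E/I offsets), one per row.
#' @param trial Optional trial labels.
#' @param metric_kind One of `"spike_count"`, `"peak_rate"`,
#'   `"peak_amplitude"`, `"ei_offset_ms"`.
#' @return A `direction_series` data frame.
#' @export
direction_series <- function(direction_deg, metric, trial = 1L,
                             metric_kind = c("spike_count", "peak_rate",
                                             "peak_amplitude",
                                             "ei_offset_ms")) {
  metric_kind <- match.arg(metric_kind)
  if (any(metric < 0)) stop("responses must be non-negative (clamp upstream)")
  if (length(unique(direction_deg %% 360)) < 2)
    stop("need responses in at least two distinct directions")
  out <- data.frame(direction_deg = direction_deg, metric = metric,
                    trial = trial)
  attr(out, "metric_kind") <- metric_kind
  class(out) <- c("direction_series", class(out))
  out
}

vector_sum_dsi <- function(direction_deg, metric) {
  tot <- sum(metric)
  if (tot <= 0) return(list(dsi = NA_real_, angle = NA_real_))
  th <- direction_deg * pi / 180
  re <- sum(metric * cos(th)); im <- sum(metric * sin(th))
  list(dsi = sqrt(re^2 + im^2) / tot,
       angle = (atan2(im, re) * 180 / pi) %% 360)
}

#' Direction selectivity index by normalised vector sum
#'
#' Computes `DSI = |sum_i r_i v_i| / sum_i r_i`, where `v_i` is the unit
#' vector of stimulus direction i and `r_i` the response magnitude (e.g.
#' spike count). DSI is 0 for a perfectly symmetrical response and 1 when
#' all response is confined to a single direction; the preferred angle is
#' the direction of the resultant. When the series carries multiple
#' trials, the headline DSI/angle are computed on trial-summed responses
#' and per-trial values plus across-trial standard deviations are
#' reported alongside.
#'
#' @param series A [direction_series()] data frame (or any data frame with
#'   `direction_deg`, `metric`, and optionally `trial` columns).
#' @return A `tuning_result`: list with `dsi`, `preferred_angle_deg`,
#'   `per_trial` (data frame), `sd_dsi`, `sd_angle_deg`, `n_trials`,
#'   `metric_kind`.
#' @examples
#' s <- direction_series(seq(0, 315, by = 45), c(5, 0, 0, 0, 0, 0, 0, 0))
#' direction_selectivity_index(s)$dsi  # 1
#' @export
direction_selectivity_index <- function(series) {
  stopifnot(all(c("direction_deg", "metric") %in% names(series)))
  if (any(series$metric < 0)) stop("responses must be non-negative")
  if (sum(series$metric) <= 0)
    return(structure(list(dsi = NA_real_, preferred_angle_deg = NA_real_,
                          per_trial = NULL, sd_dsi = NA_real_,
                          sd_angle_deg = NA_real_, n_trials = 0L,
                          no_response = TRUE,
                          metric_kind = attr(series, "metric_kind")),
                     class = "tuning_result"))
  pooled <- stats::aggregate(metric ~ direction_deg, data = series, FUN = sum)
  head_res <- vector_sum_dsi(pooled$direction_deg, pooled$metric)

  per_trial <- NULL; sd_dsi <- NA_real_; sd_angle <- NA_real_
  trials <- if ("trial" %in% names(series)) unique(series$trial) else 1L
  if (length(trials) >= 2) {
    per_trial <- do.call(rbind, lapply(trials, function(tr) {
      sub <- series[series$trial == tr, ]
      r <- vector_sum_dsi(sub$direction_deg, sub$metric)
      data.frame(trial = tr, dsi = r$dsi, preferred_angle_deg = r$angle)
    }))
    ok <- stats::complete.cases(per_trial)
    if (sum(ok) >= 2) {
      sd_dsi <- stats::sd(per_trial$dsi[ok])
      sd_angle <- circular_sd_deg(per_trial$preferred_angle_deg[ok])
    }
  }
  structure(list(dsi = head_res$dsi, preferred_angle_deg = head_res$angle,
                 per_trial = per_trial, sd_dsi = sd_dsi,
                 sd_angle_deg = sd_angle, n_trials = length(trials),
                 no_response = FALSE,
                 metric_kind = attr(series, "metric_kind")),
            class = "tuning_result")
}

# SD of angles (degrees) about their circular mean, via unwrapped deviations
circular_sd_deg <- function(angles_deg) {
  th <- angles_deg * pi / 180
  mu <- atan2(mean(sin(th)), mean(cos(th))) * 180 / pi
  dev <- (angles_deg - mu + 180) %% 360 - 180
  sqrt(sum(dev^2) / (length(dev) - 1))
}

#' @export
print.tuning_result <- function(x, ...) {
  if (isTRUE(x$no_response)) {
    cat("<tuning_result> no response\n"); return(invisible(x))
  }
  cat(sprintf("<tuning_result> DSI = %.3f, preferred angle = %.1f deg (%d trial%s)\n",
              x$dsi, x$preferred_angle_deg, x$n_trials,
              if (x$n_trials == 1) "" else "s"))
  if (!is.na(x$sd_dsi))
    cat(sprintf("  across-trial SD: DSI %.3f, angle %.1f deg\n",
                x$sd_dsi, x$sd_angle_deg))
  invisible(x)
}

#' Synaptic-current onset latency by 20-80% rise fit
#'
#' Estimates response onset the way EPSC/IPSC latencies are measured:
#' the 20-80% rise of the current (amplitude measured baseline to first
#' peak) is fit by a least-squares straight line through all samples in
#' the band, and the onset is the time at which the extrapolated line
#' crosses the baseline level.
#'
#' @param trace A `recording` (trace mode) or data frame with `time_ms`
#'   and value column.
#' @param polarity `"auto"`, `"positive"` (outward, e.g. IPSC at 0 mV) or
#'   `"negative"` (inward, e.g. EPSC at the inhibitory reversal); the trace
#'   is polarity-normalised before fitting.
#' @param baseline_window_ms Length of the initial window used for the
#'   baseline mean and noise SD (default 200 ms, truncated to the trace).
#' @param detect_sd Peak must exceed baseline by this many baseline SDs
#'   (default 5) to count as a response.
#' @param min_amplitude Absolute amplitude floor (same units as trace) for
#'   response detection; with noise-free traces any positive deflection
#'   qualifies.
#' @param smooth_ms Width (ms) of a Gaussian pre-smoother used only when
#'   baseline noise is present, to stabilise first-peak identification;
#'   `0` disables.
#' @return An `onset_estimate` list: `onset_ms`, `t20_ms`, `t80_ms`,
#'   `slope`, `amplitude`, `baseline`, `no_response`.
#' @export
onset_latency <- function(trace, polarity = c("auto", "positive", "negative"),
                          baseline_window_ms = 200, detect_sd = 5,
                          min_amplitude = 0, smooth_ms = 0.5) {
  polarity <- match.arg(polarity)
  if (inherits(trace, "recording")) {
    tt <- trace$time_ms; y <- trace$values
  } else {
    tt <- trace$time_ms; y <- trace[[setdiff(names(trace), "time_ms")[1]]]
  }
  no_resp <- list(onset_ms = NA_real_, t20_ms = NA_real_, t80_ms = NA_real_,
                  slope = NA_real_, amplitude = NA_real_,
                  baseline = NA_real_, no_response = TRUE)
  class(no_resp) <- "onset_estimate"
  if (length(tt) < 3) return(no_resp)
  dt <- tt[2] - tt[1]

  bl_idx <- which(tt <= tt[1] + baseline_window_ms)
  if (length(bl_idx) < 2) bl_idx <- seq_len(min(20L, length(y)))
  bl <- mean(y[bl_idx]); bl_sd <- stats::sd(y[bl_idx])

  yc <- y - bl
  if (polarity == "auto")
    polarity <- if (abs(min(yc)) > abs(max(yc))) "negative" else "positive"
  if (polarity == "negative") yc <- -yc

  # light smoothing for peak localisation when the baseline is noisy
  ys <- yc
  if (bl_sd > 0 && smooth_ms > 0) {
    half <- max(1L, ceiling(2 * smooth_ms / dt))
    k <- stats::dnorm(seq(-half, half) * dt, sd = smooth_ms)
    k <- k / sum(k)
    ys <- as.numeric(stats::filter(yc, k, sides = 2))
    ys[is.na(ys)] <- yc[is.na(ys)]
    bl_sd_s <- stats::sd(ys[bl_idx])
  } else bl_sd_s <- bl_sd

  thresh <- max(detect_sd * bl_sd_s, min_amplitude, 0)
  # response must clear the threshold on both the raw and smoothed trace
  if (max(ys) <= thresh || max(yc) <= max(detect_sd * bl_sd, min_amplitude) ||
      max(ys) <= 0) return(no_resp)

  # first local maximum above threshold (first-peak rule); candidates must
  # also reach half the global deflection so stray noise maxima on the
  # baseline cannot anchor the fit
  floor_amp <- max(thresh, 0.5 * max(ys))
  above <- which(ys > floor_amp)
  peak_idx <- NA_integer_
  for (i in above) {
    if (i > 1 && i < length(ys) && ys[i] >= ys[i - 1] && ys[i] >= ys[i + 1]) {
      peak_idx <- i; break
    }
  }
  if (is.na(peak_idx)) peak_idx <- which.max(ys)
  amp <- ys[peak_idx]

  lev20 <- 0.2 * amp; lev80 <- 0.8 * amp
  # crossings anchored to the rise: walk back from the peak to the last
  # samples below each level, so baseline noise crossings are ignored
  below20 <- which(ys[seq_len(peak_idx)] < lev20)
  below80 <- which(ys[seq_len(peak_idx)] < lev80)
  i20 <- if (length(below20)) max(below20) + 1L else 1L
  i80 <- if (length(below80)) max(below80) + 1L else 1L
  if (i80 < i20) return(no_resp)
  t20 <- cross_time(tt, ys, i20, lev20)
  t80 <- cross_time(tt, ys, i80, lev80)
  band <- which(tt >= t20 & tt <= t80)
  if (length(band) < 2) band <- unique(c(max(1L, i20 - 1L), i20, i80))
  fit <- stats::lm.fit(cbind(1, tt[band]), ys[band])
  b0 <- fit$coefficients[1]; b1 <- fit$coefficients[2]
  if (!is.finite(b1) || b1 <= 0) return(no_resp)
  onset <- -b0 / b1   # line crosses the (baseline-subtracted) zero level
  structure(list(onset_ms = unname(onset), t20_ms = t20, t80_ms = t80,
                 slope = unname(b1), amplitude = amp, baseline = bl,
                 no_response = FALSE),
            class = "onset_estimate")
}

cross_time <- function(tt, ys, i, level) {
  if (i == 1) return(tt[1])
  y0 <- ys[i - 1]; y1 <- ys[i]
  if (y1 == y0) return(tt[i])
  tt[i - 1] + (level - y0) / (y1 - y0) * (tt[i] - tt[i - 1])
}

#' @export
print.onset_estimate <- function(x, ...) {
  if (x$no_response) cat("<onset_estimate> no response\n")
  else cat(sprintf("<onset_estimate> onset %.2f ms (20%%/80%% at %.2f/%.2f ms)\n",
                   x$onset_ms, x$t20_ms, x$t80_ms))
  invisible(x)
}

#' Excitation/inhibition temporal offset
#'
#' Estimates the onsets of an EPSC and an IPSC with the 20-80% rise fit
#' and returns `offset_ms = inhibition_onset - excitation_onset`: positive
#' when excitation leads inhibition. The clamped variant (negative offsets
#' set to 0) is the quantity used as a DSI metric.
#'
#' @param epsc,ipsc `recording`s of the excitatory and inhibitory currents
#'   on a shared time base (EPSC held at the inhibitory reversal, inward
#'   negative; IPSC held at 0 mV, outward positive).
#' @param ... Passed to [onset_latency()].
#' @return An `offset_estimate` list: `excitation_onset_ms`,
#'   `inhibition_onset_ms`, `offset_ms`, `clamped_offset_ms`, and the two
#'   onset diagnostics.
#' @export
ei_temporal_offset <- function(epsc, ipsc, ...) {
  e <- onset_latency(epsc, polarity = "auto", ...)
  i <- onset_latency(ipsc, polarity = "auto", ...)
  off <- if (e$no_response || i$no_response) NA_real_
  else i$onset_ms - e$onset_ms
  structure(list(excitation_onset_ms = e$onset_ms,
                 inhibition_onset_ms = i$onset_ms,
                 offset_ms = off,
                 clamped_offset_ms = if (is.na(off)) NA_real_ else max(off, 0),
                 excitation_fit = e, inhibition_fit = i),
            class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf("<offset_estimate> E onset %.2f ms, I onset %.2f ms, offset %+.2f ms (clamped %.2f)\n",
              x$excitation_onset_ms, x$inhibition_onset_ms, x$offset_ms,
              x$clamped_offset_ms))
  invisible(x)
}

#' Convert a temporal offset to a spatial offset
#'
#' `offset_um = offset_ms * velocity / 1000`; the algebraic inverse of the
#' schedule's division of spatial offsets by stimulus velocity.
#'
#' @param offset_ms Temporal offset (ms).
#' @param velocity_um_s Stimulus velocity (um/s, > 0).
#' @return Spatial offset (um).
#' @examples
#' temporal_to_spatial_offset(50, 1000)  # 50 um
#' @export
temporal_to_spatial_offset <- function(offset_ms, velocity_um_s) {
  if (any(velocity_um_s <= 0)) stop("velocity must be positive")
  offset_ms * velocity_um_s / 1000
}

#' Phase-resolved direction tuning
#'
#' Splits each trial's spike train into an early window (the `early_span_ms`
#' before the stimulus enters the glutamate receptive field) and a peak
#' window (`peak_span_ms` centred on the preferred-direction peak of the
#' trial-averaged sigma = 25 ms smoothed rate), and computes DSI, preferred
#' angle and across-trial variability for each window.
#'
#' @param spikes A data frame with columns `direction_deg`, `trial`, and a
#'   list-column `spike_times_ms`, or a list of spike-time `recording`s
#'   whose metadata carry `direction_deg` and `trial`.
#' @param glut_rf_entry_ms Time (ms) the stimulus enters the glutamate
#'   receptive field, used to align trials (one value, or one per
#'   direction in direction order).
#' @param early_span_ms,peak_span_ms Window lengths (ms, default 50).
#' @param sigma_ms Rate-smoothing kernel SD for locating the peak.
#' @return List with `early` and `peak` [`tuning_result`]s plus
#'   `peak_window_ms` (the window actually used).
#' @export
phase_tuning <- function(spikes, glut_rf_entry_ms, early_span_ms = 50,
                         peak_span_ms = 50, sigma_ms = 25) {
  df <- as_spike_table(spikes)
  dirs <- sort(unique(df$direction_deg))
  entry <- rep_len(glut_rf_entry_ms, length(dirs))
  names(entry) <- as.character(dirs)

  # preferred direction from total counts, then locate the rate peak there
  tot <- vapply(dirs, function(d)
    sum(lengths(df$spike_times_ms[df$direction_deg == d])), numeric(1))
  if (sum(tot) < 1)
    stop("no spikes in any direction; cannot resolve phases")
  pref_dir <- dirs[nearest_direction(vector_sum_dsi(dirs, tot)$angle, dirs)]
  pref_spikes <- sort(unlist(df$spike_times_ms[df$direction_deg == pref_dir]))
  n_tr <- length(unique(df$trial))
  rate <- smooth_firing_rate(pref_spikes, sigma_ms = sigma_ms, dt_ms = 1)
  peak_t <- rate$time_ms[which.max(rate$rate_hz)]
  peak_win <- c(peak_t - peak_span_ms / 2, peak_t + peak_span_ms / 2)

  count_in <- function(ts, lo, hi) sum(ts >= lo & ts < hi)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    en <- entry[as.character(df$direction_deg[i])]
    data.frame(direction_deg = df$direction_deg[i], trial = df$trial[i],
               early = count_in(df$spike_times_ms[[i]], en - early_span_ms, en),
               peak = count_in(df$spike_times_ms[[i]], peak_win[1], peak_win[2]))
  })
  tab <- do.call(rbind, rows)

  mk <- function(col) {
    s <- direction_series(tab$direction_deg, tab[[col]], trial = tab$trial,
                          metric_kind = "spike_count")
    direction_selectivity_index(s)
  }
  list(early = mk("early"), peak = mk("peak"),
       peak_window_ms = peak_win, preferred_direction_used = pref_dir,
       counts = tab)
}

nearest_direction <- function(angle, dirs) {
  which.min(abs((dirs - angle + 180) %% 360 - 180))
}

as_spike_table <- function(spikes) {
  if (is.data.frame(spikes)) {
    stopifnot(all(c("direction_deg", "trial", "spike_times_ms") %in%
                    names(spikes)))
    return(spikes)
  }
  rows <- lapply(spikes, function(r) {
    stopifnot(inherits(r, "recording"), r$mode == "spike_times")
    data.frame(direction_deg = r$metadata$direction_deg,
               trial = r$metadata$trial)
  })
  df <- do.call(rbind, rows)
  df$spike_times_ms <- lapply(spikes, function(r) r$values)
  df
}
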