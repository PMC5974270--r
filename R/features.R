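new_feature_series <- function(base, n_per_step, times, modality,
                               feature_names, accumulate, trial_ids,
                               intensity, latency) {
  stopifnot(ncol(base) == n_per_step * length(times))
  structure(
    list(base = base, n_per_step = n_per_step, times = times,
         modality = modality, feature_names = feature_names,
         accumulate = accumulate, trial_ids = trial_ids,
         intensity = intensity, latency = latency),
    class = "feature_series"
  )
}

#' Design matrix of a feature series at one time bin
#'
#' For accumulated series this is the leading `bin * n_per_step` columns of
#' the underlying trials x features matrix (the prefix property: features at
#' bin k are exactly the leading columns of those at bin k+1); for
#' non-accumulated series it is the k-th per-step block alone.
#'
#' @param fs a `feature_series`
#' @param bin time-bin index (1-based into `fs$times`)
#' @return a trials x features numeric matrix
#' @export
feature_matrix <- function(fs, bin) {
  stopifnot(inherits(fs, "feature_series"),
            bin >= 1, bin <= length(fs$times))
  p <- fs$n_per_step
  if (isTRUE(fs$accumulate)) {
    fs$base[, seq_len(bin * p), drop = FALSE]
  } else {
    fs$base[, ((bin - 1) * p + 1):(bin * p), drop = FALSE]
  }
}

#' Cumulative 50-ms spike-count features
#'
#' Bins each unit's spikes into consecutive 50-ms bins from laser onset to the
#' horizon (100 bins at the defaults) and accumulates them: the feature vector
#' at bin k concatenates bins 1..k for all C units, so its dimension grows
#' from C to 100*C. Bin membership is half-open `(start, end]`: a spike
#' exactly at time 0 belongs to the baseline, not to bin 1.
#'
#' @param session a `pain_session`
#' @param bin_s bin width, seconds (default 0.05)
#' @param horizon_s accumulation horizon, seconds (default 5); must be an
#'   integer multiple of `bin_s`
#' @return a `feature_series` with modality `"spike"`
#' @export
cumulative_spike_features <- function(session, bin_s = 0.05, horizon_s = 5) {
  C <- length(session$trials[[1]]$spikes)
  if (C == 0) stop("session has no units")
  S <- horizon_s / bin_s
  if (abs(S - round(S)) > 1e-9) stop("bin_s must divide horizon_s")
  S <- round(S)
  nt <- length(session$trials)
  base <- matrix(0, nrow = nt, ncol = C * S)
  for (i in seq_len(nt)) {
    spikes <- session$trials[[i]]$spikes
    for (u in seq_len(C)) {
      sp <- spikes[[u]]
      sp <- sp[sp > 0 & sp <= horizon_s]
      if (length(sp)) {
        b <- pmax(1L, floor((sp - 1e-12) / bin_s) + 1L)
        counts <- tabulate(b, nbins = S)
        base[i, (seq_len(S) - 1L) * C + u] <- counts
      }
    }
  }
  times <- seq_len(S) * bin_s
  nms <- as.vector(t(outer(seq_len(S), seq_len(C),
                           function(j, u) sprintf("u%d_bin%d", u, j))))
  new_feature_series(
    base, n_per_step = C, times = times, modality = "spike",
    feature_names = nms, accumulate = TRUE,
    trial_ids = vapply(session$trials, function(x) x$trial_id, 0),
    intensity = session_labels(session),
    latency = session_latencies(session)
  )
}

#' Sliding-window LFP band-power features
#'
#' At every 50-ms step t the multitaper band power of the trailing 1-s window
#' `[t - 1, t)` of the denoised trace is computed for each requested band
#' (all five bands concatenated per step gives the "all frequency" feature
#' set). By default features accumulate across steps exactly like the spike
#' bins, mirroring the cumulative decoding trajectory; `accumulate = FALSE`
#' gives per-window features instead. For early steps (t < 1 s) the trailing
#' window deliberately extends into the pre-stimulus baseline, keeping the
#' 50-ms grid aligned with the spike bins from time 0.
#'
#' @param session a preprocessed `pain_session`
#' @param bands band definition data frame (default all five)
#' @param window_s trailing window length, seconds
#' @param step_s step size, seconds
#' @param horizon_s last step time, seconds
#' @param TW,K per-window multitaper parameters
#' @param accumulate concatenate features across steps (default `TRUE`)
#' @param steps optional integer step indices to compute; must be `1:k` when
#'   accumulating, may be any subset otherwise (used to cut cost when only a
#'   few evaluation times are needed)
#' @return a `feature_series` with modality `"lfp_all"` (several bands) or
#'   `"lfp_band"` (one band)
#' @export
lfp_band_features <- function(session, bands = band_definitions(),
                              window_s = 1, step_s = 0.05, horizon_s = 5,
                              TW = 3, K = NULL, accumulate = TRUE,
                              steps = NULL) {
  cfg <- session$config
  S <- round(horizon_s / step_s)
  steps <- as.integer(steps %||% seq_len(S))
  if (accumulate && !identical(steps, seq_len(max(steps)))) {
    stop("accumulated features require steps to be a contiguous prefix 1:k")
  }
  fs_hz <- cfg$fs
  win <- round(window_s * fs_hz)
  tap <- dpss_tapers(win, TW, K)
  p <- nrow(bands)
  nt <- length(session$trials)
  nsamp <- round(fs_hz * diff(cfg$t_range))
  base <- matrix(NA_real_, nrow = nt, ncol = p * length(steps))
  for (i in seq_len(nt)) {
    den <- session$trials[[i]]$denoised
    if (is.null(den)) {
      stop("trial ", session$trials[[i]]$trial_id,
           " has no denoised trace; run preprocess_session() first")
    }
    for (sj in seq_along(steps)) {
      tend <- steps[sj] * step_s
      i1 <- round((tend - window_s - cfg$t_range[1]) * fs_hz) + 1
      if (i1 < 1 || i1 + win - 1 > nsamp) {
        stop("window [", tend - window_s, ", ", tend,
             ") exceeds the available signal")
      }
      est <- multitaper_psd(den[i1:(i1 + win - 1)], fs_hz, tap)
      base[i, ((sj - 1) * p + 1):(sj * p)] <-
        vapply(seq_len(p), function(b) band_power(est, bands[b, ]), 0)
    }
  }
  times <- steps * step_s
  nms <- as.vector(vapply(seq_along(steps), function(sj)
    sprintf("%s_t%.2f", bands$name, times[sj]), character(p)))
  new_feature_series(
    base, n_per_step = p, times = times,
    modality = if (p == 1) "lfp_band" else "lfp_all",
    feature_names = nms, accumulate = accumulate,
    trial_ids = vapply(session$trials, function(x) x$trial_id, 0),
    intensity = session_labels(session),
    latency = session_latencies(session)
  )
}

#' Combine two feature series column-wise
#'
#' Concatenates the per-step feature blocks of two series defined on the same
#' trials and time grid (e.g. spike counts plus LFP band powers), preserving
#' the prefix property.
#'
#' @param a,b `feature_series` objects with identical trials, times and
#'   accumulation mode
#' @return a `feature_series` with modality `"combined"`
#' @export
combine_features <- function(a, b) {
  stopifnot(inherits(a, "feature_series"), inherits(b, "feature_series"))
  if (!isTRUE(all.equal(a$times, b$times))) stop("time grids differ")
  if (!identical(a$trial_ids, b$trial_ids)) stop("trial sets differ")
  if (!identical(a$accumulate, b$accumulate)) {
    stop("accumulation modes differ")
  }
  S <- length(a$times)
  pa <- a$n_per_step; pb <- b$n_per_step
  cols <- unlist(lapply(seq_len(S), function(s) {
    c((s - 1) * pa + seq_len(pa), pa * S + (s - 1) * pb + seq_len(pb))
  }))
  base <- cbind(a$base, b$base)[, cols, drop = FALSE]
  nms <- c(a$feature_names, b$feature_names)[cols]
  new_feature_series(
    base, n_per_step = pa + pb, times = a$times, modality = "combined",
    feature_names = nms, accumulate = a$accumulate,
    trial_ids = a$trial_ids, intensity = a$intensity, latency = a$latency
  )
}
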