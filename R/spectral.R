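.taper_cache <- new.env(parent = emptyenv())

# Exact DPSS via the symmetric tridiagonal eigenproblem (Slepian's
# commuting-matrix formulation): diagonal ((N-1-2k)/2)^2 cos(2*pi*W),
# off-diagonal k(N-k)/2. The top-K eigenvectors are the K most
# frequency-concentrated tapers.
.dpss_dense <- function(N, W, K) {
  i <- 0:(N - 1)
  A <- matrix(0, N, N)
  diag(A) <- ((N - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off <- (1:(N - 1)) * (N - (1:(N - 1))) / 2
  A[cbind(1:(N - 1), 2:N)] <- off
  A[cbind(2:N, 1:(N - 1))] <- off
  eigen(A, symmetric = TRUE)$vectors[, seq_len(K), drop = FALSE]
}

# Polarity convention: symmetric tapers have positive sum, antisymmetric
# tapers a positive first half.
.dpss_fix_sign <- function(V) {
  for (k in seq_len(ncol(V))) {
    v <- V[, k]
    s <- sum(v)
    if (abs(s) > 1e-8) {
      if (s < 0) V[, k] <- -v
    } else if (sum(v[seq_len(length(v) %/% 2)]) < 0) {
      V[, k] <- -v
    }
  }
  V
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' The first K Slepian sequences of length N for time-bandwidth product TW,
#' each unit-norm and mutually orthogonal, ordered by spectral concentration
#' in `[-W, W]` with `W = TW/N` cycles/sample. At the defaults `TW = 3`,
#' `K = 2*TW - 1 = 5`. For short windows the tapers are computed exactly from
#' the tridiagonal eigenproblem; for long windows (N > 1536) they are computed
#' at a 1024-sample base length, spline-interpolated to N and re-orthonormalized
#' by QR, so orthonormality is exact in either path. Results are cached per
#' (N, TW, K).
#'
#' @param N window length in samples (N >= K)
#' @param TW time-bandwidth product (default 3)
#' @param K number of tapers; defaults to `2*TW - 1`. Requesting more than
#'   `2*TW` tapers triggers a warning (poorly concentrated tapers).
#' @return an object of class `taper_set`: list with `N`, `TW`, `K`,
#'   `W` (cycles/sample) and the `N x K` matrix `tapers`.
#' @examples
#' ts <- dpss_tapers(512, TW = 3)
#' ts$K                       # 5
#' crossprod(ts$tapers)[1:2, 1:2]
#' @export
dpss_tapers <- function(N, TW = 3, K = NULL) {
  K <- as.integer(K %||% round(2 * TW - 1))
  if (TW <= 0) stop("TW must be positive")
  if (K < 1 || N < K) stop("need N >= K >= 1")
  if (TW / N >= 0.5) stop("TW/N must be < 1/2")
  if (K > floor(2 * TW)) {
    warning("K > 2*TW: tapers beyond 2*TW are poorly concentrated")
  }
  key <- paste(N, TW, K, sep = "_")
  hit <- get0(key, envir = .taper_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  if (N <= 1536) {
    V <- .dpss_dense(N, TW / N, K)
  } else {
    base_n <- 1024
    V0 <- dpss_tapers(base_n, TW, K)$tapers
    x0 <- seq(0, 1, length.out = base_n)
    x1 <- seq(0, 1, length.out = N)
    V <- vapply(seq_len(K), function(k) spline(x0, V0[, k], xout = x1)$y,
                numeric(N))
    V <- qr.Q(qr(V))
  }
  V <- .dpss_fix_sign(V)
  out <- structure(list(N = N, TW = TW, K = K, W = TW / N, tapers = V),
                   class = "taper_set")
  assign(key, out, envir = .taper_cache)
  out
}

new_spectral_estimate <- function(freqs, power, times = NULL, params = list()) {
  structure(list(freqs = freqs, power = power, times = times, params = params),
            class = "spectral_estimate")
}

#' Multitaper power spectral density
#'
#' Averages the K eigenspectra (squared FFT magnitudes of the taper-windowed
#' trace) into a single one-sided PSD with frequency resolution `fs/N` and no
#' zero padding. Power is non-negative everywhere and scales with the square
#' of the signal amplitude.
#'
#' @param trace numeric vector
#' @param fs sampling rate, Hz
#' @param tapers optional [dpss_tapers()] result matching `length(trace)`
#' @param TW,K taper parameters used when `tapers` is not supplied
#' @return a `spectral_estimate` with `freqs` (Hz, 0 to fs/2) and `power`
#' @export
multitaper_psd <- function(trace, fs, tapers = NULL, TW = 3, K = NULL) {
  N <- length(trace)
  tapers <- tapers %||% dpss_tapers(N, TW, K)
  if (tapers$N != N) {
    stop("taper length (", tapers$N, ") does not match trace length (", N, ")")
  }
  Y <- mvfft(tapers$tapers * trace)
  P <- Mod(Y)^2 / fs
  nh <- N %/% 2 + 1
  onesided <- rep(2, nh)
  onesided[1] <- 1
  if (N %% 2 == 0) onesided[nh] <- 1
  power <- rowMeans(P[seq_len(nh), , drop = FALSE]) * onesided
  new_spectral_estimate(
    freqs = (seq_len(nh) - 1) * fs / N, power = power,
    params = list(TW = tapers$TW, K = tapers$K, fs = fs, N = N)
  )
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper PSD. With window w and step s samples the number
#' of time points is `floor((N - w)/s) + 1`; times are window centers.
#'
#' @inheritParams multitaper_psd
#' @param window_s,step_s window length and step, seconds
#' @param t_start time (s) of the first sample of `trace`
#' @return a `spectral_estimate` whose `power` is a times x freqs matrix
#' @export
multitaper_spectrogram <- function(trace, fs, window_s = 0.5, step_s = 0.05,
                                   TW = 3, K = NULL, t_start = 0) {
  N <- length(trace)
  win <- round(window_s * fs)
  step <- round(step_s * fs)
  if (win > N) stop("window longer than trace")
  if (step < 1) stop("step must cover at least one sample")
  nw <- (N - win) %/% step + 1
  tap <- dpss_tapers(win, TW, K)
  nh <- win %/% 2 + 1
  pow <- matrix(0, nrow = nw, ncol = nh)
  for (i in seq_len(nw)) {
    seg <- trace[((i - 1) * step + 1):((i - 1) * step + win)]
    pow[i, ] <- multitaper_psd(seg, fs, tap)$power
  }
  new_spectral_estimate(
    freqs = (seq_len(nh) - 1) * fs / win, power = pow,
    times = t_start + ((seq_len(nw) - 1) * step + win / 2) / fs,
    params = list(TW = tap$TW, K = tap$K, fs = fs, window_s = window_s,
                  step_s = step_s)
  )
}

#' Band power from a spectral estimate
#'
#' Sums estimated power over the frequency bins in `[lo, hi)`. For a
#' spectrogram, returns one value per time point.
#'
#' @param est a `spectral_estimate`
#' @param band a band name (see [band_definitions()]) or any list/row with
#'   `lo` and `hi` fields in Hz
#' @return scalar (PSD) or numeric vector over time (spectrogram)
#' @export
band_power <- function(est, band) {
  bd <- if (is.character(band)) band_definitions(band) else band
  sel <- est$freqs >= bd$lo & est$freqs < bd$hi
  if (!any(sel)) stop("band [", bd$lo, ", ", bd$hi, ") contains no frequency bins")
  if (is.matrix(est$power)) {
    rowSums(est$power[, sel, drop = FALSE])
  } else {
    sum(est$power[sel])
  }
}

#' Baseline-referenced band-power z-scores
#'
#' For each trial, band power is computed by multitaper PSD over the response
#' epoch and the pre-stimulus baseline; the z-score references the response
#' power to the across-trial distribution of baseline powers:
#' `z = (response - mean(baseline)) / sd(baseline)`. A positive z is an
#' event-related synchronization (power increase) in that band. Epochs are
#' half-open `[a, b)` on the sample grid.
#'
#' @param session a preprocessed `pain_session` (see [preprocess_session()])
#' @param band band name or definition (see [band_power()])
#' @param response_epoch,baseline_epoch `c(from, to)` in seconds
#' @param TW,K multitaper parameters
#' @return a data frame with one row per trial: `trial_id`, `intensity`,
#'   `condition`, `band`, `raw_power`, `baseline_power`, `z`
#' @export
zscore_band_power <- function(session, band, response_epoch = c(0, 5),
                              baseline_epoch = c(-5, 0), TW = 3, K = NULL) {
  if (length(session$trials) < 2) {
    stop("need at least 2 trials to estimate baseline dispersion")
  }
  cfg <- session$config
  tr_range <- cfg$t_range
  for (ep in list(response_epoch, baseline_epoch)) {
    if (ep[1] < tr_range[1] || ep[2] > tr_range[2] || ep[1] >= ep[2]) {
      stop("epochs must be increasing and lie inside the trial time range")
    }
  }
  bd <- if (is.character(band)) band_definitions(band) else band
  t <- trial_times(cfg)
  ridx <- which(t >= response_epoch[1] & t < response_epoch[2])
  bidx <- which(t >= baseline_epoch[1] & t < baseline_epoch[2])
  tap_r <- dpss_tapers(length(ridx), TW, K)
  tap_b <- if (length(bidx) == length(ridx)) tap_r else
    dpss_tapers(length(bidx), TW, K)
  pw <- vapply(session$trials, function(trl) {
    den <- trl$denoised
    if (is.null(den)) stop("trial ", trl$trial_id,
                           " has no denoised trace; run preprocess_session() first")
    c(band_power(multitaper_psd(den[ridx], cfg$fs, tap_r), bd),
      band_power(multitaper_psd(den[bidx], cfg$fs, tap_b), bd))
  }, numeric(2))
  resp <- pw[1, ]; base <- pw[2, ]
  sdb <- sd(base)
  if (sdb == 0) stop("baseline band powers have zero dispersion")
  data.frame(
    trial_id = vapply(session$trials, function(x) x$trial_id, 0),
    intensity = session_labels(session),
    condition = session$condition,
    band = bd$name %||% paste0(bd$lo, "-", bd$hi),
    raw_power = resp, baseline_power = base,
    z = (resp - mean(base)) / sdb,
    stringsAsFactors = FALSE
  )
}
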