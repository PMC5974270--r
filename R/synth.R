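# Laser power (mW) for the three stimulus intensities.
.intensity_power_mw <- c(NS = 50, LS = 150, HS = 250)

#' Stimulus intensity descriptor
#'
#' Maps a stimulus label to its laser power: non-noxious NS = 50 mW,
#' low-intensity noxious LS = 150 mW, high-intensity noxious HS = 250 mW.
#' The mapping is fixed and ordered NS < LS < HS.
#'
#' @param label one of `"NS"`, `"LS"`, `"HS"`
#' @return an object of class `stimulus_intensity` with fields `label` and
#'   `laser_power_mw`.
#' @export
stimulus_intensity <- function(label) {
  label <- match.arg(label, names(.intensity_power_mw))
  structure(
    list(label = label, laser_power_mw = unname(.intensity_power_mw[label])),
    class = "stimulus_intensity"
  )
}

intensity_label <- function(x) {
  if (inherits(x, "stimulus_intensity")) return(x$label)
  match.arg(x, names(.intensity_power_mw))
}

#' Default event-related synchronization gains
#'
#' Power multipliers applied to each band during the stimulus epoch, per
#' intensity. Non-noxious stimulation leaves all bands at their baseline power
#' (gain 1); noxious stimulation drives theta and high gamma, scaling with
#' intensity. Other bands stay null by default.
#'
#' @return a 5 x 3 numeric matrix (bands x intensities), all entries >= 1.
#' @export
default_ers_gain <- function() {
  g <- matrix(1, nrow = 5, ncol = 3,
              dimnames = list(band_definitions()$name, c("NS", "LS", "HS")))
  g["theta", ]      <- c(1, 2.5, 4.0)
  g["high_gamma", ] <- c(1, 2.0, 3.5)
  g
}

#' Configuration for the synthetic session generator
#'
#' Collects every tunable of the generative model: trial counts, LFP sampling
#' and noise structure, per-band/per-intensity ERS gains, the chronic-pain
#' (CFA) gain multiplier, Poisson unit parameters, and per-intensity
#' withdrawal-latency distributions. Defaults reproduce the recording
#' conditions the pipeline is designed for: 1 kHz LFP over [-5, +5) s around
#' stimulus onset, 8 channels (one per tetrode), ~60 trials per session, and a
#' minority (~25%) of stimulus-modulated units.
#'
#' @param n_trials_per_class trials per stimulus class (>= 15, so that a
#'   session holds at least 30 trials)
#' @param channels number of LFP channels
#' @param fs sampling rate, samples/s
#' @param t_range trial time span in seconds around onset at 0; the sample
#'   grid is half-open: sample k sits at `t_range[1] + k/fs`, k = 0, 1, ...
#' @param background_exponent exponent alpha of the 1/f^alpha pink background
#' @param lfp_sd per-channel background standard deviation, microvolts
#' @param channel_mix fraction (0-1) of channel variance carried by a latent
#'   component shared across channels
#' @param ers_gain bands x intensities matrix of power multipliers applied
#'   during the stimulus epoch (see [default_ers_gain()])
#' @param cfa_gain_multiplier multiplier applied to the ERS excess (gain - 1)
#'   of LS and HS trials under the CFA condition
#' @param ers_onset_s time (s, >= 0) at which the ERS begins after laser onset
#' @param n_units number of simultaneously recorded units
#' @param frac_modulated fraction of units with a stimulus-locked rate change
#' @param base_rate background firing rate, spikes/s
#' @param modulated_rate_gain rate multiplier of modulated units at full
#'   intensity drive
#' @param intensity_drive named vector in [0, 1]: how strongly each intensity
#'   recruits the modulated units (NS = 0 keeps them at baseline)
#' @param latency_params per-intensity `c(shape=, rate=)` of the gamma
#'   withdrawal-latency distribution, truncated to (0, 5] s
#' @param seed default master seed for [make_session()]
#' @return an object of class `synth_config`
#' @export
synth_config <- function(n_trials_per_class = 30,
                         channels = 8,
                         fs = 1000,
                         t_range = c(-5, 5),
                         background_exponent = 1,
                         lfp_sd = 40,
                         channel_mix = 0.6,
                         ers_gain = default_ers_gain(),
                         cfa_gain_multiplier = 1.5,
                         ers_onset_s = 0,
                         n_units = 8,
                         frac_modulated = 0.25,
                         base_rate = 5,
                         modulated_rate_gain = 2,
                         intensity_drive = c(NS = 0, LS = 0.6, HS = 1),
                         latency_params = list(LS = c(shape = 9, rate = 3),
                                               HS = c(shape = 8, rate = 4)),
                         seed = 1L) {
  if (n_trials_per_class < 15) {
    stop("n_trials_per_class must be >= 15 (sessions hold at least 30 trials)")
  }
  if (channels < 1 || n_units < 1) stop("channels and n_units must be >= 1")
  if (fs <= 0) stop("fs must be positive")
  dur <- diff(t_range)
  if (dur <= 0) stop("t_range must span a positive duration")
  if (abs(fs * dur - round(fs * dur)) > 1e-9) {
    stop("fs * duration must be an integer sample count")
  }
  if (any(ers_gain < 0) || cfa_gain_multiplier < 0 || modulated_rate_gain < 0) {
    stop("all gains must be >= 0")
  }
  if (frac_modulated < 0 || frac_modulated > 1) {
    stop("frac_modulated must lie in [0, 1]")
  }
  if (base_rate < 0) stop("base_rate must be >= 0")
  if (ers_onset_s < 0) stop("ers_onset_s must be >= 0")
  if (channel_mix < 0 || channel_mix > 1) stop("channel_mix must lie in [0, 1]")
  if (!all(rownames(ers_gain) %in% band_definitions()$name) ||
      !identical(colnames(ers_gain), c("NS", "LS", "HS"))) {
    stop("ers_gain must have band rownames and colnames NS, LS, HS")
  }
  structure(
    list(n_trials_per_class = n_trials_per_class, channels = channels,
         fs = fs, t_range = t_range,
         background_exponent = background_exponent, lfp_sd = lfp_sd,
         channel_mix = channel_mix, ers_gain = ers_gain,
         cfa_gain_multiplier = cfa_gain_multiplier, ers_onset_s = ers_onset_s,
         n_units = n_units, frac_modulated = frac_modulated,
         base_rate = base_rate, modulated_rate_gain = modulated_rate_gain,
         intensity_drive = intensity_drive, latency_params = latency_params,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Number of stimulus-modulated units: round half up.
n_modulated_units <- function(config) {
  floor(config$frac_modulated * config$n_units + 0.5)
}

trial_times <- function(config) {
  n <- round(config$fs * diff(config$t_range))
  config$t_range[1] + (seq_len(n) - 1) / config$fs
}

# Effective ERS power gain for a band/intensity/condition. Under CFA the
# *excess* over baseline is multiplied, and only for noxious trials, so null
# bands stay null.
effective_ers_gain <- function(config, band, label, condition) {
  g <- if (band %in% rownames(config$ers_gain)) config$ers_gain[band, label] else 1
  if (identical(condition, "CFA") && label %in% c("LS", "HS")) {
    g <- 1 + (g - 1) * config$cfa_gain_multiplier
  }
  g
}

# 1/f^alpha Gaussian noise via spectral synthesis; scaled to sd_target.
pink_noise <- function(n, fs, alpha, sd_target) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- f^(-alpha / 2)
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  if (n %% 2 == 0) z[nf] <- complex(real = Re(z[nf]) * sqrt(2), imaginary = 0)
  s <- complex(n)
  s[1 + (1:nf)] <- z
  s[n + 1 - (1:nf)] <- Conj(z)
  if (n %% 2 == 0) s[nf + 1] <- z[nf]
  x <- Re(fft(s, inverse = TRUE)) / n
  sx <- sd(x)
  if (sx > 0) x * (sd_target / sx) else x
}

# Unit-variance Gaussian noise band-limited to [lo, hi) Hz.
band_limited_noise <- function(n, fs, lo, hi) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  sel <- f >= lo & f < hi
  if (!any(sel)) stop("band [", lo, ", ", hi, ") empty at this fs/n")
  z <- complex(n %/% 2)
  z[sel] <- complex(real = rnorm(sum(sel)), imaginary = rnorm(sum(sel)))
  if (n %% 2 == 0) z[nf] <- complex(real = Re(z[nf]), imaginary = 0)
  s <- complex(n)
  s[1 + (1:nf)] <- z
  s[n + 1 - (1:nf)] <- Conj(z)
  if (n %% 2 == 0) s[nf + 1] <- z[nf]
  x <- Re(fft(s, inverse = TRUE)) / n
  sx <- sd(x)
  if (sx > 0) x / sx else x
}

# Fraction of the 1/f^alpha background variance that falls inside [lo, hi).
pink_band_fraction <- function(n, fs, alpha, lo, hi) {
  f <- (1:(n %/% 2)) * fs / n
  sum(f[f >= lo & f < hi]^(-alpha)) / sum(f^(-alpha))
}

# Raised-cosine windowed envelope: 0 outside [from, to], 50-ms cosine ramps
# at both edges to avoid spectral splatter.
ers_envelope <- function(t, from, to, ramp = 0.05) {
  env <- numeric(length(t))
  if (to <= from) return(env)
  r <- min(ramp, (to - from) / 2)
  inside <- t >= from & t <= to
  env[inside] <- 1
  if (r > 0) {
    up <- t >= from & t < from + r
    env[up] <- 0.5 * (1 - cos(pi * (t[up] - from) / r))
    dn <- t > to - r & t <= to
    env[dn] <- 0.5 * (1 - cos(pi * (to - t[dn]) / r))
  }
  env
}

#' Simulate one trial's withdrawal latency
#'
#' Non-noxious (NS) trials never trigger withdrawal and return `NA` (the
#' stimulus epoch then lasts the full 5 s). Noxious trials draw from the
#' configured gamma distribution truncated to (0, 5] via the inverse-CDF
#' method; under the default parameters HS withdrawals are faster than LS.
#'
#' @param intensity stimulus label or [stimulus_intensity()] object
#' @param config a [synth_config()]
#' @param seed integer seed
#' @return latency in seconds within (0, 5], or `NA_real_` for NS
#' @export
synth_withdrawal <- function(intensity, config, seed) {
  lab <- intensity_label(intensity)
  if (lab == "NS") return(NA_real_)
  p <- config$latency_params[[lab]]
  if (is.null(p)) stop("no latency parameters configured for ", lab)
  with_seed(seed, {
    u <- runif(1, 0, pgamma(5, shape = p[["shape"]], rate = p[["rate"]]))
    qgamma(u, shape = p[["shape"]], rate = p[["rate"]])
  })
}

#' Simulate per-unit spike trains for one trial
#'
#' Every unit fires as a homogeneous Poisson process at `base_rate` over the
#' whole trial. Units in the modulated subset multiply their rate by
#' `1 + (modulated_rate_gain - 1) * intensity_drive[intensity]` during the
#' stimulus epoch `[ers_onset_s, min(latency, 5)]`; the modulated identities
#' are fixed per session by [make_session()].
#'
#' @inheritParams synth_withdrawal
#' @param condition `"naive"` or `"CFA"` (spiking is condition-independent)
#' @param latency withdrawal latency in seconds, `NA` for no withdrawal
#' @param modulated_units integer indices of the modulated subset; defaults to
#'   the first `round(frac_modulated * n_units)` units
#' @return a list of `n_units` numeric vectors of spike times (s, relative to
#'   laser onset), each sorted within `t_range`
#' @export
synth_spikes <- function(intensity, condition, config, seed,
                         latency = NA_real_, modulated_units = NULL) {
  lab <- intensity_label(intensity)
  t0 <- config$t_range[1]; t1 <- config$t_range[2]
  dur <- t1 - t0
  epoch_end <- if (is.na(latency)) 5 else min(latency, 5)
  epoch_start <- config$ers_onset_s
  drive <- config$intensity_drive[[lab]]
  m <- 1 + (config$modulated_rate_gain - 1) * drive
  if (is.null(modulated_units)) {
    modulated_units <- seq_len(n_modulated_units(config))
  }
  with_seed(seed, {
    lapply(seq_len(config$n_units), function(u) {
      sp <- runif(rpois(1, config$base_rate * dur), t0, t1)
      if (u %in% modulated_units && epoch_end > epoch_start && m != 1) {
        if (m > 1) {
          extra <- runif(rpois(1, config$base_rate * (m - 1) *
                                 (epoch_end - epoch_start)),
                         epoch_start, epoch_end)
          sp <- c(sp, extra)
        } else {
          # rate decrease: thin epoch spikes with probability m
          in_ep <- sp >= epoch_start & sp <= epoch_end
          keep <- !in_ep | (runif(length(sp)) < m)
          sp <- sp[keep]
        }
      }
      sort(sp)
    })
  })
}

#' Simulate one trial's multi-channel LFP
#'
#' Each channel is 1/f^alpha pink noise built from a latent component shared
#' across channels plus independent channel noise. During the stimulus epoch
#' `[ers_onset_s, min(latency, 5)]`, band-limited Gaussian noise is added
#' (shared across channels, 50-ms raised-cosine ramps at the epoch edges)
#' with variance `(g - 1)` times the background power in that band, so that
#' band power is multiplied by the effective gain g; the baseline `[-5, 0)` s
#' is left untouched, and g = 1 adds nothing.
#'
#' @inheritParams synth_spikes
#' @return a `channels x samples` matrix (microvolts) on the half-open grid
#'   `[t_range[1], t_range[2])`
#' @export
synth_lfp_trial <- function(intensity, condition, config, seed,
                            latency = NA_real_) {
  lab <- intensity_label(intensity)
  fs <- config$fs
  n <- round(fs * diff(config$t_range))
  t <- trial_times(config)
  epoch_end <- if (is.na(latency)) 5 else min(latency, 5)
  with_seed(seed, {
    common <- pink_noise(n, fs, config$background_exponent, config$lfp_sd)
    lfp <- matrix(0, nrow = config$channels, ncol = n)
    for (ch in seq_len(config$channels)) {
      own <- pink_noise(n, fs, config$background_exponent, config$lfp_sd)
      lfp[ch, ] <- sqrt(config$channel_mix) * common +
        sqrt(1 - config$channel_mix) * own
    }
    env <- ers_envelope(t, config$ers_onset_s, epoch_end)
    if (any(env > 0)) {
      for (b in rownames(config$ers_gain)) {
        g <- effective_ers_gain(config, b, lab, condition)
        if (g > 1) {
          bd <- band_definitions(b)
          w <- pink_band_fraction(n, fs, config$background_exponent,
                                  bd$lo, bd$hi)
          burst <- band_limited_noise(n, fs, bd$lo, bd$hi) *
            (config$lfp_sd * sqrt((g - 1) * w)) * env
          lfp <- lfp + matrix(burst, nrow = config$channels, ncol = n,
                              byrow = TRUE)
        }
      }
    }
    lfp
  })
}

#' Generate a full synthetic recording session
#'
#' Draws a balanced, randomly interleaved sequence of trials for a two-class
#' stimulus pair, fixing the identity of the stimulus-modulated units once per
#' session. Fully deterministic given `(config, class_pair, condition, seed)`.
#'
#' @param config a [synth_config()]
#' @param class_pair two distinct labels among NS, LS, HS
#' @param condition `"naive"` or `"CFA"`
#' @param seed master integer seed (defaults to `config$seed`)
#' @return an object of class `pain_session`: a list with `trials` (each trial
#'   holding `lfp`, `spikes`, `intensity`, `withdrawal_latency`),
#'   `class_pair`, `condition`, `config`, `seed`.
#' @examples
#' cfg <- synth_config(n_trials_per_class = 15, channels = 2, fs = 250,
#'                     n_units = 2)
#' ses <- make_session(cfg, c("NS", "HS"), "naive", seed = 7)
#' length(ses$trials)
#' @export
make_session <- function(config, class_pair = c("NS", "HS"),
                         condition = c("naive", "CFA"), seed = config$seed) {
  condition <- match.arg(condition)
  if (length(class_pair) != 2 ||
      !all(class_pair %in% names(.intensity_power_mw)) ||
      class_pair[1] == class_pair[2]) {
    stop("class_pair must name two distinct intensities among NS, LS, HS")
  }
  n <- config$n_trials_per_class
  labels <- with_seed(derive_seed(seed, 97),
                      sample(rep(class_pair, each = n)))
  mod_units <- with_seed(derive_seed(seed, 11),
                         sort(sample(config$n_units, n_modulated_units(config))))
  trials <- lapply(seq_along(labels), function(i) {
    lab <- labels[i]
    lat <- synth_withdrawal(lab, config, derive_seed(seed, i, 1))
    spikes <- synth_spikes(lab, condition, config, derive_seed(seed, i, 2),
                           latency = lat, modulated_units = mod_units)
    lfp <- synth_lfp_trial(lab, condition, config, derive_seed(seed, i, 3),
                           latency = lat)
    list(trial_id = i, intensity = stimulus_intensity(lab),
         condition = condition, lfp = lfp, spikes = spikes,
         withdrawal_latency = lat)
  })
  structure(
    list(trials = trials, class_pair = class_pair, condition = condition,
         modulated_units = mod_units, config = config, seed = as.integer(seed)),
    class = "pain_session"
  )
}

#' @export
print.pain_session <- function(x, ...) {
  labs <- session_labels(x)
  cat(sprintf("<pain_session> %s vs %s, %s condition\n",
              x$class_pair[1], x$class_pair[2], x$condition))
  cat(sprintf("  %d trials (%s), %d channels at %g Hz, %d units\n",
              length(x$trials),
              paste(sprintf("%s: %d", names(table(labs)), table(labs)),
                    collapse = ", "),
              x$config$channels, x$config$fs, x$config$n_units))
  invisible(x)
}

#' Per-trial stimulus labels of a session
#' @param session a `pain_session`
#' @return character vector of labels, one per trial
#' @export
session_labels <- function(session) {
  vapply(session$trials, function(tr) tr$intensity$label, "")
}

#' Per-trial withdrawal latencies of a session
#' @param session a `pain_session`
#' @return numeric vector (s), `NA` where no withdrawal occurred
#' @export
session_latencies <- function(session) {
  vapply(session$trials, function(tr) tr$withdrawal_latency, 0)
}
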