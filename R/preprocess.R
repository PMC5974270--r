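#' Remove a linear trend from a trace
#'
#' Least-squares removal of the best-fit line over the sample index; the
#' output has (numerically) zero mean and zero residual slope, and the
#' operation is idempotent.
#'
#' @param x numeric vector, length >= 2
#' @return detrended numeric vector of the same length
#' @export
detrend <- function(x) {
  n <- length(x)
  if (n < 2) stop("detrend requires at least 2 samples")
  k <- seq_len(n)
  kc <- k - mean(k)
  beta <- sum(kc * x) / sum(kc * kc)
  x - (mean(x) + beta * kc)
}

#' Reject artifact channels by robust z-score of log total power
#'
#' A channel is flagged when the absolute robust z-score of its log total
#' power -- (log P - median) / (1.4826 * MAD), computed across channels --
#' exceeds the threshold. The statistic is scale-equivariant: rescaling all
#' channels by a common factor changes no decision. Zero cross-channel
#' dispersion (all channels alike) keeps every channel.
#'
#' @param lfp channels x samples numeric matrix (>= 2 channels)
#' @param robust_z_threshold rejection threshold on |z| (default 3)
#' @return an object of class `channel_mask`: list with logical `kept`,
#'   numeric `z` and character `reason` (`"high_power"`/`"low_power"` for
#'   rejected channels, `""` otherwise).
#' @export
reject_artifact_channels <- function(lfp, robust_z_threshold = 3) {
  if (!is.matrix(lfp) || nrow(lfp) < 2) {
    stop("artifact rejection needs at least 2 channels")
  }
  logp <- log(rowSums(lfp^2) + 1e-300)
  med <- median(logp)
  madv <- mad(logp)
  if (madv == 0) {
    z <- rep(0, nrow(lfp))
  } else {
    z <- (logp - med) / madv
  }
  kept <- abs(z) <= robust_z_threshold
  if (!any(kept)) {
    stop("all channels rejected: trial unusable")
  }
  reason <- ifelse(kept, "", ifelse(z > 0, "high_power", "low_power"))
  structure(list(kept = kept, z = z, reason = reason), class = "channel_mask")
}

#' Project multi-channel LFP onto its first principal component
#'
#' Eigendecomposition of the channel covariance (channels as variables,
#' samples as observations); the returned trace is the projection onto the
#' leading eigenvector, so its variance equals the largest eigenvalue. The
#' eigenvector sign is fixed so the output correlates non-negatively with the
#' across-channel mean. A single-channel input is returned unchanged.
#'
#' @param lfp channels x samples numeric matrix (channels should already be
#'   detrended)
#' @return numeric vector, the denoised single-channel trace
#' @export
pca_first_component <- function(lfp) {
  if (!is.matrix(lfp)) lfp <- matrix(lfp, nrow = 1)
  if (nrow(lfp) == 1) return(as.vector(lfp))
  xc <- lfp - rowMeans(lfp)
  cmat <- tcrossprod(xc) / (ncol(lfp) - 1)
  w <- eigen(cmat, symmetric = TRUE)$vectors[, 1]
  y <- as.vector(w %*% xc)
  mu <- colMeans(lfp)
  if (sd(y) > 0 && sd(mu) > 0 && cor(y, mu) < 0) y <- -y
  y
}

#' Denoise every trial of a session to a single channel
#'
#' Per trial: detrend each channel, reject artifact channels, then project the
#' surviving channels onto their first principal component. The result is
#' stored as `trial$denoised` (with the `channel_mask` alongside) and is the
#' input that [zscore_band_power()] and [lfp_band_features()] expect. PCA is
#' fitted per trial on the trial's own samples (baseline plus response).
#'
#' @param session a `pain_session`
#' @param robust_z_threshold threshold passed to [reject_artifact_channels()]
#' @return the session with `denoised` and `channel_mask` added to each trial
#' @export
preprocess_session <- function(session, robust_z_threshold = 3) {
  session$trials <- lapply(session$trials, function(tr) {
    det <- t(apply(tr$lfp, 1, detrend))
    if (nrow(det) >= 2) {
      mask <- reject_artifact_channels(det, robust_z_threshold)
    } else {
      mask <- structure(list(kept = TRUE, z = 0, reason = ""),
                        class = "channel_mask")
    }
    tr$channel_mask <- mask
    tr$denoised <- pca_first_component(det[mask$kept, , drop = FALSE])
    tr
  })
  session
}
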