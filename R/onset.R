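#' Estimate pain-signal onset from a decoding trajectory
#'
#' The dynamic range is `peak accuracy - chance level`; the onset is the first
#' time, scanning forward from the laser onset up to the peak, at which the
#' mean accuracy reaches `chance + f * dynamic range`. The default criterion
#' `f = 1/e` (~0.37) follows the convention used for sizing visual receptive
#' fields; `f = 1/2` is the common alternative. The crossing is linearly
#' interpolated between the straddling 50-ms bins, with the trajectory
#' anchored at (0, chance). A trajectory whose dynamic range does not exceed
#' the minimum-range gate (by default 3 x the across-shuffle SD of the chance
#' level) yields a "no detectable onset" result rather than a number.
#'
#' @param traj a `decoding_trajectory`
#' @param f threshold fraction in (0, 1]; `exp(-1)` or `0.5`
#' @param chance chance level; defaults to `traj$chance` (a [chance_level()]
#'   object or scalar)
#' @param chance_sd across-shuffle SD of the chance level; defaults to the
#'   attached chance object's SD
#' @param min_dynamic_range explicit gate on the dynamic range; defaults to
#'   `3 * chance_sd` (0 if no SD is available)
#' @return an object of class `onset_estimate`: `detected`, `onset_time`,
#'   `threshold_acc`, `peak_time`, `peak_acc`, `chance`, `dynamic_range`,
#'   `criterion`
#' @export
onset_from_trajectory <- function(traj, f = exp(-1), chance = NULL,
                                  chance_sd = NULL,
                                  min_dynamic_range = NULL) {
  stopifnot(inherits(traj, "decoding_trajectory"), f > 0, f <= 1)
  ch <- normalize_chance(chance) %||% normalize_chance(traj$chance)
  if (is.null(ch)) stop("a chance level is required (see chance_level())")
  if (!is.null(chance_sd)) ch$sd <- chance_sd
  gate <- min_dynamic_range %||% (if (is.finite(ch$sd)) 3 * ch$sd else 0)
  dr <- traj$peak_acc - ch$mean
  base <- list(criterion = f, chance = ch$mean, chance_sd = ch$sd,
               peak_acc = traj$peak_acc, peak_time = traj$peak_time,
               dynamic_range = dr)
  if (dr <= 0 || dr <= gate) {
    return(structure(c(base, list(detected = FALSE, onset_time = NA_real_,
                                  threshold_acc = NA_real_)),
                     class = "onset_estimate"))
  }
  thr <- ch$mean + f * dr
  pk <- which.max(traj$mean_acc)
  tt <- c(0, traj$times[seq_len(pk)])
  aa <- c(ch$mean, traj$mean_acc[seq_len(pk)])
  i <- which(aa >= thr)[1]
  onset <- if (i == 1) {
    0
  } else if (aa[i] == aa[i - 1]) {
    tt[i]
  } else {
    tt[i - 1] + (thr - aa[i - 1]) / (aa[i] - aa[i - 1]) * (tt[i] - tt[i - 1])
  }
  structure(c(base, list(detected = TRUE, onset_time = onset,
                         threshold_acc = thr)),
            class = "onset_estimate")
}

#' @export
print.onset_estimate <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "<onset_estimate> onset %.3f s (criterion f = %.3f, threshold %.3f)\n",
      x$onset_time, x$criterion, x$threshold_acc))
    cat(sprintf("  peak %.3f at %.2f s, chance %.3f, dynamic range %.3f\n",
                x$peak_acc, x$peak_time, x$chance, x$dynamic_range))
  } else {
    cat(sprintf(
      "<onset_estimate> no detectable onset (dynamic range %.3f below gate)\n",
      x$dynamic_range))
  }
  invisible(x)
}

#' Compare decoded onsets with withdrawal latencies
#'
#' Pairs each session's decoded onset with its mean withdrawal latency and
#' summarizes the signed differences (onset - withdrawal): median and IQR,
#' Spearman rank correlation, and a Mann-Whitney rank-sum comparison of the
#' two sets of timings.
#'
#' @param onsets list of `onset_estimate` objects (or numeric onsets),
#'   one per session
#' @param latencies numeric vector of per-session mean withdrawal latencies
#'   (s), same length and order
#' @return an object of class `onset_comparison`: a per-session `table`
#'   (onset, withdrawal, difference), `median_diff`, `iqr_diff`,
#'   `spearman_rho` and the `ranksum` result
#' @export
compare_onset_withdrawal <- function(onsets, latencies) {
  ot <- vapply(onsets, function(o) {
    if (inherits(o, "onset_estimate")) o$onset_time else as.numeric(o)
  }, numeric(1))
  if (length(ot) != length(latencies)) {
    stop("onsets and latencies must be paired (same length)")
  }
  d <- ot - latencies
  ok <- !is.na(ot) & !is.na(latencies)
  rho <- if (sum(ok) >= 3 && sd(ot[ok]) > 0 && sd(latencies[ok]) > 0) {
    cor(ot[ok], latencies[ok], method = "spearman")
  } else if (sum(ok) >= 1 && all(d[ok] == 0)) {
    1
  } else {
    NA_real_
  }
  structure(
    list(table = data.frame(onset = ot, withdrawal = latencies,
                            difference = d),
         median_diff = median(d, na.rm = TRUE),
         iqr_diff = IQR(d, na.rm = TRUE),
         spearman_rho = rho,
         ranksum = ranksum_compare(ot[ok], latencies[!is.na(latencies)])),
    class = "onset_comparison"
  )
}

#' @export
print.onset_comparison <- function(x, ...) {
  cat(sprintf(
    "<onset_comparison> %d pairs: median diff %.3f s (IQR %.3f), rho = %.3f\n",
    nrow(x$table), x$median_diff, x$iqr_diff, x$spearman_rho))
  cat(sprintf("  rank-sum p = %.4f\n", x$ranksum$p.value))
  invisible(x)
}
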