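# Config <-> plain-list conversion for JSON embedding (the ers_gain matrix
# is stored as a named list of rows so dimnames survive the round trip).
serialize_config <- function(config) {
  out <- unclass(config)
  out$ers_gain <- apply(config$ers_gain, 1, as.list, simplify = FALSE)
  out$latency_params <- lapply(config$latency_params, as.list)
  out
}

deserialize_config <- function(lst) {
  g <- do.call(rbind, lapply(lst$ers_gain, function(r) unlist(r)))
  rownames(g) <- names(lst$ers_gain)
  lst$ers_gain <- g
  lst$latency_params <- lapply(lst$latency_params, unlist)
  lst$intensity_drive <- unlist(lst$intensity_drive)
  lst$t_range <- unlist(lst$t_range)
  do.call(synth_config, lst)
}

#' Write a session to a plain-text JSON container
#'
#' One file per session: trial LFP matrices (row-major), per-unit spike time
#' lists, per-trial metadata (intensity, condition, withdrawal latency), the
#' class pair, seed and an embedded config snapshot. Values are stored with 8
#' significant digits; the container is text, so it diffs and checksums
#' cleanly.
#'
#' @param session a `pain_session`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_session <- function(session, path) {
  obj <- list(
    format = "pain-session/1",
    class_pair = session$class_pair,
    condition = session$condition,
    seed = session$seed,
    modulated_units = session$modulated_units,
    config = serialize_config(session$config),
    trials = lapply(session$trials, function(tr) {
      out <- list(trial_id = tr$trial_id,
                  intensity = tr$intensity$label,
                  withdrawal_latency = tr$withdrawal_latency,
                  lfp = tr$lfp,
                  spikes = lapply(tr$spikes, function(s) as.list(s)))
      if (!is.null(tr$denoised)) out$denoised <- tr$denoised
      out
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 8, na = "null",
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path path to a session JSON container
#' @return a `pain_session`
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(obj$format, "pain-session/1")) {
    stop("not a pain-session container: ", path)
  }
  config <- deserialize_config(obj$config)
  trials <- lapply(obj$trials, function(tr) {
    lfp <- tr$lfp
    if (!is.matrix(lfp)) lfp <- matrix(unlist(lfp), nrow = length(tr$lfp),
                                       byrow = TRUE)
    list(trial_id = tr$trial_id,
         intensity = stimulus_intensity(tr$intensity),
         condition = obj$condition,
         lfp = lfp,
         spikes = lapply(tr$spikes, function(s) as.numeric(unlist(s))),
         withdrawal_latency = if (is.null(tr$withdrawal_latency))
           NA_real_ else tr$withdrawal_latency,
         denoised = if (is.null(tr$denoised)) NULL else
           as.numeric(tr$denoised))
  })
  structure(
    list(trials = trials, class_pair = obj$class_pair,
         condition = obj$condition,
         modulated_units = as.integer(obj$modulated_units),
         config = config, seed = as.integer(obj$seed)),
    class = "pain_session"
  )
}
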