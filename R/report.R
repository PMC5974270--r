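#' Mann-Whitney rank-sum comparison of two groups
#'
#' Two-sample rank-sum test on the group medians (exact where feasible,
#' normal approximation with mid-ranked ties otherwise), the default test
#' used throughout the pipeline's group comparisons. The p-value is invariant
#' to monotone transformations of the pooled values.
#'
#' @param group_a,group_b non-empty numeric vectors
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#' @return list with `statistic` (Mann-Whitney U / Wilcoxon W), `p.value`,
#'   group sizes `n` and a `method` string
#' @examples
#' ranksum_compare(c(1, 2, 3), c(10, 11, 12))$p.value  # exact p = 0.1
#' @export
ranksum_compare <- function(group_a, group_b, alternative = "two.sided") {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = alternative)
  )
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       n = c(n_a = length(group_a), n_b = length(group_b)),
       method = "Mann-Whitney rank-sum")
}

run_stage <- function(stage, context, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed for ", context, ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full decoding pipeline end to end
#'
#' For every condition x stimulus-pair combination: generates a synthetic
#' session, denoises it, computes band-power z-score tables, builds the
#' requested feature modalities, decodes the accuracy trajectory with its
#' permutation chance level, and estimates onsets under each criterion.
#' Tidy CSV tables (z-scores, trajectories, onsets) are written to `out_dir`
#' together with a JSON run manifest listing every output file with its MD5
#' checksum, the seeds used and per-stage wall-clock times. Deterministic
#' stages reproduce their checksums when re-run with the same seeds.
#'
#' @param config a [synth_config()]
#' @param out_dir output directory (created if needed)
#' @param conditions subset of `c("naive", "CFA")`
#' @param pairs list of two-label stimulus pairs
#' @param modalities subset of `c("spike", "lfp_all", "combined")`
#' @param n_mc,folds,n_shuffle,spec decoding parameters (see
#'   [decode_trajectory()] and [chance_level()])
#' @param bins evaluation bin indices for the trajectories (default: all)
#' @param zscore_bands bands for the z-score tables
#' @param criteria named vector of onset threshold fractions
#' @param seed master seed; each condition/pair derives its own substream
#' @return (invisibly) list with the `manifest`, the `onsets` data frame and
#'   the per-combination `trajectories`
#' @export
run_pipeline <- function(config = synth_config(), out_dir,
                         conditions = c("naive", "CFA"),
                         pairs = list(c("NS", "LS"), c("NS", "HS"),
                                      c("LS", "HS")),
                         modalities = c("spike", "lfp_all", "combined"),
                         n_mc = 20, folds = 5, n_shuffle = 100,
                         spec = svm_spec(), bins = NULL,
                         zscore_bands = c("theta", "high_gamma"),
                         criteria = c("1/e" = exp(-1), "1/2" = 0.5),
                         seed = config$seed) {
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  timing <- list()
  onset_rows <- list()
  trajectories <- list()
  ci <- 0L
  for (cond in conditions) {
    for (pair in pairs) {
      ci <- ci + 1L
      tag <- paste0(cond, "_", pair[1], "-", pair[2])
      t_start <- proc.time()[["elapsed"]]
      ses_seed <- derive_seed(seed, ci)
      ses <- run_stage("synth", tag,
                       make_session(config, pair, cond, seed = ses_seed))
      ses <- run_stage("preprocess", tag, preprocess_session(ses))
      zs <- run_stage("spectral", tag, do.call(rbind, lapply(
        zscore_bands, function(b) zscore_band_power(ses, b))))
      zfile <- file.path(out_dir, paste0("zscores_", tag, ".csv"))
      write.csv(zs, zfile, row.names = FALSE)
      files <- c(files, zfile)
      fs_spike <- run_stage("features", tag, cumulative_spike_features(ses))
      fs_lfp <- run_stage("features", tag, lfp_band_features(ses))
      feats <- list(spike = fs_spike, lfp_all = fs_lfp,
                    combined = combine_features(fs_spike, fs_lfp))
      noxious <- setdiff(pair, "NS")
      lat <- session_latencies(ses)
      mean_wd <- mean(lat[session_labels(ses) %in% noxious], na.rm = TRUE)
      for (mod in modalities) {
        fm <- feats[[mod]]
        ch <- run_stage("decode", tag,
                        chance_level(fm, spec = spec, n_shuffle = n_shuffle,
                                     folds = folds,
                                     seed = derive_seed(seed, ci, 2)))
        traj <- run_stage("decode", tag,
                          decode_trajectory(fm, spec = spec, n_mc = n_mc,
                                            folds = folds, bins = bins,
                                            seed = derive_seed(seed, ci, 3),
                                            chance = ch))
        trajectories[[paste0(tag, "_", mod)]] <- traj
        tfile <- file.path(out_dir, paste0("trajectory_", tag, "_", mod,
                                           ".csv"))
        write.csv(data.frame(time = traj$times, mean_acc = traj$mean_acc,
                             sem_acc = traj$sem_acc, chance = ch$mean,
                             chance_sd = ch$sd),
                  tfile, row.names = FALSE)
        files <- c(files, tfile)
        for (cn in names(criteria)) {
          oe <- run_stage("onset", tag,
                          onset_from_trajectory(traj, f = criteria[[cn]]))
          onset_rows[[length(onset_rows) + 1L]] <- data.frame(
            condition = cond, pair = paste(pair, collapse = "-"),
            modality = mod, criterion = cn, detected = oe$detected,
            onset = oe$onset_time, peak_acc = oe$peak_acc,
            peak_time = oe$peak_time, chance = oe$chance,
            chance_sd = oe$chance_sd, dynamic_range = oe$dynamic_range,
            mean_withdrawal = mean_wd, stringsAsFactors = FALSE
          )
        }
      }
      timing[[tag]] <- proc.time()[["elapsed"]] - t_start
    }
  }
  onsets <- do.call(rbind, onset_rows)
  ofile <- file.path(out_dir, "onsets.csv")
  write.csv(onsets, ofile, row.names = FALSE)
  files <- c(files, ofile)
  manifest <- list(
    package = "nocidecode",
    version = as.character(utils::packageVersion("nocidecode")),
    seed = seed,
    config = serialize_config(config),
    n_mc = n_mc, folds = folds, n_shuffle = n_shuffle,
    files = as.list(tools::md5sum(files)),
    elapsed_s = timing
  )
  mfile <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mfile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(manifest = manifest, onsets = onsets,
                 trajectories = trajectories))
}

#' Verify a pipeline run against its manifest
#'
#' Recomputes the MD5 checksum of every file listed in a run manifest and
#' reports missing or altered files.
#'
#' @param manifest_path path to a `manifest.json` written by [run_pipeline()]
#' @return (invisibly) logical: TRUE if every listed file exists with its
#'   recorded checksum. Mismatches are reported via warning.
#' @export
verify_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  ok <- TRUE
  for (f in names(man$files)) {
    if (!file.exists(f)) {
      warning("missing file: ", f)
      ok <- FALSE
    } else if (!identical(unname(tools::md5sum(f)), man$files[[f]])) {
      warning("checksum mismatch: ", f)
      ok <- FALSE
    }
  }
  invisible(ok)
}
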