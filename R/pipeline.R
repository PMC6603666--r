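#' Per-minute feature table for a synthetic cohort
#'
#' Runs each subject's record through epoching (optionally the full
#' artifact-removal chain first) and feature extraction, then joins the
#' per-minute reference index and state labels.
#'
#' @param cohort A list of `synthetic_patient` objects ([simulate_cohort()]).
#' @param preprocess If `TRUE`, apply [preprocess_pipeline()] to each record
#'   (use when records are raw/contaminated or not at 100 Hz); otherwise
#'   records are epoched directly (clean 100 Hz cohorts).
#' @param config [preprocess_config()] used when `preprocess = TRUE`.
#' @param pe_cfg,spec_cfg Feature configurations.
#' @return Tibble with columns `subject`, `minute`, `pe`, `br`, `sef95`,
#'   `sfs`, `flags`, `ref_index`, `state`.
#' @export
cohort_features <- function(cohort, preprocess = FALSE,
                            config = preprocess_config(),
                            pe_cfg = pe_config(),
                            spec_cfg = spectral_config()) {
  subjects <- names(cohort) %||% sprintf("subject_%02d", seq_along(cohort))
  rows <- purrr::map2(cohort, subjects, function(pat, nm) {
    epochs <- if (preprocess || abs(pat$record$fs - 100) > 1e-9) {
      preprocess_pipeline(pat$record, config = config)
    } else {
      epoch_record(pat$record)
    }
    if (nrow(epochs) == 0) return(NULL)
    feats <- extract_features(epochs, fs = 100, pe_cfg = pe_cfg,
                              config = spec_cfg)
    feats$subject <- nm
    dplyr::inner_join(feats, pat$minutes, by = "minute")
  })
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "subject", "minute", dplyr::all_of(doa_features()),
                "flags", "ref_index", "state")
}

#' Run the end-to-end synthetic study
#'
#' Orchestrates simulate -> (optional artifact injection + preprocessing) ->
#' feature extraction -> LOOCV training/evaluation, writing flat-file
#' artifacts and a reproducibility manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_subjects Cohort size (default 16).
#' @param fs Simulation sampling rate; 128 engages the full preprocessing
#'   chain (resampling to 100 Hz), 100 with `inject = FALSE` skips it.
#' @param inject If `TRUE`, EOG/EMG/outlier artifacts are injected before
#'   preprocessing.
#' @param model_kind `"ann"`, `"svr"`, or `"both"`.
#' @param seed Master seed; all stage seeds derive from it.
#' @param hyper [ann_control()] for ANN training.
#' @param write_records If `TRUE`, also write each subject's EEG as EDF
#'   (large; off by default).
#' @return A `run_manifest` list: config, seeds, artifact checksums, and the
#'   evaluation report(s).
#' @export
run_pipeline <- function(out_dir, n_subjects = 16, fs = 100, inject = FALSE,
                         model_kind = c("ann", "svr", "both"), seed = 1,
                         hyper = ann_control(), write_records = FALSE) {
  model_kind <- match.arg(model_kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 4L)

  cohort <- simulate_cohort(n_subjects = n_subjects, fs = fs, seed = seeds[1])
  if (inject) {
    art_seeds <- derive_seeds(seeds[2], n_subjects)
    for (i in seq_along(cohort)) {
      cohort[[i]]$record <- inject_artifacts(
        cohort[[i]]$record, eog_rate = 2, emg_rate = 1, outlier_rate = 1,
        seed = art_seeds[i]
      )
    }
  }
  for (i in seq_along(cohort)) {
    write_index_series(
      dplyr::rename(cohort[[i]]$minutes, value = "ref_index"),
      file.path(out_dir, sprintf("%s_ref_index.csv", names(cohort)[i]))
    )
    if (write_records) {
      write_record(cohort[[i]]$record,
                   file.path(out_dir, sprintf("%s.edf", names(cohort)[i])))
    }
  }

  feats <- cohort_features(cohort, preprocess = inject || abs(fs - 100) > 1e-9)
  utils::write.csv(as.data.frame(feats),
                   file.path(out_dir, "features.csv"), row.names = FALSE)

  kinds <- if (model_kind == "both") c("ann", "svr") else model_kind
  reports <- list()
  for (k in kinds) {
    ev <- loocv(feats, model_kind = k, hyper = hyper, seed = seeds[3])
    reports[[k]] <- ev
    report <- list(
      model_kind = k,
      accuracy = ev$accuracy,
      sensitivities = setNames(as.list(ev$sensitivities$sensitivity),
                               as.character(ev$sensitivities$state)),
      pearson_r = ev$pearson$r, pearson_p = ev$pearson$p_value,
      bland_altman = as.list(ev$bland_altman),
      per_fold = ev$per_fold
    )
    jsonlite::write_json(report, file.path(out_dir, sprintf("report_%s.json", k)),
                         auto_unbox = TRUE, digits = NA, na = "null")
    utils::write.csv(as.data.frame(unclass(ev$confusion)),
                     file.path(out_dir, sprintf("confusion_%s.csv", k)))
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("doafuse")),
    config = list(
      n_subjects = n_subjects, fs = fs, inject = inject,
      model_kind = model_kind, hyper = unclass(hyper)
    ),
    seed = as.integer(seed),
    stage_seeds = as.list(setNames(seeds, c("simulate", "artifacts",
                                            "train", "reserved"))),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(c(manifest, list(reports = reports)),
                      class = "run_manifest"))
}
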