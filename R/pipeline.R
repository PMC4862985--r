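CONFIG_BLOCKS <- list(
  protocol = c("baseline_mmHg", "step_mmHg", "block_durations_s",
               "inter_block_s", "lead_in_s", "tail_s"),
  qc = c("n_discard", "max_censor", "fd_threshold_mm"),
  mapping = c("lag_search", "max_lag", "signal_floor", "baseline_tol_mmHg",
              "write_maps"),
  stats = c("alpha", "variables"),
  paths = c("subjects", "out_dir")
)

#' Build and validate a pipeline run configuration
#'
#' All defaults are materialised into the returned object so a serialized
#' config fully documents the run. Unknown keys are rejected.
#'
#' @param protocol,qc,mapping,stats,paths Named lists overriding block
#'   defaults (see `cvrkit:::CONFIG_BLOCKS` for the accepted keys).
#' @param seed Integer seed recorded in the manifest and used for any
#'   stochastic stage.
#' @return A `run_config` object (a named list).
#' @export
run_config <- function(protocol = list(), qc = list(), mapping = list(),
                       stats = list(), paths = list(), seed = 1L) {
  blocks <- list(protocol = protocol, qc = qc, mapping = mapping,
                 stats = stats, paths = paths)
  for (b in names(blocks)) {
    unknown <- setdiff(names(blocks[[b]]), CONFIG_BLOCKS[[b]])
    if (length(unknown)) {
      cvr_abort(sprintf("Unknown key(s) in `%s` block: %s.", b,
                        paste(unknown, collapse = ", ")), "invalid_argument")
    }
  }
  cfg <- list(
    protocol = modifyList(list(baseline_mmHg = 35, step_mmHg = 10,
                               block_durations_s = c(45, 130),
                               inter_block_s = 90, lead_in_s = 60,
                               tail_s = 185), protocol),
    qc = modifyList(list(n_discard = 3L, max_censor = 9L,
                         fd_threshold_mm = 0.9), qc),
    mapping = modifyList(list(lag_search = FALSE, max_lag = 5L,
                              signal_floor = NULL, baseline_tol_mmHg = 1,
                              write_maps = FALSE), mapping),
    stats = modifyList(list(alpha = 0.05,
                            variables = c("sss", "scat2", "wm_cvr", "gm_cvr",
                                          "brain_cvr", "wm_volume_cm3",
                                          "gm_volume_cm3")), stats),
    paths = modifyList(list(subjects = NULL, out_dir = NULL), paths),
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  top_unknown <- setdiff(names(raw), c(names(CONFIG_BLOCKS), "seed"))
  if (length(top_unknown)) {
    cvr_abort(sprintf("Unknown top-level config key(s): %s.",
                      paste(top_unknown, collapse = ", ")), "invalid_argument")
  }
  run_config(protocol = raw$protocol %||% list(), qc = raw$qc %||% list(),
             mapping = raw$mapping %||% list(), stats = raw$stats %||% list(),
             paths = raw$paths %||% list(), seed = raw$seed %||% 1L)
}

#' Write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[cvrkit] ", fmt), ...))
}

#' Run the full per-subject CVR pipeline and cohort analysis
#'
#' For every row of the subjects table: read the capnograph trace, detect
#' end-tidal points, resample them onto the BOLD TR grid, read BOLD and
#' tissue masks, apply QC (discard + censoring), fit the voxelwise CVR map,
#' and summarise tissue ROI indexes and volumes. The per-subject ROI rows
#' are merged with the subject covariates into a cohort table, on which the
#' statistical battery runs. All outputs are written under
#' `config$paths$out_dir` with a manifest (config hash + seed); reruns with
#' the same config and inputs are byte-identical.
#'
#' The subjects CSV needs columns `subject_id, group, visit, age_years, sex,
#' scat2, sss, days_post_injury, bold_file, capno_file, masks_file` and
#' optionally `censor_file` (one censored volume index per line).
#'
#' @param config A [run_config()] with `paths$subjects` and `paths$out_dir`
#'   set.
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with `cohort`, `stats`, `demographics`, and the
#'   output file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$paths$subjects) || is.null(config$paths$out_dir)) {
    cvr_abort("Config must set paths$subjects and paths$out_dir.",
              "invalid_argument")
  }
  subjects <- readr::read_csv(config$paths$subjects, show_col_types = FALSE)
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "qc"), recursive = TRUE, showWarnings = FALSE)

  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   seed = config$seed, n_subjects = nrow(subjects),
                   status = "running", outputs = character())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_manifest()

  base_dir <- dirname(config$paths$subjects)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))

  rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sub <- subjects[i, ]
    sid <- sub$subject_id
    stage <- "read-capno"
    row <- tryCatch({
      trace <- read_capno_csv(resolve(sub$capno_file))
      stage <- "read-bold"
      bold <- read_bold_nifti(resolve(sub$bold_file))
      stage <- "read-masks"
      masks <- read_tissue_masks_nifti(resolve(sub$masks_file))
      stage <- "end-tidal"
      ets <- detect_end_tidal(trace)
      reg <- resample_to_tr(ets, tr_s = bold$tr_s, n_volumes = dim(bold$data)[4])
      stage <- "qc"
      censor <- integer()
      if ("censor_file" %in% names(sub) && !is.na(sub$censor_file) &&
          nzchar(sub$censor_file)) {
        censor <- as.integer(readLines(resolve(sub$censor_file)))
      }
      qc <- qc_spec(n_discard = config$qc$n_discard, censor_volumes = censor,
                    max_censor = config$qc$max_censor)
      stage <- "map"
      map <- compute_cvr_map(
        bold, reg, qc = qc, mask = masks,
        baseline_mmHg = config$protocol$baseline_mmHg,
        baseline_tol_mmHg = config$mapping$baseline_tol_mmHg,
        signal_floor = config$mapping$signal_floor,
        lag_search = config$mapping$lag_search,
        max_lag = config$mapping$max_lag)
      stage <- "summarize"
      roi <- summarize_rois(map, masks)
      jsonlite::write_json(map$qc_report,
                           file.path(out_dir, "qc", paste0(sid, "_visit", sub$visit, "_qc.json")),
                           auto_unbox = TRUE, digits = NA)
      if (isTRUE(config$mapping$write_maps)) {
        write_cvr_map(map, file.path(out_dir, paste0(sid, "_visit", sub$visit)))
      }
      pipeline_log(quiet, "subject %s visit %s: %d voxels valid (%.1f%%), lag %d",
                   sid, sub$visit, sum(map$valid), map$qc_report$pct_valid,
                   map$qc_report$lag_volumes)
      dplyr::bind_cols(
        sub[intersect(c("subject_id", "group", "visit", "age_years", "sex",
                        "days_post_injury", "scat2", "sss"), names(sub))],
        roi,
        tibble::tibble(petco2_min = min(ets$petco2_mmHg),
                       petco2_max = max(ets$petco2_mmHg))
      )
    }, cvrkit_error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_subject <<- sid
      manifest$failed_stage <<- stage
      write_manifest()
      cvr_abort(sprintf("Pipeline failed for subject %s at stage `%s`: %s",
                        sid, stage, conditionMessage(e)), "pipeline")
    })
    rows[[i]] <- row
  }

  cohort <- dplyr::bind_rows(rows)
  files <- c(cohort = file.path(out_dir, "cohort.csv"),
             stats = file.path(out_dir, "stats.csv"),
             demographics = file.path(out_dir, "demographics.csv"))
  readr::write_csv(cohort, files["cohort"])

  pipeline_log(quiet, "cohort assembled: %d rows; running statistics", nrow(cohort))
  stats_tbl <- run_cohort_analyses(cohort, alpha = config$stats$alpha,
                                   variables = intersect(config$stats$variables,
                                                         names(cohort)))
  readr::write_csv(stats_tbl, files["stats"])
  demo <- summarize_demographics(cohort)
  readr::write_csv(demo, files["demographics"])

  manifest$status <- "ok"
  manifest$outputs <- unname(files)
  write_manifest()

  invisible(list(cohort = cohort, stats = stats_tbl, demographics = demo,
                 files = files, manifest = manifest))
}

#' Simulate a complete imaging study on disk
#'
#' Generates a synthetic cohort, then writes one digital phantom per
#' subject-visit whose GM/WM generating gains equal that subject's tabular
#' CVR indexes, together with a simulated capnograph trace, producing the
#' exact input layout [run_pipeline()] consumes. This closes the loop: the
#' pipeline's recovered tissue CVR indexes can be compared against the
#' cohort table that generated the images.
#'
#' @param out_dir Output directory.
#' @param params A [cohort_params()] (use small `n_*` for quick runs).
#' @param grid_dims Phantom grid.
#' @param n_volumes BOLD volumes per run.
#' @param tr_s Repetition time (s).
#' @param noise_scale Phantom noise multiplier.
#' @param capno_noise_sd_mmHg Plateau noise of the simulated capnograph.
#' @param seed Base seed; per-subject seeds are derived from it.
#' @return The path of the written subjects CSV.
#' @export
simulate_study <- function(out_dir, params = cohort_params(),
                           grid_dims = c(12, 12, 8), n_volumes = 160,
                           tr_s = 2, noise_scale = 1,
                           capno_noise_sd_mmHg = 0.5, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(params, seed = seed)
  proto <- hypercapnia_protocol()
  reg <- build_protocol_waveform(proto, tr_s = tr_s, n_volumes = n_volumes)

  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    rec <- cohort[i, ]
    tag <- sprintf("%s_visit%d", rec$subject_id, rec$visit)
    comp <- tissue_presets("healthy-control")
    comp$true_cvr_pct_per_mmHg[comp$tissue == "gm"] <- rec$gm_cvr
    comp$true_cvr_pct_per_mmHg[comp$tissue == "wm"] <- rec$wm_cvr
    sub_seed <- (seed * 10007L + i * 97L) %% .Machine$integer.max
    spec <- phantom_spec(grid_dims = grid_dims, compartments = comp,
                         tr_s = tr_s, n_volumes = n_volumes,
                         baseline_mmHg = proto$baseline_mmHg,
                         noise_scale = noise_scale, seed = sub_seed)
    ph <- generate_phantom(spec, reg)
    bold_file <- file.path(out_dir, paste0(tag, "_bold.nii.gz"))
    masks_file <- file.path(out_dir, paste0(tag, "_masks.nii.gz"))
    capno_file <- file.path(out_dir, paste0(tag, "_capno.csv"))
    write_bold_nifti(ph$bold, bold_file)
    write_tissue_masks_nifti(ph$masks, masks_file)
    trace <- simulate_capnograph(proto, noise_sd_mmHg = capno_noise_sd_mmHg,
                                 duration_s = n_volumes * tr_s,
                                 seed = sub_seed + 1L)
    write_capno_csv(trace, capno_file)
    dplyr::bind_cols(
      rec[c("subject_id", "group", "visit", "age_years", "sex",
            "days_post_injury", "scat2", "sss")],
      tibble::tibble(bold_file = basename(bold_file),
                     capno_file = basename(capno_file),
                     masks_file = basename(masks_file))
    )
  })
  subjects <- dplyr::bind_rows(rows)
  path <- file.path(out_dir, "subjects.csv")
  readr::write_csv(subjects, path)
  invisible(path)
}
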