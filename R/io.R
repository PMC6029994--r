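#' @title File formats and the pipeline driver
#' @name io_cli
#' @description
#' Plain-text CSV/JSON interchange for TACs, blood curves, blood samples
#' and fit results, plus the end-to-end simulate -> fit -> refit -> metrics
#' pipeline. No imaging formats are touched: image-domain processing is out
#' of scope.
NULL

read_csv_checked <- function(path, cols) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(d))
  if (length(missing))
    stop_invalid("missing column(s) ", paste(missing, collapse = ", "),
                 " in ", path)
  for (cc in setdiff(cols, "region"))
    if (!is.numeric(d[[cc]]))
      stop_invalid("non-numeric values in column '", cc, "' of ", path)
  d
}

#' Read regional TACs from CSV
#'
#' Expects columns `region,frame_start_min,frame_duration_min,activity_kBq_ml`,
#' one row per region-frame. All regions must share one contiguous,
#' non-overlapping frame schedule.
#'
#' @param path CSV file path
#' @return named list of [region_tac]
#' @export
read_tacs <- function(path) {
  d <- read_csv_checked(path, c("region", "frame_start_min",
                                "frame_duration_min", "activity_kBq_ml"))
  regions <- unique(d$region)
  first <- d[d$region == regions[1], ]
  ord <- order(first$frame_start_min)
  sched <- frame_schedule(first$frame_start_min[ord],
                          first$frame_duration_min[ord])
  out <- lapply(regions, function(rg) {
    dd <- d[d$region == rg, ]
    dd <- dd[order(dd$frame_start_min), ]
    if (!isTRUE(all.equal(dd$frame_start_min, sched$starts)) ||
        !isTRUE(all.equal(dd$frame_duration_min, sched$durations)))
      stop_invalid("region '", rg, "' does not share the common schedule")
    region_tac(rg, sched, dd$activity_kBq_ml)
  })
  stats::setNames(out, regions)
}

#' Write regional TACs to CSV
#'
#' @param tacs list of [region_tac]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_tacs <- function(tacs, path) {
  rows <- do.call(rbind, lapply(tacs, function(x)
    data.frame(region = x$region, frame_start_min = x$schedule$starts,
               frame_duration_min = x$schedule$durations,
               activity_kBq_ml = x$values)))
  utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a whole-blood curve from CSV (`time_min,activity_kBq_ml`)
#' @param path CSV file path
#' @return [whole_blood_curve]
#' @export
read_blood_curve <- function(path) {
  d <- read_csv_checked(path, c("time_min", "activity_kBq_ml"))
  whole_blood_curve(d$time_min, d$activity_kBq_ml)
}

#' Write a whole-blood curve to CSV
#' @param wb [whole_blood_curve]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_blood_curve <- function(wb, path) {
  utils::write.csv(data.frame(time_min = wb$times,
                              activity_kBq_ml = wb$activities),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read parent-fraction samples from CSV (`time_min,parent_fraction`)
#' @param path CSV file path
#' @return data.frame with `time_min`, `parent_fraction`
#' @export
read_parent_fractions <- function(path) {
  read_csv_checked(path, c("time_min", "parent_fraction"))
}

#' Read plasma/whole-blood samples (`time_min,plasma_kBq_ml,wholeblood_kBq_ml`)
#' @param path CSV file path
#' @return data.frame with the three columns
#' @export
read_plasma_samples <- function(path) {
  read_csv_checked(path, c("time_min", "plasma_kBq_ml", "wholeblood_kBq_ml"))
}

#' Write a synthetic study to a directory
#'
#' Emits `tacs.csv`, `wb.csv`, `pf.csv`, `samples.csv` and `truth.json`.
#'
#' @param study [generate_study] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tacs(study$tacs, file.path(dir, "tacs.csv"))
  write_blood_curve(study$wb, file.path(dir, "wb.csv"))
  utils::write.csv(data.frame(time_min = study$samples$pf_times,
                              parent_fraction = study$samples$pf),
                   file.path(dir, "pf.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(time_min = study$samples$times,
                              plasma_kBq_ml = study$samples$plasma,
                              wholeblood_kBq_ml = study$samples$wholeblood),
                   file.path(dir, "samples.csv"), row.names = FALSE, quote = FALSE)
  tr <- study$truth
  jsonlite::write_json(list(
    profile = tr$profile, seed = study$seed, noise = study$noise,
    feng = unclass(tr$feng), hill = unclass(tr$hill), ratio = unclass(tr$ratio),
    kinetics = lapply(tr$kinetics, unclass)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(config[setdiff(names(config), NULL)], file = tf)
  unname(tools::md5sum(tf))
}

#' Write a SIME fit result to JSON
#'
#' Serialises all estimated parameters, macroparameters, convergence
#' diagnostics, the seed, and an MD5 hash of the configuration (so any
#' bound or tolerance change is visible in the provenance).
#'
#' @param result converged [sime_result]
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "sime_result"))
  aif <- if (result$mode == "constrained")
    list(hill = unclass(result$aif_params$hill),
         ratio = unclass(result$aif_params$ratio))
  else list(feng = unclass(result$aif_params))
  jsonlite::write_json(list(
    mode = result$mode, converged = result$converged,
    aif_params = aif,
    kinetics = lapply(result$kinetics, function(k)
      unclass(k)[c("K1", "k2", "k3", "k4", "vb")]),
    vt = as.list(result$vt), bp = as.list(result$bp),
    reference = result$reference, cost = result$cost,
    convergence = result$convergence,
    seed = result$config$seed, config_hash = config_hash(result$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a SIME result JSON back into a list
#' @param path JSON path written by [write_result]
#' @return list mirroring the serialised fields
#' @export
read_result <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Run the full simulate -> fit -> refit -> metrics pipeline
#'
#' Orchestrates a complete synthetic experiment: generates (or loads) a
#' study, fits the requested SIME mode(s), and summarises V_T / BP_ND
#' recovery against the generating truth. Any stage failure halts with a
#' stage-tagged error.
#'
#' @param mode `"constrained"`, `"original"` or `"both"`
#' @param profile truth profile for the simulator
#' @param noise noise level
#' @param seed master seed
#' @param config [sime_config]
#' @param study optional pre-built [generate_study] result (skips simulate)
#' @param out_dir optional directory for result JSON / study CSV artefacts
#' @param verbose print one line per completed stage
#' @return list with `study`, per-mode `fits`, and `summary` (data.frame of
#'   region, mode, true and estimated V_T, percent error)
#' @export
run_pipeline <- function(mode = c("constrained", "original", "both"),
                         profile = "default", noise = "none", seed = 1,
                         config = sime_config(seed = seed), study = NULL,
                         out_dir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    if (verbose)
      message(sprintf("[%s] done in %.1fs", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    r
  }
  study <- stage("simulate", {
    if (is.null(study)) generate_study(generate_truth(profile, seed),
                                       noise, seed = seed)
    else study
  })
  if (!is.null(out_dir)) stage("write-study", write_study(study, out_dir))
  modes <- if (mode == "both") c("constrained", "original") else mode
  fits <- lapply(modes, function(md) stage(paste0("fit-", md), {
    fit_sime(sime_problem(unname(study$tacs), mode = md,
                          wb = if (md == "constrained") study$wb else NULL),
             config)
  }))
  names(fits) <- modes
  summary <- stage("metrics", {
    true_vt <- vapply(study$truth$kinetics, volume_of_distribution, 0)
    do.call(rbind, lapply(modes, function(md) {
      est <- fits[[md]]$vt[names(true_vt)]
      data.frame(mode = md, region = names(true_vt), vt_true = unname(true_vt),
                 vt_est = unname(est),
                 pct_error = unname(percent_error(est, true_vt)))
    }))
  })
  if (!is.null(out_dir))
    for (md in modes)
      stage(paste0("write-", md),
            write_result(fits[[md]], file.path(out_dir,
                                               paste0("result_", md, ".json"))))
  list(study = study, fits = fits, summary = summary)
}
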