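# CSV/JSON interfaces and the end-to-end analysis pipeline.
# File boundary units: seconds and mM; internal units: minutes and mM.

CURVE_COLUMNS <- c("patient_id", "time_s", "cp_mM", "ctis_mM")

#' Read per-patient concentration curves from CSV
#'
#' Expects the header `patient_id,time_s,cp_mM,ctis_mM`, one row per sample.
#' Rows may arrive in any order; they are sorted by time within patient.
#' Times are converted from seconds to minutes.
#'
#' @param path CSV file path.
#' @return Named list, one element per patient: `list(cp = conc_ts,
#'   ctis = conc_ts)`.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(CURVE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("time_s", "cp_mM", "ctis_mM")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | !is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row(s): %s",
                   col, paste(utils::head(bad, 5), collapse = ", ")))
    df[[col]] <- v
  }
  dup <- duplicated(df[, c("patient_id", "time_s")])
  if (any(dup))
    stop("duplicate (patient_id, time_s) at data row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  out <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$time_s), ]
    list(cp = conc_ts(d$time_s / 60, d$cp_mM, d$patient_id[1L]),
         ctis = conc_ts(d$time_s / 60, d$ctis_mM, d$patient_id[1L]))
  })
  out[order(names(out))]
}

#' Write per-patient concentration curves to CSV
#'
#' Inverse of [read_curves()]: `write_curves` then `read_curves` restores the
#' same series to full precision.
#'
#' @param curves A named list as returned by [read_curves()], or an
#'   `aif_study` from [simulate_study()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "aif_study"))
    curves <- stats::setNames(
      lapply(curves$patients, function(p) list(cp = p$cp, ctis = p$ctis)),
      vapply(curves$patients, `[[`, "", "patient_id"))
  rows <- lapply(names(curves), function(id) {
    cp <- curves[[id]]$cp
    ct <- curves[[id]]$ctis
    data.frame(patient_id = id, time_s = cp$times * 60,
               cp_mM = cp$values, ctis_mM = ct$values)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the ground-truth rate-constant sidecar
#'
#' JSON of the form `{"patient_01": {"k1": ..., "k2": ...}, ...}`.
#'
#' @param study An `aif_study`.
#' @param path JSON path.
#' @return `path` invisibly (`write`), or a named list (`read`).
#' @export
write_ground_truth <- function(study, path) {
  stopifnot(inherits(study, "aif_study"))
  gt <- stats::setNames(
    lapply(study$patients, function(p) list(k1 = p$k1, k2 = p$k2)),
    vapply(study$patients, `[[`, "", "patient_id"))
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) jsonlite::read_json(path)

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param curves_csv Optional input CSV of measured curves; if `NULL` the
#'   study in `study_cfg` is simulated instead.
#' @param study_cfg A [study_config()] used when `curves_csv` is `NULL`.
#' @param mode Density mode for [fit_aif_density()].
#' @param solver Maximum-entropy solver.
#' @param alpha MAP prior weight.
#' @param use_fitted_aif Rebuild the design matrix's AIF column from the
#'   fitted density before the MAP step (the blind-AIF pipeline); otherwise
#'   the measured plasma curve is used directly.
#' @param seed Integer seed stamped into all outputs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("aifmem_"),
                            curves_csv = NULL,
                            study_cfg = study_config(),
                            mode = c("value_density", "time_density"),
                            solver = c("dual_descent", "tlbo"),
                            alpha = 0.01,
                            use_fitted_aif = FALSE,
                            seed = 1L) {
  if (!is.null(curves_csv) && !file.exists(curves_csv))
    stop("input file not found: ", curves_csv)
  structure(list(out_dir = out_dir, curves_csv = curves_csv,
                 study_cfg = study_cfg, mode = match.arg(mode),
                 solver = match.arg(solver), alpha = alpha,
                 use_fitted_aif = isTRUE(use_fitted_aif),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
  invisible(NULL)
}

# CSV with a leading '#'-comment stamp line (seed + config hash).
write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full blind-AIF analysis pipeline
#'
#' Stages: simulate (or read) the study curves; fit the maximum-entropy AIF
#' density per patient; estimate kinetic parameters by MAP (with the LLSQ
#' comparator); compute goodness metrics. Writes `curves.csv`,
#' `densities/<patient>.json`, `kinetics.csv` and `metrics.csv` into
#' `cfg$out_dir`; every artifact embeds the seed and a config hash. Any stage
#' failure aborts with the stage name, removing partial outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Emit stage-progress messages.
#' @return Invisibly, a list with `kinetics` and `metrics` data frames,
#'   per-patient `fits`, `seed`, `config_hash`, `out_dir`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(cfg$out_dir, "densities"), showWarnings = FALSE)
  created <- character(0)
  fail <- function(stage, e) {
    unlink(created)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  stamp <- sprintf("# seed=%d config_hash=%s", cfg$seed, hash)

  # stage: input curves
  curves <- tryCatch({
    if (is.null(cfg$curves_csv)) {
      scfg <- cfg$study_cfg
      scfg$seed <- cfg$seed
      study <- simulate_study(scfg)
      stats::setNames(
        lapply(study$patients, function(p)
          list(cp = p$cp, ctis = p$ctis, k1 = p$k1, k2 = p$k2)),
        vapply(study$patients, `[[`, "", "patient_id"))
    } else read_curves(cfg$curves_csv)
  }, error = function(e) fail("input", e))
  pipeline_log(verbose, "input: %d patients", length(curves))

  curves_path <- file.path(cfg$out_dir, "curves.csv")
  tryCatch({
    df <- do.call(rbind, lapply(names(curves), function(id)
      data.frame(patient_id = id,
                 time_s = curves[[id]]$cp$times * 60,
                 cp_mM = curves[[id]]$cp$values,
                 ctis_mM = curves[[id]]$ctis$values)))
    write_stamped_csv(df, curves_path, stamp)
    created <- c(created, curves_path)
  }, error = function(e) fail("write-curves", e))

  # stage: per-patient AIF density fit
  fits <- tryCatch(lapply(names(curves), function(id) {
    f <- fit_aif_density(curves[[id]]$cp, mode = cfg$mode,
                         solver = cfg$solver,
                         control = list(seed = cfg$seed))
    dpath <- file.path(cfg$out_dir, "densities", paste0(id, ".json"))
    maxent_to_json(f$density, dpath)
    created <<- c(created, dpath)
    pipeline_log(verbose,
                 "fit-aif [%s]: max residual %.3g (converged: %s)", id,
                 max(abs(f$density$residuals)), f$density$converged)
    f
  }), error = function(e) fail("fit-aif", e))
  names(fits) <- names(curves)

  # stage: kinetic parameter estimation (MAP + LLSQ comparator)
  kin <- tryCatch(do.call(rbind, lapply(names(curves), function(id) {
    cp <- if (cfg$use_fitted_aif) fits[[id]]$aif else curves[[id]]$cp
    ct <- curves[[id]]$ctis
    mapf <- kinetic_fit(cp, ct, method = "map", alpha = cfg$alpha)
    lsf <- suppressWarnings(kinetic_fit(cp, ct, method = "llsq"))
    data.frame(patient_id = id,
               k1_map = mapf$k1, k2_map = mapf$k2,
               k1_llsq = lsf$k1, k2_llsq = lsf$k2,
               sigma2 = mapf$diagnostics$sigma2,
               alpha = cfg$alpha,
               k1_true = if (!is.null(curves[[id]]$k1)) curves[[id]]$k1 else NA_real_,
               k2_true = if (!is.null(curves[[id]]$k2)) curves[[id]]$k2 else NA_real_)
  })), error = function(e) fail("fit-kinetics", e))

  kin_path <- file.path(cfg$out_dir, "kinetics.csv")
  write_stamped_csv(kin, kin_path, stamp)
  created <- c(created, kin_path)

  # stage: evaluation metrics
  met <- tryCatch(do.call(rbind, lapply(names(curves), function(id) {
    cp <- curves[[id]]$cp
    est <- fits[[id]]$aif
    fm <- fit_metrics(est$values, cp$values, n_params = length(coef(fits[[id]]$density)) - 1L)
    mapf_row <- kin[kin$patient_id == id, ]
    pred_ct <- drop(murase_design(cp, curves[[id]]$ctis)$A %*%
                      c(mapf_row$k1_map, mapf_row$k2_map))
    ct_fm <- fit_metrics(pred_ct, curves[[id]]$ctis$values, n_params = 2L)
    data.frame(patient_id = id,
               aif_mae = fm$mae, aif_rmse = fm$rmse, aif_r2 = fm$r2,
               ctis_rmse = ct_fm$rmse, ctis_r2 = ct_fm$r2,
               ctis_chi_square = ct_fm$chi_square)
  })), error = function(e) fail("evaluate", e))

  met_path <- file.path(cfg$out_dir, "metrics.csv")
  write_stamped_csv(met, met_path, stamp)
  created <- c(created, met_path)
  pipeline_log(verbose, "done: outputs in %s", cfg$out_dir)

  invisible(list(kinetics = kin, metrics = met, fits = fits,
                 seed = cfg$seed, config_hash = hash,
                 out_dir = cfg$out_dir))
}
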