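# End-to-end orchestration: simulate (or load) TCSPC stacks, run the fitting
# and phasor stages independently, calibrate, compute fUVA-Mel against the
# matched native condition, summarize over quadrant ROIs, compare conditions,
# and export maps/tables with full provenance.

#' Pipeline run configuration
#'
#' @param presets Character vector of melanin condition presets to simulate
#'   (see [melanin_presets()]); alternatively `paths` may name TCSPC stacks
#'   on disk (named by condition).
#' @param paths Optional named character vector of stack paths (read with
#'   [read_tcspc_stack()]) instead of simulation.
#' @param acq Acquisition geometry for simulation (default desk-scale
#'   128 x 128).
#' @param photons_per_pixel Mean photons per raw pixel for simulation
#'   (default 25 = 1e4 per 20 x 20 super-pixel).
#' @param fit_binning Binning for the fitting stage (default 20 x 20
#'   sliding, 2 channels).
#' @param phasor_bin Spatial binning for the phasor stage (default 10).
#' @param qc A [qc_policy()].
#' @param fit_stride Stride of the fitting stage (default 8 at desk scale;
#'   see [fit_image()]).
#' @param calibration `list(tau_ref =)` — the phasor stage simulates a
#'   fluorescein frame with that reference lifetime and calibrates against
#'   it. `NULL` makes the phasor stage refuse to run.
#' @param out_dir Output directory (created); `NULL` disables file output.
#' @param write_maps Write parametric-map TIFFs (default TRUE when `out_dir`
#'   is set).
#' @param seed Integer seed recorded in all outputs.
#' @return A `run_config` object.
#' @export
run_config <- function(presets = c("dhica_native", "dhica_uva1", "dhica_uva7"),
                       paths = NULL, acq = acq_preset("desk"),
                       photons_per_pixel = 25,
                       fit_binning = binning_policy(20L, 2L),
                       phasor_bin = 10L, qc = qc_policy(),
                       fit_stride = 8L,
                       calibration = list(tau_ref = 4e-9),
                       out_dir = NULL, write_maps = !is.null(out_dir),
                       seed = 1L) {
  reg <- names(melanin_presets())
  if (is.null(paths)) {
    unknown <- setdiff(presets, reg)
    if (length(unknown))
      stop("unknown preset(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(presets = presets, paths = paths, acq = acq,
                 photons_per_pixel = photons_per_pixel,
                 fit_binning = fit_binning, phasor_bin = phasor_bin,
                 qc = qc, fit_stride = as.integer(fit_stride),
                 calibration = calibration, out_dir = out_dir,
                 write_maps = write_maps, seed = as.integer(seed)),
            class = "run_config")
}

pipeline_parameters <- c("tau1", "a1_pct", "tau2", "a2_pct", "tau_av_int",
                         "tau_av_amp", "g", "s", "tau_phi", "tau_m", "fuva")

melanin_type_of <- function(cond) sub("_(native|uva1|uva7)$", "", cond)

#' Run the full analysis pipeline
#'
#' Stages: simulate or load stacks; fit stage (binning, per-pixel
#' bi-exponential reconvolution fits, QC); phasor stage (binning, transform,
#' fluorescein calibration, phase/modulation lifetimes); fUVA-Mel against the
#' native condition of each melanin type; quadrant-ROI summaries of the 11
#' quantification parameters; pairwise within-type condition contrasts
#' (Student t-test + Cohen's d). The fitting and phasor stages read only the
#' raw stack, never each other's outputs. Deterministic under a fixed seed.
#'
#' @param config A [run_config()].
#' @return A list with `summary` (ROI-level data.frame), `contrasts`,
#'   `table2` (condition-level report, see [table2_report()]),
#'   `calibration_record`, `conditions` (per-condition stage outputs),
#'   `truth`, and `provenance`. When `config$out_dir` is set, also writes
#'   `summary.csv`, `contrasts.csv`, `table2.csv`, `provenance.json`,
#'   phasor scatter CSVs and (optionally) parametric-map TIFFs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log <- list()
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    out <- force(expr)
    log[[name]] <<- round(proc.time()[["elapsed"]] - ts, 2)
    out
  }

  # --- input stage -----------------------------------------------------
  irf <- default_irf(config$acq)
  if (is.null(config$paths)) {
    fx <- stage("simulate", make_fixture_set(
      config$presets, seed = config$seed, acq = config$acq,
      photons_per_pixel = config$photons_per_pixel, irf = irf))
    images <- fx$images
    truth <- fx$truth
  } else {
    images <- stage("load", lapply(config$paths, read_tcspc_stack))
    truth <- NULL
  }

  # --- calibration stage ----------------------------------------------
  if (is.null(config$calibration))
    stop("phasor stage requires calibration against a mono-exponential ",
         "reference (fluorescein); provide config$calibration = ",
         "list(tau_ref = ...)")
  tau_ref <- config$calibration$tau_ref
  cal_rec <- stage("calibration", {
    cal_acq <- config$acq
    cal_img <- render_phantom(
      uniform_layout(cal_acq, decay_model(tau1 = tau_ref, a1_frac = 1),
                     config$photons_per_pixel),
      irf, cal_acq, seed = config$seed + 900L)
    cal_map <- phasor_image(cal_img, spatial_bin = config$phasor_bin)
    calibrate(cal_map, cal_map, tau_ref,
              reference_name = "fluorescein")$record
  })

  # --- per-condition fit + phasor stages -------------------------------
  conds <- list()
  for (cond in names(images)) {
    img <- images[[cond]]
    fit <- stage(paste0("fit_", cond),
                 fit_image(img, irf, binning = config$fit_binning,
                           qc = config$qc, stride = config$fit_stride))
    ph <- stage(paste0("phasor_", cond), {
      raw <- phasor_image(img, spatial_bin = config$phasor_bin)
      m <- apply_calibration(raw, cal_rec)
      lt <- phasor_lifetimes(m$g, m$s, m$acq)
      list(map = m,
           tau_phi = parametric_map("tau_phi",
                                    matrix(lt$tau_phi, nrow(m$g)), "s"),
           tau_m = parametric_map("tau_m",
                                  matrix(lt$tau_m, nrow(m$g)), "s"))
    })
    conds[[cond]] <- list(fit = fit, phasor = ph)
  }

  # --- fUVA-Mel against the matched native condition -------------------
  types <- unique(vapply(names(conds), melanin_type_of, ""))
  for (ty in types) {
    native <- paste0(ty, "_native")
    if (!native %in% names(conds)) next
    centroid <- reference_centroid(conds[[native]]$phasor$map)
    for (cond in names(conds)) {
      if (melanin_type_of(cond) != ty) next
      fm <- fraction_modified(conds[[cond]]$phasor$map, centroid)
      conds[[cond]]$fuva <- fm
    }
  }

  # --- quantify stage --------------------------------------------------
  summary_rows <- list()
  for (cond in names(conds)) {
    co <- conds[[cond]]
    shp <- dim(co$phasor$map$g)
    rois_fit <- define_rois(dim(co$fit$maps$tau1$values))
    rois_ph <- define_rois(shp)
    maps <- list(
      tau1 = co$fit$maps$tau1, a1_pct = co$fit$maps$a1_pct,
      tau2 = co$fit$maps$tau2, a2_pct = co$fit$maps$a2_pct,
      tau_av_int = co$fit$maps$tau_av_int,
      tau_av_amp = co$fit$maps$tau_av_amp,
      g = parametric_map("g", co$phasor$map$g, "dimensionless"),
      s = parametric_map("s", co$phasor$map$s, "dimensionless"),
      tau_phi = co$phasor$tau_phi, tau_m = co$phasor$tau_m)
    if (!is.null(co$fuva)) maps$fuva <- co$fuva$map
    for (nm in names(maps)) {
      rois <- if (nm %in% c("tau1", "a1_pct", "tau2", "a2_pct",
                            "tau_av_int", "tau_av_amp")) rois_fit else rois_ph
      sm <- summarize_parameter(maps[[nm]], rois)
      sm$condition <- cond
      summary_rows[[length(summary_rows) + 1L]] <- sm
    }
    conds[[cond]]$maps <- maps
  }
  summary <- do.call(rbind, summary_rows)
  summary <- summary[, c("condition", "roi", "parameter", "mean", "sd", "n")]
  rownames(summary) <- NULL

  # --- condition contrasts (within melanin type) -----------------------
  values <- data.frame(condition = summary$condition,
                       parameter = summary$parameter,
                       value = summary$mean, stringsAsFactors = FALSE)
  pairs <- list()
  for (ty in types) {
    cs <- names(conds)[vapply(names(conds), melanin_type_of, "") == ty]
    if (length(cs) >= 2) {
      cmb <- utils::combn(cs, 2)
      for (k in seq_len(ncol(cmb)))
        pairs[[length(pairs) + 1L]] <- data.frame(
          condition_a = cmb[1, k], condition_b = cmb[2, k],
          stringsAsFactors = FALSE)
    }
  }
  contrasts <- if (length(pairs))
    compare_conditions(values, plan = do.call(rbind, pairs))
  else NULL
  tab2 <- table2_report(summary)

  provenance <- list(
    seed = config$seed, presets = names(images),
    acq = acq_to_list(config$acq),
    photons_per_pixel = config$photons_per_pixel,
    fit_binning = unclass(config$fit_binning),
    phasor_bin = config$phasor_bin, fit_stride = config$fit_stride,
    qc = unclass(config$qc),
    calibration = list(tau_ref = tau_ref,
                       phase_correction = cal_rec$phase_correction,
                       modulation_correction = cal_rec$modulation_correction),
    software_version = MELFLIM_VERSION,
    stage_seconds = log,
    qc_counts = lapply(conds, function(co)
      list(n_fit = co$fit$n_fit, n_qc_pass = co$fit$n_qc_pass)))

  # --- export stage ----------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_summary_table(summary, file.path(config$out_dir, "summary.csv"))
    if (!is.null(contrasts))
      utils::write.csv(contrasts, file.path(config$out_dir, "contrasts.csv"),
                       row.names = FALSE, quote = FALSE)
    utils::write.csv(tab2, file.path(config$out_dir, "table2.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(provenance,
                         file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (cond in names(conds)) {
      m <- conds[[cond]]$maps
      sc <- data.frame(g = as.vector(m$g$values), s = as.vector(m$s$values))
      sc <- sc[is.finite(sc$g) & is.finite(sc$s), ]
      utils::write.csv(sc, file.path(config$out_dir,
                                     paste0("phasor_", cond, ".csv")),
                       row.names = FALSE, quote = FALSE)
      if (isTRUE(config$write_maps)) {
        for (nm in names(m))
          write_parametric_map(m[[nm]], file.path(
            config$out_dir, paste0(cond, "_", nm, ".tif")))
      }
    }
  }
  list(summary = summary, contrasts = contrasts, table2 = tab2,
       calibration_record = cal_rec, conditions = conds, truth = truth,
       provenance = provenance,
       elapsed = proc.time()[["elapsed"]] - t0)
}

#' Condition-level report in the reference-table layout
#'
#' One row per condition with the 11 quantification parameters in the
#' conventional column order (tau1, a1%, tau2, a2%, tauAvInt, tauAvAmp, g, s,
#' tau_phi, tau_m, fUVA); lifetimes are presented in nanoseconds. The value
#' is the mean of the ROI means (equal-area ROIs) and the spread the SD of
#' the ROI means.
#'
#' @param summary ROI-level summary data.frame (columns `condition`, `roi`,
#'   `parameter`, `mean`, `sd`, `n`).
#' @return A data.frame with `condition` plus `<param>` and `<param>_sd`
#'   columns; missing parameters stay `NA` with a warning.
#' @export
table2_report <- function(summary) {
  conds <- unique(summary$condition)
  ns_scale <- c(tau1 = 1e9, tau2 = 1e9, tau_av_int = 1e9, tau_av_amp = 1e9,
                tau_phi = 1e9, tau_m = 1e9)
  rows <- list()
  for (cond in conds) {
    row <- list(condition = cond)
    for (p in pipeline_parameters) {
      v <- summary$mean[summary$condition == cond & summary$parameter == p]
      v <- v[is.finite(v)]
      sc <- if (p %in% names(ns_scale)) ns_scale[[p]] else 1
      if (!length(v)) {
        warning("condition ", cond, " missing parameter '", p, "'",
                call. = FALSE)
        row[[p]] <- NA_real_
        row[[paste0(p, "_sd")]] <- NA_real_
      } else {
        row[[p]] <- mean(v) * sc
        row[[paste0(p, "_sd")]] <- if (length(v) > 1) stats::sd(v) * sc
          else NA_real_
      }
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
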