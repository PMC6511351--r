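#' Pipeline run configuration
#'
#' Collects every stage parameter of an end-to-end run. Defaults mirror
#' the reference analysis: discard 4 volumes, band-pass 0.01--0.08 Hz,
#' 6 mm FWHM functional smoothing, 3 mm sigma gray-matter smoothing,
#' motion exclusion at 2 mm / 2 degrees, voxel-level FWE threshold
#' 0.0002, FC comparison FDR 0.05.
#'
#' @param cohort An in-memory cohort from [simulate_cohort()], or `NULL`.
#' @param manifest_dir Directory with a cohort manifest (alternative to
#'   `cohort`).
#' @param out_dir Output directory for tables, figures and the run log.
#' @param stages Character subset of
#'   `c("preprocess", "vbm", "netfc", "correlate")`.
#' @param n_discard,low_hz,high_hz,fwhm_mm,filter_method Preprocessing
#'   parameters (see [preprocess_run()]).
#' @param gm_sigma_mm Gaussian sigma (mm) applied to gray-matter maps.
#' @param max_translation_mm,max_rotation_deg Motion exclusion thresholds.
#' @param tfce A [tfce_params()].
#' @param n_perm Permutations for the VBM FWE correction.
#' @param vbm_alpha Corrected-p threshold for cluster reporting.
#' @param fc_alpha FDR level for the network comparison.
#' @param covariates Clinical covariates to correlate with FC changes.
#' @param seed Master seed for the permutation stage.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = NULL, manifest_dir = NULL, out_dir,
                       stages = c("preprocess", "vbm", "netfc", "correlate"),
                       n_discard = 4, low_hz = 0.01, high_hz = 0.08,
                       fwhm_mm = 6, filter_method = "fft",
                       gm_sigma_mm = 3,
                       max_translation_mm = 2, max_rotation_deg = 2,
                       tfce = tfce_params(), n_perm = 5000,
                       vbm_alpha = 0.0002, fc_alpha = 0.05,
                       covariates = c("ammonia", "bilirubin"),
                       seed = 1L) {
  if (is.null(cohort) && is.null(manifest_dir))
    stop("provide either `cohort` or `manifest_dir`")
  stopifnot(vbm_alpha > 0, vbm_alpha < 1, fc_alpha > 0, fc_alpha < 1)
  structure(list(cohort = cohort, manifest_dir = manifest_dir,
                 out_dir = out_dir, stages = stages,
                 n_discard = n_discard, low_hz = low_hz, high_hz = high_hz,
                 fwhm_mm = fwhm_mm, filter_method = filter_method,
                 gm_sigma_mm = gm_sigma_mm,
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 tfce = tfce, n_perm = n_perm, vbm_alpha = vbm_alpha,
                 fc_alpha = fc_alpha, covariates = covariates,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' All keys of [run_config()] except `cohort` may appear in the file;
#' `tfce` may be a mapping with keys `E`, `H`, `dh`, `n_steps`,
#' `connectivity`.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$tfce)) y$tfce <- do.call(tfce_params, y$tfce)
  do.call(run_config, y)
}

subject_data <- function(sub, what) {
  x <- sub[[what]]
  if (is.null(x)) return(NULL)
  if (!is.character(x)) return(x)
  switch(what, bold = read_bold(x), gm = read_gm(x), motion = read_motion(x))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — preprocessing with motion-based
#' exclusion, voxel-based morphometry with TFCE + permutation FWE and
#' cluster reporting, network functional connectivity with FDR-controlled
#' group comparison, and clinical correlation — then renders the report
#' bundle into `config$out_dir`. Subjects excluded by motion QC are
#' dropped from every downstream stage and listed in the QC table. A run
#' log records the configuration hash, seed and per-stage timings.
#'
#' @param config A [run_config()].
#' @return A `pipeline_results` list with elements `qc`, `vbm`
#'   (`corrected_p` + cluster table), `fc` (`group_fc_comparison` +
#'   per-subject matrices), `clinical_correlations`, `excluded`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$cohort)) config$cohort
            else read_manifest(config$manifest_dir)
  atlas <- cohort$atlas
  clinical <- cohort$clinical
  voxel_mm <- atlas$voxel_size_mm
  results <- list(config = config)
  timings <- c()
  tic <- function(expr, stage) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  # ---- preprocessing + motion QC ------------------------------------
  qc_rows <- list()
  roi_series <- list()
  included <- character(0)
  if ("preprocess" %in% config$stages) {
    tic(stage = "preprocess", {
      for (sub in cohort$subjects) {
        motion <- subject_data(sub, "motion")
        qc <- motion_qc(motion, config$max_translation_mm,
                        config$max_rotation_deg)
        qc_rows[[sub$id]] <- data.frame(
          subject_id = sub$id, group = sub$group, pass = qc$pass,
          max_translation_mm = qc$max_translation,
          max_rotation_deg = qc$max_rotation)
        if (!qc$pass) next
        included <- c(included, sub$id)
        run <- subject_data(sub, "bold")
        if (!is.null(run) && "netfc" %in% config$stages) {
          run <- discard_initial_volumes(run, config$n_discard)
          run <- bandpass(run, config$low_hz, config$high_hz,
                          method = config$filter_method)
          if (config$fwhm_mm > 0)
            run <- smooth_gaussian(run, config$fwhm_mm, voxel_mm)
          roi_series[[sub$id]] <- extract_roi_timeseries(run, atlas)
        }
      }
    })
    results$qc <- do.call(rbind, unname(qc_rows))
    results$excluded <- setdiff(names(cohort$subjects), included)
  } else {
    included <- names(cohort$subjects)
    results$excluded <- character(0)
  }

  groups <- vapply(cohort$subjects, `[[`, "", "group")

  # ---- voxel-based morphometry --------------------------------------
  if ("vbm" %in% config$stages) {
    tic(stage = "vbm", {
      keep <- intersect(included, names(cohort$subjects))
      gm_of <- function(g) lapply(keep[groups[keep] == g], function(id) {
        m <- subject_data(cohort$subjects[[id]], "gm")
        if (config$gm_sigma_mm > 0)
          m <- smooth_gaussian(m, config$gm_sigma_mm * 2 * sqrt(2 * log(2)),
                               voxel_mm)
        m
      })
      pat <- gm_of("patient"); ctl <- gm_of("control")
      # contrast: control minus patient (gray-matter reduction in patients)
      pmap <- permutation_fwe(ctl, pat, params = config$tfce,
                              n_perm = config$n_perm, seed = config$seed)
      results$vbm <- list(
        pmap = pmap,
        clusters = report_clusters(pmap, alpha = config$vbm_alpha,
                                   connectivity = config$tfce$connectivity,
                                   label_atlas = atlas))
    })
  }

  # ---- network functional connectivity ------------------------------
  if ("netfc" %in% config$stages && length(roi_series)) {
    tic(stage = "netfc", {
      mats <- lapply(roi_series, function(ts)
        network_matrix(roi_fc(ts), atlas))
      pat <- mats[groups[names(mats)] == "patient"]
      ctl <- mats[groups[names(mats)] == "control"]
      results$fc <- compare_groups(pat, ctl, alpha = config$fc_alpha)
      results$fc$subject_matrices <- mats
    })
  }

  # ---- clinical correlation -----------------------------------------
  if ("correlate" %in% config$stages && !is.null(results$fc)) {
    tic(stage = "correlate", {
      tab <- results$fc$table
      mats <- results$fc$subject_matrices
      pat_ids <- names(mats)[groups[names(mats)] == "patient"]
      rows <- list()
      for (k in which(tab$significant)) {
        nn <- strsplit(tab$pair[k], "-", fixed = TRUE)[[1]]
        if (length(nn) == 1) nn <- c(nn, nn)
        fc_vals <- vapply(mats[pat_ids], function(m) m[nn[1], nn[2]], 0)
        for (cv in config$covariates) {
          cov_vals <- clinical[[cv]][match(pat_ids, clinical$subject_id)]
          if (all(is.na(cov_vals))) next
          cc <- correlate_clinical(fc_vals, cov_vals)
          rows[[length(rows) + 1]] <- data.frame(
            pair = tab$pair[k], covariate = cv, r = cc$r, p = cc$p,
            slope = cc$slope, n = cc$n, significant = cc$significant)
        }
      }
      results$clinical_correlations <- if (length(rows))
        do.call(rbind, rows)
      else data.frame(pair = character(0), covariate = character(0),
                      r = numeric(0), p = numeric(0), slope = numeric(0),
                      n = integer(0), significant = logical(0))
    })
  }

  results$log <- list(seed = config$seed,
                      config_hash = rlang::hash(config[setdiff(
                        names(config), "cohort")]),
                      timings = timings,
                      n_included = length(included),
                      n_excluded = length(results$excluded))
  class(results) <- "pipeline_results"
  if (!is.null(config$out_dir)) render_report(results, config$out_dir)
  results
}

#' Render the report bundle
#'
#' Writes, under `out_dir`: a human-readable `report.md`; the QC table;
#' the cluster table (columns `cluster_size_voxels, x_mm, y_mm, z_mm,
#' peak_p, label`); the network comparison table (group means ± SD, raw
#' and FDR-adjusted p per network pair); group-mean and difference
#' (patients minus controls) 3x3 connectivity matrices as CSV; clinical
#' correlations; a heat-map figure of the three matrices; and the run
#' log as JSON. With no completed stage an explanatory stub report is
#' produced.
#'
#' @param results A `pipeline_results`.
#' @param out_dir Output directory (created if needed).
#' @param figures Render PNG heat maps (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(results, out_dir, figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  emit <- function(x, file, ...) {
    p <- file.path(out_dir, file)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE, ...)
    paths <<- c(paths, p)
    p
  }
  md <- c("# visionet run report", "")
  if (is.null(results$qc) && is.null(results$vbm) && is.null(results$fc)) {
    md <- c(md, "No stage produced results; nothing to report.")
    writeLines(md, file.path(out_dir, "report.md"))
    return(invisible(file.path(out_dir, "report.md")))
  }
  if (!is.null(results$qc)) {
    emit(results$qc, "qc.tsv")
    md <- c(md, "## Motion quality control",
            sprintf("%d/%d subjects passed (threshold %g mm / %g deg); excluded: %s",
                    sum(results$qc$pass), nrow(results$qc),
                    results$config$max_translation_mm,
                    results$config$max_rotation_deg,
                    if (length(results$excluded))
                      paste(results$excluded, collapse = ", ") else "none"),
            "")
  }
  if (!is.null(results$vbm)) {
    cl <- results$vbm$clusters
    emit(cl, "clusters.tsv")
    md <- c(md, "## Voxel-based morphometry",
            if (nrow(cl) == 0)
              sprintf("No significant clusters at corrected p < %g.",
                      results$config$vbm_alpha)
            else sprintf(
              "%d cluster(s) at corrected p < %g (largest: %d voxels, peak p = %.4g at [%.0f, %.0f, %.0f] mm, %s).",
              nrow(cl), results$config$vbm_alpha, cl$cluster_size_voxels[1],
              cl$peak_p[1], cl$x_mm[1], cl$y_mm[1], cl$z_mm[1], cl$label[1]),
            "")
  }
  if (!is.null(results$fc)) {
    tab <- results$fc$table
    emit(tab, "fc_comparison.tsv")
    for (nm in c("mean_patient", "mean_control", "difference")) {
      p <- file.path(out_dir, paste0("fc_", nm, ".csv"))
      write.csv(as.data.frame(unclass(results$fc[[nm]])), p, row.names = TRUE)
      paths <- c(paths, p)
    }
    sig <- tab$pair[tab$significant & !is.na(tab$significant)]
    md <- c(md, "## Network functional connectivity",
            sprintf("Significant group differences (FDR %.2f, per family): %s",
                    results$fc$alpha,
                    if (length(sig)) paste(sig, collapse = ", ") else "none"),
            "")
    if (figures) {
      fig <- file.path(out_dir, "fc_matrices.png")
      grDevices::png(fig, width = 1200, height = 420)
      graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 2))
      plot_fc_matrix(results$fc$mean_patient, "Patients")
      plot_fc_matrix(results$fc$mean_control, "Controls")
      plot_fc_matrix(results$fc$difference, "Patients minus controls")
      grDevices::dev.off()
      paths <- c(paths, fig)
    }
  }
  if (!is.null(results$clinical_correlations)) {
    emit(results$clinical_correlations, "clinical_correlations.tsv")
    cc <- results$clinical_correlations
    md <- c(md, "## Clinical correlation",
            if (nrow(cc) == 0)
              "No significant FC pair to correlate, or no covariates available."
            else sprintf("%d correlation(s) computed; %d significant at p < 0.05.",
                         nrow(cc), sum(cc$significant)),
            "")
  }
  if (!is.null(results$log)) {
    p <- file.path(out_dir, "run_log.json")
    jsonlite::write_json(results$log, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
    md <- c(md, sprintf("Seed %d; config hash %s.", results$log$seed,
                        results$log$config_hash))
  }
  report <- file.path(out_dir, "report.md")
  writeLines(md, report)
  invisible(c(report, paths))
}

plot_fc_matrix <- function(m, title) {
  m2 <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m2,
                  col = grDevices::hcl.colors(25, "RdBu", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", main = title)
  graphics::axis(1, seq_len(nrow(m)), rownames(m))
  graphics::axis(2, seq_len(ncol(m)), rev(colnames(m)), las = 1)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    graphics::text(i, j, sprintf("%.3f", m2[i, j]))
}
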