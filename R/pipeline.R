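#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: either a synthetic-cohort
#' specification (generate geometries) or a manifest path (load STLs written
#' by [write_cohort()]), plus anatomy, rheology, waveform and output settings.
#'
#' @param cohort a [cohort_spec()], or `NULL` when loading from `manifest`.
#' @param manifest path to a cohort `manifest.csv`, or `NULL`.
#' @param anatomy an [anatomy_params()] object (generation only).
#' @param rheology a [rheology_params()] object.
#' @param waveform_kinds subset of `c("sharp", "flat", "real")`.
#' @param peak_velocity inlet peak velocity, m/s.
#' @param period cardiac period, s.
#' @param n_steps waveform samples per cycle.
#' @param n_stations axial stations for the quasi-1D reduction.
#' @param out_dir output directory for CSV/JSON reports (`NULL`: no files).
#' @param write_stl also write the generated STLs and manifest to `out_dir`.
#' @param verbosity `"quiet"`, `"info"` or `"debug"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), manifest = NULL,
                       anatomy = anatomy_params(), rheology = rheology_params(),
                       waveform_kinds = c("sharp", "flat", "real"),
                       peak_velocity = 0.4, period = 1.0, n_steps = 64,
                       n_stations = 33, out_dir = NULL, write_stl = FALSE,
                       verbosity = c("info", "quiet", "debug")) {
  if (is.null(cohort) == is.null(manifest)) {
    stop("exactly one of 'cohort' and 'manifest' must be given")
  }
  if (!is.null(cohort) && !inherits(cohort, "cohort_spec")) {
    stop("cohort must be a cohort_spec")
  }
  waveform_kinds <- match.arg(waveform_kinds, several.ok = TRUE)
  structure(list(cohort = cohort, manifest = manifest, anatomy = anatomy,
                 rheology = rheology, waveform_kinds = waveform_kinds,
                 peak_velocity = peak_velocity, period = period,
                 n_steps = as.integer(n_steps),
                 n_stations = as.integer(n_stations),
                 out_dir = out_dir, write_stl = isTRUE(write_stl),
                 verbosity = match.arg(verbosity)),
            class = "run_config")
}

#' Read a run configuration from YAML (or JSON)
#'
#' Top-level keys mirror the [run_config()] arguments; `anatomy`, `cohort`
#' and `rheology` may be nested maps of their constructor arguments.
#'
#' @param path YAML or JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(cfg$manifest)) {
    args$manifest <- cfg$manifest
    args$cohort <- NULL
  } else if (!is.null(cfg$cohort)) {
    args$cohort <- do.call(cohort_spec, cfg$cohort)
  }
  if (!is.null(cfg$anatomy)) args$anatomy <- do.call(anatomy_params, cfg$anatomy)
  if (!is.null(cfg$rheology)) args$rheology <- do.call(rheology_params, cfg$rheology)
  for (key in c("waveform_kinds", "peak_velocity", "period", "n_steps",
                "n_stations", "out_dir", "write_stl", "verbosity")) {
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  }
  do.call(run_config, args)
}

pipeline_log <- function(config, level, stage, msg) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[config$verbosity]] >= levels[[level]]) {
    message(sprintf("[%s] %s", stage, msg))
  }
}

#' Run the full assessment pipeline
#'
#' Generates (or loads) the cohort, evaluates every patient with
#' [evaluate_patient()], and assembles the cohort-level report: per-object
#' geometry, per-waveform WSS totals and drag forces, migration-risk
#' verdicts, mean +/- SEM summaries, correlations, and the
#' shape-versus-WSS regressions (one row per graft type per waveform).
#'
#' @param config a [run_config()].
#' @return An object of class `graft_risk_report` with data frames
#'   `geometry`, `wss`, `risk`, `regressions`, `correlations`, a `summary`
#'   list and the evaluated `records`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  t0 <- Sys.time()
  cohort <- if (!is.null(config$manifest)) {
    pipeline_log(config, "info", "load", paste("manifest", config$manifest))
    read_cohort(config$manifest)
  } else {
    pipeline_log(config, "info", "generate",
                 sprintf("n = %d patients, seed = %d",
                         config$cohort$n_patients, config$cohort$seed))
    make_cohort(config$cohort, config$anatomy)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (config$write_stl && is.null(config$manifest)) {
      pipeline_log(config, "info", "write-stl", config$out_dir)
      write_cohort(cohort, file.path(config$out_dir, "geometries"))
    }
  }
  waveforms <- lapply(config$waveform_kinds, make_waveform,
                      peak_velocity = config$peak_velocity,
                      period = config$period, n_samples = config$n_steps)
  records <- lapply(cohort, function(rec) {
    t1 <- Sys.time()
    out <- evaluate_patient(rec$aaa, rec$sl, rec$ss, waveforms = waveforms,
                            rheo = config$rheology,
                            n_stations = config$n_stations,
                            patient_id = rec$patient_id)
    pipeline_log(config, "debug", "evaluate",
                 sprintf("patient %d in %.2f s", rec$patient_id,
                         as.numeric(Sys.time() - t1, units = "secs")))
    out
  })
  report <- build_report(records, config)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  pipeline_log(config, "info", "done",
               sprintf("%d patients, %d waveforms in %.1f s", length(records),
                       length(waveforms),
                       as.numeric(Sys.time() - t0, units = "secs")))
  report
}

build_report <- function(records, config) {
  objs <- c("AAA", "SL", "SS")
  kinds <- config$waveform_kinds
  geometry <- do.call(rbind, lapply(records, function(r) {
    do.call(rbind, lapply(objs, function(o) {
      g <- r$geometry[[o]]
      data.frame(patient_id = r$patient_id, object = o,
                 height_mm = g$height, side_surface_mm2 = g$side_surface,
                 volume_mm3 = g$volume, ref_diameter_mm = g$ref_diameter,
                 phi_ref = g$phi_ref,
                 phi_AS = if (o == "AAA") NA_real_ else r$shape_pair[[o]]$phi_AS,
                 volume_ratio = if (o == "AAA") NA_real_ else
                   r$shape_pair[[o]]$volume_ratio)
    }))
  }))
  wss <- do.call(rbind, lapply(records, function(r) {
    do.call(rbind, lapply(r$waveform_kinds, function(k) {
      h <- r$hemodynamics[[k]]
      data.frame(patient_id = r$patient_id, waveform = k, object = objs,
                 wss_tot_pa = as.numeric(h$wss_tot[objs]),
                 drag_n = c(NA_real_, as.numeric(h$drag[c("SL", "SS")])),
                 phi_wss = c(NA_real_, as.numeric(h$phi_wss[c("SL", "SS")])))
    }))
  }))
  risk <- do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$patient_id,
               mean_drag_sl_n = r$mean_drag[["SL"]],
               mean_drag_ss_n = r$mean_drag[["SS"]],
               verdict = r$verdict)
  }))
  n <- length(records)
  summarise <- function(v) if (n >= 2) mean_sem(v) else
    list(mean = mean(v), sem = NA_real_, n = n)
  summary <- list(
    n_patients = n,
    phi_ref = lapply(stats::setNames(objs, objs), function(o) {
      summarise(geometry$phi_ref[geometry$object == o])
    }),
    volume_ratio = lapply(stats::setNames(c("SL", "SS"), c("SL", "SS")),
                          function(o) {
      summarise(geometry$volume_ratio[geometry$object == o])
    }),
    wss_tot = lapply(stats::setNames(kinds, kinds), function(k) {
      lapply(stats::setNames(objs, objs), function(o) {
        summarise(wss$wss_tot_pa[wss$waveform == k & wss$object == o])
      })
    }),
    verdicts = as.list(table(risk$verdict)))
  regressions <- NULL
  correlations <- NULL
  if (n >= 3) {
    regressions <- do.call(rbind, lapply(c("SL", "SS"), function(g) {
      do.call(rbind, lapply(kinds, function(k) {
        fit <- shape_wss_regression(records, g, k)
        data.frame(graft_type = g, waveform = k, slope = fit$slope,
                   slope_se = fit$slope_se, intercept = fit$intercept,
                   intercept_se = fit$intercept_se, n = fit$n)
      }))
    }))
    correlations <- cohort_correlations(records, geometry, wss, kinds)
  }
  structure(list(records = records, geometry = geometry, wss = wss,
                 risk = risk, summary = summary, regressions = regressions,
                 correlations = correlations, config = config),
            class = "graft_risk_report")
}

# Pearson correlations mirroring the standard cohort pairings: each real
# geometry against its reference cylinder (volumes), each implant against the
# aneurysm (volumes), and implant WSS against aneurysm WSS per waveform.
cohort_correlations <- function(records, geometry, wss, kinds) {
  rows <- list()
  vols <- function(o) geometry$volume_mm3[geometry$object == o]
  refvols <- function(o) {
    vapply(records, function(r) r$geometry[[o]]$ref_volume, numeric(1))
  }
  for (o in c("AAA", "SL", "SS")) {
    ct <- pearson_cor(vols(o), refvols(o))
    rows[[length(rows) + 1L]] <- data.frame(
      pairing = sprintf("%s_vs_reference_cylinder_volume", o),
      rho = ct$rho, p = ct$p, n = ct$n)
  }
  for (o in c("SL", "SS")) {
    ct <- pearson_cor(vols("AAA"), vols(o))
    rows[[length(rows) + 1L]] <- data.frame(
      pairing = sprintf("%s_vs_AAA_volume", o), rho = ct$rho, p = ct$p,
      n = ct$n)
  }
  for (k in kinds) {
    for (o in c("SL", "SS")) {
      x <- wss$wss_tot_pa[wss$waveform == k & wss$object == "AAA"]
      y <- wss$wss_tot_pa[wss$waveform == k & wss$object == o]
      ct <- pearson_cor(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        pairing = sprintf("WSS_%s_vs_AAA_%s", o, k), rho = ct$rho, p = ct$p,
        n = ct$n)
    }
  }
  do.call(rbind, rows)
}

#' Write a risk report's tables to disk
#'
#' `geometry.csv`, `wss.csv`, `risk.csv`, `regressions.csv`,
#' `correlations.csv` and `summary.json` under `dir`.
#'
#' @param report a `graft_risk_report`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(dir, name), row.names = FALSE)
    }
  }
  w(report$geometry, "geometry.csv")
  w(report$wss, "wss.csv")
  w(report$risk, "risk.csv")
  w(report$regressions, "regressions.csv")
  w(report$correlations, "correlations.csv")
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the default demonstration cohort
#'
#' Twenty synthetic patients, three inflow waveforms, deterministic for a
#' fixed seed.
#'
#' @param seed cohort RNG seed.
#' @param out_dir optional output directory for the report files.
#' @param n_patients cohort size.
#' @param verbosity logging level.
#' @return A `graft_risk_report`.
#' @export
run_demo <- function(seed = 1, out_dir = NULL, n_patients = 20,
                     verbosity = "info") {
  run_pipeline(run_config(cohort = cohort_spec(n_patients = n_patients,
                                               seed = seed),
                          out_dir = out_dir, verbosity = verbosity))
}

#' @export
print.graft_risk_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("graft_risk_report: %d patients, waveforms: %s\n",
              s$n_patients, paste(x$config$waveform_kinds, collapse = ", ")))
  for (o in names(s$phi_ref)) {
    cat(sprintf("  shape factor %-3s : %.3f +/- %.3f (SEM)\n", o,
                s$phi_ref[[o]]$mean, s$phi_ref[[o]]$sem))
  }
  cat("  verdicts:", paste(sprintf("%s = %s", names(s$verdicts), unlist(s$verdicts)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.graft_risk_report <- function(object, ...) {
  print(object)
  if (!is.null(object$regressions)) {
    cat("shape-vs-WSS regressions (slope +/- SE, intercept +/- SE):\n")
    r <- object$regressions
    for (i in seq_len(nrow(r))) {
      cat(sprintf("  %s / %-5s : %7.3f +/- %.3f | %6.3f +/- %.3f\n",
                  r$graft_type[i], r$waveform[i], r$slope[i], r$slope_se[i],
                  r$intercept[i], r$intercept_se[i]))
    }
  }
  invisible(object)
}

#' @export
plot.graft_risk_report <- function(x, which = c("shape", "regression"), ...) {
  which <- match.arg(which)
  if (which == "shape") {
    s <- x$summary$phi_ref
    m <- vapply(s, `[[`, numeric(1), "mean")
    e <- vapply(s, `[[`, numeric(1), "sem")
    bp <- graphics::barplot(m, ylim = c(0, max(m + 2 * e, na.rm = TRUE)),
                            ylab = "shape factor vs reference cylinder", ...)
    graphics::arrows(bp, m - e, bp, m + e, angle = 90, code = 3, length = 0.05)
  } else {
    g <- x$geometry
    w <- x$wss
    kinds <- x$config$waveform_kinds
    k <- kinds[1]
    cols <- c(SL = "steelblue", SS = "firebrick")
    xs <- NULL; ys <- NULL
    for (o in c("SL", "SS")) {
      xo <- g$volume_ratio[g$object == o]
      yo <- w$wss_tot_pa[w$waveform == k & w$object == o] /
        w$wss_tot_pa[w$waveform == k & w$object == "AAA"]
      xs <- c(xs, xo); ys <- c(ys, yo)
    }
    graphics::plot(NA, xlim = range(xs), ylim = range(ys),
                   xlab = "volume ratio graft/AAA",
                   ylab = sprintf("WSS ratio graft/AAA ('%s')", k), ...)
    for (o in c("SL", "SS")) {
      xo <- g$volume_ratio[g$object == o]
      yo <- w$wss_tot_pa[w$waveform == k & w$object == o] /
        w$wss_tot_pa[w$waveform == k & w$object == "AAA"]
      graphics::points(xo, yo, col = cols[[o]], pch = 19)
      if (length(xo) >= 3) graphics::abline(stats::lm(yo ~ xo), col = cols[[o]])
    }
    graphics::legend("topright", legend = names(cols), col = cols, pch = 19)
  }
  invisible(x)
}
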