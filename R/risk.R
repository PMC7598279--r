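#' Wall shear stress factor
#'
#' Dimensionless ratio of aneurysm to stent-graft wall shear stress,
#' `phi_WSS = WSS_aneurysm / WSS_graft`. Values below 1 indicate the graft
#' wall carries a higher shear load than the native aneurysm did.
#'
#' @param wss_aneurysm aneurysm WSS, Pa (> 0).
#' @param wss_graft stent-graft WSS, Pa (> 0).
#' @return Dimensionless ratio.
#' @export
wss_factor <- function(wss_aneurysm, wss_graft) {
  if (any(wss_aneurysm <= 0) || any(wss_graft <= 0)) {
    stop("WSS inputs must be > 0")
  }
  wss_aneurysm / wss_graft
}

#' Evaluate one patient: geometry, hemodynamics and migration-risk verdict
#'
#' Runs the full per-patient chain on an aneurysm mesh and its two virtual
#' stent-graft configurations: common-height reference cylinders and shape
#' factors, quasi-1D WSS series per inflow waveform, cycle totals, drag
#' forces, WSS factors, and the long-versus-short verdict. The configuration
#' with the strictly lower mean drag force across the requested waveforms is
#' judged the lower migration risk; relative differences under
#' `indifference` are reported as indeterminate rather than resolved by
#' numerical noise.
#'
#' @param aaa,sl,ss aneurysm, long-body and short-body graft [tri_mesh]es;
#'   axial heights must agree within 1%.
#' @param waveforms list of [velocity_waveform] objects (distinct kinds).
#' @param rheo a [rheology_params()] object.
#' @param n_stations stations for [tube_from_mesh()].
#' @param indifference relative drag-force band treated as a tie.
#' @param patient_id identifier carried into reports.
#' @return An object of class `cohort_record`.
#' @export
evaluate_patient <- function(aaa, sl, ss, waveforms = list(make_waveform("sharp")),
                             rheo = rheology_params(), n_stations = 33,
                             indifference = 0.01, patient_id = NA_integer_) {
  heights <- c(aaa = axial_height(aaa), sl = axial_height(sl),
               ss = axial_height(ss))
  if (max(heights) / min(heights) - 1 > 0.01) {
    stop(sprintf("patient %s: object heights differ by more than 1%% (%s)",
                 patient_id, paste(sprintf("%.2f", heights), collapse = "/")))
  }
  meshes <- list(AAA = aaa, SL = sl, SS = ss)
  kinds <- vapply(waveforms, function(w) w$kind, character(1))
  if (anyDuplicated(kinds)) stop("waveform kinds must be distinct")
  names(waveforms) <- kinds

  h_ref <- heights[["aaa"]]
  geom <- lapply(meshes, function(m) {
    rc <- build_reference_cylinder(m, height_override = h_ref)
    vol <- enclosed_volume(m)
    list(height = axial_height(m), side_surface = rc$side_surface,
         volume = vol, ref_diameter = rc$diameter, ref_volume = rc$volume,
         phi_ref = rc$volume / vol)
  })
  pair <- list(
    SL = shape_factor_pair(aaa, sl, direction = "aneurysm_over_graft"),
    SS = shape_factor_pair(aaa, ss, direction = "aneurysm_over_graft"))

  tubes <- lapply(meshes, tube_from_mesh, n_stations = n_stations)
  hemo <- lapply(kinds, function(kind) {
    wf <- waveforms[[kind]]
    totals <- vapply(names(meshes), function(obj) {
      wss_total(wss_series(tubes[[obj]], wf, rheo))
    }, numeric(1))
    drags <- vapply(c("SL", "SS"), function(obj) {
      totals[[obj]] * geom[[obj]]$side_surface * 1e-6
    }, numeric(1))
    list(wss_tot = totals,
         drag = drags,
         phi_wss = c(SL = wss_factor(totals[["AAA"]], totals[["SL"]]),
                     SS = wss_factor(totals[["AAA"]], totals[["SS"]])))
  })
  names(hemo) <- kinds

  mean_drag <- c(
    SL = mean(vapply(hemo, function(h) h$drag[["SL"]], numeric(1))),
    SS = mean(vapply(hemo, function(h) h$drag[["SS"]], numeric(1))))
  verdict <- drag_verdict(mean_drag[["SL"]], mean_drag[["SS"]], indifference)

  structure(list(patient_id = patient_id, heights = heights, geometry = geom,
                 shape_pair = pair, hemodynamics = hemo,
                 mean_drag = mean_drag, verdict = verdict,
                 waveform_kinds = kinds),
            class = "cohort_record")
}

# Lower mean drag <=> lower migration risk; near-ties are indeterminate.
drag_verdict <- function(drag_sl, drag_ss, indifference = 0.01) {
  rel <- abs(drag_sl - drag_ss) / max(drag_sl, drag_ss)
  if (!is.finite(rel) || rel < indifference) return("indeterminate")
  if (drag_sl < drag_ss) "long_lower_risk" else "short_lower_risk"
}

#' @export
print.cohort_record <- function(x, ...) {
  cat(sprintf("cohort_record (patient %s): height %.1f mm\n",
              x$patient_id, x$heights[["aaa"]]))
  cat(sprintf("  phi_ref AAA/SL/SS: %.3f / %.3f / %.3f\n",
              x$geometry$AAA$phi_ref, x$geometry$SL$phi_ref,
              x$geometry$SS$phi_ref))
  cat(sprintf("  mean drag SL/SS: %.4g / %.4g N -> %s\n",
              x$mean_drag[["SL"]], x$mean_drag[["SS"]], x$verdict))
  invisible(x)
}

#' Shape-factor versus WSS regression across a cohort
#'
#' Ordinary least squares of the graft-to-aneurysm WSS ratio (y) on the
#' graft-to-aneurysm enclosed-volume ratio (x), per graft type and inflow
#' waveform — the cohort-level relation between spatial configuration and
#' shear load. Delegates to [linear_fit()].
#'
#' @param records list of [evaluate_patient()] results (>= 3).
#' @param graft_type `"SL"` or `"SS"`.
#' @param waveform_kind waveform label present in the records.
#' @return [linear_fit()] result plus `graft_type` and `waveform_kind`.
#' @export
shape_wss_regression <- function(records, graft_type = c("SL", "SS"),
                                 waveform_kind = "sharp") {
  graft_type <- match.arg(graft_type)
  if (length(records) < 3L) stop("need at least 3 cohort records")
  x <- vapply(records, function(r) r$shape_pair[[graft_type]]$volume_ratio,
              numeric(1))
  y <- vapply(records, function(r) {
    h <- r$hemodynamics[[waveform_kind]]
    if (is.null(h)) stop("waveform kind '", waveform_kind, "' not in records")
    h$wss_tot[[graft_type]] / h$wss_tot[["AAA"]]
  }, numeric(1))
  c(linear_fit(x, y),
    list(graft_type = graft_type, waveform_kind = waveform_kind))
}
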