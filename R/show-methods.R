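setMethod("show", "LocusLayout", function(object) {
  g <- locusGeometry(object)
  cat("LocusLayout:", sprintf("origin %s, arrays at %s / %s (%g kb each)",
      format(object@origin_pos, big.mark = ","),
      format(object@array1_pos, big.mark = ","),
      format(object@array2_pos, big.mark = ","), object@array_len), "\n")
  cat("  mid-to-mid distance:", g$mid_to_mid_kb, "kb\n")
  if (!is.na(object@obstacle_pos))
    cat(sprintf("  obstacle at %s (%s strand): %.1f kb after array 1, %.1f kb before array 2\n",
        format(object@obstacle_pos, big.mark = ","), object@obstacle_strand,
        g$array1_to_obstacle_kb, g$obstacle_to_array2_kb))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig '%s': %d cells, fork %.2f kb/min (CV %.2f)\n",
      object@label, as.integer(object@n_cells), object@fork_speed_mean,
      object@fork_speed_cv))
  cat(sprintf("  pause %.1f min (%s) in folded fraction %.2f; firing %.0f +/- %.0f min\n",
      object@pause_mean, object@pause_model, object@folded_fraction,
      object@firing_time_mean, object@firing_time_sd))
})

setMethod("show", "AcquisitionConfig", function(object) {
  cat(sprintf("AcquisitionConfig: %d frames x %.3g min, %d z x %.2g um, %dx%d px (%.3g um)\n",
      as.integer(object@n_frames), object@frame_interval, as.integer(object@n_z),
      object@z_step, as.integer(object@n_y), as.integer(object@n_x),
      object@pixel_size))
  cat(sprintf("  PSF sigma %.2g/%.2g um (xy/z), bg %.3g, read sd %.3g, bleach %.3g/min\n",
      object@psf_sigma_xy, object@psf_sigma_z, object@background_level,
      object@read_noise_sd, object@bleach_rate))
})

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("MovieStack: %d frames, %d channels, %d z, %dx%d px",
      d[1], d[2], d[3], d[4], d[5]))
  if (nrow(object@truth)) cat(sprintf(" (simulated, %d cells)", nrow(object@truth)))
  cat("\n")
})

setMethod("show", "CellTrace", function(object) {
  n <- length(object@times)
  cat(sprintf("CellTrace %s (%s): %d frames, %.4g-%.4g min, %d/%d missing (g/r)\n",
      object@cell_id, object@provenance, n,
      if (n) min(object@times) else NA, if (n) max(object@times) else NA,
      sum(is.na(object@intensity_green)), sum(is.na(object@intensity_red))))
})

setMethod("show", "FocusTrack", function(object) {
  cat(sprintf("FocusTrack (%s): frames %d-%d, %d detections, %d gap frame(s)\n",
      object@channel, min(object@detections$frame), max(object@detections$frame),
      nrow(object@detections), length(object@gaps)))
})

setMethod("show", "SigmoidFit", function(object) {
  if (!object@converged) {
    cat(sprintf("SigmoidFit (%s): NOT converged\n", object@channel))
  } else {
    cat(sprintf("SigmoidFit (%s): t_mid %.2f min, tau %.2f, fold %.3f, bleach %.4f/min, r2 %.3f\n",
        object@channel, object@t_mid, object@tau, plateauFold(object),
        object@bleach_rate, object@r_squared))
  }
})

setMethod("show", "CohortResult", function(object) {
  cat(sprintf("CohortResult '%s': n = %d, delta t = %.2f +/- %.2f min (SEM), rate %.2f kb/min\n",
      object@label, as.integer(object@n), object@mean_delta_t, object@sem,
      object@mean_rate))
})

setMethod("show", "ResamplingTestResult", function(object) {
  cat(sprintf("Monte Carlo resampling test (%s, %s): diff = %.3f min, p = %.4g (%s), %s iterations\n",
      object@method, if (object@two_sided) "two-sided" else "one-sided",
      object@observed_diff, object@p_value, starSignificance(object@p_value),
      format(object@n_iterations, big.mark = ",")))
})

setMethod("show", "MeltingCurve", function(object) {
  cat(sprintf("MeltingCurve '%s': %d points, %.1f-%.1f degC\n", object@label,
      length(object@temps), min(object@temps), max(object@temps)))
})

setMethod("show", "MeltingFit", function(object) {
  if (!object@converged) {
    cat("MeltingFit: NOT converged", if (length(object@flags))
      paste0("(", paste(object@flags, collapse = ", "), ")") else "", "\n")
  } else {
    cat(sprintf("MeltingFit: Tm = %.2f degC, dH = %.1f kcal/mol, r2 = %.4f%s\n",
        object@Tm, object@dH_vH, object@r_squared,
        if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ", "), "]") else ""))
  }
})

setMethod("show", "GelLaneProfile", function(object) {
  cat(sprintf("GelLaneProfile: %d points, windows: %s%s\n",
      length(object@positions), paste(names(object@band_windows), collapse = ", "),
      if (!is.na(object@time)) sprintf(" (t = %g min)", object@time) else ""))
})
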