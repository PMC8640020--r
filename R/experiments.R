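#' In-silico calibration and validation experiments
#'
#' Reproduces the bench calibration/validation designs end to end in
#' simulation: ground-truth phases are generated, propagated to the two
#' capture planes, reconstructed by the full chain, analyzed, and tabulated
#' as induced-versus-recovered values with mean +/- SD and range summaries.
#'
#' Experiments:
#' \describe{
#'   \item{`defocus_series`}{13 defocus values spanning -6..+6 D on a 7 mm
#'     pupil; reports recovered spherical equivalent and its error.}
#'   \item{`cylinder_series`}{trial cylinders +0.50, +1.00, +2.00, +3.00 D at
#'     axes 90, 45, 22 degrees; reports recovered plus-cylinder power and
#'     axis errors (axis error is the circular mod-180 distance).}
#'   \item{`dm_validation`}{random 66-term Zernike maps, peak-to-valley
#'     0.35..2.8 um in 0.35 um steps (`maps_per_amplitude` each) on a 4 mm
#'     pupil; reports the RMS residual between reconstruction and ground
#'     truth (piston removed) on the analysis circle.}
#'   \item{`repeatability`}{`n_repeats` acquisitions of one fixed eye with
#'     photon/read noise per the config; reports total and band RMS spread.}
#' }
#'
#' @param name experiment name.
#' @param config a [sim_config()]; experiment-appropriate pupil sizes are
#'   applied on top unless the config was built explicitly for them.
#' @param seed integer seed (drives texture and any random phases).
#' @param k,refine,rim_guard reconstruction settings, see [wfpi()].
#' @param defocus_range,defocus_steps defocus series design.
#' @param cyl_powers,cyl_axes cylinder series design (plus-cylinder D /
#'   degrees).
#' @param amplitudes,maps_per_amplitude DM-validation design (um P-V).
#' @param n_repeats repeatability design.
#' @return list of class `"wfpi_experiment"` with `name`, `table`
#'   (data.frame) and `summary` (named list of statistics).
#' @export
run_experiment <- function(name = c("defocus_series", "cylinder_series",
                                    "dm_validation", "repeatability"),
                           config = NULL, seed = 1L, k = 60L, refine = 5L,
                           rim_guard = 2,
                           defocus_range = c(-6, 6), defocus_steps = 13L,
                           cyl_powers = c(0.5, 1, 2, 3),
                           cyl_axes = c(90, 45, 22),
                           amplitudes = seq(0.35, 2.8, by = 0.35),
                           maps_per_amplitude = 5L,
                           n_repeats = 20L) {
  name <- match.arg(name)
  recon <- function(cfg, ph, sd) {
    pair <- propagate(ph, make_illumination(cfg, seed = sd), cfg)
    if (cfg$noise == "photon+read") {
      pair$i1 <- add_noise(pair$i1, cfg$photon_scale, cfg$read_sigma, sd + 7L)
      pair$i2 <- add_noise(pair$i2, cfg$photon_scale, cfg$read_sigma, sd + 11L)
    }
    wfpi(pair$i1, pair$i2, delta_z = cfg$delta_z, pixel_size = cfg$pixel_pitch,
         k = k, refine = refine, rim_guard = rim_guard)
  }

  if (name == "defocus_series") {
    cfg <- config %||% sim_config(pupil_diameter = 7e-3, seed = seed)
    induced <- seq(defocus_range[1], defocus_range[2], length.out = defocus_steps)
    rows <- lapply(seq_along(induced), function(i) {
      ph <- phase_from_refraction(induced[i], 0, 0, cfg)
      fit <- recon(cfg, ph, seed + i)
      data.frame(induced_D = induced[i], recovered_D = fit$refraction$M,
                 error_D = fit$refraction$M - induced[i])
    })
    tab <- do.call(rbind, rows)
    summ <- list(mean_abs_error_D = mean(abs(tab$error_D)),
                 sd_abs_error_D = stats::sd(abs(tab$error_D)),
                 range_abs_error_D = range(abs(tab$error_D)))
  } else if (name == "cylinder_series") {
    cfg <- config %||% sim_config(pupil_diameter = 7e-3, seed = seed)
    design <- expand.grid(power = cyl_powers, axis = cyl_axes)
    rows <- lapply(seq_len(nrow(design)), function(i) {
      ph <- phase_from_refraction(0, design$power[i], design$axis[i], cfg)
      fit <- recon(cfg, ph, seed + i)
      plus <- as_plus_cylinder(fit$refraction)
      axis_err <- abs(plus$axis - design$axis[i]) %% 180
      axis_err <- min(axis_err, 180 - axis_err)
      data.frame(induced_cyl_D = design$power[i], induced_axis_deg = design$axis[i],
                 recovered_cyl_D = plus$cylinder, recovered_axis_deg = plus$axis,
                 recovered_sphere_D = plus$sphere,
                 cyl_error_D = plus$cylinder - design$power[i],
                 axis_error_deg = axis_err)
    })
    tab <- do.call(rbind, rows)
    summ <- list(mean_abs_cyl_error_D = mean(abs(tab$cyl_error_D)),
                 sd_abs_cyl_error_D = stats::sd(abs(tab$cyl_error_D)),
                 range_abs_cyl_error_D = range(abs(tab$cyl_error_D)),
                 mean_axis_error_deg = mean(tab$axis_error_deg),
                 sd_axis_error_deg = stats::sd(tab$axis_error_deg),
                 range_axis_error_deg = range(tab$axis_error_deg))
  } else if (name == "dm_validation") {
    cfg <- config %||% sim_config(pupil_diameter = 4e-3, seed = seed)
    design <- expand.grid(rep = seq_len(maps_per_amplitude), pv = amplitudes)
    rows <- lapply(seq_len(nrow(design)), function(i) {
      sd_i <- seed + 1000L + i
      ph <- random_dm_phase(design$pv[i], seed = sd_i, config = cfg)
      fit <- recon(cfg, ph, sd_i)
      truth <- analysis_view(ph, fit$circle)
      meas <- fit$analysis$phase
      m <- phase_metrics(meas, truth)
      data.frame(amplitude_pv_um = design$pv[i], map_seed = sd_i,
                 rms_error_um = m$rms_piston_removed,
                 pv_recovered_um = fit$analysis$pv)
    })
    tab <- do.call(rbind, rows)
    summ <- list(max_rms_error_um = max(tab$rms_error_um),
                 mean_rms_error_um = mean(tab$rms_error_um),
                 sd_rms_error_um = stats::sd(tab$rms_error_um))
  } else {                                   # repeatability
    cfg <- config %||% sim_config(pupil_diameter = 7e-3, seed = seed,
                                  noise = "photon+read")
    ph <- phase_from_refraction(0.5, 0, 0, cfg)
    illum <- make_illumination(cfg, seed = seed)
    pair0 <- propagate(ph, illum, cfg)
    rows <- lapply(seq_len(n_repeats), function(i) {
      p <- pair0
      if (cfg$noise == "photon+read") {
        p$i1 <- add_noise(p$i1, cfg$photon_scale, cfg$read_sigma, seed + 2L * i)
        p$i2 <- add_noise(p$i2, cfg$photon_scale, cfg$read_sigma, seed + 2L * i + 1L)
      }
      fit <- wfpi(p$i1, p$i2, delta_z = cfg$delta_z, pixel_size = cfg$pixel_pitch,
                  k = k, refine = refine, rim_guard = rim_guard)
      data.frame(repeat_id = i, total_rms_um = fit$analysis$total_rms,
                 low_um = fit$analysis$bands["low"],
                 medium_um = fit$analysis$bands["medium"],
                 high_um = fit$analysis$bands["high"])
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    summ <- list(mean_total_rms_um = mean(tab$total_rms_um),
                 sd_total_rms_um = stats::sd(tab$total_rms_um),
                 max_pairwise_diff_um = diff(range(tab$total_rms_um)),
                 mean_band_rms_um = c(low = mean(tab$low_um),
                                      medium = mean(tab$medium_um),
                                      high = mean(tab$high_um)))
  }
  structure(list(name = name, table = tab, summary = summ, seed = seed),
            class = "wfpi_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ground-truth phase restricted to an analysis circle, piston/tip/tilt
# removed, for like-for-like comparison with analyze_eye output
analysis_view <- function(phase, circle) {
  g <- pupil_grid(nrow(phase$values), ncol(phase$values),
                  circle$center, circle$radius)
  keep <- g$disk & phase$mask
  vals <- phase$values; vals[!keep] <- NA_real_
  remove_ptt(phase_map(vals, keep, phase$pixel_pitch))
}

#' @export
print.wfpi_experiment <- function(x, ...) {
  cat(sprintf("<wfpi_experiment> %s (%d runs, seed %d)\n",
              x$name, nrow(x$table), x$seed))
  for (nm in names(x$summary)) {
    v <- x$summary[[nm]]
    cat(sprintf("  %s: %s\n", nm, paste(signif(v, 4), collapse = " ")))
  }
  invisible(x)
}
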