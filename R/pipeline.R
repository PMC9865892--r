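#' Pipeline configuration
#'
#' Central configuration for an end-to-end synthesize -> analyze -> report
#' run. Every tolerance and threshold used by any stage is representable
#' here and is serialised with the results, so each number in a report
#' traces back to a config value and a seed.
#'
#' @param systems character vector of generator presets (see
#'   [preset_bilayer_spec()]) or a named list of [bilayer_spec()] objects
#' @param n_frames frames to generate per system
#' @param dt frame spacing, ps
#' @param seed master seed; per-system child seeds are derived from it
#' @param hbond_frames number of frames (evenly spaced) used for
#'   hydrogen-bond and ion-contact counting
#' @param rdf_r_max,rdf_dr RDF range and bin width, nm
#' @param shell_cutoff first hydration shell radius, nm
#' @param hb_distance,hb_angle hydrogen-bond criteria
#' @param ion_cutoff cation-contact cutoff, nm
#' @param lag_window diffusion fit window (fractions of trajectory length)
#' @param out_dir output directory for CSV tables and the JSON report;
#'   NULL keeps results in memory only
#' @return object of class \code{pipeline_config}
#' @export
pipeline_config <- function(systems = c("UL35", "ML35"), n_frames = 200L,
                            dt = 5, seed = 1L, hbond_frames = 8L,
                            rdf_r_max = 1.0, rdf_dr = 0.005,
                            shell_cutoff = 0.3, hb_distance = 0.3,
                            hb_angle = 30, ion_cutoff = 0.32,
                            lag_window = c(0.1, 0.5), out_dir = NULL) {
  cfg <- list(systems = systems, n_frames = as.integer(n_frames), dt = dt,
              seed = as.integer(seed), hbond_frames = as.integer(hbond_frames),
              rdf_r_max = rdf_r_max, rdf_dr = rdf_dr,
              shell_cutoff = shell_cutoff, hb_distance = hb_distance,
              hb_angle = hb_angle, ion_cutoff = ion_cutoff,
              lag_window = lag_window, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  required <- c("systems", "n_frames", "dt", "seed")
  missing <- required[vapply(required, function(k)
    is.null(cfg[[k]]) || !length(cfg[[k]]), logical(1))]
  if (length(missing))
    stop("pipeline config is missing required keys: ",
         paste(missing, collapse = ", "))
  if (cfg$dt <= 0) stop("dt must be positive")
  if (cfg$n_frames < 3) stop("n_frames must be at least 3")
  invisible(cfg)
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file with the fields of [pipeline_config()]
#' @return a \code{pipeline_config}
#' @export
read_pipeline_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, lst)
}

# resolve the systems entry into named bilayer_spec objects
resolve_systems <- function(systems) {
  if (is.character(systems)) {
    specs <- lapply(systems, preset_bilayer_spec)
    names(specs) <- systems
    specs
  } else if (is.list(systems)) {
    if (is.null(names(systems)) || any(names(systems) == ""))
      stop("list-form 'systems' must be named")
    for (s in systems)
      if (!inherits(s, "bilayer_spec")) stop("systems must be bilayer_specs")
    systems
  } else stop("'systems' must be preset names or a named list of specs")
}

# analyse one synthetic system end to end
analyse_system <- function(name, spec, cfg, seed) {
  t0 <- Sys.time()
  base <- build_bilayer(spec, seed = seed)
  traj <- evolve(base, cfg$n_frames, cfg$dt, spec = spec,
                 seed = child_seed(seed, 1))
  atoms <- traj$atoms
  hb_frames <- unique(round(seq(2, n_frames(traj), length.out =
                                  min(cfg$hbond_frames, n_frames(traj)))))

  apl <- area_per_lipid(traj, spec$lipids_per_leaflet)
  th <- membrane_thickness(traj, frames = hb_frames)
  scd <- order_parameters(traj, frames = hb_frames)
  hg <- select_headgroup_atoms(atoms)
  ow <- select_water_oxygens(atoms)
  g <- rdf(traj, hg, ow, r_max = cfg$rdf_r_max, dr = cfg$rdf_dr,
           frames = hb_frames)
  ang <- angular_distribution(traj, hg, cutoff = cfg$shell_cutoff,
                              frames = hb_frames)
  ctr <- costheta_vs_distance(traj, hg, frames = hb_frames)
  tilt <- dipole_tilt_profile(traj, frames = hb_frames)
  hb <- count_by_class(traj, hbond_criteria(cfg$hb_distance, cfg$hb_angle),
                       frames = hb_frames)
  ic <- ion_contacts(traj, cutoff = cfg$ion_cutoff, frames = hb_frames)
  dw <- water_diffusion(traj, lag_window = cfg$lag_window)
  dl <- lateral_diffusion(traj, lag_window = cfg$lag_window)

  TK <- celsius_to_kelvin(spec$temperature_C)
  kappa <- if (apl$sd > 0)
    area_compressibility(apl$series$apl * spec$lipids_per_leaflet, TK)
  else NA_real_
  KA <- if (is.finite(kappa) && kappa > 0)
    bending_modulus(th$thickness, kappa) else NA_real_

  scd_plateau <- mean(scd$minus_scd)
  ang_max <- ang$cos_theta[which.max(ang$density)]

  metrics <- data.frame(
    metric = c("apl_nm2", "thickness_nm", "minus_scd_plateau",
               "hb_lipid_lipid_per_molecule", "hb_water_water_per_molecule",
               "hb_water_lipid", "ion_contacts", "D_water_cm2s",
               "Dxy_lipid_cm2s", "angular_max_cos_theta"),
    value = c(apl$mean, th$thickness, scd_plateau,
              hb$summary$per_molecule[hb$summary$class == "lipid-lipid"],
              hb$summary$per_molecule[hb$summary$class == "water-water"],
              hb$summary$mean[hb$summary$class == "water-lipid"],
              ic$mean, dw$D_cm2s, dl$D_cm2s, ang_max),
    sd = c(apl$sd, th$error, stats::sd(scd$minus_scd),
           hb$summary$sd[hb$summary$class == "lipid-lipid"] / hb$n_lipids,
           hb$summary$sd[hb$summary$class == "water-water"] /
             max(1, hb$n_waters),
           hb$summary$sd[hb$summary$class == "water-lipid"],
           ic$sd, dw$D_se_cm2s, dl$D_se_cm2s, NA))

  list(name = name, spec = spec, seed = seed, metrics = metrics,
       apl = apl, thickness = th, scd = scd, rdf = g, angular = ang,
       costheta_r = ctr, dipole_tilt = tilt, hbonds = hb,
       ion_contacts = ic, water_D = dw, lipid_Dxy = dl,
       kappa_A = kappa, K_A = KA,
       elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Run the full synthesize -> analyze -> report pipeline
#'
#' Builds and propagates every configured system, runs the structural,
#' interfacial-water, hydrogen-bond and diffusion analyses, and (when two
#' or more systems are present) emits a UL-versus-ML comparison table of
#' APL, thickness, chain-order plateau, hydrogen-bond classes with
#' per-molecule normalisation, water D and lipid D_xy. Identical config +
#' seed reproduces the report exactly.
#'
#' @param config a [pipeline_config()], a path to a JSON config, or a list
#'   of config fields
#' @return a \code{run_report}: list with per-system results,
#'   \code{comparison}, \code{config} and provenance
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  specs <- resolve_systems(config$systems)
  results <- list()
  for (i in seq_along(specs)) {
    results[[names(specs)[i]]] <-
      analyse_system(names(specs)[i], specs[[i]], config,
                     seed = child_seed(config$seed, 100 + i))
  }
  comparison <- if (length(results) >= 2)
    compare_systems(results[[1]], results[[2]]) else NULL
  report <- structure(list(
    systems = results, comparison = comparison, config = config,
    provenance = list(package_version =
                        as.character(utils::packageVersion("lamellipid")),
                      seed = config$seed, date = "run-time")),
    class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Compare two analysed systems
#'
#' For every shared metric the ratio a/b and the difference a-b are
#' reported; SDs are propagated by the first-order delta method
#' (sd(a/b) = |a/b| sqrt((sd_a/a)^2 + (sd_b/b)^2), sd(a-b) by quadrature).
#'
#' @param report_a,report_b per-system results from [run_pipeline()] (the
#'   elements of \code{$systems}), or any lists carrying a \code{metrics}
#'   data.frame (metric, value, sd)
#' @return data.frame with value_a, value_b, ratio, ratio_sd, diff, diff_sd
#' @export
compare_systems <- function(report_a, report_b) {
  ma <- report_a$metrics; mb <- report_b$metrics
  shared <- intersect(ma$metric, mb$metric)
  a <- ma[match(shared, ma$metric), ]
  b <- mb[match(shared, mb$metric), ]
  ratio <- a$value / b$value
  ratio_sd <- abs(ratio) * sqrt((a$sd / a$value)^2 + (b$sd / b$value)^2)
  data.frame(metric = shared,
             value_a = a$value, value_b = b$value,
             ratio = ratio, ratio_sd = ratio_sd,
             diff = a$value - b$value,
             diff_sd = sqrt(a$sd^2 + b$sd^2))
}

# serialise a run report: per-analysis CSV tables plus a JSON summary
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  for (sys in report$systems) {
    pre <- file.path(out_dir, sys$name)
    meta <- list(system = sys$name, seed = sys$seed,
                 n_frames = cfg$n_frames, dt_ps = cfg$dt)
    write_result_csv(sys$apl$series, paste0(pre, "_apl.csv"),
                     c(meta, units = "nm^2"))
    write_result_csv(sys$scd, paste0(pre, "_scd.csv"), meta)
    write_result_csv(as.data.frame(sys$rdf), paste0(pre, "_rdf.csv"),
                     c(meta, units = "nm"))
    write_result_csv(sys$angular, paste0(pre, "_angular.csv"), meta)
    write_result_csv(sys$costheta_r$profile, paste0(pre, "_costheta_r.csv"),
                     meta)
    write_result_csv(sys$costheta_r$cumulative,
                     paste0(pre, "_costheta_cum.csv"), meta)
    write_result_csv(sys$dipole_tilt, paste0(pre, "_cosphi_z.csv"), meta)
    write_result_csv(sys$hbonds$summary, paste0(pre, "_hbonds.csv"), meta)
    write_result_csv(sys$metrics, paste0(pre, "_metrics.csv"), meta)
  }
  if (!is.null(report$comparison))
    write_result_csv(report$comparison, file.path(out_dir, "comparison.csv"),
                     list(systems = paste(names(report$systems)[1:2],
                                          collapse = " vs ")))
  summary <- list(
    config = unclass(cfg),
    provenance = report$provenance,
    systems = lapply(report$systems, function(s)
      list(name = s$name, seed = s$seed,
           metrics = s$metrics, kappa_A = s$kappa_A, K_A = s$K_A)),
    comparison = report$comparison)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d system(s): %s (seed %d)\n",
              length(x$systems), paste(names(x$systems), collapse = ", "),
              x$config$seed))
  for (s in x$systems) {
    cat("--", s$name, "--\n")
    print(s$metrics, digits = 4)
  }
  if (!is.null(x$comparison)) {
    cat("-- comparison (a/b) --\n")
    print(x$comparison, digits = 4)
  }
  invisible(x)
}
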