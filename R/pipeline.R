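## End-to-end orchestration: simulate -> segment -> register -> track-tube ->
## drift -> summarize, with a YAML-configurable parameter set and JSON
## artifacts per stage. The command-line wrapper in exec/punctnav is a thin
## shell over these functions.

#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list; any element can
#' be overridden via `overrides` or a YAML file ([load_pipeline_config()]).
#'
#' @param outdir output directory for stage artifacts.
#' @param seed master seed; stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("punctnav_run_"), seed = 0L) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    phantom = list(spacing = 1.0),
    camera = list(nx = 320L, ny = 240L, fov_deg = 29.9,
                  noise_sigma = 0.1, dropout = 0.0, distance = 1200),
    pose = list(angle_deg = 8, axis = c(0, 0, 1), translation = c(25, -10, 5)),
    icp = list(max_iterations = 100L, rel_tolerance = 1e-6,
               subsample_size = 5000L, trim_fraction = 0.2),
    registration = list(quality_threshold = 1.0, max_restarts = 3L),
    ransac = list(distance_threshold = 0.6, max_iterations = 1000L,
                  min_inlier_fraction = 0.3, normal_k = 12L),
    tube = list(radius = 5, length = 80, angular_coverage = 180,
                n_points = 2000L, noise_sigma = 0.2, outlier_fraction = 0.1),
    tolerance = list(max_angle_deg = 3, max_offset_mm = 2),
    drift = list(surface_shift_mm = c(0.0, 0.0, 0.0),
                 extra_bone_shift_mm = c(0.3, 0.0, 0.0)),
    verbosity = 1L), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over the defaults; keys absent from the
#' file keep their default values.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param outdir,seed convenience overrides applied after the file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path = NULL, outdir = NULL, seed = NULL) {
  cfg <- pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user)
  }
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

.merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      .merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

#' Dump a configuration as YAML text
#' @param cfg a `pipeline_config`.
#' @return YAML character string, invisibly; also printed.
#' @export
dump_config <- function(cfg = pipeline_config()) {
  txt <- yaml::as.yaml(unclass(cfg))
  cat(txt)
  invisible(txt)
}

.transform_json <- function(t) {
  list(rotation = as.vector(t(t$rotation)), translation = t$translation)
}

.log_stage <- function(cfg, ...) {
  if (isTRUE(cfg$verbosity >= 1L)) message(sprintf(...))
}

#' Run the full navigation rehearsal pipeline
#'
#' Executes, in order: phantom simulation (CT volume + ground-truth meshes +
#' landmarks), CT segmentation (surface and skeleton models), intraoperative
#' scan simulation and two-step registration, guiding-tube tracking against a
#' planned path, drift injection and assessment, and the cohort summary of
#' the shipped specimen table. Writes per-stage JSON artifacts plus a
#' combined `report.json` into `cfg$outdir`; every artifact records the seed.
#' Any stage failure raises an error naming the stage.
#'
#' @param cfg a [pipeline_config()].
#' @return The combined report list, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed)
  stage <- function(name, expr) {
    .log_stage(cfg, "[punctnav] stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  ## --- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    spec <- phantom_spec(seed = cfg$seed)
    ph <- make_phantom(spec)
    vol <- voxelize_ct(ph$skin, ph$bone, spacing = cfg$phantom$spacing)
    write_volume(vol, file.path(cfg$outdir, "phantom_ct.nii.gz"))
    write_stl(ph$skin, file.path(cfg$outdir, "phantom_skin.stl"))
    write_stl(ph$bone, file.path(cfg$outdir, "phantom_bone.stl"))
    list(phantom = ph, volume = vol)
  })
  report$simulate <- list(voxels = dim(sim$volume$values),
                          landmarks = nrow(sim$phantom$landmarks), seed = cfg$seed)

  ## --- segment ----------------------------------------------------------
  seg <- stage("segment", {
    surface <- segment_model(sim$volume, "surface")
    skeleton <- segment_model(sim$volume, "skeleton")
    write_stl(surface, file.path(cfg$outdir, "ct_surface.stl"))
    write_stl(skeleton, file.path(cfg$outdir, "ct_skeleton.stl"))
    list(surface = surface, skeleton = skeleton)
  })
  report$segment <- list(surface_faces = nrow(seg$surface$faces),
                         skeleton_faces = nrow(seg$skeleton$faces))

  ## --- register ---------------------------------------------------------
  reg <- stage("register", {
    pose <- rotation_transform(cfg$pose$axis, cfg$pose$angle_deg, cfg$pose$translation)
    posed_skin <- apply_transform(sim$phantom$skin, pose)
    center <- colMeans(posed_skin$vertices)
    cam <- sli_camera(position = center + c(0, -cfg$camera$distance, 0),
                      look_at = center, nx = cfg$camera$nx, ny = cfg$camera$ny,
                      fov_deg = cfg$camera$fov_deg,
                      noise_sigma = cfg$camera$noise_sigma,
                      dropout = cfg$camera$dropout, seed = cfg$seed + 1L)
    scan <- simulate_sli(posed_skin, cam)
    scan <- crop_and_denoise(scan)
    lm <- list(src = sim$phantom$landmarks,
               dst = apply_transform(sim$phantom$landmarks, pose))
    write_landmarks(lm$src, lm$dst, file.path(cfg$outdir, "landmarks.txt"))
    write_ply(scan, file.path(cfg$outdir, "scan.ply"))
    p <- icp_params(max_iterations = cfg$icp$max_iterations,
                    rel_tolerance = cfg$icp$rel_tolerance,
                    subsample_size = cfg$icp$subsample_size,
                    trim_fraction = cfg$icp$trim_fraction, seed = cfg$seed)
    res <- register_two_step(scan, seg$surface, lm, p,
                             quality_threshold = cfg$registration$quality_threshold,
                             max_restarts = cfg$registration$max_restarts)
    write_ply(apply_transform(seg$surface, res$total),
              file.path(cfg$outdir, "ct_surface_in_sli.ply"))
    list(result = res, pose = pose, scan = scan)
  })
  report$register <- list(rms = reg$result$rms, iterations = reg$result$iterations,
                          converged = reg$result$converged,
                          restarts = reg$result$restarts, seed = reg$result$seed,
                          coarse = .transform_json(reg$result$coarse),
                          fine = .transform_json(reg$result$fine),
                          total = .transform_json(reg$result$total))

  ## --- track-tube -------------------------------------------------------
  tube <- stage("track-tube", {
    entry <- reg$scan$points[which.max(reg$scan$points[, 3]), ]
    path <- plan_path(entry, entry + c(5, 10, -40))
    true_tube <- cylinder_model(path$entry + (cfg$tube$length / 2) * path$direction,
                                path$direction, cfg$tube$radius, cfg$tube$length)
    cloud <- make_tube_cloud(true_tube, cfg$tube$angular_coverage,
                             cfg$tube$n_points, cfg$tube$noise_sigma,
                             cfg$tube$outlier_fraction, seed = cfg$seed + 2L)
    rp <- ransac_params(distance_threshold = cfg$ransac$distance_threshold,
                        max_iterations = cfg$ransac$max_iterations,
                        min_inlier_fraction = cfg$ransac$min_inlier_fraction,
                        normal_k = cfg$ransac$normal_k, seed = cfg$seed)
    fit <- fit_cylinder_ransac(cloud, rp)
    dev <- path_deviation(fit$model, path)
    gate <- check_tolerance(dev, cfg$tolerance$max_angle_deg, cfg$tolerance$max_offset_mm)
    write_stl(cylinder_mesh(fit$model), file.path(cfg$outdir, "tube_fit.stl"))
    list(fit = fit, dev = dev, gate = gate)
  })
  report$track_tube <- list(radius = tube$fit$model$radius,
                            length = tube$fit$model$length,
                            inlier_fraction = tube$fit$inlier_fraction,
                            angle = tube$dev$angle,
                            lateral_offset = tube$dev$lateral_offset,
                            tip_gap = tube$dev$tip_gap,
                            pass = tube$gate$pass, message = tube$gate$message)

  ## --- drift ------------------------------------------------------------
  drift <- stage("drift", {
    shifted <- inject_drift(sim$phantom$skin, sim$phantom$bone,
                            translation_transform(cfg$drift$surface_shift_mm),
                            translation_transform(cfg$drift$extra_bone_shift_mm))
    # pre/post surface registration via landmarks + ICP on skin vertices
    lm <- list(src = sim$phantom$landmarks,
               dst = apply_transform(sim$phantom$landmarks, shifted$truth$surface_shift))
    p <- icp_params(subsample_size = 2000L, seed = cfg$seed)
    surf_reg <- register_two_step(point_cloud(shifted$skin$vertices),
                                  sim$phantom$skin,
                                  list(src = lm$src, dst = lm$dst), p)
    surf <- drift_field(sim$phantom$skin, shifted$skin, surf_reg$total,
                        source_label = "preoperative surface",
                        target_label = "postoperative surface")
    skel <- skeletal_drift(sim$phantom$bone, shifted$bone, surf_reg$total)
    export_heatmap(sim$phantom$bone, skel$distances,
                   file.path(cfg$outdir, "skeletal_drift_heatmap.ply"))
    list(surface = surf, skeletal = skel, truth = shifted$truth)
  })
  report$drift <- list(surface_rms = drift$surface$rms,
                       surface_mean = drift$surface$mean,
                       skeletal_mean = drift$skeletal$mean,
                       skeletal_rms = drift$skeletal$rms,
                       injected_bone_shift = drift$truth$bone_shift_magnitude)

  ## --- summarize --------------------------------------------------------
  summ <- stage("summarize", {
    s <- summarize_drift_table()
    lapply(s$columns, function(cs) list(mean = cs$mean, sd = cs$sd, n = cs$n))
  })
  report$summarize <- summ

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_stage(cfg, "[punctnav] report written to %s",
             file.path(cfg$outdir, "report.json"))
  invisible(report)
}
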