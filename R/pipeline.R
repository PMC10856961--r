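#' Pipeline configuration
#'
#' Collects every tunable of the scan-to-volume pipeline with documented
#' defaults. Serializes losslessly to YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param camera Camera geometry and noise: `distance` (m), `height` (m),
#'   `noise_sigma_mm`, `dropout_rate`, `image_scale` (1 = native
#'   512 x 424).
#' @param segmentation Threshold policy (`"otsu"` or a number),
#'   region-growth tolerance `tol_frac`, morphology radii, minimum
#'   component size and the platform depth-offset rule (mm).
#' @param icp ICP controls: `max_iter`, `tol`, `trim`.
#' @param reconstruction `normal_k`, `poisson_depth`,
#'   `min_component_frac`, `smooth_iters`.
#' @param platform_height_m Standing-platform height (m).
#' @param seed Integer seed; all pipeline randomness flows from it.
#' @param out_dir Output directory (default: a session temp directory).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(camera = list(), segmentation = list(),
                            icp = list(), reconstruction = list(),
                            platform_height_m = 0.3, seed = 1L,
                            out_dir = NULL) {
  merge_defaults <- function(user, def) {
    bad <- setdiff(names(user), names(def))
    if (length(bad))
      stop_bodyscan("invalid_config",
                    paste0("unknown config fields: ", paste(bad, collapse = ", ")))
    utils::modifyList(def, user)
  }
  cfg <- list(
    camera = merge_defaults(camera, list(
      distance = 1.9, height = 1.1, noise_sigma_mm = 0, dropout_rate = 0,
      image_scale = 1)),
    segmentation = merge_defaults(segmentation, list(
      threshold = "otsu", tol_frac = 0.25, open_radius_px = 1,
      close_radius_px = 2, min_component_px = 64, platform_offset_mm = 120)),
    icp = merge_defaults(icp, list(max_iter = 50, tol = 1e-6, trim = 0.1,
                                   prior_sigma_t = 0.005,
                                   prior_sigma_deg = 0.5)),
    reconstruction = merge_defaults(reconstruction, list(
      normal_k = 30, poisson_depth = 8, min_component_frac = 0.01,
      smooth_iters = 5)),
    platform_height_m = platform_height_m,
    seed = as.integer(seed),
    out_dir = out_dir
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config), precision = 17), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(camera = x$camera, segmentation = x$segmentation,
                  icp = x$icp, reconstruction = x$reconstruction,
                  platform_height_m = x$platform_height_m,
                  seed = x$seed, out_dir = x$out_dir)
}

config_cameras <- function(cfg) {
  cc <- cfg$camera
  s <- cc$image_scale
  base <- function(eye, target) camera_model(
    fx = 365 * s, fy = 365 * s, cx = 256 * s, cy = 212 * s,
    width = round(512 * s), height = round(424 * s),
    pose = look_at_pose(eye, target),
    noise_sigma_mm = cc$noise_sigma_mm, dropout_rate = cc$dropout_rate)
  list(
    anterior = base(c(0, cc$height, cc$distance), c(0, cc$height, 0)),
    posterior = base(c(0, cc$height, -cc$distance), c(0, cc$height, 0))
  )
}

#' Estimate body volume from an anterior/posterior scene pair
#'
#' The core scan-to-volume chain: segment each IR frame, remove the
#' platform band, clean the mask, fuse with depth, back-project both
#' views, register them with ICP, reconstruct and clean the surface, and
#' integrate the enclosed volume.
#'
#' @param anterior,posterior `scene_render` objects (rendered or read
#'   from disk).
#' @param config A [pipeline_config()].
#' @return A `volume_estimate`: `raw_liters`, `fitted_liters` (`NA` until
#'   calibrated), `mesh`, and provenance (point counts, ICP RMS,
#'   watertightness).
#' @export
estimate_volume <- function(anterior, posterior, config = pipeline_config()) {
  sg <- config$segmentation
  process_view <- function(sc) {
    mask <- segment_body(sc$ir, threshold = sg$threshold,
                         tol_frac = sg$tol_frac)
    attr(mask, "view") <- sc$view
    mask <- exclude_platform(mask, sc$depth, offset_mm = sg$platform_offset_mm)
    mask <- clean_mask(mask, open_radius_px = sg$open_radius_px,
                       close_radius_px = sg$close_radius_px,
                       min_component_px = sg$min_component_px)
    md <- apply_mask(sc$depth, mask, near_mm = sc$camera$near * 1000,
                     far_mm = sc$camera$far * 1000)
    backproject(md, sc$camera)
  }
  cl_a <- process_view(anterior)
  cl_p <- process_view(posterior)
  reg <- align_views(cl_a, cl_p, max_iter = config$icp$max_iter,
                     tol = config$icp$tol, trim = config$icp$trim,
                     prior_sigma_t = config$icp$prior_sigma_t,
                     prior_sigma_deg = config$icp$prior_sigma_deg)
  rc <- config$reconstruction
  mesh <- reconstruct_surface(reg$merged, normal_k = rc$normal_k,
                              poisson_depth = rc$poisson_depth)
  mesh <- clean_mesh(mesh, min_component_frac = rc$min_component_frac,
                     smooth_iters = rc$smooth_iters)
  structure(
    list(raw_liters = mesh_volume(mesh), fitted_liters = NA_real_,
         mesh = mesh,
         provenance = list(
           n_points_anterior = nrow(cl_a$points),
           n_points_posterior = nrow(cl_p$points),
           icp_rms = reg$rms, icp_iterations = reg$iterations,
           watertight = is_watertight(mesh)$watertight)),
    class = "volume_estimate"
  )
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("<volume_estimate> raw %.3f L%s\n", x$raw_liters,
              if (!is.na(x$fitted_liters))
                sprintf(", fitted %.3f L", x$fitted_liters) else ""))
  invisible(x)
}

#' Run the full pipeline over scene files and/or a cohort table
#'
#' Executes, as requested by the inputs: per scene pair
#' segment -> reconstruct -> volume; then, when a cohort table is given,
#' replicate selection -> calibration -> fat mass -> agreement. Writes
#' JSON reports (and PLY meshes when `write_meshes`) under the config's
#' output directory and returns a run manifest capturing the config,
#' input digests, package version and per-stage records, so a rerun with
#' the same manifest reproduces identical numbers for deterministic
#' stages.
#'
#' @param config A [pipeline_config()].
#' @param scene_index Optional tibble with columns `id`, `anterior` and
#'   `posterior` (scene file prefixes), e.g. from [make_fixture_cohort()].
#' @param cohort Optional cohort tibble or CSV path (columns `id`,
#'   `sex_code`, `age_years`, `height_m`, `weight_kg`, `pa_min_week`,
#'   `bodpod_bv_l_1..3`, `dxa_fm_kg`).
#' @param write_meshes Write one PLY per scene pair.
#' @return A list of class `run_manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), scene_index = NULL,
                         cohort = NULL, write_meshes = FALSE) {
  out_dir <- config$out_dir %||% file.path(tempdir(), "bodyscan_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("bodyscan")),
                   inputs = list(), stages = list(), outputs = character(0))
  add_stage <- function(name, params, warnings, secs) {
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(stage = name, params = params, warnings = warnings,
           seconds = secs)
  }
  volumes <- NULL
  if (!is.null(scene_index)) {
    stopifnot(all(c("id", "anterior", "posterior") %in% names(scene_index)))
    files <- unlist(lapply(c(scene_index$anterior, scene_index$posterior),
                           function(p) unlist(scene_paths(p))))
    manifest$inputs$scenes <- as.list(tools::md5sum(files[file.exists(files)]))
    t0 <- Sys.time()
    warns <- character(0)
    rows <- lapply(seq_len(nrow(scene_index)), function(i) {
      pre_a <- scene_index$anterior[i]
      pre_p <- scene_index$posterior[i]
      est <- withCallingHandlers(
        tryCatch(
          estimate_volume(read_scene(pre_a), read_scene(pre_p), config),
          error = function(e) {
            stop_bodyscan("stage_error",
                          sprintf("volume stage failed for '%s': %s",
                                  scene_index$id[i], conditionMessage(e)))
          }),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (write_meshes) {
        ply <- file.path(out_dir, paste0(basename(pre_a), "_mesh.ply"))
        write_ply(est$mesh, ply)
        manifest$outputs <<- c(manifest$outputs, ply)
      }
      tibble::tibble(id = scene_index$id[i], scene = basename(pre_a),
                     raw_bv_l = est$raw_liters,
                     icp_rms = est$provenance$icp_rms)
    })
    volumes <- dplyr::bind_rows(rows)
    add_stage("segment+reconstruct+volume",
              list(n_scenes = nrow(scene_index)), unique(warns),
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    vol_path <- file.path(out_dir, "volumes.json")
    jsonlite::write_json(volumes, vol_path, digits = NA)
    manifest$outputs <- c(manifest$outputs, vol_path)
  }
  report <- NULL
  if (!is.null(cohort)) {
    if (is.character(cohort)) {
      if (!file.exists(cohort))
        stop_bodyscan("stage_error",
                      paste0("cohort stage: file not found: ", cohort))
      manifest$inputs$cohort <- as.list(tools::md5sum(cohort))
      cohort <- readr::read_csv(cohort, show_col_types = FALSE)
    }
    t0 <- Sys.time()
    warns <- character(0)
    withCallingHandlers({
      cohort <- tibble::as_tibble(cohort)
      rep_cols <- grep("^bodpod_bv_l", names(cohort), value = TRUE)
      cohort$bodpod_bv_l <- vapply(seq_len(nrow(cohort)), function(i) {
        select_replicates(as.numeric(cohort[i, rep_cols]))$selected_value
      }, numeric(1))
      if (!is.null(volumes)) {
        per_subj <- dplyr::summarise(
          dplyr::group_by(volumes, .data$id),
          kinect_raw_bv_l = mean(.data$raw_bv_l), .groups = "drop")
        cohort <- dplyr::left_join(
          dplyr::select(cohort, -dplyr::any_of("kinect_raw_bv_l")),
          per_subj, by = "id")
      }
      stopifnot("kinect_raw_bv_l" %in% names(cohort))
      calib <- fit_bv_calibration(cohort$kinect_raw_bv_l, cohort$bodpod_bv_l)
      cohort$fitted_bv_l <- apply_calibration(calib, cohort$kinect_raw_bv_l)
      cohort <- estimate_fat_mass(cohort, bv_col = "fitted_bv_l")
      ba_bv <- bland_altman(cohort$bodpod_bv_l, cohort$fitted_bv_l)
      ba_fm <- if ("dxa_fm_kg" %in% names(cohort))
        bland_altman(cohort$dxa_fm_kg, cohort$fm_kg) else NULL
      report <- list(
        n = nrow(cohort),
        calibration = glance(calib),
        bv_error_raw = report_bv_error(cohort$kinect_raw_bv_l,
                                       cohort$bodpod_bv_l),
        bv_error_fitted = report_bv_error(cohort$fitted_bv_l,
                                          cohort$bodpod_bv_l),
        agreement_bv = glance(ba_bv),
        agreement_fm = if (!is.null(ba_fm)) glance(ba_fm) else NULL,
        cohort = cohort
      )
    }, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    add_stage("calibrate+fm+agree", list(n = nrow(cohort)), unique(warns),
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    rep_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report[setdiff(names(report), "cohort")], rep_path,
                         digits = NA, auto_unbox = TRUE)
    manifest$outputs <- c(manifest$outputs, rep_path)
  }
  manifest$volumes <- volumes
  manifest$report <- report
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest[c("config", "package_version", "inputs",
                                  "stages", "outputs")],
                       man_path, digits = NA, auto_unbox = TRUE, force = TRUE)
  manifest$outputs <- c(manifest$outputs, man_path)
  class(manifest) <- "run_manifest"
  manifest
}

#' Strip volatile fields (timings) from a manifest for comparison
#'
#' @param manifest A `run_manifest`.
#' @return The manifest with per-stage timings removed.
#' @export
manifest_fingerprint <- function(manifest) {
  m <- unclass(manifest)[c("config", "package_version", "inputs", "stages",
                           "volumes", "report")]
  m$stages <- lapply(m$stages, function(s) s[setdiff(names(s), "seconds")])
  m
}
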