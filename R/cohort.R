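#' Generate a synthetic validation cohort with rendered scenes
#'
#' Emulates the study design the package is validated against: `n`
#' standing adults, each scanned six times (two independent observers,
#' three repeats each) by the two-camera rig, alongside reference
#' air-displacement body-volume replicates and a reference fat mass.
#' Covariates are drawn from cohort-like distributions (heights around
#' 1.60/1.72 m and weights around 61/78 kg for women/men, ages 20-42,
#' mixed activity levels); each subject gets a humanoid phantom with the
#' subject's stature and a bulk chosen so the phantom volume matches a
#' plausible body volume (`weight / 1.05` L). Reference columns are
#' produced by a known generative rule so that recovery is checkable:
#' `bodpod_bv_l_*` are the phantom volume plus 40 mL replicate noise, and
#' `dxa_fm_kg` follows the package's fat-mass equation on the true volume
#' plus 1.2 kg noise. Observer/repeat scans jitter the camera rig
#' (repeat jitter SD 2 cm in stand-off, 1 cm in height and lateral
#' offset; observer 2 stands 1.5 cm further back) and apply the depth
#' noise model, then write the scene files.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param seed Integer seed; the only source of randomness.
#' @param dir Output directory for `cohort.csv` and scene files (created;
#'   default a temp directory).
#' @param render Render and write the 6 scene pairs per subject (set
#'   `FALSE` to generate the table only).
#' @param noise_sigma_mm,dropout_rate Depth noise model of the rig.
#' @param image_scale Camera resolution scale (1 = native 512 x 424).
#' @param platform_height_m Standing-platform height.
#' @param voxel_mm Phantom ground-truth voxelization resolution.
#' @return List with `cohort` (tibble), `scene_index` (tibble: `id`,
#'   `observer`, `repeat_no`, `anterior`, `posterior` prefixes; one row
#'   per scene pair), `dir` and `csv` (path).
#' @export
make_fixture_cohort <- function(n_subjects, seed, dir = NULL, render = TRUE,
                                noise_sigma_mm = 2, dropout_rate = 0.02,
                                image_scale = 1, platform_height_m = 0.3,
                                voxel_mm = 3) {
  if (n_subjects < 3)
    stop_bodyscan("input_error", "need at least 3 subjects")
  dir <- dir %||% file.path(tempdir(), sprintf("bodyscan_cohort_%d", seed))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_local_seed(seed, {
    sex <- sample(rep(1:2, length.out = n_subjects))
    height <- ifelse(sex == 1, stats::rnorm(n_subjects, 1.60, 0.07),
                     stats::rnorm(n_subjects, 1.72, 0.05))
    height <- pmin(pmax(height, 1.45), 1.85)
    weight <- ifelse(sex == 1, stats::rnorm(n_subjects, 61.2, 8.2),
                     stats::rnorm(n_subjects, 78.1, 12.9))
    weight <- pmin(pmax(weight, 40), 120)
    age <- round(pmin(pmax(stats::rnorm(n_subjects, 28.3, 6), 20), 42))
    sedentary <- stats::runif(n_subjects) < 0.43
    pa <- ifelse(sedentary, stats::runif(n_subjects, 0, 150),
                 stats::runif(n_subjects, 150, 600))
    pa <- round(pa)

    target_bv <- weight / 1.05
    phantoms <- vector("list", n_subjects)
    ref_bv <- numeric(n_subjects)
    for (i in seq_len(n_subjects)) {
      v0 <- humanoid_phantom(height[i], bulk = 1,
                             voxel_mm = voxel_mm)$reference_volume_liters
      bulk <- min(max(sqrt(target_bv[i] / v0), 0.6), 1.5)
      phantoms[[i]] <- humanoid_phantom(height[i], bulk = bulk,
                                        voxel_mm = voxel_mm)
      ref_bv[i] <- phantoms[[i]]$reference_volume_liters
    }
    bodpod <- vapply(seq_len(n_subjects), function(i)
      ref_bv[i] + stats::rnorm(3, 0, 0.04), numeric(3))
    fm_true <- fat_mass_eq1(
      list(sex_code = sex, pa_min_week = pa, height_m = height),
      ref_bv)$fm_kg
    dxa_fm <- fm_true + stats::rnorm(n_subjects, 0, 1.2)

    cohort <- tibble::tibble(
      id = sprintf("s%02d", seq_len(n_subjects)),
      sex_code = sex, age_years = age, height_m = height,
      weight_kg = weight, pa_min_week = pa,
      bodpod_bv_l_1 = bodpod[1, ], bodpod_bv_l_2 = bodpod[2, ],
      bodpod_bv_l_3 = bodpod[3, ],
      dxa_fm_kg = dxa_fm, ref_bv_l = ref_bv
    )

    grid <- expand.grid(repeat_no = 1:3, observer = 1:2,
                        subject = seq_len(n_subjects))
    scene_index <- tibble::tibble(
      id = cohort$id[grid$subject],
      observer = grid$observer, repeat_no = grid$repeat_no,
      anterior = file.path(dir, sprintf("%s_o%d_r%d_anterior",
                                        cohort$id[grid$subject],
                                        grid$observer, grid$repeat_no)),
      posterior = file.path(dir, sprintf("%s_o%d_r%d_posterior",
                                         cohort$id[grid$subject],
                                         grid$observer, grid$repeat_no))
    )
    if (render) {
      for (r in seq_len(nrow(scene_index))) {
        subj <- match(scene_index$id[r], cohort$id)
        obs_off <- if (scene_index$observer[r] == 2) 0.015 else 0
        dist <- 1.9 + obs_off + stats::rnorm(1, 0, 0.02)
        hgt <- 1.1 + stats::rnorm(1, 0, 0.01)
        lat <- stats::rnorm(1, 0, 0.01)
        s <- image_scale
        mk <- function(eye, target) camera_model(
          fx = 365 * s, fy = 365 * s, cx = 256 * s, cy = 212 * s,
          width = round(512 * s), height = round(424 * s),
          pose = look_at_pose(eye, target),
          noise_sigma_mm = noise_sigma_mm, dropout_rate = dropout_rate)
        cams <- list(
          anterior = mk(c(lat, hgt, dist), c(lat, hgt, 0)),
          posterior = mk(c(-lat, hgt, -dist), c(-lat, hgt, 0)))
        scene_seed <- as.integer((as.numeric(seed) * 1000 + r) %% 2147483647)
        rv <- render_views(phantoms[[subj]], cams$anterior, cams$posterior,
                           platform_height_m = platform_height_m,
                           seed = scene_seed)
        write_scene(rv$anterior, scene_index$anterior[r])
        write_scene(rv$posterior, scene_index$posterior[r])
      }
    }
  })
  csv <- file.path(dir, "cohort.csv")
  readr::write_csv(cohort, csv)
  list(cohort = cohort, scene_index = scene_index, dir = dir, csv = csv)
}
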