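#' Built-in phantom landmark templates
#'
#' Canonical world positions (mm) for the synthetic skull phantoms. `toy8`
#' places the 8-landmark midline/mandible subset (N, S, A, B, Pog, Me, GoL,
#' GoR) inside the default 76.8 mm cube; `full46` lays out all 46 clinical
#' landmarks in an anatomically plausible arrangement inside a 120 mm head
#' frame (midline at x = 60, left side at larger x). These are schematic
#' skulls for exercising the pipeline, not anatomical atlases.
#'
#' @param name `"toy8"` or `"full46"`.
#' @return Named matrix (id x xyz) of template positions in mm.
#' @export
phantom_template <- function(name = "toy8") {
  if (name == "toy8") {
    m <- rbind(N = c(38, 60, 52), S = c(38, 42, 50), A = c(38, 62, 36),
               B = c(38, 60, 26), Pog = c(38, 59, 20), Me = c(38, 56, 14),
               GoL = c(18, 34, 22), GoR = c(58, 34, 22))
  } else if (name == "full46") {
    mid <- rbind(N = c(60, 95, 80), S = c(60, 70, 78), Ba = c(60, 52, 48),
                 ANS = c(60, 98, 60), PNS = c(60, 70, 58),
                 A = c(60, 99, 56), B = c(60, 97, 38),
                 Pog = c(60, 96, 30), Gn = c(60, 94, 26),
                 Me = c(60, 90, 22), SM = c(60, 86, 27),
                 FI = c(60, 88, 54), CUI = c(60, 96, 50),
                 CLI = c(60, 95, 42))
    left <- rbind(Co = c(88, 58, 66), Po = c(92, 54, 64),
                  Or = c(78, 88, 66), Go = c(85, 62, 30),
                  J = c(82, 84, 56), FInf = c(75, 90, 64),
                  FMan = c(84, 64, 40), FMen = c(72, 90, 28),
                  FPal = c(68, 74, 54), UMol = c(74, 80, 48),
                  LMol = c(74, 80, 42), PcmU = c(73, 82, 46),
                  UIA = c(63, 94, 54), UIE = c(63, 96, 46),
                  LIA = c(63, 93, 36), LIE = c(63, 95, 44))
    right <- left
    right[, 1] <- 120 - right[, 1]
    rownames(left) <- paste0(rownames(left), "L")
    rownames(right) <- paste0(rownames(right), "R")
    m <- rbind(left, right, mid)
    m <- m[landmark_schema("clinical46")$id, ]
  } else {
    stop("unknown phantom template: ", name, call. = FALSE)
  }
  colnames(m) <- c("x", "y", "z")
  m
}

#' Phantom specification
#'
#' Defines the synthetic study conditions: a dark background with bright
#' ellipsoidal bone-like shells, a bright sphere at every landmark
#' (radially decreasing intensity, brightest at the landmark), per-case
#' anatomical jitter, a shared per-case rigid perturbation, intensity
#' noise, and an optional cohort shift applied to cohort "B" templates.
#'
#' @param template `"toy8"` (default), `"full46"`, or a named id-by-xyz
#'   matrix of canonical positions in mm.
#' @param grid_size voxels per axis (length 1 or 3; default 48).
#' @param spacing isotropic mm per voxel (default 1.6, the training grid).
#' @param jitter_sd per-landmark anatomical variation, mm (default 2).
#' @param blob_radius radius of the bright landmark sphere, mm (default 4).
#' @param shells list of ellipsoidal shells, each
#'   `list(center =, radii =, thickness =, intensity =)` in mm/intensity
#'   units; defaults provide a cranial and a mandibular shell scaled to the
#'   template extent.
#' @param blob_intensity peak landmark intensity (default 1).
#' @param noise_sd additive Gaussian intensity noise (default 0.05).
#' @param rigid_rotation_max,rigid_translation_max magnitude of the shared
#'   per-case rigid perturbation (degrees / mm; defaults 5 and 3).
#' @param cohort_shift length-3 mm offset added to cohort "B" templates
#'   (default zero).
#' @param seed master seed; each case derives its own stream from
#'   `(seed, case_index)`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(template = "toy8", grid_size = 48, spacing = 1.6,
                         jitter_sd = 2, blob_radius = 4, shells = NULL,
                         blob_intensity = 1, noise_sd = 0.05,
                         rigid_rotation_max = 5, rigid_translation_max = 3,
                         cohort_shift = c(0, 0, 0), seed = 1L) {
  tpl <- if (is.character(template)) phantom_template(template) else {
    stopifnot(is.matrix(template), ncol(template) == 3,
              !is.null(rownames(template)))
    template
  }
  grid_size <- as.integer(rep(grid_size, length.out = 3))
  spacing <- rep(spacing, length.out = 3)
  stopifnot(jitter_sd >= 0, noise_sd >= 0, blob_radius > 0,
            all(grid_size >= 4), all(spacing > 0))
  extent <- (grid_size - 1) * spacing
  margin <- 4 * jitter_sd
  if (any(tpl < margin - 1e-9) ||
      any(sweep(tpl, 2, extent - margin) > 1e-9))
    stop("template positions must lie inside the grid with a 4*jitter_sd ",
         "margin", call. = FALSE)
  if (is.null(shells)) {
    ctr <- colMeans(rbind(rep(0, 3), extent))
    shells <- list(
      list(center = ctr + c(0, 0.05, 0.12) * extent,
           radii = 0.34 * extent, thickness = 3, intensity = 0.5),
      list(center = ctr + c(0, 0.08, -0.28) * extent,
           radii = c(0.28, 0.22, 0.14) * extent, thickness = 2.5,
           intensity = 0.5))
  }
  structure(list(template = tpl, grid_size = grid_size, spacing = spacing,
                 jitter_sd = jitter_sd, blob_radius = blob_radius,
                 shells = shells, blob_intensity = blob_intensity,
                 noise_sd = noise_sd,
                 rigid_rotation_max = rigid_rotation_max,
                 rigid_translation_max = rigid_translation_max,
                 cohort_shift = as.numeric(cohort_shift),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

case_seed <- function(seed, case_index, cohort = "A") {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(case_index) * 7919 +
                (cohort == "B") * 499979) %% 2147483647)
}

#' Generate one phantom case
#'
#' Deterministic given `(spec$seed, case_index)`: draws per-landmark
#' Gaussian jitter (regenerated up to 10 times if a landmark would escape
#' the grid), a shared rigid perturbation applied identically to landmarks
#' and image content, renders shells and landmark blobs analytically in
#' world space, and adds intensity noise.
#'
#' @param spec a [phantom_spec()].
#' @param case_index positive integer.
#' @param cohort `"A"` (template as-is) or `"B"` (template plus
#'   `cohort_shift`).
#' @param render if `FALSE`, skip image synthesis and return only the
#'   landmarks (used by statistics-only simulations).
#' @return `list(volume =, landmarks =, case_id =, cohort =)`; `volume` is
#'   NULL when `render = FALSE`.
#' @export
generate_case <- function(spec, case_index, cohort = "A", render = TRUE) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old))
  set.seed(case_seed(spec$seed, case_index, cohort))
  tpl <- spec$template
  if (cohort == "B") tpl <- sweep(tpl, 2, -spec$cohort_shift)
  extent <- (spec$grid_size - 1) * spec$spacing
  gc <- extent / 2
  rot <- runif(3, -spec$rigid_rotation_max, spec$rigid_rotation_max)
  trans <- runif(3, -spec$rigid_translation_max, spec$rigid_translation_max)
  R <- rot_matrix(rot)

  ok <- FALSE
  for (try in 1:10) {
    jit <- matrix(rnorm(length(tpl), sd = spec$jitter_sd), nrow(tpl), 3)
    pts <- tpl + jit
    world <- t(R %*% (t(pts) - gc) + gc + trans)
    if (all(world >= 0) && all(sweep(world, 2, extent) <= 0)) {
      ok <- TRUE
      break
    }
  }
  if (!ok)
    stop("phantom spec error: landmarks escape the grid even after 10 ",
         "jitter draws; enlarge the grid or reduce jitter", call. = FALSE)
  dimnames(world) <- list(rownames(tpl), c("x", "y", "z"))
  lms <- landmark_set(world, schema = rownames(tpl))

  vol <- NULL
  if (render) {
    d <- spec$grid_size
    w <- voxel_grid_coords(d) * rep(spec$spacing, each = prod(d))
    img <- numeric(prod(d))
    # shells are defined in template space; map voxels back through the
    # rigid transform so the shells move with the landmarks
    x_tpl <- t(t(w) - gc - trans) %*% R # R^T (w - gc - t), rows
    x_tpl <- t(t(x_tpl) + gc)
    for (sh in spec$shells) {
      radii <- rep(sh$radii, length.out = 3)
      r <- sqrt(((x_tpl[, 1] - sh$center[1]) / radii[1])^2 +
                ((x_tpl[, 2] - sh$center[2]) / radii[2])^2 +
                ((x_tpl[, 3] - sh$center[3]) / radii[3])^2)
      thr <- sh$thickness / mean(radii)
      img <- pmax(img, ifelse(r <= 1 & r >= 1 - thr, sh$intensity, 0))
    }
    # landmark blobs: parabolic cap, brightest exactly at the landmark
    rb <- spec$blob_radius
    for (i in seq_len(nrow(world))) {
      d2 <- (w[, 1] - world[i, 1])^2 + (w[, 2] - world[i, 2])^2 +
        (w[, 3] - world[i, 3])^2
      inside <- d2 < rb^2
      img[inside] <- pmax(img[inside],
                          spec$blob_intensity * (1 - d2[inside] / rb^2))
    }
    if (spec$noise_sd > 0)
      img <- img + rnorm(length(img), sd = spec$noise_sd)
    vol <- volume(array(img, d), spacing = spec$spacing)
  }
  list(volume = vol, landmarks = lms,
       case_id = sprintf("%s%03d", cohort, case_index), cohort = cohort)
}

#' Generate a two-cohort phantom dataset
#'
#' Cohort "A" uses the template as-is; cohort "B" uses the template plus
#' `spec$cohort_shift` (with zero shift the cohorts are exchangeable).
#' Case indices run `1..n_per_cohort` within each cohort with independent
#' derived seeds.
#'
#' @param spec a [phantom_spec()].
#' @param n_per_cohort cases per cohort (>= 1).
#' @param render pass `FALSE` to generate landmarks only.
#' @return `list(cases = <list of generate_case() results>, metadata =
#'   <data.frame case_id, cohort>)`.
#' @export
generate_cohorts <- function(spec, n_per_cohort, render = TRUE) {
  stopifnot(n_per_cohort >= 1)
  cases <- c(lapply(seq_len(n_per_cohort), function(i)
    generate_case(spec, i, "A", render)),
    lapply(seq_len(n_per_cohort), function(i)
      generate_case(spec, i, "B", render)))
  metadata <- data.frame(case_id = vapply(cases, `[[`, "", "case_id"),
                         cohort = vapply(cases, `[[`, "", "cohort"))
  list(cases = cases, metadata = metadata)
}

#' Perturb landmarks with isotropic Gaussian error
#'
#' Simulates a predictor of known accuracy by displacing every present
#' landmark with iid Gaussian noise; used for statistical-calibration
#' studies where training a network per replicate is unnecessary.
#'
#' @param set a [landmark_set()].
#' @param sd per-axis error SD in mm.
#' @return The perturbed `landmark_set`.
#' @export
perturb_landmarks <- function(set, sd = 1) {
  m <- set$coords
  pres <- stats::complete.cases(m)
  m[pres, ] <- m[pres, ] + rnorm(3 * sum(pres), sd = sd)
  out <- set
  out$coords <- m
  out
}
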