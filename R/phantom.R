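#' Parameters of the synthetic midshaft phantom
#'
#' Describes a hollow, eccentric, tubular cortical shell with a sharp
#' anterior ridge, mimicking a long-bone midshaft section. The anterior
#' direction is -x (x runs anterior to posterior).
#'
#' @param n_slices number of axial (z) slices.
#' @param outer_radius mean outer radius, voxels.
#' @param wall_thickness cortical wall thickness, voxels; must be >= 3 so
#'   the cortex survives binarization and hole morphology.
#' @param crest_amplitude height of the anterior ridge, voxels; modelled as
#'   a Gaussian bump on the outer radius as a function of polar angle.
#' @param crest_width angular width (SD) of the ridge, radians.
#' @param eccentricity dimensionless in [0, 1); shifts the medullary
#'   cavity posteriorly by `eccentricity * wall_thickness / 2` voxels.
#' @param intensity_bone,intensity_background grayscale levels.
#' @param blur_sigma Gaussian partial-volume blur, voxels.
#' @param taper relative sinusoidal modulation of the outer radius along z.
#' @param roughness amplitude (voxels, SD) of fine-scale correlated surface
#'   roughness applied to both surfaces.
#' @param bump_amplitude SD of the localized surface bump/pit heights,
#'   as a fraction of the wall thickness (0 disables the bumps).
#' @param radius_jitter relative SD of seeded low-order angular
#'   perturbations of the outer radius (gives each phantom an individual,
#'   reproducible cross-section).
#' @param size_xy in-plane image size, voxels; `NULL` chooses a size that
#'   comfortably contains the section.
#' @param seed integer seed controlling the shape perturbation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 96, outer_radius = 24, wall_thickness = 6,
                         crest_amplitude = 8, crest_width = 0.35,
                         eccentricity = 0.3,
                         intensity_bone = 180, intensity_background = 20,
                         blur_sigma = 1, taper = 0.03, radius_jitter = 0.04,
                         roughness = 1.2, bump_amplitude = 0.25,
                         size_xy = NULL, seed = 1) {
  if (wall_thickness < 3)
    stop("geometry error: wall_thickness must be >= 3 voxels")
  if (eccentricity < 0 || eccentricity >= 1)
    stop("eccentricity must be in [0, 1)")
  if (is.null(size_xy))
    size_xy <- 2 * ceiling(outer_radius * (1 + taper) + crest_amplitude) + 13
  structure(list(n_slices = n_slices, outer_radius = outer_radius,
                 wall_thickness = wall_thickness,
                 crest_amplitude = crest_amplitude, crest_width = crest_width,
                 eccentricity = eccentricity,
                 intensity_bone = intensity_bone,
                 intensity_background = intensity_background,
                 blur_sigma = blur_sigma, taper = taper,
                 radius_jitter = radius_jitter, roughness = roughness,
                 bump_amplitude = bump_amplitude,
                 size_xy = size_xy, seed = seed),
            class = "phantom_spec")
}

# counter-based fan-out of a master seed into independent stream seeds,
# kept below 2^31 so they remain valid R integers
derive_seed <- function(master, counter) {
  as.integer((as.double(master %% 2147483647L) * 48271 +
                as.double(counter) * 1009 + 1) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a grayscale midshaft phantom volume
#'
#' Builds a hollow eccentric tube with an anterior crest ridge, assigns
#' bone/background grayscale levels and applies a partial-volume Gaussian
#' blur. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param spacing voxel size in micrometres.
#' @return A [volume_image()] whose thresholded form is an annular tube
#'   with a single anterior ridge.
#' @export
make_midshaft_phantom <- function(spec, spacing = 10.4) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$wall_thickness < 3)
    stop("geometry error: wall_thickness must be >= 3 voxels")
  n <- spec$size_xy
  nz <- spec$n_slices
  cx <- (n - 1) / 2
  # seeded low-order angular perturbation (orders 2..4 keep the centroid)
  nb_out <- 16L
  nb_in <- 10L
  pert <- with_seed(spec$seed, list(
    amp = rnorm(3, 0, spec$radius_jitter * spec$outer_radius),
    phase = runif(3, 0, 2 * pi),
    twist = sample(c(-2L, -1L, 1L, 2L), 3, replace = TRUE),
    amp_phase = runif(3, 0, 2 * pi),
    amp_in = rnorm(3, 0, spec$radius_jitter * spec$outer_radius),
    phase_in = runif(3, 0, 2 * pi),
    twist_in = sample(c(-2L, -1L, 1L, 2L), 3, replace = TRUE),
    crest_phase = runif(1, 0, 2 * pi),
    taper_phase = runif(1, 0, 2 * pi),
    # localized surface bumps/pits (vascular ridges, foramina-like relief)
    # giving the surface strong longitudinal intensity gradients
    bump_th = runif(nb_out, -pi, pi),
    bump_z = runif(nb_out, 0, nz),
    bump_a = rnorm(nb_out, 0, spec$bump_amplitude * spec$wall_thickness),
    bump_sth = runif(nb_out, 0.15, 0.35),
    bump_sz = runif(nb_out, 3, 6),
    bin_th = runif(nb_in, -pi, pi),
    bin_z = runif(nb_in, 0, nz),
    bin_a = rnorm(nb_in, 0, spec$bump_amplitude * spec$wall_thickness),
    bin_sth = runif(nb_in, 0.15, 0.35),
    bin_sz = runif(nb_in, 3, 6),
    rough_out = matrix(rnorm(96 * nz), 96, nz),
    rough_in = matrix(rnorm(96 * nz), 96, nz)))
  pert$bump_a <- pmin(pmax(pert$bump_a, -0.4 * spec$wall_thickness),
                      0.4 * spec$wall_thickness)
  pert$bin_a <- pmin(pmax(pert$bin_a, -0.3 * spec$wall_thickness),
                     0.3 * spec$wall_thickness)
  # fine-scale correlated surface roughness (periodic in theta, smoothed in
  # z), the micro-relief real cortical surfaces show at this resolution
  smooth_field <- function(g, s = 2) {
    kr <- 3 * s
    ker <- exp(-0.5 * ((-kr):kr)^2 / s^2); ker <- ker / sum(ker)
    nth <- nrow(g); nzz <- ncol(g)
    gw <- rbind(g[(nth - kr + 1):nth, , drop = FALSE], g,
                g[1:kr, , drop = FALSE])
    g <- apply(gw, 2, function(col) stats::filter(col, ker)[(kr + 1):(kr + nth)])
    gz <- cbind(g[, rep(1, kr), drop = FALSE], g,
                g[, rep(nzz, kr), drop = FALSE])
    g <- t(apply(gz, 1, function(row) stats::filter(row, ker)[(kr + 1):(kr + nzz)]))
    g / sd(as.vector(g))
  }
  pert$rough_out <- smooth_field(pert$rough_out) * spec$roughness
  pert$rough_in <- smooth_field(pert$rough_in) * spec$roughness
  xg <- matrix(rep(0:(n - 1), n), n, n) - cx
  yg <- t(xg)
  r <- sqrt(xg^2 + yg^2)
  theta <- atan2(yg, xg)
  # crest points anterior (-x), i.e. theta = pi
  dth <- atan2(sin(theta - pi), cos(theta - pi))
  crest0 <- exp(-dth^2 / (2 * spec$crest_width^2))
  r_in <- spec$outer_radius - spec$wall_thickness
  off <- spec$eccentricity * spec$wall_thickness / 2
  r_inner <- sqrt((xg - off)^2 + yg^2)
  vox <- array(spec$intensity_background, c(n, n, nz))
  for (k in seq_len(nz)) {
    z <- k - 1
    zf <- 2 * pi * z / nz
    rad_mod <- 1 + spec$taper * sin(zf + pert$taper_phase)
    # longitudinally varying surface relief: helically rotating angular
    # perturbations with axially modulated amplitudes, plus an axially
    # modulated crest height, as on real cortical surfaces (a surface of
    # revolution would leave tangential displacements unobservable)
    angular <- spec$crest_amplitude *
      (1 + 0.3 * sin(zf + pert$crest_phase)) * crest0
    for (m in 1:3)
      angular <- angular + pert$amp[m] * (1 + 0.5 * sin(zf + pert$amp_phase[m])) *
        cos((m + 1) * theta + pert$phase[m] + pert$twist[m] * zf)
    inner_ang <- 0
    for (m in 1:3)
      inner_ang <- inner_ang + pert$amp_in[m] *
        cos((m + 1) * theta + pert$phase_in[m] + pert$twist_in[m] * zf)
    for (b in seq_len(nb_out)) {
      dzb <- z - pert$bump_z[b]
      if (abs(dzb) > 3 * pert$bump_sz[b]) next
      dthb <- atan2(sin(theta - pert$bump_th[b]), cos(theta - pert$bump_th[b]))
      angular <- angular + pert$bump_a[b] *
        exp(-dthb^2 / (2 * pert$bump_sth[b]^2) - dzb^2 / (2 * pert$bump_sz[b]^2))
    }
    for (b in seq_len(nb_in)) {
      dzb <- z - pert$bin_z[b]
      if (abs(dzb) > 3 * pert$bin_sz[b]) next
      dthb <- atan2(sin(theta - pert$bin_th[b]), cos(theta - pert$bin_th[b]))
      inner_ang <- inner_ang + pert$bin_a[b] *
        exp(-dthb^2 / (2 * pert$bin_sth[b]^2) - dzb^2 / (2 * pert$bin_sz[b]^2))
    }
    # periodic-in-theta lookup of the roughness rows for this slice
    th_pos <- (theta + pi) / (2 * pi) * 96
    i0 <- floor(th_pos); wth <- th_pos - i0
    i0 <- (as.integer(i0) %% 96L) + 1L
    i1 <- (i0 %% 96L) + 1L
    r_o <- (1 - wth) * pert$rough_out[i0, k] + wth * pert$rough_out[i1, k]
    r_i <- (1 - wth) * pert$rough_in[i0, k] + wth * pert$rough_in[i1, k]
    dim(r_o) <- dim(theta); dim(r_i) <- dim(theta)
    r_out_k <- spec$outer_radius * rad_mod + angular + r_o
    # the endosteal surface never approaches the periosteal one closer than
    # ~three voxels (accounting for the cavity center offset), so the
    # annulus survives blurring and binarization everywhere
    r_in_k <- pmin(pmax(r_in * rad_mod + inner_ang + r_i, 1),
                   r_out_k - 3 - off)
    bone <- (r <= r_out_k) & (r_inner >= r_in_k)
    vox[, , k][bone] <- spec$intensity_bone
  }
  img <- volume_image(vox, spacing)
  if (spec$blur_sigma > 0) img <- blur_volume(img, spec$blur_sigma)
  img
}

# ------------------------------------------------------------- deformations

#' Virtual deformation fields
#'
#' Constructors for the virtual displacement fields used in the
#' registration validation studies: uniform translations (possibly
#' fractional), one-axis affine stretches/compressions of a sub-region,
#' and ordered compositions of both.
#'
#' An affine region is anchored at the plane `x0` (zero displacement) and
#' reaches its full stretch factor `Tc` at the active edge `x_e`; voxels
#' outside the interval are untouched. The displacement along the axis is
#' `u = (Tc - 1) * (x - x0)` inside the region.
#'
#' @param translation 3-vector, voxel units (may be fractional).
#' @param axis one of "x", "y", "z".
#' @param x0 anchor plane coordinate, voxels (0-based).
#' @param x_e active edge coordinate, voxels.
#' @param Tc dimensionless affine coefficient.
#' @param steps for `composite_deformation`, a list of deformation specs
#'   applied in order.
#' @param interp optional per-step interpolation tag ("nearest"/"linear")
#'   consulted by [apply_deformation()].
#' @return An object of class `deformation_spec`.
#' @export
translation_deformation <- function(translation, interp = NULL) {
  stopifnot(length(translation) == 3)
  structure(list(kind = "translation", translation = as.double(translation),
                 interp = interp),
            class = "deformation_spec")
}

#' @rdname translation_deformation
#' @export
affine_deformation <- function(axis = "x", x0, x_e, Tc, interp = NULL) {
  stopifnot(axis %in% c("x", "y", "z"), x0 != x_e)
  structure(list(kind = "affine_region", axis = axis, x0 = x0, x_e = x_e,
                 Tc = Tc, interp = interp),
            class = "deformation_spec")
}

#' @rdname translation_deformation
#' @export
composite_deformation <- function(steps) {
  stopifnot(all(vapply(steps, inherits, TRUE, "deformation_spec")))
  structure(list(kind = "composite", steps = steps), class = "deformation_spec")
}

axis_index <- function(axis) match(axis, c("x", "y", "z"))

forward_map <- function(defspec, points) {
  points <- as_points(points)
  switch(defspec$kind,
    translation = sweep(points, 2, defspec$translation, "+"),
    affine_region = {
      a <- axis_index(defspec$axis)
      side <- sign(defspec$x_e - defspec$x0)
      p <- points
      inside <- (p[, a] - defspec$x0) * side >= 0
      p[inside, a] <- defspec$x0 + defspec$Tc * (p[inside, a] - defspec$x0)
      p
    },
    composite = {
      p <- points
      for (s in defspec$steps) p <- forward_map(s, p)
      p
    },
    stop("unknown deformation kind: ", defspec$kind))
}

#' Ground-truth displacement of a virtual deformation at given points
#'
#' The single source of truth for the validation studies: for a
#' translation this is the constant vector; for an affine region along
#' axis a with anchor `x0`, `u = (Tc - 1) * (x - x0)` on that axis inside
#' the region and zero outside; compositions chain the forward maps
#' exactly.
#'
#' @param defspec a `deformation_spec`.
#' @param points n x 3 matrix of 0-based voxel coordinates.
#' @param dim optional volume dimensions; if given, out-of-bounds points
#'   raise an error.
#' @return n x 3 matrix of displacement vectors (voxels).
#' @export
imposed_displacement <- function(defspec, points, dim = NULL) {
  points <- as_points(points)
  if (!is.null(dim)) {
    out <- points < 0 | sweep(points, 2, dim - 1, ">")
    if (any(out)) stop("points outside image bounds")
  }
  forward_map(defspec, points) - points
}

inverse_map <- function(defspec, points) {
  # returns list(points, outside): source coordinates and a mask of target
  # points whose source falls outside the deformed content
  points <- as_points(points)
  switch(defspec$kind,
    translation = list(points = sweep(points, 2, defspec$translation, "-"),
                       outside = rep(FALSE, nrow(points))),
    affine_region = {
      a <- axis_index(defspec$axis)
      side <- sign(defspec$x_e - defspec$x0)
      p <- points
      outside <- rep(FALSE, nrow(points))
      act <- (p[, a] - defspec$x0) * side >= 0
      s <- defspec$x0 + (p[act, a] - defspec$x0) / defspec$Tc
      p[act, a] <- s
      beyond <- (s - defspec$x_e) * side > 0
      outside[which(act)[beyond]] <- TRUE
      list(points = p, outside = outside)
    },
    composite = {
      p <- points
      outside <- rep(FALSE, nrow(points))
      for (s in rev(defspec$steps)) {
        inv <- inverse_map(s, p)
        p <- inv$points
        outside <- outside | inv$outside
      }
      list(points = p, outside = outside)
    },
    stop("unknown deformation kind: ", defspec$kind))
}

#' Apply a virtual deformation to a volume
#'
#' Resamples the volume under the deformation by inverse mapping. Integer
#' translations with nearest interpolation are exact index shifts. After
#' linear interpolation, binary inputs are re-thresholded at 0.5.
#' Composite deformations are applied as successive resampling steps, in
#' order, honouring each step's own `interp` tag when present.
#'
#' @param image a [volume_image()] or [binary_volume()].
#' @param defspec a `deformation_spec`.
#' @param interpolation "nearest" or "linear" (default), used for steps
#'   that do not carry their own tag.
#' @param fill background value for voxels mapped from outside the image;
#'   defaults to the volume minimum.
#' @return A deformed volume of the same class and shape.
#' @export
apply_deformation <- function(image, defspec, interpolation = "linear",
                              fill = NULL) {
  if (!interpolation %in% c("nearest", "linear"))
    stop("unknown interpolation tag: ", interpolation)
  if (defspec$kind == "composite") {
    out <- image
    for (s in defspec$steps) {
      itp <- if (!is.null(s$interp)) s$interp else interpolation
      out <- apply_deformation(out, s, itp, fill)
    }
    return(out)
  }
  itp <- if (!is.null(defspec$interp)) defspec$interp else interpolation
  d <- dim(image$voxels)
  binary <- is_binary_volume(image)
  if (is.null(fill)) fill <- min(image$voxels)
  grid <- cbind(
    rep.int(0:(d[1] - 1), d[2] * d[3]),
    rep.int(rep(0:(d[2] - 1), each = d[1]), d[3]),
    rep(0:(d[3] - 1), each = d[1] * d[2]))
  inv <- inverse_map(defspec, grid)
  src <- inv$points
  if (itp == "nearest") {
    idx <- round(src)
    ok <- !inv$outside &
      idx[, 1] >= 0 & idx[, 1] < d[1] &
      idx[, 2] >= 0 & idx[, 2] < d[2] &
      idx[, 3] >= 0 & idx[, 3] < d[3]
    v <- rep(fill, nrow(idx))
    lin <- idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3]) + 1
    v[ok] <- image$voxels[lin]
  } else {
    v <- cpp_trilinear(as.double(image$voxels), d, src, FALSE, fill)
    v[inv$outside] <- fill
  }
  vox <- array(v, d)
  if (binary) {
    vox <- array(as.integer(vox >= 0.5), d)
    binary_volume(vox, image$spacing, image$origin)
  } else {
    volume_image(vox, image$spacing, image$origin)
  }
}

# ------------------------------------------------------------------- noise

#' Region noise description
#'
#' Zero-mean Gaussian intensity noise with separate standard deviations
#' for the bone and background regions.
#'
#' @param sd_bone,sd_background grayscale standard deviations (>= 0).
#' @param seed integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd_bone, sd_background, seed = 1) {
  if (sd_bone < 0 || sd_background < 0) stop("noise SDs must be non-negative")
  structure(list(sd_bone = sd_bone, sd_background = sd_background, seed = seed),
            class = "noise_spec")
}

#' Measure per-region intensity noise
#'
#' Sample standard deviation of the intensities inside the bone mask and
#' in the background, as used to calibrate simulated image noise.
#'
#' @param image a [volume_image()].
#' @param bone_mask a [binary_volume()] of the same shape.
#' @param seed seed to carry into the returned [noise_spec()].
#' @return A [noise_spec()].
#' @export
measure_region_noise <- function(image, bone_mask, seed = 1) {
  if (!all(dim(image$voxels) == dim(bone_mask$voxels)))
    stop("mask and image shapes differ")
  m <- bone_mask$voxels == 1L
  if (sum(m) < 2 || sum(!m) < 2)
    stop("both bone and background regions need at least two voxels")
  noise_spec(sd(image$voxels[m]), sd(image$voxels[!m]), seed)
}

#' Add region-specific Gaussian noise to a volume
#'
#' Independent zero-mean draws per voxel with the region's standard
#' deviation. Deterministic given `noise$seed`.
#'
#' @inheritParams measure_region_noise
#' @param noise a [noise_spec()].
#' @return A noisy [volume_image()].
#' @export
add_region_noise <- function(image, bone_mask, noise) {
  if (!all(dim(image$voxels) == dim(bone_mask$voxels)))
    stop("mask and image shapes differ")
  if (noise$sd_bone < 0 || noise$sd_background < 0)
    stop("noise SDs must be non-negative")
  m <- bone_mask$voxels == 1L
  vox <- image$voxels
  with_seed(noise$seed, {
    if (noise$sd_bone > 0) vox[m] <- vox[m] + rnorm(sum(m), 0, noise$sd_bone)
    if (noise$sd_background > 0)
      vox[!m] <- vox[!m] + rnorm(sum(!m), 0, noise$sd_background)
  })
  volume_image(vox, image$spacing, image$origin)
}

# -------------------------------------------------------------- populations

#' Score-distribution model for synthetic populations
#'
#' Per-mode distributions of subject scores: a subject's baseline score is
#' `N(0, baseline_sd)`; at the second timepoint the treated group gains a
#' `treated_shift` and the control group a `control_shift`, each perturbed
#' by `N(0, within_sd)` (both timepoints carry independent within noise).
#' Vectors are recycled over planted modes.
#'
#' @param baseline_sd between-subject score SD at baseline.
#' @param treated_shift mean score change (t2 - t1) in the treated group.
#' @param control_shift mean score change in the control group.
#' @param within_sd within-subject (timepoint) score SD.
#' @return An object of class `score_model`.
#' @export
score_model <- function(baseline_sd = 5, treated_shift = 10,
                        control_shift = 0, within_sd = 1) {
  structure(list(baseline_sd = baseline_sd, treated_shift = treated_shift,
                 control_shift = control_shift, within_sd = within_sd),
            class = "score_model")
}

#' Generate a longitudinal population with planted shape modes
#'
#' Fabricates mesh observations (two timepoints per subject, a treated and
#' a control group) whose only systematic shape variation lies along a set
#' of planted, mutually orthogonal per-vertex displacement fields. Ground
#' truth scores are recorded for recovery tests. Cohort sizes default to
#' the study design of five control and six treated subjects.
#'
#' @param base_mesh a [surface_mesh()] serving as the reference geometry.
#' @param planted_modes list of N x 3 matrices (per-vertex 3-vector
#'   fields); they are centered and unit-normalized internally and must be
#'   mutually orthogonal after centering.
#' @param n_treated,n_control subjects per group.
#' @param timepoints two timepoint labels (weeks).
#' @param model a [score_model()].
#' @param noise_sd SD of iid per-coordinate vertex jitter (voxels).
#' @param seed master integer seed.
#' @return An object of class `shape_population`: a list with `$shapes`
#'   (list of shape vectors), `$meta` (subject/group/timepoint), `$truth`
#'   (orthonormal planted fields and true scores) and `$base_mesh`.
#' @export
make_population <- function(base_mesh, planted_modes, n_treated = 6,
                            n_control = 5, timepoints = c(18, 24),
                            model = score_model(), noise_sd = 0, seed = 1) {
  stopifnot(inherits(base_mesh, "surface_mesh"), length(timepoints) == 2)
  nvert <- nrow(base_mesh$vertices)
  K <- length(planted_modes)
  modes <- matrix(0, K, 3 * nvert)
  for (k in seq_len(K)) {
    f <- as.matrix(planted_modes[[k]])
    if (!all(dim(f) == c(nvert, 3)))
      stop("planted mode ", k, " must be an N x 3 field matching the mesh")
    f <- sweep(f, 2, colMeans(f))
    modes[k, ] <- as.vector(t(f))
  }
  nrm <- sqrt(rowSums(modes^2))
  if (any(nrm == 0)) stop("planted modes must be non-zero after centering")
  modes <- modes / nrm
  if (K > 1) {
    g <- modes %*% t(modes)
    if (max(abs(g[upper.tri(g)])) > 1e-8)
      stop("planted modes must be mutually orthogonal after centering")
  }
  bs <- rep_len(model$baseline_sd, K)
  ts <- rep_len(model$treated_shift, K)
  cs <- rep_len(model$control_shift, K)
  ws <- rep_len(model$within_sd, K)
  groups <- c(rep("treated", n_treated), rep("control", n_control))
  nsub <- length(groups)
  subjects <- sprintf("S%02d", seq_len(nsub))
  base_vec <- as.vector(t(base_mesh$vertices))
  shapes <- list()
  meta <- data.frame(subject = character(), group = character(),
                     timepoint = numeric(), stringsAsFactors = FALSE)
  scores <- array(0, c(nsub, max(K, 1), 2),
                  dimnames = list(subjects, NULL, as.character(timepoints)))
  ctr <- 0
  for (j in seq_len(nsub)) {
    sseed <- derive_seed(seed, j)
    draws <- with_seed(sseed, list(
      b = rnorm(K, 0, bs),
      w1 = rnorm(K, 0, ws),
      w2 = rnorm(K, 0, ws),
      e1 = if (noise_sd > 0) rnorm(3 * nvert, 0, noise_sd) else 0,
      e2 = if (noise_sd > 0) rnorm(3 * nvert, 0, noise_sd) else 0))
    shift <- if (groups[j] == "treated") ts else cs
    a1 <- draws$b + draws$w1
    a2 <- draws$b + shift + draws$w2
    if (K > 0) scores[j, , 1] <- a1
    if (K > 0) scores[j, , 2] <- a2
    v1 <- base_vec + (if (K) as.vector(a1 %*% modes) else 0) + draws$e1
    v2 <- base_vec + (if (K) as.vector(a2 %*% modes) else 0) + draws$e2
    for (tix in 1:2) {
      ctr <- ctr + 1
      shapes[[ctr]] <- shape_vector(if (tix == 1) v1 else v2,
                                    subject = subjects[j], group = groups[j],
                                    timepoint = timepoints[tix])
      meta[ctr, ] <- list(subjects[j], groups[j], timepoints[tix])
    }
  }
  structure(list(shapes = shapes, meta = meta,
                 truth = list(modes = modes, scores = scores, model = model),
                 base_mesh = base_mesh),
            class = "shape_population")
}

#' Generate a longitudinal population of phantom volumes
#'
#' Image-level counterpart of [make_population()] for end-to-end pipeline
#' runs: each subject receives a seeded individual phantom; at the second
#' timepoint treated subjects gain an enlarged anterior crest (the planted
#' treatment effect) while controls keep their geometry.
#'
#' @param n_treated,n_control subjects per group.
#' @param base_spec a [phantom_spec()] giving the shared geometry.
#' @param treat_crest added crest amplitude (voxels) at the second
#'   timepoint in the treated group.
#' @param timepoints two timepoint labels (weeks).
#' @param seed master integer seed.
#' @return List with `$volumes` (named list of grayscale
#'   [volume_image()]s) and `$meta` (one row per volume).
#' @export
make_image_population <- function(n_treated = 2, n_control = 2,
                                  base_spec = phantom_spec(n_slices = 64,
                                                           size_xy = 64,
                                                           outer_radius = 18,
                                                           wall_thickness = 5,
                                                           crest_amplitude = 5),
                                  treat_crest = 2, timepoints = c(18, 24),
                                  seed = 1) {
  groups <- c(rep("treated", n_treated), rep("control", n_control))
  subjects <- sprintf("S%02d", seq_along(groups))
  volumes <- list()
  meta <- data.frame(subject = character(), group = character(),
                     timepoint = numeric(), stringsAsFactors = FALSE)
  ctr <- 0
  for (j in seq_along(groups)) {
    for (tix in 1:2) {
      sp <- base_spec
      sp$seed <- derive_seed(seed, j)  # same anatomy at both timepoints
      if (groups[j] == "treated" && tix == 2)
        sp$crest_amplitude <- sp$crest_amplitude + treat_crest
      ctr <- ctr + 1
      id <- sprintf("%s_w%s", subjects[j], timepoints[tix])
      volumes[[id]] <- make_midshaft_phantom(sp)
      meta[ctr, ] <- list(subjects[j], groups[j], timepoints[tix])
    }
  }
  rownames(meta) <- names(volumes)
  list(volumes = volumes, meta = meta)
}
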