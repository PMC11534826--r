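#' The six virtual-displacement validation studies
#'
#' Returns the canonical suite of registration validation studies of
#' increasing complexity: (1) uniform integer translations of 2, 4 or 6
#' voxels per axis on binarized images; (2) anisotropic integer
#' translation (2, 2, 4); (3) fractional translation (2.5, 2.5) resampled
#' bilinearly plus 2 voxels along z on binarized images; (4) the same
#' translation applied to the grayscale images with binarization and
#' geometry correction afterwards; (5) one-axis affine deformations on
#' top of study #4 (posterior half Tc = 0.95; a smaller posterior part
#' with Tc in 0.85/0.95/1.15; anterior half Tc = 1.2); (6) the study #5
#' fields after injecting measured-statistics image noise, run at NS 5
#' and 10.
#'
#' @param ns nodal spacings swept by studies 1-5 (default 5 to 50 by 5).
#' @param posterior_fraction axial extent of the "smaller posterior part"
#'   as a fraction of the x extent (default 0.25).
#' @return List of six `study_spec` objects.
#' @export
study_suite <- function(ns = seq(5, 50, 5), posterior_fraction = 0.25) {
  tr_int <- function(t) function(d) translation_deformation(t, interp = "nearest")
  tr_frac <- function(d) composite_deformation(list(
    translation_deformation(c(2.5, 2.5, 0), interp = "linear"),
    translation_deformation(c(0, 0, 2), interp = "nearest")))
  aff <- function(where, Tc) function(d) {
    nx <- d[1]
    mid <- (nx - 1) / 2
    if (where == "anterior_half")
      affine_deformation("x", x0 = mid, x_e = 0, Tc = Tc, interp = "linear")
    else if (where == "posterior_half")
      affine_deformation("x", x0 = mid, x_e = nx - 1, Tc = Tc, interp = "linear")
    else # posterior smaller part
      affine_deformation("x", x0 = (1 - posterior_fraction) * (nx - 1),
                         x_e = nx - 1, Tc = Tc, interp = "linear")
  }
  v5 <- list(
    list(name = "posterior_half_Tc0.95", affine = aff("posterior_half", 0.95)),
    list(name = "posterior_part_Tc0.85", affine = aff("posterior_part", 0.85)),
    list(name = "posterior_part_Tc0.95", affine = aff("posterior_part", 0.95)),
    list(name = "posterior_part_Tc1.15", affine = aff("posterior_part", 1.15)),
    list(name = "anterior_half_Tc1.2", affine = aff("anterior_half", 1.2)))
  mk <- function(id, domain, variants, noise = FALSE, ns_list = ns)
    structure(list(id = id, domain = domain, variants = variants,
                   noise = noise, ns = ns_list), class = "study_spec")
  list(
    mk(1L, "binary", list(
      list(name = "t2", build = tr_int(c(2, 2, 2))),
      list(name = "t4", build = tr_int(c(4, 4, 4))),
      list(name = "t6", build = tr_int(c(6, 6, 6))))),
    mk(2L, "binary", list(list(name = "t224", build = tr_int(c(2, 2, 4))))),
    mk(3L, "binary", list(list(name = "frac", build = tr_frac))),
    mk(4L, "grayscale_then_binarize",
       list(list(name = "frac", build = tr_frac))),
    mk(5L, "grayscale_then_binarize",
       lapply(v5, function(v) list(name = v$name, affine = v$affine,
                                   build = NULL))),
    mk(6L, "grayscale_then_binarize",
       lapply(v5, function(v) list(name = v$name, affine = v$affine,
                                   build = NULL)),
       noise = TRUE, ns_list = c(5, 10)))
}

# per-image work shared by every variant of a study: the preprocessed moving
# image and, for the grayscale studies, the translated-then-binarized base
prepare_base <- function(image, spec, seed = 1) {
  moved <- preprocess_volume(image)
  if (spec$domain == "binary")
    return(list(moved = moved))
  gray <- image
  if (isTRUE(spec$noise)) {
    thr <- compute_threshold(gray)
    mask <- binarize(gray, thr)
    ns_meas <- measure_region_noise(gray, mask, seed = seed)
    gray <- add_region_noise(gray, mask, ns_meas)
  }
  tr <- composite_deformation(list(
    translation_deformation(c(2.5, 2.5, 0), interp = "linear"),
    translation_deformation(c(0, 0, 2), interp = "nearest")))
  base_fixed <- preprocess_volume(apply_deformation(gray, tr))
  list(moved = moved, base_fixed = base_fixed, tr = tr)
}

# build (moved binary, fixed binary, ground-truth defspec) for one variant
prepare_pair <- function(image, spec, variant, seed = 1, base = NULL) {
  d <- dim(image$voxels)
  if (is.null(base)) base <- prepare_base(image, spec, seed)
  if (spec$domain == "binary") {
    defspec <- variant$build(d)
    fixed <- apply_deformation(base$moved, defspec)
    return(list(moved = base$moved, fixed = fixed, defspec = defspec))
  }
  fixed <- base$base_fixed
  steps <- base$tr$steps
  if (!is.null(variant$affine)) {
    adef <- variant$affine(d)
    fixed <- apply_deformation(fixed, adef)
    steps <- c(steps, list(adef))
  }
  list(moved = base$moved, fixed = fixed,
       defspec = composite_deformation(steps))
}

#' Run one validation study over a set of images
#'
#' For each moved image and variant, synthesizes the fixed image by
#' applying the study's virtual deformation, registers the pair at each
#' nodal spacing, and compares the estimated displacement with the
#' imposed ground truth at the bone boundary voxels of the moved image.
#' The mean and standard deviation of the per-voxel Euclidean error
#' magnitudes, pooled over all images, are the accuracy and precision
#' errors; per-component mean absolute differences are also reported.
#'
#' @param spec a `study_spec` from [study_suite()].
#' @param moved_images list of grayscale [volume_image()] phantoms (or
#'   [binary_volume()]s for the binary studies).
#' @param params a `reg_params` object.
#' @param ns optional nodal spacings overriding the study's own list.
#' @param seed seed for the noise study.
#' @param keep_errors retain per-voxel errors (for [error_map()]).
#' @return An object of class `error_report`: data frame (study, variant,
#'   NS, accuracy_vox, precision_vox, accuracy_um, precision_um,
#'   err_x, err_y, err_z, n_voxels, converged); per-voxel errors in
#'   attribute `"voxel_errors"` when requested.
#' @export
run_study <- function(spec, moved_images, params = reg_params(), ns = NULL,
                      seed = 1, keep_errors = FALSE) {
  stopifnot(inherits(spec, "study_spec"))
  if (is.null(ns)) ns <- spec$ns
  rows <- list()
  vox_err <- list()
  spacing <- moved_images[[1]]$spacing
  bases <- lapply(seq_along(moved_images), function(i)
    prepare_base(moved_images[[i]], spec, seed = derive_seed(seed, i)))
  for (variant in spec$variants) {
    pairs <- lapply(seq_along(moved_images), function(i)
      prepare_pair(moved_images[[i]], spec, variant,
                   seed = derive_seed(seed, i), base = bases[[i]]))
    for (one_ns in ns) {
      errs <- list(); comps <- list(); conv <- TRUE
      for (i in seq_along(pairs)) {
        pr <- pairs[[i]]
        grid <- withCallingHandlers(
          register_volumes(pr$fixed, pr$moved, ns = one_ns, params = params),
          warning = function(w) {
            conv <<- FALSE
            invokeRestart("muffleWarning")
          })
        bv <- boundary_voxels(pr$moved)
        est <- interpolate_displacement(grid, bv)
        imp <- imposed_displacement(pr$defspec, bv)
        dfv <- est - imp
        errs[[i]] <- sqrt(rowSums(dfv^2))
        comps[[i]] <- colMeans(abs(dfv))
        if (keep_errors)
          vox_err[[sprintf("s%d_%s_ns%g_img%d", spec$id, variant$name,
                           one_ns, i)]] <-
            list(coords = bv, errors = errs[[i]])
      }
      e <- unlist(errs)
      cm <- colMeans(do.call(rbind, comps))
      rows[[length(rows) + 1]] <- data.frame(
        study = spec$id, variant = variant$name, NS = one_ns,
        accuracy_vox = mean(e), precision_vox = sd(e),
        accuracy_um = mean(e) * spacing, precision_um = sd(e) * spacing,
        err_x = cm[1], err_y = cm[2], err_z = cm[3],
        n_voxels = length(e), converged = conv)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_errors) attr(out, "voxel_errors") <- vox_err
  class(out) <- c("error_report", "data.frame")
  out
}

#' Map boundary-voxel errors onto a surface mesh
#'
#' Assigns each mesh vertex the error of its nearest boundary voxel, for
#' contour visualization of the spatial error distribution.
#'
#' @param coords m x 3 boundary voxel coordinates (0-based).
#' @param errors m per-voxel error magnitudes.
#' @param mesh a [surface_mesh()].
#' @param max_radius search radius (voxels).
#' @return Numeric vector, one error value per vertex.
#' @export
error_map <- function(coords, errors, mesh, max_radius = 4) {
  stopifnot(length(errors) == nrow(coords), nrow(coords) > 0,
            inherits(mesh, "surface_mesh"))
  d <- apply(mesh$vertices, 1, function(v) {
    dx <- coords[, 1] - v[1]
    ok <- abs(dx) <= max_radius
    if (!any(ok)) ok <- rep(TRUE, nrow(coords))
    d2 <- (coords[ok, 1] - v[1])^2 + (coords[ok, 2] - v[2])^2 +
      (coords[ok, 3] - v[3])^2
    which(ok)[which.min(d2)]
  })
  errors[d]
}

#' Default evaluation phantom set
#'
#' Six seeded midshaft phantoms with varied eccentricity and crest
#' amplitude, standing in for the six representative specimens used in
#' the validation studies.
#'
#' @param n number of phantoms.
#' @param n_slices,size_xy phantom dimensions, voxels.
#' @param seed master seed.
#' @return List of grayscale [volume_image()]s.
#' @export
evaluation_phantoms <- function(n = 6, n_slices = 96, size_xy = 96, seed = 1) {
  ecc <- seq(0.15, 0.4, length.out = n)
  # geometry scales with the frame so the section stays clear of the border
  r_out <- round(size_xy / 4)
  crest <- seq(size_xy / 16, size_xy / 9.6, length.out = n)
  wall <- max(3, round(size_xy / 16))
  lapply(seq_len(n), function(i)
    make_midshaft_phantom(phantom_spec(
      n_slices = n_slices, size_xy = size_xy, outer_radius = r_out,
      wall_thickness = wall, crest_amplitude = crest[i], eccentricity = ecc[i],
      seed = derive_seed(seed, i))))
}
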