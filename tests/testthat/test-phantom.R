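test_that("phantom generation is deterministic and rejects thin walls", {
  a <- make_midshaft_phantom(tiny_spec())
  b <- make_midshaft_phantom(tiny_spec())
  expect_identical(a$voxels, b$voxels)
  c <- make_midshaft_phantom(tiny_spec(seed = 8))
  expect_false(identical(a$voxels, c$voxels))
  expect_error(phantom_spec(wall_thickness = 2), "wall_thickness")
})

test_that("degenerate specs give circular, centered annuli", {
  img <- make_midshaft_phantom(smooth_spec())
  bin <- binarize(img, 100)
  expect_true(attr(check_topology(bin), "pass"))
  # centroid of foreground per slice at the image center (+- half voxel)
  d <- dim(bin$voxels)
  ctr <- (d[1] - 1) / 2
  for (k in c(1, 12, 24)) {
    sl <- bin$voxels[, , k]
    w <- which(sl == 1L, arr.ind = TRUE) - 1
    expect_lt(max(abs(colMeans(w) - ctr)), 0.5)
    # circularity: the outer radius is uniform across angular octants
    r <- sqrt((w[, 1] - ctr)^2 + (w[, 2] - ctr)^2)
    oct <- cut(atan2(w[, 2] - ctr, w[, 1] - ctr), seq(-pi, pi, by = pi / 4))
    expect_lt(diff(range(tapply(r, oct, max))), 1)
  }
  # eccentric spec shifts the cavity, not the outer boundary
  ecc <- binarize(make_midshaft_phantom(smooth_spec(eccentricity = 0.8)), 100)
  cav <- which(ecc$voxels[, , 12] == 0L, arr.ind = TRUE) - 1
  cav <- cav[sqrt(rowSums(sweep(cav, 2, ctr)^2)) < 10, ]
  expect_gt(mean(cav[, 1]) - ctr, 0.5)
})

test_that("imposed displacement matches the analytic virtual fields", {
  pts <- rbind(c(100, 0, 0), c(0, 5, 5), c(50, 1, 2))
  aff <- affine_deformation("x", x0 = 0, x_e = 100, Tc = 1.2)
  u <- imposed_displacement(aff, pts)
  expect_equal(u[1, 1], 20)        # (1.2 - 1) * 100
  expect_equal(u[2, ], c(0, 0, 0)) # anchor plane
  expect_equal(u[3, 1], 10)
  expect_equal(u[, 2:3], matrix(0, 3, 2))
  # anchor-plane continuity: left/right limits both vanish
  eps <- 1e-8
  near <- rbind(c(50 - eps, 0, 0), c(50 + eps, 0, 0))
  aff2 <- affine_deformation("x", x0 = 50, x_e = 100, Tc = 0.95)
  expect_lt(max(abs(imposed_displacement(aff2, near))), 1e-6)
  # uniform translation everywhere
  tr <- translation_deformation(c(2, 2, 4))
  expect_equal(imposed_displacement(tr, pts),
               matrix(rep(c(2, 2, 4), each = 3), 3))
  # composition chains the forward maps exactly
  comp <- composite_deformation(list(tr, aff))
  expect_equal(imposed_displacement(comp, pts[2, , drop = FALSE])[1, ],
               c(2 + 0.2 * 2, 2, 4))
  expect_error(imposed_displacement(tr, rbind(c(-1, 0, 0)), dim = c(10, 10, 10)),
               "bounds")
})

test_that("integer translations with nearest interpolation are index shifts", {
  bin <- tiny_binary()
  def <- translation_deformation(c(2, 0, 0))
  out <- apply_deformation(bin, def, "nearest")
  d <- dim(bin$voxels)
  expect_identical(out$voxels[3:d[1], , ], bin$voxels[1:(d[1] - 2), , ])
  expect_true(all(out$voxels[1:2, , ] == 0L))
  expect_error(apply_deformation(bin, def, "cubic"), "interpolation")
})

test_that("deformation followed by its inverse approximates identity", {
  img <- blur_volume(tiny_phantom(), 2)  # smooth field: interpolation-friendly
  def <- translation_deformation(c(1.5, -2.5, 0.5))
  inv <- translation_deformation(-c(1.5, -2.5, 0.5))
  back <- apply_deformation(apply_deformation(img, def), inv)
  core <- 6:50  # stay away from edges
  diff <- abs(back$voxels[core, core, 6:42] - img$voxels[core, core, 6:42])
  expect_lt(mean(diff), 0.01 * diff(range(img$voxels)))
  # affine round-trip
  adef <- affine_deformation("x", x0 = 28, x_e = 0, Tc = 1.1)
  ainv <- affine_deformation("x", x0 = 28, x_e = 0, Tc = 1 / 1.1)
  back2 <- apply_deformation(apply_deformation(img, adef), ainv)
  diff2 <- abs(back2$voxels[core, core, 6:42] - img$voxels[core, core, 6:42])
  expect_lt(mean(diff2), 0.01 * diff(range(img$voxels)))
})

test_that("region noise measurement and injection follow the region SDs", {
  img <- tiny_phantom()
  mask <- binarize(img, compute_threshold(img))
  # constant image: both SDs zero
  flat <- volume_image(array(5, dim(img$voxels)))
  expect_equal(measure_region_noise(flat, mask)$sd_bone, 0)
  # hand computation: sample SD of bone voxels {10, 12, 14} = 2
  small <- volume_image(array(c(10, 12, 14, 0, 0), c(5, 1, 1)))
  msk <- binary_volume(array(c(1L, 1L, 1L, 0L, 0L), c(5, 1, 1)))
  expect_equal(measure_region_noise(small, msk)$sd_bone, 2)
  # shift invariance
  shifted <- volume_image(img$voxels + 7, img$spacing)
  a <- measure_region_noise(img, mask); b <- measure_region_noise(shifted, mask)
  expect_equal(a$sd_bone, b$sd_bone)
  expect_equal(a$sd_background, b$sd_background)
  # zero noise is the identity; same seed reproduces; SDs recovered
  expect_identical(add_region_noise(img, mask, noise_spec(0, 0))$voxels, img$voxels)
  ns <- noise_spec(4, 2, seed = 11)
  n1 <- add_region_noise(img, mask, ns)
  n2 <- add_region_noise(img, mask, ns)
  expect_identical(n1$voxels, n2$voxels)
  dd <- n1$voxels - img$voxels
  expect_lt(abs(sd(dd[mask$voxels == 1L]) - 4) / 4, 0.05)
  expect_lt(abs(sd(dd[mask$voxels == 0L]) - 2) / 2, 0.05)
  expect_error(noise_spec(-1, 0), "non-negative")
})

test_that("population generator plants recoverable modes", {
  mesh <- tiny_mesh()
  fields <- planted_fields(mesh, 2)
  # zero amplitudes: both timepoints identical
  pop0 <- make_population(mesh, fields[1],
                          model = score_model(baseline_sd = 0, treated_shift = 0,
                                              control_shift = 0, within_sd = 0),
                          noise_sd = 0, seed = 5)
  expect_equal(as.double(pop0$shapes[[1]]), as.double(pop0$shapes[[2]]))
  # noise-free planted scores recovered by projection to high accuracy
  pop <- make_population(mesh, fields,
                         model = score_model(baseline_sd = 4, treated_shift = 8,
                                             control_shift = 0, within_sd = 1),
                         noise_sd = 0, seed = 5)
  ds <- assemble_dataset(pop$shapes)
  for (j in seq_len(nrow(ds$P))) {
    sub <- pop$meta$subject[j]
    tix <- if (pop$meta$timepoint[j] == 18) 1 else 2
    truth <- pop$truth$scores[sub, , tix]
    # projection of the raw shape onto the orthonormal planted fields
    raw <- ds$P[j, ] + ds$x0
    base <- as.vector(t(mesh$vertices))
    proj <- as.vector((raw - base) %*% t(pop$truth$modes))
    expect_lt(max(abs(proj - truth)) / max(abs(truth)), 1e-6)
  }
  # non-orthogonal fields are rejected
  skew <- list(fields[[1]], fields[[1]] + 0.5 * fields[[2]])
  expect_error(make_population(mesh, skew), "orthogonal")
})

test_that("single planted mode dominates the fitted PCA", {
  mesh <- tiny_mesh()
  fields <- planted_fields(mesh, 1)
  pop <- make_population(mesh, fields,
                         model = score_model(baseline_sd = 3, treated_shift = 8,
                                             control_shift = 0, within_sd = 1),
                         noise_sd = 0, seed = 9)
  m <- suppressWarnings(fit_pca(assemble_dataset(pop$shapes)))  # rank 1 by design
  cs <- abs(sum(m$modes[1, ] * pop$truth$modes[1, ]))
  expect_gte(cs, 0.99)
})
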