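test_that("nodal interpolation is exactly trilinear", {
  g <- displacement_grid(5, c(21, 21, 21))
  set.seed(3)
  g$u <- matrix(rnorm(prod(g$nnode) * 3), ncol = 3)
  # exact at nodes
  node <- c(2, 1, 3)
  at_node <- interpolate_displacement(g, rbind(node * 5))
  lin <- 1 + node[1] + g$nnode[1] * (node[2] + g$nnode[2] * node[3])
  expect_equal(as.vector(at_node), g$u[lin, ])
  # cell center equals the mean of the 8 surrounding nodes
  ctr <- interpolate_displacement(g, rbind(c(7.5, 7.5, 7.5)))
  corners <- expand.grid(1:2, 1:2, 1:2)
  ids <- 1 + corners[, 1] + g$nnode[1] * (corners[, 2] + g$nnode[2] * corners[, 3])
  expect_equal(as.vector(ctr), colMeans(g$u[ids, ]), tolerance = 1e-12)
  # partition of unity: constant nodal vectors interpolate to the constant
  g$u <- matrix(rep(c(1.5, -2, 0.25), each = nrow(g$u)), ncol = 3)
  set.seed(4)
  pts <- matrix(runif(60, 0, 20), ncol = 3)
  expect_equal(interpolate_displacement(g, pts),
               matrix(rep(c(1.5, -2, 0.25), each = 20), ncol = 3),
               tolerance = 1e-12)
  expect_error(interpolate_displacement(g, rbind(c(-3, 0, 0))), "hull")
  # agreement with an independent naive implementation
  set.seed(5)
  g$u <- matrix(rnorm(prod(g$nnode) * 3), ncol = 3)
  pts <- matrix(runif(30, 0, 20), ncol = 3)
  got <- interpolate_displacement(g, pts)
  for (i in seq_len(nrow(pts))) {
    for (c in 1:3) {
      comp <- array(g$u[, c], g$nnode)
      expect_equal(got[i, c], naive_trilinear(comp, pts[i, ] / 5),
                   tolerance = 1e-12)
    }
  }
})

test_that("warping a mesh adds the interpolated displacement", {
  mesh <- tiny_mesh()
  g <- displacement_grid(5, dim(tiny_binary()$voxels))
  expect_equal(warp_mesh(mesh, g)$vertices, mesh$vertices)
  g$u[, 1] <- 2
  w <- warp_mesh(mesh, g)
  expect_equal(w$vertices[, 1], mesh$vertices[, 1] + 2)
  expect_equal(w$vertices[, 2:3], mesh$vertices[, 2:3])
  expect_identical(w$faces, mesh$faces)
  expect_identical(w$labels, mesh$labels)
})

test_that("boundary voxels are the mixed-neighborhood set", {
  all1 <- binary_volume(array(1L, c(5, 5, 5)))
  expect_equal(nrow(boundary_voxels(all1)), 0)
  single <- array(0L, c(7, 7, 7)); single[4, 4, 4] <- 1L
  bv <- boundary_voxels(binary_volume(single))
  expect_equal(nrow(bv), 27)  # the voxel plus its 26 neighbours
  expect_true(all(abs(bv - 3) <= 1))
  # on the phantom, boundary voxels hug the extracted fine surface
  bin <- tiny_binary()
  bvs <- boundary_voxels(bin, foreground_only = TRUE)
  fine <- memo("tiny_fine_mesh", extract_surfaces(tiny_binary()))
  set.seed(2)
  sub <- bvs[sample(nrow(bvs), 200), ]
  d <- tibiassm:::cpp_point_mesh_dist(matrix(as.double(sub), ncol = 3),
                                      fine$vertices, fine$faces)
  # a voxel adjacent to background only across a corner diagonal can sit
  # up to ~sqrt(3) voxels from the facet
  expect_lt(max(d), 1.5)
})

test_that("registering an image to itself yields a null field", {
  bin <- tiny_binary()
  g <- register_volumes(bin, bin, ns = 5)
  expect_lt(max(abs(g$u)), 1e-3)
  expect_true(attr(g, "converged"))
  expect_error(register_volumes(bin, binary_volume(array(0L, c(4, 4, 4)))),
               "shape")
  expect_error(register_volumes(bin, bin, ns = 1), "NS")
})

test_that("integer translations are recovered at the boundary voxels", {
  bin <- tiny_binary()
  def <- translation_deformation(c(2, 4, 6), interp = "nearest")
  fixed <- apply_deformation(bin, def, "nearest")
  g <- register_volumes(fixed, bin, ns = 5)
  bv <- boundary_voxels(bin)
  err <- sqrt(rowSums((interpolate_displacement(g, bv) -
                         imposed_displacement(def, bv))^2))
  expect_lt(mean(err), 0.05)
})

test_that("registration is equivariant under a common integer shift", {
  img <- tiny_phantom()
  bin <- preprocess_volume(img)
  def <- translation_deformation(c(1.5, 0.5, 1), interp = "linear")
  fixed <- apply_deformation(bin, def)
  s <- c(0, 3, 0)
  shift <- translation_deformation(s, interp = "nearest")
  bin_s <- apply_deformation(bin, shift, "nearest")
  fixed_s <- apply_deformation(fixed, shift, "nearest")
  g1 <- suppressWarnings(register_volumes(fixed, bin, ns = 5))
  g2 <- suppressWarnings(register_volumes(fixed_s, bin_s, ns = 5))
  bv <- boundary_voxels(bin)
  keep <- bv[, 2] < dim(bin$voxels)[2] - 8  # stay clear of the shifted-out band
  u1 <- interpolate_displacement(g1, bv[keep, ])
  u2 <- interpolate_displacement(g2, sweep(bv[keep, ], 2, s, "+"))
  # interior agreement; nodes near the shifted-in face differ by design
  expect_lt(mean(sqrt(rowSums((u1 - u2)^2))), 0.3)
})

test_that("displacement grids survive a text round-trip", {
  g <- displacement_grid(5, c(21, 21, 21))
  set.seed(6)
  g$u <- matrix(rnorm(prod(g$nnode) * 3), ncol = 3)
  path <- tempfile(fileext = ".csv")
  write_displacement_grid(g, path)
  g2 <- read_displacement_grid(path)
  expect_equal(g2$ns, g$ns)
  expect_equal(g2$nnode, g$nnode)
  expect_equal(g2$u, g$u, tolerance = 1e-12)
})
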