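rand_dataset <- function(m = 8, n = 30, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(m * 3 * n), m)
  assemble_dataset(lapply(seq_len(m), function(i)
    shape_vector(X[i, ], subject = paste0("S", i), group = "g", timepoint = 1)))
}

test_that("PCA factorization is exact with orthonormal modes", {
  ds <- rand_dataset()
  m <- fit_pca(ds)
  expect_lt(norm(ds$P - m$scores %*% m$modes, "F") / norm(ds$P, "F"), 1e-9)
  G <- m$modes %*% t(m$modes)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-9)
  # scores columns mutually orthogonal
  S <- crossprod(m$scores)
  expect_lt(max(abs(S - diag(diag(S)))), 1e-6 * max(diag(S)))
  # eigenvalue sum equals the Frobenius total variance
  expect_equal(sum(m$eigenvalues), sum(ds$P^2) / (nrow(ds$P) - 1),
               tolerance = 1e-9)
  # exactly M - 1 modes for generic data
  expect_equal(length(m$singular), nrow(ds$P) - 1)
})

test_that("a single direction of variation gives a single mode", {
  dir <- c(1, -2, 0.5, 3, 0, 1)
  shapes <- lapply(c(-2, -1, 0, 1, 2), function(c)
    shape_vector(c * dir, subject = paste0("S", c + 3), group = "g", timepoint = 1))
  m <- suppressWarnings(fit_pca(assemble_dataset(shapes)))
  ev <- explained_variance(m)
  expect_equal(ev$fraction[1], 1)
  expect_gt(abs(sum(m$modes[1, ] * dir / sqrt(sum(dir^2)))), 1 - 1e-9)
})

test_that("rotations of the coordinates leave eigenvalues invariant", {
  ds <- rand_dataset(m = 6, n = 10, seed = 2)
  theta <- 0.7
  R <- diag(3); R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta),
                                        -sin(theta), cos(theta)), 2)
  rot <- t(apply(ds$P + rep(1, nrow(ds$P)) %o% ds$x0, 1, function(row) {
    v <- matrix(row, ncol = 3, byrow = TRUE) %*% t(R)
    as.vector(t(v))
  }))
  ds2 <- assemble_dataset(lapply(seq_len(nrow(rot)), function(i)
    shape_vector(rot[i, ], paste0("S", i), "g", 1)))
  m1 <- fit_pca(ds); m2 <- fit_pca(ds2)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-9)
})

test_that("explained variance fractions follow the eigenvalue ratios", {
  # two orthogonal directions with variance ratio 3:1
  d1 <- c(1, 0, 0, 0, 0, 0); d2 <- c(0, 1, 0, 0, 0, 0)
  a <- sqrt(3) * c(-1, 1, -1, 1); b <- c(-1, -1, 1, 1)
  shapes <- lapply(1:4, function(i)
    shape_vector(a[i] * d1 + b[i] * d2, paste0("S", i), "g", 1))
  m <- suppressWarnings(fit_pca(assemble_dataset(shapes)))
  ev <- explained_variance(m)
  expect_equal(ev$fraction[1:2], c(0.75, 0.25), tolerance = 1e-9)
  expect_true(all(diff(ev$cumulative) >= -1e-12))
  expect_equal(ev$cumulative[length(ev$cumulative)], 1, tolerance = 1e-9)
})

test_that("group variance fractions partition the total", {
  ds <- rand_dataset(m = 9, seed = 3)
  expect_equal(group_variance(ds, rep(TRUE, 9)), 1)
  g1 <- 1:4; g2 <- 5:9
  expect_equal(group_variance(ds, g1) + group_variance(ds, g2), 1,
               tolerance = 1e-12)
  # two rows with norms 1 and 3 split 0.1 / 0.9
  w <- c(1, 0, 0, 0, 0, 0)
  shapes <- list(shape_vector(2 * w, "a", "g", 1),
                 shape_vector(-2 * w, "b", "g", 1),
                 shape_vector(6 * w, "c", "g", 1),
                 shape_vector(-6 * w, "d", "g", 1))
  ds2 <- assemble_dataset(shapes)
  expect_equal(group_variance(ds2, c(1, 2)), 0.1, tolerance = 1e-12)
  expect_error(group_variance(ds2, rep(FALSE, 4)), "empty")
})

test_that("projection and reconstruction are mutually consistent", {
  ds <- rand_dataset(m = 7, seed = 4)
  m <- fit_pca(ds)
  expect_equal(project(m, m$x0), rep(0, length(m$singular)), tolerance = 1e-9)
  # training rows project to their stored scores
  for (i in c(1, 4, 7))
    expect_equal(project(m, ds$P[i, ] + ds$x0), m$scores[i, ], tolerance = 1e-8)
  # a pure mode displacement projects onto that mode alone
  p <- project(m, m$x0 + 2.5 * m$modes[2, ])
  expect_equal(p[2], 2.5, tolerance = 1e-9)
  expect_lt(max(abs(p[-2])), 1e-9)
  # reconstruction identities
  expect_equal(reconstruct(m, numeric(0), integer(0)), m$x0)
  x <- ds$P[3, ] + ds$x0
  expect_equal(reconstruct(m, project(m, x)), x, tolerance = 1e-8)
  expect_error(reconstruct(m, 1, 99), "mode")
  expect_error(project(m, 1:5), "length")
})

test_that("planted two-mode populations are recovered exactly without noise", {
  mesh <- tiny_mesh()
  fields <- planted_fields(mesh, 2)
  pop <- make_population(mesh, fields,
                         model = score_model(baseline_sd = c(10, 5),
                                             treated_shift = 0,
                                             control_shift = 0, within_sd = 0),
                         noise_sd = 0, seed = 21)
  ds <- assemble_dataset(pop$shapes)
  m <- suppressWarnings(fit_pca(ds))
  # exactly two numerically nonzero eigenvalues
  expect_equal(sum(m$eigenvalues > 1e-8 * max(m$eigenvalues)), 2)
  # principal angles between fitted and planted subspaces vanish
  Yf <- m$modes[1:2, ]
  Yp <- pop$truth$modes
  sv <- svd(Yf %*% t(Yp))$d
  angles <- acos(pmin(sv, 1))
  expect_lt(max(angles), 1e-6)
  # variance fractions follow the planted score SDs (10, 5) -> (0.8, 0.2)
  ev <- explained_variance(m)
  expect_equal(ev$fraction[1], 0.8, tolerance = 0.15)
})

test_that("subspace recovery improves monotonically as noise shrinks", {
  mesh <- tiny_mesh()
  fields <- planted_fields(mesh, 1)
  angle_at <- function(noise_sd) {
    med <- vapply(1:5, function(s) {
      pop <- make_population(mesh, fields,
                             model = score_model(baseline_sd = 5,
                                                 treated_shift = 0,
                                                 control_shift = 0,
                                                 within_sd = 0),
                             noise_sd = noise_sd, seed = 100 + s)
      m <- suppressWarnings(fit_pca(assemble_dataset(pop$shapes)))
      acos(min(1, abs(sum(m$modes[1, ] * pop$truth$modes[1, ]))))
    }, 0.0)
    median(med)
  }
  a <- vapply(c(0.5, 0.1, 0.01), angle_at, 0.0)
  expect_true(all(diff(a) < 0))
})

test_that("leave-one-out reconstructs in-span subjects to numerical zero", {
  mesh <- tiny_mesh()
  fields <- planted_fields(mesh, 2)
  pop <- make_population(mesh, fields, n_treated = 6, n_control = 5,
                         model = score_model(baseline_sd = c(8, 4),
                                             treated_shift = c(6, 0),
                                             control_shift = 0,
                                             within_sd = c(1, 1)),
                         noise_sd = 0, seed = 33)
  ds <- assemble_dataset(pop$shapes)
  rep <- suppressWarnings(loo_errors(ds, "S01"))  # training set is rank 2
  # the held-out pair lies in the planted 2-mode span of the training set
  expect_lt(max(rep$errors), 1e-6)
  expect_equal(rep$errors_um, rep$errors * 10.4)
  expect_true(all(rep$errors >= 0))
  expect_error(loo_errors(ds, "nobody"), "both timepoints")
})
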