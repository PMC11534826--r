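# Shared fixtures, memoized so expensive volumes and meshes are built once
# per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small textured phantom used across module tests
tiny_spec <- function(seed = 7, ...) {
  phantom_spec(n_slices = 48, size_xy = 56, outer_radius = 15,
               wall_thickness = 5, crest_amplitude = 4, eccentricity = 0.25,
               roughness = 0.8, seed = seed, ...)
}

tiny_phantom <- function() memo("tiny_phantom", make_midshaft_phantom(tiny_spec()))

tiny_binary <- function() memo("tiny_binary", preprocess_volume(tiny_phantom()))

tiny_mesh <- function() memo("tiny_mesh", {
  coarsen(extract_surfaces(tiny_binary()), 400)
})

# perfectly smooth annulus (degenerate spec: no crest, no relief)
smooth_spec <- function(eccentricity = 0) {
  phantom_spec(n_slices = 24, size_xy = 48, outer_radius = 14,
               wall_thickness = 5, crest_amplitude = 0,
               eccentricity = eccentricity, radius_jitter = 0, roughness = 0,
               bump_amplitude = 0, taper = 0, blur_sigma = 0, seed = 1)
}

# a hand-built binary slice stack: annulus with optional extra structures
annulus_stack <- function(n = 32, nz = 10, r_out = 11, r_in = 6) {
  cx <- (n - 1) / 2
  xg <- matrix(rep(0:(n - 1), n), n, n) - cx
  yg <- t(xg)
  r <- sqrt(xg^2 + yg^2)
  sl <- ifelse(r <= r_out & r >= r_in, 1L, 0L)
  binary_volume(array(rep(sl, nz), c(n, n, nz)))
}

# ------------------------------------------------------- brute-force oracles

# exact two-sided signed-rank p by enumeration of all sign assignments
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  rk <- rank(abs(x))
  v_obs <- sum(rk[x > 0])
  m <- 2^n
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  mu <- n * (n + 1) / 4
  # two-sided: probability of |V - mu| >= |v_obs - mu|
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_rank_sum_p <- function(a, b) {
  na <- length(a)
  pool <- c(a, b)
  rk <- rank(pool)
  w_obs <- sum(rk[seq_len(na)])
  combs <- utils::combn(length(pool), na)
  w_all <- apply(combs, 2, function(ix) sum(rk[ix]))
  mu <- na * (length(pool) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# naive trilinear interpolation (independent of the compiled path)
naive_trilinear <- function(vol, p) {
  i0 <- floor(p)
  f <- p - i0
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    idx <- pmin(pmax(i0 + c(dx, dy, dz), 0), dim(vol) - 1)
    acc <- acc + w * vol[idx[1] + 1, idx[2] + 1, idx[3] + 1]
  }
  acc
}

# smooth planted displacement fields on a mesh, orthogonalized after centering
planted_fields <- function(mesh, k = 1) {
  nrm <- mesh_vertex_normals(mesh)
  v <- mesh$vertices
  ctr <- colMeans(v)
  th <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
  zr <- (v[, 3] - min(v[, 3])) / max(1, diff(range(v[, 3])))
  raw <- list(nrm * exp(-2 * (cos(th) + 1)),        # anterior-weighted
              nrm * sin(pi * zr),                   # axially graded
              nrm * cos(2 * th))
  raw <- raw[seq_len(k)]
  flat <- lapply(raw, function(f) as.vector(t(scale(f, scale = FALSE))))
  # Gram-Schmidt on the centered flattened fields
  for (i in seq_along(flat)) {
    if (i > 1)
      for (j in seq_len(i - 1))
        flat[[i]] <- flat[[i]] - sum(flat[[i]] * flat[[j]]) /
          sum(flat[[j]]^2) * flat[[j]]
  }
  lapply(flat, function(x) matrix(x, ncol = 3, byrow = TRUE))
}
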