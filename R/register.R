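#' Registration parameters
#'
#' @param sigma Gaussian pre-blur of the (binary) inputs, voxels; creates
#'   the intensity gradients the solver follows.
#' @param lambda dimensionless regularization weight on the discrete
#'   Laplacian of the nodal displacement field, relative to the data term.
#' @param max_iter maximal Gauss-Newton iterations per resolution level.
#' @param tol convergence tolerance on the maximal nodal update, voxels.
#' @param levels number of coarse-to-fine resolution levels.
#' @param band intensity band (fraction of dynamic range) defining the
#'   active voxels that drive the data term.
#' @param init_shift initialize the field with the integer shift that
#'   maximizes the FFT cross-correlation of the two images (captures
#'   rigid misalignments beyond the local basin of the solver).
#' @param min_level_dim smallest image extent allowed in the pyramid;
#'   deeper levels would destroy the thin cortical wall.
#' @return An object of class `reg_params`.
#' @export
reg_params <- function(sigma = 1.5, lambda = 0.05, max_iter = 30, tol = 5e-4,
                       levels = 3, band = 0.02, init_shift = TRUE,
                       min_level_dim = 32) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(sigma = sigma, lambda = lambda, max_iter = max_iter,
                 tol = tol, levels = levels, band = band,
                 init_shift = init_shift, min_level_dim = min_level_dim),
            class = "reg_params")
}

#' Nodal displacement grid
#'
#' Cubic registration grid with nodal spacing `ns` voxels covering the
#' full image domain (every voxel has eight enclosing nodes), holding one
#' displacement vector per node.
#'
#' @param ns nodal spacing, voxels (>= 2).
#' @param image_dim dimensions of the image the grid covers.
#' @param u optional nodes x 3 displacement matrix (voxel units); zero if
#'   omitted. Node order: x fastest.
#' @return An object of class `displacement_grid`.
#' @export
displacement_grid <- function(ns, image_dim, u = NULL) {
  if (ns < 2) stop("nodal spacing NS must be >= 2 voxels")
  nn <- as.integer(ceiling((image_dim - 1) / ns) + 1)
  k <- prod(nn)
  if (is.null(u)) u <- matrix(0, k, 3)
  stopifnot(nrow(u) == k, ncol(u) == 3)
  structure(list(ns = ns, nnode = nn, u = u, image_dim = image_dim),
            class = "displacement_grid")
}

#' @export
print.displacement_grid <- function(x, ...) {
  cat(sprintf("<displacement_grid> NS = %g voxels, %d x %d x %d nodes, max |u| = %.4g voxels\n",
              x$ns, x$nnode[1], x$nnode[2], x$nnode[3],
              max(abs(x$u))))
  invisible(x)
}

#' Trilinear interpolation of nodal displacements
#'
#' Each point's displacement is the trilinear blend of the vectors at its
#' eight enclosing registration grid nodes; exact at the nodes.
#'
#' @param grid a [displacement_grid()].
#' @param points n x 3 matrix of 0-based voxel coordinates inside the
#'   grid hull.
#' @return n x 3 matrix of displacement vectors (voxels).
#' @export
interpolate_displacement <- function(grid, points) {
  points <- as_points(points)
  g <- points / grid$ns
  if (any(g < -1e-9) || any(sweep(g, 2, grid$nnode - 1, "-") > 1e-9))
    stop("points outside the registration grid hull")
  out <- matrix(0, nrow(points), 3)
  for (c in 1:3) {
    comp <- array(grid$u[, c], grid$nnode)
    out[, c] <- cpp_trilinear(as.double(comp), grid$nnode, g, TRUE, 0)
  }
  out
}

#' Warp a surface mesh through a displacement grid
#'
#' Adds the interpolated nodal displacement to every vertex; connectivity
#' and endosteal/periosteal labels are unchanged.
#'
#' @param mesh a [surface_mesh()].
#' @param grid a [displacement_grid()].
#' @return The warped `surface_mesh`.
#' @export
warp_mesh <- function(mesh, grid) {
  stopifnot(inherits(mesh, "surface_mesh"))
  mesh$vertices <- mesh$vertices + interpolate_displacement(grid, mesh$vertices)
  mesh
}

#' Bone boundary voxels
#'
#' Voxels whose neighborhood (26-connected by default) contains both bone
#' and background; the locations at which registration errors are
#' evaluated.
#'
#' @param binary a [binary_volume()].
#' @param conn neighborhood: 26 (default) or 6.
#' @param foreground_only restrict to bone voxels.
#' @return m x 3 matrix of 0-based voxel coordinates.
#' @export
boundary_voxels <- function(binary, conn = 26, foreground_only = FALSE) {
  stopifnot(is_binary_volume(binary), conn %in% c(6, 26))
  cpp_boundary_voxels(binary$voxels, dim(binary$voxels), as.integer(conn),
                      foreground_only)
}

# sparse trilinear weight matrix: active voxel coords -> grid nodes
trilinear_weights <- function(points, ns, nnode) {
  n <- nrow(points)
  g <- points / ns
  i0 <- pmin(pmax(floor(g), 0), matrix(rep(nnode - 2, each = n), n, 3))
  f <- g - i0
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  idx <- function(ix, iy, iz) 1 + ix + nnode[1] * (iy + nnode[2] * iz)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    keep <- w > 0
    rows <- c(rows, which(keep))
    cols <- c(cols, idx(i0[keep, 1] + dx, i0[keep, 2] + dy, i0[keep, 3] + dz))
    vals <- c(vals, w[keep])
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(n, prod(nnode)))
}

grid_laplacian <- function(nnode) {
  k <- prod(nnode)
  idx <- array(seq_len(k), nnode)
  pairs_i <- integer(0); pairs_j <- integer(0)
  add_axis <- function(ax) {
    sel_a <- lapply(nnode, seq_len)
    sel_b <- sel_a
    sel_a[[ax]] <- seq_len(nnode[ax] - 1)
    sel_b[[ax]] <- 2:nnode[ax]
    a <- idx[sel_a[[1]], sel_a[[2]], sel_a[[3]]]
    b <- idx[sel_b[[1]], sel_b[[2]], sel_b[[3]]]
    pairs_i <<- c(pairs_i, as.vector(a))
    pairs_j <<- c(pairs_j, as.vector(b))
  }
  for (ax in 1:3) if (nnode[ax] > 1) add_axis(ax)
  A <- Matrix::sparseMatrix(i = c(pairs_i, pairs_j), j = c(pairs_j, pairs_i),
                            x = 1, dims = c(k, k))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(x = deg) - A
}

normalize_pair <- function(a, b) {
  lo <- min(min(a), min(b)); hi <- max(max(a), max(b))
  if (hi <= lo) stop("cannot register constant images")
  list(a = (a - lo) / (hi - lo), b = (b - lo) / (hi - lo))
}

# integer shift s maximizing sum_x moved(x) * fixed(x + s), by FFT
# cross-correlation over circular shifts, unwrapped to signed offsets
estimate_integer_shift <- function(fixed_arr, moved_arr) {
  d <- dim(fixed_arr)
  cc <- Re(fft(Conj(fft(moved_arr)) * fft(fixed_arr), inverse = TRUE))
  s <- which(cc == max(cc), arr.ind = TRUE)[1, ] - 1
  ifelse(s > d / 2, s - d, s)
}

# one pyramid level of Gauss-Newton SSD minimization; u in level voxels
register_level <- function(fixed_blur, moved_blur, ns, params, U0, nnode) {
  d <- dim(moved_blur)
  band <- params$band
  act <- which((moved_blur > band & moved_blur < 1 - band) |
               (fixed_blur > band & fixed_blur < 1 - band))
  if (!length(act)) return(list(u = U0, converged = TRUE, iters = 0L))
  a0 <- act - 1L
  pts <- cbind(a0 %% d[1], (a0 %/% d[1]) %% d[2], a0 %/% (d[1] * d[2]))
  storage.mode(pts) <- "double"
  mv <- as.double(moved_blur)[act]
  W <- trilinear_weights(pts, ns, nnode)
  L <- grid_laplacian(nnode)
  LtL <- Matrix::crossprod(L)
  k <- prod(nnode)
  U <- U0
  fb <- as.double(fixed_blur)
  # voxels whose warped position leaves the fixed domain carry no data
  # information (content truncated at the image border): weight them out
  mrg <- ceiling(3 * params$sigma)
  valid_w <- function(p) {
    as.double(p[, 1] >= mrg & p[, 1] <= d[1] - 1 - mrg &
              p[, 2] >= mrg & p[, 2] <= d[2] - 1 - mrg &
              p[, 3] >= mrg & p[, 3] <= d[3] - 1 - mrg)
  }
  ssd_of <- function(U, lam_eff) {
    p <- pts + as.matrix(W %*% U)
    val <- cpp_trilinear(fb, d, p, TRUE, 0)
    sum(valid_w(p) * (mv - val)^2) + lam_eff * sum(as.matrix(L %*% U)^2)
  }
  converged <- FALSE
  iters <- 0L
  lam_eff <- NA_real_
  Hfact <- NULL
  stale <- 0L
  build_normal <- function(sg, vw) {
    GW <- vector("list", 3)
    for (c in 1:3) GW[[c]] <- Matrix::Diagonal(x = vw * sg[, c + 1]) %*% W
    JtJ_rows <- vector("list", 3)
    for (c in 1:3) {
      row <- vector("list", 3)
      for (cc in 1:3) {
        row[[cc]] <- if (cc >= c) Matrix::crossprod(GW[[c]], GW[[cc]]) else
          Matrix::t(JtJ_rows[[cc]][[c]])
      }
      JtJ_rows[[c]] <- row
    }
    H <- rbind(cbind(JtJ_rows[[1]][[1]], JtJ_rows[[1]][[2]], JtJ_rows[[1]][[3]]),
               cbind(JtJ_rows[[2]][[1]], JtJ_rows[[2]][[2]], JtJ_rows[[2]][[3]]),
               cbind(JtJ_rows[[3]][[1]], JtJ_rows[[3]][[2]], JtJ_rows[[3]][[3]]))
    mdiag <- mean(Matrix::diag(H))
    if (is.na(lam_eff))
      lam_eff <<- params$lambda * max(mdiag, 1e-12) / mean(Matrix::diag(LtL))
    reg_blk <- lam_eff * LtL
    H <- H + Matrix::bdiag(reg_blk, reg_blk, reg_blk) +
      Matrix::Diagonal(3 * k, x = 1e-10 * max(mdiag, 1e-12))
    Matrix::forceSymmetric(H)
  }
  refactor <- function(Hs) Matrix::Cholesky(Hs, perm = TRUE, super = TRUE)
  for (it in seq_len(params$max_iter)) {
    iters <- it
    p <- pts + as.matrix(W %*% U)
    sg <- cpp_trilinear_grad(fb, d, p)
    vw <- valid_w(p)
    r <- vw * (mv - sg[, 1])
    # the normal matrix changes slowly along the iteration; refresh it only
    # every few steps (inexact Newton with the true gradient every step)
    if (is.null(Hfact) || stale >= 6L) {
      Hfact <- refactor(build_normal(sg, vw))
      stale <- 0L
    }
    GWc <- vector("list", 3)
    for (c in 1:3) GWc[[c]] <- vw * sg[, c + 1]
    rhs <- matrix(0, 3 * k, 1)
    for (c in 1:3)
      rhs[((c - 1) * k + 1):(c * k), 1] <-
        as.vector(Matrix::crossprod(W, GWc[[c]] * r)) -
        lam_eff * as.vector(LtL %*% U[, c])
    delta <- matrix(as.vector(Matrix::solve(Hfact, rhs)), k, 3)
    if (!all(is.finite(delta))) break
    f_old <- ssd_of(U, lam_eff)
    alpha <- 1
    improved <- FALSE
    for (bt in 1:6) {
      U_try <- U + alpha * delta
      if (ssd_of(U_try, lam_eff) <= f_old + 1e-12) { improved <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!improved) {
      if (stale > 0L) { stale <- 99L; next }  # retry with a fresh Hessian
      break
    }
    stale <- stale + 1L
    U <- U + alpha * delta
    if (max(abs(alpha * delta)) < params$tol) { converged <- TRUE; break }
  }
  list(u = U, converged = converged, iters = iters)
}

#' Deformable registration on a cubic nodal grid
#'
#' Estimates the displacement field mapping the moved (reference) image
#' onto the fixed (target) image, parameterized by one displacement
#' vector per node of a cubic grid with nodal spacing `ns` voxels and
#' trilinear interpolation inside cells. Inputs are pre-blurred
#' (`params$sigma`) to create intensity gradients (essential for binary
#' images) and the sum of squared intensity differences, regularized by a
#' discrete Laplacian on the nodal field, is minimized by Gauss-Newton
#' iterations over a coarse-to-fine image pyramid. The solver is fully
#' deterministic.
#'
#' The returned displacement lives on the moved image domain: adding the
#' interpolated displacement to a reference surface vertex gives the
#' anatomically corresponding location on the fixed image.
#'
#' @param fixed,moved [volume_image()]s (or [binary_volume()]s) of
#'   identical shape and spacing.
#' @param ns nodal spacing, voxels (>= 2; default 5).
#' @param params a [reg_params()].
#' @return A [displacement_grid()] with attributes `"converged"` (logical)
#'   and `"iterations"`. A warning is emitted when the final level stopped
#'   at `max_iter` without meeting the tolerance.
#' @export
register_volumes <- function(fixed, moved, ns = 5, params = reg_params()) {
  if (!all(dim(fixed$voxels) == dim(moved$voxels)))
    stop("fixed and moved images must have the same shape")
  if (fixed$spacing != moved$spacing)
    stop("fixed and moved images must share the voxel spacing")
  if (ns < 2) stop("nodal spacing NS must be >= 2 voxels")
  nrm <- normalize_pair(as.double(fixed$voxels), as.double(moved$voxels))
  d <- dim(fixed$voxels)
  # image pyramid (factor 2), not descending below ~3 grid cells per axis
  pyr_f <- list(array(nrm$a, d))
  pyr_m <- list(array(nrm$b, d))
  dims <- list(d)
  for (l in seq_len(params$levels - 1)) {
    dd <- dims[[l]]
    if (any(floor((dd + 1) / 2) < params$min_level_dim)) break
    pyr_f[[l + 1]] <- cpp_downsample2(pyr_f[[l]], dd)
    pyr_m[[l + 1]] <- cpp_downsample2(pyr_m[[l]], dd)
    dims[[l + 1]] <- dim(pyr_f[[l + 1]])
  }
  nlev <- length(pyr_f)
  U <- NULL
  nnode_prev <- NULL
  converged <- TRUE
  iters_total <- 0L
  for (l in nlev:1) {
    dl <- dims[[l]]
    ns_l <- max(2, ns)
    nnode <- as.integer(ceiling((dl - 1) / ns_l) + 1)
    if (is.null(U)) {
      U0 <- matrix(0, prod(nnode), 3)
      if (isTRUE(params$init_shift)) {
        s <- estimate_integer_shift(pyr_f[[l]], pyr_m[[l]])
        U0 <- matrix(rep(as.double(s), each = prod(nnode)), prod(nnode), 3)
      }
    } else {
      # prolong previous (coarser-image) solution: positions scale by 2
      node_pos <- as.matrix(expand.grid(0:(nnode[1] - 1), 0:(nnode[2] - 1),
                                        0:(nnode[3] - 1))) * ns_l
      gpts <- node_pos / 2 / ns_l  # in previous grid's node units
      gpts <- pmin(pmax(gpts, 0), matrix(rep(nnode_prev - 1, each = nrow(gpts)),
                                         ncol = 3))
      U0 <- matrix(0, prod(nnode), 3)
      for (c in 1:3) {
        comp <- array(U[, c], nnode_prev)
        U0[, c] <- 2 * cpp_trilinear(as.double(comp), nnode_prev, gpts, TRUE, 0)
      }
    }
    # zero padding keeps the blur consistent with the zero background used
    # when content is truncated at the image border
    fb <- cpp_gauss_blur(as.double(pyr_f[[l]]), dl, params$sigma, TRUE)
    mb <- cpp_gauss_blur(as.double(pyr_m[[l]]), dl, params$sigma, TRUE)
    res <- register_level(array(fb, dl), array(mb, dl), ns_l, params, U0, nnode)
    U <- res$u
    nnode_prev <- nnode
    iters_total <- iters_total + res$iters
    if (l == 1) converged <- res$converged
  }
  if (!converged)
    warning("registration did not meet tolerance within max_iter; returning best iterate")
  grid <- displacement_grid(ns, d, u = U)
  attr(grid, "converged") <- converged
  attr(grid, "iterations") <- iters_total
  grid
}

#' Write a displacement grid as a columnar text table
#'
#' One row per node: integer node index triple (0-based), then the three
#' displacement components in voxels. Grid geometry is kept in header
#' comment lines.
#'
#' @param grid a [displacement_grid()].
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_displacement_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# ns %g", grid$ns),
               sprintf("# nnode %d %d %d", grid$nnode[1], grid$nnode[2], grid$nnode[3]),
               sprintf("# image_dim %d %d %d", grid$image_dim[1],
                       grid$image_dim[2], grid$image_dim[3]),
               "i,j,k,ux,uy,uz"), con)
  nn <- grid$nnode
  idx <- as.matrix(expand.grid(0:(nn[1] - 1), 0:(nn[2] - 1), 0:(nn[3] - 1)))
  writeLines(paste(idx[, 1], idx[, 2], idx[, 3], grid$u[, 1], grid$u[, 2],
                   grid$u[, 3], sep = ","), con)
  invisible(path)
}

#' Read a displacement grid written by [write_displacement_grid()]
#'
#' @param path input path.
#' @return A [displacement_grid()].
#' @export
read_displacement_grid <- function(path) {
  ln <- readLines(path)
  ns <- as.numeric(strsplit(ln[1], " ")[[1]][3])
  nn <- as.integer(strsplit(ln[2], " ")[[1]][3:5])
  d <- as.integer(strsplit(ln[3], " ")[[1]][3:5])
  tab <- read.csv(text = ln[-(1:3)])
  u <- as.matrix(tab[, c("ux", "uy", "uz")])
  dimnames(u) <- NULL
  displacement_grid(ns, d, u = u)
}
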