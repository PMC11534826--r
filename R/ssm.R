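#' PCA decomposition of the centered shape matrix
#'
#' Factorizes the M x 3N centered matrix P as P = a Y, where the rows of
#' Y are orthonormal mode shapes (right singular vectors of P, ordered by
#' descending singular value) and a holds one score per observation and
#' mode. Centering removes one rank, so at most M - 1 modes are retained;
#' modes with (numerically) zero singular value are dropped with a
#' warning. Implemented via SVD for stability at 3N >> M. Each mode's
#' sign is pinned so that its largest-magnitude component is positive,
#' making reports reproducible.
#'
#' @param dataset a `shape_dataset` from [assemble_dataset()] from [assemble_dataset()] (M >= 3).
#' @return An object of class `shape_pca`: list with `$scores` (M x K),
#'   `$modes` (K x 3N, orthonormal rows), `$eigenvalues` (variance per
#'   mode, Frobenius convention with M - 1 denominator), `$singular`
#'   (singular values), `$x0` and `$meta`.
#' @export
fit_pca <- function(dataset) {
  stopifnot(inherits(dataset, "shape_dataset"))
  P <- dataset$P
  m <- nrow(P)
  if (m < 3) stop("need M >= 3 observations")
  sv <- svd(P, nu = m, nv = 0)
  # rotate basis without forming the full 3N x 3N right factor
  kmax <- m - 1
  dtol <- max(sv$d) * 1e-10
  keep <- which(sv$d[seq_len(kmax)] > dtol)
  if (length(keep) < kmax)
    warning("rank-deficient beyond centering: retained ", length(keep),
            " of ", kmax, " modes")
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  Y <- crossprod(U, P) / d  # rows = right singular vectors
  a <- U %*% diag(d, nrow = length(d))
  # sign convention
  for (k in seq_along(keep)) {
    j <- which.max(abs(Y[k, ]))
    if (Y[k, j] < 0) {
      Y[k, ] <- -Y[k, ]
      a[, k] <- -a[, k]
    }
  }
  structure(list(scores = a, modes = Y, singular = d,
                 eigenvalues = d^2 / (m - 1), x0 = dataset$x0,
                 meta = dataset$meta),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  ev <- explained_variance(x)
  cat(sprintf("<shape_pca> %d observations, %d modes; top modes explain %s\n",
              nrow(x$scores), length(x$singular),
              paste0(round(100 * ev$fraction[seq_len(min(3, length(ev$fraction)))], 1),
                     "%", collapse = ", ")))
  invisible(x)
}

#' Per-mode and cumulative explained variance
#'
#' @param model a fitted [fit_pca()] model.
#' @return Data frame with columns mode, fraction, cumulative; cumulative
#'   is non-decreasing and ends at 1.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "shape_pca"))
  fr <- model$eigenvalues / sum(model$eigenvalues)
  data.frame(mode = seq_along(fr), fraction = fr, cumulative = cumsum(fr))
}

#' Proportional shape variance of a subgroup
#'
#' Fraction of the total shape variance (sum of squared centered shape
#' vectors) carried by the selected rows; the variance normalization
#' constant cancels in the fraction.
#'
#' @param dataset a `shape_dataset` from [assemble_dataset()].
#' @param group_mask logical or integer row selector (>= 1 row).
#' @return A single fraction between 0 and 1.
#' @export
group_variance <- function(dataset, group_mask) {
  stopifnot(inherits(dataset, "shape_dataset"))
  rows <- seq_len(nrow(dataset$P))[group_mask]
  if (!length(rows)) stop("empty group mask")
  sq <- rowSums(dataset$P^2)
  sum(sq[rows]) / sum(sq)
}

#' Project a shape vector onto the fitted modes
#'
#' Scores are `(x - x0) . t(Y)`; projecting a training row returns its
#' stored score row exactly (orthonormal modes).
#'
#' @param model a `shape_pca` model from [fit_pca()].
#' @param shape_vector numeric vector of length 3N.
#' @return Numeric score vector, one entry per mode.
#' @export
project <- function(model, shape_vector) {
  stopifnot(inherits(model, "shape_pca"))
  x <- as.double(shape_vector)
  if (length(x) != length(model$x0))
    stop("shape vector length does not match the model")
  as.vector((x - model$x0) %*% t(model$modes))
}

#' Reconstruct a shape from scores
#'
#' x0 plus the superposition of the selected mode shapes weighted by
#' their scores.
#'
#' @param model a `shape_pca` model from [fit_pca()].
#' @param scores numeric scores; either full length or matching
#'   `mode_subset`.
#' @param mode_subset mode indices to use (default: all). An empty subset
#'   returns the mean shape.
#' @return Numeric shape vector of length 3N.
#' @export
reconstruct <- function(model, scores, mode_subset = NULL) {
  stopifnot(inherits(model, "shape_pca"))
  k <- length(model$singular)
  if (is.null(mode_subset)) mode_subset <- seq_len(k)
  if (length(mode_subset) == 0) return(model$x0)
  if (any(mode_subset < 1 | mode_subset > k)) stop("unknown mode index")
  s <- as.double(scores)
  if (length(s) == k) s <- s[mode_subset]
  if (length(s) != length(mode_subset))
    stop("scores do not conform to the mode subset")
  model$x0 + as.vector(s %*% model$modes[mode_subset, , drop = FALSE])
}

#' Leave-one-out reconstruction errors
#'
#' Removes both timepoint observations of one subject, refits the PCA on
#' the remaining rows, projects and reconstructs the held-out shapes with
#' all modes, and reports the per-vertex Euclidean distance between the
#' reconstructed and original corresponding vertices.
#'
#' @param dataset a `shape_dataset` from [assemble_dataset()].
#' @param holdout_subject subject id present at both timepoints.
#' @param spacing voxel size in micrometres for the `errors_um` field.
#' @return An object of class `loo_report`: list with `$subject`,
#'   `$errors` (vertices x timepoints matrix, voxels), `$errors_um` and
#'   `$summary` (per-timepoint mean/sd/median/max).
#' @export
loo_errors <- function(dataset, holdout_subject, spacing = 10.4) {
  stopifnot(inherits(dataset, "shape_dataset"))
  idx <- which(dataset$meta$subject == holdout_subject)
  if (length(idx) < 2)
    stop("holdout subject must have both timepoints in the dataset")
  X <- sweep(dataset$P, 2, -dataset$x0)  # original uncentered shapes
  train <- lapply(setdiff(seq_len(nrow(X)), idx), function(i)
    shape_vector(X[i, ], dataset$meta$subject[i], dataset$meta$group[i],
                 dataset$meta$timepoint[i]))
  model <- fit_pca(assemble_dataset(train))
  nvert <- ncol(X) / 3
  errs <- matrix(0, nvert, length(idx))
  tps <- dataset$meta$timepoint[idx]
  for (t in seq_along(idx)) {
    orig <- X[idx[t], ]
    rec <- reconstruct(model, project(model, orig))
    dv <- matrix(rec - orig, ncol = 3, byrow = TRUE)
    errs[, t] <- sqrt(rowSums(dv^2))
  }
  colnames(errs) <- paste0("week", tps)
  summ <- data.frame(timepoint = tps,
                     mean = colMeans(errs), sd = apply(errs, 2, sd),
                     median = apply(errs, 2, median), max = apply(errs, 2, max))
  structure(list(subject = holdout_subject, errors = errs,
                 errors_um = errs * spacing, summary = summ,
                 model = model),
            class = "loo_report")
}
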