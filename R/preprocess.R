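#' Histogram-based global threshold
#'
#' Builds a 256-bin intensity histogram, smooths it with a fixed 5-bin
#' moving average, locates the two most prominent local maxima (the
#' background and bone peaks) and returns the arithmetic mean of the two
#' peak intensities. Ties between equally prominent peaks are broken
#' toward the extreme intensities.
#'
#' @param image a [volume_image()].
#' @param n_bins number of histogram bins.
#' @return A single grayscale threshold.
#' @export
compute_threshold <- function(image, n_bins = 256) {
  v <- as.vector(image$voxels)
  rng <- range(v)
  if (diff(rng) == 0) stop("flat image: fewer than two histogram peaks; set a manual threshold")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  centers <- (br[-1] + br[-length(br)]) / 2
  k <- rep(1 / 5, 5)
  hs <- as.vector(stats::filter(c(rep(h[1], 2), h, rep(h[n_bins], 2)), k))
  hs <- hs[!is.na(hs)]
  # dominant peak (usually the background mode), then the strongest local
  # maximum outside an exclusion window around it (the bone mode); the
  # mixed partial-volume shoulder between the modes stays well below both
  p1 <- which.max(hs)
  excl <- round(n_bins / 4)
  local_max <- which(hs >= c(-Inf, hs[-n_bins]) & hs >= c(hs[-1], -Inf) & hs > 0)
  cand <- local_max[abs(local_max - p1) > excl]
  if (!length(cand))
    stop("fewer than two histogram peaks detected; set a manual threshold")
  # ties between equal candidates break toward the extreme intensities
  best <- max(hs[cand])
  cand <- cand[hs[cand] >= best * (1 - 1e-12)]
  p2 <- cand[which.max(abs(cand - p1))]
  mean(centers[sort(c(p1, p2))])
}

#' Binarize a volume at a single grayscale level
#'
#' @param image a [volume_image()].
#' @param threshold grayscale level; voxels `>= threshold` become bone (1).
#' @return A [binary_volume()].
#' @export
binarize <- function(image, threshold) {
  binary_volume(array(as.integer(image$voxels >= threshold), dim(image$voxels)),
                image$spacing, image$origin)
}

# -- 2D slice helpers (x along rows, y along columns) -----------------------

shift2d <- function(m, di, dj, fill = 0L) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  si <- max(1, 1 - di):min(n, n - di)
  sj <- max(1, 1 - dj):min(p, p - dj)
  out[si + di, sj + dj] <- m[si, sj]
  out
}

dilate2d <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1)
    if (di || dj) out <- out | shift2d(m, di, dj)
  out * 1L
}

erode2d <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1)
    if (di || dj) out <- out & shift2d(m, di, dj, fill = 1L)
  out * 1L
}

close2d <- function(m, r) {
  out <- m
  for (i in seq_len(r)) out <- dilate2d(out)
  for (i in seq_len(r)) out <- erode2d(out)
  out
}

open2d <- function(m, r = 1) {
  out <- m
  for (i in seq_len(r)) out <- erode2d(out)
  for (i in seq_len(r)) out <- dilate2d(out)
  out
}

# background components of a slice that do not touch the slice border
# (4-connected background against the 8-connected foreground)
enclosed_bg_labels <- function(bone_slice) {
  bg <- 1L - bone_slice
  lab <- cpp_label2d(bg, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  list(lab = lab, enclosed = setdiff(sort(unique(lab[lab > 0])), border))
}

boundary_pixel_count <- function(mask) {
  # pixels of the component having an 8-neighbour outside the component
  inner <- erode2d(mask)
  sum(mask) - sum(inner)
}

#' Fill small enclosed holes slice by slice
#'
#' Per axial slice, background components fully enclosed by bone whose
#' boundary-pixel count is smaller than `perimeter_max` are filled with
#' bone. Larger enclosed features are left untouched and recorded for the
#' paired-timepoint resolution step. Background regions touching the
#' slice border are never holes.
#'
#' @param binary a [binary_volume()].
#' @param perimeter_max perimeter limit in pixels (default 50).
#' @return List with `$volume` (corrected [binary_volume()]) and
#'   `$features` (data frame: id, kind, slice, area, perimeter, action).
#' @export
fill_small_holes <- function(binary, perimeter_max = 50) {
  stopifnot(is_binary_volume(binary))
  if (perimeter_max <= 0) stop("perimeter_max must be positive")
  vox <- binary$voxels
  nz <- dim(vox)[3]
  rec <- list()
  idc <- 0
  for (k in seq_len(nz)) {
    sl <- vox[, , k]
    eb <- enclosed_bg_labels(sl)
    for (lb in eb$enclosed) {
      mask <- (eb$lab == lb) * 1L
      per <- boundary_pixel_count(mask)
      idc <- idc + 1
      if (per < perimeter_max) {
        sl[mask == 1L] <- 1L
        rec[[idc]] <- data.frame(id = idc, kind = "small_hole", slice = k,
                                 area = sum(mask), perimeter = per,
                                 action = "filled")
      } else {
        rec[[idc]] <- data.frame(id = idc, kind = "large_hole", slice = k,
                                 area = sum(mask), perimeter = per,
                                 action = "none")
      }
    }
    vox[, , k] <- sl
  }
  features <- if (length(rec)) do.call(rbind, rec) else
    data.frame(id = integer(), kind = character(), slice = integer(),
               area = integer(), perimeter = integer(), action = character())
  list(volume = binary_volume(vox, binary$spacing, binary$origin),
       features = features)
}

# 3D grouping of per-slice enclosed background regions. Returns the union
# mask of enclosed background, its 6-connected 3D labels, and the label of
# the medullary cavity (largest component).
enclosed_bg_3d <- function(vox) {
  d <- dim(vox)
  enc <- array(0L, d)
  for (k in seq_len(d[3])) {
    eb <- enclosed_bg_labels(vox[, , k])
    if (length(eb$enclosed))
      enc[, , k][eb$lab %in% eb$enclosed] <- 1L
  }
  lab <- cpp_label3d(enc, d, 6L)
  sizes <- tabulate(lab[lab > 0])
  cavity <- if (length(sizes)) which.max(sizes) else 0L
  list(mask = enc, lab = lab, cavity = cavity)
}

# delete the thin bone corridor separating a feature from the cavity in one
# slice: bone pixels on minimal-length paths between the two regions
delete_trabecula_slice <- function(sl, feature_mask, cavity_mask) {
  if (!any(feature_mask) || !any(cavity_mask)) return(sl)
  df <- cpp_bfs_dist2d(feature_mask * 1L)
  dc <- cpp_bfs_dist2d(cavity_mask * 1L)
  tot <- df + dc
  bone <- sl == 1L
  if (!any(bone)) return(sl)
  mn <- min(tot[bone])
  corridor <- bone & tot <= mn + 1
  sl[corridor] <- 0L
  sl
}

feature_spans <- function(lab, labels) {
  vapply(labels, function(lb) {
    ks <- which(apply(lab == lb, 3, any))
    length(unique(ks))
  }, 0L)
}

#' Resolve large intracortical features across a timepoint pair
#'
#' Applies the paired-timepoint geometry-correction rules to the large
#' hole-like features surviving [fill_small_holes()]. For each feature the
#' number of adjacent slices containing it is counted at both timepoints;
#' if both counts are below `span_limit` the bone strut bounding the hole
#' (a trabecula) is deleted in all slices of both volumes, merging the
#' feature into the medullary cavity. Remaining features are classified by
#' their structural change between timepoints: features whose slice span
#' changes substantially are treated as trabecular cavities (strut
#' deleted), stable features as cortical pores (filled). Transverse gaps
#' that breach the cortex are closed; thin bone spurs protruding into the
#' cavity (early-stage trabeculae) can additionally be removed with
#' `remove_spurs`.
#'
#' @param binary_t1,binary_t2 aligned [binary_volume()]s of one subject.
#' @param span_limit slice-count rule threshold (default 7 slices).
#' @param span_change_min span difference (slices) above which a stable
#'   classification flips to trabecular.
#' @param remove_spurs also delete thin bone spurs protruding into the
#'   cavity (early-stage trabeculae). Off by default: spur removal is the
#'   semi-automatic part of the correction and is best reviewed by an
#'   operator.
#' @param spur_area_max maximal pixel area of a deletable cavity spur.
#' @return List with `$volume_t1`, `$volume_t2` and `$features` (data
#'   frame: id, kind, span_t1, span_t2, action).
#' @export
resolve_large_features <- function(binary_t1, binary_t2, span_limit = 7,
                                   span_change_min = 3, remove_spurs = FALSE,
                                   spur_area_max = 25) {
  stopifnot(is_binary_volume(binary_t1), is_binary_volume(binary_t2))
  if (!all(dim(binary_t1$voxels) == dim(binary_t2$voxels)))
    stop("timepoint volumes are misaligned (different shapes)")
  v1 <- binary_t1$voxels
  v2 <- binary_t2$voxels
  d <- dim(v1)
  rec <- list(); idc <- 0

  repair <- function(v) {
    # transverse gap repair: per slice, close the cortex until the annulus
    # (one foreground component, one enclosed cavity) is restored
    for (k in seq_len(d[3])) {
      sl <- v[, , k]
      if (!any(sl == 1L)) next
      ok <- function(s) {
        fg <- cpp_label2d(s, 8L)
        nc <- length(enclosed_bg_labels(s)$enclosed)
        max(fg) == 1 && nc >= 1
      }
      if (ok(sl)) next
      for (r in 1:5) {
        cl <- close2d(sl, r)
        if (ok(cl)) {
          idc <<- idc + 1
          rec[[idc]] <<- data.frame(id = idc, kind = "transverse_pore",
                                    span_t1 = 1L, span_t2 = 1L,
                                    action = "filled")
          sl <- cl
          break
        }
      }
      v[, , k] <- sl
    }
    v
  }
  v1 <- repair(v1)
  v2 <- repair(v2)

  e1 <- enclosed_bg_3d(v1)
  e2 <- enclosed_bg_3d(v2)
  f1 <- setdiff(sort(unique(e1$lab[e1$lab > 0])), e1$cavity)
  f2 <- setdiff(sort(unique(e2$lab[e2$lab > 0])), e2$cavity)

  # pair features across timepoints by voxel overlap
  match2 <- function(lb) {
    ov <- e2$lab[e1$lab == lb]
    ov <- ov[ov > 0 & ov != e2$cavity]
    if (!length(ov)) return(0L)
    as.integer(names(sort(-table(ov)))[1])
  }
  apply_action <- function(v, enc, lb, action) {
    if (lb == 0L) return(v)
    fm <- enc$lab == lb
    if (action == "filled") {
      v[fm] <- 1L
    } else {
      ks <- which(apply(fm, 3, any))
      for (k in ks)
        v[, , k] <- delete_trabecula_slice(v[, , k], fm[, , k],
                                           (enc$lab[, , k] == enc$cavity))
    }
    v
  }

  seen2 <- integer()
  for (lb in f1) {
    m2 <- match2(lb)
    seen2 <- c(seen2, m2)
    s1 <- feature_spans(e1$lab, lb)
    s2 <- if (m2 > 0) feature_spans(e2$lab, m2) else 0L
    idc <- idc + 1
    if (s1 < span_limit && s2 < span_limit) {
      kind <- "trabecula"; action <- "deleted"
    } else if (abs(s1 - s2) >= span_change_min) {
      kind <- "trabecular_cavity"; action <- "deleted"
    } else {
      kind <- "cortical_pore"; action <- "filled"
    }
    rec[[idc]] <- data.frame(id = idc, kind = kind, span_t1 = s1,
                             span_t2 = s2, action = action)
    v1 <- apply_action(v1, e1, lb, action)
    v2 <- apply_action(v2, e2, m2, action)
  }
  for (lb in setdiff(f2, seen2)) {
    s2 <- feature_spans(e2$lab, lb)
    idc <- idc + 1
    if (s2 < span_limit) { kind <- "trabecula"; action <- "deleted" }
    else { kind <- "cortical_pore"; action <- "filled" }
    rec[[idc]] <- data.frame(id = idc, kind = kind, span_t1 = 0L,
                             span_t2 = s2, action = action)
    v2 <- apply_action(v2, e2, lb, action)
  }

  despur <- function(v) {
    # early-stage trabeculae: thin spurs into the cavity removed by opening
    for (k in seq_len(d[3])) {
      sl <- v[, , k]
      if (!any(sl == 1L)) next
      eb <- enclosed_bg_labels(sl)
      if (!length(eb$enclosed)) next
      cav <- (eb$lab %in% eb$enclosed) * 1L
      dim(cav) <- dim(sl)
      spur <- sl - open2d(sl)
      if (!any(spur == 1L)) next
      sp_lab <- cpp_label2d(spur, 8L)
      near_cav <- dilate2d(cav)
      for (s in sort(unique(sp_lab[sp_lab > 0]))) {
        m <- sp_lab == s
        if (sum(m) <= spur_area_max && any(near_cav[m] == 1L)) {
          # removal must not disconnect the cortex
          cand <- sl; cand[m] <- 0L
          if (max(cpp_label2d(cand, 8L)) == max(cpp_label2d(sl, 8L))) {
            sl <- cand
            idc <<- idc + 1
            rec[[idc]] <<- data.frame(id = idc, kind = "trabecula",
                                      span_t1 = 1L, span_t2 = 1L,
                                      action = "deleted")
          }
        }
      }
      v[, , k] <- sl
    }
    v
  }
  if (isTRUE(remove_spurs)) {
    v1 <- despur(v1)
    v2 <- despur(v2)
  }

  features <- if (length(rec)) do.call(rbind, rec) else
    data.frame(id = integer(), kind = character(), span_t1 = integer(),
               span_t2 = integer(), action = character())
  list(volume_t1 = binary_volume(v1, binary_t1$spacing, binary_t1$origin),
       volume_t2 = binary_volume(v2, binary_t2$spacing, binary_t2$origin),
       features = features)
}

#' Per-slice topology report
#'
#' For each axial slice, counts 8-connected foreground components and
#' enclosed (4-connected, non-border) background cavities. A corrected
#' cortical section passes when every slice reports exactly one of each.
#'
#' @param binary a [binary_volume()].
#' @return A data frame (slice, n_foreground, n_cavities, pass) with an
#'   overall logical attribute `"pass"`.
#' @export
check_topology <- function(binary) {
  stopifnot(is_binary_volume(binary))
  d <- dim(binary$voxels)
  out <- data.frame(slice = seq_len(d[3]), n_foreground = 0L,
                    n_cavities = 0L, pass = FALSE)
  for (k in seq_len(d[3])) {
    sl <- binary$voxels[, , k]
    nf <- max(cpp_label2d(sl, 8L))
    nc <- length(enclosed_bg_labels(sl)$enclosed)
    out$n_foreground[k] <- nf
    out$n_cavities[k] <- nc
    out$pass[k] <- nf == 1L && nc == 1L
  }
  attr(out, "pass") <- all(out$pass)
  out
}

#' Binarize and geometry-correct a grayscale section
#'
#' Convenience wrapper: histogram threshold, binarization and small-hole
#' filling for a single volume.
#'
#' @param image a [volume_image()].
#' @param threshold optional manual threshold; default from
#'   [compute_threshold()].
#' @param perimeter_max small-hole perimeter limit, pixels.
#' @return A [binary_volume()].
#' @export
preprocess_volume <- function(image, threshold = NULL, perimeter_max = 50) {
  if (is_binary_volume(image)) return(fill_small_holes(image, perimeter_max)$volume)
  if (is.null(threshold)) threshold <- compute_threshold(image)
  fill_small_holes(binarize(image, threshold), perimeter_max)$volume
}
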