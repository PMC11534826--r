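#' Labeled endosteal/periosteal surface mesh
#'
#' Triangulated surface of a cortical section with one label per vertex:
#' `"endosteal"` for the cavity-facing shell, `"periosteal"` for the
#' outer shell. Vertices are 0-based voxel coordinates; physical
#' micrometres are `vertices * spacing`.
#'
#' @param vertices N x 3 coordinate matrix, voxel units.
#' @param faces M x 3 matrix of 1-based vertex indices, oriented so face
#'   normals point from bone into background.
#' @param labels character vector of per-vertex labels.
#' @param spacing voxel size, micrometres.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, labels, spacing = 10.4) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            length(labels) == nrow(vertices),
            all(labels %in% c("endosteal", "periosteal")))
  storage.mode(faces) <- "integer"
  structure(list(vertices = vertices, faces = faces, labels = labels,
                 spacing = spacing),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices (%d endosteal, %d periosteal), %d faces, spacing %.3g um\n",
              nrow(x$vertices), sum(x$labels == "endosteal"),
              sum(x$labels == "periosteal"), nrow(x$faces), x$spacing))
  invisible(x)
}

#' Extract the labeled bone surface from a corrected binary volume
#'
#' Isosurfaces the bone/background interface at 0.5 (marching tetrahedra)
#' and labels each vertex endosteal or periosteal by its adjacency to the
#' enclosed medullary cavity versus the outer background. The volume must
#' pass [check_topology()]. The two shells are open at the proximal and
#' distal crop planes (no artificial end caps are generated there);
#' vertices ambiguous between the shells are assigned periosteal with a
#' warning.
#'
#' @param binary a [binary_volume()].
#' @return A [surface_mesh()] with exactly two labeled shells.
#' @export
extract_surfaces <- function(binary) {
  stopifnot(is_binary_volume(binary))
  topo <- check_topology(binary)
  if (!attr(topo, "pass"))
    stop("topology check failed on ", sum(!topo$pass),
         " slice(s); run geometry correction first")
  d <- dim(binary$voxels)
  # pad x and y with background so the outer shell closes laterally; leave z
  # unpadded so the section remains open at its crop planes
  pad <- array(0, d + c(2, 2, 0))
  pad[2:(d[1] + 1), 2:(d[2] + 1), ] <- binary$voxels
  iso <- cpp_marching_tets(as.double(pad), dim(pad), 0.5)
  verts <- iso$vertices
  verts[, 1] <- verts[, 1] - 1
  verts[, 2] <- verts[, 2] - 1
  enc <- enclosed_bg_3d(binary$voxels)
  cav <- array(0, d)
  cav[enc$mask == 1L] <- 1
  outer <- array(as.double(binary$voxels == 0L), d) - cav
  cs <- cpp_trilinear(as.double(cav), d, verts, TRUE, 0)
  os <- cpp_trilinear(outer, d, verts, TRUE, 0)
  amb <- abs(cs - os) < 1e-9 & cs > 0
  if (any(amb))
    warning(sum(amb), " vertices touch both cavity and outer background; assigned periosteal")
  labels <- ifelse(cs > os & !amb, "endosteal", "periosteal")
  if (!any(labels == "endosteal"))
    stop("no endosteal shell found (solid section?)")
  surface_mesh(verts, iso$faces, labels, binary$spacing)
}

#' Coarsen a surface mesh by quadric edge collapse
#'
#' Decimates the mesh to approximately `target_vertices` vertices using
#' quadric-error edge collapse. Collapses never cross the
#' endosteal/periosteal label boundary (the shells are disjoint
#' components), open rim edges are preserved by constraint quadrics, and
#' collapses that would pinch the surface are rejected. The coarsening
#' error (distance from every input vertex to the coarse surface) is
#' measured on every run and attached as attribute `"coarsen_error"`.
#'
#' @param mesh a [surface_mesh()].
#' @param target_vertices requested vertex count (< current count for an
#'   actual reduction; equal count returns the mesh unchanged).
#' @return The coarsened [surface_mesh()].
#' @export
coarsen <- function(mesh, target_vertices) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$vertices)
  if (target_vertices > n) stop("target_vertices exceeds current vertex count")
  if (target_vertices == n) {
    attr(mesh, "coarsen_error") <- list(mean = 0, max = 0)
    return(mesh)
  }
  lab_int <- ifelse(mesh$labels == "endosteal", 1L, 2L)
  res <- cpp_decimate(mesh$vertices, mesh$faces, lab_int,
                      as.integer(target_vertices))
  labels <- ifelse(res$labels == 1L, "endosteal", "periosteal")
  if (length(unique(labels)) < 2 || nrow(res$faces) == 0)
    stop("target too small: a labeled shell was lost during decimation")
  out <- surface_mesh(res$vertices, res$faces, labels, mesh$spacing)
  derr <- cpp_point_mesh_dist(mesh$vertices, out$vertices, out$faces)
  attr(out, "coarsen_error") <- list(mean = mean(derr), max = max(derr))
  out
}

#' Area-weighted outward vertex normals
#'
#' @param mesh a [surface_mesh()].
#' @return N x 3 matrix of unit normals pointing from bone into
#'   background.
#' @export
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  vn <- matrix(0, nrow(v), 3)
  for (c in 1:3) {
    for (k in 1:3) {
      acc <- tapply(fn[, c], f[, k], sum)
      vn[as.integer(names(acc)), c] <- vn[as.integer(names(acc)), c] + acc
    }
  }
  nrm <- sqrt(rowSums(vn^2))
  nrm[nrm == 0] <- 1
  vn / nrm
}

# -------------------------------------------------------------- shape data

#' Flatten a mesh into a shape vector
#'
#' Concatenates vertex coordinates in the canonical reference order as
#' (x1, y1, z1, x2, y2, z2, ...). All samples mapped through the same
#' reference mesh share vertex semantics position by position.
#'
#' @param mesh a [surface_mesh()] (or an N x 3 vertex matrix).
#' @param subject,group,timepoint sample metadata carried as attributes.
#' @return A numeric vector of class `shape_vector`, length 3N.
#' @export
build_shape_vector <- function(mesh, subject = NA_character_,
                               group = NA_character_, timepoint = NA_real_) {
  v <- if (inherits(mesh, "surface_mesh")) mesh$vertices else as.matrix(mesh)
  shape_vector(as.vector(t(v)), subject, group, timepoint)
}

#' @rdname build_shape_vector
#' @param x numeric vector of interleaved coordinates, length 3N.
#' @export
shape_vector <- function(x, subject = NA_character_, group = NA_character_,
                         timepoint = NA_real_) {
  structure(as.double(x), subject = subject, group = group,
            timepoint = timepoint, class = "shape_vector")
}

#' Rebuild a mesh from a shape vector
#'
#' @param x a shape vector (length 3N).
#' @param reference a [surface_mesh()] providing faces and labels.
#' @return A [surface_mesh()] with replaced vertex positions.
#' @export
unflatten_shape_vector <- function(x, reference) {
  stopifnot(inherits(reference, "surface_mesh"),
            length(x) == 3 * nrow(reference$vertices))
  reference$vertices <- matrix(as.double(x), ncol = 3, byrow = TRUE)
  reference
}

#' Assemble the centered shape data matrix
#'
#' Stacks shape vectors into an M x 3N matrix, subtracts the mean shape
#' x0 and keeps metadata aligned with rows.
#'
#' @param shape_vectors list of equal-length shape vectors (M >= 3).
#' @return An object of class `shape_dataset`: list with `$P` (centered
#'   matrix), `$x0` (mean shape) and `$meta` (data frame).
#' @export
assemble_dataset <- function(shape_vectors) {
  m <- length(shape_vectors)
  if (m < 3) stop("need at least 3 shape vectors")
  lens <- vapply(shape_vectors, length, 0L)
  if (length(unique(lens)) != 1) stop("shape vectors have inconsistent lengths")
  X <- do.call(rbind, lapply(shape_vectors, as.double))
  x0 <- colMeans(X)
  P <- sweep(X, 2, x0)
  meta <- data.frame(
    subject = vapply(shape_vectors, function(s) as.character(attr(s, "subject")), ""),
    group = vapply(shape_vectors, function(s) as.character(attr(s, "group")), ""),
    timepoint = vapply(shape_vectors, function(s) as.double(attr(s, "timepoint")), 0.0),
    stringsAsFactors = FALSE)
  structure(list(P = P, x0 = x0, meta = meta), class = "shape_dataset")
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat(sprintf("<shape_dataset> M = %d observations x 3N = %d coordinates\n",
              nrow(x$P), ncol(x$P)))
  invisible(x)
}

# ---------------------------------------------------------------- mesh IO

#' Write a labeled mesh as ASCII PLY
#'
#' Vertices carry an integer `label` property (1 endosteal, 2 periosteal).
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  lab <- ifelse(mesh$labels == "endosteal", 1L, 2L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               "property int label",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                   lab), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh written by [write_ply()]
#'
#' @param path input path.
#' @param spacing voxel size to attach, micrometres.
#' @return A [surface_mesh()].
#' @export
read_ply <- function(path, spacing = 10.4) {
  ln <- readLines(path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", ln, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", ln, value = TRUE)))
  start <- which(ln == "end_header") + 1
  vrows <- do.call(rbind, strsplit(ln[start:(start + nv - 1)], " "))
  verts <- matrix(as.double(vrows[, 1:3]), ncol = 3)
  labels <- ifelse(as.integer(vrows[, 4]) == 1L, "endosteal", "periosteal")
  frows <- do.call(rbind, strsplit(ln[(start + nv):(start + nv + nf - 1)], " "))
  faces <- matrix(as.integer(frows[, 2:4]), ncol = 3) + 1L
  surface_mesh(verts, faces, labels, spacing)
}

#' Write a mesh as ASCII STL with a label sidecar
#'
#' STL stores no per-vertex attributes, so the endosteal/periosteal
#' labels are written to a CSV sidecar (`<path>.labels.csv`).
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid surface", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(sprintf("facet normal %g %g %g", n[i, 1], n[i, 2], n[i, 3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", v[f[i, ], 1], v[f[i, ], 2],
                         v[f[i, ], 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid surface", con)
  write.csv(data.frame(vertex = seq_len(nrow(v)), label = mesh$labels),
            paste0(path, ".labels.csv"), row.names = FALSE)
  invisible(path)
}

#' Write and read a shape dataset as a CSV pair
#'
#' The centered matrix plus mean shape go to `<stem>_matrix.csv` (first
#' row x0, then one row per observation) and the metadata to
#' `<stem>_meta.csv`.
#'
#' @param dataset a `shape_dataset` from [assemble_dataset()].
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_shape_dataset <- function(dataset, stem) {
  stopifnot(inherits(dataset, "shape_dataset"))
  m <- rbind(x0 = dataset$x0, dataset$P)
  utils::write.table(m, paste0(stem, "_matrix.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  write.csv(dataset$meta, paste0(stem, "_meta.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_shape_dataset
#' @export
read_shape_dataset <- function(stem) {
  m <- as.matrix(utils::read.table(paste0(stem, "_matrix.csv"), sep = ","))
  dimnames(m) <- NULL
  meta <- read.csv(paste0(stem, "_meta.csv"), stringsAsFactors = FALSE)
  structure(list(P = m[-1, , drop = FALSE], x0 = m[1, ], meta = meta),
            class = "shape_dataset")
}
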