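#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. When `volumes` is
#' `NULL`, a synthetic phantom population is generated from the
#' population arguments.
#'
#' @param out_dir run directory; created (must not already contain a
#'   completed run - stages never mutate upstream artifacts).
#' @param volumes optional named list of grayscale [volume_image()]s.
#' @param meta data frame (subject, group, timepoint) aligned with
#'   `volumes`; required when `volumes` is given.
#' @param reference id (name in `volumes`) of the reference sample; the
#'   default picks the first baseline observation deterministically.
#' @param spacing voxel size, micrometres.
#' @param ns registration nodal spacing, voxels.
#' @param perimeter_max small-hole perimeter rule, pixels.
#' @param span_limit paired slice-count rule, slices.
#' @param target_vertices coarse reference mesh size.
#' @param alpha significance level for mode categorization.
#' @param seed master seed.
#' @param n_treated,n_control,treat_crest phantom population parameters
#'   used when `volumes` is `NULL` (see [make_image_population()]).
#' @param base_spec [phantom_spec()] for the generated population
#'   (default: the [make_image_population()] default geometry).
#' @param reg registration parameters ([reg_params()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, volumes = NULL, meta = NULL,
                            reference = NULL, spacing = 10.4, ns = 5,
                            perimeter_max = 50, span_limit = 7,
                            target_vertices = 800, alpha = 0.05, seed = 1,
                            n_treated = 2, n_control = 2, treat_crest = 2,
                            base_spec = NULL, reg = reg_params()) {
  if (!is.null(volumes) && is.null(meta))
    stop("meta is required when volumes are supplied")
  structure(list(out_dir = out_dir, volumes = volumes, meta = meta,
                 reference = reference, spacing = spacing, ns = ns,
                 perimeter_max = perimeter_max, span_limit = span_limit,
                 target_vertices = target_vertices, alpha = alpha,
                 seed = seed, n_treated = n_treated, n_control = n_control,
                 treat_crest = treat_crest, base_spec = base_spec, reg = reg),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: phantom generation (when no volumes are given),
#' binarization and geometry correction per subject pair, reference
#' surface extraction and coarsening, deformable registration of the
#' reference onto every sample with mesh mapping, PCA shape
#' decomposition, and mode categorization. All artifacts are written
#' under `config$out_dir` (append-only; the directory must not hold a
#' previous run), together with a manifest capturing the configuration.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `$run_dir`, `$dataset`, `$model`,
#'   `$report` (a `mode_report`), `$reference_mesh` and `$features`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_dir <- config$out_dir
  if (file.exists(file.path(run_dir, "mode_report.csv")))
    stop("run directory already contains a completed run; use a fresh directory")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)

  # Step 0: inputs
  if (is.null(config$volumes)) {
    args <- list(n_treated = config$n_treated, n_control = config$n_control,
                 treat_crest = config$treat_crest, seed = config$seed)
    if (!is.null(config$base_spec)) args$base_spec <- config$base_spec
    pop <- do.call(make_image_population, args)
    volumes <- pop$volumes
    meta <- pop$meta
  } else {
    volumes <- config$volumes
    meta <- config$meta
  }
  if (is.null(rownames(meta)) || !all(rownames(meta) == names(volumes)))
    rownames(meta) <- names(volumes)

  # Step 1-2: binarization + geometry correction per subject pair
  binaries <- list()
  feats <- list()
  for (s in unique(meta$subject)) {
    ids <- rownames(meta)[meta$subject == s]
    ids <- ids[order(meta[ids, "timepoint"])]
    if (length(ids) != 2) stop("subject ", s, " must have exactly two timepoints")
    b1 <- preprocess_volume(volumes[[ids[1]]], perimeter_max = config$perimeter_max)
    b2 <- preprocess_volume(volumes[[ids[2]]], perimeter_max = config$perimeter_max)
    rl <- resolve_large_features(b1, b2, span_limit = config$span_limit)
    binaries[[ids[1]]] <- rl$volume_t1
    binaries[[ids[2]]] <- rl$volume_t2
    if (nrow(rl$features)) feats[[s]] <- cbind(subject = s, rl$features)
    for (id in ids) {
      topo <- check_topology(binaries[[id]])
      if (!attr(topo, "pass"))
        stop("stage preprocess: topology check failed for ", id)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(subject = character(), id = integer(), kind = character(),
               span_t1 = integer(), span_t2 = integer(), action = character())
  write.csv(features, file.path(run_dir, "features.csv"), row.names = FALSE)

  # Step 3: reference surface
  ref_id <- config$reference
  if (is.null(ref_id)) {
    base <- rownames(meta)[meta$timepoint == min(meta$timepoint)]
    ref_id <- base[1]
  }
  if (!ref_id %in% names(binaries))
    stop("stage surface: reference image '", ref_id, "' not found")
  ref_mesh <- coarsen(extract_surfaces(binaries[[ref_id]]),
                      config$target_vertices)
  write_ply(ref_mesh, file.path(run_dir, "reference_mesh.ply"))

  # Step 4: register reference onto every sample; build shape vectors
  shapes <- list()
  for (id in names(binaries)) {
    if (id == ref_id) {
      warped <- ref_mesh
    } else {
      grid <- register_volumes(fixed = binaries[[id]],
                               moved = binaries[[ref_id]],
                               ns = config$ns, params = config$reg)
      write_displacement_grid(grid, file.path(run_dir, paste0("grid_", id, ".csv")))
      warped <- warp_mesh(ref_mesh, grid)
    }
    shapes[[id]] <- build_shape_vector(warped, subject = meta[id, "subject"],
                                       group = meta[id, "group"],
                                       timepoint = meta[id, "timepoint"])
  }

  # PCA + effects
  dataset <- assemble_dataset(shapes)
  model <- fit_pca(dataset)
  report <- mode_report(model, treated = "treated", control = "control",
                        alpha = config$alpha, mesh = ref_mesh,
                        spacing = config$spacing)
  write.csv(as.data.frame(report), file.path(run_dir, "mode_report.csv"),
            row.names = FALSE)
  manifest <- list(
    ns = config$ns, spacing = config$spacing,
    perimeter_max = config$perimeter_max, span_limit = config$span_limit,
    target_vertices = config$target_vertices, alpha = config$alpha,
    seed = config$seed, reference = ref_id,
    n_samples = length(binaries),
    package_version = as.character(utils::packageVersion("tibiassm")))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(
    list(modes = as.list(as.data.frame(report))),
    file.path(run_dir, "mode_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(run_dir = run_dir, dataset = dataset, model = model,
                 report = report, reference_mesh = ref_mesh,
                 features = features))
}
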