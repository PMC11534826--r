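#' Temporal score changes per subject and mode
#'
#' For every subject with scores at both timepoints, the change
#' `delta = a(t2) - a(t1)` is computed for each mode. Subjects missing a
#' timepoint are excluded with a warning.
#'
#' @param model a `shape_pca` model from [fit_pca()] whose `$meta` carries subject, group
#'   and timepoint per row.
#' @param timepoints the two timepoint labels, ordered (t1, t2); default
#'   the two sorted unique values present.
#' @return A data frame of class `score_change_table`: subject, group,
#'   then one `delta_mode<k>` column per mode.
#' @export
score_changes <- function(model, timepoints = NULL) {
  stopifnot(inherits(model, "shape_pca"))
  meta <- model$meta
  if (is.null(timepoints)) timepoints <- sort(unique(meta$timepoint))
  stopifnot(length(timepoints) == 2)
  subjects <- unique(meta$subject)
  k <- ncol(model$scores)
  rows <- list()
  for (s in subjects) {
    i1 <- which(meta$subject == s & meta$timepoint == timepoints[1])
    i2 <- which(meta$subject == s & meta$timepoint == timepoints[2])
    if (length(i1) != 1 || length(i2) != 1) {
      warning("subject ", s, " lacks one of the timepoints; excluded")
      next
    }
    d <- model$scores[i2, ] - model$scores[i1, ]
    rows[[s]] <- data.frame(subject = s, group = meta$group[i1],
                            t(setNames(d, paste0("delta_mode", seq_len(k)))),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("score_change_table", "data.frame")
  out
}

#' Two-sided Wilcoxon signed-rank test of zero median change
#'
#' Exact distribution for small samples without ties (zeros are dropped
#' first, following Wilcoxon's original treatment); tie-corrected normal
#' approximation otherwise. All-zero inputs return p = 1 with a warning.
#'
#' @param deltas numeric vector of within-subject changes (n >= 1).
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(deltas) {
  stopifnot(length(deltas) >= 1)
  nz <- deltas[deltas != 0]
  if (!length(nz)) {
    warning("all changes are exactly zero; p = 1")
    return(1)
  }
  ties <- any(duplicated(abs(nz)))
  exact <- !ties && length(nz) <= 25
  p <- suppressWarnings(
    wilcox.test(nz, mu = 0, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
  min(p, 1)
}

#' Two-sided Mann-Whitney U test between two groups
#'
#' Exact distribution for small tie-free samples, tie-corrected normal
#' approximation otherwise.
#'
#' @param deltas_a,deltas_b numeric vectors (both non-empty).
#' @return Two-sided p-value.
#' @export
mann_whitney_u <- function(deltas_a, deltas_b) {
  if (!length(deltas_a) || !length(deltas_b)) stop("both groups must be non-empty")
  ties <- any(duplicated(c(deltas_a, deltas_b)))
  exact <- !ties && min(length(deltas_a), length(deltas_b)) <= 25
  p <- suppressWarnings(
    wilcox.test(deltas_a, deltas_b, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
  min(p, 1)
}

#' Categorize a mode's temporal change
#'
#' Pure function of the within-group significance pattern at level
#' `alpha`: a change significant only in the treated group is an effect
#' of treatment alone; only in the control group, an effect not due to
#' treatment; in both groups, a partial treatment effect; in neither,
#' no temporal effect. Baseline (t1) between-group significance is
#' reported as a caveat flag, not a category change.
#'
#' @param p_treated,p_control within-group signed-rank p-values on the
#'   temporal score changes.
#' @param p_baseline between-group p-value on the t1 scores.
#' @param alpha significance level (two-sided), default 0.05.
#' @return List with `$category` (one of `"treatment_only"`,
#'   `"not_treatment"`, `"partial"`, `"none"`) and `$baseline_caveat`.
#' @export
classify_mode <- function(p_treated, p_control, p_baseline, alpha = 0.05) {
  stopifnot(all(c(p_treated, p_control, p_baseline) >= 0),
            all(c(p_treated, p_control, p_baseline) <= 1))
  st <- p_treated < alpha
  sc <- p_control < alpha
  category <- if (st && !sc) "treatment_only" else
    if (!st && sc) "not_treatment" else
      if (st && sc) "partial" else "none"
  list(category = category, baseline_caveat = p_baseline < alpha)
}

#' Cohen's d of within-group score changes
#'
#' Ratio of the mean to the sample standard deviation (n - 1 denominator)
#' of the changes. A zero SD yields an infinite-effect sentinel with a
#' warning.
#'
#' @param deltas numeric vector, n >= 2.
#' @return Standardized effect size.
#' @export
cohens_d <- function(deltas) {
  stopifnot(length(deltas) >= 2)
  s <- sd(deltas)
  if (s == 0) {
    warning("zero standard deviation; effect size undefined (Inf sentinel)")
    return(sign(mean(deltas)) * Inf)
  }
  mean(deltas) / s
}

#' Median surface-change field of a mode
#'
#' Scales the mode shape by the group's median temporal score change:
#' `MSC_k = median(a(t2) - a(t1)) * Y_k`, reshaped to one 3-vector per
#' vertex. When a reference mesh is supplied, the magnitude field and the
#' formation/resorption direction (sign of the field against the outward
#' surface normal; positive = bone formation) are also returned. The
#' median of an even count is the midpoint of the two central values.
#'
#' @param model a `shape_pca` model from [fit_pca()].
#' @param k mode index.
#' @param changes a `score_change_table` from [score_changes()].
#' @param group group label to summarize (non-empty in the table).
#' @param mesh optional reference [surface_mesh()] for normals.
#' @param spacing voxel size, micrometres (for mm conversion).
#' @return List with `$field` (N x 3, voxels), `$magnitude_vox`,
#'   `$magnitude_mm`, `$median_delta` and, with a mesh, `$formation`
#'   (signed magnitude along the outward normal).
#' @export
surface_change <- function(model, k, changes, group, mesh = NULL,
                           spacing = 10.4) {
  stopifnot(inherits(model, "shape_pca"),
            inherits(changes, "score_change_table"))
  if (k < 1 || k > length(model$singular)) stop("unknown mode index")
  rows <- changes$group == group
  if (!any(rows)) stop("empty group: ", group)
  med <- median(changes[rows, paste0("delta_mode", k)])
  field <- matrix(med * model$modes[k, ], ncol = 3, byrow = TRUE)
  mag <- sqrt(rowSums(field^2))
  out <- list(field = field, magnitude_vox = mag,
              magnitude_mm = mag * spacing / 1000, median_delta = med)
  if (!is.null(mesh)) {
    nrm <- mesh_vertex_normals(mesh)
    out$formation <- rowSums(field * nrm)
  }
  out
}

#' Full mode report: tests, categories, effect sizes and surface changes
#'
#' Runs the complete score post-processing for every mode: within-group
#' signed-rank tests of the temporal score changes, the between-group
#' Mann-Whitney comparison of the changes, a baseline between-group test
#' on t1 scores, the three-way categorization, Cohen's d per group and
#' the treated-group median surface change magnitude.
#'
#' @param model a `shape_pca` model from [fit_pca()] with subject/group/timepoint metadata.
#' @param treated,control group labels.
#' @param alpha significance level.
#' @param holm apply a Holm correction across modes to the within-group
#'   p-values before categorization (off by default).
#' @param mesh optional reference [surface_mesh()] for formation signs.
#' @param spacing voxel size, micrometres.
#' @return An object of class `mode_report`: data frame with one row per
#'   mode (p-values, category, effect sizes, variance fractions, max
#'   surface change in mm), with the per-mode surface-change fields in
#'   attribute `"fields"` and the score-change table in `"changes"`.
#' @export
mode_report <- function(model, treated = "treated", control = "control",
                        alpha = 0.05, holm = FALSE, mesh = NULL,
                        spacing = 10.4) {
  stopifnot(inherits(model, "shape_pca"))
  changes <- score_changes(model)
  k <- ncol(model$scores)
  tps <- sort(unique(model$meta$timepoint))
  base_rows <- model$meta$timepoint == tps[1]
  ev <- explained_variance(model)
  pt <- pc <- pb <- pbw <- numeric(k)
  for (i in seq_len(k)) {
    dt <- changes[changes$group == treated, paste0("delta_mode", i)]
    dc <- changes[changes$group == control, paste0("delta_mode", i)]
    pt[i] <- wilcoxon_signed_rank(dt)
    pc[i] <- wilcoxon_signed_rank(dc)
    pbw[i] <- mann_whitney_u(dt, dc)
    pb[i] <- mann_whitney_u(model$scores[base_rows & model$meta$group == treated, i],
                            model$scores[base_rows & model$meta$group == control, i])
  }
  pt_adj <- if (holm) stats::p.adjust(pt, "holm") else pt
  pc_adj <- if (holm) stats::p.adjust(pc, "holm") else pc
  fields <- vector("list", k)
  out <- data.frame(mode = seq_len(k), variance_fraction = ev$fraction,
                    p_treated = pt, p_control = pc, p_between = pbw,
                    p_baseline = pb, category = NA_character_,
                    baseline_caveat = NA, d_treated = NA_real_,
                    d_control = NA_real_, msc_max_mm = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    cl <- classify_mode(pt_adj[i], pc_adj[i], pb[i], alpha)
    out$category[i] <- cl$category
    out$baseline_caveat[i] <- cl$baseline_caveat
    dt <- changes[changes$group == treated, paste0("delta_mode", i)]
    dc <- changes[changes$group == control, paste0("delta_mode", i)]
    if (length(dt) >= 2) out$d_treated[i] <- suppressWarnings(cohens_d(dt))
    if (length(dc) >= 2) out$d_control[i] <- suppressWarnings(cohens_d(dc))
    sc <- surface_change(model, i, changes, treated, mesh, spacing)
    fields[[i]] <- sc
    out$msc_max_mm[i] <- max(sc$magnitude_mm)
  }
  attr(out, "fields") <- fields
  attr(out, "changes") <- changes
  class(out) <- c("mode_report", "data.frame")
  out
}
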