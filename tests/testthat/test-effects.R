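fit_population_model <- function(treated_shift, seed, within_sd = 1,
                                 baseline_sd = 4, noise_sd = 0, k = 1) {
  mesh <- tiny_mesh()
  fields <- planted_fields(mesh, k)
  pop <- make_population(mesh, fields,
                         model = score_model(baseline_sd = baseline_sd,
                                             treated_shift = treated_shift,
                                             control_shift = 0,
                                             within_sd = within_sd),
                         noise_sd = noise_sd, seed = seed)
  # a noise-free single-mode population is rank 1 by construction
  m <- suppressWarnings(fit_pca(assemble_dataset(pop$shapes)))
  list(model = m, pop = pop, mesh = mesh)
}

test_that("temporal score changes reproduce planted shifts exactly", {
  mesh <- tiny_mesh()
  fields <- planted_fields(mesh, 1)
  pop <- make_population(mesh, fields,
                         model = score_model(baseline_sd = 4, treated_shift = 7,
                                             control_shift = 0, within_sd = 0),
                         noise_sd = 0, seed = 17)
  m <- suppressWarnings(fit_pca(assemble_dataset(pop$shapes)))
  ch <- score_changes(m)
  d1 <- ch[, "delta_mode1"]
  # noise-free: treated changes all equal +-7, control changes all zero
  expect_equal(abs(d1[ch$group == "treated"]), rep(7, 6), tolerance = 1e-6)
  expect_lt(max(abs(d1[ch$group == "control"])), 1e-6)
  # adding a constant to every shape is absorbed by the mean shape
  shifted <- lapply(pop$shapes, function(s)
    shape_vector(as.double(s) + 3, attr(s, "subject"), attr(s, "group"),
                 attr(s, "timepoint")))
  m2 <- suppressWarnings(fit_pca(assemble_dataset(shifted)))
  ch2 <- score_changes(m2)
  expect_equal(abs(ch2[, "delta_mode1"]), abs(d1), tolerance = 1e-6)
})

test_that("signed-rank p-values match exhaustive enumeration for n <= 8", {
  # worked values
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6)), 2 / 64)
  expect_equal(wilcoxon_signed_rank(c(0.3, 1.2, 0.7, 2.2, 0.1)), 2 / 32)
  # symmetric pattern sits at the null mean
  expect_equal(wilcoxon_signed_rank(c(1.5, -1.5, 2.5, -2.5)), 1)
  # all-zero input
  expect_warning(p0 <- wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  expect_equal(p0, 1)
  # exhaustive oracle comparison across sizes and draws
  set.seed(41)
  for (n in 2:8) {
    for (rep in 1:5) {
      x <- round(rnorm(n, 0.3, 1), 3)
      x <- x[x != 0]
      if (length(x) < 2 || any(duplicated(abs(x)))) next
      expect_equal(wilcoxon_signed_rank(x), oracle_signed_rank_p(x),
                   tolerance = 1e-12,
                   info = paste("n =", n, "rep =", rep))
    }
  }
})

test_that("rank-sum p-values match exhaustive enumeration for small groups", {
  # fully separated groups of 5 and 6
  a <- 1:5; b <- 6:11
  expect_equal(mann_whitney_u(a, b), 2 * factorial(5) * factorial(6) / factorial(11))
  # identical groups
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3)), 1)
  # label swap symmetry
  set.seed(42)
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(mann_whitney_u(x, y), mann_whitney_u(y, x))
  expect_error(mann_whitney_u(numeric(0), y), "non-empty")
  # exhaustive oracle
  for (na in 2:4) for (nb in 2:4) {
    for (rep in 1:4) {
      x <- round(rnorm(na), 3); y <- round(rnorm(nb), 3)
      if (any(duplicated(c(x, y)))) next
      expect_equal(mann_whitney_u(x, y), oracle_rank_sum_p(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("mode categorization is total over the significance patterns", {
  expect_equal(classify_mode(0.03, 0.44, 0.6)$category, "treatment_only")
  expect_equal(classify_mode(0.2, 0.2, 0.9)$category, "none")
  expect_equal(classify_mode(0.01, 0.01, 0.9)$category, "partial")
  expect_equal(classify_mode(0.8, 0.01, 0.9)$category, "not_treatment")
  # baseline flag is a caveat, never a category change
  lo <- classify_mode(0.03, 0.44, 0.01)
  expect_equal(lo$category, "treatment_only")
  expect_true(lo$baseline_caveat)
  # exhaustive over the 8 patterns at alpha = 0.05
  vals <- c(0.01, 0.5)
  seen <- character()
  for (pt in vals) for (pc in vals) for (pb in vals) {
    cl <- classify_mode(pt, pc, pb)
    expect_true(cl$category %in%
                  c("treatment_only", "not_treatment", "partial", "none"))
    seen <- c(seen, cl$category)
  }
  expect_setequal(unique(seen),
                  c("treatment_only", "not_treatment", "partial", "none"))
  expect_error(classify_mode(1.2, 0.5, 0.5), "p")
})

test_that("effect size is the mean over the sample SD", {
  expect_equal(cohens_d(c(2, 4, 6)), 2)
  expect_equal(cohens_d(c(-3, -1, 1, 3)), 0)
  d <- cohens_d(c(0.5, 1.5, 4))
  expect_equal(cohens_d(10 * c(0.5, 1.5, 4)), d)
  expect_warning(dd <- cohens_d(c(2, 2, 2)), "zero")
  expect_equal(dd, Inf)
})

test_that("median surface change scales the mode by the group median", {
  fm <- fit_population_model(treated_shift = 7, seed = 23, within_sd = 0)
  ch <- score_changes(fm$model)
  sc <- surface_change(fm$model, 1, ch, "treated", mesh = fm$mesh)
  # single group, noise-free: field = median delta times the mode row
  med <- median(ch[ch$group == "treated", "delta_mode1"])
  expect_equal(as.vector(t(sc$field)), med * fm$model$modes[1, ],
               tolerance = 1e-9)
  expect_equal(sc$magnitude_mm, sc$magnitude_vox * 10.4 / 1000)
  # control group has zero change
  sc0 <- surface_change(fm$model, 1, ch, "control")
  expect_lt(max(sc0$magnitude_vox), 1e-6)
  # planted-field recovery: direction and amplitude
  planted <- fm$pop$truth$modes[1, ]
  flat <- as.vector(t(sc$field))
  cs <- abs(sum(flat * planted)) / sqrt(sum(flat^2))
  expect_gte(cs, 0.99)
  expect_lt(abs(sqrt(sum(flat^2)) - 7) / 7, 0.05)
  expect_error(surface_change(fm$model, 1, ch, "nogroup"), "empty")
})

test_that("the full report flags the planted mode as a treatment effect", {
  fm <- fit_population_model(treated_shift = 8, seed = 29, within_sd = 1)
  rep <- mode_report(fm$model, mesh = fm$mesh)
  expect_s3_class(rep, "mode_report")
  expect_equal(rep$category[1], "treatment_only")
  expect_lt(rep$p_treated[1], 0.05)
  expect_gt(rep$p_control[1], 0.05)
  expect_gt(abs(rep$d_treated[1]), 2)
  flds <- attr(rep, "fields")
  expect_equal(length(flds), ncol(fm$model$scores))
  expect_equal(length(flds[[1]]$magnitude_mm), nrow(fm$mesh$vertices))
})
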