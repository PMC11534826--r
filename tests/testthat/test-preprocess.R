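test_that("histogram threshold is the mean of the two intensity peaks", {
  # pure two-valued image
  two <- volume_image(array(rep(c(0, 255), each = 500), c(10, 10, 10)))
  expect_equal(compute_threshold(two), 127.5, tolerance = 1e-6)
  # blurred phantom: threshold near the midpoint of the region means
  expect_gt(compute_threshold(tiny_phantom()), 90)
  expect_lt(compute_threshold(tiny_phantom()), 110)
  # unimodal image has no second peak
  flat <- volume_image(array(50, c(8, 8, 8)))
  expect_error(compute_threshold(flat), "threshold")
})

test_that("binarization is a simple level set and idempotent", {
  img <- tiny_phantom()
  hi <- binarize(img, max(img$voxels) + 1)
  expect_true(all(hi$voxels == 0L))
  lo <- binarize(img, min(img$voxels))
  expect_true(all(lo$voxels == 1L))
  b <- binarize(img, 100)
  rebin <- binarize(volume_image(b$voxels * 255, b$spacing), 128)
  expect_identical(rebin$voxels, b$voxels)
})

test_that("small enclosed holes are filled, large and open ones are not", {
  vol <- annulus_stack(n = 64, nz = 3, r_out = 29, r_in = 10)
  v <- vol$voxels
  # 3x3 enclosed hole inside the wall -> filled
  v[44:46, 31:33, 2] <- 0L
  # 20x20 enclosed "hole" cannot fit in the wall; build a separate wide slab
  slab <- array(1L, c(64, 64, 1))
  slab[21:40, 21:40, 1] <- 0L
  bin2 <- binary_volume(slab)
  out2 <- fill_small_holes(bin2)
  rec2 <- out2$features
  expect_equal(nrow(rec2), 1)
  expect_equal(rec2$action, "none")
  expect_equal(rec2$perimeter, 4 * 20 - 4)
  expect_identical(out2$volume$voxels, bin2$voxels)
  # the 3x3 hole
  bin <- binary_volume(v)
  out <- fill_small_holes(bin)
  expect_equal(sum(out$volume$voxels) - sum(v), 9)
  expect_true(any(out$features$kind == "small_hole" & out$features$action == "filled"))
  # background touching the border is never filled
  open_slab <- array(1L, c(20, 20, 1))
  open_slab[1:5, 8:12, 1] <- 0L
  o <- fill_small_holes(binary_volume(open_slab))
  expect_identical(o$volume$voxels, open_slab)
  expect_equal(nrow(o$features), 0)
  expect_error(fill_small_holes(bin, perimeter_max = 0), "positive")
})

test_that("hole filling only adds bone and leaves non-feature voxels alone", {
  vol <- annulus_stack(n = 64, nz = 4, r_out = 29, r_in = 10)
  v <- vol$voxels
  v[44:46, 31:33, 2] <- 0L
  v[20:22, 20:21, 3] <- 0L
  out <- fill_small_holes(binary_volume(v))
  expect_true(all(out$volume$voxels >= v))   # monotone: fill adds bone only
  changed <- which(out$volume$voxels != v)
  expect_equal(length(changed), 9 + 6)       # exactly the recorded footprints
})

test_that("paired slice-count rule deletes short-span trabeculae", {
  # annulus with a chamber next to the cavity, bounded by a 1-px strut,
  # spanning 3 slices at t1 and 5 at t2
  mk <- function(span) {
    vol <- annulus_stack(n = 48, nz = 12, r_out = 21, r_in = 9)
    v <- vol$voxels
    for (k in seq(4, 3 + span)) {
      # pocket carved fully inside the wall; the thin wall band between it
      # and the cavity is the bounding trabecula
      v[35:38, 22:26, k] <- 0L
    }
    binary_volume(v)
  }
  b1 <- mk(3); b2 <- mk(5)
  res <- resolve_large_features(b1, b2, span_limit = 7)
  feat <- res$features[res$features$kind %in%
                         c("trabecula", "trabecular_cavity"), , drop = FALSE]
  expect_true(any(feat$action == "deleted"))
  expect_true(all(res$features$span_t1[res$features$action == "deleted"] < 7 |
                  res$features$span_t2[res$features$action == "deleted"] < 7))
  # deletion removes bone only (monotone) and merges pocket into the cavity
  expect_true(all(res$volume_t1$voxels <= b1$voxels))
  expect_true(attr(check_topology(res$volume_t1), "pass"))
  expect_true(attr(check_topology(res$volume_t2), "pass"))
})

test_that("long-span stable features are classified pores, not auto-deleted", {
  mk <- function(span) {
    vol <- annulus_stack(n = 48, nz = 14, r_out = 21, r_in = 9)
    v <- vol$voxels
    for (k in seq(3, 2 + span)) {
      v[35:38, 22:26, k] <- 0L
    }
    binary_volume(v)
  }
  b1 <- mk(10); b2 <- mk(10)
  res <- resolve_large_features(b1, b2, span_limit = 7)
  f <- res$features[res$features$span_t1 == 10, , drop = FALSE]
  expect_gte(nrow(f), 1)
  expect_equal(unique(f$kind), "cortical_pore")
  expect_equal(unique(f$action), "filled")
  # the bounding strut survives; the pocket was filled with bone instead
  expect_true(all(res$volume_t1$voxels >= b1$voxels))
  # no features at all: volumes pass through untouched
  clean <- annulus_stack()
  res0 <- resolve_large_features(clean, clean)
  expect_identical(res0$volume_t1$voxels, clean$voxels)
  expect_equal(nrow(res0$features), 0)
  expect_error(resolve_large_features(clean, annulus_stack(n = 30)), "misaligned")
})

test_that("topology report demands one wall and one cavity per slice", {
  expect_true(attr(check_topology(tiny_binary()), "pass"))
  # solid cylinder: no cavity
  solid <- annulus_stack(r_in = 0)
  rep <- check_topology(solid)
  expect_false(attr(rep, "pass"))
  expect_true(all(rep$n_cavities == 0))
  # transverse cut: two wall components on the cut slices
  cut <- annulus_stack()
  v <- cut$voxels
  v[, 14:18, 5] <- 0L
  rep2 <- check_topology(binary_volume(v))
  expect_false(rep2$pass[5])
  expect_gte(rep2$n_foreground[5], 2)
})
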