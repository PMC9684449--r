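## A flat 10 x 10 x 5 grey-matter slab with known values exercises the metric
## arithmetic; the solver fixtures exercise the geometric paths.

slab <- function() {
  lab <- array(4L, c(10, 10, 5))
  fake_phantom(lab, h = 1)
}

test_that("ROI mean averages masked voxels inside the radius", {
  ph <- slab()
  e <- array(0.25, dim(ph$label))
  sol <- fake_solution(ph, e)
  roi <- roi_spec(c(5, 5, 2.5), radius_mm = 3)
  expect_equal(roi_mean(sol, roi), 0.25)
  ## scaling the field scales the mean exactly
  sol2 <- fake_solution(ph, 2 * e)
  expect_equal(roi_mean(sol2, roi), 0.5)
  expect_error(roi_spec(c(5, 5, 2.5), radius_mm = 0), "invalid-spec")
  expect_error(roi_mean(sol, roi_spec(c(200, 5, 2), 1)), "empty-mask")
})

test_that("a three-voxel ROI averages its values exactly", {
  ph <- slab()
  ctr <- c(5.3, 5.1, 2.45)   # off-center so voxel distances are distinct
  vox <- tdcsim:::mask_voxels(ph, 4L)
  d <- sqrt(rowSums((tdcsim:::voxel_centers(ph, vox) -
                       rep(ctr, each = length(vox)))^2))
  ord <- order(d)
  radius <- mean(d[ord][3:4])          # captures exactly three voxels
  e <- array(0, dim(ph$label))
  e[vox[ord][1:3]] <- c(0.1, 0.2, 0.6)
  expect_equal(roi_mean(fake_solution(ph, e), roi_spec(ctr, radius)), 0.3)
})

test_that("the 99th-percentile mean matches brute force with fractional weighting", {
  ph <- slab()
  e <- array(0, dim(ph$label))
  n <- length(e)
  ## 1..100-style check on the first 100 voxels is subsumed by random values:
  set.seed(31)
  vals <- runif(n)
  e[] <- vals
  got <- p99_mean(fake_solution(ph, e), mask = 4L, top_frac = 0.01)
  s <- sort(vals, decreasing = TRUE)
  k <- 0.01 * n
  brute <- (sum(s[1:floor(k)]) + (k - floor(k)) * s[floor(k) + 1]) / k
  expect_equal(got, brute, tolerance = 1e-12)
  ## uniform field: the top-1% mean is the field value
  expect_equal(p99_mean(fake_solution(ph, array(0.7, dim(ph$label))), 4L), 0.7)
  ## 100 equal-volume voxels valued 1..100: top 1% is the single best voxel
  ph100 <- fake_phantom(array(4L, c(100, 1, 1)), h = 1)
  e100 <- array(as.numeric(1:100), c(100, 1, 1))
  expect_equal(p99_mean(fake_solution(ph100, e100), 4L), 100)
})

test_that("focality volume thresholds at the requested fraction of the robust peak", {
  ph10 <- fake_phantom(array(4L, c(10, 1, 1)), h = 1)
  e <- array(c(rep(1, 9), 10), c(10, 1, 1))
  got <- focality_volume(fake_solution(ph10, e), mask = 4L,
                         level_fraction = 0.5, peak_percentile = 100)
  expect_equal(got, 1)
  ## uniform field: everything exceeds half the peak
  ph <- slab()
  expect_equal(focality_volume(fake_solution(ph, array(2, dim(ph$label))), 4L),
               500)
  ## brute force on 500 random voxels
  set.seed(77)
  ph500 <- fake_phantom(array(4L, c(500, 1, 1)), h = 2)
  vals <- rexp(500)
  e500 <- array(vals, c(500, 1, 1))
  got <- focality_volume(fake_solution(ph500, e500), 4L, 0.5, 99.9)
  thr <- 0.5 * tdcsim:::weighted_quantile(vals, 0.999)
  expect_equal(got, sum(vals >= thr) * 8)
  ## nonincreasing in the level fraction
  lf <- seq(0.1, 1, by = 0.1)
  vols <- vapply(lf, function(l) focality_volume(fake_solution(ph500, e500),
                                                 4L, l, 99.9), numeric(1))
  expect_true(all(diff(vols) <= 0))
  expect_error(focality_volume(fake_solution(ph500, e500), 4L, 0), "invalid-spec")
})

test_that("focality and peak location are invariant under field scaling", {
  ph <- sphere2()
  r <- solve_montage(ph, sphere2_eeg(), "APPS")
  s2 <- r$sol
  s8 <- scale_to_current(s2, 8)
  expect_equal(focality_volume(s2), focality_volume(s8))
  expect_equal(as.numeric(peak_offset(s2, r$montage)),
               as.numeric(peak_offset(s8, r$montage)))
  expect_equal(p99_mean(s8), 4 * p99_mean(s2), tolerance = 1e-12)
})

test_that("the ROI sits in grey matter under C3 at the analytic shell depth", {
  ph <- sphere2()
  eeg <- sphere2_eeg()
  roi <- locate_roi(ph, eeg, "C3", 10)
  expect_equal(tdcsim:::label_at(ph, matrix(roi$center_mm, 1)), 4L)
  ## center on the C3-to-centroid segment
  p0 <- eeg["C3", ]
  v1 <- roi$center_mm - p0
  v2 <- ph$center_mm - p0
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  expect_gt(cosang, 0.995)   # voxel-center snap allows ~1 mm lateral offset
  ## depth below the scalp within the closed-form shell bounds (skin 6 +
  ## skull 6 + csf 2 = 14 mm to the grey-matter surface, 8 mm of grey matter)
  depth <- sqrt(sum((p0 - roi$center_mm)^2))
  expect_gt(depth, 14 - ph$voxel_size_mm)
  expect_lt(depth, 22 + ph$voxel_size_mm)
  expect_error(locate_roi(ph, eeg, "C3", 0), "invalid-spec")
  expect_error(locate_roi(ph, eeg, "Zz"), "lookup error")
})

test_that("a single hot voxel pulls the peak centroid onto itself", {
  ph <- coarse_head()
  eeg <- coarse_head_eeg()
  m <- build_study_montage("APPS", ph, eeg)
  e <- array(NA_real_, dim(ph$label))
  vox <- tdcsim:::mask_voxels(ph, c(4L, 5L))
  e[vox] <- 0.01
  hot <- vox[123]
  e[hot] <- 5
  sol <- fake_solution(ph, e)
  off <- peak_offset(sol, m, peak_percentile = 99.999)
  hotc <- tdcsim:::voxel_centers(ph, hot)[1, ]
  gmpt <- tdcsim:::project_to_gm(
    ph, tdcsim:::arc_point_frac(ph, m$electrodes[[1]]$center,
                                m$electrodes[[2]]$center, 0.5))
  expect_equal(as.numeric(off), sqrt(sum((hotc - gmpt)^2)), tolerance = 1e-8)
  expect_identical(attr(off, "reference"), "midpoint")
})

test_that("multi-cathode montages report the offset to the central electrode", {
  ph <- sphere2()
  r <- solve_montage(ph, sphere2_eeg(), "HD")
  off <- peak_offset(r$sol, r$montage)
  expect_identical(attr(off, "reference"), "central_electrode")
  expect_lt(as.numeric(off), 25)
})
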