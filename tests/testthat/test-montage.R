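test_that("pad footprints project onto the scalp with near-nominal area", {
  ph <- coarse_sphere()
  eeg <- coarse_sphere_eeg()
  pad <- make_pad(eeg["C3", ], pad_shape("rect", 7, 5), "anode", ph)
  a <- electrode_area(pad, ph)
  expect_gte(a, 35 * 0.95)
  expect_lte(a, 35 * 1.05)
  disc <- make_pad(eeg["C3", ], pad_shape("disc", diameter_cm = 0.5), "anode", ph)
  ad <- electrode_area(disc, ph)
  expect_lt(abs(ad - pi * 0.25^2) / (pi * 0.25^2), 0.05)
  expect_error(make_pad(eeg["C3", ], pad_shape("rect", 0, 5), "anode", ph),
               "invalid-shape")
  expect_error(make_pad(eeg["C3", ], pad_shape("rect", 40, 40), "anode", ph),
               "projection error")
})

test_that("edge distance reduces to center distance minus half-widths in the planar limit", {
  ## a 2 m sphere is locally flat at centimeter scale
  big <- build_phantom(phantom_spec(outer_radius_mm = 2000,
                                    thickness_mm = c(skin = 20, skull = 20,
                                                     csf = 10, gm = 30),
                                    voxel_size_mm = 150))
  big$cache <- new.env(parent = emptyenv())
  top <- c(0, 0, 2000)
  p2 <- tdcsim:::walk_arc(big, top, c(0, 1, 0), 71.2)
  e1 <- make_pad(top, pad_shape("rect", 1, 1), "anode", big,
                 axis_hint = c(1, 0, 0))
  e2 <- make_pad(p2, pad_shape("rect", 1, 1), "cathode", big,
                 axis_hint = c(1, 0, 0))
  m <- montage("planar", list(e1, e2), big)
  expect_lt(abs(edge_to_edge_distance(m, big) - 6.12), 0.01)
})

test_that("the fifteen study configurations build with their defining geometry", {
  ph <- coarse_head()
  eeg <- coarse_head_eeg()
  cat_tbl <- montage_catalog()
  expect_equal(nrow(cat_tbl), 15)
  expect_error(build_study_montage("NOPE", ph, eeg), "lookup error")

  ms <- lapply(unique(cat_tbl$name), build_study_montage, phantom = ph, eeg = eeg)
  names(ms) <- unique(cat_tbl$name)
  for (m in ms) {
    expect_true(check_no_overlap(m, ph))
    expect_equal(m$total_current_mA, 2)
  }
  ## defining anchors
  expect_lt(sqrt(sum((ms$APPS$electrodes[[1]]$center - eeg["CP3", ])^2)), 1e-6)
  expect_lt(sqrt(sum((ms$APPS$electrodes[[2]]$center - eeg["FC3", ])^2)), 1e-6)
  expect_identical(ms$APPS$electrodes[[1]]$polarity, "anode")
  hd_pol <- vapply(ms$HD$electrodes, function(e) e$polarity, character(1))
  expect_equal(sum(hd_pol == "anode"), 1)
  expect_equal(sum(hd_pol == "cathode"), 4)
  expect_true(all(vapply(ms$HD$electrodes,
                         function(e) e$shape$diameter_cm == 0.5, logical(1))))

  ## Round 2: matched edge-to-edge distance across sizes (within 1 mm)
  ed <- vapply(ms[c("APPS_1x1", "APPS_3x3", "APPS_5x5", "APPS_7x5")],
               edge_to_edge_distance, numeric(1), phantom = ph)
  expect_lt(max(ed) - min(ed), 0.1)
  ## Round 3: edge distances at baseline +2/+4/+6/+8 cm (within 2 mm)
  base <- edge_to_edge_distance(ms$APPS, ph)
  for (k in 1:4) {
    got <- edge_to_edge_distance(ms[[paste0("APPS_p", 2 * k)]], ph)
    expect_lt(abs(got - (base + 2 * k)), 0.2)
  }
  ## Round 4: 1x1 pads exactly 2 cm closer than the 1x1 baseline
  expect_lt(abs(edge_to_edge_distance(ms$OPT_APPS, ph) - (ed[["APPS_1x1"]] - 2)),
            0.1)
  shp <- ms$OPT_APPS$electrodes[[1]]$shape
  expect_equal(c(shp$width_cm, shp$height_cm), c(1, 1))
})

test_that("montage construction is deterministic given phantom and EEG map", {
  ph <- coarse_head()
  eeg <- coarse_head_eeg()
  m1 <- build_study_montage("APPS_p4", ph, eeg)
  m2 <- build_study_montage("APPS_p4", ph, eeg)
  expect_equal(m1, m2)
})

test_that("anterior/posterior offsets preserve shape and shift separation", {
  ph <- coarse_head()
  eeg <- coarse_head_eeg()
  m <- build_study_montage("APPS", ph, eeg)
  expect_identical(offset_along_ap(m, 0, ph), m)
  m4 <- offset_along_ap(m, 4, ph)
  d0 <- edge_to_edge_distance(m, ph)
  expect_lt(abs(edge_to_edge_distance(m4, ph) - d0 - 4), 0.2)
  a0 <- electrode_area(m$electrodes[[1]], ph)
  a4 <- electrode_area(m4$electrodes[[1]], ph)
  expect_lt(abs(a4 - a0) / a0, 0.01)
  expect_error(offset_along_ap(m, -2 * d0 - 2, ph), "geometry error")
})

test_that("overlap detection rejects touching or coincident footprints", {
  ph <- coarse_sphere()
  eeg <- coarse_sphere_eeg()
  p1 <- make_pad(eeg["C3", ], pad_shape("rect", 7, 5), "anode", ph)
  p2 <- make_pad(eeg["C3", ], pad_shape("rect", 7, 5), "cathode", ph)
  expect_false(check_no_overlap(structure(list(name = "x", electrodes = list(p1, p2)),
                                          class = "montage"), ph))
  expect_error(montage("x", list(p1, p2), ph), "geometry error")
  expect_error(montage("x", list(p1), ph), "configuration error")
  apps <- build_study_montage("APPS", coarse_head(), coarse_head_eeg())
  expect_true(check_no_overlap(apps, coarse_head()))
})

test_that("montage definitions round-trip through JSON", {
  ph <- coarse_head()
  m <- build_study_montage("HD", ph, coarse_head_eeg())
  path <- tempfile(fileext = ".json")
  write_montage_json(m, path)
  m2 <- read_montage_json(path, ph)
  expect_equal(m2$name, m$name)
  expect_equal(m2$total_current_mA, m$total_current_mA)
  expect_equal(length(m2$electrodes), length(m$electrodes))
  for (i in seq_along(m$electrodes)) {
    expect_equal(m2$electrodes[[i]]$center, m$electrodes[[i]]$center)
    expect_equal(m2$electrodes[[i]]$polarity, m$electrodes[[i]]$polarity)
    expect_equal(m2$electrodes[[i]]$shape, m$electrodes[[i]]$shape)
  }
})
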