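test_that("the conjugate-gradient core solves a 1-d chain to the closed form", {
  ## 12 unknowns in a line, unit conductance, Dirichlet 1 and 0 at the ends:
  ## the potential is linear and the field constant
  N <- 12
  nbr <- matrix(-1L, N, 6)
  cnd <- matrix(0, N, 6)
  g <- 0.7
  nbr[2:N, 1] <- 0:(N - 2); cnd[2:N, 1] <- g       # x- neighbors
  nbr[1:(N - 1), 2] <- 1:(N - 1); cnd[1:(N - 1), 2] <- g
  dg <- rep(2 * g, N)                              # ends connect to Dirichlet
  b <- c(g * 1, rep(0, N - 2), g * 0)
  res <- tdcsim:::cg_stencil(nbr, cnd, dg, b, 1e-12, 1000)
  want <- seq(1 - 1 / (N + 1), 1 / (N + 1), length.out = N)
  expect_equal(res$x, want, tolerance = 1e-10)
  expect_lt(res$relres, 1e-12)
  expect_equal(max(abs(diff(res$x))), 1 / (N + 1), tolerance = 1e-10)
})

test_that("the assembled system is a symmetric M-matrix with conservative rows", {
  ph <- coarse_sphere()
  m <- build_study_montage("APPS", ph, coarse_sphere_eeg())
  sys <- assemble_system(ph, default_conductivities(), m)
  A <- system_matrix(sys)
  expect_lt(max(abs(A - Matrix::t(A))), 1e-15)
  offdiag <- A
  Matrix::diag(offdiag) <- 0
  expect_lte(max(offdiag@x), 0)
  rs <- Matrix::rowSums(A)
  expect_gte(min(rs), -1e-12)
  ## rows without Dirichlet neighbors balance exactly (zero row sum); the
  ## Dirichlet-adjacent conductance is diag minus the unknown-neighbor sum
  dir_g <- sys$diag - rowSums(sys$cnd)
  interior <- dir_g < 1e-15
  expect_lt(max(abs(rs[interior])), 1e-12)
  expect_true(all(rs[!interior] > 0))
})

test_that("montages without both polarities are rejected at assembly", {
  ph <- coarse_sphere()
  eeg <- coarse_sphere_eeg()
  m <- build_study_montage("APPS", ph, eeg)
  m$electrodes[[2]]$polarity <- "anode"
  expect_error(assemble_system(ph, default_conductivities(), m),
               "configuration error")
  expect_error(conduction_grid(ph, c(skin = 0.4)), "configuration error")
  expect_error(conduction_grid(ph, c(skin = -1, skull = 1, csf = 1, gm = 1, wm = 1)),
               "configuration error")
})

test_that("uniform conductivity scaling leaves the unit-drive potential unchanged", {
  ph <- coarse_sphere()
  eeg <- coarse_sphere_eeg()
  m <- build_study_montage("BILAT_M1", ph, eeg)
  sig1 <- c(skin = 0.3, skull = 0.3, csf = 0.3, gm = 0.3, wm = 0.3)
  s1 <- solve_potential(assemble_system(ph, sig1, m))
  s2 <- solve_potential(assemble_system(ph, 2 * sig1, m))
  expect_lt(max(abs(s1$phi - s2$phi), na.rm = TRUE), 1e-6)
  expect_equal(s2$delivered_current_A, 2 * s1$delivered_current_A,
               tolerance = 1e-8)
})

test_that("current scaling is exactly linear and zero current kills the field", {
  ph <- coarse_sphere()
  r <- solve_montage(ph, coarse_sphere_eeg(), "APPS")
  s2 <- r$sol
  s4 <- scale_to_current(s2, 4)
  expect_equal(s4$e_mag[ph$label > 0], 2 * s2$e_mag[ph$label > 0],
               tolerance = 1e-13)
  expect_equal(s4$delivered_current_A, 4e-3, tolerance = 1e-10)
  s0 <- scale_to_current(s2, 0)
  expect_true(all(s0$e_mag[ph$label > 0] == 0))
  expect_equal(s2$delivered_current_A, 2e-3, tolerance = 2e-6) # within 0.1%
})

test_that("swapping polarity negates the field vectors but not the magnitude", {
  ph <- coarse_sphere()
  eeg <- coarse_sphere_eeg()
  m <- build_study_montage("APPS", ph, eeg)
  m_sw <- m
  m_sw$electrodes[[1]]$polarity <- "cathode"
  m_sw$electrodes[[2]]$polarity <- "anode"
  s1 <- solve_potential(assemble_system(ph, default_conductivities(), m))
  s2 <- solve_potential(assemble_system(ph, default_conductivities(), m_sw))
  inh <- ph$label > 0
  scale <- max(s1$e_mag[inh])
  for (ax in c("x", "y", "z")) {
    expect_lt(max(abs(s1$e_vec[[ax]][inh] + s2$e_vec[[ax]][inh])) / scale, 1e-5)
  }
  expect_lt(max(abs(s1$e_mag[inh] - s2$e_mag[inh])) / scale, 1e-5)
})

test_that("a symmetric montage yields a mirror-symmetric field", {
  ph <- sphere2()
  r <- solve_montage(ph, sphere2_eeg(), "BILAT_M1")
  emag <- r$sol$e_mag
  n <- dim(emag)
  flipped <- emag[n[1]:1, , ]
  inh <- ph$label > 0 & !is.na(flipped)
  scale <- max(emag[inh])
  expect_lt(stats::quantile(abs(emag[inh] - flipped[inh]), 0.999) / scale, 0.02)
})

test_that("discrete current is conserved through separating and closed surfaces", {
  ph <- sphere2()
  r <- solve_montage(ph, sphere2_eeg(), "APPS", current_mA = 2)
  sol <- r$sol
  ## plane between the electrodes (anode CP3 is posterior: y < 0 side)
  flux <- current_through_surface(sol, list(type = "plane", axis = "y", mm = 0))
  expect_lt(abs(abs(flux) - 2) / 2, 0.01)
  ## closed box containing no electrode: net flux ~ 0
  box0 <- current_through_surface(sol, list(
    type = "box", lo = c(-30, -30, -80), hi = c(30, 30, -20)))
  expect_lt(abs(box0) / 2, 0.01)
  ## posterior half-box enclosing only the anode (gap midplane at y = 0):
  ## +2 mA net outward
  box1 <- current_through_surface(sol, list(
    type = "box", lo = c(-92, -92, -92), hi = c(92, 0, 92)))
  expect_lt(abs(box1 - 2) / 2, 0.01)
  expect_error(current_through_surface(sol, list(type = "plane", axis = "x",
                                                 mm = 1e4)), "geometry error")
})

test_that("repeated solves are deterministic", {
  ph <- coarse_sphere()
  m <- build_study_montage("LRPS", ph, coarse_sphere_eeg())
  s1 <- solve_potential(assemble_system(ph, default_conductivities(), m))
  s2 <- solve_potential(assemble_system(ph, default_conductivities(), m))
  expect_identical(s1$phi, s2$phi)
})
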