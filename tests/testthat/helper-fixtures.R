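## Shared fixtures, memoized across test files (test_dir runs in one session).

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

## Coarse spherical phantom (4 mm voxels): fast geometry and solver fixture.
coarse_sphere <- function() memo("coarse_sphere", {
  ph <- build_phantom(phantom_spec(voxel_size_mm = 4))
  ph$cache <- new.env(parent = emptyenv())
  ph
})

coarse_sphere_eeg <- function() memo("coarse_sphere_eeg", locate_1010(coarse_sphere()))

## Coarse head-shaped phantom (population axis ratios).
coarse_head <- function() memo("coarse_head", {
  ph <- build_phantom(phantom_spec(voxel_size_mm = 4,
                                   axis_ratios = head_axis_ratios()))
  ph$cache <- new.env(parent = emptyenv())
  ph
})

coarse_head_eeg <- function() memo("coarse_head_eeg", locate_1010(coarse_head()))

## Default-resolution (2 mm) spherical phantom for solver physics tests.
sphere2 <- function() memo("sphere2", {
  ph <- build_phantom(phantom_spec(voxel_size_mm = 2))
  ph$cache <- new.env(parent = emptyenv())
  ph
})

sphere2_eeg <- function() memo("sphere2_eeg", locate_1010(sphere2()))

## Minimal hand-built phantom-like object for metric arithmetic tests.
fake_phantom <- function(label, h = 1, origin = c(0, 0, 0)) {
  list(label = label, voxel_size_mm = h, origin_mm = origin,
       center_mm = origin + dim(label) / 2 * h, id = "fake")
}

## Minimal field-solution-like object carrying just what the metrics need.
fake_solution <- function(phantom, e_mag) {
  structure(list(phi = NULL, e_vec = NULL, e_mag = e_mag,
                 delivered_current_A = 2e-3, montage_name = "fake",
                 phantom = phantom),
            class = "field_solution")
}

## Small end-to-end study shared by the study and io tests.
tiny_study <- function() memo("tiny_study", {
  pop <- sample_population(3, seed = 21, voxel_size_mm = 4)
  cfg <- study_config(voxel_size_mm = 4, n_subjects = 3)
  run_study(pop, montages = c("APPS", "LRPS", "M1_SO"), config = cfg)
})

## Unit-drive solve of one study montage on a fixture phantom, memoized per
## (phantom, montage, current).
solve_montage <- function(ph, eeg, name, current_mA = 2) {
  cg <- memo(paste("cgrid", ph$id), conduction_grid(ph, default_conductivities()))
  memo(paste("solve", ph$id, name, current_mA), {
    m <- build_study_montage(name, ph, eeg, current_mA)
    sys <- assemble_system(ph, cg, m)
    list(montage = m,
         sol = scale_to_current(solve_potential(sys), current_mA))
  })
}
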