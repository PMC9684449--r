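#' @useDynLib tdcsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile pf ptukey sd var setNames
#' @importFrom utils write.csv read.csv modifyList
NULL

#' Tissue label codes
#'
#' Integer labels of the phantom compartments: 0 = outside, 1 = skin,
#' 2 = skull, 3 = cerebrospinal fluid, 4 = grey matter, 5 = white matter.
#'
#' @return Named integer vector.
#' @export
tissue_labels <- function() {
  c(outside = 0L, skin = 1L, skull = 2L, csf = 3L, gm = 4L, wm = 5L)
}

#' Default tissue conductivities
#'
#' Conductivity in S/m per tissue label: skin 0.465, bone (skull) 0.01,
#' cerebrospinal fluid 1.654, grey matter 0.275, white matter 0.126.
#' These are the standard literature values for quasi-static tDCS modeling.
#'
#' @return Named numeric vector (S/m) with elements `skin`, `skull`, `csf`,
#'   `gm`, `wm`.
#' @export
default_conductivities <- function() {
  c(skin = 0.465, skull = 0.01, csf = 1.654, gm = 0.275, wm = 0.126)
}

#' Specify a synthetic head phantom
#'
#' A phantom is five nested ellipsoidal shells (skin, skull, CSF, grey matter,
#' with white matter filling the interior) with an optional smooth low-order
#' surface perturbation shared by all shells. With the default spherical
#' geometry the shell boundary radii are 92 / 86 / 80 / 78 / 70 mm.
#'
#' @param outer_radius_mm Scalp radius (semi-axis scale) in mm.
#' @param thickness_mm Named numeric vector with positive entries `skin`,
#'   `skull`, `csf`, `gm` (mm). White matter fills the remainder.
#' @param axis_ratios Length-3 positive multipliers of the semi-axes (x = left-
#'   right, y = anterior-posterior, z = inferior-superior).
#' @param perturbation_amplitude_mm Amplitude (mm) of a smooth low-order radial
#'   perturbation applied identically to every shell boundary; inter-shell gaps
#'   are therefore preserved exactly.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param seed Integer seed controlling the perturbation shape.
#' @param center_mm Phantom center in RAS mm coordinates.
#' @param inferior_crop_frac Fraction of the inferior semi-axis below which
#'   the modeled head ends (0 = full ellipsoid). Population phantoms use 0.25
#'   so the conduction domain stops below the ears, as a real head does at
#'   the neck.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_radius_mm = 92,
                         thickness_mm = c(skin = 6, skull = 6, csf = 2, gm = 8),
                         axis_ratios = c(1, 1, 1),
                         perturbation_amplitude_mm = 0,
                         voxel_size_mm = 2,
                         seed = 1L,
                         center_mm = c(0, 0, 0),
                         inferior_crop_frac = 0) {
  thickness_mm <- thickness_mm[c("skin", "skull", "csf", "gm")]
  if (anyNA(thickness_mm)) {
    stop("invalid-spec: thickness_mm must name skin, skull, csf and gm")
  }
  if (any(thickness_mm <= 0)) stop("invalid-spec: all thicknesses must be > 0")
  if (voxel_size_mm <= 0) stop("invalid-spec: voxel_size_mm must be > 0")
  if (outer_radius_mm <= sum(thickness_mm)) {
    stop("invalid-spec: outer radius must exceed the summed shell thicknesses")
  }
  if (length(axis_ratios) != 3L || any(axis_ratios <= 0)) {
    stop("invalid-spec: axis_ratios must be three positive numbers")
  }
  if (perturbation_amplitude_mm < 0) {
    stop("invalid-spec: perturbation amplitude must be >= 0")
  }
  inner_min <- outer_radius_mm * min(axis_ratios) - sum(thickness_mm)
  if (perturbation_amplitude_mm >= inner_min) {
    stop("geometry error: perturbation amplitude would collapse the innermost shell")
  }
  if (inferior_crop_frac < 0 || inferior_crop_frac >= 1) {
    stop("invalid-spec: inferior_crop_frac must be in [0, 1)")
  }
  structure(list(
    outer_radius_mm = outer_radius_mm,
    thickness_mm = thickness_mm,
    axis_ratios = as.numeric(axis_ratios),
    perturbation_amplitude_mm = perturbation_amplitude_mm,
    voxel_size_mm = voxel_size_mm,
    seed = as.integer(seed),
    center_mm = as.numeric(center_mm),
    inferior_crop_frac = inferior_crop_frac
  ), class = "phantom_spec")
}

## Shell boundary semi-axes (5 x 3 matrix, outermost first): thickness is
## subtracted equally from every semi-axis so a spherical spec gives radii
## R, R - t_skin, ...
shell_semiaxes <- function(spec) {
  tcum <- c(0, cumsum(spec$thickness_mm))
  ax <- outer(rep(spec$outer_radius_mm, 5), spec$axis_ratios)
  ax <- ax - tcum
  if (any(ax <= 0)) stop("invalid-spec: shells collapse under these thicknesses")
  rownames(ax) <- c("scalp", "skull", "csf", "gm", "wm")
  ax
}

## Seeded low-order angular perturbation field, normalized to max |P| = 1.
## Returns a function of an n x 3 matrix of unit directions.
perturbation_field <- function(spec) {
  if (spec$perturbation_amplitude_mm == 0) {
    return(function(u) rep(0, nrow(u)))
  }
  coef <- with_seed(spec$seed, rnorm(8))
  raw <- function(u) {
    x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
    cbind(x * y, y * z, x * z, x^2 - y^2, 3 * z^2 - 1,
          x * (5 * z^2 - 1), y * (5 * z^2 - 1), x * y * z) %*% coef
  }
  ref <- fibonacci_directions(4000)
  m <- max(abs(raw(ref)))
  if (m < .Machine$double.eps) m <- 1
  function(u) as.numeric(raw(u)) / m
}

## Quasi-uniform unit directions (Fibonacci sphere), used for normalization
## and surface sampling.
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

## Evaluate seeded code with a local RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Boundary radius of shell k (1 = scalp .. 5 = wm) along unit directions u.
shell_radius <- function(spec, u, k, pert = NULL) {
  ax <- shell_semiaxes(spec)
  if (is.null(pert)) pert <- perturbation_field(spec)
  base <- 1 / sqrt((u[, 1] / ax[k, 1])^2 + (u[, 2] / ax[k, 2])^2 +
                     (u[, 3] / ax[k, 3])^2)
  base + spec$perturbation_amplitude_mm * pert(u)
}

#' Build a voxelized head phantom from a specification
#'
#' Labels a regular voxel grid with nested tissue compartments
#' (0 = outside, 1 = skin, 2 = skull, 3 = CSF, 4 = grey matter,
#' 5 = white matter) and records the anatomical landmarks (nasion, inion,
#' left/right preauricular points, vertex) on the scalp surface. Coordinates
#' are RAS in mm, voxel indices are 0-based, and voxel centers sit at
#' `origin + (index + 0.5) * voxel_size`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `head_phantom` with elements `label`
#'   (3-d integer array), `voxel_size_mm`, `origin_mm`, `landmarks`
#'   (5 x 3 matrix), `spec` and a cached surface perturbation field.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  spec <- do.call(phantom_spec, unclass(spec))   # re-validate all invariants
  ax <- shell_semiaxes(spec)
  pert <- perturbation_field(spec)
  h <- spec$voxel_size_mm
  bound <- ax[1, ] + spec$perturbation_amplitude_mm + h
  n <- ceiling(2 * bound / h)
  if (prod(n) > 5e8) {
    stop("invalid-spec: voxel grid would exceed 5e8 voxels; increase voxel_size_mm")
  }
  origin <- spec$center_mm - n / 2 * h
  cx <- origin[1] + (seq_len(n[1]) - 0.5) * h
  cy <- origin[2] + (seq_len(n[2]) - 0.5) * h
  cz <- origin[3] + (seq_len(n[3]) - 0.5) * h

  dx <- rep(cx - spec$center_mm[1], times = n[2] * n[3])
  dy <- rep(rep(cy - spec$center_mm[2], each = n[1]), times = n[3])
  dz <- rep(cz - spec$center_mm[3], each = n[1] * n[2])
  r <- sqrt(dx^2 + dy^2 + dz^2)
  rr <- pmax(r, .Machine$double.eps)
  if (spec$perturbation_amplitude_mm > 0) {
    p <- pert(cbind(dx / rr, dy / rr, dz / rr))
    s <- pmax(r - spec$perturbation_amplitude_mm * p, 0) / rr
  } else {
    s <- r / rr
  }
  sx <- s * dx; sy <- s * dy; sz <- s * dz
  label <- integer(prod(n))
  for (k in 1:5) {
    q <- (sx / ax[k, 1])^2 + (sy / ax[k, 2])^2 + (sz / ax[k, 3])^2
    label <- label + (q <= 1)
  }
  if (spec$inferior_crop_frac > 0) {
    label[dz < -spec$inferior_crop_frac * ax[1, 3]] <- 0L
  }
  dim(label) <- n

  dirs <- rbind(nasion = c(0, 1, 0), inion = c(0, -1, 0),
                lpa = c(-1, 0, 0), rpa = c(1, 0, 0), vertex = c(0, 0, 1))
  lr <- shell_radius(spec, dirs, 1, pert)
  landmarks <- dirs * lr + rep(spec$center_mm, each = 5)

  structure(list(
    label = label,
    voxel_size_mm = h,
    origin_mm = origin,
    center_mm = spec$center_mm,
    landmarks = landmarks,
    spec = spec,
    pert = pert,
    id = phantom_id(spec)
  ), class = "head_phantom")
}

phantom_id <- function(spec) {
  paste0("ph_", paste(signif(c(spec$outer_radius_mm, spec$thickness_mm,
                               spec$axis_ratios, spec$perturbation_amplitude_mm,
                               spec$voxel_size_mm), 8), collapse = "_"),
         "_s", spec$seed)
}

#' @export
print.head_phantom <- function(x, ...) {
  n <- dim(x$label)
  cat(sprintf("<head_phantom> %d x %d x %d voxels @ %.3g mm, %d in-head\n",
              n[1], n[2], n[3], x$voxel_size_mm, sum(x$label > 0)))
  invisible(x)
}

## Scalp radius along unit directions (n x 3).
scalp_radius <- function(phantom, u) {
  shell_radius(phantom$spec, u, 1, phantom$pert)
}

## Voxel-center coordinates for linear indices (1-based) into the label array.
voxel_centers <- function(phantom, idx) {
  n <- dim(phantom$label)
  idx0 <- idx - 1L
  i <- idx0 %% n[1]
  j <- (idx0 %/% n[1]) %% n[2]
  k <- idx0 %/% (n[1] * n[2])
  cbind(phantom$origin_mm[1] + (i + 0.5) * phantom$voxel_size_mm,
        phantom$origin_mm[2] + (j + 0.5) * phantom$voxel_size_mm,
        phantom$origin_mm[3] + (k + 0.5) * phantom$voxel_size_mm)
}

#' Sample a population of phantom specifications
#'
#' Draws `n` independent phantom specifications with parameters uniform over
#' the supplied ranges, emulating subject-to-subject variation in head size,
#' skull thickness and scalp-to-cortex distance.
#'
#' @param n Number of phantoms (>= 0).
#' @param variability Named list of length-2 ranges. Recognized names:
#'   `outer_radius_mm`, `skin_mm`, `skull_mm`, `csf_mm`, `gm_mm`,
#'   `perturbation_amplitude_mm`. Defaults: radius \[84, 90\], skin \[5, 7\],
#'   skull \[4, 9\], CSF \[1.5, 3.5\], GM \[7, 11\], perturbation \[0, 2\] mm.
#' @param seed Integer seed; identical seed reproduces the identical list.
#' @param voxel_size_mm Voxel size given to every spec.
#' @param axis_ratios Semi-axis ratios shared by the population (default
#'   [head_axis_ratios()]).
#' @return List of `phantom_spec` objects.
#' @export
sample_population <- function(n, variability = list(), seed = 1L,
                              voxel_size_mm = 2,
                              axis_ratios = head_axis_ratios()) {
  stopifnot(n >= 0)
  v <- modifyList(list(
    outer_radius_mm = c(84, 90),
    skin_mm = c(5, 7),
    skull_mm = c(4, 9),
    csf_mm = c(1.5, 3.5),
    gm_mm = c(7, 11),
    perturbation_amplitude_mm = c(0, 2)
  ), variability)
  for (nm in names(v)) {
    if (length(v[[nm]]) != 2L || diff(v[[nm]]) < 0) {
      stop("invalid-range: ", nm, " must be a nondecreasing length-2 range")
    }
  }
  if (any(unlist(v[c("skin_mm", "skull_mm", "csf_mm", "gm_mm")]) <= 0)) {
    stop("invalid-range: thickness ranges must be positive")
  }
  max_thick <- v$skin_mm[2] + v$skull_mm[2] + v$csf_mm[2] + v$gm_mm[2]
  if (v$outer_radius_mm[1] * min(axis_ratios) - max_thick -
      v$perturbation_amplitude_mm[2] <= 0) {
    stop("invalid-range: ranges permit non-nesting shells")
  }
  if (n == 0) return(list())
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      c(runif(1, v$outer_radius_mm[1], v$outer_radius_mm[2]),
        runif(1, v$skin_mm[1], v$skin_mm[2]),
        runif(1, v$skull_mm[1], v$skull_mm[2]),
        runif(1, v$csf_mm[1], v$csf_mm[2]),
        runif(1, v$gm_mm[1], v$gm_mm[2]),
        runif(1, v$perturbation_amplitude_mm[1], v$perturbation_amplitude_mm[2]))
    })
  })
  lapply(seq_len(n), function(i) {
    d <- draws[[i]]
    phantom_spec(outer_radius_mm = d[1],
                 thickness_mm = c(skin = d[2], skull = d[3], csf = d[4], gm = d[5]),
                 axis_ratios = axis_ratios,
                 perturbation_amplitude_mm = d[6],
                 voxel_size_mm = voxel_size_mm,
                 seed = as.integer((as.numeric(seed) * 1000 + i) %%
                                     .Machine$integer.max),
                 inferior_crop_frac = 0.25)
  })
}

## Analytic tissue label at arbitrary points (vectorized; same convention as
## the voxelization: boundary ties to the inner compartment, inferior crop
## applied).
tissue_at <- function(phantom, pts) {
  spec <- phantom$spec
  ax <- shell_semiaxes(spec)
  d <- sweep(pts, 2, spec$center_mm)
  r <- sqrt(rowSums(d^2))
  rr <- pmax(r, .Machine$double.eps)
  if (spec$perturbation_amplitude_mm > 0) {
    p <- phantom$pert(d / rr)
    s <- pmax(r - spec$perturbation_amplitude_mm * p, 0) / rr
  } else s <- r / rr
  sx <- s * d[, 1]; sy <- s * d[, 2]; sz <- s * d[, 3]
  lab <- integer(nrow(pts))
  for (k in 1:5) {
    q <- (sx / ax[k, 1])^2 + (sy / ax[k, 2])^2 + (sz / ax[k, 3])^2
    lab <- lab + (q <= 1)
  }
  if (spec$inferior_crop_frac > 0) {
    lab[d[, 3] < -spec$inferior_crop_frac * ax[1, 3]] <- 0L
  }
  lab
}

#' Anthropomorphic head axis ratios
#'
#' Fixed left-right / anterior-posterior / inferior-superior semi-axis ratios
#' used for the phantom population. Chosen so the 10-10 inter-electrode scalp
#' distances of the study montages fall in the ranges reported for adult
#' heads (heads are longer and taller-domed than they are wide; cephalic
#' index about 0.8).
#'
#' @return Numeric length-3 vector `c(0.97, 1.15, 1.55)`.
#' @export
head_axis_ratios <- function() c(0.97, 1.15, 1.55)

#' Analytic shell volumes of an unperturbed phantom
#'
#' Closed-form ellipsoid shell volumes (mm^3) per tissue, used as the oracle
#' for voxel-counted volumes.
#'
#' @param spec A [phantom_spec()].
#' @return Named numeric vector of per-tissue volumes in mm^3.
#' @export
analytic_shell_volumes <- function(spec) {
  ax <- shell_semiaxes(spec)
  v <- 4 / 3 * pi * apply(ax, 1, prod)
  out <- c(skin = v[1] - v[2], skull = v[2] - v[3], csf = v[3] - v[4],
           gm = v[4] - v[5], wm = v[5])
  unname(out)
  setNames(as.numeric(out), c("skin", "skull", "csf", "gm", "wm"))
}
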