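## Finite-volume conduction solver on the labeled voxel grid.
## The quasi-static potential solves div(sigma grad phi) = 0 with Dirichlet
## values on the electrode contact voxels (anode group +1 V, cathode group
## 0 V for the unit drive) and zero normal current on the free scalp. Face
## conductances use the harmonic mean of the adjacent voxel conductivities,
## which yields a symmetric M-matrix system solved by an incomplete-Cholesky
## preconditioned conjugate gradient.

#' Per-voxel face conductances for a phantom
#'
#' Precomputes the conduction grid shared by every montage on the same
#' phantom: harmonic-mean face conductances (S) in the three axis directions.
#'
#' @param phantom A `head_phantom`.
#' @param sigma Named conductivities (S/m), default [default_conductivities()].
#' @param subsample Number of sample points for the sub-voxel series
#'   correction of tissue-boundary faces (0 disables). A face between voxels
#'   of different tissues gets the conductance of the exact series resistance
#'   `integral of dr/sigma` along the segment between the voxel centers,
#'   sampled from the analytic phantom geometry. This removes the
#'   thin-shell thickness-quantization bias of pure center-label sampling
#'   (the voxelized skull is otherwise effectively leakier than the analytic
#'   one).
#' @return Object of class `conduction_grid`.
#' @export
conduction_grid <- function(phantom, sigma = default_conductivities(),
                            subsample = 8L) {
  sigma <- unlist(sigma)
  need <- c("skin", "skull", "csf", "gm", "wm")
  if (!all(need %in% names(sigma))) {
    stop("configuration error: sigma must name ", paste(need, collapse = ", "))
  }
  if (any(sigma[need] <= 0)) stop("configuration error: conductivities must be > 0")
  lab <- phantom$label
  n <- dim(lab)
  sig <- array(c(0, sigma[need])[lab + 1L], n)
  h_m <- phantom$voxel_size_mm / 1000
  harm <- function(a, b) ifelse(a > 0 & b > 0, 2 * a * b / (a + b), 0)
  gx <- array(0, n); gy <- array(0, n); gz <- array(0, n)
  gx[1:(n[1] - 1), , ] <- harm(sig[1:(n[1] - 1), , ], sig[2:n[1], , ]) * h_m
  gy[, 1:(n[2] - 1), ] <- harm(sig[, 1:(n[2] - 1), ], sig[, 2:n[2], ]) * h_m
  gz[, , 1:(n[3] - 1)] <- harm(sig[, , 1:(n[3] - 1)], sig[, , 2:n[3]]) * h_m
  if (subsample > 0L && !is.null(phantom$spec)) {
    ## resistor-network homogenization of faces near tissue interfaces:
    ## 3 x 3 parallel strands over the face area, each strand the exact
    ## series resistance sampled from the analytic geometry along the
    ## segment between the voxel centers. Strands leaving the head are open.
    lut <- c(0, sigma[need])
    h <- phantom$voxel_size_mm
    step <- c(1L, n[1], n[1] * n[2])
    bnd <- array(FALSE, n)
    for (d in 1:3) bnd <- bnd | shift_neq(lab, d) | shift_lower_neq(lab, d)
    glist <- list(gx, gy, gz)
    toff <- as.matrix(expand.grid(c(-h / 3, 0, h / 3), c(-h / 3, 0, h / 3)))
    for (d in 1:3) {
      inhead_hi <- array(FALSE, n)
      if (d == 1) inhead_hi[1:(n[1] - 1), , ] <- lab[2:n[1], , ] > 0L
      if (d == 2) inhead_hi[, 1:(n[2] - 1), ] <- lab[, 2:n[2], ] > 0L
      if (d == 3) inhead_hi[, , 1:(n[3] - 1)] <- lab[, , 2:n[3]] > 0L
      lo <- which(lab > 0L & inhead_hi & (bnd | shift_bnd(bnd, d)))
      if (!length(lo)) next
      c1 <- voxel_centers(phantom, lo)
      dirv <- c(0, 0, 0); dirv[d] <- h
      tax <- setdiff(1:3, d)
      gsum <- numeric(length(lo))
      for (s in seq_len(nrow(toff))) {
        base <- c1
        base[, tax[1]] <- base[, tax[1]] + toff[s, 1]
        base[, tax[2]] <- base[, tax[2]] + toff[s, 2]
        inv_acc <- numeric(length(lo))
        open <- logical(length(lo))
        for (k in seq_len(subsample)) {
          t <- (k - 0.5) / subsample
          p <- base + matrix(dirv * t, length(lo), 3, byrow = TRUE)
          sv <- lut[tissue_at(phantom, p) + 1L]
          open <- open | sv <= 0
          inv_acc <- inv_acc + 1 / pmax(sv, 1e-12)
        }
        ## strand conductance: (A/strands) / (integral dr / sigma)
        gs <- (h_m / nrow(toff)) * subsample / inv_acc
        gs[open] <- 0
        gsum <- gsum + gs
      }
      keep <- gsum > 0
      glist[[d]][lo[keep]] <- gsum[keep]
    }
    gx <- glist[[1]]; gy <- glist[[2]]; gz <- glist[[3]]
  }
  structure(list(gx = gx, gy = gy, gz = gz, dim = n, subsample = subsample,
                 h_mm = phantom$voxel_size_mm, sigma = sigma,
                 phantom_id = phantom$id),
            class = "conduction_grid")
}

## TRUE where the -d neighbor is in-head with a different label.
shift_lower_neq <- function(lab, d) {
  n <- dim(lab)
  out <- array(FALSE, n)
  if (d == 1) {
    out[2:n[1], , ] <- lab[1:(n[1] - 1), , ] > 0L &
      lab[1:(n[1] - 1), , ] != lab[2:n[1], , ]
  } else if (d == 2) {
    out[, 2:n[2], ] <- lab[, 1:(n[2] - 1), ] > 0L &
      lab[, 1:(n[2] - 1), ] != lab[, 2:n[2], ]
  } else {
    out[, , 2:n[3]] <- lab[, , 1:(n[3] - 1)] > 0L &
      lab[, , 1:(n[3] - 1)] != lab[, , 2:n[3]]
  }
  out
}

## TRUE where the +d neighbor (shifted mask) is flagged.
shift_bnd <- function(bnd, d) {
  n <- dim(bnd)
  out <- array(FALSE, n)
  if (d == 1) out[1:(n[1] - 1), , ] <- bnd[2:n[1], , ]
  if (d == 2) out[, 1:(n[2] - 1), ] <- bnd[, 2:n[2], ]
  if (d == 3) out[, , 1:(n[3] - 1)] <- bnd[, , 2:n[3]]
  out
}

## TRUE where the +d neighbor is in-head with a *different* tissue label
## (i.e. the face between them crosses a tissue boundary).
shift_neq <- function(lab, d) {
  n <- dim(lab)
  out <- array(FALSE, n)
  if (d == 1) {
    out[1:(n[1] - 1), , ] <- lab[2:n[1], , ] > 0L &
      lab[2:n[1], , ] != lab[1:(n[1] - 1), , ]
  } else if (d == 2) {
    out[, 1:(n[2] - 1), ] <- lab[, 2:n[2], ] > 0L &
      lab[, 2:n[2], ] != lab[, 1:(n[2] - 1), ]
  } else {
    out[, , 1:(n[3] - 1)] <- lab[, , 2:n[3]] > 0L &
      lab[, , 2:n[3]] != lab[, , 1:(n[3] - 1)]
  }
  out
}

#' Assemble the discrete conduction system for a montage
#'
#' Builds the sparse symmetric positive-definite system for the unit-drive
#' Dirichlet problem: potential fixed to +1 on the anode contact voxels and 0
#' on the cathode group (all cathodes share one terminal value), zero normal
#' current elsewhere.
#'
#' @param phantom A `head_phantom`.
#' @param sigma Conductivities (S/m) or a precomputed [conduction_grid()].
#' @param m A `montage`.
#' @return Object of class `conduction_system`.
#' @export
assemble_system <- function(phantom, sigma, m) {
  cg <- if (inherits(sigma, "conduction_grid")) sigma else
    conduction_grid(phantom, sigma)
  pol <- vapply(m$electrodes, function(e) e$polarity, character(1))
  if (!any(pol == "anode")) stop("configuration error: montage has no anode")
  if (!any(pol == "cathode")) stop("configuration error: montage has no cathode")
  fp <- lapply(m$electrodes, footprint_voxels, phantom = phantom)
  anode <- sort(unique(unlist(fp[pol == "anode"])))
  cath <- sort(unique(unlist(fp[pol == "cathode"])))
  if (length(intersect(anode, cath))) {
    stop("geometry error: anode and cathode contact voxels intersect")
  }
  lab <- phantom$label
  n <- dim(lab)
  nvox <- prod(n)
  inh <- lab > 0L
  unk <- which(inh)
  N <- length(unk)
  map <- rep(-1L, nvox)
  map[unk] <- seq_len(N) - 1L

  ## electrode contact: the terminal potential couples to each contact voxel
  ## through its exposed outer faces, half a cell deep (g = 2 sigma A / h per
  ## face), so the electrode sits on the scalp surface, not at voxel centers
  sig_lut <- c(0, unlist(cg$sigma)[c("skin", "skull", "csf", "gm", "wm")])
  exposed <- exposed_face_count(lab)
  h_m <- cg$h_mm / 1000
  contact_g <- function(vox) 2 * sig_lut[lab[vox] + 1L] * h_m * exposed[vox]
  g_an <- contact_g(anode)
  g_ca <- contact_g(cath)
  if (all(g_an == 0) || all(g_ca == 0)) {
    stop("geometry error: electrode footprint has no exposed scalp faces")
  }

  offs <- c(-1L, 1L, -n[1], n[1], -n[1] * n[2], n[1] * n[2])
  gof <- list(cg$gx, cg$gx, cg$gy, cg$gy, cg$gz, cg$gz)
  nbr <- matrix(-1L, N, 6)
  cnd <- matrix(0, N, 6)
  dg <- numeric(N)
  b <- numeric(N)
  for (k in 1:6) {
    nb <- unk + offs[k]
    g <- if (k %% 2 == 1) gof[[k]][nb] else gof[[k]][unk]
    inh_nb <- inh[nb]
    g[!inh_nb] <- 0
    dg <- dg + g
    nb_unk <- map[nb]
    is_unk <- inh_nb & nb_unk >= 0L
    nbr[is_unk, k] <- nb_unk[is_unk]
    cnd[is_unk, k] <- g[is_unk]
  }
  ## terminal couplings (anode at +1 V, cathode group at 0 V)
  dg[map[anode] + 1L] <- dg[map[anode] + 1L] + g_an
  b[map[anode] + 1L] <- b[map[anode] + 1L] + g_an * 1
  dg[map[cath] + 1L] <- dg[map[cath] + 1L] + g_ca
  structure(list(nbr = nbr, cnd = cnd, diag = dg, b = b,
                 unk = unk, dir_idx = integer(0), dir_val = numeric(0),
                 anode = anode, cathode = cath,
                 g_anode = g_an, g_cathode = g_ca,
                 dim = n, h_mm = cg$h_mm, cgrid = cg,
                 montage = m, phantom = phantom),
            class = "conduction_system")
}

#' Explicit sparse matrix of an assembled system
#'
#' Mainly for inspection and testing on small grids.
#'
#' @param sys A `conduction_system`.
#' @return A symmetric `Matrix::dgCMatrix`.
#' @export
system_matrix <- function(sys) {
  N <- length(sys$diag)
  ii <- rep(seq_len(N), 6)
  jj <- as.integer(sys$nbr) + 1L
  keep <- jj >= 1L
  Matrix::sparseMatrix(
    i = c(seq_len(N), ii[keep]),
    j = c(seq_len(N), jj[keep]),
    x = c(sys$diag, -as.numeric(sys$cnd)[keep]),
    dims = c(N, N))
}

#' Solve the unit-drive conduction problem
#'
#' Conjugate-gradient solve to a relative residual of `tol`, followed by the
#' natural central-difference gradient E = -grad(phi) per voxel.
#'
#' @param sys A `conduction_system` from [assemble_system()].
#' @param tol Relative residual tolerance (default 1e-8).
#' @param maxit Iteration cap.
#' @return Object of class `field_solution` with potential (V), E-field
#'   vector and magnitude (V/m) on the voxel grid, and the delivered current
#'   (A) of the unit drive.
#' @export
solve_potential <- function(sys, tol = 1e-8, maxit = 20000L) {
  res <- cg_stencil(sys$nbr, sys$cnd, sys$diag, sys$b, tol, maxit)
  if (res$relres > tol) {
    stop(sprintf("solver error: no convergence (relative residual %.3g after %d iterations)",
                 res$relres, res$iters))
  }
  n <- sys$dim
  phi <- array(NA_real_, n)
  phi[sys$unk] <- res$x
  ef <- efield_from_potential(phi, sys$phantom$label > 0L, sys$h_mm)
  delivered <- sum(sys$g_anode * (1 - phi[sys$anode]))
  ## keep the geometry/conductance context for flux integrals, but drop the
  ## assembled solver arrays (they are large and no longer needed)
  sys_light <- sys[setdiff(names(sys), c("nbr", "cnd", "diag", "b"))]
  structure(list(
    phi = phi, e_vec = ef$e_vec, e_mag = ef$e_mag,
    delivered_current_A = delivered,
    current_scale = 1,
    solve_residual = res$relres, iters = res$iters,
    montage_name = sys$montage$name, phantom = sys$phantom,
    system = sys_light),
    class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %s on %s: I = %.4g mA, residual %.2g\n",
              x$montage_name, x$phantom$id, x$delivered_current_A * 1000,
              x$solve_residual))
  invisible(x)
}

## Exposed outer faces per voxel (faces whose neighbor lies outside the head).
exposed_face_count <- function(lab) {
  n <- dim(lab)
  cnt <- array(0L, n)
  cnt[2:n[1], , ] <- cnt[2:n[1], , ] + (lab[1:(n[1] - 1), , ] == 0L)
  cnt[1:(n[1] - 1), , ] <- cnt[1:(n[1] - 1), , ] + (lab[2:n[1], , ] == 0L)
  cnt[, 2:n[2], ] <- cnt[, 2:n[2], ] + (lab[, 1:(n[2] - 1), ] == 0L)
  cnt[, 1:(n[2] - 1), ] <- cnt[, 1:(n[2] - 1), ] + (lab[, 2:n[2], ] == 0L)
  cnt[, , 2:n[3]] <- cnt[, , 2:n[3]] + (lab[, , 1:(n[3] - 1)] == 0L)
  cnt[, , 1:(n[3] - 1)] <- cnt[, , 1:(n[3] - 1)] + (lab[, , 2:n[3]] == 0L)
  cnt[lab == 0L] <- 0L
  cnt
}

## E = -grad(phi) by central differences (one-sided at the tissue boundary).
efield_from_potential <- function(phi, inhead, h_mm) {
  n <- dim(phi)
  h_m <- h_mm / 1000
  grad1 <- function(sh) {
    lo <- array(NA_real_, n); hi <- array(NA_real_, n)
    if (sh == 1) {
      hi[1:(n[1] - 1), , ] <- phi[2:n[1], , ]; lo[2:n[1], , ] <- phi[1:(n[1] - 1), , ]
    } else if (sh == 2) {
      hi[, 1:(n[2] - 1), ] <- phi[, 2:n[2], ]; lo[, 2:n[2], ] <- phi[, 1:(n[2] - 1), ]
    } else {
      hi[, , 1:(n[3] - 1)] <- phi[, , 2:n[3]]; lo[, , 2:n[3]] <- phi[, , 1:(n[3] - 1)]
    }
    g <- array(0, n)
    both <- !is.na(hi) & !is.na(lo)
    g[both] <- (hi[both] - lo[both]) / (2 * h_m)
    onlyhi <- !is.na(hi) & is.na(lo) & !is.na(phi)
    g[onlyhi] <- (hi[onlyhi] - phi[onlyhi]) / h_m
    onlylo <- is.na(hi) & !is.na(lo) & !is.na(phi)
    g[onlylo] <- (phi[onlylo] - lo[onlylo]) / h_m
    g[!inhead | is.na(phi)] <- NA_real_
    g
  }
  ex <- -grad1(1); ey <- -grad1(2); ez <- -grad1(3)
  emag <- sqrt(ex^2 + ey^2 + ez^2)
  list(e_vec = list(x = ex, y = ey, z = ez), e_mag = emag)
}

#' Scale a unit-drive solution to a prescribed total current
#'
#' All potentials and fields are multiplied by `target_mA / delivered`; by
#' linearity of the conduction equation this realizes current-controlled
#' stimulation exactly.
#'
#' @param sol A `field_solution`.
#' @param target_mA Target total current in mA.
#' @return Scaled `field_solution`.
#' @export
scale_to_current <- function(sol, target_mA) {
  if (abs(sol$delivered_current_A) < 1e-300) {
    stop("scaling error: zero delivered current")
  }
  k <- (target_mA / 1000) / sol$delivered_current_A
  sol$phi <- sol$phi * k
  sol$e_vec <- lapply(sol$e_vec, function(a) a * k)
  sol$e_mag <- sol$e_mag * abs(k)
  sol$delivered_current_A <- sol$delivered_current_A * k
  sol$current_scale <- sol$current_scale * k
  sol
}

#' Current through a separating plane or closed box
#'
#' Integrates sigma E . n over the requested surface by summing the discrete
#' face currents of the finite-volume solution, in mA.
#'
#' @param sol A `field_solution`.
#' @param surface Either `list(type = "plane", axis = "x"|"y"|"z", mm = value)`
#'   (flux in the +axis direction through the face layer nearest the given
#'   coordinate) or `list(type = "box", lo = c(x,y,z), hi = c(x,y,z))`
#'   (net outward flux).
#' @return Current in mA.
#' @export
current_through_surface <- function(sol, surface) {
  sys <- sol$system
  n <- sys$dim
  phi <- sol$phi
  g <- list(x = sys$cgrid$gx, y = sys$cgrid$gy, z = sys$cgrid$gz)
  ph <- sol$phantom
  face_flux <- function(axis, layer) {
    ## flux through faces between slice `layer` and `layer + 1` (+axis dir)
    d <- match(axis, c("x", "y", "z"))
    if (layer < 1 || layer >= n[d]) stop("geometry error: plane outside grid")
    idx <- switch(axis,
                  x = cbind(layer, rep(1:n[2], n[3]), rep(1:n[3], each = n[2])),
                  y = cbind(rep(1:n[1], n[3]), layer, rep(1:n[3], each = n[1])),
                  z = cbind(rep(1:n[1], n[2]), rep(1:n[2], each = n[1]), layer))
    lin <- idx[, 1] + (idx[, 2] - 1) * n[1] + (idx[, 3] - 1) * n[1] * n[2]
    step <- c(1L, n[1], n[1] * n[2])[d]
    gv <- g[[axis]][lin]
    p1 <- phi[lin]; p2 <- phi[lin + step]
    ok <- gv > 0 & !is.na(p1) & !is.na(p2)
    sum(gv[ok] * (p1[ok] - p2[ok]))
  }
  layer_of <- function(axis, mm) {
    d <- match(axis, c("x", "y", "z"))
    ## face between layers k and k+1 sits at origin + k*h
    round((mm - ph$origin_mm[d]) / ph$voxel_size_mm)
  }
  if (surface$type == "plane") {
    lay <- layer_of(surface$axis, surface$mm)
    return(face_flux(surface$axis, lay) * 1000)
  }
  if (surface$type == "box") {
    lo <- vapply(c("x", "y", "z"), function(a) layer_of(a, surface$lo[match(a, c("x", "y", "z"))]), numeric(1))
    hi <- vapply(c("x", "y", "z"), function(a) layer_of(a, surface$hi[match(a, c("x", "y", "z"))]), numeric(1))
    if (any(hi <= lo)) stop("geometry error: degenerate box")
    out <- 0
    for (d in 1:3) {
      ax <- c("x", "y", "z")[d]
      ## faces on each side of the box, restricted to the box cross-section
      rng <- list(x = (lo[1] + 1):hi[1], y = (lo[2] + 1):hi[2], z = (lo[3] + 1):hi[3])
      other <- setdiff(1:3, d)
      grid2 <- expand.grid(a = rng[[other[1]]], b = rng[[other[2]]])
      lin_at <- function(layer) {
        co <- matrix(0L, nrow(grid2), 3)
        co[, d] <- layer
        co[, other[1]] <- grid2$a
        co[, other[2]] <- grid2$b
        co[, 1] + (co[, 2] - 1L) * n[1] + (co[, 3] - 1L) * n[1] * n[2]
      }
      step <- c(1L, n[1], n[1] * n[2])[d]
      for (side in c("lo", "hi")) {
        layer <- if (side == "lo") lo[d] else hi[d]
        lin <- lin_at(layer)
        gv <- g[[ax]][lin]
        p1 <- phi[lin]; p2 <- phi[lin + step]
        ok <- gv > 0 & !is.na(p1) & !is.na(p2)
        fl <- sum(gv[ok] * (p1[ok] - p2[ok]))   # +axis direction
        out <- out + if (side == "hi") fl else -fl
      }
    }
    return(out * 1000)
  }
  stop("geometry error: unknown surface type")
}
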