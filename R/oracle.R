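## Analytic Legendre-series solution for concentric multi-shell spheres with
## surface current electrodes: the solver's independent ground truth.
##
## In shell k (outermost first) each degree-l harmonic of the potential is
## a_k (r/R_k)^l + b_k (R_{k+1}/r)^{l+1}; coefficients propagate inside-out
## through the continuity of potential and radial current density at each
## interface, and the overall scale per degree comes from the Neumann
## condition sigma_1 dphi/dr = j_l at the outer surface. A point electrode
## injects j_l proportional to (2l+1); a uniform spherical-cap electrode of
## angular radius alpha multiplies each degree by the cap factor
## (P_{l-1}(cos a) - P_{l+1}(cos a)) / ((2l+1)(1 - cos a)).

#' Define a concentric multi-shell sphere model
#'
#' @param radii_mm Strictly decreasing boundary radii (outermost first), mm.
#' @param sigmas Conductivity per shell (S/m), same length as `radii_mm`.
#' @param anode,cathode Unit direction vectors of the two surface electrodes.
#' @param cap_deg Angular radius (degrees) of a uniform-current spherical-cap
#'   electrode; 0 for point electrodes.
#' @param order Series truncation order (default 300).
#' @return Object of class `shell_model`.
#' @export
shell_model <- function(radii_mm, sigmas, anode = c(0, 0, 1),
                        cathode = c(0, 0, -1), cap_deg = 0, order = 300) {
  if (any(diff(radii_mm) >= 0)) stop("radii must be strictly decreasing")
  if (any(sigmas <= 0)) stop("sigmas must be > 0")
  if (length(radii_mm) != length(sigmas)) stop("radii and sigmas must align")
  if (order < 1) stop("series_order must be >= 1")
  structure(list(radii_m = radii_mm / 1000, sigmas = sigmas,
                 anode = anode / sqrt(sum(anode^2)),
                 cathode = cathode / sqrt(sum(cathode^2)),
                 cap_rad = cap_deg * pi / 180, order = as.integer(order)),
            class = "shell_model")
}

## Radial coefficients (alpha_k, beta_k per shell, per degree l = 1..L) and
## the per-degree scale for unit injected current. Returns list of matrices.
shell_coefficients <- function(model) {
  R <- model$radii_m
  sg <- model$sigmas
  K <- length(R)
  L <- model$order
  alpha <- matrix(0, K, L)
  beta <- matrix(0, K, L)
  l <- seq_len(L)
  alpha[K, ] <- 1
  if (K > 1) {
    for (k in (K - 1):1) {
      rho <- R[k + 1]
      q <- (rho / R[k])^l
      w <- if (k + 2 <= K) (R[k + 2] / rho)^(l + 1) else 0
      rhs1 <- alpha[k + 1, ] + beta[k + 1, ] * w
      rhs2 <- sg[k + 1] * (alpha[k + 1, ] * l - beta[k + 1, ] * (l + 1) * w)
      alpha[k, ] <- (rhs2 + sg[k] * (l + 1) * rhs1) / (sg[k] * (2 * l + 1) * q)
      beta[k, ] <- rhs1 - alpha[k, ] * q
    }
  }
  ## Neumann scale: sigma_1 * dphi/dr at R[1] must equal j_l for unit current
  w1 <- if (K >= 2) (R[2] / R[1])^(l + 1) else 0
  dcoef <- sg[1] * (alpha[1, ] * l / R[1] - beta[1, ] * (l + 1) / R[1] * w1)
  jl <- (2 * l + 1) / (4 * pi * R[1]^2)
  if (model$cap_rad > 0) {
    ca <- cos(model$cap_rad)
    P <- legendre_table(c(ca), L + 1)  # P_0 .. P_{L+1}
    Pm1 <- P[1:L]                      # P_{l-1}, l = 1..L
    Pp1 <- P[3:(L + 2)]                # P_{l+1}, l = 1..L
    jl <- jl * (Pm1 - Pp1) / ((2 * l + 1) * (1 - ca))
  }
  scale <- jl / dcoef
  list(alpha = alpha, beta = beta, scale = scale, R = R, K = K, L = L)
}

## P_0..P_Lmax at scalar or vector x; returns matrix length(x) x (Lmax+1).
legendre_table <- function(x, Lmax) {
  n <- length(x)
  P <- matrix(0, n, Lmax + 1)
  P[, 1] <- 1
  if (Lmax >= 1) P[, 2] <- x
  if (Lmax >= 2) for (l in 2:Lmax) {
    P[, l + 1] <- ((2 * l - 1) * x * P[, l] - (l - 1) * P[, l - 1]) / l
  }
  if (n == 1) as.numeric(P) else P
}

## P'_0..P'_Lmax via the derivative recurrence P'_l = P'_{l-2} + (2l-1)P_{l-1}.
legendre_deriv_table <- function(x, Lmax) {
  n <- length(x)
  P <- legendre_table(x, Lmax)
  if (n == 1) P <- matrix(P, 1)
  D <- matrix(0, n, Lmax + 1)
  if (Lmax >= 1) D[, 2] <- 1
  if (Lmax >= 2) for (l in 2:Lmax) {
    D[, l + 1] <- (if (l >= 2) D[, l - 1] else 0) + (2 * l - 1) * P[, l]
  }
  D
}

## Per-point radial profile c_l(r) and derivative c'_l(r): matrices n x L.
shell_radial <- function(co, r) {
  n <- length(r)
  L <- co$L
  l <- seq_len(L)
  region <- findInterval(-r, -co$R) # 1..K: index k with R[k+1] <= r <= R[k]
  region[region < 1] <- 1
  region[region > co$K] <- co$K
  c_l <- matrix(0, n, L)
  d_l <- matrix(0, n, L)
  for (k in sort(unique(region))) {
    sel <- region == k
    rr <- pmax(r[sel], 1e-12)
    u <- outer(rr / co$R[k], l, function(a, b) a^b)
    if (k + 1 <= co$K) {
      v <- outer(co$R[k + 1] / rr, l + 1, function(a, b) a^b)
    } else v <- matrix(0, sum(sel), L)
    al <- matrix(co$alpha[k, ], sum(sel), L, byrow = TRUE)
    be <- matrix(co$beta[k, ], sum(sel), L, byrow = TRUE)
    sc <- matrix(co$scale, sum(sel), L, byrow = TRUE)
    c_l[sel, ] <- sc * (al * u + be * v)
    lmat <- matrix(l, sum(sel), L, byrow = TRUE)
    d_l[sel, ] <- sc * (al * u * lmat / rr - be * v * (lmat + 1) / rr)
  }
  list(c = c_l, d = d_l, region = region)
}

#' Series potential of a multi-shell sphere with two surface electrodes
#'
#' Superposes +I at the anode and -I at the cathode position; gauge is zero
#' mean over the outer surface (the series contains no degree-0 term).
#'
#' @param model A [shell_model()].
#' @param pts_mm Evaluation points, n x 3 matrix in mm (sphere center at the
#'   origin), strictly inside the outer radius.
#' @param I_mA Injected current in mA.
#' @return Potential in volts at each point.
#' @export
shell_potential <- function(model, pts_mm, I_mA = 2, chunk = 20000L) {
  pts <- as.matrix(pts_mm) / 1000
  r <- sqrt(rowSums(pts^2))
  if (any(r > model$radii_m[1] * (1 + 1e-9))) {
    stop("evaluation points must lie inside the outer radius")
  }
  co <- shell_coefficients(model)
  I <- I_mA / 1000
  n <- nrow(pts)
  phi <- numeric(n)
  tail_done <- FALSE
  for (start in seq(1, n, by = chunk)) {
    sel <- start:min(start + chunk - 1, n)
    rad <- shell_radial(co, r[sel])
    u <- pts[sel, , drop = FALSE] / pmax(r[sel], 1e-12)
    acc <- numeric(length(sel))
    for (elec in list(list(dir = model$anode, s = +1),
                      list(dir = model$cathode, s = -1))) {
      x <- pmin(1, pmax(-1, u %*% elec$dir))
      P <- legendre_table(as.numeric(x), co$L)
      if (length(sel) == 1) P <- matrix(P, 1)
      acc <- acc + elec$s * I * rowSums(rad$c * P[, -1, drop = FALSE])
    }
    phi[sel] <- acc
    if (!tail_done) { tail_check(rad$c, co$L); tail_done <- TRUE }
  }
  phi
}

#' Series electric field of a multi-shell sphere
#'
#' Analytic gradient of the series, negated: E = -grad(phi), in V/m.
#'
#' @inheritParams shell_potential
#' @return n x 3 matrix of E-field vectors (V/m).
#' @export
shell_efield <- function(model, pts_mm, I_mA = 2, chunk = 20000L) {
  pts <- as.matrix(pts_mm) / 1000
  r <- sqrt(rowSums(pts^2))
  co <- shell_coefficients(model)
  I <- I_mA / 1000
  n <- nrow(pts)
  E <- matrix(0, n, 3)
  for (start in seq(1, n, by = chunk)) {
    sel <- start:min(start + chunk - 1, n)
    m <- length(sel)
    rad <- shell_radial(co, r[sel])
    rr <- pmax(r[sel], 1e-12)
    u <- pts[sel, , drop = FALSE] / rr
    for (elec in list(list(dir = model$anode, s = +1),
                      list(dir = model$cathode, s = -1))) {
      x <- as.numeric(pmin(1, pmax(-1, u %*% elec$dir)))
      P <- legendre_table(x, co$L); if (m == 1) P <- matrix(P, 1)
      D <- legendre_deriv_table(x, co$L)
      ## grad phi = sum_l [ c'_l P_l rhat + (c_l / r) P'_l (e - x rhat) ]
      radial <- rowSums(rad$d * P[, -1, drop = FALSE])
      tang <- rowSums(rad$c * D[, -1, drop = FALSE]) / rr
      gx <- radial * u + tang * (matrix(elec$dir, m, 3, byrow = TRUE) - x * u)
      E[sel, ] <- E[sel, ] - elec$s * I * gx
    }
  }
  E
}

## Convergence warning when the largest degree still contributes materially.
tail_check <- function(cmat, L, tol = 1e-6) {
  peak <- max(abs(cmat))
  tail <- max(abs(cmat[, L]))
  if (peak > 0 && tail > tol * peak) {
    warning(sprintf("series truncation: last-degree contribution %.2g of peak; increase order",
                    tail / peak))
  }
  invisible(tail)
}

#' Closed-form potential in a homogeneous sphere with two point electrodes
#'
#' Reference solution used to validate the series machinery: potential inside
#' an insulated homogeneous sphere of radius R and conductivity sigma with +I
#' and -I point current electrodes on the surface.
#'
#' @param R_mm Sphere radius (mm).
#' @param sigma Conductivity (S/m).
#' @param anode,cathode Unit electrode directions.
#' @param pts_mm Interior evaluation points (n x 3, mm).
#' @param I_mA Current (mA).
#' @return Potential in volts (zero-mean over the sphere surface gauge).
#' @export
homogeneous_sphere_potential <- function(R_mm, sigma, anode, cathode,
                                         pts_mm, I_mA = 2) {
  R <- R_mm / 1000
  pts <- as.matrix(pts_mm) / 1000
  I <- I_mA / 1000
  r <- sqrt(rowSums(pts^2))
  t <- r / R
  u <- pts / pmax(r, 1e-12)
  term <- function(edir, s) {
    x <- as.numeric(pmin(1, pmax(-1, u %*% (edir / sqrt(sum(edir^2))))))
    d <- sqrt(pmax(1 - 2 * t * x + t^2, 1e-300))
    s * I / (4 * pi * sigma * R) * (2 / d - 2 + log(2 / (1 - t * x + d)))
  }
  term(anode, +1) + term(cathode, -1)
}
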