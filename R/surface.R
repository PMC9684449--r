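## Scalp-surface geometry: great-arc sampling, geodesic arc lengths, tangent
## frames and plane/surface intersection curves. The scalp is star-shaped with
## respect to the phantom center, so any plane through the center intersects
## it in a curve that can be sampled exactly by radial rays; planes not through
## the center (the 10% ring and the FC/CP chains) are handled by a vectorized
## bisection along in-plane rays.

## Spherical linear interpolation between unit vectors u1, u2 at fractions t.
## Antipodal endpoints are routed through a deterministic perpendicular
## waypoint (the connecting plane is otherwise undefined).
slerp <- function(u1, u2, t) {
  d <- sum(u1 * u2)
  d <- max(-1, min(1, d))
  om <- acos(d)
  if (om < 1e-12) {
    return(matrix(rep(u1, length(t)), ncol = 3, byrow = TRUE))
  }
  if (om > pi - 1e-9) {
    ref <- diag(3)[, which.min(abs(u1))]
    mid <- ref - sum(ref * u1) * u1
    mid <- mid / sqrt(sum(mid^2))
    lo <- t <= 0.5
    out <- matrix(0, length(t), 3)
    if (any(lo)) out[lo, ] <- slerp(u1, mid, t[lo] * 2)
    if (any(!lo)) out[!lo, ] <- slerp(mid, u2, (t[!lo] - 0.5) * 2)
    return(out)
  }
  s <- sin(om)
  outer(sin((1 - t) * om) / s, u1) + outer(sin(t * om) / s, u2)
}

## Sample the scalp arc between two surface points p1, p2 in the plane through
## the phantom center. Returns points, cumulative arc length and total length.
scalp_arc <- function(phantom, p1, p2, n = 96) {
  ctr <- phantom$center_mm
  u1 <- p1 - ctr; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- p2 - ctr; u2 <- u2 / sqrt(sum(u2^2))
  t <- seq(0, 1, length.out = n)
  u <- slerp(u1, u2, t)
  u <- u / sqrt(rowSums(u^2))
  r <- scalp_radius(phantom, u)
  pts <- u * r + rep(ctr, each = n)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  list(pts = pts, s = s, total = s[n])
}

## Geodesic (in-plane-arc) distance between two scalp points.
geo_dist <- function(phantom, p1, p2, n = 96) scalp_arc(phantom, p1, p2, n)$total

## Point at a given fraction of the arc length between two scalp points.
arc_point_frac <- function(phantom, p1, p2, frac, n = 192) {
  a <- scalp_arc(phantom, p1, p2, n)
  target <- frac * a$total
  interp_on_path(phantom, a, target)
}

## Interpolate a point on a sampled arc at arc length `target`, re-projected
## onto the scalp.
interp_on_path <- function(phantom, a, target) {
  ctr <- phantom$center_mm
  i <- findInterval(target, a$s, all.inside = TRUE)
  w <- (target - a$s[i]) / max(a$s[i + 1] - a$s[i], 1e-12)
  p <- a$pts[i, ] * (1 - w) + a$pts[i + 1, ] * w
  u <- p - ctr; u <- u / sqrt(sum(u^2))
  as.numeric(ctr + u * scalp_radius(phantom, matrix(u, 1)))
}

## Walk a geodesic distance `dist_mm` from a scalp point along the arc whose
## plane contains the center and the tangent direction `tang`. Signed
## distances walk backwards.
walk_arc <- function(phantom, p, tang, dist_mm, n = 384) {
  ctr <- phantom$center_mm
  u1 <- p - ctr; r1 <- sqrt(sum(u1^2)); u1 <- u1 / r1
  tg <- tang - sum(tang * u1) * u1
  nt <- sqrt(sum(tg^2))
  if (nt < 1e-12) stop("geometry error: degenerate tangent direction")
  tg <- tg / nt
  if (dist_mm < 0) { tg <- -tg; dist_mm <- -dist_mm }
  ang_max <- min(pi * 0.999, 2.5 * dist_mm / r1 + 0.3)
  th <- seq(0, ang_max, length.out = n)
  u <- outer(cos(th), u1) + outer(sin(th), tg)
  u <- u / sqrt(rowSums(u^2))
  r <- scalp_radius(phantom, u)
  pts <- u * r + rep(ctr, each = n)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (dist_mm > s[n]) stop("geometry error: walk leaves the modeled scalp cap")
  interp_on_path(phantom, list(pts = pts, s = s), dist_mm)
}

## Orthonormal tangent frame at a scalp point. `ref` picks the first axis
## direction (projected onto the tangent plane of the radial direction).
tangent_frame <- function(phantom, p, ref = c(1, 0, 0)) {
  ctr <- phantom$center_mm
  u <- p - ctr; u <- u / sqrt(sum(u^2))
  e1 <- ref - sum(ref * u) * u
  n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-9) {
    ref <- c(0, 1, 0)
    e1 <- ref - sum(ref * u) * u
    n1 <- sqrt(sum(e1^2))
  }
  e1 <- e1 / n1
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(normal = u, e1 = e1, e2 = e2)
}

## Closed intersection curve of the scalp with an arbitrary plane
## (point `q0` + normal). Samples `n` azimuths about the projection of the
## phantom center onto the plane; radial distance found by bisection.
## Returns points, cumulative arc length and total (closed) length.
plane_curve <- function(phantom, q0, normal, n = 720) {
  ctr <- phantom$center_mm
  nn <- normal / sqrt(sum(normal^2))
  c0 <- ctr + sum((q0 - ctr) * nn) * nn   # center projected onto the plane
  a1 <- c(1, 0, 0) - nn[1] * nn
  if (sqrt(sum(a1^2)) < 1e-6) a1 <- c(0, 1, 0) - nn[2] * nn
  a1 <- a1 / sqrt(sum(a1^2))
  a2 <- c(nn[2] * a1[3] - nn[3] * a1[2],
          nn[3] * a1[1] - nn[1] * a1[3],
          nn[1] * a1[2] - nn[2] * a1[1])
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  dirs <- outer(cos(th), a1) + outer(sin(th), a2)
  rmax <- max(shell_semiaxes(phantom$spec)[1, ]) +
    phantom$spec$perturbation_amplitude_mm
  lo <- rep(0, n); hi <- rep(2.5 * rmax, n)
  f <- function(s) {
    p <- dirs * s + rep(c0, each = n)
    d <- p - rep(ctr, each = n)
    r <- sqrt(rowSums(d^2))
    u <- d / pmax(r, 1e-12)
    r - scalp_radius(phantom, u)
  }
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    neg <- f(mid) < 0
    lo[neg] <- mid[neg]
    hi[!neg] <- mid[!neg]
  }
  s <- (lo + hi) / 2
  pts <- dirs * s + rep(c0, each = n)
  ptsc <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums((ptsc[-1, , drop = FALSE] - ptsc[-(n + 1), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  list(pts = pts, s = cum[1:n], total = cum[n + 1], closed = TRUE)
}

## Arc-length position (0..total) of the curve point nearest to `p`.
curve_locate <- function(curve, p) {
  d2 <- rowSums((curve$pts - rep(p, each = nrow(curve$pts)))^2)
  curve$s[which.min(d2)]
}

## Point on a closed curve at arc length `s` (wrapped).
curve_at <- function(phantom, curve, s) {
  s <- s %% curve$total
  n <- nrow(curve$pts)
  sall <- c(curve$s, curve$total)
  pall <- rbind(curve$pts, curve$pts[1, ])
  i <- findInterval(s, sall, all.inside = TRUE)
  w <- (s - sall[i]) / max(sall[i + 1] - sall[i], 1e-12)
  p <- pall[i, ] * (1 - w) + pall[i + 1, ] * w
  ctr <- phantom$center_mm
  u <- p - ctr; u <- u / sqrt(sum(u^2))
  as.numeric(ctr + u * scalp_radius(phantom, matrix(u, 1)))
}

## Signed arc length from point a to b along a closed curve, walking in the
## direction that keeps the step shorter than half the circumference when
## `shortest`, else in increasing-s direction.
curve_arclen <- function(curve, sa, sb) {
  d <- (sb - sa) %% curve$total
  if (d > curve$total / 2) d <- d - curve$total
  d
}
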