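## Electrode montages: scalp pads and discs realized as geodesic patches on
## the phantom surface, plus the fifteen study configurations (Rounds 1-4).

#' Create a scalp electrode
#'
#' Realizes a rectangular pad or circular disc as the geodesic projection of
#' the nominal shape onto the scalp, centered at `center`. The patch is
#' defined in geodesic polar coordinates about the center: a surface point at
#' geodesic distance s and tangent bearing beta belongs to a rectangle iff
#' |s cos(beta)| <= width/2 and |s sin(beta)| <= height/2 (disc: s <= d/2).
#'
#' @param center Scalp point (mm).
#' @param shape `pad_shape("rect", width_cm, height_cm)` or
#'   `pad_shape("disc", diameter_cm)`.
#' @param polarity `"anode"` or `"cathode"`.
#' @param phantom A `head_phantom`.
#' @param axis_hint Tangent direction for the rectangle width axis (first
#'   local axis); default left-right.
#' @param label Optional electrode label.
#' @return An object of class `electrode`.
#' @export
make_pad <- function(center, shape, polarity = c("anode", "cathode"),
                     phantom, axis_hint = c(1, 0, 0), label = NULL) {
  polarity <- match.arg(polarity)
  if (shape$type == "rect") {
    if (shape$width_cm <= 0 || shape$height_cm <= 0) {
      stop("invalid-shape: pad dimensions must be positive")
    }
    half_max <- max(shape$width_cm, shape$height_cm) * 10 / 2
  } else {
    if (shape$diameter_cm <= 0) stop("invalid-shape: disc diameter must be positive")
    half_max <- shape$diameter_cm * 10 / 2
  }
  rmin <- min(shell_semiaxes(phantom$spec)[1, ]) -
    phantom$spec$perturbation_amplitude_mm
  if (half_max >= 0.9 * pi * rmin / 2) {
    stop("projection error: shape larger than the available scalp cap")
  }
  fr <- tangent_frame(phantom, center, ref = axis_hint)
  structure(list(center = as.numeric(center), shape = shape,
                 polarity = polarity, e1 = fr$e1, e2 = fr$e2,
                 normal = fr$normal, label = label),
            class = "electrode")
}

#' Electrode shape descriptor
#' @param type `"rect"` or `"disc"`.
#' @param width_cm,height_cm Rectangle dimensions (cm).
#' @param diameter_cm Disc diameter (cm).
#' @return Shape list used by [make_pad()].
#' @export
pad_shape <- function(type = c("rect", "disc"), width_cm = NULL,
                      height_cm = NULL, diameter_cm = NULL) {
  type <- match.arg(type)
  if (type == "rect") list(type = "rect", width_cm = width_cm, height_cm = height_cm)
  else list(type = "disc", diameter_cm = diameter_cm)
}

## Map chart coordinates (u, v) in mm (electrode tangent frame) to scalp
## points by walking geodesic arcs in planes through the phantom center.
chart_to_surface <- function(phantom, el, uv, K = 64) {
  n <- nrow(uv)
  s <- sqrt(uv[, 1]^2 + uv[, 2]^2)
  beta <- atan2(uv[, 2], uv[, 1])
  ctr <- phantom$center_mm
  u0 <- el$normal
  r0 <- sqrt(sum((el$center - ctr)^2))
  out <- matrix(0, n, 3)
  zero <- s < 1e-9
  if (any(zero)) out[zero, ] <- matrix(el$center, sum(zero), 3, byrow = TRUE)
  if (all(zero)) return(out)
  act <- which(!zero)
  dirs <- outer(cos(beta[act]), el$e1) + outer(sin(beta[act]), el$e2)
  thmax <- pmin(pi * 0.999, 2.0 * s[act] / r0 + 0.15)
  tgrid <- seq(0, 1, length.out = K)
  for (ii in seq_along(act)) {
    i <- act[ii]
    th <- tgrid * thmax[ii]
    u <- outer(cos(th), u0) + outer(sin(th), dirs[ii, ])
    u <- u / sqrt(rowSums(u^2))
    r <- scalp_radius(phantom, u)
    pts <- u * r + rep(ctr, each = K)
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-K, , drop = FALSE])^2))
    cum <- c(0, cumsum(seg))
    if (s[i] > cum[K]) stop("projection error: electrode extends past the scalp cap")
    out[i, ] <- interp_on_path(phantom, list(pts = pts, s = cum), s[i])
  }
  out
}

## Geodesic polar coordinates (s mm, bearing beta) of scalp points about an
## electrode center. Arc length approximated as angle x mean radius (exact on
## spheres).
polar_about <- function(phantom, el, pts) {
  ctr <- phantom$center_mm
  d <- pts - rep(ctr, each = nrow(pts))
  r <- sqrt(rowSums(d^2))
  u <- d / pmax(r, 1e-12)
  cg <- pmin(1, pmax(-1, u %*% el$normal))
  gam <- acos(cg)
  r0 <- sqrt(sum((el$center - ctr)^2))
  s <- gam * (r + r0) / 2
  t <- u - outer(as.numeric(cg), el$normal)
  nt <- sqrt(rowSums(t^2))
  t <- t / pmax(nt, 1e-12)
  beta <- atan2(t %*% el$e2, t %*% el$e1)
  cbind(s = as.numeric(s), beta = as.numeric(beta))
}

## Membership of scalp points in an electrode footprint.
in_footprint <- function(el, phantom, pts, tol_mm = 0) {
  pb <- polar_about(phantom, el, pts)
  if (el$shape$type == "disc") {
    pb[, 1] <= el$shape$diameter_cm * 10 / 2 + tol_mm
  } else {
    u <- pb[, 1] * cos(pb[, 2]); v <- pb[, 1] * sin(pb[, 2])
    abs(u) <= el$shape$width_cm * 10 / 2 + tol_mm &
      abs(v) <= el$shape$height_cm * 10 / 2 + tol_mm
  }
}

## Sampled boundary points of an electrode footprint on the scalp.
electrode_boundary <- function(el, phantom, n = 40) {
  if (el$shape$type == "disc") {
    R <- el$shape$diameter_cm * 10 / 2
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    uv <- cbind(R * cos(th), R * sin(th))
  } else {
    w <- el$shape$width_cm * 10 / 2
    h <- el$shape$height_cm * 10 / 2
    m <- ceiling(n / 4)
    t <- seq(-1, 1, length.out = m)
    uv <- rbind(cbind(t * w, -h), cbind(t * w, h), cbind(-w, t * h), cbind(w, t * h))
  }
  chart_to_surface(phantom, el, uv)
}

#' Curved-surface area of an electrode footprint
#'
#' Numerically integrates the surface patch covered by the electrode in its
#' geodesic chart; within a few percent of the nominal flat-shape area on
#' head-scale curvature.
#'
#' @param el An `electrode`.
#' @param phantom A `head_phantom`.
#' @param n Grid resolution per axis.
#' @return Area in cm^2.
#' @export
electrode_area <- function(el, phantom, n = 21) {
  if (el$shape$type == "disc") {
    R <- el$shape$diameter_cm * 10 / 2
    g <- seq(-R, R, length.out = n)
    uv <- as.matrix(expand.grid(u = g, v = g))
    keep <- uv[, 1]^2 + uv[, 2]^2 <= R^2
  } else {
    w <- el$shape$width_cm * 10 / 2
    h <- el$shape$height_cm * 10 / 2
    gu <- seq(-w, w, length.out = n)
    gv <- seq(-h, h, length.out = n)
    uv <- as.matrix(expand.grid(u = gu, v = gv))
    keep <- rep(TRUE, nrow(uv))
  }
  pts <- matrix(NA_real_, nrow(uv), 3)
  pts[keep, ] <- chart_to_surface(phantom, el, uv[keep, , drop = FALSE])
  px <- array(pts[, 1], c(n, n)); py <- array(pts[, 2], c(n, n))
  pz <- array(pts[, 3], c(n, n))
  area <- 0
  for (i in 1:(n - 1)) for (j in 1:(n - 1)) {
    q <- rbind(c(px[i, j], py[i, j], pz[i, j]),
               c(px[i + 1, j], py[i + 1, j], pz[i + 1, j]),
               c(px[i + 1, j + 1], py[i + 1, j + 1], pz[i + 1, j + 1]),
               c(px[i, j + 1], py[i, j + 1], pz[i, j + 1]))
    if (anyNA(q)) next
    a1 <- pracma_cross(q[2, ] - q[1, ], q[3, ] - q[1, ])
    a2 <- pracma_cross(q[3, ] - q[1, ], q[4, ] - q[1, ])
    area <- area + 0.5 * (sqrt(sum(a1^2)) + sqrt(sum(a2^2)))
  }
  ## disc: quads partially outside the rim are skipped; correct by the ratio of
  ## nominal to covered flat area
  if (el$shape$type == "disc") {
    R <- el$shape$diameter_cm * 10 / 2
    du <- (2 * R / (n - 1))^2
    flat <- sum(keep) ; # approximate covered count
    cnt <- 0
    kmat <- array(keep, c(n, n))
    for (i in 1:(n - 1)) for (j in 1:(n - 1)) {
      if (kmat[i, j] && kmat[i + 1, j] && kmat[i + 1, j + 1] && kmat[i, j + 1]) cnt <- cnt + 1
    }
    area <- area * (pi * R^2) / max(cnt * du, 1e-12)
  }
  area / 100  # mm^2 -> cm^2
}

## Linear indices of outer skin-surface voxels (skin voxels with an exposed
## face), cached on the phantom.
scalp_voxels <- function(phantom) {
  if (!is.null(phantom$cache) && !is.null(phantom$cache$scalp_vox)) {
    return(phantom$cache$scalp_vox)
  }
  lab <- phantom$label
  n <- dim(lab)
  inh <- lab > 0L
  exposed <- array(FALSE, n)
  idx <- function(a, d, s) {
    out <- array(FALSE, n)
    if (d == 1) { if (s > 0) out[1:(n[1] - 1), , ] <- !inh[2:n[1], , ] else out[2:n[1], , ] <- !inh[1:(n[1] - 1), , ] }
    if (d == 2) { if (s > 0) out[, 1:(n[2] - 1), ] <- !inh[, 2:n[2], ] else out[, 2:n[2], ] <- !inh[, 1:(n[2] - 1), ] }
    if (d == 3) { if (s > 0) out[, , 1:(n[3] - 1)] <- !inh[, , 2:n[3]] else out[, , 2:n[3]] <- !inh[, , 1:(n[3] - 1)] }
    out
  }
  for (d in 1:3) for (s in c(-1, 1)) exposed <- exposed | idx(inh, d, s)
  v <- which(inh & exposed & lab == 1L)
  if (!is.null(phantom$cache)) phantom$cache$scalp_vox <- v
  v
}

## Dirichlet voxel set of an electrode: surface skin voxels inside the
## footprint (at least the voxel nearest the center).
footprint_voxels <- function(el, phantom) {
  sv <- scalp_voxels(phantom)
  pts <- voxel_centers(phantom, sv)
  member <- in_footprint(el, phantom, pts)
  out <- sv[member]
  if (length(out) == 0) {
    d2 <- rowSums((pts - rep(el$center, each = nrow(pts)))^2)
    out <- sv[which.min(d2)]
  }
  out
}

#' Assemble a montage from electrodes
#'
#' @param name Montage identifier.
#' @param electrodes List of `electrode` objects (>= 1 anode and >= 1 cathode).
#' @param phantom A `head_phantom` (for the overlap check).
#' @param total_current_mA Total injected current (default 2 mA).
#' @param round_tag Modeling round label.
#' @return An object of class `montage`.
#' @export
montage <- function(name, electrodes, phantom, total_current_mA = 2,
                    round_tag = NA_character_) {
  pol <- vapply(electrodes, function(e) e$polarity, character(1))
  if (!any(pol == "anode") || !any(pol == "cathode")) {
    stop("configuration error: montage needs at least one anode and one cathode")
  }
  if (total_current_mA <= 0) stop("configuration error: total current must be > 0")
  m <- structure(list(name = name, electrodes = electrodes,
                      total_current_mA = total_current_mA,
                      round_tag = round_tag),
                 class = "montage")
  if (!check_no_overlap(m, phantom)) {
    stop("geometry error: electrode footprints touch or overlap")
  }
  m
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %s: %d electrodes, %.3g mA (round %s)\n", x$name,
              length(x$electrodes), x$total_current_mA, x$round_tag))
  invisible(x)
}

#' Check that no two electrode footprints touch or overlap
#'
#' @param m A `montage`.
#' @param phantom A `head_phantom`.
#' @param clearance_mm Minimum required boundary-to-boundary clearance.
#' @return `TRUE` iff all pairwise footprints are disjoint with positive
#'   clearance.
#' @export
check_no_overlap <- function(m, phantom, clearance_mm = 0.5) {
  els <- m$electrodes
  if (length(els) < 2) return(TRUE)
  bnds <- lapply(els, electrode_boundary, phantom = phantom)
  for (i in seq_along(els)) for (j in seq_along(els)) {
    if (i >= j) next
    ci <- matrix(els[[i]]$center, 1)
    cj <- matrix(els[[j]]$center, 1)
    if (in_footprint(els[[j]], phantom, ci) ||
        in_footprint(els[[i]], phantom, cj)) return(FALSE)
    if (any(in_footprint(els[[j]], phantom, bnds[[i]])) ||
        any(in_footprint(els[[i]], phantom, bnds[[j]]))) return(FALSE)
    if (boundary_min_dist(phantom, bnds[[i]], bnds[[j]]) < clearance_mm) return(FALSE)
  }
  TRUE
}

## Minimum geodesic distance between two boundary point sets.
boundary_min_dist <- function(phantom, b1, b2, K = 32) {
  ctr <- phantom$center_mm
  n1 <- nrow(b1); n2 <- nrow(b2)
  u1 <- (b1 - rep(ctr, each = n1)); u1 <- u1 / sqrt(rowSums(u1^2))
  u2 <- (b2 - rep(ctr, each = n2)); u2 <- u2 / sqrt(rowSums(u2^2))
  cg <- pmin(1, pmax(-1, u1 %*% t(u2)))
  gam <- acos(cg)
  ## coarse: angle x local mean radius; refine the few nearest pairs exactly
  r1 <- sqrt(rowSums((b1 - rep(ctr, each = n1))^2))
  r2 <- sqrt(rowSums((b2 - rep(ctr, each = n2))^2))
  approx_d <- gam * (outer(r1, rep(1, n2)) + outer(rep(1, n1), r2)) / 2
  ord <- order(approx_d)[seq_len(min(8, length(approx_d)))]
  best <- Inf
  for (o in ord) {
    i <- (o - 1) %% n1 + 1
    j <- (o - 1) %/% n1 + 1
    best <- min(best, geo_dist(phantom, b1[i, ], b2[j, ], n = K))
  }
  best
}

## Geodesic distance (mm) between the footprint boundaries of two electrodes
## measured along the scalp arc through their centers (the tape-measure
## separation between the facing edges; identical to the global
## boundary-to-boundary minimum for discs and in the planar limit).
facing_edge_dist <- function(phantom, ea, eb) {
  arc <- scalp_arc(phantom, ea$center, eb$center, n = 192)
  csep <- arc$total
  reach <- function(el, from_start) {
    ## largest arc length from this electrode's center (toward the partner)
    ## still inside its footprint
    lo <- 0; hi <- csep
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      s <- if (from_start) mid else csep - mid
      p <- interp_on_path(phantom, arc, s)
      if (in_footprint(el, phantom, matrix(p, 1))) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  d <- csep - reach(ea, TRUE) - reach(eb, FALSE)
  if (d <= 0) stop("geometry error: footprints overlap; edge distance undefined")
  d
}

#' Edge-to-edge distance between montage electrodes
#'
#' Geodesic scalp distance between the footprint boundaries measured along
#' the arc through the electrode centers (the scalp tape-measure separation
#' of the facing edges), in cm. For the 4x1 high-definition montage the mean
#' over the four anode-cathode pairs is returned.
#'
#' @param m A `montage`.
#' @param phantom A `head_phantom`.
#' @return Distance in cm.
#' @export
edge_to_edge_distance <- function(m, phantom) {
  if (!check_no_overlap(m, phantom, clearance_mm = 0)) {
    stop("geometry error: footprints overlap; edge distance undefined")
  }
  els <- m$electrodes
  pol <- vapply(els, function(e) e$polarity, character(1))
  an <- which(pol == "anode"); ca <- which(pol == "cathode")
  if (length(els) == 2) {
    return(facing_edge_dist(phantom, els[[1]], els[[2]]) / 10)
  }
  if (length(an) == 1 && length(ca) >= 2) {
    d <- vapply(ca, function(j) facing_edge_dist(phantom, els[[an]], els[[j]]),
                numeric(1))
    return(mean(d) / 10)
  }
  stop("geometry error: edge distance defined for 2-electrode or 4x1 montages")
}

#' Move a two-electrode montage apart (or together) along its connecting arc
#'
#' Each electrode moves `|delta|/2` cm along the scalp geodesic through both
#' centers: away from the partner for positive `delta_cm`, toward it for
#' negative. Electrode shape and current are unchanged; local orientation is
#' re-derived at the new centers.
#'
#' @param m Two-electrode `montage`.
#' @param delta_cm Signed change of separation in cm.
#' @param phantom A `head_phantom`.
#' @return New `montage`.
#' @export
offset_along_ap <- function(m, delta_cm, phantom) {
  if (length(m$electrodes) != 2) {
    stop("geometry error: offset requires a two-electrode montage")
  }
  if (abs(delta_cm) < 1e-12) return(m)
  e1 <- m$electrodes[[1]]; e2 <- m$electrodes[[2]]
  new_els <- list()
  for (k in 1:2) {
    this <- if (k == 1) e1 else e2
    other <- if (k == 1) e2 else e1
    a <- scalp_arc(phantom, this$center, other$center, n = 64)
    tang <- a$pts[2, ] - a$pts[1, ]          # toward the partner
    newc <- walk_arc(phantom, this$center, tang, -delta_cm * 10 / 2)
    ## orientation: height axis along the (new) connecting direction
    a2 <- scalp_arc(phantom, newc, other$center, n = 64)
    conn <- a2$pts[2, ] - a2$pts[1, ]
    fr <- tangent_frame(phantom, newc, ref = conn)
    new_els[[k]] <- make_pad(newc, this$shape, this$polarity, phantom,
                             axis_hint = fr$e2, label = this$label)
  }
  montage(m$name, new_els, phantom, m$total_current_mA, m$round_tag)
}

## Pad whose height (second) axis is aligned with the scalp direction toward
## `toward`; width axis perpendicular.
surround_pad <- function(phantom, center, toward, shape, polarity, label) {
  a <- scalp_arc(phantom, center, toward, n = 64)
  conn <- a$pts[2, ] - a$pts[1, ]
  fr <- tangent_frame(phantom, center, ref = conn)
  make_pad(center, shape, polarity, phantom, axis_hint = fr$e2, label = label)
}

#' The fifteen study montage configurations
#'
#' @return Data frame with columns `name`, `round`, `description`. `APPS`
#'   appears as both the Round 1 anterior-posterior surround montage and the
#'   Round 3 baseline distance, giving 15 configurations over 14 distinct
#'   geometries.
#' @export
montage_catalog <- function() {
  data.frame(
    name = c("BILAT_M1", "M1_SO", "HD", "LRPS", "APPS",
             "APPS_1x1", "APPS_3x3", "APPS_5x5", "APPS_7x5",
             "APPS", "APPS_p2", "APPS_p4", "APPS_p6", "APPS_p8",
             "OPT_APPS"),
    round = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3, 3, 4),
    description = c(
      "7x5 cm pads, anode C3, cathode C4",
      "7x5 cm pads, anode C3, cathode Fp2",
      "0.5 cm discs, anode C3, cathodes FC3/C1/CP3/C5",
      "7x5 cm pads, anode C1, cathode C5",
      "7x5 cm pads, anode CP3, cathode FC3",
      "1x1 cm pads at CP3-FC3",
      "3x3 cm pads, matched edge distance to 1x1 at CP3-FC3",
      "5x5 cm pads, matched edge distance to 1x1 at CP3-FC3",
      "7x5 cm pads, matched edge distance to 1x1 at CP3-FC3",
      "Round 3 baseline: 7x5 cm pads at CP3-FC3",
      "7x5 cm pads, CP3-FC3 + 2 cm apart",
      "7x5 cm pads, CP3-FC3 + 4 cm apart",
      "7x5 cm pads, CP3-FC3 + 6 cm apart",
      "7x5 cm pads, CP3-FC3 + 8 cm apart",
      "1x1 cm pads on the CP3-FC3 axis, 2 cm closer than the 1x1 baseline"),
    stringsAsFactors = FALSE)
}

#' Edge-to-edge distance after a Round 3 anterior/posterior offset
#'
#' In the planar limit, moving electrodes along the connecting geodesic
#' changes the edge-to-edge separation by exactly the offset.
#' @param baseline_cm Baseline edge distance (cm).
#' @param offset_cm Applied offset (cm).
#' @return Edge distance in cm.
#' @export
round3_edge_cm <- function(baseline_cm, offset_cm) baseline_cm + offset_cm

#' Edge-to-edge distance of the optimized surround montage
#'
#' The optimized configuration places the 1x1 cm electrodes 2 cm closer than
#' the 1x1 baseline at CP3-FC3.
#' @param baseline_1x1_cm Edge distance of the 1x1 pads at CP3-FC3 (cm).
#' @return Edge distance in cm.
#' @export
opt_apps_edge_cm <- function(baseline_1x1_cm) baseline_1x1_cm - 2

#' Build one of the fifteen study montages
#'
#' Constructs the named configuration on a phantom given its 10-10 map:
#' conventional bilateral M1 (C3-C4) and M1-SO (C3-Fp2) 7x5 cm pads, the 4x1
#' high-definition montage (0.5 cm discs, anode C3, cathodes FC3/C1/CP3/C5),
#' left-right (C1-C5) and anterior-posterior (CP3-FC3) pad surrounds, the
#' Round 2 size family at matched edge-to-edge distance, the Round 3 distance
#' family (+2 .. +8 cm), and the Round 4 optimized 1x1 cm surround placed 2 cm
#' closer than the 1x1 baseline.
#'
#' @param name Montage identifier (see [montage_catalog()]).
#' @param phantom A `head_phantom`.
#' @param eeg An `eeg_map` from [locate_1010()].
#' @param total_current_mA Total current, default 2.
#' @return A `montage`.
#' @export
build_study_montage <- function(name, phantom, eeg, total_current_mA = 2) {
  cat_tbl <- montage_catalog()
  if (!name %in% cat_tbl$name) stop("lookup error: unknown montage '", name, "'")
  need <- function(labels) {
    miss <- setdiff(labels, rownames(eeg))
    if (length(miss)) stop("lookup error: EEG map lacks ", paste(miss, collapse = ", "))
  }
  p75 <- pad_shape("rect", 7, 5)
  rt <- as.character(cat_tbl$round[match(name, cat_tbl$name)])

  if (name == "BILAT_M1") {
    need(c("C3", "C4"))
    els <- list(make_pad(eeg["C3", ], p75, "anode", phantom, label = "C3"),
                make_pad(eeg["C4", ], p75, "cathode", phantom, label = "C4"))
    return(montage(name, els, phantom, total_current_mA, rt))
  }
  if (name == "M1_SO") {
    need(c("C3", "Fp2"))
    els <- list(make_pad(eeg["C3", ], p75, "anode", phantom, label = "C3"),
                make_pad(eeg["Fp2", ], p75, "cathode", phantom, label = "Fp2"))
    return(montage(name, els, phantom, total_current_mA, rt))
  }
  if (name == "HD") {
    need(c("C3", "FC3", "C1", "CP3", "C5"))
    disc <- pad_shape("disc", diameter_cm = 0.5)
    els <- c(list(make_pad(eeg["C3", ], disc, "anode", phantom, label = "C3")),
             lapply(c("FC3", "C1", "CP3", "C5"), function(l) {
               make_pad(eeg[l, ], disc, "cathode", phantom, label = l)
             }))
    return(montage(name, els, phantom, total_current_mA, rt))
  }
  if (name == "LRPS") {
    need(c("C1", "C5"))
    els <- list(surround_pad(phantom, eeg["C1", ], eeg["C5", ], p75, "anode", "C1"),
                surround_pad(phantom, eeg["C5", ], eeg["C1", ], p75, "cathode", "C5"))
    return(montage(name, els, phantom, total_current_mA, rt))
  }
  need(c("CP3", "FC3"))
  cp3 <- eeg["CP3", ]; fc3 <- eeg["FC3", ]
  if (name == "APPS") {
    els <- list(surround_pad(phantom, cp3, fc3, p75, "anode", "CP3"),
                surround_pad(phantom, fc3, cp3, p75, "cathode", "FC3"))
    return(montage(name, els, phantom, total_current_mA, rt))
  }
  if (name == "APPS_1x1") {
    s11 <- pad_shape("rect", 1, 1)
    els <- list(surround_pad(phantom, cp3, fc3, s11, "anode", "CP3"),
                surround_pad(phantom, fc3, cp3, s11, "cathode", "FC3"))
    return(montage(name, els, phantom, total_current_mA, rt))
  }
  d0 <- geo_dist(phantom, cp3, fc3)            # CP3-FC3 center arc, mm
  if (name %in% c("APPS_3x3", "APPS_5x5", "APPS_7x5")) {
    shp <- switch(name,
                  APPS_3x3 = pad_shape("rect", 3, 3),
                  APPS_5x5 = pad_shape("rect", 5, 5),
                  APPS_7x5 = pad_shape("rect", 7, 5))
    target_edge <- d0 - 10                      # 1x1 edge distance at CP3-FC3
    half_ap <- shp$height_cm * 10 / 2
    csep <- target_edge + 2 * half_ap
    mid <- arc_point_frac(phantom, cp3, fc3, 0.5)
    a <- scalp_arc(phantom, mid, cp3, n = 64)
    tang <- a$pts[2, ] - a$pts[1, ]
    c_an <- walk_arc(phantom, mid, tang, csep / 2)
    c_ca <- walk_arc(phantom, mid, tang, -csep / 2)
    els <- list(surround_pad(phantom, c_an, c_ca, shp, "anode", "CP3ward"),
                surround_pad(phantom, c_ca, c_an, shp, "cathode", "FC3ward"))
    return(montage(name, els, phantom, total_current_mA, rt))
  }
  if (name %in% c("APPS_p2", "APPS_p4", "APPS_p6", "APPS_p8")) {
    delta <- c(APPS_p2 = 2, APPS_p4 = 4, APPS_p6 = 6, APPS_p8 = 8)[[name]]
    base <- build_study_montage("APPS", phantom, eeg, total_current_mA)
    m <- offset_along_ap(base, delta, phantom)
    m$name <- name
    m$round_tag <- rt
    return(m)
  }
  if (name == "OPT_APPS") {
    s11 <- pad_shape("rect", 1, 1)
    csep <- d0 - 20                             # edge = (d0 - 1 cm) - 2 cm
    if (csep <= 10) stop("geometry error: optimized separation collapses")
    mid <- arc_point_frac(phantom, cp3, fc3, 0.5)
    a <- scalp_arc(phantom, mid, cp3, n = 64)
    tang <- a$pts[2, ] - a$pts[1, ]
    c_an <- walk_arc(phantom, mid, tang, csep / 2)
    c_ca <- walk_arc(phantom, mid, tang, -csep / 2)
    els <- list(surround_pad(phantom, c_an, c_ca, s11, "anode", "CP3ward"),
                surround_pad(phantom, c_ca, c_an, s11, "cathode", "FC3ward"))
    return(montage(name, els, phantom, total_current_mA, rt))
  }
  stop("lookup error: unhandled montage '", name, "'")
}
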