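#' Locate 10-10 EEG coordinates on a phantom scalp
#'
#' Proportional nested-arc construction of the 10-10 electrode system on the
#' discretized scalp. The midline positions subdivide the nasion-inion arc in
#' 10% steps (Cz at 50%); the central row subdivides the preauricular arc
#' through Cz (C3 at 30% of the full arc from the left preauricular point);
#' the FC and CP rows are placed on the scalp curves through FT7-FCz-FT8 and
#' TP7-CPz-TP8 at the standard proportional subdivisions; Fp1/Fp2 sit on the
#' 10% circumferential ring, 5% of the ring circumference lateral to Fpz.
#'
#' @param phantom A [build_phantom()] result with all five landmarks.
#' @return An `eeg_map`: numeric matrix (rows = labels, columns x, y, z in mm)
#'   of scalp points.
#' @export
locate_1010 <- function(phantom) {
  lm <- phantom$landmarks
  req <- c("nasion", "inion", "lpa", "rpa", "vertex")
  if (!all(req %in% rownames(lm))) stop("landmark error: missing landmarks")
  d <- as.matrix(stats::dist(lm[req, ]))
  if (any(d[upper.tri(d)] < 1e-6)) {
    stop("landmark error: coincident landmarks")
  }

  pts <- list()

  ## --- midline sagittal arc: nasion -> vertex -> inion, fractions of total
  mid_labels <- c(Fpz = 0.1, AFz = 0.2, Fz = 0.3, FCz = 0.4, Cz = 0.5,
                  CPz = 0.6, Pz = 0.7, POz = 0.8, Oz = 0.9)
  a1 <- scalp_arc(phantom, lm["nasion", ], lm["vertex", ], n = 256)
  a2 <- scalp_arc(phantom, lm["vertex", ], lm["inion", ], n = 256)
  tot <- a1$total + a2$total
  for (nm in names(mid_labels)) {
    s <- mid_labels[[nm]] * tot
    pts[[nm]] <- if (s <= a1$total) interp_on_path(phantom, a1, s) else
      interp_on_path(phantom, a2, s - a1$total)
  }

  ## --- central coronal row: LPA -> Cz -> RPA; fractions measured per half so
  ## Cz is the shared 50% point by construction
  cl <- scalp_arc(phantom, lm["lpa", ], pts$Cz, n = 256)
  cr <- scalp_arc(phantom, pts$Cz, lm["rpa", ], n = 256)
  left_row <- c(T7 = 0.2, C5 = 0.4, C3 = 0.6, C1 = 0.8)   # fractions of LPA->Cz
  for (nm in names(left_row)) {
    pts[[nm]] <- interp_on_path(phantom, cl, left_row[[nm]] * cl$total)
  }
  right_row <- c(C2 = 0.2, C4 = 0.4, C6 = 0.6, T8 = 0.8)  # fractions of Cz->RPA
  for (nm in names(right_row)) {
    pts[[nm]] <- interp_on_path(phantom, cr, right_row[[nm]] * cr$total)
  }

  ## --- 10% circumferential ring through Fpz, T7, Oz, T8 (least-squares plane)
  ring_pts <- rbind(pts$Fpz, pts$T7, pts$Oz, pts$T8)
  q0 <- colMeans(ring_pts)
  sv <- svd(sweep(ring_pts, 2, q0))
  normal <- sv$v[, 3]
  if (normal[3] < 0) normal <- -normal
  ring <- plane_curve(phantom, q0, normal, n = 1440)
  s_fpz <- curve_locate(ring, pts$Fpz)
  s_t7 <- curve_locate(ring, pts$T7)
  s_t8 <- curve_locate(ring, pts$T8)
  dir_l <- sign(curve_arclen(ring, s_fpz, s_t7))   # increasing-s toward left?
  step <- ring$total * 0.05
  pts$Fp1 <- curve_at(phantom, ring, s_fpz + dir_l * step)
  pts$Fp2 <- curve_at(phantom, ring, s_fpz - dir_l * step)
  pts$FT7 <- curve_at(phantom, ring, s_fpz + dir_l * 4 * step)
  pts$FT8 <- curve_at(phantom, ring, s_fpz - dir_l * 4 * step)
  pts$TP7 <- curve_at(phantom, ring, s_fpz + dir_l * 6 * step)
  pts$TP8 <- curve_at(phantom, ring, s_fpz - dir_l * 6 * step)

  ## --- FC and CP rows: scalp curve through the row's temporal endpoints and
  ## midline point; lateral positions at the proportional subdivisions of the
  ## midline-to-temporal segment (x3 at 50%, x1 at 25%, x5 at 75%)
  row_chain <- function(end_l, mid, end_r, labs_l, labs_r) {
    nrm <- pracma_cross(end_r - end_l, mid - end_l)
    crv <- plane_curve(phantom, mid, nrm, n = 1440)
    s_m <- curve_locate(crv, mid)
    s_l <- curve_locate(crv, end_l)
    out <- list()
    dl <- curve_arclen(crv, s_m, s_l)
    for (i in seq_along(labs_l)) {
      fr <- c(0.25, 0.5, 0.75)[i]
      out[[labs_l[i]]] <- curve_at(phantom, crv, s_m + fr * dl)
    }
    s_r <- curve_locate(crv, end_r)
    dr <- curve_arclen(crv, s_m, s_r)
    for (i in seq_along(labs_r)) {
      fr <- c(0.25, 0.5, 0.75)[i]
      out[[labs_r[i]]] <- curve_at(phantom, crv, s_m + fr * dr)
    }
    out
  }
  fc <- row_chain(pts$FT7, pts$FCz, pts$FT8,
                  c("FC1", "FC3", "FC5"), c("FC2", "FC4", "FC6"))
  cp <- row_chain(pts$TP7, pts$CPz, pts$TP8,
                  c("CP1", "CP3", "CP5"), c("CP2", "CP4", "CP6"))
  pts <- c(pts, fc, cp)

  m <- do.call(rbind, pts)
  rownames(m) <- names(pts)
  colnames(m) <- c("x", "y", "z")
  structure(m, class = c("eeg_map", "matrix", "array"),
            phantom_id = phantom$id)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.eeg_map <- function(x, ...) {
  cat(sprintf("<eeg_map> %d 10-10 positions\n", nrow(x)))
  print(unclass(x)[order(rownames(x)), ])
  invisible(x)
}

#' Export an EEG map to CSV
#'
#' Writes `label,x,y,z` rows (mm, RAS).
#'
#' @param eeg An `eeg_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(eeg, path) {
  df <- data.frame(label = rownames(eeg), x = eeg[, 1], y = eeg[, 2],
                   z = eeg[, 3], row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
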