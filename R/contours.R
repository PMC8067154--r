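#' @section Slice contours:
#' A `slice_contour` is a tibble of ordered boundary points in physical
#' mm (columns `theta`, `r_mm`, `x_mm`, `y_mm`, `provenance`) with the
#' symmetry axis at `x = 0`. Attributes carry the ray centre, the gap
#' (defect) ray indices and the defect endpoints D / D'.
#' @name slice_contour
NULL

new_slice_contour <- function(pts, gap, endpoints, center_y, spacing,
                              closed) {
  structure(pts,
            class = c("slice_contour", class(pts)),
            gap = gap, defect_endpoints = endpoints,
            center_y = center_y, pixel_spacing = spacing,
            closed = closed)
}

# bilinear interpolation of an image at physical points; outside -> 0.
# Physical frame: x along columns (0 at axis_col), y up (+y = row 1).
interp_image <- function(img, xs, ys, spacing, axis_col, center_row) {
  ci <- xs / spacing + axis_col        # fractional column
  ri <- center_row - ys / spacing      # fractional row
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  ok <- r0 >= 1 & r0 < nr & c0 >= 1 & c0 < nc
  v <- numeric(length(xs))
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    i00 <- (c0k - 1) * nr + r0k
    v[ok] <- img[i00]       * (1 - frk) * (1 - fck) +
             img[i00 + 1]   * frk       * (1 - fck) +
             img[i00 + nr]  * (1 - frk) * fck +
             img[i00 + nr + 1] * frk    * fck
  }
  v
}

#' Extract a skull outline from one bone-mask slice
#'
#' Traces the outer (or inner) boundary of the bone mask by casting
#' `n_theta` equiangular rays from the slice centre and locating the
#' sub-pixel 0.5 iso-level crossing of the bilinearly interpolated mask
#' along each ray. Rays that meet no bone form the defect gap; the
#' outline points flanking the gap are the defect endpoints D and D'.
#' Skull cross-sections are star-shaped about their centre, so the
#' radial parameterization is faithful and makes the later mirror step
#' an index permutation.
#'
#' @param image Binary bone-mask matrix (bone = 1), row 1 = anterior.
#' @param spacing Pixel spacing, mm/pixel.
#' @param axis_col Symmetry-axis column (sub-pixel allowed); default
#'   image centre.
#' @param n_theta Number of rays (even; default 720).
#' @param boundary `"outer"` (default) or `"inner"` annulus boundary.
#' @return A [slice_contour] ordered counter-clockwise (theta
#'   increasing from 0); gap rays keep `NA` radii until filled.
#' @export
extract_outline <- function(image, spacing, axis_col = NULL,
                            n_theta = 720L, boundary = c("outer", "inner")) {
  boundary <- match.arg(boundary)
  if (n_theta %% 2L != 0L) abort("n_theta must be even")
  if (!any(image > 0)) abort("empty mask: no bone pixels")
  if (is.null(axis_col)) axis_col <- (ncol(image) + 1) / 2
  nr <- nrow(image)
  # centre the rays on the axis column and the bone centroid row
  rows <- which(image > 0, arr.ind = TRUE)[, 1]
  center_row <- mean(range(rows))
  center_y <- 0  # physical y measured from center_row
  th <- (0:(n_theta - 1)) * 2 * pi / n_theta
  rmax <- min(axis_col, ncol(image) - axis_col,
              center_row, nr - center_row) * spacing
  step <- spacing / 2
  rs <- seq(step, rmax, by = step)
  m <- length(rs)
  # sample the mask along every ray
  xs <- outer(cos(th), rs)
  ys <- outer(sin(th), rs)
  v <- interp_image(image, as.vector(xs), as.vector(ys), spacing,
                    axis_col, center_row)
  v <- matrix(v, n_theta, m)
  inside <- v >= 0.5
  hit <- rowSums(inside) > 0
  r_mm <- rep(NA_real_, n_theta)
  idx <- which(hit)
  for (i in idx) {
    if (boundary == "outer") {
      j <- max(which(inside[i, ]))
      if (j < m) {
        dv <- v[i, j] - v[i, j + 1]
        f <- if (dv > 0) (v[i, j] - 0.5) / dv else 0
        r_mm[i] <- rs[j] + f * step
      } else r_mm[i] <- rs[j]
    } else {
      j <- min(which(inside[i, ]))
      if (j > 1) {
        dv <- v[i, j] - v[i, j - 1]
        f <- if (dv > 0) (v[i, j] - 0.5) / dv else 0
        r_mm[i] <- rs[j] - f * step
      } else r_mm[i] <- rs[j]
    }
  }
  gap <- !hit
  endpoints <- NULL
  if (any(gap) && !all(gap)) {
    d_idx <- flank_gap(gap)  # errors if the gap is not one block
    ray_hits <- function(theta) {
      v <- interp_image(image, rs * cos(theta), rs * sin(theta),
                        spacing, axis_col, center_row)
      any(v >= 0.5)
    }
    dth <- 2 * pi / n_theta
    # bisect each flank between its last hit ray and first miss ray to
    # locate the cut angle to sub-ray precision
    cut <- numeric(2)
    for (s in 1:2) {
      lo <- th[d_idx[s]]                      # hit
      hi <- lo + if (s == 1) dth else -dth     # miss
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        if (ray_hits(mid)) lo <- mid else hi <- mid
      }
      cut[s] <- (lo + hi) / 2
    }
    r_flank <- r_mm[d_idx]
    # rays angularly within one pixel of the cut see a partially removed
    # bone wedge: their 0.5-level crossing sits on the cut face, not the
    # skull surface, so treat them as part of the gap
    guard <- spacing / min(r_flank)
    span <- (cut[2] - cut[1]) %% (2 * pi)
    rel <- (th - cut[1] + guard) %% (2 * pi)
    gap <- gap | (rel <= span + 2 * guard)
    if (all(gap)) abort("defect sector leaves no reliable outline")
    d_idx <- flank_gap(gap)
    r_mm[gap] <- NA_real_
    # endpoint radii from the nearest clean rays (the excluded rays'
    # radii are unreliable by construction)
    endpoints <- cbind(x = r_mm[d_idx] * cos(cut),
                       y = r_mm[d_idx] * sin(cut))
    rownames(endpoints) <- c("D", "Dprime")
  } else if (all(gap)) {
    abort("empty outline: no ray meets bone")
  }
  pts <- tibble(
    theta = th, r_mm = r_mm,
    x_mm = r_mm * cos(th), y_mm = r_mm * sin(th),
    provenance = "original"
  )
  new_slice_contour(pts, gap = gap, endpoints = endpoints,
                    center_y = center_row, spacing = spacing,
                    closed = !any(gap))
}

# indices of the two non-gap rays flanking the (single, wrap-aware)
# gap block: first returned index precedes the gap in CCW order
flank_gap <- function(gap) {
  n <- length(gap)
  gi <- which(gap)
  if (length(gi) == 0) return(NULL)
  # find a gap element whose predecessor is not gap -> block start
  starts <- gi[!gap[(gi - 2) %% n + 1]]
  ends <- gi[!gap[gi %% n + 1]]
  if (length(starts) != 1) abort("multiple boundary gaps: disconnected outline")
  c((starts - 2) %% n + 1, ends %% n + 1)
}

#' Fill the defect by mirror reflection (regular contour)
#'
#' Replaces the defect gap with the reflection of the contralateral
#' outline across the symmetry axis (`x = 0`): each gap ray at angle
#' theta receives the traced radius at pi - theta. The filled segment
#' necessarily meets the original outline at the defect endpoints D and
#' D', and the result is a closed contour. Filled points are tagged
#' `"reconstructed"`.
#'
#' @param contour A [slice_contour] from [extract_outline()].
#' @return A closed [slice_contour]; returned unchanged when there is
#'   no gap.
#' @export
mirror_fill <- function(contour) {
  gap <- attr(contour, "gap")
  if (!any(gap)) return(contour)
  n <- length(gap)
  mirror_idx <- function(i) (n / 2 - (i - 1)) %% n + 1
  gi <- which(gap)
  mi <- mirror_idx(gi)
  if (any(gap[mi])) abort("contralateral outline is itself defective")
  out <- contour
  out$r_mm[gi] <- contour$r_mm[mi]
  out$x_mm[gi] <- out$r_mm[gi] * cos(out$theta[gi])
  out$y_mm[gi] <- out$r_mm[gi] * sin(out$theta[gi])
  out$provenance[gi] <- "reconstructed"
  attr(out, "closed") <- TRUE
  out
}

#' Elevate the reconstructed contour outward
#'
#' Simulates post-craniectomy bulging: let P be the intersection of the
#' mirror-filled (regular) segment with the perpendicular bisector of
#' the defect chord DD', and X the point `k` mm outward of P along that
#' bisector. The reconstructed segment is replaced by the circular arc
#' through D, X and D' (falling back to the polyline D-X-D' if the
#' three points are collinear). `k = 0` keeps P on the arc, so the
#' regular contour is reproduced at the bisector.
#'
#' @param contour A mirror-filled [slice_contour].
#' @param k Elevation height, mm (>= 0).
#' @return A closed [slice_contour] with the elevated segment tagged
#'   `"reconstructed"`.
#' @export
elevate_contour <- function(contour, k) {
  if (k < 0) abort("elevation k must be >= 0")
  gap <- attr(contour, "gap")
  if (!any(gap)) {
    if (k == 0) return(contour)
    abort("contour has no defect segment to elevate")
  }
  if (anyNA(contour$r_mm)) abort("contour must be mirror-filled first")
  n <- length(gap)
  ends <- flank_gap(gap)
  D <- c(contour$x_mm[ends[1]], contour$y_mm[ends[1]])
  Dp <- c(contour$x_mm[ends[2]], contour$y_mm[ends[2]])
  M <- (D + Dp) / 2
  chord <- Dp - D
  nrm <- c(chord[2], -chord[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  if (sum(nrm * M) < 0) nrm <- -nrm  # outward: away from the centre
  # walk the reconstructed segment to find its bisector crossing P
  gi <- which(gap)
  # order the gap indices along the contour starting after D
  gi <- ((ends[1]) %% n + seq_len(length(gi)) - 1) %% n + 1
  seg <- rbind(D, cbind(contour$x_mm[gi], contour$y_mm[gi]), Dp)
  s <- (seg[, 1] - M[1]) * chord[1] + (seg[, 2] - M[2]) * chord[2]
  t <- (seg[, 1] - M[1]) * nrm[1] + (seg[, 2] - M[2]) * nrm[2]
  cr <- which(s[-length(s)] * s[-1] <= 0 & pmax(t[-length(s)], t[-1]) > 0)
  if (length(cr) == 0) abort("regular segment does not cross the bisector")
  i <- cr[1]
  f <- if (s[i + 1] != s[i]) s[i] / (s[i] - s[i + 1]) else 0
  tP <- t[i] + f * (t[i + 1] - t[i])
  X <- M + (tP + k) * nrm
  arc <- arc_through(D, X, Dp, length(gi))
  out <- contour
  out$x_mm[gi] <- arc[, 1]
  out$y_mm[gi] <- arc[, 2]
  out$r_mm[gi] <- sqrt(arc[, 1]^2 + arc[, 2]^2)
  out$theta[gi] <- atan2(arc[, 2], arc[, 1]) %% (2 * pi)
  out$provenance[gi] <- "reconstructed"
  attr(out, "closed") <- TRUE
  attr(out, "elevation_mm") <- k
  attr(out, "arc_points") <- rbind(D = D, X = X, Dprime = Dp)
  out
}

# m interior points of the circular arc D -> X -> Dp (excluding D, Dp);
# collinear fallback: points along the polyline D-X-Dp
arc_through <- function(D, X, Dp, m) {
  d1 <- X - D; d2 <- Dp - D
  cross <- d1[1] * d2[2] - d1[2] * d2[1]
  scale <- sqrt(sum(d2^2))
  if (abs(cross) < 1e-9 * scale^2) {
    # collinear: sample the two straight segments D-X and X-Dp
    tt <- seq(0, 2, length.out = m + 2)[-c(1, m + 2)]
    return(t(vapply(tt, function(u) {
      if (u <= 1) D + u * (X - D) else X + (u - 1) * (Dp - X)
    }, numeric(2))))
  }
  # circumcentre of the three points
  ax <- D[1]; ay <- D[2]; bx <- X[1]; by <- X[2]; cx <- Dp[1]; cy <- Dp[2]
  dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / dd
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / dd
  C <- c(ux, uy)
  R <- sqrt(sum((D - C)^2))
  phiD <- atan2(D[2] - C[2], D[1] - C[1])
  phiX <- atan2(X[2] - C[2], X[1] - C[1])
  phiP <- atan2(Dp[2] - C[2], Dp[1] - C[1])
  # choose the sweep direction from D to Dp that passes through X
  ccw_to <- function(from, to) (to - from) %% (2 * pi)
  if (ccw_to(phiD, phiX) <= ccw_to(phiD, phiP)) {
    sweep <- ccw_to(phiD, phiP)
    phis <- phiD + sweep * seq_len(m) / (m + 1)
  } else {
    sweep <- ccw_to(phiP, phiD)
    phis <- phiD - sweep * seq_len(m) / (m + 1)
  }
  cbind(C[1] + R * cos(phis), C[2] + R * sin(phis))
}

#' Default contour-elevation schedule
#'
#' Elevations of 0 to 30 mm in 2 mm steps, then 35 to 50 mm in 5 mm
#' steps: 20 heights in total.
#'
#' @return Numeric vector of elevation heights, mm.
#' @export
schedule_default <- function() {
  c(seq(0, 30, by = 2), seq(35, 50, by = 5))
}

#' Reconstruct (and optionally elevate) contours for a whole stack
#'
#' Runs [extract_outline()] and [mirror_fill()] on every slice, then
#' [elevate_contour()] with elevation `k` on the defect slices.
#'
#' @param stack A `slice_stack`.
#' @param k Elevation height, mm (0 = regular contour).
#' @param n_theta Rays per slice.
#' @param boundary Boundary to trace (`"outer"` or `"inner"`).
#' @return List of closed [slice_contour]s, one per slice.
#' @export
reconstruct_contours <- function(stack, k = 0, n_theta = 720L,
                                 boundary = "outer") {
  stopifnot(inherits(stack, "slice_stack"))
  lapply(seq_len(stack$n_slices), function(i) {
    ct <- extract_outline(stack$images[[i]], stack$pixel_spacing,
                          axis_col = stack$symmetry_axis_col,
                          n_theta = n_theta, boundary = boundary)
    if (any(attr(ct, "gap"))) {
      ct <- mirror_fill(ct)
      if (k > 0) ct <- elevate_contour(ct, k)
    }
    ct
  })
}

#' Enclosed area of a closed contour
#' @param contour A closed [slice_contour].
#' @return Area, mm^2 (shoelace formula).
#' @export
contour_area <- function(contour) {
  x <- contour$x_mm; y <- contour$y_mm
  if (anyNA(x)) abort("contour is not closed (gap not filled)")
  j <- c(seq_along(x)[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Is a closed contour simple (non-self-intersecting)?
#'
#' Brute-force segment-pair intersection scan with a bounding-box
#' prefilter; adjacent segments are exempt.
#'
#' @param contour A closed [slice_contour] (or a 2-column matrix).
#' @return TRUE/FALSE.
#' @export
is_simple_contour <- function(contour) {
  if (is.matrix(contour)) P <- contour
  else P <- cbind(contour$x_mm, contour$y_mm)
  n <- nrow(P)
  Q <- P[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]
    if (length(js) == 0) next
    # bounding-box reject
    keep <- pmin(P[js, 1], Q[js, 1]) <= max(P[i, 1], Q[i, 1]) &
            pmax(P[js, 1], Q[js, 1]) >= min(P[i, 1], Q[i, 1]) &
            pmin(P[js, 2], Q[js, 2]) <= max(P[i, 2], Q[i, 2]) &
            pmax(P[js, 2], Q[js, 2]) >= min(P[i, 2], Q[i, 2])
    js <- js[keep]
    for (j in js) {
      if (segments_cross(P[i, ], Q[i, ], P[j, ], Q[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Serialize stack contours to CSV
#'
#' Columns `slice_index,point_index,x_mm,y_mm,provenance`; slice and
#' point indices are 0-based.
#'
#' @param contours List of [slice_contour]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  tbl <- bind_rows(lapply(seq_along(contours), function(i) {
    ct <- contours[[i]]
    tibble(slice_index = i - 1L,
           point_index = seq_len(nrow(ct)) - 1L,
           x_mm = ct$x_mm, y_mm = ct$y_mm,
           provenance = ct$provenance)
  }))
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
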