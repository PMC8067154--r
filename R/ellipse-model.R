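#' Idealized elliptical skull cross-section
#'
#' The axial cross-section of the skull at the level of the defect is
#' modelled as an ellipse \eqn{x^2/a^2 + y^2/b^2 = 1}. The defect is a
#' chord perpendicular to the x-axis at distance `h` from the centre;
#' the chord length (the "tangential diameter") is a proxy for how much
#' bone the craniectomy removed.
#'
#' @param a Semi-axis along the defect axis (x), mm. Default 65, a
#'   typical adult lateral half-width.
#' @param b Semi-axis along the chord direction (y), mm. Default 75.
#' @return An object of class `ellipse_spec`.
#' @examples
#' e <- ellipse_spec()
#' tangent_diameter(0, e)     # full axis, 150 mm
#' @export
ellipse_spec <- function(a = 65, b = 75) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1)
  if (a <= 0 || b <= 0) abort("semi-axes must be positive")
  structure(list(a = a, b = b), class = "ellipse_spec")
}

#' @export
print.ellipse_spec <- function(x, ...) {
  cat(sprintf("<ellipse_spec> a = %g mm, b = %g mm\n", x$a, x$b))
  invisible(x)
}

#' Tangential diameter of the skull defect
#'
#' Length of the chord at distance `h` from the ellipse centre:
#' \eqn{d = 2 b \sqrt{1 - h^2/a^2}}. Monotone decreasing in `h`; the
#' widest possible defect (`h = 0`) has `d = 2b`.
#'
#' @param h Distance from centre to the defect chord, mm. Vectorized.
#' @param spec An [ellipse_spec()].
#' @return Chord length(s), mm.
#' @export
tangent_diameter <- function(h, spec = ellipse_spec()) {
  if (any(h < 0 | h > spec$a)) abort("h must lie in [0, a]")
  2 * spec$b * sqrt(1 - h^2 / spec$a^2)
}

#' Geometry of one defect chord and its elevated contour
#'
#' Collects the derived quantities for a defect chord at distance `h`
#' with contour elevation `k`: the chord length `d`, the semi-axes of
#' the "new" ellipse that models the elevated contour
#' (\eqn{b_h = b\sqrt{1 - h^2/a^2}}, \eqn{a_h = a + k - h}), centred at
#' the chord midpoint.
#'
#' @inheritParams tangent_diameter
#' @param k Contour elevation height, mm (>= 0).
#' @return A list of class `tangent_section` with fields `h`, `k`, `d`,
#'   `b_h`, `a_h` plus the parent `spec`.
#' @export
tangent_section <- function(h, k, spec = ellipse_spec()) {
  stopifnot(length(h) == 1, length(k) == 1)
  if (h < 0 || h > spec$a) abort("h must lie in [0, a]")
  if (k < 0) abort("elevation k must be >= 0")
  structure(list(
    h = h, k = k,
    d = 2 * spec$b * sqrt(1 - h^2 / spec$a^2),
    b_h = spec$b * sqrt(1 - h^2 / spec$a^2),
    a_h = spec$a + k - h,
    spec = spec
  ), class = "tangent_section")
}

#' Ordinate of the elevated contour
#'
#' The elevated contour over the defect is the upper half of the new
#' ellipse centred at the chord foot (`h`, 0):
#' \eqn{y_h(x) = b_h \sqrt{1 - (x-h)^2/a_h^2}} for
#' \eqn{h \le x \le a + k}. The first factor is the constant
#' \eqn{b_h = b\sqrt{1 - h^2/a^2}} (half the tangential diameter), so
#' the curve meets the original outline at the chord ends and extends
#' `k` mm beyond the original vertex.
#'
#' @param x Abscissa (mm), vectorized; must lie in `[h, a + k]`.
#' @param section A [tangent_section()].
#' @return Ordinate(s) `y_h` in mm.
#' @export
elevated_half_contour <- function(x, section) {
  stopifnot(inherits(section, "tangent_section"))
  if (any(x < section$h - 1e-12 | x > section$spec$a + section$k + 1e-12))
    abort("x must lie in [h, a + k]")
  section$b_h * sqrt(pmax(0, 1 - (x - section$h)^2 / section$a_h^2))
}

# upper half of the original ellipse, clamped for roundoff at the vertex
ellipse_half <- function(x, spec) {
  spec$b * sqrt(pmax(0, 1 - x^2 / spec$a^2))
}

#' Newly gained cross-sectional area by the rectangle rule
#'
#' Area enclosed between the elevated contour and the original ellipse
#' over the defect, per the rectangle method of numerical integration.
#' The first-quadrant gain is
#' \deqn{\Delta A = \sum_{i=0}^{n-1} \frac{k}{n} y_h(a + i k / n)
#'   + \sum_{i=1}^{n} \frac{a-h}{n}\left[y_h(x_i) - y(x_i)\right],
#'   \quad x_i = h + i\,(a-h)/n,}
#' i.e. left endpoints on `[a, a+k]` and right endpoints on `[h, a]`.
#' The overall new area doubles this (both quadrants). The
#' volume-increasing rate divides the first-quadrant gain by twice the
#' left-endpoint rectangle sum for the quarter-ellipse area (the
#' original half cross-section) and is reported in percent.
#'
#' @inheritParams tangent_section
#' @param n_rect Number of rectangles per integral (default 2000).
#' @return A one-row tibble with columns `h_mm`, `d_mm`, `delta_A_mm2`
#'   (first quadrant), `new_area_mm2` (doubled) and `rate_pct`.
#' @examples
#' area_increase(18.85, k = 10)   # near the plateau for K = 10
#' @export
area_increase <- function(h, k, spec = ellipse_spec(), n_rect = 2000) {
  stopifnot(n_rect >= 1)
  sec <- tangent_section(h, k, spec)
  a <- spec$a
  i0 <- 0:(n_rect - 1)
  i1 <- 1:n_rect
  # cap segment: elevated contour beyond the original vertex, left endpoints
  s1 <- sum((k / n_rect) * elevated_half_contour(a + i0 * k / n_rect, sec))
  # over the defect span: elevated minus original, right endpoints
  xi <- h + i1 * (a - h) / n_rect
  s2 <- sum(((a - h) / n_rect) *
              (elevated_half_contour(xi, sec) - ellipse_half(xi, spec)))
  delta_A <- s1 + s2
  denom <- 2 * sum((a / n_rect) * ellipse_half(i0 * a / n_rect, spec))
  tibble(
    h_mm = h, d_mm = sec$d,
    delta_A_mm2 = delta_A,
    new_area_mm2 = 2 * delta_A,
    rate_pct = delta_A / denom * 100
  )
}

#' Sweep the newly gained area over defect widths
#'
#' Evaluates [area_increase()] for a fixed elevation `k` on the grid
#' \eqn{h_i = i\,a/n_{grid}}, \eqn{i = 0, \dots, n_{grid}-1} (widest
#' defect first, `h = a` excluded), giving the gained area and
#' volume-increasing rate as functions of the tangential diameter.
#'
#' @inheritParams area_increase
#' @param n_grid Number of chord positions (default 500, a 0.13 mm step
#'   for the default ellipse).
#' @return A tibble of class `dc_sweep` with one row per `h`, columns
#'   `h_mm`, `d_mm`, `delta_A_mm2`, `new_area_mm2`, `rate_pct`, and
#'   attributes `k`, `spec`, `n_grid`, `n_rect`.
#' @examples
#' s <- sweep_tangent_diameters(k = 10, n_grid = 50, n_rect = 200)
#' find_plateau(s)
#' @export
sweep_tangent_diameters <- function(k, spec = ellipse_spec(),
                                    n_grid = 500, n_rect = 2000) {
  if (k <= 0) abort("elevation k must be > 0")
  stopifnot(n_grid >= 2)
  hs <- (0:(n_grid - 1)) * spec$a / n_grid
  rows <- bind_rows(lapply(hs, area_increase, k = k, spec = spec,
                           n_rect = n_rect))
  structure(rows,
            class = c("dc_sweep", class(rows)),
            k = k, spec = spec, n_grid = n_grid, n_rect = n_rect)
}

#' Plateau of the gained area over the sweep
#'
#' The gained area is not monotone in defect width: it rises, peaks at
#' a tangential diameter strictly below the full axis `2b`, then
#' declines as the defect approaches the midline. This returns the grid
#' row maximizing `new_area_mm2`; ties (not observed on the default
#' grid) break toward the larger diameter.
#'
#' @param sweep A `dc_sweep` from [sweep_tangent_diameters()].
#' @return A one-row tibble: the plateau row.
#' @export
find_plateau <- function(sweep) {
  stopifnot(inherits(sweep, "dc_sweep") || is.data.frame(sweep))
  if (nrow(sweep) == 0) abort("empty sweep")
  best <- max(sweep$new_area_mm2)
  cand <- which(sweep$new_area_mm2 == best)
  i <- cand[which.max(sweep$d_mm[cand])]
  tibble::as_tibble(sweep[i, , drop = FALSE])
}

#' Approximate ellipse perimeter
#'
#' The coarse perimeter approximation \eqn{2\pi b + 4(a - b)} for an
#' ellipse with semi-major axis `a_major` and semi-minor axis
#' `b_minor` (exact for a circle). Used to express defect-margin arc
#' length in the scalp-elevation formula.
#'
#' @param a_major,b_minor Semi-axes, mm, with `a_major >= b_minor > 0`.
#' @param pi_const Value of pi to use (defaults to exact `pi`).
#' @return Approximate perimeter, mm.
#' @export
ellipse_perimeter_approx <- function(a_major, b_minor, pi_const = pi) {
  if (any(b_minor <= 0) || any(a_major < b_minor))
    abort("require a_major >= b_minor > 0")
  2 * pi_const * b_minor + 4 * (a_major - b_minor)
}

#' Closed-form maximal scalp-elevation height
#'
#' If the scalp over the defect can stretch by at most `extension` mm
#' of arc length, the maximal outward elevation `K` follows from
#' comparing the approximate perimeters of the original skull ellipse
#' (semi-axes `a_ap`, `b_lat`) and the elevated one (`a_ap`,
#' `b_lat + K`):
#' \deqn{K = \frac{4\,ext\,a + (2\,ext\,\pi - 4\,ext)\,b}{X\,(2\pi - 4)},}
#' where `X` is the arc length of the defect margin. With
#' `extension = 4.1` and `pi_const = 3.14` this is
#' \eqn{(16.4a + 9.348b) / (2.28 X)}.
#'
#' @param a_ap Anteroposterior semi-axis, mm (default 75).
#' @param b_lat Lateral semi-axis, mm (default 65).
#' @param X Arc length of the defect margin, mm.
#' @param extension Maximal extra arc length the scalp allows, mm
#'   (default 4.1).
#' @param pi_const Value of pi (default exact `pi`; use 3.14 to
#'   reproduce hand calculations done with that rounding).
#' @return Elevation height `K`, mm.
#' @examples
#' X <- ellipse_perimeter_approx(75, 65, pi_const = 3.14) / 2  # 224.1
#' scalp_elevation_K(75, 65, X, pi_const = 3.14)               # 3.596...
#' @export
scalp_elevation_K <- function(a_ap = 75, b_lat = 65, X,
                              extension = 4.1, pi_const = pi) {
  if (X <= 0) abort("arc length X must be > 0")
  if (a_ap <= 0 || b_lat <= 0 || extension <= 0)
    abort("all lengths must be > 0")
  (4 * extension * a_ap + (2 * extension * pi_const - 4 * extension) * b_lat) /
    (X * (2 * pi_const - 4))
}

#' @export
tidy.dc_sweep <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("h_mm", "d_mm", "delta_A_mm2",
                                 "new_area_mm2", "rate_pct")])
}

#' @export
glance.dc_sweep <- function(x, ...) {
  p <- find_plateau(x)
  tibble(
    k_mm = attr(x, "k"),
    d_plateau_mm = p$d_mm,
    new_area_plateau_mm2 = p$new_area_mm2,
    rate_plateau_pct = p$rate_pct,
    n_grid = attr(x, "n_grid"),
    n_rect = attr(x, "n_rect")
  )
}

#' Plot a tangential-diameter sweep
#'
#' Gained area and volume-increasing rate against tangential diameter,
#' with the plateau marked.
#'
#' @param object A `dc_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dc_sweep <- function(object, ...) {
  long <- bind_rows(
    tibble(d_mm = object$d_mm, value = object$new_area_mm2,
           quantity = "newly increased area (mm²)"),
    tibble(d_mm = object$d_mm, value = object$rate_pct,
           quantity = "volume-increasing rate (%)")
  )
  p <- find_plateau(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$d_mm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = p$d_mm, linetype = "dashed") +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "tangential diameter (mm)",
      y = NULL,
      title = sprintf("Contour elevation K = %g mm", attr(object, "k")),
      subtitle = sprintf("plateau at d = %.2f mm", p$d_mm)
    )
}
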