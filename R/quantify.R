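#' Per-slice defect margin projected on the sagittal plane
#'
#' Collects the defect endpoints D / D' of every defect slice and
#' projects them onto the sagittal plane through the defect (drop the
#' left-right coordinate): each slice contributes the anteroposterior
#' positions of its two margin points at its craniocaudal height.
#'
#' @param stack A `slice_stack`.
#' @param n_theta Rays per slice for outline extraction.
#' @return Tibble with columns `slice_index`, `z_mm`, `y_d_mm`,
#'   `y_dprime_mm` (anteroposterior coordinates of D and D').
#' @export
defect_margin <- function(stack, n_theta = 720L) {
  stopifnot(inherits(stack, "slice_stack"))
  rows <- list()
  for (i in seq_len(stack$n_slices)) {
    if (!isTRUE(stack$defect[[i]]$active)) next
    ct <- extract_outline(stack$images[[i]], stack$pixel_spacing,
                          axis_col = stack$symmetry_axis_col,
                          n_theta = n_theta)
    ep <- attr(ct, "defect_endpoints")
    if (is.null(ep)) next
    rows[[length(rows) + 1]] <- tibble(
      slice_index = i,
      z_mm = (i - 1) * stack$slice_thickness,
      y_d_mm = min(ep[, "y"]),
      y_dprime_mm = max(ep[, "y"]))
  }
  bind_rows(rows)
}

#' Skull-defect area from the projected margin
#'
#' Closes the projected margin into a polygon (up one margin edge,
#' down the other) and evaluates the shoelace formula. For a margin
#' table with constant width `w` over height `h` this is exactly
#' `w * h`.
#'
#' @param margin Tibble as returned by [defect_margin()]: one row per
#'   slice with `z_mm`, `y_d_mm`, `y_dprime_mm`.
#' @return Defect area, cm2.
#' @export
defect_area <- function(margin) {
  if (nrow(margin) < 2) abort("need at least 2 margin slices (3+ points)")
  m <- margin[order(margin$z_mm), ]
  y <- c(m$y_d_mm, rev(m$y_dprime_mm))
  z <- c(m$z_mm, rev(m$z_mm))
  j <- c(seq_along(y)[-1], 1)
  area_mm2 <- abs(sum(y * z[j] - y[j] * z)) / 2
  area_mm2 / 100
}

#' Defect-area group
#'
#' Clinical grouping of craniectomy size: group 1 below 125 cm2,
#' group 2 for 125 <= area < 150 cm2, group 3 at or above 150 cm2.
#'
#' @param area Defect area, cm2 (vectorized).
#' @return Integer group 1/2/3.
#' @export
assign_group <- function(area) {
  if (any(area < 0)) abort("area must be non-negative")
  ifelse(area < 125, 1L, ifelse(area < 150, 2L, 3L))
}

#' Volume-increasing rate over an elevation schedule
#'
#' `rate_i = (V_i - V_0) / V_0 * 100`, with `V_0` the volume at
#' elevation 0.
#'
#' @param volumes Tibble with columns `elevation_mm` and `volume_cm3`,
#'   containing elevation 0.
#' @return The input with a `rate_pct` column appended.
#' @export
volume_increasing_rate <- function(volumes) {
  stopifnot(all(c("elevation_mm", "volume_cm3") %in% names(volumes)))
  i0 <- which(volumes$elevation_mm == 0)
  if (length(i0) != 1) abort("volumes must contain elevation 0 exactly once")
  v0 <- volumes$volume_cm3[i0]
  if (v0 <= 0) abort("baseline volume must be positive")
  dplyr::mutate(volumes, rate_pct = (.data$volume_cm3 - v0) / v0 * 100)
}

#' Quantify a skull-defect stack over an elevation schedule
#'
#' End-to-end per-stack analysis: extracts and mirror-fills the slice
#' outlines once, then for every elevation in the schedule elevates the
#' reconstructed segment, stitches the contours into a watertight mesh
#' and measures the enclosed volume; reports the defect area (sagittal
#' projection), its clinical group, and the volume-increasing rate per
#' elevation. By default the model is bounded by the outer skull
#' surface (the "whole" model including the bone shell); set
#' `boundary = "inner"` to bound at the inner table instead.
#'
#' @param stack A `slice_stack` with a unilateral defect.
#' @param schedule Elevation heights, mm; default [schedule_default()].
#' @param n_theta Rays per slice.
#' @param boundary `"outer"` (default) or `"inner"` skull boundary.
#' @return A `dc_quant`: list with `defect_area_cm2`, `group` and
#'   `table` (tibble `elevation_mm`, `volume_cm3`, `rate_pct`).
#' @export
quantify_stack <- function(stack, schedule = schedule_default(),
                           n_theta = 360L, boundary = "outer") {
  stopifnot(inherits(stack, "slice_stack"))
  if (schedule[1] != 0 || any(diff(schedule) <= 0))
    abort("schedule must start at 0 and increase")
  base <- reconstruct_contours(stack, k = 0, n_theta = n_theta,
                               boundary = boundary)
  has_gap <- vapply(base, function(ct) any(attr(ct, "gap")), logical(1))
  vols <- vapply(schedule, function(k) {
    cts <- base
    if (k > 0) {
      for (i in which(has_gap)) cts[[i]] <- elevate_contour(base[[i]], k)
    }
    mesh <- build_mesh(cts, slice_thickness = stack$slice_thickness)
    enclosed_volume(mesh)
  }, numeric(1))
  tbl <- volume_increasing_rate(
    tibble(elevation_mm = schedule, volume_cm3 = vols))
  marg <- defect_margin(stack, n_theta = n_theta)
  area <- if (nrow(marg) >= 2) defect_area(marg) else NA_real_
  structure(list(
    defect_area_cm2 = area,
    group = if (is.na(area)) NA_integer_ else assign_group(area),
    table = tbl
  ), class = "dc_quant")
}

#' @export
print.dc_quant <- function(x, ...) {
  cat(sprintf("<dc_quant> defect area %.1f cm2 (group %s)\n",
              x$defect_area_cm2, x$group))
  print(x$table)
  invisible(x)
}

#' @export
tidy.dc_quant <- function(x, ...) x$table

#' @export
glance.dc_quant <- function(x, ...) {
  tibble(
    defect_area_cm2 = x$defect_area_cm2,
    group = x$group,
    volume_baseline_cm3 = x$table$volume_cm3[x$table$elevation_mm == 0],
    rate_max_pct = max(x$table$rate_pct),
    n_elevations = nrow(x$table)
  )
}

#' Plot volume and rate against contour elevation
#' @param object A `dc_quant`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dc_quant <- function(object, ...) {
  long <- bind_rows(
    tibble(elevation_mm = object$table$elevation_mm,
           value = object$table$volume_cm3, quantity = "volume (cm³)"),
    tibble(elevation_mm = object$table$elevation_mm,
           value = object$table$rate_pct,
           quantity = "volume-increasing rate (%)")
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$elevation_mm, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "contour elevation (mm)", y = NULL,
                  title = sprintf("Defect area %.1f cm² (group %s)",
                                  object$defect_area_cm2, object$group))
}
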