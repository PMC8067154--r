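#' Skull-defect description for the phantom
#'
#' Angular sector of bone removed from the phantom annulus, emulating a
#' unilateral craniectomy. Angles are polar angles in radians measured
#' from the +x (lateral) axis at the slice centre, counter-clockwise;
#' the sector must stay strictly within one lateral half so the
#' contralateral outline remains intact for mirror reconstruction.
#'
#' @param side `"right"` (+x half) or `"left"` (-x half).
#' @param start,end Sector limits in radians. For `side = "right"`
#'   both must lie in (-pi/2, pi/2); for `"left"` in (pi/2, 3*pi/2).
#' @param slice_range Integer first/last slice index (1-based) carrying
#'   the defect.
#' @param extent_fn Optional `function(index)` returning `c(start, end)`
#'   per slice, overriding the fixed sector (e.g. to taper the defect
#'   toward its cranial/caudal ends).
#' @return A `defect_spec`.
#' @export
defect_spec <- function(side = c("right", "left"), start, end,
                        slice_range, extent_fn = NULL) {
  side <- match.arg(side)
  stopifnot(length(slice_range) == 2, slice_range[1] <= slice_range[2])
  half <- if (side == "right") c(-pi / 2, pi / 2) else c(pi / 2, 3 * pi / 2)
  chk <- function(s, e) {
    if (s > e || s <= half[1] || e >= half[2])
      abort("defect sector must lie strictly within one lateral half")
  }
  if (is.null(extent_fn)) chk(start, end)
  structure(list(side = side, start = start, end = end,
                 slice_range = as.integer(slice_range),
                 extent_fn = extent_fn, half = half, check = chk),
            class = "defect_spec")
}

defect_sector <- function(defect, index) {
  if (is.null(defect)) return(NULL)
  if (index < defect$slice_range[1] || index > defect$slice_range[2])
    return(NULL)
  if (!is.null(defect$extent_fn)) {
    se <- defect$extent_fn(index)
    defect$check(se[1], se[2])
    se
  } else c(defect$start, defect$end)
}

#' Synthetic CT-like skull stack specification
#'
#' Describes a stack of axial bone-mask slices: elliptical bone annuli
#' on a square pixel grid, optionally with a unilateral defect sector
#' removed. Defaults emulate a clinical head CT: 512 x 512 matrix over
#' a 300 mm field of view (0.586 mm/pixel) and 1.25 mm slice thickness.
#'
#' @param n_slices Number of slices (inferior to superior).
#' @param semi_axes Either a `n_slices` x 2 matrix of per-slice outer
#'   semi-axes `(a, b)` in mm, or a `function(index)` returning
#'   `c(a, b)`. Use [ellipsoid_profile()] for an ellipsoidal taper.
#' @param grid Image size in pixels (square), default 512.
#' @param fov_mm Field of view, mm; pixel spacing is `fov_mm / grid`.
#' @param slice_thickness Slice thickness, mm (default 1.25).
#' @param bone_thickness Annulus thickness, mm (default 6).
#' @param defect A [defect_spec()] or NULL.
#' @param jitter_sd Standard deviation (mm) of per-slice semi-axis
#'   jitter; 0 (default) disables it.
#' @param seed RNG seed used only for jitter.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(n_slices, semi_axes, grid = 512L, fov_mm = 300,
                         slice_thickness = 1.25, bone_thickness = 6,
                         defect = NULL, jitter_sd = 0, seed = 1L) {
  stopifnot(n_slices >= 1, grid >= 16, fov_mm > 0,
            slice_thickness > 0, bone_thickness > 0)
  if (is.function(semi_axes)) {
    semi_axes <- t(vapply(seq_len(n_slices), semi_axes, numeric(2)))
  }
  semi_axes <- as.matrix(semi_axes)
  stopifnot(nrow(semi_axes) == n_slices, ncol(semi_axes) == 2)
  if (any(semi_axes <= 0)) abort("semi-axes must be positive on all slices")
  if (!is.null(defect)) {
    stopifnot(inherits(defect, "defect_spec"))
    if (defect$slice_range[2] > n_slices)
      abort("defect slice_range exceeds the stack")
  }
  if (jitter_sd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    semi_axes <- semi_axes + matrix(stats::rnorm(2 * n_slices, 0, jitter_sd),
                                    ncol = 2)
    .Random.seed_restore(old)
    if (any(semi_axes <= bone_thickness))
      abort("jitter collapsed a slice annulus")
  }
  structure(list(
    n_slices = as.integer(n_slices), semi_axes = semi_axes,
    grid = as.integer(grid), fov_mm = fov_mm,
    pixel_spacing = fov_mm / grid,
    slice_thickness = slice_thickness,
    bone_thickness = bone_thickness,
    defect = defect, jitter_sd = jitter_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Per-slice semi-axes of an ellipsoidal skull
#'
#' Outer semi-axes profile for a skull modelled as an ellipsoid with
#' semi-axes `(a, b, c)`; slice `i` sits at height
#' `z_i = (i - 1/2) * slice_thickness - c` so the slice midplanes tile
#' `[-c, c]`. Returns a function suitable for [phantom_spec()]'s
#' `semi_axes` argument.
#'
#' @param a,b,c Ellipsoid semi-axes, mm (x lateral, y anteroposterior,
#'   z craniocaudal).
#' @param slice_thickness Slice thickness, mm.
#' @param floor_mm Minimal semi-axis returned near the poles, mm.
#' @return `function(index) -> c(a_i, b_i)`.
#' @export
ellipsoid_profile <- function(a, b, c, slice_thickness = 1.25,
                              floor_mm = 2) {
  function(index) {
    z <- (index - 0.5) * slice_thickness - c
    f <- sqrt(max(0, 1 - z^2 / c^2))
    pmax(c(a, b) * f, floor_mm)
  }
}

#' Number of slices tiling an ellipsoid of height 2c
#' @param c Craniocaudal semi-axis, mm.
#' @param slice_thickness Slice thickness, mm.
#' @return Integer slice count `floor(2c / t)`.
#' @export
ellipsoid_n_slices <- function(c, slice_thickness = 1.25) {
  as.integer(floor(2 * c / slice_thickness))
}

# physical coordinates of pixel centres: x along columns (axis at the
# central column = x 0), y along rows with +y anterior (row 1 = top)
pixel_coords <- function(grid, spacing) {
  c0 <- (grid + 1) / 2
  list(x = (seq_len(grid) - c0) * spacing,
       y = (c0 - seq_len(grid)) * spacing)
}

#' Rasterize one phantom slice
#'
#' Bone annulus between the outer ellipse `(a_i, b_i)` and the inner
#' ellipse `(a_i - w, b_i - w)` (`w` = bone thickness), with the defect
#' sector removed when the slice lies in the defect range. Pixel
#' centres sit at integer grid coordinates; the physical origin and the
#' symmetry axis are at the image centre.
#'
#' @param spec A [phantom_spec()].
#' @param index Slice index, 1-based.
#' @return A `grid` x `grid` integer matrix (bone = 1).
#' @export
generate_slice <- function(spec, index) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (index < 1 || index > spec$n_slices) abort("slice index out of range")
  ab <- spec$semi_axes[index, ]
  w <- spec$bone_thickness
  if (any(ab <= w)) abort("degenerate slice: semi-axis <= bone thickness")
  pc <- pixel_coords(spec$grid, spec$pixel_spacing)
  X <- matrix(pc$x, spec$grid, spec$grid, byrow = TRUE)
  Y <- matrix(pc$y, spec$grid, spec$grid)
  outer_in <- (X / ab[1])^2 + (Y / ab[2])^2 <= 1
  inner_in <- (X / (ab[1] - w))^2 + (Y / (ab[2] - w))^2 < 1
  bone <- outer_in & !inner_in
  sec <- defect_sector(spec$defect, index)
  if (!is.null(sec) && sec[2] > sec[1]) {
    th <- atan2(Y, X)
    # normalize into [start, start + 2pi) so left-side sectors crossing
    # pi are handled uniformly
    th <- (th - sec[1]) %% (2 * pi) + sec[1]
    bone <- bone & !(th >= sec[1] & th <= sec[2])
  }
  mode(bone) <- "integer"
  bone
}

#' Generate the full phantom stack
#'
#' @param spec A [phantom_spec()].
#' @return A `slice_stack`: list with `images` (list of binary
#'   matrices, inferior to superior), `pixel_spacing`, `slice_thickness`,
#'   `symmetry_axis_col`, `n_slices`, per-slice `defect` annotations and
#'   the originating `spec`.
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  imgs <- lapply(seq_len(spec$n_slices), function(i) generate_slice(spec, i))
  ann <- lapply(seq_len(spec$n_slices), function(i) {
    sec <- defect_sector(spec$defect, i)
    if (is.null(sec)) list(active = FALSE)
    else list(active = TRUE, start = sec[1], end = sec[2],
              side = spec$defect$side)
  })
  structure(list(
    images = imgs,
    pixel_spacing = spec$pixel_spacing,
    slice_thickness = spec$slice_thickness,
    symmetry_axis_col = (spec$grid + 1) / 2,
    n_slices = spec$n_slices,
    defect = ann,
    spec = spec
  ), class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  nd <- sum(vapply(x$defect, `[[`, logical(1), "active"))
  cat(sprintf(
    "<slice_stack> %d slices of %dx%d px (%.3f mm/px, %.2f mm thick), %d defect slice(s)\n",
    x$n_slices, nrow(x$images[[1]]), ncol(x$images[[1]]),
    x$pixel_spacing, x$slice_thickness, nd))
  invisible(x)
}

#' Phantom presets spanning the defect-area groups
#'
#' Ready-made phantoms: an intact ellipsoidal skull (`"intact"`) and
#' three defect phantoms whose sagittal-projection defect areas fall in
#' the three clinical groups (small < 125 cm2, medium 125-150 cm2,
#' large >= 150 cm2). All use the default 512 px / 300 mm grid,
#' 1.25 mm slices and an ellipsoidal 65 x 75 x 80 mm outer profile.
#'
#' @param name One of `"intact"`, `"defect-small"`, `"defect-medium"`,
#'   `"defect-large"`.
#' @param grid Pixel grid (default 512); reduce for quick experiments.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("intact", "defect-small",
                                    "defect-medium", "defect-large"),
                           grid = 512L) {
  name <- match.arg(name)
  a <- 65; b <- 75; cc <- 80; t <- 1.25
  ns <- ellipsoid_n_slices(cc, t)
  prof <- ellipsoid_profile(a, b, cc, t, floor_mm = 8)
  defect <- switch(
    name,
    "intact" = NULL,
    # sectors centred on the right lateral axis; widths and spans set so
    # the projected margin areas fall in the three clinical groups
    "defect-small" = defect_spec("right", -0.75, 0.75,
                                 slice_range = c(30, 100)),
    "defect-medium" = defect_spec("right", -1.2, 1.2,
                                  slice_range = c(18, 112)),
    "defect-large" = defect_spec("right", -1.35, 1.35,
                                 slice_range = c(12, 118))
  )
  phantom_spec(n_slices = ns, semi_axes = prof, grid = grid,
               slice_thickness = t, defect = defect)
}

#' Write a slice stack to disk
#'
#' One grayscale PNG per slice (`slice_000.png`, ...) plus a
#' `stack.json` sidecar recording `spacing_mm`, `slice_thickness_mm`,
#' `symmetry_axis_col` and the per-slice defect annotation, so
#' [read_stack()] reconstructs the stack bit-exactly.
#'
#' @param stack A `slice_stack`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "slice_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(stack$n_slices)) {
    png::writePNG(stack$images[[i]] * 1,
                  file.path(dir, sprintf("slice_%03d.png", i - 1)))
  }
  meta <- list(
    spacing_mm = stack$pixel_spacing,
    slice_thickness_mm = stack$slice_thickness,
    symmetry_axis_col = stack$symmetry_axis_col,
    n_slices = stack$n_slices,
    defect = stack$defect
  )
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a slice stack written by [write_stack()]
#' @param dir Directory containing `slice_*.png` and `stack.json`.
#' @return A `slice_stack`.
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = FALSE)
  n <- meta$n_slices
  imgs <- lapply(seq_len(n), function(i) {
    m <- png::readPNG(file.path(dir, sprintf("slice_%03d.png", i - 1)))
    m <- round(m)
    mode(m) <- "integer"
    m
  })
  ann <- lapply(meta$defect, function(d) {
    if (isTRUE(d$active))
      list(active = TRUE, start = d$start, end = d$end, side = d$side)
    else list(active = FALSE)
  })
  structure(list(
    images = imgs,
    pixel_spacing = meta$spacing_mm,
    slice_thickness = meta$slice_thickness_mm,
    symmetry_axis_col = meta$symmetry_axis_col,
    n_slices = n,
    defect = ann,
    spec = NULL
  ), class = "slice_stack")
}
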