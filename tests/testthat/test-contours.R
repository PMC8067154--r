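# shared fixtures: one intact slice and one matching defect slice
intact_spec <- phantom_spec(n_slices = 1, semi_axes = function(i) c(50, 60),
                            grid = 192, fov_mm = 300, slice_thickness = 2,
                            bone_thickness = 6)
defect_spec1 <- phantom_spec(n_slices = 1,
                             semi_axes = function(i) c(50, 60),
                             grid = 192, fov_mm = 300, slice_thickness = 2,
                             bone_thickness = 6,
                             defect = defect_spec("right", -0.6, 0.6,
                                                  slice_range = c(1, 1)))
spacing <- intact_spec$fov_mm / intact_spec$grid
img_intact <- generate_slice(intact_spec, 1)
img_defect <- generate_slice(defect_spec1, 1)

test_that("outline of an intact slice is closed and tracks the ellipse", {
  ct <- extract_outline(img_intact, spacing, n_theta = 360)
  expect_true(attr(ct, "closed"))
  expect_null(attr(ct, "defect_endpoints"))
  expect_false(any(attr(ct, "gap")))
  truth <- ellipse_radius(ct$theta, 50, 60)
  expect_lt(max(abs(ct$r_mm - truth)), 2 * spacing)
  expect_error(extract_outline(matrix(0L, 32, 32), spacing), "empty mask")
})

test_that("defect endpoints are found within two pixels of the arc ends", {
  ct <- extract_outline(img_defect, spacing, n_theta = 720)
  ep <- attr(ct, "defect_endpoints")
  expect_equal(nrow(ep), 2)
  for (th in c(-0.6, 0.6)) {
    r <- ellipse_radius(th, 50, 60)
    truth <- c(r * cos(th), r * sin(th))
    expect_lt(min(sqrt(colSums((t(ep) - truth)^2))), 2 * spacing)
  }
  # inner boundary traces the inner ellipse
  cti <- extract_outline(img_intact, spacing, n_theta = 360,
                         boundary = "inner")
  truth <- ellipse_radius(cti$theta, 44, 54)
  expect_lt(max(abs(cti$r_mm - truth)), 2 * spacing)
})

test_that("mirror fill recovers the intact outline and tags its points", {
  ct <- extract_outline(img_defect, spacing, n_theta = 720)
  ref <- extract_outline(img_intact, spacing, n_theta = 720)
  filled <- mirror_fill(ct)
  expect_true(attr(filled, "closed"))
  expect_false(anyNA(filled$r_mm))
  expect_lt(max(abs(filled$r_mm - ref$r_mm)), 2 * spacing)
  gap <- attr(ct, "gap")
  expect_true(all(filled$provenance[gap] == "reconstructed"))
  expect_true(all(filled$provenance[!gap] == "original"))
  # no gap -> identity
  expect_identical(mirror_fill(ref), ref)
})

test_that("the mirror index map is an involution", {
  n <- length(attr(extract_outline(img_defect, spacing, n_theta = 360),
                   "gap"))
  mirror_idx <- function(i) (n / 2 - (i - 1)) %% n + 1
  i <- seq_len(n)
  expect_equal(mirror_idx(mirror_idx(i)), i)
})

test_that("a displaced symmetry axis displaces the filled apex by 2*delta", {
  delta_px <- 3
  ax <- (ncol(img_defect) + 1) / 2
  f0 <- mirror_fill(extract_outline(img_defect, spacing, n_theta = 720))
  f1 <- mirror_fill(extract_outline(img_defect, spacing,
                                    axis_col = ax + delta_px,
                                    n_theta = 720))
  # apex = filled point straight toward the defect (theta = 0), physical
  # x measured from each frame's axis; compare in the common pixel frame
  apex0 <- f0$x_mm[1] + ax * spacing
  apex1 <- f1$x_mm[1] + (ax + delta_px) * spacing
  expect_equal(apex1 - apex0, 2 * delta_px * spacing,
               tolerance = 2 * spacing)
})

test_that("elevated contours stay simple, grow with k and honor k = 0", {
  filled <- mirror_fill(extract_outline(img_defect, spacing, n_theta = 720))
  a0 <- contour_area(filled)
  e0 <- elevate_contour(filled, 0)
  expect_equal(contour_area(e0), a0, tolerance = 0.01)
  areas <- vapply(c(0, 4, 10, 25, 50),
                  function(k) contour_area(elevate_contour(filled, k)),
                  numeric(1))
  expect_true(all(diff(areas) > 0))
  for (k in c(0, 10, 50)) {
    ek <- elevate_contour(filled, k)
    expect_true(is_simple_contour(ek))
    expect_true(attr(ek, "closed"))
  }
  expect_error(elevate_contour(filled, -1), "k must")
})

test_that("elevation displaces the reconstructed segment outward, nested in k", {
  filled <- mirror_fill(extract_outline(img_defect, spacing, n_theta = 720))
  gap <- which(attr(filled, "gap"))
  e1 <- elevate_contour(filled, 5)
  e2 <- elevate_contour(filled, 15)
  expect_true(all(e2$r_mm[gap] >= e1$r_mm[gap] - 1e-9))
  expect_gt(max(e2$r_mm[gap] - e1$r_mm[gap]), 5)
})

test_that("the elevated arc is the circle through D, X and D-prime", {
  filled <- mirror_fill(extract_outline(img_defect, spacing, n_theta = 720))
  k <- 12
  ek <- elevate_contour(filled, k)
  gap <- which(attr(ek, "gap"))
  P <- cbind(ek$x_mm[gap], ek$y_mm[gap])
  ap <- attr(ek, "arc_points")
  D <- ap["D", ]; Dp <- ap["Dprime", ]
  X <- ap["X", ]
  M <- (D + Dp) / 2
  half <- sqrt(sum((Dp - D)^2)) / 2
  # sagitta s = apex height over the chord; circle radius from the
  # chord/sagitta closed form
  u <- (X - M) / sqrt(sum((X - M)^2))
  s <- sqrt(sum((X - M)^2))
  R_expected <- (half^2 + s^2) / (2 * s)
  C <- X - R_expected * u
  radii <- sqrt((P[, 1] - C[1])^2 + (P[, 2] - C[2])^2)
  expect_equal(max(radii) - min(radii), 0, tolerance = 1e-6)
  expect_equal(mean(radii), R_expected, tolerance = 1e-6)
})

test_that("the default elevation schedule is the 20-step 2/5 mm ladder", {
  s <- schedule_default()
  expect_length(s, 20)
  expect_equal(s[1], 0)
  expect_equal(s[length(s)], 50)
  expect_true(all(diff(s) > 0))
  expect_equal(s[2] - s[1], 2)
  expect_equal(s[length(s)] - s[length(s) - 1], 5)
})

test_that("stack reconstruction closes every slice and serializes to CSV", {
  sp <- tiny_defect_spec(grid = 96L)
  st <- generate_stack(sp)
  cts <- reconstruct_contours(st, k = 6, n_theta = 180)
  expect_length(cts, st$n_slices)
  expect_true(all(vapply(cts, function(ct) !anyNA(ct$r_mm), logical(1))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours_csv(cts, path)
  tbl <- utils::read.csv(path)
  expect_named(tbl, c("slice_index", "point_index", "x_mm", "y_mm",
                      "provenance"))
  expect_equal(nrow(tbl), sum(vapply(cts, nrow, integer(1))))
  expect_true("reconstructed" %in% tbl$provenance)
})
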