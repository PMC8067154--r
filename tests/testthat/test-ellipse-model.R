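e <- ellipse_spec()  # a = 65, b = 75

test_that("tangential diameter follows the chord formula and its limits", {
  expect_equal(tangent_diameter(0, e), 150)
  expect_equal(tangent_diameter(65, e), 0)
  expect_equal(tangent_diameter(18.85, e), 143.554, tolerance = 1e-5)
  hs <- seq(0, 65, length.out = 100)
  expect_true(all(diff(tangent_diameter(hs, e)) < 0))
  expect_error(tangent_diameter(-1, e), "h must")
  expect_error(tangent_diameter(66, e), "h must")
})

test_that("elevated contour is the new-ellipse ordinate with constant b_h", {
  sec <- tangent_section(18.85, 10, e)
  expect_equal(sec$b_h, 71.7769984048, tolerance = 1e-9)
  expect_equal(sec$a_h, 56.15)
  expect_equal(elevated_half_contour(sec$h, sec), sec$b_h)
  expect_equal(elevated_half_contour(e$a + sec$k, sec), 0)
  expect_equal(elevated_half_contour(40, sec), 66.4904544735, tolerance = 1e-9)
  expect_error(elevated_half_contour(80, sec), "x must")
  expect_error(tangent_section(10, -1, e), "k must")
})

test_that("rectangle-rule area gain matches the closed-form ellipse segments", {
  # fixed probe plus a deterministic grid of (h, k) pairs
  res <- area_increase(18.85, 10, e, n_rect = 2000)
  expect_equal(res$new_area_mm2, closed_form_new_area(18.85, 10),
               tolerance = 1e-3)
  # across the domain the endpoint scheme carries a small one-sided
  # discretization error, largest for shallow elevations at wide defects
  for (h in seq(0, 60, by = 12)) {
    for (k in c(5, 20, 50)) {
      got <- area_increase(h, k, e, n_rect = 2000)$new_area_mm2
      expect_equal(got, closed_form_new_area(h, k), tolerance = 2.5e-3)
    }
  }
  # the error is O(1/n): refining by 10x shrinks it accordingly
  err <- function(n) abs(area_increase(0, 5, e, n)$new_area_mm2 -
                           closed_form_new_area(0, 5))
  expect_lt(err(20000), err(2000) / 5)
  fine <- area_increase(18.85, 10, e, n_rect = 2e5)$new_area_mm2
  expect_equal(fine, closed_form_new_area(18.85, 10), tolerance = 1e-5)
})

test_that("degenerate tangent at h = a yields exactly zero gain", {
  res <- area_increase(65, 10, e)
  expect_identical(res$new_area_mm2, 0)
  expect_identical(res$rate_pct, 0)
})

test_that("area gain is strictly monotone in the elevation height", {
  for (h in c(0, 20, 40)) {
    areas <- vapply(c(2, 5, 10, 20, 40),
                    function(k) area_increase(h, k, e)$new_area_mm2,
                    numeric(1))
    expect_true(all(diff(areas) > 0))
  }
})

test_that("rate denominator approximates half the ellipse area", {
  res <- area_increase(30, 10, e, n_rect = 2000)
  denom <- res$delta_A_mm2 / res$rate_pct * 100
  expect_equal(denom, pi * e$a * e$b / 2, tolerance = 1e-3)
})

test_that("sweep grid places h = 18.85 at step 145 and honors row counts", {
  s <- sweep_tangent_diameters(10, e, n_grid = 500, n_rect = 200)
  expect_equal(nrow(s), 500)
  expect_equal(s$h_mm[146], 18.85)
  expect_equal(s$d_mm[146], 143.554, tolerance = 1e-5)
  expect_true(all(diff(s$h_mm) > 0))
  s2 <- sweep_tangent_diameters(10, e, n_grid = 2, n_rect = 50)
  expect_equal(nrow(s2), 2)
  expect_error(sweep_tangent_diameters(0, e), "k must")
})

test_that("plateau search is an argmax with ties toward the larger diameter", {
  mono <- tibble::tibble(h_mm = 1:5, d_mm = 10 - 1:5,
                         new_area_mm2 = 1:5, rate_pct = 1:5)
  expect_equal(find_plateau(mono)$h_mm, 5)  # strictly increasing -> last row
  tied <- tibble::tibble(h_mm = 1:3, d_mm = c(9, 7, 5),
                         new_area_mm2 = c(2, 2, 1), rate_pct = 1:3)
  expect_equal(find_plateau(tied)$d_mm, 9)
  expect_error(find_plateau(mono[0, ]), "empty")
})

test_that("gain rises to one interior maximum and the plateau drifts with K", {
  prev_d <- 0
  for (k in c(10, 20, 30, 40, 50)) {
    s <- sweep_tangent_diameters(k, e, n_grid = 100, n_rect = 400)
    i <- which.max(s$new_area_mm2)
    expect_gt(i, 1)                      # maximum strictly below d = 2b
    expect_lt(find_plateau(s)$d_mm, 2 * e$b)
    d <- diff(s$new_area_mm2)
    expect_true(all(d[seq_len(i - 1)] > 0))
    expect_true(all(d[i:length(d)] < 0))
    expect_gte(find_plateau(s)$d_mm, prev_d)
    prev_d <- find_plateau(s)$d_mm
  }
})

test_that("perimeter approximation and its circle limit", {
  expect_equal(ellipse_perimeter_approx(75, 65, pi_const = 3.14), 448.2)
  expect_equal(ellipse_perimeter_approx(75, 65, pi_const = 3.14) / 2, 224.1)
  r <- 12.3
  expect_equal(ellipse_perimeter_approx(r, r), 2 * pi * r)
  expect_error(ellipse_perimeter_approx(5, 7), "a_major")
})

test_that("scalp elevation height: worked example and limits", {
  K <- scalp_elevation_K(75, 65, X = 224.1, pi_const = 3.14)
  expect_equal(round(K, 3), 3.596)
  expect_lt(scalp_elevation_K(75, 65, X = 1e6, pi_const = 3.14), 1e-3)
  expect_error(scalp_elevation_K(75, 65, X = -1), "X must")
})

test_that("scalp elevation height equals the perimeter-ratio root", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 60, 100)
    b <- runif(1, 40, a)
    X <- runif(1, 100, 400)
    ext <- runif(1, 2, 8)
    pic <- sample(c(pi, 3.14), 1)
    K <- scalp_elevation_K(a, b, X, extension = ext, pi_const = pic)
    expect_equal(K, scalp_K_root_oracle(a, b, X, ext, pic),
                 tolerance = 1e-9)
  }
})

test_that("sweep tidiers and plot expose the plateau", {
  s <- sweep_tangent_diameters(10, e, n_grid = 20, n_rect = 100)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("h_mm", "d_mm", "delta_A_mm2", "new_area_mm2",
                     "rate_pct"))
  g <- glance(s)
  expect_equal(g$k_mm, 10)
  expect_equal(g$new_area_plateau_mm2, max(s$new_area_mm2))
  expect_s3_class(autoplot(s), "ggplot")
})
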