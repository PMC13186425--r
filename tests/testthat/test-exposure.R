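test_that("NDVI closed form", {
  expect_equal(ndvi(0.4, 0.4), 0)
  expect_equal(ndvi(0.8, 0), 1)
  expect_equal(ndvi(0, 0.8), -1)
  expect_equal(ndvi(0.6, 0.2), 0.5)
  expect_true(is.na(ndvi(0, 0)))
  expect_error(ndvi(-0.1, 0.2), "non-negative")
  # vectorised, stays in [-1, 1]
  set.seed(5)
  n <- runif(50); r <- runif(50)
  expect_true(all(abs(ndvi(n, r)) <= 1))
})

make_stack <- function(truth, clouds, water = NULL) {
  scenes <- lapply(clouds, function(cl) {
    list(nir = (1 + truth) / 2, red = (1 - truth) / 2,
         cloud = cl, coverage = mean(cl))
  })
  structure(list(scenes = scenes, water_mask = water,
                 origin = c(0, nrow(truth)), cellsize = 1),
            class = "scene_stack")
}

test_that("NDVI compositing masks clouds, drops cloudy scenes, masks water", {
  truth <- matrix(0.5, 4, 4)
  clear <- matrix(FALSE, 4, 4)
  # cloud-free stack returns truth exactly
  comp <- composite_ndvi(make_stack(truth, list(clear, clear)))
  expect_equal(comp$values, truth)

  # a scene with >= 20% flagged pixels never influences the composite
  poison <- matrix(0.9, 4, 4)  # scene built from different "truth"
  cl25 <- matrix(FALSE, 4, 4); cl25[1, ] <- TRUE  # 25% coverage
  st <- make_stack(truth, list(clear))
  st$scenes[[2]] <- list(nir = (1 + poison) / 2, red = (1 - poison) / 2,
                         cloud = cl25, coverage = mean(cl25))
  comp <- composite_ndvi(st)
  expect_equal(comp$values, truth)

  # exactly 20% coverage is also discarded (strict < threshold)
  truth20 <- matrix(0.5, 4, 5)
  poison20 <- matrix(0.9, 4, 5)
  cl20 <- matrix(FALSE, 4, 5); cl20[1, 1:4] <- TRUE
  expect_equal(mean(cl20), 0.20)
  st20 <- make_stack(truth20, list(matrix(FALSE, 4, 5)))
  st20$scenes[[2]] <- list(nir = (1 + poison20) / 2, red = (1 - poison20) / 2,
                           cloud = cl20, coverage = mean(cl20))
  expect_equal(composite_ndvi(st20)$values, truth20)

  # per-pixel mean over clear observations: {0.2, 0.6}, cloudy third -> 0.4
  t1 <- matrix(0.2, 3, 3); t2 <- matrix(0.6, 3, 3); t3 <- matrix(0.9, 3, 3)
  st3 <- make_stack(t1, list(matrix(FALSE, 3, 3)))
  st3$scenes[[2]] <- list(nir = (1 + t2) / 2, red = (1 - t2) / 2,
                          cloud = matrix(FALSE, 3, 3), coverage = 0)
  st3$scenes[[3]] <- list(nir = (1 + t3) / 2, red = (1 - t3) / 2,
                          cloud = matrix(TRUE, 3, 3), coverage = 1)
  comp <- composite_ndvi(st3)
  expect_equal(comp$values[1, 1], 0.4)
  # mask one pixel of scene 1 (1/9 coverage, scene retained): that pixel
  # then sees only scene 2, the rest keep the two-scene mean
  cl_px <- matrix(FALSE, 3, 3); cl_px[1, 1] <- TRUE
  st3$scenes[[1]]$cloud <- cl_px
  st3$scenes[[1]]$coverage <- mean(cl_px)
  comp <- composite_ndvi(st3)
  expect_equal(comp$values[1, 1], 0.6)
  expect_equal(comp$values[2, 2], 0.4)

  # water pixels become nodata
  wm <- matrix(FALSE, 4, 4); wm[4, 4] <- TRUE
  comp <- composite_ndvi(make_stack(truth, list(clear), water = wm))
  expect_true(is.na(comp$values[4, 4]))
  expect_equal(comp$values[1, 1], 0.5)

  # all scenes cloudy -> error
  allcl <- matrix(TRUE, 4, 4)
  expect_error(composite_ndvi(make_stack(truth, list(allcl, allcl))),
               "no usable scenes")
})

test_that("adding a fully cloudy scene never changes the composite", {
  set.seed(6)
  truth <- matrix(runif(16, -0.2, 0.9), 4, 4)
  cl <- matrix(runif(16) < 0.15, 4, 4)
  st <- make_stack(truth, list(cl, matrix(FALSE, 4, 4)))
  base <- composite_ndvi(st)
  st$scenes[[3]] <- list(nir = matrix(1, 4, 4), red = matrix(0, 4, 4),
                         cloud = matrix(TRUE, 4, 4), coverage = 1)
  expect_identical(composite_ndvi(st)$values, base$values)
})

test_that("zonal mean weights cells by exact overlap area", {
  r <- unit_raster(matrix(c(2, 4), 1, 2))  # two cells, values 2 and 4
  # constant raster -> the constant
  rc <- unit_raster(matrix(7, 3, 3))
  expect_equal(as.numeric(zonal_mean(rc, random_convex_poly(1.5, 1.5, 0.3, 1))), 7)
  # polygon covering both cells equally -> 3
  expect_equal(as.numeric(zonal_mean(r, rect_poly(0, 0, 2, 1))), 3)
  # cell A fully, cell B half -> (2 + 4 * 0.5) / 1.5 = 8/3
  expect_equal(as.numeric(zonal_mean(r, rect_poly(0, 0, 1.5, 1))), 8 / 3)
  # nodata cells excluded from numerator and denominator
  rna <- unit_raster(matrix(c(2, NA), 1, 2))
  expect_equal(as.numeric(zonal_mean(rna, rect_poly(0, 0, 2, 1))), 2)
  z <- zonal_mean(rna, rect_poly(0, 0, 2, 1))
  expect_equal(attr(z, "valid_fraction"), 0.5)
  # polygon entirely over nodata -> NA
  expect_true(is.na(zonal_mean(rna, rect_poly(1.2, 0.2, 1.8, 0.8))))
  # no overlap at all -> NA
  expect_true(is.na(zonal_mean(r, rect_poly(10, 10, 11, 11))))
})

test_that("zonal mean is bounded by overlapped cells and matches enumeration", {
  set.seed(77)
  for (i in 1:10) {
    vals <- matrix(runif(36, 5, 15), 6, 6)
    r <- unit_raster(vals)
    poly <- random_convex_poly(runif(1, 1.5, 4.5), runif(1, 1.5, 4.5), 0.3, 1.4)
    z <- as.numeric(zonal_mean(r, poly))
    cw <- parkequity:::cell_weights(r, poly)
    touched <- vals[cbind(cw$ri, cw$ci)]
    expect_gte(z, min(touched) - 1e-9)
    expect_lte(z, max(touched) + 1e-9)
    # direct enumeration over the same weights reproduces the mean
    expect_equal(z, sum(cw$w * touched) / sum(cw$w), tolerance = 1e-12)
    # weights sum to the polygon area
    expect_equal(sum(cw$w), poly_area(poly), tolerance = 1e-9)
  }
})

test_that("tract park exposure is the area-weighted mean of section means", {
  r <- unit_raster(matrix(c(10, 20), 1, 2))
  # single section: its zonal mean
  s1 <- data.frame(park_id = "a", tract_id = "t", area_km2 = 0.25)
  s1$poly <- list(rect_poly(0.25, 0.25, 0.75, 0.75))
  expect_equal(tract_park_exposure(s1, r)$park_mean, 10)
  # sections of area 1 and 3 with zonal means 10 and 20 -> 17.5
  # (areas here are the recorded weights)
  s2 <- data.frame(park_id = c("a", "b"), tract_id = "t", area_km2 = c(1, 3))
  s2$poly <- list(rect_poly(0, 0, 1, 1), rect_poly(1, 0, 2, 1))
  expect_equal(tract_park_exposure(s2, r)$park_mean, 17.5)
  # no sections -> undefined
  expect_true(is.na(tract_park_exposure(NULL, r)$park_mean))
  # a section with no valid cells drops out with its weight
  rna <- unit_raster(matrix(c(10, NA), 1, 2))
  pe <- tract_park_exposure(s2, rna)
  expect_equal(pe$park_mean, 10)
  expect_equal(pe$valid_fraction, 0.25)
})

test_that("non-park exposure complements the park mean", {
  r <- unit_raster(matrix(c(1, 3), 1, 2))
  tract <- c(0, 0, 2, 1)
  # no parks: equals the whole-tract zonal mean
  expect_equal(nonpark_exposure(tract, NULL, r), 2)
  # constant raster: non-park equals park equals the constant
  rc <- unit_raster(matrix(6, 1, 2))
  s <- data.frame(park_id = "a", tract_id = "t", area_km2 = 0.5)
  s$poly <- list(rect_poly(0, 0, 1, 0.5))
  expect_equal(nonpark_exposure(tract, s, rc), 6)
  expect_equal(tract_park_exposure(s, rc)$park_mean, 6)
  # half-tract park on a two-valued raster: complement by enumeration.
  # park = left cell entirely; remaining weight: right cell only
  s2 <- data.frame(park_id = "a", tract_id = "t", area_km2 = 1)
  s2$poly <- list(rect_poly(0, 0, 1, 1))
  expect_equal(nonpark_exposure(tract, s2, r), 3)
  # parks covering the whole tract -> undefined
  sall <- data.frame(park_id = "a", tract_id = "t", area_km2 = 2)
  sall$poly <- list(rect_poly(0, 0, 2, 1))
  expect_true(is.na(nonpark_exposure(tract, sall, r)))
})

test_that("park and non-park weights balance to the tract area", {
  set.seed(88)
  city <- generate_city(small_config(seed = 9))
  secs <- section_parks(city$parks, city$tracts)
  r <- city$rasters$no2
  for (i in sample(nrow(city$tracts), 6)) {
    tid <- city$tracts$tract_id[i]
    idx <- which(secs$tract_id == tid)
    sec <- if (length(idx)) secs[idx, , drop = FALSE] else NULL
    park_w <- if (is.null(sec)) 0 else union_area(sec$poly)
    tract_rect <- c(city$tracts$x0[i], city$tracts$y0[i],
                    city$tracts$x1[i], city$tracts$y1[i])
    tp <- rect_poly(tract_rect[1], tract_rect[2], tract_rect[3], tract_rect[4])
    cw <- parkequity:::cell_weights(r, tp)
    expect_equal(sum(cw$w), poly_area(tp), tolerance = 1e-9)
    # nonpark mean sits between cell extremes when defined
    np <- nonpark_exposure(tract_rect, sec, r)
    if (!is.na(np)) {
      vals <- r$values[cbind(cw$ri, cw$ci)]
      expect_gte(np, min(vals) - 1e-9)
      expect_lte(np, max(vals) + 1e-9)
    }
    expect_lte(park_w, poly_area(tp) + 1e-9)
  }
})

test_that("urban mean enumerates land cells over the extent", {
  # two-cell city with values 1 and 3 -> 2
  r <- unit_raster(matrix(c(1, 3), 1, 2))
  expect_equal(urban_mean(r, c(0, 0, 2, 1)), 2)
  # constant raster -> the constant
  expect_equal(urban_mean(unit_raster(matrix(4, 3, 3)), c(0, 0, 3, 3)), 4)
  # nodata excluded
  rna <- unit_raster(matrix(c(1, 3, NA, NA), 2, 2))
  expect_equal(urban_mean(rna, c(0, 0, 2, 2)), 2)
})
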