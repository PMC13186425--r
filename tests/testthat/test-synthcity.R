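test_that("config validation rejects degenerate geometry and bad fractions", {
  expect_error(city_config(tract_size = 0), "tract_size")
  expect_error(city_config(tract_size = -1), "tract_size")
  expect_error(city_config(raster_resolution = 0.3), "divide")
  expect_error(city_config(cloud_pixel_fraction = 1.5), "cloud fractions")
  expect_error(city_config(exposure_params = list(
    no2 = list(intercept = 1, slope = 0, noise_sd = -1))), "noise_sd")
  expect_error(city_config(park_size_range = c(0, 1)), "park_size_range")
})

test_that("identical config and seed give bit-identical cities", {
  a <- generate_city(small_config(seed = 123))
  b <- generate_city(small_config(seed = 123))
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$tracts, b$tracts)
  expect_identical(lapply(a$parks, `[[`, "poly"), lapply(b$parks, `[[`, "poly"))
  expect_identical(a$rasters$no2$values, b$rasters$no2$values)
  expect_identical(lapply(a$scenes$scenes, `[[`, "cloud"),
                   lapply(b$scenes$scenes, `[[`, "cloud"))
  # a different seed changes the draws
  c <- generate_city(small_config(seed = 124))
  expect_false(identical(a$rasters$no2$values, c$rasters$no2$values))
})

test_that("tracts tile the urban rectangle exactly", {
  city <- generate_city(small_config(seed = 3))
  areas <- (city$tracts$x1 - city$tracts$x0) * (city$tracts$y1 - city$tracts$y0)
  ext_area <- (city$extent[3] - city$extent[1]) * (city$extent[4] - city$extent[2])
  expect_equal(sum(areas), ext_area, tolerance = 1e-9)
  # no overlap: total cells of the tract lattice are distinct
  expect_equal(anyDuplicated(city$tracts[, c("ix", "iy")]), 0)
  # every park intersects the urban rectangle
  for (p in city$parks) {
    expect_false(is.null(clip_to_rect(p$poly, city$extent[1], city$extent[2],
                                      city$extent[3], city$extent[4])))
  }
})

test_that("noise-free rasters equal intercept + slope x latent exactly", {
  cfg <- small_config(seed = 10, exposure_params = list(
    no2 = list(intercept = 12, slope = -5, noise_sd = 0)))
  city <- generate_city(cfg)
  r <- city$rasters$no2
  cpt <- as.integer(round(cfg$tract_size / cfg$raster_resolution))
  for (i in sample(nrow(city$tracts), 8)) {
    t <- city$tracts[i, ]
    rows <- ((cfg$n_tracts_y - t$iy) * cpt + 1):((cfg$n_tracts_y - t$iy + 1) * cpt)
    cols <- ((t$ix - 1) * cpt + 1):(t$ix * cpt)
    expect_equal(unique(as.vector(r$values[rows, cols])),
                 12 - 5 * t$latent, tolerance = 1e-12)
  }
})

test_that("scene bands reconstruct the planted NDVI at clear pixels", {
  city <- generate_city(small_config(seed = 4, cloud_pixel_fraction = 0.3,
                                     cloud_scene_fraction = 0))
  s <- city$scenes$scenes[[1]]
  v <- ndvi(s$nir, s$red)
  expect_equal(v, city$ndvi_truth$values, tolerance = 1e-12)
})

test_that("per-pixel clear-scene counts follow the binomial expectation", {
  cfg <- small_config(seed = 15, n_scenes = 10, cloud_pixel_fraction = 0.3,
                      cloud_scene_fraction = 0)
  city <- generate_city(cfg)
  clear <- Reduce(`+`, lapply(city$scenes$scenes, function(s) !s$cloud))
  # expected 7 clear scenes per pixel; average over 144 pixels
  expect_equal(mean(clear), 7, tolerance = 0.15)
})

test_that("computed ICE correlates positively with latent privilege", {
  # noise-free (expected-count) demographics: near-perfect rank agreement
  city <- generate_city(small_config(seed = 20, n_tracts_x = 8, n_tracts_y = 8,
                                     demographics = "expected"))
  cp <- select_income_cutpoints(city$demographics, 0.20)
  ice <- compute_ice_table(city$demographics, cp, "combined")
  m <- merge(ice, city$tracts[, c("tract_id", "latent")], by = "tract_id")
  expect_gt(cor(m$ice, m$latent, method = "spearman"), 0.9)
  # sampled demographics still correlate strongly
  city2 <- generate_city(small_config(seed = 21, n_tracts_x = 8, n_tracts_y = 8))
  cp2 <- select_income_cutpoints(city2$demographics, 0.20)
  ice2 <- compute_ice_table(city2$demographics, cp2, "combined")
  m2 <- merge(ice2, city2$tracts[, c("tract_id", "latent")], by = "tract_id")
  expect_gt(cor(m2$ice, m2$latent, method = "spearman"), 0.7)
  # stratum counts never exceed the all-race bracket counts
  for (b in sprintf("b%02d", 1:10)) {
    expect_true(all(city2$demographics[[paste0("hh_black_", b)]] +
                    city2$demographics[[paste0("hh_white_nh_", b)]] <=
                    city2$demographics[[paste0("hh_all_", b)]]))
  }
})

test_that("ICE tracks planted exposure gradients across seeds", {
  # planted slope -5 for NO2: computed ICE and mean tract NO2 must
  # correlate negatively in essentially every realisation
  neg <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cfg <- small_config(seed = 3000 + s, n_tracts_x = 10, n_tracts_y = 10,
                        n_scenes = 1, water_fraction = 0)
    city <- generate_city(cfg)
    cp <- select_income_cutpoints(city$demographics, 0.20)
    ice <- compute_ice_table(city$demographics, cp, "combined")
    no2 <- tract_cell_means(city, "no2")
    neg <- neg + (cor(ice$ice[match(city$tracts$tract_id, ice$tract_id)],
                      no2) < 0)
  }
  expect_gte(neg, n_seeds - 1)
})

test_that("park placement bias concentrates park area in privileged tracts", {
  city <- generate_city(small_config(seed = 31, n_parks = 80,
                                     park_placement_bias = 3))
  secs <- section_parks(city$parks, city$tracts)
  tot <- tapply(secs$area_km2, secs$tract_id, sum)
  lat <- city$tracts$latent[match(names(tot), city$tracts$tract_id)]
  expect_gt(cor(as.numeric(tot), lat, method = "spearman"), 0)
})

test_that("a written city round-trips through read_city", {
  dir <- withr::local_tempdir()
  city <- generate_city(small_config(seed = 7, n_tracts_x = 4, n_tracts_y = 4,
                                     n_parks = 6))
  write_city(city, dir)
  back <- read_city(dir)
  expect_equal(back$extent, city$extent)
  expect_equal(nrow(back$tracts), nrow(city$tracts))
  m <- match(city$tracts$tract_id, back$tracts$tract_id)
  expect_equal(back$tracts$x0[m], city$tracts$x0)
  expect_equal(back$tracts$latent[m], city$tracts$latent, tolerance = 1e-12)
  expect_equal(back$rasters$no2$values, city$rasters$no2$values,
               tolerance = 1e-12)
  expect_equal(back$demographics[order(back$demographics$tract_id),
                                 sort(names(back$demographics))],
               city$demographics[order(city$demographics$tract_id),
                                 sort(names(city$demographics))],
               ignore_attr = TRUE)
  for (i in seq_along(city$parks)) {
    expect_equal(back$parks[[i]]$poly, city$parks[[i]]$poly,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(length(back$scenes$scenes), length(city$scenes$scenes))
  expect_equal(back$scenes$scenes[[1]]$nir, city$scenes$scenes[[1]]$nir,
               tolerance = 1e-12)
  expect_identical(back$scenes$scenes[[1]]$cloud, city$scenes$scenes[[1]]$cloud)
  expect_identical(back$water_mask, city$water_mask)

  # an empty park set still writes a valid (empty) feature collection
  city0 <- generate_city(small_config(seed = 8, n_parks = 0,
                                      n_tracts_x = 4, n_tracts_y = 4))
  dir0 <- withr::local_tempdir()
  write_city(city0, dir0)
  expect_length(read_geojson(file.path(dir0, "parks.geojson")), 0)
})

test_that("writing is deterministic: identical file hashes across runs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_config(seed = 99, n_tracts_x = 4, n_tracts_y = 4, n_parks = 5)
  write_city(generate_city(cfg), d1)
  write_city(generate_city(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- vapply(file.path(d1, f1), function(f) unname(tools::md5sum(f)), "")
  h2 <- vapply(file.path(d2, f1), function(f) unname(tools::md5sum(f)), "")
  expect_identical(unname(h1), unname(h2))
})
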