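test_that("screen tables are reproducible and honour hit_fraction", {
  a <- make_screen_table(50, hit_fraction = 0.2, seed = 3)
  b <- make_screen_table(50, hit_fraction = 0.2, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, make_screen_table(50, hit_fraction = 0.2, seed = 4)))
  none <- make_screen_table(50, hit_fraction = 0, seed = 1)
  expect_true(all(none$truth$true_category == "none"))
  full <- make_screen_table(202, hit_fraction = 51 / 202, seed = 1)
  expect_equal(sum(full$truth$true_category != "none"), 51)
  expect_error(make_screen_table(202, plate_noise_sd = 0), "positive")
  expect_error(make_screen_table(3), ">= 4")
  expect_true(all(a$wells$migration_index_basal >= 0 &
                  a$wells$migration_index_basal <= 100))
})

test_that("screen-table means converge to the requested truths", {
  # n = 1e4 draws of the control condition; 3-sigma band on the mean
  st <- make_screen_table(n_genes = 5000, hit_fraction = 0, plate_noise_sd = 3,
                          replicates = 2, seed = 21)
  m <- mean(st$wells$migration_index_basal)
  se <- 3 / sqrt(nrow(st$wells))
  expect_lt(abs(m - 55), 3 * se)
  m2 <- mean(st$wells$migration_index_hgf)
  expect_lt(abs(m2 - 70), 3 * se)
})

test_that("wound scenes reach the requested coverage", {
  s0 <- make_wound_scene(coverage_target = 0, timepoint = "t24", seed = 5)
  expect_equal(s0$seeded_fraction, 0)
  expect_true(any(s0$wound_mask))
  s1 <- make_wound_scene(coverage_target = 1, timepoint = "t24", seed = 5)
  expect_gte(s1$seeded_fraction, 0.98)
  s55 <- make_wound_scene(coverage_target = 0.55, timepoint = "t24", seed = 5)
  expect_lt(abs(s55$seeded_fraction - 0.55), 0.02)
  expect_identical(s55, make_wound_scene(coverage_target = 0.55,
                                         timepoint = "t24", seed = 5))
  expect_error(make_wound_scene(dot_radius = 0), "positive")
  expect_error(make_wound_scene(coverage_target = 1.2), "0, 1")
})

test_that("mask generator returns analytic geometry", {
  mm <- make_masks("disc", r = 50, dim = c(256, 256))
  expect_equal(mm$area, pi * 50^2)
  expect_equal(mm$perimeter, 2 * pi * 50)
  expect_lt(abs(sum(mm$mask) - mm$area) / mm$area, 0.02)   # pixel-count oracle
  me <- make_masks("ellipse", a = 60, b = 30)
  expect_equal(me$area, pi * 60 * 30)
  expect_equal(me$perimeter, pi * (3 * 90 - sqrt((180 + 30) * (60 + 90))))
  expect_error(make_masks("ellipse", a = 0, b = 10), "positive")
  expect_error(make_masks("disc", r = 300, dim = c(256, 256)), "fit")
})

test_that("biosensor movies record scripted truth and reject bad scripts", {
  mv <- make_biosensor_movie(function(d) d, rep(1, 3), n_frames = 4, seed = 2)
  expect_length(mv$frames, 4)
  expect_equal(dim(mv$velocity), c(3, 1))
  expect_identical(mv, make_biosensor_movie(function(d) d, rep(1, 3),
                                            n_frames = 4, seed = 2))
  expect_error(make_biosensor_movie(function(d) d, rep(40, 3), n_frames = 4),
               "off the grid")
  expect_error(make_biosensor_movie(function(d) d, rep(0, 2), n_frames = 1),
               ">= 2")
  # static, constant-activity movie is flat inside the mask
  mv0 <- make_biosensor_movie(function(d) 2, rep(0, 2), n_frames = 3,
                              seed = 3, noise_sd = 0)
  expect_true(all(mv0$frames[[1]][mv0$masks[[1]]] == 2))
})

test_that("file round-trips preserve tables, tracks and images", {
  td <- withr::local_tempdir()
  st <- make_screen_table(10, seed = 2)
  p <- write_wells_csv(st$wells, file.path(td, "wells.csv"))
  expect_equal(read_wells_csv(p), st$wells, tolerance = 1e-12)
  pars <- model_params(state_params(0.2, 0.1, 1), state_params(1, 0.2, 0.3),
                       alpha = 0.4, dwell = 5)
  sim <- simulate_tracks(pars, 3, 12, 4, seed = 1)
  tp <- write_tracks_csv(sim$tracks, file.path(td, "tracks.csv"))
  back <- read_tracks_csv(tp)
  expect_equal(back[[2]]$positions, sim$tracks[[2]]$positions, tolerance = 1e-6)
  expect_equal(back[[1]]$dt, 4)
  img <- make_masks("disc", r = 20, dim = c(64, 64))$mask
  ip <- write_image_tiff(list(img * 1, img * 0.5), file.path(td, "mv.tif"))
  pages <- read_image_tiff(ip)
  expect_equal(pages[[2]], img * 0.5, tolerance = 1e-6)
  fit <- fit_one_state(sim$tracks)
  fp <- write_fit_json(fit, file.path(td, "fit.json"))
  rt <- read_fit_json(fp)
  expect_equal(rt$params$state1$mu_s, fit$params$state1$mu_s)
  expect_equal(rt$log_likelihood, fit$log_likelihood)
  sy <- write_sidecar_yaml(list(seed = 7, dt = 4), file.path(td, "tracks.csv"))
  expect_equal(yaml::read_yaml(sy)$seed, 7)
})
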