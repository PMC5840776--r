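test_that("distance profiles recover planted activity structure", {
  mv <- make_biosensor_movie(function(d) 1, rep(0, 2), n_frames = 3,
                             seed = 1, noise_sd = 0)
  pr <- distance_profile(mv$frames[[1]], mv$masks[[1]])
  expect_true(all(pr$mean_activity == 1))                    # flat
  # activity equal to the distance transform: profile = bin centres
  m <- make_masks("disc", r = 25, dim = c(64, 64))$mask
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1)))
  pr2 <- distance_profile(d, m, bin_width = 1)
  expect_true(all(abs(pr2$mean_activity - pr2$distance) <= 0.5 + 1e-9))
  # edge-peaked truth: recovered maximum in the bin nearest the edge
  mv3 <- make_biosensor_movie(function(x) exp(-x / 2), rep(0, 2), n_frames = 3,
                              seed = 2, noise_sd = 0.02)
  pr3 <- distance_profile(mv3$frames[[1]], mv3$masks[[1]])
  expect_equal(which.max(pr3$mean_activity), 1L)
  # mask thinner than a bin
  thin <- matrix(FALSE, 32, 32); thin[16, 5:28] <- TRUE
  expect_warning(distance_profile(matrix(1, 32, 32), thin, bin_width = 4),
                 "thinner")
  expect_error(distance_profile(matrix(1, 8, 8), matrix(FALSE, 8, 8)), "empty")
})

test_that("edge velocity has the protrusion sign convention", {
  m0 <- make_masks("disc", r = 20, dim = c(64, 64))$mask
  ev0 <- edge_velocity(m0, m0, dt = 1)
  expect_true(all(ev0$velocity == 0))                        # static edge
  # uniform growth: +2 px over 1 min at 0.5 um/px -> +1 um/min
  m1 <- make_masks("disc", r = 22, dim = c(64, 64))$mask
  ev <- edge_velocity(m0, m1, dt = 1, pixel_size = 0.5)
  expect_true(all(ev$velocity > 0))
  expect_lt(abs(mean(ev$velocity) - 1), 0.25)                # discretization
  # retraction is negative, and time reversal flips the whole field
  evr <- edge_velocity(m1, m0, dt = 1, pixel_size = 0.5)
  expect_true(all(evr$velocity < 0))
  expect_equal(ev$field, -evr$field)
  expect_error(edge_velocity(matrix(FALSE, 8, 8), m0[1:8, 1:8], 1), "empty")
})

test_that("scripted sector protrusion gives the right velocity signs", {
  scr <- cbind(rep(2, 2), rep(-2, 2), rep(0, 2), rep(0, 2))
  mv <- make_biosensor_movie(function(d) 1, scr, n_frames = 3, seed = 3,
                             noise_sd = 0)
  ev <- edge_velocity(mv$masks[[1]], mv$masks[[2]], dt = 1)
  nr <- nrow(mv$masks[[1]])
  ang <- atan2(((ev$edge_idx - 1) %/% nr) + 1 - 64.5,
               ((ev$edge_idx - 1) %% nr) + 1 - 64.5)
  sector <- 1L + floor((ang + pi) / (2 * pi) * 4)
  expected <- c(2, -2, 0, 0)[pmin(sector, 4)]
  frac_ok <- mean(sign(ev$velocity) == sign(expected))
  expect_gte(frac_ok, 0.9)   # sector boundaries blur a few pixels
})

test_that("activity-velocity maps conserve samples and rank categories", {
  # static mask, uniform activity: one velocity column, uniform means
  mv0 <- make_biosensor_movie(function(d) 3, rep(0, 3), n_frames = 4,
                              seed = 4, noise_sd = 0)
  m0 <- activity_velocity_map(mv0$frames, mv0$masks, dt = 1)
  expect_equal(sum(m0$sample_counts), m0$n_sampled)
  vcols <- which(colSums(m0$sample_counts) > 0)
  expect_length(vcols, 1L)    # a single velocity column, containing v = 0
  expect_lte(m0$velocity_breaks[vcols], 0)
  expect_gte(m0$velocity_breaks[vcols + 1L], 0)
  expect_true(all(abs(m0$mean_activity[!is.na(m0$mean_activity)] - 3) < 1e-9))
  expect_equal(m0$categories["static", "n"], m0$n_sampled)
  # activity confined to the protruding sector dominates that category
  scr <- cbind(rep(2, 3), rep(0, 3), rep(0, 3), rep(0, 3))
  mv <- make_biosensor_movie(function(d, a) ifelse(a <= -pi / 2, 1, 0.1),
                             scr, n_frames = 4, seed = 5, noise_sd = 0.02)
  mp <- activity_velocity_map(mv$frames, mv$masks, dt = 1, pixel_size = 0.5)
  expect_equal(sum(mp$sample_counts), mp$n_sampled)
  expect_gt(mp$categories["protruding", "mean_activity"],
            3 * mp$categories["static", "mean_activity"])
  # uniform-activity null: category means equal within noise
  mvu <- make_biosensor_movie(function(d) 2, scr, n_frames = 4, seed = 6,
                              noise_sd = 0.02)
  mu <- activity_velocity_map(mvu$frames, mvu$masks, dt = 1, pixel_size = 0.5)
  ca <- mu$categories$mean_activity
  expect_lt(max(ca, na.rm = TRUE) - min(ca, na.rm = TRUE), 0.05)
})
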