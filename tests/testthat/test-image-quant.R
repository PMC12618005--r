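test_that("average-intensity projection is the pixelwise mean", {
  s <- array(c(matrix(2, 4, 5), matrix(4, 4, 5)), dim = c(4, 5, 2))
  expect_equal(z_project_mean(s), matrix(3, 4, 5))
  one <- matrix(runif(20), 4, 5)
  expect_equal(z_project_mean(array(one, dim = c(4, 5, 1))), one)
  set.seed(3)
  st <- array(runif(4 * 5 * 5), dim = c(4, 5, 5))
  want <- apply(st, c(1, 2), mean)  # elementwise oracle
  expect_equal(z_project_mean(st), want, tolerance = 1e-14)
  expect_error(z_project_mean(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "identically shaped")
})

test_that("ROI means follow pixel-center membership", {
  img <- matrix(7, 20, 20)
  sq <- data.frame(x = c(2.5, 10.5, 10.5, 2.5), y = c(2.5, 2.5, 10.5, 10.5))
  q <- roi_mean_fluorescence(img, list(box = sq))
  expect_equal(q$mean_fluorescence, 7)
  expect_equal(q$n_pixels, 64L)  # centers 3..10 in both axes
  # half-bright image, ROI covering both halves equally
  img2 <- cbind(matrix(0, 20, 10), matrix(10, 20, 10))
  roi <- data.frame(x = c(6.5, 14.5, 14.5, 6.5), y = c(0.5, 0.5, 20.5, 20.5))
  expect_equal(roi_mean_fluorescence(img2, list(r = roi))$mean_fluorescence, 5)
  # shrinking an ROI into the brighter region raises its mean
  small <- data.frame(x = c(10.5, 14.5, 14.5, 10.5), y = c(0.5, 0.5, 20.5, 20.5))
  expect_gt(roi_mean_fluorescence(img2, list(r = small))$mean_fluorescence, 5)
  # an ROI with no interior pixel centers names itself in the error
  tiny <- data.frame(x = c(5.1, 5.4, 5.4, 5.1), y = c(5.1, 5.1, 5.4, 5.4))
  expect_error(roi_mean_fluorescence(img, list(empty_one = tiny)),
               "empty_one")
})

test_that("per-nucleus means recover planted intensities exactly", {
  p <- image_sim_params(width = 96, height = 96, n_nuclei = 3,
                        per_nucleus_intensity = c(50, 150, 100),
                        background = 10, noise_sd = 0, seed = 4)
  sim <- simulate_image_stack(p)
  proj <- z_project_mean(sim$stack)
  q <- nucleus_mean_fluorescence(proj, sim$mask)
  expect_equal(q$mean_fluorescence, c(60, 160, 110), tolerance = 1e-12)
  # after median-background subtraction the planted ratio is exact
  qb <- nucleus_mean_fluorescence(proj, sim$mask, "median_background")
  expect_equal(qb$mean_fluorescence[2] / qb$mean_fluorescence[1], 3,
               tolerance = 1e-12)
})

test_that("label handling: empty masks, relabelling invariance", {
  img <- matrix(runif(100), 10, 10)
  empty <- matrix(0L, 10, 10)
  expect_equal(nrow(nucleus_mean_fluorescence(img, empty)), 0L)
  p <- image_sim_params(width = 64, height = 64, n_nuclei = 2,
                        per_nucleus_intensity = c(30, 90), noise_sd = 0,
                        seed = 6)
  sim <- simulate_image_stack(p)
  proj <- z_project_mean(sim$stack)
  q1 <- nucleus_mean_fluorescence(proj, sim$mask)
  swapped <- sim$mask
  swapped[sim$mask == 1L] <- 2L
  swapped[sim$mask == 2L] <- 1L
  q2 <- nucleus_mean_fluorescence(proj, swapped)
  expect_equal(sort(q1$mean_fluorescence), sort(q2$mean_fluorescence))
  expect_equal(q1$mean_fluorescence, rev(q2$mean_fluorescence))
})

test_that("region means recompose the global mean over a partition", {
  p <- image_sim_params(width = 80, height = 80, n_nuclei = 4,
                        per_nucleus_intensity = c(20, 40, 60, 80),
                        noise_sd = 2, seed = 8)
  sim <- simulate_image_stack(p)
  proj <- z_project_mean(sim$stack)
  q <- nucleus_mean_fluorescence(proj, sim$mask)
  bg <- sim$mask == 0L
  parts <- rbind(q[, c("n_pixels", "mean_fluorescence")],
                 data.frame(n_pixels = sum(bg),
                            mean_fluorescence = mean(proj[bg])))
  recomposed <- sum(parts$n_pixels * parts$mean_fluorescence) /
    sum(parts$n_pixels)
  expect_equal(recomposed, mean(proj), tolerance = 1e-9)
})

test_that("stack simulation is deterministic and errors on infeasible packing", {
  p <- image_sim_params(width = 64, height = 64, n_nuclei = 3, noise_sd = 1,
                        seed = 10)
  expect_identical(simulate_image_stack(p), simulate_image_stack(p))
  cramped <- image_sim_params(width = 30, height = 30, n_nuclei = 50,
                              nucleus_radius = 6, seed = 1)
  expect_error(simulate_image_stack(cramped, max_tries = 50), "overlap")
  expect_error(image_sim_params(per_nucleus_intensity = -5), ">= 0")
})
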