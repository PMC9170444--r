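test_that("neighborhood_mean averages in-mask neighbors without the center", {
  # constant image: means equal the image
  cst <- gray_image(matrix(3, 5, 5))
  expect_equal(neighborhood_mean(cst, 1), cst$intensities)

  # 1-D fixture: interior voxel ignores its own value
  nb <- neighborhood_mean(gray_image(c(0, 9, 0)), 1)
  expect_equal(nb[2], 0)

  # mean stays inside the image's value range
  set.seed(4)
  img <- gray_image(array(runif(4^3), c(4, 4, 4)))
  nb3 <- neighborhood_mean(img, 1)
  expect_true(all(nb3 >= min(img$intensities) - 1e-12))
  expect_true(all(nb3 <= max(img$intensities) + 1e-12))

  # out-of-mask neighbors are dropped from the average
  msk <- matrix(TRUE, 3, 3); msk[1, 1] <- FALSE
  img2 <- gray_image(matrix(c(100, 1, 1, 1, 1, 1, 1, 1, 1), 3, 3),
                     mask = msk)
  nb2 <- neighborhood_mean(img2, 1)
  expect_equal(nb2[2, 2], 1) # the 100 at (1,1) is masked out

  # a voxel with no in-mask neighbor keeps its own intensity
  msk3 <- matrix(FALSE, 3, 3); msk3[2, 2] <- TRUE
  img3 <- gray_image(matrix(7, 3, 3), mask = msk3)
  expect_equal(neighborhood_mean(img3, 1)[2, 2], 7)

  # hand check with mirror padding on a 2-D corner: for a 2x2 image the
  # reflected 3x3 window at (1,1) hits (2,1) twice, (1,2) twice and (2,2)
  # four times, never the center itself
  m4 <- matrix(c(1, 2, 3, 4), 2, 2)
  nb4 <- neighborhood_mean(gray_image(m4), 1)
  expect_equal(nb4[1, 1], (2 * 2 + 3 * 2 + 4 * 4) / 8)
})

test_that("kernel_distance_sq follows the Gaussian kernel geometry", {
  expect_equal(kernel_distance_sq(3, 3, 1), 0)
  expect_equal(kernel_distance_sq(1, 0, 1), 2 * (1 - exp(-1)),
               tolerance = 1e-12)
  # monotone approach to the bound 2 (saturates to 2 in floating point)
  d <- kernel_distance_sq(c(1, 2, 3, 4), 0, 1)
  expect_true(all(diff(d) > 0))
  expect_true(all(d < 2))
  expect_equal(kernel_distance_sq(50, 0, 1), 2, tolerance = 1e-9)
  expect_error(kernel_distance_sq(1, 0, 0), class = "ikfcm_usage_error")
})

test_that("update_centers_spatial generalizes the plain center update", {
  set.seed(6)
  m <- runif(50)
  B <- random_membership(3, 50, seed = 2)
  nb <- rev(m) # arbitrary neighborhood values

  # theta = 0 reduces to classical FCM centers
  expect_equal(update_centers_spatial(m, nb, B, 2, theta = 0),
               update_centers(m, B, 2), tolerance = 1e-14)

  # constant image: centers equal the constant for any theta
  cc <- update_centers_spatial(rep(4, 20), rep(4, 20),
                               random_membership(2, 20, 3), 2, theta = 0.7)
  expect_equal(cc, c(4, 4))

  # scalar-loop oracle
  expect_equal(update_centers_spatial(m, nb, B, 1.8, theta = 0.4),
               oracle_centers_spatial(m, nb, B, 1.8, 0.4),
               tolerance = 1e-12)
})

test_that("update_membership_kernel matches the oracle and its limits", {
  set.seed(9)
  m <- runif(40)
  nb <- runif(40)
  A <- c(0.2, 0.5, 0.9)

  B <- update_membership_kernel(m, nb, A, 2, theta = 0.4, delta = 0.3)
  expect_equal(B, oracle_membership_kernel(m, nb, A, 2, 0.4, 0.3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colSums(B), rep(1, 40), tolerance = 1e-10)

  # theta = 0 with a very wide kernel approaches Euclidean memberships
  Bk <- update_membership_kernel(m, nb, A, 2, theta = 0, delta = 1e6)
  Be <- update_membership(m, A, 2)
  expect_lt(max(abs(Bk - Be)), 1e-3)

  # voxel and neighborhood both at a center: all mass there
  B1 <- update_membership_kernel(0.5, 0.5, c(0.1, 0.5), 2, 0.4, 0.3)
  expect_equal(as.numeric(B1), c(0, 1))

  # symmetric voxel between two centers with symmetric neighborhood
  B2 <- update_membership_kernel(0.5, 0.5, c(0.2, 0.8), 2, 0.4, 0.3)
  expect_equal(as.numeric(B2), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("hesitation_correct sharpens columns without moving the argmax", {
  B <- matrix(c(0.6, 0.3, 0.1), 3, 1)
  expect_equal(as.numeric(hesitation_correct(B, 1)), c(0.6, 0.3, 0.1))
  expect_equal(as.numeric(hesitation_correct(B, 0)), c(1, 0, 0))
  expect_equal(as.numeric(hesitation_correct(B, 0.5)), c(0.8, 0.15, 0.05))

  set.seed(10)
  for (rep in 1:10) {
    B <- random_membership(4, 25, seed = rep)
    pi_y <- runif(25)
    out <- hesitation_correct(B, pi_y)
    expect_equal(colSums(out), rep(1, 25), tolerance = 1e-12)
    # winner never decreases, argmax preserved
    w <- max.col(t(B), ties.method = "first")
    w2 <- max.col(t(out), ties.method = "first")
    expect_identical(w, w2)
    expect_true(all(out[cbind(w, 1:25)] >= B[cbind(w, 1:25)] - 1e-12))
  }

  expect_error(hesitation_correct(B, rep(1.5, 25)),
               class = "ikfcm_data_error")
})

test_that("fit_ikfcm segments plateaus, is deterministic, and beats or ties
           plain FCM under impulse noise", {
  # noiseless 3-plateau phantom: near-perfect recovery
  tissues <- default_tissues()[c("CSF", "GM", "WM")]
  geom <- default_geometry()[1:3]
  ph <- make_phantom(shape = c(32, 32, 32), geometry = geom,
                     tissues = tissues, sigma = 0, seed = 1)
  fit <- fit_ikfcm(ph$image, clusters = 3, seed = 1)
  expect_gte(segmentation_accuracy(fit$labels, ph$labels), 0.999)

  # determinism: bit-identical reruns
  fit2 <- fit_ikfcm(ph$image, clusters = 3, seed = 1)
  expect_identical(fit$membership, fit2$membership)
  expect_identical(fit$centers, fit2$centers)
  expect_identical(fit$labels, fit2$labels)

  # salt-and-pepper corruption: improved algorithm is at least as accurate
  phn <- make_phantom(shape = c(48, 48), noise = "salt_pepper",
                      sigma = 0.1, seed = 4)
  acc_i <- segmentation_accuracy(fit_ikfcm(phn$image, 4, seed = 2)$labels,
                                 phn$labels)
  acc_f <- segmentation_accuracy(defuzzify(fit_fcm(phn$image, 4, seed = 2)),
                                 phn$labels)
  expect_gte(acc_i, acc_f)
})

test_that("spatial weight does not hurt accuracy under heavy noise", {
  ph0 <- make_phantom(shape = c(64, 64), sigma = 0, seed = 11)
  sigma <- 0.1 * diff(range(ph0$signals))
  ph <- make_phantom(shape = c(64, 64), sigma = sigma, seed = 11)
  acc <- vapply(c(0, 0.5), function(th) {
    segmentation_accuracy(
      fit_ikfcm(ph$image, clusters = 4, seed = 2, theta = th)$labels,
      ph$labels)
  }, numeric(1))
  expect_gte(acc[2], acc[1])
})

test_that("3-D and 2-D runs use the same machinery", {
  ph3 <- make_phantom(shape = c(24, 24, 24), sigma = 0.01, seed = 5)
  fit3 <- fit_ikfcm(ph3$image, clusters = 4, seed = 1)
  expect_identical(dim(fit3$labels), c(24L, 24L, 24L))
  expect_gte(segmentation_accuracy(fit3$labels, ph3$labels), 0.95)
})
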