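test_that("static video tracks to zero displacement, all frames valid", {
  sc <- small_scene(duration = 2, noise_sd = 0)
  rv <- render_video_pair(sc)
  roi <- roi_spec("benign_1", "benign", sc$regions[[2]]$bbox)
  trk <- track_roi(rv$white, roi)
  expect_true(all(trk$displacement == 0))
  expect_true(all(trk$valid))
  expect_identical(unname(trk$displacement[1, ]), c(0, 0))
})

test_that("sinusoidal jitter is recovered with MAE <= 1 px", {
  n <- 180
  jit <- sinusoidal_jitter(n, amplitude = 3, period_s = 4, fps = 30)
  sc <- small_scene(duration = 6, jitter = jit, noise_sd = 0)
  rv <- render_video_pair(sc)
  roi <- roi_spec("benign_1", "benign", sc$regions[[2]]$bbox)
  trk <- track_roi(rv$white, roi)
  mae <- mean(abs(trk$displacement - rv$displacement))
  expect_lte(mae, 1)
  expect_true(all(trk$valid))
  # with moderate sensor noise on the tracking channel as well
  sc2 <- small_scene(duration = 6, jitter = jit, noise_sd = 0,
                     white_noise_sd = 2000)
  rv2 <- render_video_pair(sc2)
  trk2 <- track_roi(rv2$white, roi)
  expect_lte(mean(abs(trk2$displacement - rv2$displacement)), 1)
})

test_that("an all-black frame is flagged invalid; neighbours unaffected", {
  sc <- small_scene(duration = 2, noise_sd = 0)
  rv <- render_video_pair(sc)
  white <- rv$white
  white[, , 30] <- 0L
  roi <- roi_spec("benign_1", "benign", sc$regions[[2]]$bbox)
  trk <- track_roi(white, roi)
  expect_false(trk$valid[30])
  expect_true(trk$valid[29] && trk$valid[31])
  expect_equal(trk$score[30], 0)
})

test_that("tracking is translation-equivariant for constant integer shifts", {
  set.seed(5)
  canvas <- matrix(sample(0:65535, 80 * 80, TRUE), 80, 80)
  shift <- c(4L, -3L)
  frame0 <- canvas[21:60, 21:60]
  shifted <- canvas[(21 - shift[1]):(60 - shift[1]),
                    (21 - shift[2]):(60 - shift[2])]
  stack <- array(c(frame0, shifted, shifted), c(40, 40, 3))
  roi <- roi_spec("r", "unknown", c(10, 10, 25, 25))
  trk <- track_roi(stack, roi)
  expect_equal(unname(trk$displacement[2, ]), as.numeric(shift))
  expect_equal(unname(trk$displacement[3, ]), as.numeric(shift))
})

test_that("subpixel refinement stays within half a pixel of the integer peak", {
  jit <- sinusoidal_jitter(60, amplitude = 2, period_s = 2, fps = 30)
  sc <- small_scene(duration = 2, jitter = jit, noise_sd = 0)
  rv <- render_video_pair(sc)
  roi <- roi_spec("benign_1", "benign", sc$regions[[2]]$bbox)
  ti <- track_roi(rv$white, roi, track_config(subpixel = FALSE))
  ts <- track_roi(rv$white, roi, track_config(subpixel = TRUE))
  expect_true(all(abs(ti$displacement - ts$displacement) <= 0.5))
  expect_lte(mean(abs(ts$displacement - rv$displacement)), 1)
})

test_that("curve extraction reproduces constants and generator curves", {
  nir <- array(7L, c(32, 32, 50))
  roi <- roi_spec("r", "unknown", c(5, 5, 15, 15))
  trk <- structure(list(roi_id = "r", displacement = matrix(0, 50, 2),
                        valid = rep(TRUE, 50), score = rep(1, 50)),
                   class = "roi_track")
  cv <- extract_curve(nir, trk, roi, fps = 30)
  expect_equal(cv$intensities, rep(7, 50))
  expect_equal(cv$times, (0:49) / 30)

  # synthetic lesion with ground-truth track vs generating curve
  sc <- small_scene(duration = 6, noise_sd = 4,
                    jitter = sinusoidal_jitter(180, 2, 3, 30))
  rv <- render_video_pair(sc)
  roi2 <- roi_spec("malignant_1", "malignant", sc$regions[[3]]$bbox)
  gt <- structure(list(roi_id = "malignant_1",
                       displacement = rv$displacement,
                       valid = rep(TRUE, 180), score = rep(1, 180)),
                  class = "roi_track")
  cv2 <- extract_curve(rv$nir, gt, roi2, fps = 30)
  b <- roi2$bbox
  tol <- 3 * 4 / sqrt((b[3] - b[1]) * (b[4] - b[2]))
  expect_lt(mean(abs(cv2$intensities - rv$curves[["malignant_1"]])), tol)
})

test_that("estimated-track curve matches ground-truth-track curve", {
  sc <- small_scene(duration = 6, noise_sd = 3,
                    jitter = sinusoidal_jitter(180, 3, 4, 30))
  rv <- render_video_pair(sc)
  roi <- roi_spec("benign_1", "benign", sc$regions[[2]]$bbox)
  est <- track_roi(rv$white, roi)
  expect_lte(mean(abs(est$displacement - rv$displacement)), 1)
  gt <- structure(list(roi_id = roi$id, displacement = rv$displacement,
                       valid = rep(TRUE, 180), score = rep(1, 180)),
                  class = "roi_track")
  c_est <- extract_curve(rv$nir, est, roi, fps = 30)
  c_gt <- extract_curve(rv$nir, gt, roi, fps = 30)
  expect_lt(mean(abs(c_est$intensities - c_gt$intensities)), 2)
})

test_that("invalid frames are interpolated (or dropped on request)", {
  nir <- array(rep(seq_len(20), each = 25), c(5, 5, 20))
  roi <- roi_spec("r", "unknown", c(0, 0, 5, 5), polygon = NULL)
  valid <- rep(TRUE, 20); valid[c(1, 10, 11, 20)] <- FALSE
  trk <- structure(list(roi_id = "r", displacement = matrix(0, 20, 2),
                        valid = valid, score = as.numeric(valid)),
                   class = "roi_track")
  cv <- extract_curve(nir, trk, roi, fps = 10)
  expect_equal(length(cv$intensities), 20)
  # linear in time between frame 9 (value 9) and frame 12 (value 12)
  expect_equal(cv$intensities[10], 10)
  expect_equal(cv$intensities[11], 11)
  expect_equal(cv$intensities[1], cv$intensities[2])    # endpoint hold
  expect_equal(cv$intensities[20], cv$intensities[19])
  dropped <- extract_curve(nir, trk, roi, fps = 10, invalid_policy = "drop")
  expect_equal(length(dropped$intensities), 16)
})

test_that("bounds violations are reported with the offending frame", {
  sc <- small_scene(duration = 1, noise_sd = 0)
  rv <- render_video_pair(sc)
  roi <- roi_spec("benign_1", "benign", sc$regions[[2]]$bbox)
  trk <- structure(list(roi_id = roi$id,
                        displacement = rbind(matrix(0, 15, 2),
                                             matrix(c(0, 60), 15, 2,
                                                    byrow = TRUE)),
                        valid = rep(TRUE, 30), score = rep(1, 30)),
                   class = "roi_track")
  expect_error(extract_curve(rv$nir, trk, roi, fps = 30),
               "outside frame at frame 15")
  expect_error(track_roi(rv$white, roi_spec("x", "unknown",
                                            c(0, 0, 80, 80))),
               "out of bounds")
  all_bad <- structure(list(roi_id = roi$id,
                            displacement = matrix(0, 30, 2),
                            valid = rep(FALSE, 30), score = rep(0, 30)),
                       class = "roi_track")
  expect_error(extract_curve(rv$nir, all_bad, roi, fps = 30),
               "all frames invalid")
})
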