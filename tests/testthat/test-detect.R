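test_that("letterbox is the identity on an already-square target image", {
  withr::with_seed(30, {
    img <- array(runif(640 * 640 * 3, 0, 255), c(640, 640, 3))
  })
  lb <- letterbox(img)
  expect_equal(lb$scale, 1)
  expect_equal(unname(lb$pad), c(0, 0))
  expect_equal(lb$image, img)
  again <- letterbox(lb$image)
  expect_equal(again$image, lb$image)   # idempotent
})

test_that("a 2:1 landscape image gets centered 114-valued bands", {
  img <- array(200, c(640, 1280, 3))   # h = 640, w = 1280
  lb <- letterbox(img)
  expect_equal(lb$scale, 0.5)
  expect_equal(dim(lb$image), c(640, 640, 3))
  expect_equal(unname(lb$pad), c(160, 0))
  # top and bottom fill bands
  expect_true(all(lb$image[1:160, , ] == 114))
  expect_true(all(lb$image[501:640, , ] == 114))
  # content band is the (constant) resized image
  expect_true(all(lb$image[161:480, , ] == 200))
  expect_error(letterbox(array(0, c(0, 10, 3))), "non-empty")
})

test_that("model input conversion transposes, reorders and rescales", {
  img <- array(0, c(4, 6, 3))
  img[, , 1] <- 255   # "B" plane in BGR
  out <- toModelInput(img)
  expect_equal(dim(out), c(6, 4, 3))
  expect_true(all(out >= 0 & out <= 1))
  expect_true(all(out[, , 3] == 1))   # B moved to the last (RGB) plane
  expect_true(all(out[, , 1] == 0))
  lbimg <- letterbox(array(runif(100 * 300 * 3, 0, 255),
                           c(100, 300, 3)))$image
  expect_true(all(toModelInput(lbimg) >= 0 & toModelInput(lbimg) <= 1))
})

test_that("letterbox geometry round-trips to original pixels", {
  img <- array(1, c(300, 500, 3))
  lb <- letterbox(img)
  # map original corners through the forward transform, then invert
  corners <- cbind(x = c(0, 500, 250), y = c(0, 300, 150))
  fwd <- cbind(corners[, 1] * lb$scale + lb$pad[["left"]],
               corners[, 2] * lb$scale + lb$pad[["top"]])
  back <- unletterbox(fwd, lb)
  expect_true(all(abs(back - corners) < 0.5))
})

test_that("nms keeps the confident box among duplicates", {
  b1 <- detectionBoxes("high", 0.5, 0.5, 0.2, 0.2, 0.9)
  expect_equal(nrow(nms(b1)), 1)
  dup <- rbind(b1, detectionBoxes("high", 0.5, 0.5, 0.2, 0.2, 0.8))
  kept <- nms(dup)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)
  # below-threshold boxes are dropped before suppression
  weak <- detectionBoxes("high", 0.1, 0.1, 0.1, 0.1, 0.2)
  expect_equal(nrow(nms(rbind(dup, weak))), 1)
  expect_equal(nrow(nms(weak)), 0)
  # different classes are never suppressed against each other
  other <- detectionBoxes("low", 0.5, 0.5, 0.2, 0.2, 0.5)
  expect_equal(nrow(nms(rbind(b1, other))), 2)
})

test_that("nms equals the brute-force oracle on random instances", {
  withr::with_seed(31, seeds <- sample(10000, 30))
  for (s in seeds) {
    boxes <- randomBoxes(5 + s %% 46, seed = s)
    got <- nms(boxes, 0.25, 0.45)
    want <- oracleNMS(boxes, 0.25, 0.45)
    expect_equal(got, want)
    # invariant: survivors of one class never overlap above the threshold
    if (nrow(got) > 1) {
      for (i in seq_len(nrow(got) - 1)) {
        same <- which(got$class == got$class[i])
        same <- same[same > i]
        if (length(same)) {
          expect_true(all(iou(got[i, ], got[same, , drop = FALSE]) <= 0.45))
        }
      }
    }
  }
})

test_that("top1 takes the highest confidence with stable ties", {
  expect_null(top1Box(detectionBoxes(character(0), numeric(0), numeric(0),
                                     numeric(0), numeric(0), numeric(0))))
  three <- detectionBoxes(c("a", "b", "c"), c(0.2, 0.5, 0.8),
                          c(0.2, 0.5, 0.8), rep(0.1, 3), rep(0.1, 3),
                          c(0.3, 0.7, 0.5))
  expect_equal(top1Box(three)$confidence, 0.7)
  tie <- detectionBoxes(c("a", "b"), c(0.2, 0.8), c(0.2, 0.8),
                        rep(0.1, 2), rep(0.1, 2), c(0.6, 0.6))
  expect_equal(top1Box(tie)$class, "a")
})

test_that("YOLO label files round-trip", {
  boxes <- randomBoxes(7, seed = 32)
  path <- withr::local_tempfile(fileext = ".txt")
  writeYoloLabels(boxes, path)
  back <- readYoloLabels(path)
  expect_equal(back$class, boxes$class)
  expect_equal(back$x_center, boxes$x_center, tolerance = 1e-6)
  expect_equal(back$confidence, boxes$confidence, tolerance = 1e-6)
  writeLines("0 0.5 0.5", path)
  expect_error(readYoloLabels(path), "malformed YOLO label")
})
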