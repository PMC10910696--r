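test_that("confusion counts match direct enumeration", {
  gt <- matrix(0, 10, 10); gt[1:5, ] <- 1
  expect_equal(confusionCounts(gt, gt), c(TP = 50, FP = 0, FN = 0, TN = 50))
  gt2 <- matrix(0, 10, 10); gt2[1, ] <- 1
  expect_equal(confusionCounts(matrix(1, 10, 10), gt2),
               c(TP = 10, FP = 90, FN = 0, TN = 0))
  set.seed(31)
  for (trial in 1:20) {
    a <- matrix(rbinom(64, 1, 0.5), 8, 8)
    b <- matrix(rbinom(64, 1, 0.5), 8, 8)
    expect_equal(confusionCounts(a, b), oracle_confusion(a, b))
  }
  expect_error(confusionCounts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("F1 and Dice agree with hand computation and with each other", {
  counts <- c(TP = 8, FP = 2, FN = 2, TN = 10)
  expect_equal(unname(precisionRecall(counts)), c(0.8, 0.8))
  expect_equal(f1Score(counts), 0.8)
  expect_equal(diceScore(counts), 16 / 20)
  expect_equal(f1Score(c(TP = 5, FP = 0, FN = 0, TN = 5)), 1)
  # empty-union conventions
  expect_equal(f1Score(c(TP = 0, FP = 0, FN = 0, TN = 9)), 1)
  expect_equal(f1Score(c(TP = 0, FP = 3, FN = 0, TN = 6)), 0)
  expect_equal(f1Score(c(TP = 0, FP = 0, FN = 3, TN = 6)), 0)
  # F1 == DC identity on random binary mask pairs, via both formulas
  set.seed(32)
  for (trial in 1:100) {
    a <- matrix(rbinom(16, 1, runif(1, 0.2, 0.8)), 4, 4)
    b <- matrix(rbinom(16, 1, runif(1, 0.2, 0.8)), 4, 4)
    cc <- confusionCounts(a, b)
    expect_equal(f1Score(cc), diceScore(cc), tolerance = 1e-12)
  }
})

test_that("radial contours recover known geometry", {
  # centered disc of radius 10
  m <- ellipse_mask_helper(41, c(20, 20), c(10, 10))
  cr <- contourRadii(m)
  expect_length(cr$radii, 24L)
  expect_true(all(abs(cr$radii - 10) <= 0.5))
  # full-canvas square: analytic ray-box intersections from the centroid
  sq <- matrix(1, 21, 21)
  cr8 <- contourRadii(sq, n_rays = 8L)
  box_t <- vapply(cr8$angles, function(th) {
    dx <- cos(th); dy <- sin(th)
    tx <- if (abs(dx) < 1e-12) Inf else (10) / abs(dx)
    ty <- if (abs(dy) < 1e-12) Inf else (10) / abs(dy)
    min(tx, ty)
  }, numeric(1))
  # half-pixel rasterization widens diagonal hits by up to 0.5/cos(45 deg)
  expect_true(all(abs(cr8$radii - box_t) <= 0.85))
  # axis-aligned ellipse, 4 rays: (east, north, west, south)
  el <- ellipse_mask_helper(61, c(30, 30), c(10, 20))
  cr4 <- contourRadii(el, n_rays = 4L)
  expect_equal(cr4$radii, c(20, 10, 20, 10), tolerance = 0.08)
  expect_error(contourRadii(matrix(0, 4, 4)), "empty")
})

test_that("BLE is the mean absolute radial gap with the documented edge cases", {
  m <- ellipse_mask_helper(41, c(20, 20), c(10, 10))
  c1 <- contourRadii(m)
  expect_equal(bleError(c1, c1), 0)
  # concentric circles of radii 10 and 8 -> BLE = 2
  m8 <- ellipse_mask_helper(41, c(20, 20), c(8, 8))
  c8 <- contourRadii(m8, center = c(20, 20))
  c10 <- contourRadii(m, center = c(20, 20))
  expect_equal(bleError(c8, c10), 2, tolerance = 0.15)
  expect_equal(bleError(c8, c10), bleError(c10, c8))  # symmetry
  expect_error(bleError(c8$radii[1:10], c10$radii), "mismatched")
  # strict printed formula: NaN once the prediction overshoots
  expect_true(is.nan(bleError(c(5, 3), c(4, 4), strict_formula = TRUE)))
  expect_equal(bleError(c(3, 4), c(5, 5), strict_formula = TRUE),
               mean(sqrt(c(25 - 9, 25 - 16))))
  # linear scaling of a uniform dilation gap
  expect_equal(bleError(2 * c8$radii, 2 * c10$radii), 2 * bleError(c8, c10))
})

test_that("vertical cup-to-disc ratio follows the extent definition", {
  disc <- matrix(0, 120, 120); disc[11:110, 20:100] <- 1   # vertical extent 100
  cup <- matrix(0, 120, 120); cup[41:80, 40:80] <- 1       # vertical extent 40
  expect_equal(cupDiscRatio(disc, cup), 0.4)
  expect_equal(cupDiscRatio(disc, disc), 1)
  expect_warning(ratio <- cupDiscRatio(disc, matrix(0, 120, 120)), "empty cup")
  expect_equal(ratio, 0)
  expect_error(cupDiscRatio(matrix(0, 5, 5), cup), "empty disc")
  # generator cross-check: concentric cup_scale = 0.4
  fi <- makeSample(sceneParams(disc_axes = c(30, 30), cup_scale = 0.4, seed = 4))
  expect_equal(cupDiscRatio(discMask(fi), cupMask(fi)), 0.4, tolerance = 0.05)
})

test_that("mask metrics are invariant to joint translation", {
  fi <- makeSample(sceneParams(seed = 5))
  pd <- discMask(fi); pc <- cupMask(fi)
  # a slightly eroded prediction
  pred_d <- ellipse_mask_helper(128, fi@params$disc_center,
                                fi@params$disc_axes * 0.93)
  pred_c <- ellipse_mask_helper(128, fi@params$disc_center,
                                fi@params$disc_axes * fi@params$cup_scale * 0.9)
  base <- evaluateMasks(pred_d, pred_c, pd, pc)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  trans <- evaluateMasks(shift(pred_d, 7, 5), shift(pred_c, 7, 5),
                         shift(pd, 7, 5), shift(pc, 7, 5))
  for (col in c("disc_f1", "cup_f1", "disc_dice", "cup_dice", "cdr_gt"))
    expect_equal(base[[col]], trans[[col]], tolerance = 1e-12)
  for (col in c("disc_ble", "cup_ble"))
    expect_equal(base[[col]], trans[[col]], tolerance = 0.1)
})
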