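test_that("connected components are 8-connected with raster-order labels", {
  m <- matrix(0L, 6, 6)
  m[1:2, 1:2] <- 1; m[5:6, 5:6] <- 1
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], 1)  # first raster occurrence gets label 1
  expect_equal(lab[5, 5], 2)
  # diagonal touch merges under 8-connectivity
  d <- matrix(0L, 4, 4); d[1, 1] <- 1; d[2, 2] <- 1
  expect_equal(max(label_components(d)), 1)
  expect_equal(max(label_components(matrix(0L, 4, 4))), 0)
})

test_that("object matching applies the 50% overlap rule", {
  gt <- matrix(0L, 8, 8); gt[3:6, 3:6] <- 1        # 4x4 ground truth
  pred <- matrix(0L, 8, 8); pred[3:5, 3:6] <- 1    # 3 of 4 rows: IoU 12/16
  m <- match_objects(gt, pred)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 0, 0))
  expect_equal(m$pairs$score, 0.75)
  pred1 <- matrix(0L, 8, 8); pred1[3, 3:6] <- 1    # 1 row: IoU 4/16
  m1 <- match_objects(gt, pred1)
  expect_equal(c(m1$TP, m1$FP, m1$FN), c(0, 1, 1))
  # identical masks: all matched
  gt2 <- gt; gt2[1, 1] <- 2L
  mi <- match_objects(gt2, gt2)
  expect_equal(c(mi$TP, mi$FP, mi$FN), c(2, 0, 0))
  expect_error(match_objects(gt, matrix(0L, 4, 4)), "mismatch")
})

test_that("gt-coverage rule accepts low-IoU but covering predictions", {
  gt <- matrix(0L, 8, 8); gt[3:4, 3:4] <- 1        # 2x2 gt
  pred <- matrix(0L, 8, 8); pred[1:8, 1:8] <- 1    # covers everything
  expect_equal(match_objects(gt, pred, rule = "iou")$TP, 0)
  expect_equal(match_objects(gt, pred, rule = "gt-coverage")$TP, 1)
})

test_that("precision/recall/F1 follow their defining ratios", {
  r <- object_prf(list(TP = 3, FP = 1, FN = 1))
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.75)
  expect_equal(r$f1, 0.75)
  perfect <- object_prf(list(TP = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, f1 = 1))
  zero <- object_prf(list(TP = 0, FP = 0, FN = 0))
  expect_equal(unlist(zero), c(precision = 0, recall = 0, f1 = 0))
})

test_that("Dice coefficient counts pixel overlap", {
  a <- matrix(0L, 6, 6); a[1:4, 1:4] <- 1          # 16 px
  b <- matrix(0L, 6, 6); b[1:4, 1:3] <- 1          # 12 px, all inside a
  expect_equal(dice(a, b), 24 / 28)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, matrix(0L, 6, 6)), 0)
  expect_equal(dice(matrix(0L, 6, 6), matrix(0L, 6, 6)), 1)
})

test_that("AJI penalizes spurious predictions by their full size", {
  gt <- matrix(0L, 8, 8); gt[2:4, 2:4] <- 1
  pred <- gt
  pred[7:8, 7:8] <- 2L  # extra 4-pixel instance
  expect_equal(aji(gt, gt), 1)
  expect_equal(aji(gt, pred), 9 / (9 + 4))
  # removing a prediction (false negative) also lowers it
  expect_equal(aji(pred, gt), 9 / 13)
})

test_that("metrics equal brute-force oracles on random small mask pairs", {
  set.seed(99)
  for (rep in 1:150) {
    h <- sample(4:8, 1); w <- sample(4:8, 1)
    gt <- random_instance_mask(h, w, 3)
    pred <- random_instance_mask(h, w, 3)
    expect_equal(dice(gt, pred), oracle_dice(gt, pred))
    expect_equal(aji(gt, pred), oracle_aji(gt, pred),
                 info = sprintf("rep %d", rep))
    expect_equal(match_objects(gt, pred)$TP, oracle_max_tp(gt, pred),
                 info = sprintf("rep %d", rep))
  }
})

test_that("adding a false positive never raises AJI or precision", {
  set.seed(55)
  for (rep in 1:25) {
    gt <- random_instance_mask(8, 8, 2)
    pred <- random_instance_mask(8, 8, 2)
    free <- which(pred == 0 & gt == 0)
    if (length(free) == 0 || max(gt) == 0) next
    pred2 <- pred
    pred2[free[1]] <- max(pred) + 1L
    expect_lte(aji(gt, pred2), aji(gt, pred))
    p1 <- object_prf(match_objects(gt, pred))$precision
    p2 <- object_prf(match_objects(gt, pred2))$precision
    expect_lte(p2, p1)
  }
})

test_that("directory evaluation pairs files and macro-averages", {
  gtd <- file.path(tempdir(), "gt"); prd <- file.path(tempdir(), "pred")
  dir.create(gtd, showWarnings = FALSE); dir.create(prd, showWarnings = FALSE)
  on.exit(unlink(c(gtd, prd), recursive = TRUE))
  for (i in 1:3) {
    m <- random_instance_mask(16, 16, 3)
    write_mask(m, file.path(gtd, sprintf("im%d.tif", i)))
    write_mask(m, file.path(prd, sprintf("im%d.tif", i)))
  }
  df <- evaluate_masks(gtd, prd)
  expect_equal(nrow(df), 4)
  expect_true(all(df$dice == 1 & df$aji == 1))
  expect_true(all(df$f1[df$image != "macro_average"] %in% c(0, 1)))
  # unpaired file is an error naming the file
  file.remove(file.path(prd, "im3.tif"))
  expect_error(evaluate_masks(gtd, prd), "im3")
})
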