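test_that("confusion counts tally every pixel once", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  cc <- confusion_counts(m, m)
  expect_equal(unclass(cc), list(tp = 2L, fp = 0L, fn = 0L, tn = 2L))
  cc2 <- confusion_counts(!m, m)
  expect_equal(cc2$tp, 0L); expect_equal(cc2$tn, 0L)
  set.seed(11)
  pair <- random_mask_pair()
  expect_equal(unclass(confusion_counts(pair$a, pair$b)),
               bf_confusion(pair$a, pair$b))
  expect_error(confusion_counts(m, matrix(TRUE, 3, 3)), "shape")
})

test_that("dice and rand index follow their count formulas", {
  expect_equal(dice(counts(6, 2, 2, 10)), 0.75)
  expect_equal(dice(counts(0, 3, 4, 10)), 0)
  expect_equal(dice(counts(0, 0, 0, 10)), 1)   # both empty: agreement limit
  expect_equal(rand_index(counts(1, 1, 1, 1)), 0.5)
  m <- matrix(runif(64) < 0.5, 8, 8)
  expect_equal(dice(confusion_counts(m, m)), 1)
  expect_equal(rand_index(confusion_counts(m, m)), 1)
  expect_equal(rand_index(confusion_counts(!m, m)), 0)
})

test_that("voi is an information distance", {
  m <- matrix(runif(64) < 0.4, 8, 8)
  expect_equal(voi(m, m), 0)
  # label permutation also gives zero distance
  expect_equal(voi(!m, m), 0, tolerance = 1e-12)

  # independent labelings: VOI = H(a) + H(b) (product joint)
  a <- matrix(rep(c(TRUE, FALSE), each = 32), 8, 8)       # split by column
  b <- matrix(rep(c(TRUE, FALSE), length.out = 64), 8, 8) # alternate rows
  h <- function(p) -p * log(p) - (1 - p) * log(1 - p)
  expect_equal(voi(a, b), h(0.5) + h(0.5), tolerance = 1e-12)

  set.seed(12)
  for (i in 1:20) {
    pr <- random_mask_pair()
    expect_equal(voi(pr$a, pr$b), bf_voi(pr$a, pr$b), tolerance = 1e-12)
    # information inequality
    pa <- mean(pr$a); pb <- mean(pr$b)
    expect_lte(voi(pr$a, pr$b), h(pa) + h(pb) + 1e-12)
    # base-2 option rescales by log(2)
    expect_equal(voi(pr$a, pr$b, base = 2) * log(2), voi(pr$a, pr$b),
                 tolerance = 1e-12)
  }
})

test_that("gce vanishes for refinements and matches the set oracle", {
  m <- matrix(runif(64) < 0.5, 8, 8)
  expect_equal(gce(m, m), 0)
  # any binary mask refines the all-foreground segmentation
  allfg <- matrix(TRUE, 8, 8)
  sub <- matrix(FALSE, 8, 8); sub[3:5, 3:5] <- TRUE
  expect_equal(gce(sub, allfg), 0)

  set.seed(13)
  for (i in 1:15) {
    pr <- random_mask_pair()
    g <- gce(pr$a, pr$b)
    expect_equal(g, bf_gce(pr$a, pr$b), tolerance = 1e-12)
    expect_equal(g, gce(pr$b, pr$a), tolerance = 1e-12)
    expect_gte(g, 0); expect_lte(g, 1)
  }
})

test_that("bde measures symmetric boundary displacement", {
  m <- matrix(FALSE, 12, 12); m[4:8, 4:8] <- TRUE
  expect_equal(bde(m, m), 0)

  # two single-pixel masks 5 apart
  a <- matrix(FALSE, 10, 10); a[2, 2] <- TRUE
  b <- matrix(FALSE, 10, 10); b[2, 7] <- TRUE
  expect_equal(bde(a, b), 5)
  expect_equal(bde(a, b, "pred_to_truth"), 5)

  # concentric squares: against the all-pairs oracle
  big <- matrix(FALSE, 30, 30); big[4:27, 4:27] <- TRUE
  small <- matrix(FALSE, 30, 30); small[6:25, 6:25] <- TRUE
  expect_equal(bde(big, small), bf_bde(big, small), tolerance = 1e-12)
  expect_equal(bde(big, small), bde(small, big))

  expect_error(bde(matrix(FALSE, 5, 5), m[1:5, 1:5]), "boundary")
})

test_that("mae and psnr work on the display scale", {
  m <- matrix(runif(64) < 0.5, 8, 8)
  expect_equal(mae(m, m), 0)
  expect_equal(psnr(m, m), Inf)
  expect_equal(mae(matrix(FALSE, 4, 4), matrix(TRUE, 4, 4)), 255)
  expect_equal(psnr(matrix(0, 4, 4), matrix(128 / 255, 4, 4)),
               10 * log10(255^2 / 128^2), tolerance = 1e-9)
  # an image off by the full scale everywhere sits at 0 dB
  expect_equal(psnr(matrix(0, 4, 4), matrix(1, 4, 4)), 0)
  set.seed(14)
  pr <- random_mask_pair()
  expect_equal(mae(pr$a, pr$b), bf_mae(pr$a, pr$b), tolerance = 1e-12)
  img1 <- matrix(runif(64), 8, 8); img2 <- matrix(runif(64), 8, 8)
  expect_equal(mae(img1, img2), mean(abs(img1 - img2)) * 255)
})

test_that("classification ratios and kappa follow the confusion table", {
  perfect <- counts(10, 0, 0, 10)
  cm <- classification_metrics(perfect)
  expect_true(all(unlist(cm) == 1))

  cm2 <- classification_metrics(counts(21, 0, 3, 15))
  expect_equal(cm2$accuracy, 36 / 39)
  expect_equal(cm2$sensitivity, 21 / 24)
  expect_equal(cm2$specificity, 1)
  expect_true(is.na(classification_metrics(counts(0, 0, 5, 5))$ppv))

  # all-positive predictor on balanced data
  cm3 <- classification_metrics(counts(10, 10, 0, 0))
  expect_equal(cm3$sensitivity, 1)
  expect_equal(cm3$specificity, 0)

  expect_equal(cohen_kappa(counts(40, 10, 10, 40)), 0.6)
  expect_equal(cohen_kappa(counts(30, 0, 0, 20)), 1)
  # independence (product table) scores zero
  expect_equal(cohen_kappa(counts(36, 24, 24, 16)), 0)
  expect_true(is.na(cohen_kappa(counts(10, 0, 0, 0))))
})

test_that("roc auc equals pairwise concordance and the pROC reference", {
  sep <- roc_auc(c(0.9, 0.8, 0.7, 0.2, 0.1), c(1, 1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)

  scores <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.4)
  labels <- c(0, 0, 1, 1, 1, 0)
  got <- roc_auc(scores, labels)
  expect_equal(got$auc, bf_auc(scores, labels))
  expect_equal(got$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
  expect_equal(got$curve$fpr[1], 0); expect_equal(got$curve$tpr[1], 0)
  expect_equal(got$curve$fpr[nrow(got$curve)], 1)

  set.seed(15)
  for (i in 1:10) {
    s <- runif(20); l <- rbinom(20, 1, 0.5)
    if (sum(l) %in% c(0, 20)) next
    expect_equal(roc_auc(s, l)$auc, bf_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("metric identities and symmetries hold on random pairs", {
  set.seed(16)
  for (i in 1:10) {
    pr <- random_mask_pair(10, 10)
    cc <- confusion_counts(pr$a, pr$b)
    cc_rev <- confusion_counts(pr$b, pr$a)
    expect_equal(dice(cc), dice(cc_rev))
    expect_equal(rand_index(cc), rand_index(cc_rev))
    expect_equal(voi(pr$a, pr$b), voi(pr$b, pr$a))
    expect_equal(bde(pr$a, pr$b), bde(pr$b, pr$a))
  }
})

test_that("metrics_report assembles all seven quantities", {
  set.seed(17)
  pr <- random_mask_pair(12, 12)
  rep <- metrics_report(pr$a, pr$b, params = list(seed = 17))
  expect_named(rep[1:7], c("dice", "rand_index", "voi", "gce", "bde",
                           "psnr", "mae"))
  expect_equal(rep$dice, bf_dice(pr$a, pr$b))
  expect_equal(rep$params$seed, 17)
  # empty prediction: BDE is reported as NA, rest still defined
  empty <- matrix(FALSE, 12, 12)
  r2 <- metrics_report(empty, pr$b)
  expect_true(is.na(r2$bde))
  expect_equal(r2$dice, 0)
})
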