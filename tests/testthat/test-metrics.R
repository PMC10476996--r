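# Classification metrics, geometric metrics vs brute-force oracles,
# superior truncation, Wilcoxon signed-rank.

test_that("classification report reproduces hand-computed metrics", {
  voc <- c("A", "B", "C")
  rep0 <- classification_report(c("A", "A", "A", "B"),
                                c("A", "A", "B", "B"), voc)
  # class A: TP 2, FP 0, FN 1 -> precision 1, recall 2/3, F1 0.8
  pa <- rep0$per_class[rep0$per_class$class == "A", ]
  expect_equal(pa$precision, 1)
  expect_equal(pa$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(pa$f1, 0.8, tolerance = 1e-12)
  # class C never predicted nor present -> 0s with flags
  pc <- rep0$per_class[rep0$per_class$class == "C", ]
  expect_equal(pc$precision, 0)
  expect_true(pc$precision_undefined && pc$recall_undefined)
  expect_equal(rep0$accuracy, 0.75)
  expect_equal(rep0$macro_label_accuracy, mean(c(2 / 3, 1, 0)),
               tolerance = 1e-12)
  # weighted recall is plain accuracy
  expect_equal(unname(rep0$weighted["recall"]), rep0$accuracy,
               tolerance = 1e-12)
  # confusion matrix + row-normalized view
  expect_equal(unname(rep0$confusion["A", "B"]), 1)
  expect_equal(unname(rowSums(rep0$confusion_normalized)[c("A", "B")]),
               c(1, 1))
  # perfect predictions
  perf <- classification_report(c("A", "B"), c("A", "B"), voc)
  expect_equal(unname(perf$macro["f1"] * 0 + perf$accuracy), 1)
  expect_true(all(diag(perf$confusion)[c("A", "B")] == 1))
  expect_error(classification_report("A", "Z", voc), "vocabulary")
})

test_that("dice follows the overlap formula and empty conventions", {
  a <- array(0L, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- 1L          # 8 voxels
  b <- array(0L, c(4, 4, 4)); b[2:3, 1:2, 1:2] <- 1L          # 8, overlap 4
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  disj <- array(0L, c(4, 4, 4)); disj[4, 4, 4] <- 1L
  expect_equal(dice(a, disj), 0)
  both <- dice(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2)))
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_empty"))
})

test_that("hd95/msd match the all-pairs brute-force oracle within 1e-9", {
  spacing <- c(3, 2, 2)
  for (seed in 1:4) {
    a <- random_blob(c(9, 10, 11), seed)
    b <- random_blob(c(9, 10, 11), seed + 50)
    expect_equal(hd95(a, b, spacing), oracle_hd95(a, b, spacing),
                 tolerance = 1e-9)
    expect_equal(msd(a, b, spacing), oracle_msd(a, b, spacing),
                 tolerance = 1e-9)
    expect_equal(dice(a, b), oracle_dice(a, b), tolerance = 1e-9)
    # symmetry
    expect_equal(hd95(a, b, spacing), hd95(b, a, spacing))
    expect_equal(msd(a, b, spacing), msd(b, a, spacing))
  }
})

test_that("geometric metrics scale with spacing; known shifts are exact", {
  a <- array(0L, c(3, 10, 10)); a[2, 2:9, 2:9] <- 1L
  b <- array(0L, c(3, 10, 10)); b[2, 2:9, 3:10] <- 1L  # 1 voxel in-plane
  expect_equal(hd95(a, b, c(3, 2, 2)), 2)              # 2 mm columns
  expect_equal(hd95(a, a, c(3, 2, 2)), 0)
  expect_equal(msd(a, a, c(3, 2, 2)), 0)
  two_planes_a <- array(0L, c(6, 3, 3)); two_planes_a[2, 2, 2] <- 1L
  two_planes_b <- array(0L, c(6, 3, 3)); two_planes_b[3, 2, 2] <- 1L
  expect_equal(msd(two_planes_a, two_planes_b, c(3, 1, 1)), 3)
  # spacing invariance / linearity
  m1 <- random_blob(c(8, 8, 8), 2); m2 <- random_blob(c(8, 8, 8), 12)
  expect_equal(dice(m1, m2), dice(m1, m2))
  expect_equal(hd95(m1, m2, 2 * c(1, 1, 1)),
               2 * hd95(m1, m2, c(1, 1, 1)), tolerance = 1e-9)
  expect_equal(msd(m1, m2, 3 * c(1, 1, 1)),
               3 * msd(m1, m2, c(1, 1, 1)), tolerance = 1e-9)
  expect_error(hd95(m1, array(0L, c(8, 8, 8)), c(1, 1, 1)), "empty")
})

test_that("superior truncation removes only slices above the ground truth", {
  gt <- array(0L, c(10, 4, 4)); gt[3:6, 2:3, 2:3] <- 1L
  pred <- array(0L, c(10, 4, 4)); pred[3:11 - 1, 2:3, 2:3] <- 1L
  tr <- truncate_superior(pred, gt)
  expect_true(all(tr[7:10, , ] == 0))
  expect_identical(tr[1:6, , ], pred[1:6, , ])
  inside <- array(0L, c(10, 4, 4)); inside[4:5, 2, 2] <- 1L
  expect_identical(truncate_superior(inside, gt), inside)
  # truncation never increases HD95 (property, oracle-checked)
  for (seed in 1:3) {
    a <- random_blob(c(8, 9, 9), seed + 100)
    g <- random_blob(c(8, 9, 9), seed + 200)
    t_a <- truncate_superior(a, g)
    if (sum(t_a) == 0) next
    expect_lte(hd95(t_a, g, c(2, 2, 2)),
               hd95(a, g, c(2, 2, 2)) + 1e-12)
    expect_equal(hd95(t_a, g, c(2, 2, 2)),
                 oracle_hd95(t_a, g, c(2, 2, 2)), tolerance = 1e-9)
  }
})

test_that("wilcoxon signed-rank: exact enumeration, conventions, symmetry", {
  # n = 5, all differences positive: 2/32
  w <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(w$p.value, 0.0625)
  expect_equal(w$statistic, 15)
  expect_identical(w$method, "exact enumeration")
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
  set.seed(31)
  a <- rnorm(10); b <- rnorm(10)
  w_ab <- wilcoxon_signed_rank(a, b)
  w_ba <- wilcoxon_signed_rank(b, a)
  expect_equal(w_ab$p.value, w_ba$p.value)
  # agreement with the reference implementation (exact, no ties)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(w_ab$p.value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(w_ab$statistic, unname(ref$statistic))
  # large-n branch: normal approximation close to reference
  set.seed(32)
  a2 <- rnorm(30); b2 <- rnorm(30, 0.5)
  w2 <- wilcoxon_signed_rank(a2, b2)
  ref2 <- stats::wilcox.test(a2, b2, paired = TRUE, exact = FALSE,
                             correct = TRUE)
  expect_identical(w2$method, "normal approximation")
  expect_equal(w2$p.value, unname(ref2$p.value), tolerance = 1e-10)
})
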