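# Evaluation metrics: confusion-table scores, both kappa variants,
# one-vs-rest reports, Dice / IoU and their identity.

test_that("binary metrics match hand arithmetic on constructed tables", {
  m <- binary_metrics(confusion_table(40, 40, 10, 10))
  expect_equal(unlist(m[c("precision", "recall", "f1", "specificity",
                          "npv", "accuracy")]),
               c(precision = 0.8, recall = 0.8, f1 = 0.8, specificity = 0.8,
                 npv = 0.8, accuracy = 0.8))

  perfect <- binary_metrics(confusion_table(10, 5, 0, 0))
  expect_true(all(unlist(perfect) == 1))

  m2 <- binary_metrics(confusion_table(50, 40, 10, 0))
  expect_equal(m2$precision, 50 / 60)
  expect_equal(m2$recall, 1.0)
  expect_equal(m2$f1, 2 * (5 / 6) / (11 / 6))
  expect_equal(round(m2$precision, 4), 0.8333)
  expect_equal(round(m2$f1, 4), 0.9091)
})

test_that("zero denominators give NA with a warning, never 0", {
  expect_warning(m <- binary_metrics(confusion_table(0, 50, 0, 10)),
                 "undefined")
  expect_true(is.na(m$precision))
  expect_equal(m$recall, 0)          # defined: 0/(0+10)
  expect_identical(attr(m, "undefined"), c("precision", "f1"))
  expect_equal(m$specificity, 1)
})

test_that("printed-form kappa follows its chance term exactly", {
  expect_equal(kappa_paper(confusion_table(50, 50, 0, 0)), 1.0)
  # P(a)=0.8, P(e)=(1600+100)/10000=0.17
  expect_equal(kappa_paper(confusion_table(40, 40, 10, 10)),
               (0.8 - 0.17) / (1 - 0.17))
  expect_equal(round(kappa_paper(confusion_table(40, 40, 10, 10)), 4), 0.759)
  # all counts 25: P(a)=0.5, P(e)=0.125
  expect_equal(kappa_paper(confusion_table(25, 25, 25, 25)), 0.375 / 0.875)
  expect_equal(round(kappa_paper(confusion_table(25, 25, 25, 25)), 4), 0.4286)
})

test_that("conventional kappa uses marginal products", {
  expect_equal(kappa_standard(confusion_table(40, 40, 10, 10)), 0.6)
  expect_equal(kappa_standard(confusion_table(30, 30, 0, 0)), 1.0)
  # prediction independent of truth: counts proportional to marginals
  # truth 60/40 positive, prediction 50/50 -> TP=30 FN=30 FP=20 TN=20
  expect_equal(kappa_standard(confusion_table(30, 20, 20, 30)), 0,
               tolerance = 1e-12)
})

test_that("multiclass report equals one-vs-rest collapse", {
  diag4 <- diag(c(5L, 7L, 3L, 9L))
  dimnames(diag4) <- list(smear_classes(), smear_classes())
  rep <- multiclass_report(diag4)
  expect_equal(rep$overall_accuracy, 1)
  for (cl in smear_classes())
    expect_true(all(unlist(rep$per_class[[cl]]) == 1))

  withr::with_seed(8, mc <- matrix(rpois(16, 10), 4, 4,
                                   dimnames = list(smear_classes(),
                                                   smear_classes())))
  rep2 <- multiclass_report(mc)
  expect_equal(rep2$overall_accuracy, sum(diag(mc)) / sum(mc))
  for (k in 1:4) {
    expect_equal(rep2$per_class[[k]]$recall, mc[k, k] / sum(mc[k, ]))
    # oracle equivalence: direct computation on the collapsed table
    ct <- confusion_table(TP = mc[k, k],
                          FN = sum(mc[k, ]) - mc[k, k],
                          FP = sum(mc[, k]) - mc[k, k],
                          TN = sum(mc) - sum(mc[k, ]) - sum(mc[, k]) + mc[k, k])
    expect_equal(rep2$per_class[[k]],
                 suppressWarnings(binary_metrics(ct)),
                 ignore_attr = TRUE)
  }
  expect_error(multiclass_report(matrix(0, 4, 4)), "all zero")
})

test_that("dice and IoU match hand values and their identity", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  expect_equal(dsc(a, a), 1.0)
  expect_equal(iou(a, a), 1.0)

  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_equal(dsc(a, b), 0.0)
  expect_equal(iou(a, b), 0.0)

  c2 <- matrix(0, 4, 4); c2[1:2, 2:3] <- 1    # |A|=|B|=4, overlap 2
  expect_equal(dsc(a, c2), 0.5)
  expect_equal(iou(a, c2), 1 / 3)
  expect_equal(dsc(a, c2), 2 * iou(a, c2) / (1 + iou(a, c2)))

  expect_error(dsc(a, matrix(0, 3, 3)), "shapes")
  expect_error(iou(a, matrix(2, 4, 4)), "binary")
})

test_that("DSC-IoU identity and symmetry hold on random mask pairs", {
  withr::with_seed(13, {
    for (i in 1:100) {
      a <- matrix(rbinom(64, 1, 0.4), 8, 8)
      b <- matrix(rbinom(64, 1, 0.4), 8, 8)
      d <- dsc(a, b); j <- iou(a, b)
      expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
      expect_identical(d, dsc(b, a))
      expect_identical(j, iou(b, a))
      expect_true(d >= 0 && d <= 1 && j >= 0 && j <= 1)
    }
  })
})

test_that("both-empty masks follow the configurable convention", {
  z <- matrix(0, 3, 3)
  expect_equal(dsc(z, z), 1.0)
  expect_equal(iou(z, z), 1.0)
  expect_true(is.na(dsc(z, z, both_empty = NA)))
})

test_that("probability thresholding uses the >= tie rule", {
  expect_equal(prob_to_mask(matrix(0.9, 2, 2)), matrix(1, 2, 2))
  expect_equal(prob_to_mask(0.5, 0.5), 1)
  withr::with_seed(5, p <- matrix(runif(100), 10))
  expect_equal(sum(prob_to_mask(p, 0.3)), sum(p >= 0.3))
  expect_error(prob_to_mask(p, 1.5), "threshold")
  expect_error(prob_to_mask(matrix(2, 2, 2)), "probabilities")
})
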