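# 2x2 construction, performance indicators, odds ratios, association tests,
# AUC and the paired DeLong comparison.

test_that("two_by_two counts partition the sample", {
  t <- two_by_two(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(unlist(t[c("tp", "fn", "fp", "tn")]),
               c(tp = 1, fn = 0, fp = 1, tn = 1))

  t <- two_by_two(rep(TRUE, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(t$fn, 0); expect_equal(t$tn, 0)

  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:80, 1)
    pred <- runif(n) < 0.5; truth <- runif(n) < 0.4
    t <- two_by_two(pred, truth)
    expect_equal(t$tp + t$fn + t$fp + t$tn, n)
    expect_equal(t$tp + t$fn, sum(truth))
  }
  expect_error(two_by_two(c(TRUE, FALSE), TRUE), "equal length")
  # NA pairs dropped pairwise
  t <- two_by_two(c(TRUE, NA, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(t$tp + t$fn + t$fp + t$tn, 2)
})

test_that("performance indicators and Wilson intervals", {
  # cluster abdomen row: 41 of 60 malignant
  pf <- performance(c(41, 19, 36, 80))
  expect_equal(round(100 * pf$sensitivity, 1), 68.3)
  expect_equal(round(100 * pf$specificity, 1), 69.0)

  # SI 2x2 reconstructed from printed sensitivity/specificity
  pf <- performance(c(47, 13, 46, 70))
  expect_equal(round(100 * pf$ppv, 1), 50.5)
  expect_equal(round(100 * pf$npv, 1), 84.3)

  pf <- performance(c(10, 10, 5, 15))
  expect_equal(pf$sensitivity, 0.5)

  # interval bounds ordered and clipped
  for (t in list(c(1, 0, 0, 9), c(0, 8, 3, 5), c(30, 30, 23, 93))) {
    pf <- performance(t)
    for (nm in c("sensitivity", "specificity")) {
      ci <- pf[[paste0(nm, "_ci")]]
      expect_true(ci[1] >= 0 && ci[2] <= 1)
      expect_true(ci[1] <= pf[[nm]] && pf[[nm]] <= ci[2])
    }
  }

  # undefined predictive value is a missing result
  pf <- performance(c(0, 6, 0, 10))  # nobody tests positive
  expect_true(is.na(pf$ppv))
  expect_equal(pf$npv, 10 / 16)

  expect_error(performance(c(0, 0, 3, 7)), "malignant and benign")
})

test_that("Wilson interval endpoints satisfy the score equation", {
  z <- qnorm(0.975)
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(5:200, 1); x <- sample(0:n, 1)
    ci <- wilson_ci(x, n)
    p <- x / n
    for (bound in ci[ci > 0 & ci < 1])
      expect_equal(abs(p - bound) / sqrt(bound * (1 - bound) / n), z,
                   tolerance = 1e-8)
  }
})

test_that("odds ratios: cross-product, Woolf CI, Haldane correction", {
  or <- odds_ratio(c(33, 27, 26, 90))      # cluster pain
  expect_equal(round(or$or, 1), 4.2)
  expect_false(or$corrected)
  expect_true(or$ci_low <= or$or && or$or <= or$ci_high)
  # Woolf CI matches the printed pain-cluster interval at 1 d.p. closely
  expect_equal(round(or$ci_low, 1), 2.2, tolerance = 0.11)
  expect_equal(round(or$ci_high, 1), 8.3, tolerance = 0.11)

  expect_equal(odds_ratio(c(6, 3, 10, 5))$or, 1)  # a*d == b*c

  or <- odds_ratio(c(0, 10, 5, 95))
  expect_true(or$corrected)
  expect_equal(or$or, (0.5 * 95.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_equal(round(or$or, 3), 0.827)

  # two zeros in one margin: undefined
  expect_true(is.na(odds_ratio(c(0, 0, 5, 95))$or))
  expect_true(is.na(odds_ratio(c(0, 10, 0, 95))$or))
})

test_that("association test picks chi-square or Fisher by expected counts", {
  r <- association_test(c(30, 30, 23, 93))  # pelvic pain row
  expect_equal(r$method, "chi_square")
  expect_lt(r$p_value, 0.01)
  # matches stats::chisq.test without continuity correction
  expect_equal(r$p_value,
               chisq.test(matrix(c(30, 30, 23, 93), 2), correct = FALSE)$p.value)

  r <- association_test(c(5, 5, 5, 5))
  expect_equal(r$p_value, 1)

  r <- association_test(c(2, 2, 2, 2))   # expected counts all 2 -> Fisher
  expect_equal(r$method, "fisher")
  expect_equal(r$p_value, 1)

  r <- association_test(c(0, 0, 0, 0))
  expect_true(is.na(r$p_value))
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  enum_fisher <- function(a, b, c_, d) {
    m <- a + b; n <- c_ + d; k <- a + c_
    ks <- max(0, k - n):min(k, m)
    probs <- dhyper(ks, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  set.seed(14)
  for (rep in 1:25) {
    repeat {
      cells <- as.vector(rmultinom(1, sample(8:40, 1), runif(4)))
      m <- matrix(cells, 2)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    r <- association_test(cells)
    if (identical(r$method, "fisher"))
      expect_equal(r$p_value, enum_fisher(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-9)
  }
})

test_that("AUC: worked examples, trapezoid oracle, rank invariance", {
  expect_equal(auc(c(5, 6, 7, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))$auc, 1)
  expect_equal(auc(c(0.9, 0.2, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)

  trapezoid_auc <- function(scores, labels) {
    th <- c(Inf, sort(unique(scores), decreasing = TRUE))
    sens <- vapply(th, function(t) mean(scores[labels] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(scores[!labels] >= t), numeric(1))
    sens <- c(sens, 1); fpr <- c(fpr, 1)
    sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
  }
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(10:60, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- round(rnorm(n, mean = labels), sample(0:2, 1))  # with ties
    a <- auc(scores, labels)$auc
    expect_equal(a, trapezoid_auc(scores, labels), tolerance = 1e-12)
    # invariant under strictly monotone transform
    expect_equal(auc(exp(scores), labels)$auc, a, tolerance = 1e-12)
    expect_true(a >= 0 && a <= 1)
  }
})

test_that("AUC and DeLong agree with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  for (rep in 1:5) {
    n <- 60
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    s1 <- rnorm(n, mean = labels)
    s2 <- rnorm(n, mean = 0.5 * labels)
    r1 <- suppressMessages(pROC::roc(labels, s1, direction = "<"))
    expect_equal(auc(s1, labels)$auc, as.numeric(pROC::auc(r1)),
                 tolerance = 1e-12)
    ci <- suppressMessages(as.numeric(pROC::ci.auc(r1, method = "delong")))
    expect_equal(auc(s1, labels)$ci, pmin(pmax(ci[c(1, 3)], 0), 1),
                 tolerance = 1e-9)

    r2 <- suppressMessages(pROC::roc(labels, s2, direction = "<"))
    dl <- delong_test(s1, s2, labels)
    pr <- suppressMessages(pROC::roc.test(r1, r2, method = "delong",
                                          paired = TRUE))
    expect_equal(dl$p_value, pr$p.value, tolerance = 1e-9)
  }
})

test_that("DeLong degenerate cases", {
  labels <- rep(c(TRUE, FALSE), each = 10)
  s <- rnorm(20)
  r <- delong_test(s, s, labels)
  expect_equal(r$difference, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)

  # separable scores vs their reversal: maximal, fully consistent difference
  s <- c(10:1)
  labels <- c(rep(TRUE, 5), rep(FALSE, 5))
  r <- delong_test(s, 1 - s, labels)
  expect_equal(r$auc_a, 1)
  expect_equal(r$auc_b, 0)
  expect_equal(r$p_value, 0)
  expect_true(r$degenerate)

  expect_error(delong_test(1:5, 1:5, rep(TRUE, 5)), "both classes")
  # a single subject in one class leaves the covariance undefined
  expect_error(delong_test(1:5, 5:1, c(TRUE, rep(FALSE, 4))), "at least two")
  expect_error(delong_test(1:4, 1:5, rep(c(TRUE, FALSE), c(2, 3))), "equal length")
})
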