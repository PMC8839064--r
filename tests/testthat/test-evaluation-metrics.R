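# ROC machinery, operating points, Wilson intervals, McNemar.

test_that("rocCurve enumerates tie-grouped operating points", {
  cv <- rocCurve(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
  pts <- rocPoints(cv)
  expect_equal(pts$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(pts$tpr, c(0, 0.5, 0.5, 1, 1))
})

test_that("rocCurve groups tied scores and rejects one-class input", {
  cv <- rocCurve(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(rocPoints(cv)$fpr, c(0, 1))
  expect_error(rocCurve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("auroc matches the pair-counting oracle exactly", {
  cv <- rocCurve(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
  expect_equal(auroc(cv), 0.75)
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(1:3, 1))  # force ties
    expect_equal(auroc(rocCurve(s, y)), pairCountAuroc(s, y),
                 tolerance = 1e-12)
  }
})

test_that("auroc agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  y <- rbinom(80, 1, 0.5); s <- runif(80)
  expect_equal(auroc(rocCurve(s, y)),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("bounded-error operating points use the conservative step rule", {
  cv <- new("ROCCurve", thresholds = c(Inf, 0.8, 0.5, 0.1),
            fpr = c(0, 0.02, 0.05, 1), tpr = c(0, 0.4, 0.7, 1))
  expect_equal(tprAtFpr(cv, 0.03), 0.4)
  expect_equal(tprAtFpr(cv, 0.05), 0.7)
  expect_equal(tnrAtFnr(cv, 0.3), 0.95)   # FNR at (0.05,0.7) qualifies
  diag <- new("ROCCurve", thresholds = c(Inf, 0), fpr = c(0, 1),
              tpr = c(0, 1))
  expect_equal(tprAtFpr(diag, 0.03), 0)
  # monotone in the bound
  b <- seq(0.01, 0.99, by = 0.07)
  v <- vapply(b, function(f0) tprAtFpr(cv, f0), numeric(1))
  expect_true(all(diff(v) >= 0))
})

test_that("meanROC averages vertically with SEM bands", {
  c1 <- new("ROCCurve", thresholds = c(Inf, 0.5, 0),
            fpr = c(0, 0.5, 1), tpr = c(0, 0.2, 1))
  c2 <- new("ROCCurve", thresholds = c(Inf, 0.5, 0),
            fpr = c(0, 0.5, 1), tpr = c(0, 0.8, 1))
  m <- meanROC(list(c1, c2))
  at <- which.min(abs(m@grid - 0.5))
  expect_equal(m@meanTpr[at], 0.5)
  expect_equal(m@stderr[at], sd(c(0.2, 0.8)) / sqrt(2))
  expect_equal(m@stderr[at], 0.3, tolerance = 1e-12)
  # identical curves -> zero band; mean bounded by pointwise min/max
  m2 <- meanROC(list(c1, c1))
  expect_true(all(m2@stderr == 0))
  tpr1 <- vapply(m@grid, function(g) max(c1@tpr[c1@fpr <= g]), numeric(1))
  tpr2 <- vapply(m@grid, function(g) max(c2@tpr[c2@fpr <= g]), numeric(1))
  expect_true(all(m@meanTpr >= pmin(tpr1, tpr2) - 1e-12))
  expect_true(all(m@meanTpr <= pmax(tpr1, tpr2) + 1e-12))
})

test_that("Wilson interval matches the closed form and its properties", {
  ci <- wilsonInterval(50, 100)
  expect_equal(unname(ci), c(0.4038, 0.5962), tolerance = 1e-3)
  expect_equal(unname(wilsonInterval(0, 20)[1]), 0)
  expect_equal(unname(wilsonInterval(20, 20)[2]), 1)
  expect_error(wilsonInterval(1, 0), "positive")
  # contains k/n; width shrinks with n at fixed k/n
  for (n in c(10, 40, 160)) {
    ci <- wilsonInterval(0.3 * n, n)
    expect_true(ci[1] <= 0.3 && 0.3 <= ci[2])
  }
  w <- vapply(c(10, 40, 160, 640), function(n)
    diff(unname(wilsonInterval(0.3 * n, n))), numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("cost-optimal point minimizes expected cost (exhaustive oracle)", {
  cv <- new("ROCCurve", thresholds = c(Inf, 0.7, 0.4, 0),
            fpr = c(0, 0.1, 0.4, 1), tpr = c(0, 0.8, 0.95, 1))
  expect_equal(costOptimalPoint(cv, 1)[c("fpr", "tpr")],
               list(fpr = 0.1, tpr = 0.8))
  expect_equal(costOptimalPoint(cv, 10)[c("fpr", "tpr")],
               list(fpr = 0, tpr = 0))
  # slope -> 0 degenerates to max TPR
  expect_equal(costOptimalPoint(cv, 1e-9)$tpr, 1)
  set.seed(21)
  for (i in 1:50) {
    k <- sample(3:20, 1)
    fpr <- c(0, sort(runif(k)), 1); tpr <- c(0, sort(runif(k)), 1)
    cv <- new("ROCCurve", thresholds = c(Inf, seq(1, 0, length.out = k + 1)),
              fpr = fpr, tpr = tpr)
    spec <- costSpec(p = sample(1:100, 1), n = sample(1:100, 1),
                     cFP = runif(1, 0.1, 5), cFN = runif(1, 0.1, 5))
    pt <- costOptimalPoint(cv, isoSlope(spec))
    costs <- vapply(seq_along(fpr), function(j)
      expectedCost(list(fpr = fpr[j], tpr = tpr[j]), spec), numeric(1))
    expect_equal(expectedCost(pt, spec), min(costs), tolerance = 1e-12)
  }
})

test_that("expected cost formula and iso-performance slope", {
  spec <- costSpec(p = 100, n = 200, cFP = 3, cFN = 1)
  expect_equal(isoSlope(spec), 6)
  expect_equal(isoSlope(costSpec(100, 200, 1, 3)), 2 / 3)
  expect_equal(isoSlope(costSpec(50, 50, 1, 1)), 1)
  expect_equal(expectedCost(list(fpr = 0, tpr = 1), spec), 0)
  expect_equal(expectedCost(list(fpr = 1, tpr = 1), spec), 3 * 200)
})

test_that("selected operating-point FPR is non-increasing in the cost ratio", {
  set.seed(5)
  for (i in 1:30) {
    k <- sample(3:15, 1)
    cv <- new("ROCCurve", thresholds = c(Inf, seq(1, 0, length.out = k + 1)),
              fpr = c(0, sort(runif(k)), 1), tpr = c(0, sort(runif(k)), 1))
    fprs <- vapply(c(1 / 3, 1, 3), function(ratio)
      costOptimalPoint(cv, isoSlope(costSpec(1, 1.5, ratio, 1)))$fpr,
      numeric(1))
    expect_true(all(diff(fprs) <= 1e-12))
  }
})

test_that("McNemar exact and asymptotic branches behave", {
  tab <- new("ContingencyTable", a = 10L, b = 10L, c = 0L, d = 5L)
  expect_equal(mcnemarTest(tab), 2 * (1 / 2)^10, tolerance = 1e-12)
  expect_equal(mcnemarTest(new("ContingencyTable", a = 0L, b = 5L, c = 5L,
                               d = 0L)), 1)
  # symmetry in b and c
  t1 <- new("ContingencyTable", a = 3L, b = 7L, c = 2L, d = 1L)
  t2 <- new("ContingencyTable", a = 3L, b = 2L, c = 7L, d = 1L)
  expect_equal(mcnemarTest(t1), mcnemarTest(t2))
  expect_warning(p <- mcnemarTest(new("ContingencyTable", a = 4L, b = 0L,
                                      c = 0L, d = 0L)), "discordant")
  expect_equal(p, 1)
  # large-sample branch agrees with stats::mcnemar.test
  tb <- new("ContingencyTable", a = 50L, b = 30L, c = 12L, d = 8L)
  m <- matrix(c(50, 30, 12, 8), 2, byrow = TRUE)
  expect_equal(mcnemarTest(tb), stats::mcnemar.test(m)$p.value,
               tolerance = 1e-12)
})

test_that("contingency tables partition the windows", {
  y <- c(1, 1, 0, 0, 1)
  a <- c(1, 0, 0, 1, 1); b <- c(1, 1, 1, 1, 0)
  tab <- buildContingency(a, b, y)
  expect_equal(tab@a + tab@b + tab@c + tab@d, 5L)
  expect_equal(tab@a, 1L)
  expect_equal(tab@b, 2L)
  expect_equal(tab@c, 1L)
  same <- buildContingency(a, a, y)
  expect_equal(same@b, 0L); expect_equal(same@c, 0L)
  allA <- buildContingency(y, 1 - y, y)
  expect_equal(allA@b, 5L); expect_equal(allA@c, 0L)
  expect_error(buildContingency(a, b[-1], y), "equal length")
})
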