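test_that("Fisher Z test recovers exact identities", {
  ## exactly orthogonal columns: sample correlation 0 -> p = 1, z = 0
  x <- rep(c(1, 1, -1, -1), 13)
  y <- rep(c(1, -1, 1, -1), 13)
  m <- cbind(a = x, b = y)
  ct <- fisherZTest(m, "a", "b")
  expect_identical(ct$zStatistic, 0)
  expect_identical(ct$pValue, 1)
  expect_true(ct$independent)

  ## identical column: clamped correlation, overwhelming significance
  set.seed(1)
  v <- rnorm(40)
  m2 <- cbind(a = v, b = v + rnorm(40, sd = 1e-9))
  ct2 <- fisherZTest(m2, "a", "b")
  expect_lt(ct2$pValue, 1e-10)
  expect_lte(abs(ct2$rPartial), 1)
})

test_that("Fisher Z test is symmetric in x and y", {
  set.seed(2)
  m <- matrix(rnorm(200), ncol = 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  for (cond in list(character(0), "c", c("c", "d"))) {
    p1 <- fisherZTest(m, "a", "b", cond = cond)$pValue
    p2 <- fisherZTest(m, "b", "a", cond = cond)$pValue
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("Fisher Z test rejects insufficient samples and flags degeneracy", {
  m <- matrix(rnorm(12), nrow = 4,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_error(fisherZTest(m, "a", "b", cond = "c"), "insufficient")
  mc <- cbind(a = rnorm(20), b = rep(2, 20))
  ct <- fisherZTest(mc, "a", "b")
  expect_true(ct$degenerate)
  expect_identical(ct$pValue, 1)
})

test_that("conditional Fisher Z p-value agrees with a residual permutation oracle", {
  set.seed(11)
  n <- 50
  g <- rnorm(n)
  x <- 0.5 * g + rnorm(n)
  y <- 0.4 * g + 0.25 * x + rnorm(n)
  m <- cbind(x = x, y = y, g = g)
  pZ <- fisherZTest(m, "x", "y", cond = "g")$pValue

  ## oracle: partial correlation as correlation of residuals; null by
  ## permuting one residual vector
  rx <- residuals(lm(x ~ g))
  ry <- residuals(lm(y ~ g))
  robs <- abs(cor(rx, ry))
  set.seed(12)
  rperm <- replicate(10000, abs(cor(rx, sample(ry))))
  pPerm <- mean(rperm >= robs)
  expect_lt(abs(pZ - pPerm), 0.02)
})

test_that("Welch t-test matches stats::t.test and handles edge cases", {
  a <- c(4.1, 5.2, 3.9, 6.0, 5.5)
  b <- c(7.3, 6.8, 8.1, 7.7, 6.9)
  w <- welchTTest(a, b)
  ref <- t.test(a, b)
  expect_equal(w$pValue, ref$p.value, tolerance = 1e-10)
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)

  ## identical groups: zero mean difference
  expect_identical(welchTTest(a, a)$pValue, 1)
  ## widely separated groups
  set.seed(3)
  expect_lt(welchTTest(rnorm(10, 50), rnorm(10, -50))$pValue, 1e-6)
  ## both groups constant
  expect_warning(w0 <- welchTTest(rep(1, 3), rep(1, 4)), "zero variance")
  expect_identical(w0$pValue, 1)
})

test_that("vectorized per-gene Welch p-values match per-gene t.test", {
  set.seed(4)
  X <- matrix(rnorm(40 * 25), nrow = 40)
  labels <- rep(c(0L, 1L), each = 20)
  pv <- TieSig:::.colWelchP(X, labels)
  pref <- apply(X, 2, function(col) {
    t.test(col[labels == 1], col[labels == 0])$p.value
  })
  expect_equal(pv, pref, tolerance = 1e-12)
})

test_that("BH selection matches the hand-computed step-up rule", {
  ## thresholds at q = 0.2, m = 3: 0.0667, 0.1333, 0.2
  expect_identical(bhFdr(c(0.001, 0.5, 0.9), 0.2), c(TRUE, FALSE, FALSE))
  expect_identical(bhFdr(c(1, 1, 1), 0.2), rep(FALSE, 3))
  expect_identical(bhFdr(0.01, 0.2), TRUE)
  ## step-up: a late small p rescues earlier ones
  expect_identical(bhFdr(c(0.05, 0.06, 0.04), 0.2), rep(TRUE, 3))
  expect_error(bhFdr(c(0.5, 1.2), 0.2), "0, 1")
})

test_that("BH selection is monotone in q", {
  set.seed(5)
  for (i in 1:25) {
    p <- runif(50)^sample(1:3, 1)
    q <- sort(runif(2, 0.01, 0.5))
    s1 <- bhFdr(p, q[1])
    s2 <- bhFdr(p, q[2])
    expect_true(all(s2[s1]))
  }
})

test_that("DeLong comparison satisfies its exact identities", {
  set.seed(6)
  lab <- rep(c(0L, 1L), each = 10)
  s <- rnorm(20)
  ## identical classifiers
  same <- delongAucTest(s, s, lab)
  expect_identical(same$pValue, 1)
  expect_equal(same$aucA, same$aucB)
  ## perfect vs anti-perfect ranking
  sp <- as.numeric(lab)
  pa <- delongAucTest(sp, -sp, lab)
  expect_equal(pa$aucA, 1)
  expect_equal(pa$aucB, 0)
  ## swapping the two score vectors negates z and preserves p
  s2 <- lab + rnorm(20)
  f <- delongAucTest(s, s2, lab)
  r <- delongAucTest(s2, s, lab)
  expect_equal(f$zStatistic, -r$zStatistic, tolerance = 1e-12)
  expect_equal(f$pValue, r$pValue, tolerance = 1e-12)
  expect_error(delongAucTest(s, s2, rep(1L, 20)), "both classes")
})

test_that("DeLong variance agrees with a stratified bootstrap oracle", {
  set.seed(7)
  lab <- rep(c(0L, 1L), each = 6)
  sA <- lab + rnorm(12)
  sB <- lab + rnorm(12, sd = 1.5)
  dl <- delongAucTest(sA, sB, lab)

  aucf <- function(s, l) {
    mean(outer(s[l == 1], s[l == 0], function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(8)
  boot <- replicate(10000, {
    ip <- sample(which(lab == 1), 6, replace = TRUE)
    im <- sample(which(lab == 0), 6, replace = TRUE)
    idx <- c(ip, im)
    aucf(sA[idx], lab[idx]) - aucf(sB[idx], lab[idx])
  })
  expect_lt(abs(dl$varDelta - var(boot)) / var(boot), 0.15)
})

test_that("DeLong p-values match the pROC reference implementation", {
  suppressMessages(library(pROC))
  set.seed(9)
  lab <- rep(c(0L, 1L), each = 25)
  sA <- lab + rnorm(50)
  sB <- 0.5 * lab + rnorm(50)
  mine <- delongAucTest(sA, sB, lab)
  ref <- roc.test(roc(lab, sA, quiet = TRUE), roc(lab, sB, quiet = TRUE),
                  method = "delong", paired = TRUE)
  expect_equal(mine$pValue, ref$p.value, tolerance = 1e-8)
  expect_equal(abs(mine$zStatistic), abs(unname(ref$statistic)),
               tolerance = 1e-8)
})

test_that("DeLong p-values are uniform under the null", {
  set.seed(10)
  lab <- rep(c(0L, 1L), each = 30)
  ps <- replicate(1500, delongAucTest(rnorm(60), rnorm(60), lab)$pValue)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
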