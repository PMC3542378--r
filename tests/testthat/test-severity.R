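test_that("Spearman screening matches hand-computed rank correlations", {
  M <- rbind(P1 = c(1, 2, 3), P2 = c(1, 2, 3))
  colnames(M) <- c("S1", "S2", "S3")
  y <- setNames(c(3, 1, 2), colnames(M))
  ## 1 - 6*6/(3*8) = -0.5 for P1 vs y
  expect_warning(scr <- screenSpearman(M, y, rThreshold = 0.4), "n = 3")
  expect_equal(scr$r[scr$peptideId == "P1"], -0.5)
  y2 <- setNames(c(10, 20, 30), colnames(M))
  expect_warning(scr2 <- screenSpearman(M, y2, rThreshold = 0.9), "n = 3")
  expect_equal(scr2$r, c(1, 1))
  ## the threshold is strict: |r| > 1 never holds
  expect_warning(scr3 <- screenSpearman(M, y2, rThreshold = 1), "n = 3")
  expect_equal(nrow(scr3), 0L)
})

test_that("screening is invariant to strictly monotone transforms", {
  set.seed(14)
  M <- matrix(rexp(20 * 30), nrow = 20,
              dimnames = list(sprintf("P%03d", 1:20),
                              sprintf("S%03d", 1:30)))
  M[sample(length(M), 100)] <- 0
  y <- setNames(rlnorm(30, 6, 0.5), colnames(M))
  a <- screenSpearman(M, y, rThreshold = 0)
  b <- screenSpearman(M^3, y, rThreshold = 0)
  b <- b[match(a$peptideId, b$peptideId), ]
  expect_equal(a$r, b$r, tolerance = 1e-12)
})

test_that("constant inputs are rejected or excluded", {
  M <- rbind(P1 = rep(2, 12), P2 = rexp(12))
  colnames(M) <- sprintf("S%d", 1:12)
  y <- setNames(rnorm(12), colnames(M))
  expect_warning(scr <- screenSpearman(M, y, rThreshold = 0), "constant")
  expect_false("P1" %in% scr$peptideId)
  expect_error(screenSpearman(M, setNames(rep(1, 12), colnames(M))),
               "constant")
})

test_that("a noiseless single predictor is fit exactly", {
  set.seed(2)
  x <- rexp(30, 1 / 100)
  M <- rbind(P1 = x)
  colnames(M) <- sprintf("S%d", 1:30)
  y <- setNames(5 + 3 * log1p(x), colnames(M))
  scr <- screenSpearman(M, y, rThreshold = 0.2)
  fit <- fitSeverity(M, y, scr)
  expect_equal(fit@method, "ols")
  expect_equal(unname(fit@trainingCor["pearson"]), 1, tolerance = 1e-9)
  ## slope on the raw ln(1+x) scale recovers the planted coefficient
  expect_equal(unname(fit@weights / fit@scale), 3, tolerance = 1e-9)
  ## and reduces to closed-form simple regression
  z <- log1p(x)
  expect_equal(unname(fit@weights / fit@scale),
               unname(cov(z, y) / var(z)), tolerance = 1e-10)
})

test_that("ordinary least squares is refused when p >= n", {
  set.seed(7)
  M <- matrix(rexp(12 * 8), nrow = 12,
              dimnames = list(sprintf("P%02d", 1:12), sprintf("S%d", 1:8)))
  y <- setNames(rnorm(8), colnames(M))
  scr <- data.frame(peptideId = rownames(M), r = rep(0.5, 12))
  expect_error(fitSeverity(M, y, scr, method = "ols"), "p >= n")
})

test_that("prediction is self-consistent and ignores irrelevant rows", {
  set.seed(21)
  M <- matrix(rexp(15 * 40, 1 / 50), nrow = 15,
              dimnames = list(sprintf("P%03d", 1:15),
                              sprintf("S%03d", 1:40)))
  u <- rnorm(40)
  M[1:5, ] <- exp(log(pmax(M[1:5, ], 1)) + 2 * rep(u, each = 5))
  y <- setNames(800 + 300 * u + rnorm(40, 0, 60), colnames(M))
  scr <- screenSpearman(M, y, rThreshold = 0.25)
  fit <- fitSeverity(M, y, scr)
  pred <- predictSeverity(fit, M)
  expect_equal(unname(cor(pred, y)),
               unname(fit@trainingCor["pearson"]), tolerance = 1e-12)
  withExtra <- rbind(M, X1 = runif(40))
  expect_equal(predictSeverity(fit, withExtra), pred)
  expect_error(predictSeverity(fit, M[-match(fit@peptideIds[1],
                                             rownames(M)), ]),
               fit@peptideIds[1])
})

test_that("signed-sum variant is an affine function of screened z-scores", {
  set.seed(30)
  M <- matrix(rexp(10 * 30, 1 / 20), nrow = 10,
              dimnames = list(sprintf("P%02d", 1:10),
                              sprintf("S%02d", 1:30)))
  y <- setNames(rnorm(30, 500, 100), colnames(M))
  scr <- screenSpearman(M, y, rThreshold = 0)
  fit <- fitSeverity(M, y, scr, method = "signed-sum")
  expect_equal(fit@method, "signed-sum")
  w <- fit@weights
  expect_equal(length(unique(round(abs(w), 12))), 1L)
  expect_equal(sign(unname(w)), sign(unname(fit@screeningR)))
})

test_that("held-out performance does not beat training on the same cohort", {
  ## optimism property, a scaled-down simulation
  set.seed(17)
  worse <- 0
  for (rep in 1:10) {
    cfg <- cohortConfig(nCases = 80, nControls = 0, nPeptides = 400,
                        nSeverityPeptides = 30, seed = 100 + rep)
    co <- generateCohort(cfg, representation = "matrix")
    htt <- trueHtTKV(co$truth)
    M <- co$truth@matrix
    tr <- names(htt)[1:40]; te <- names(htt)[41:80]
    scr <- screenSpearman(M[, tr], htt[tr])
    if (!nrow(scr)) next
    fit <- fitSeverity(M[, tr], htt[tr], scr)
    val <- predictSeverity(fit, M[, te], htt[te])
    if (val$spearman$r <= fit@trainingCor["spearman"]) worse <- worse + 1
  }
  expect_gte(worse, 8)
})
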