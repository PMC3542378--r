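test_that("AUC matches exhaustive pair counting on worked examples", {
  sc <- c(2, 4, 1, 3)
  lb <- c("ADPKD", "ADPKD", "healthy", "healthy")
  r <- rocAuc(sc, lb)
  expect_equal(r$auc, 0.75)
  ## perfect separation: AUC 1 and the curve passes through (0, 1)
  r2 <- rocAuc(c(5, 6, 1, 2), lb)
  expect_equal(r2$auc, 1.0)
  expect_true(any(r2$curve$fpr == 0 & r2$curve$tpr == 1))
  ## all-tied scores: midrank convention gives exactly one half
  r3 <- rocAuc(rep(1, 10), rep(c("ADPKD", "healthy"), 5))
  expect_equal(r3$auc, 0.5)
  expect_error(rocAuc(1:3, rep("ADPKD", 3)), "both classes")
})

test_that("AUC equals pair counting on random small inputs", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    sc <- sample(round(rnorm(n), 1))     # coarse rounding forces ties
    case <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(case)) < 2) next
    lb <- ifelse(case, "ADPKD", "healthy")
    expect_equal(rocAuc(sc, lb)$auc, pairCountAuc(sc, case),
                 tolerance = 1e-12)
  }
})

test_that("DeLong interval agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  sc <- rnorm(60) + rep(c(1, 0), c(20, 40))
  lb <- rep(c("ADPKD", "healthy"), c(20, 40))
  mine <- rocAuc(sc, lb)
  ref <- pROC::ci.auc(pROC::roc(response = lb, predictor = sc,
                                levels = c("healthy", "ADPKD"),
                                direction = "<", quiet = TRUE),
                      method = "delong")
  expect_equal(mine$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(mine$ci, as.numeric(ref[c(1, 3)]), tolerance = 1e-9)
})

test_that("operating points carry exact binomial intervals", {
  ## no false positive among 16 controls: specificity 100%,
  ## lower exact bound 1 - 0.025^(1/16) on the complement scale = 79.4%
  op <- countsOperatingPoint(TN = 16, FP = 0)
  expect_equal(op$specificity$estimate, 1)
  expect_equal(op$specificity$lower, 0.025^(1 / 16), tolerance = 1e-12)
  expect_equal(100 * op$specificity$lower, 79.4, tolerance = 0.05)
  expect_equal(op$specificity$upper, 1)
  ## agreement with the exact binomial test's interval
  op2 <- countsOperatingPoint(TP = 189, FN = 35)
  bt <- binom.test(189, 224)
  expect_equal(c(op2$sensitivity$lower, op2$sensitivity$upper),
               as.numeric(bt$conf.int), tolerance = 1e-12)
})

test_that("score-based and count-based operating points agree", {
  sc <- c(0.5, 0.9, -0.2, 0.1, -0.6)
  lb <- c("ADPKD", "ADPKD", "ADPKD", "healthy", "healthy")
  op <- operatingPoint(sc, lb, cutoff = 0)
  expect_equal(unname(op$counts), c(2L, 1L, 1L, 1L))  # TP FP TN FN
  expect_equal(op$sensitivity$estimate, 2 / 3)
  ## all samples above the cutoff
  op2 <- operatingPoint(sc, lb, cutoff = -1)
  expect_equal(op2$sensitivity$estimate, 1)
  expect_equal(op2$specificity$estimate, 0)
})

test_that("pooling sums counts and recomputes proportions", {
  crisp <- countsOperatingPoint(TP = 189, FN = 224 - 189, cutoff = -0.169)
  suisse <- countsOperatingPoint(TP = 23, FN = 27 - 23, cutoff = -0.169)
  pooled <- poolCohorts(list(crisp, suisse))
  expect_equal(pooled$counts[["TP"]], 212)
  expect_equal(round(100 * pooled$sensitivity$estimate, 1), 84.5)

  healthy <- countsOperatingPoint(TN = 81, FP = 5, cutoff = -0.169)
  diseased <- countsOperatingPoint(TN = 481 - 47, FP = 47,
                                   cutoff = -0.169)
  spec <- poolCohorts(list(healthy, diseased))
  expect_equal(round(100 * spec$specificity$estimate, 1), 90.8)

  ## self-pooling doubles counts but leaves proportions unchanged
  dbl <- poolCohorts(list(crisp, crisp))
  expect_equal(unname(dbl$counts), unname(2 * crisp$counts))
  expect_equal(dbl$sensitivity$estimate, crisp$sensitivity$estimate)

  other <- countsOperatingPoint(TP = 5, FN = 5, cutoff = -0.4)
  expect_error(poolCohorts(list(crisp, other)), "different cutoffs")
})

test_that("pooling commutes with concatenating score vectors", {
  set.seed(31)
  s1 <- rnorm(40); l1 <- rep(c("ADPKD", "healthy"), 20)
  s2 <- rnorm(30); l2 <- rep(c("ADPKD", "healthy"), 15)
  ct <- 0.1
  pooled <- poolCohorts(list(operatingPoint(s1, l1, ct),
                             operatingPoint(s2, l2, ct)))
  direct <- operatingPoint(c(s1, s2), c(l1, l2), ct)
  expect_identical(pooled$counts, direct$counts)
})

test_that("subgroup tables behave monotonically in the cutoff", {
  set.seed(9)
  n <- 80
  md <- data.frame(sampleId = sprintf("S%02d", 1:n),
                   age = sample(18:55, n, TRUE),
                   genotype = sample(c("PKD1", "PKD2", "none"), n, TRUE,
                                     prob = c(0.6, 0.2, 0.2)))
  lb <- rep(c("ADPKD", "healthy"), each = n / 2)
  sc <- setNames(rnorm(n) + (lb == "ADPKD"), md$sampleId)
  tab <- subgroupReport(sc, lb, md, cutoffs = c(-0.5, 0, 0.5))
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$sensAll) <= 0))      # higher cutoff, lower sens
  expect_true(all(diff(tab$specAll) >= 0))
  ## all-young cohort flags the empty column
  mdY <- md; mdY$age <- 25
  expect_warning(subgroupReport(sc, lb, mdY, cutoffs = 0), "Age30Plus")
})

test_that("clinical correlation table reports Spearman rho and p", {
  set.seed(12)
  n <- 40
  tkv <- rlnorm(n, 7, 0.5)
  cl <- data.frame(sampleId = sprintf("S%02d", 1:n), tkv = tkv,
                   egfr = rnorm(n, 90, 20),
                   sparse = c(rnorm(5), rep(NA, n - 5)))
  sc <- setNames(tkv, cl$sampleId)          # score equal to TKV
  expect_message(tab <- correlateClinical(sc, cl), "sparse")
  expect_equal(tab$rho[tab$variable == "tkv"], 1.0)
  expect_false("sparse" %in% tab$variable)
  expect_true(all(c("variable", "rho", "p") %in% names(tab)))
})

test_that("TKV growth rates follow the regression definitions", {
  s <- data.frame(timeYears = 0:2, tkvMl = c(1000, 1100, 1200))
  g <- tkvGrowth(s, height = 1.70)
  expect_equal(g$absRate, 100)
  ## slope of ln TKV = ln(1.2)/2 -> 9.54 %/yr
  expect_equal(g$relRate, (exp(log(1.2) / 2) - 1) * 100, tolerance = 1e-9)
  expect_equal(round(g$relRate, 2), 9.54, tolerance = 0.01)
  expect_equal(tkvGrowth(data.frame(timeYears = 0, tkvMl = 1023),
                         1.70)$httkv, 601.76, tolerance = 1e-4)
  expect_true(is.na(tkvGrowth(data.frame(timeYears = 0, tkvMl = 1023),
                              1.70)$absRate))
})

test_that("weaker planted effects in PKD2 cases show up as lower sensitivity", {
  ## scores built directly: PKD1 cases shifted further from controls
  ## than PKD2 cases, as genotype-dependent disease signal would be
  ok <- 0
  for (r in 1:50) {
    set.seed(400 + r)
    nCase <- 60; nCtrl <- 60
    geno <- sample(c("PKD1", "PKD2"), nCase, TRUE, prob = c(0.7, 0.3))
    shift <- ifelse(geno == "PKD1", 1.6, 0.7)
    sc <- setNames(c(rnorm(nCase) + shift, rnorm(nCtrl)),
                   sprintf("S%03d", seq_len(nCase + nCtrl)))
    lb <- rep(c("ADPKD", "healthy"), c(nCase, nCtrl))
    md <- data.frame(sampleId = names(sc),
                     age = sample(18:50, nCase + nCtrl, TRUE),
                     genotype = c(geno, rep("none", nCtrl)))
    tab <- subgroupReport(sc, lb, md, cutoffs = 0.5)
    if (isTRUE(tab$sensPKD1 > tab$sensPKD2)) ok <- ok + 1
  }
  expect_gte(ok / 50, 0.9)
})

test_that("a score independent of the clinic shows no correlation", {
  ok <- 0
  for (r in 1:20) {
    set.seed(500 + r)
    n <- 200
    cl <- data.frame(sampleId = sprintf("S%03d", 1:n),
                     tkv = rlnorm(n, 7, 0.5), egfr = rnorm(n, 90, 25))
    sc <- setNames(rnorm(n), cl$sampleId)
    tab <- correlateClinical(sc, cl)
    if (all(abs(tab$rho) < 0.2)) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.95)
})
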