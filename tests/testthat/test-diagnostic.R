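test_that("a separable toy problem is learned perfectly", {
  fix <- separableMatrix()
  m <- trainSvm(fix$M, fix$labels, markerIds = rownames(fix$M),
                grid = list(cost = c(1, 10), gamma = c(0.1, 1)),
                cv = "kfold", k = 5)
  s <- scoreSamples(m, fix$M)
  case <- fix$labels == "ADPKD"
  expect_gt(min(s[case]), max(s[!case]))
  roc <- rocAuc(s, fix$labels)
  expect_equal(roc$auc, 1.0)
})

test_that("negating the class labels negates all margin scores", {
  fix <- separableMatrix(nCase = 10, nCtrl = 10, gap = 1.5, seed = 2)
  flipped <- ifelse(fix$labels == "ADPKD", "healthy", "ADPKD")
  m1 <- trainSvm(fix$M, fix$labels, markerIds = rownames(fix$M),
                 grid = list(cost = 10, gamma = 0.5), cv = "kfold", k = 5,
                 caseLabel = "ADPKD")
  m2 <- trainSvm(fix$M, flipped, markerIds = rownames(fix$M),
                 grid = list(cost = 10, gamma = 0.5), cv = "kfold", k = 5,
                 caseLabel = "ADPKD")
  s1 <- scoreSamples(m1, fix$M)
  s2 <- scoreSamples(m2, fix$M)
  expect_equal(unname(s1), unname(-s2), tolerance = 1e-6)
})

test_that("margin scores are the kernel decision values over the w-norm", {
  fix <- separableMatrix(gap = 1.2, seed = 5)
  m <- trainSvm(fix$M, fix$labels, markerIds = rownames(fix$M),
                grid = list(cost = 10, gamma = 0.3), cv = "kfold", k = 5)
  s <- scoreSamples(m, fix$M)
  ## recompute decision values from the support set by hand
  X <- t(log1p(fix$M[m@markerIds, , drop = FALSE]))
  X <- sweep(sweep(X, 2, m@featureMin, "-"), 2,
             m@featureMax - m@featureMin, "/")
  fit <- m@fit
  K <- exp(-m@gamma * as.matrix(dist(rbind(fit$SV, X)))^2)
  K <- K[-seq_len(nrow(fit$SV)), seq_len(nrow(fit$SV)), drop = FALSE]
  dv <- as.numeric(K %*% fit$coefs) - fit$rho
  if (m@flip) dv <- -dv
  expect_equal(unname(s), dv / m@wNorm, tolerance = 1e-9)
})

test_that("scores ignore peptides outside the marker panel", {
  fix <- separableMatrix(seed = 3)
  m <- trainSvm(fix$M, fix$labels, markerIds = rownames(fix$M),
                grid = list(cost = 1, gamma = 0.1), cv = "kfold", k = 5)
  extra <- rbind(fix$M, Q999 = runif(ncol(fix$M)))
  expect_equal(scoreSamples(m, fix$M), scoreSamples(m, extra))
  expect_error(scoreSamples(m, fix$M[-1, , drop = FALSE]), "P001")
})

test_that("marker order does not change the model's scores", {
  fix <- separableMatrix(p = 4, seed = 9)
  ids <- rownames(fix$M)
  m1 <- trainSvm(fix$M, fix$labels, markerIds = ids,
                 grid = list(cost = 10, gamma = 0.2), cv = "kfold", k = 5)
  m2 <- trainSvm(fix$M, fix$labels, markerIds = rev(ids),
                 grid = list(cost = 10, gamma = 0.2), cv = "kfold", k = 5)
  expect_equal(scoreSamples(m1, fix$M), scoreSamples(m2, fix$M),
               tolerance = 1e-9)
})

test_that("constant features are dropped with a warning", {
  fix <- separableMatrix(p = 3, seed = 4)
  fix$M[3, ] <- 7
  expect_warning(
    m <- trainSvm(fix$M, fix$labels, markerIds = rownames(fix$M),
                  grid = list(cost = 1, gamma = 0.3), cv = "kfold", k = 5),
    "constant")
  expect_equal(length(markerPanel(m)), 2L)
})

test_that("training a single class is refused", {
  fix <- separableMatrix()
  expect_error(trainSvm(fix$M, rep("ADPKD", ncol(fix$M)),
                        markerIds = rownames(fix$M)), "two classes")
})

test_that("pruning removes redundant and keeps informative markers", {
  fix <- separableMatrix(nCase = 15, nCtrl = 15, p = 3, gap = 1,
                         seed = 12)
  M <- rbind(fix$M, DUP = fix$M[1, ])
  pr <- takeOneOutPrune(M, fix$labels, markerIds = rownames(M),
                        cost = 10, gamma = 0.3, cv = "kfold", k = 5)
  expect_lt(sum(c("P001", "DUP") %in% pr$markers), 2L)

  same <- takeOneOutPrune(M, fix$labels, markerIds = rownames(M),
                          cost = 10, gamma = 0.3,
                          targetSize = nrow(M), cv = "kfold", k = 5)
  expect_setequal(same$markers, rownames(M))
  expect_error(takeOneOutPrune(M, fix$labels, markerIds = rownames(M),
                               cost = 10, gamma = 0.3,
                               targetSize = 10), "exceeds")
})

test_that("the Youden cutoff is the midpoint bracketing maximal J", {
  sc <- c(0.8, 0.9, 0.1, 0.2)
  lb <- c("ADPKD", "ADPKD", "healthy", "healthy")
  expect_equal(chooseCutoff(sc, lb), 0.5)
  ## perfect separation: sensitivity and specificity both 1 at the cutoff
  op <- operatingPoint(sc, lb, chooseCutoff(sc, lb))
  expect_equal(op$sensitivity$estimate, 1)
  expect_equal(op$specificity$estimate, 1)
})

test_that("the chosen cutoff attains the exhaustive-scan maximum J", {
  set.seed(6)
  for (rep in 1:10) {
    sc <- round(rnorm(30), 2)
    lb <- sample(rep(c("ADPKD", "healthy"), 15))
    ct <- chooseCutoff(sc, lb)
    case <- lb == "ADPKD"
    jOf <- function(t) mean(sc[case] >= t) + mean(sc[!case] < t) - 1
    grid <- sort(unique(c(sc - 1e-9, sc + 1e-9)))
    expect_equal(jOf(ct), max(vapply(grid, jOf, numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("cutoff selection requires both classes and non-constant scores", {
  expect_error(chooseCutoff(c(1, 2), c("ADPKD", "ADPKD")), "two classes")
  expect_error(chooseCutoff(c(1, 1), c("ADPKD", "healthy")), "constant")
})
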