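test_that("one-hot encoding sets exactly one indicator per position block", {
  E <- encodePeptides("AAAAAA")
  expect_equal(dim(E), c(1L, 120L))
  expect_equal(sum(E), 6)
  expect_equal(unname(E[1, paste0("p", 1:6, ".A")]), rep(1, 6))

  pep <- randomPeptides(100, seed = 131)
  E <- encodePeptides(pep)
  blocks <- matrix(seq_len(120), 20)
  for (j in 1:6) expect_equal(unname(rowSums(E[, blocks[, j]])), rep(1, 100))
  expect_equal(rowSums(E), setNames(rep(6, 100), NULL))
})

test_that("decode inverts encode on random peptides", {
  pep <- randomPeptides(1000, seed = 141)
  expect_identical(decodePeptides(encodePeptides(pep)), pep)
})

test_that("naive Bayes estimates the Laplace-smoothed tables and priors", {
  ds <- HexDataset(c("NNQQNY", "AAAAAA"), c(TRUE, FALSE))
  nb <- trainNaiveBayes(ds, alpha = 1)
  expect_equal(unname(nb@priors), c(0.5, 0.5))
  ## P(N | pos 1, amyloid) = (1 + 1) / (1 + 20)
  expect_equal(unname(nb@tables["N", 1, "amyloidogenic"]), 2 / 21)
  expect_equal(unname(nb@tables["A", 1, "non-amyloidogenic"]), 2 / 21)
  expect_equal(unname(nb@tables["W", 3, "amyloidogenic"]), 1 / 21)
  ## all 12 conditional tables sum to 1
  expect_equal(as.vector(apply(nb@tables, c(2, 3), sum)), rep(1, 12),
               tolerance = 1e-12)
  expect_error(trainNaiveBayes(HexDataset("AAAAAA", TRUE)), "both classes")
})

test_that("naive Bayes recovers the generating frequencies on synthetic data", {
  cfg <- sequenceGeneratorConfig(n = 10000, prior = 0.5, seed = 151)
  ds <- samplePeptides(cfg)
  nb <- trainNaiveBayes(ds)
  expect_lt(max(abs(nb@tables[, , "amyloidogenic"] - cfg$positivePFM)), 0.02)
  expect_lt(max(abs(nb@tables[, , "non-amyloidogenic"] - cfg$negativePFM)), 0.02)
})

test_that("naive Bayes posteriors normalize and match a direct joint-probability oracle", {
  ds <- randomSmallDataset(50, seed = 161)
  nb <- trainNaiveBayes(ds)
  probe <- randomPeptides(50, seed = 162)
  post <- predict(nb, probe, type = "prob")
  ## independent oracle: direct product of probabilities, no log space
  jointOracle <- vapply(probe, function(p) {
    res <- strsplit(p, "")[[1]]
    jp <- nb@priors[2]; jn <- nb@priors[1]
    for (j in 1:6) {
      jp <- jp * nb@tables[res[j], j, "amyloidogenic"]
      jn <- jn * nb@tables[res[j], j, "non-amyloidogenic"]
    }
    jp / (jp + jn)
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(post, jointOracle, tolerance = 1e-10)
  expect_true(all(post > 0 & post < 1))

  ## symmetry: equal priors and identical tables give posterior 1/2
  sym <- nb
  sym@priors <- c("non-amyloidogenic" = 0.5, "amyloidogenic" = 0.5)
  sym@tables[, , 1] <- sym@tables[, , 2]
  expect_equal(predict(sym, probe, type = "prob"), rep(0.5, 50))

  ## duplicating the training set leaves the model unchanged
  nb2 <- trainNaiveBayes(c(ds, ds), alpha = 0)
  nb0 <- trainNaiveBayes(ds, alpha = 0)
  expect_equal(nb2@priors, nb0@priors)
  expect_equal(nb2@tables, nb0@tables, tolerance = 1e-12)
})

test_that("a single informative position drives the posterior monotonically", {
  ds <- randomSmallDataset(60, seed = 171)
  nb <- trainNaiveBayes(ds)
  base <- "NNQANY"
  ## cysteine is excluded: sanitization folds it into serine before scoring
  variants <- vapply(ALPHA19, function(r) {
    p <- base; substr(p, 4, 4) <- r; p
  }, "")
  post <- predict(nb, variants, type = "score")  # log posterior ratio
  lr <- nb@tables[ALPHA19, 4, "amyloidogenic"] /
    nb@tables[ALPHA19, 4, "non-amyloidogenic"]
  ## posterior strictly ordered by the position's likelihood ratio
  ## (ratios equal to within float rounding count as ties)
  for (i in 1:18) for (j in (i + 1):19) {
    if (isTRUE(all.equal(lr[[i]], lr[[j]], tolerance = 1e-12))) next
    if (lr[i] < lr[j]) expect_lt(post[i], post[j])
    if (lr[i] > lr[j]) expect_gt(post[i], post[j])
  }
})

test_that("the perceptron is deterministic under a seed and separates the toy set", {
  ds <- toySeparableDataset()
  m1 <- trainMLP(ds, hidden = 6, epochs = 100, seed = 7)
  m2 <- trainMLP(ds, hidden = 6, epochs = 100, seed = 7)
  expect_identical(m1@W1, m2@W1)
  expect_identical(m1@lossTrace, m2@lossTrace)
  m3 <- trainMLP(ds, hidden = 6, epochs = 100, seed = 8)
  expect_false(identical(m1@W1, m3@W1))

  ## linearly separable data -> perfect training accuracy
  big <- {
    pep <- randomPeptides(20, seed = 181)
    lab <- rep(c(TRUE, FALSE), 10)
    tmp <- pep[lab]; substr(tmp, 4, 4) <- "I"; pep[lab] <- tmp
    tmp <- pep[!lab]; substr(tmp, 4, 4) <- "P"; pep[!lab] <- tmp
    HexDataset(pep, lab)
  }
  mlp <- trainMLP(big, hidden = 6, epochs = 500, seed = 0)
  expect_equal(predict(mlp, big, type = "class"), isAmyloid(big))
  ## SGD loss trend on the separable fixture: start high, end low
  expect_lt(mean(tail(mlp@lossTrace, 10)), mean(head(mlp@lossTrace, 10)))
})

test_that("the forward pass matches an independent re-implementation and stays in (0,1)", {
  set.seed(191)
  W1 <- matrix(rnorm(120 * 5), 120, 5)
  model <- new("MLPModel", W1 = W1, b1 = rnorm(5), W2 = rnorm(5),
               b2 = rnorm(1),
               hyper = list(hidden = 5L, learningRate = 0.1, momentum = 0.2,
                            epochs = 0L, seed = 0L),
               lossTrace = numeric(0))
  probe <- randomPeptides(40, seed = 192)
  got <- predict(model, probe)
  ## naive per-peptide re-implementation
  sig <- function(x) 1 / (1 + exp(-x))
  oracle <- vapply(probe, function(p) {
    x <- as.numeric(encodePeptides(p))
    h <- sig(colSums(x * model@W1) + model@b1)
    sig(sum(h * model@W2) + model@b2)
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(got > 0 & got < 1))

  ## all-zero weights -> sigmoid(0) = 0.5 everywhere
  zero <- new("MLPModel", W1 = matrix(0, 120, 5), b1 = rep(0, 5),
              W2 = rep(0, 5), b2 = 0, hyper = model@hyper,
              lossTrace = numeric(0))
  expect_equal(predict(zero, probe), rep(0.5, 40))
})

test_that("the analytic training gradient matches finite differences", {
  set.seed(201)
  hidden <- 4L
  for (rep in 1:20) {
    W1 <- matrix(runif(120 * hidden, -0.5, 0.5), 120, hidden)
    b1 <- runif(hidden, -0.5, 0.5); W2 <- runif(hidden, -0.5, 0.5)
    b2 <- runif(1, -0.5, 0.5)
    act <- sort(sample(0:119, 6))  # active 0-based columns, one per block not required here
    y <- sample(0:1, 1)
    g <- AmyloHex:::mlp_instance_grad_cpp(act, y, W1, b1, W2, b2)
    lossAt <- function(W1., b1., W2., b2.)
      AmyloHex:::mlp_instance_loss_cpp(act, y, W1., b1., W2., b2.)
    h <- 1e-6
    ## a few random W1 coordinates (active and inactive rows)
    for (probe in 1:4) {
      i <- sample(1:120, 1); j <- sample(1:hidden, 1)
      Wp <- W1; Wp[i, j] <- Wp[i, j] + h
      Wm <- W1; Wm[i, j] <- Wm[i, j] - h
      fd <- (lossAt(Wp, b1, W2, b2) - lossAt(Wm, b1, W2, b2)) / (2 * h)
      expect_equal(g$dW1[i, j], fd, tolerance = 1e-4)
    }
    j <- sample(1:hidden, 1)
    bp <- b1; bp[j] <- bp[j] + h; bm <- b1; bm[j] <- bm[j] - h
    fd <- (lossAt(W1, bp, W2, b2) - lossAt(W1, bm, W2, b2)) / (2 * h)
    expect_equal(g$db1[j], fd, tolerance = 1e-4)
    wp <- W2; wp[j] <- wp[j] + h; wm <- W2; wm[j] <- wm[j] - h
    fd <- (lossAt(W1, b1, wp, b2) - lossAt(W1, b1, wm, b2)) / (2 * h)
    expect_equal(g$dW2[j], fd, tolerance = 1e-4)
    fd <- (lossAt(W1, b1, W2, b2 + h) - lossAt(W1, b1, W2, b2 - h)) / (2 * h)
    expect_equal(g$db2, fd, tolerance = 1e-4)
  }
})
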