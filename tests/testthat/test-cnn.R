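test_that("architecture identities are derived, not stored", {
  on <- buildOnTargetNet(1)
  expect_identical(convShape(on@spec), c(12L, 22L))
  expect_identical(pooledShape(on@spec), c(6L, 11L))
  expect_identical(flattenSize(on@spec), 3300L)
  expect_identical(on@spec@denseUnits, 650L)
  off <- buildOffTargetNet(1)
  expect_identical(convShape(off@spec), c(6L, 21L))
  expect_identical(pooledShape(off@spec), c(3L, 10L))
  expect_identical(flattenSize(off@spec), 1050L)
  expect_identical(off@spec@denseUnits, 300L)
  ## order variants
  o1 <- buildOnTargetNet(1, order = 1)
  expect_identical(o1@spec@inputShape, c(4L, 27L))
  expect_identical(o1@spec@kernel, c(4L, 1L))
  expect_identical(o1@spec@pool, c(1L, 2L))
  o3 <- buildOnTargetNet(1, order = 3)
  expect_identical(o3@spec@inputShape, c(64L, 25L))
  ## 40-nt context variant keeps the same stage, wider input
  o40 <- buildOnTargetNet(1, order = 2, L = 40)
  expect_identical(o40@spec@inputShape, c(16L, 39L))
  ## seeded init is reproducible
  expect_identical(buildOnTargetNet(5)@W1, buildOnTargetNet(5)@W1)
  expect_false(identical(buildOnTargetNet(5)@W1, buildOnTargetNet(6)@W1))
})

test_that("valid convolution matches a naive sliding-window oracle", {
  set.seed(10)
  input <- matrix(rnorm(9 * 11), 9, 11)
  filters <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  bias <- c(0.3, -0.2)
  out <- convValid(input, filters, bias, relu = TRUE)
  expect_identical(dim(out), c(7L, 8L, 2L))
  for (f in 1:2) for (r in 1:7) for (c in 1:8) {
    v <- sum(input[r:(r + 2), c:(c + 3)] * filters[, , f]) + bias[f]
    expect_equal(out[r, c, f], max(v, 0), tolerance = 1e-12)
  }
  ## printed shape identities
  expect_identical(dim(convValid(matrix(0, 16, 26),
                                 array(0, c(5, 5, 50)))), c(12L, 22L, 50L))
  expect_identical(dim(convValid(matrix(0, 12, 27),
                                 array(0, c(7, 7, 35)))), c(6L, 21L, 35L))
  ## zero input and zero bias give zero maps
  expect_true(all(convValid(matrix(0, 16, 26),
                            array(rnorm(25 * 5), c(5, 5, 5))) == 0))
  expect_error(convValid(matrix(0, 4, 4), array(0, c(5, 5, 1))), "larger")
})

test_that("sum pooling sums 2x2 blocks and truncates odd edges", {
  expect_identical(dim(sumPool(matrix(1, 12, 22))), c(6L, 11L))
  expect_true(all(sumPool(matrix(1, 12, 22)) == 4))
  expect_identical(dim(sumPool(matrix(1, 6, 21))), c(3L, 10L))
  set.seed(11)
  m <- matrix(rnorm(8 * 10), 8, 10)
  p <- sumPool(m)
  for (i in 1:4) for (j in 1:5)
    expect_equal(p[i, j], sum(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]),
                 tolerance = 1e-12)
  ## conservation when both dimensions are even
  expect_equal(sum(p), sum(m), tolerance = 1e-12)
  ## truncation drops the trailing odd column
  m2 <- matrix(rnorm(6 * 21), 6, 21)
  expect_equal(sum(sumPool(m2)), sum(m2[, 1:20]), tolerance = 1e-12)
})

test_that("untrained classifiers score exactly 0.5 and predict order-preserving", {
  set.seed(12)
  on <- buildOnTargetNet(3)
  X <- lapply(1:7, function(i) encodeOrderK(randomSeq(27), 2))
  expect_true(all(predict(on, X) == 0.5))
  ## duplicates score identically; batching does not change scores
  clf <- sharedOnTargetModel()
  Xd <- c(X, X)
  sc <- predict(clf, Xd)
  expect_equal(sc[1:7], sc[8:14])
  one <- vapply(Xd, function(m) predict(clf, list(m), batchSize = 1L),
                numeric(1))
  expect_equal(sc, one, tolerance = 1e-12)
  expect_error(predict(clf, list(encodeMismatchPair(randomTarget(),
                                                    randomTarget()))),
               "input shape")
})

test_that("training is deterministic, resumable from epoch zero, and learns", {
  d <- separableData(200, seed = 21)
  X <- lapply(d$sequences, encodeOrderK, k = 2)
  net <- buildOnTargetNet(1)
  ## epochs = 0 leaves the weights untouched
  c0 <- trainClassifier(net, X, d$y, epochs = 0, seed = 1)
  expect_identical(c0@W1, net@W1)
  expect_identical(c0@convW, net@convW)
  ## same data + seed + epochs -> identical predictions
  c1 <- trainClassifier(net, X, d$y, epochs = 8, seed = 5)
  c2 <- trainClassifier(net, X, d$y, epochs = 8, seed = 5)
  expect_identical(predict(c1, X), predict(c2, X))
  ## a single dinucleotide rule is learned to a perfect training AUC
  c3 <- trainClassifier(net, X, d$y, epochs = 30, seed = 5)
  expect_equal(rocAuc(predict(c3, X), d$y)$auc, 1.0)
  ## loss decreases on separable data
  expect_lt(c3@history[length(c3@history)], c3@history[1])
  ## degenerate labels rejected
  expect_error(trainClassifier(net, X, rep(1, length(X)), epochs = 1),
               "each class")
})

test_that("compiled and reference training engines agree", {
  d <- separableData(60, seed = 31)
  X <- lapply(d$sequences, encodeOrderK, k = 2)
  net <- buildOffTargetNet(2)
  Xm <- lapply(seq_along(X), function(i) {
    g <- randomTarget()
    encodeMismatchPair(g, mutateAt(g, sample(5:27, 1 + d$y[i] * 3)))
  })
  cc <- trainClassifier(net, Xm, d$y, epochs = 4, seed = 9,
                        engine = "compiled")
  cr <- trainClassifier(net, Xm, d$y, epochs = 4, seed = 9,
                        engine = "reference")
  expect_equal(predict(cc, Xm), predict(cr, Xm), tolerance = 1e-10)
  expect_equal(cc@history, cr@history, tolerance = 1e-10)
})

test_that("receptive fields delimit exactly the influential input cells", {
  on <- buildOnTargetNet(4)
  spec <- on@spec
  ## neuron 1 = map 1, pooled cell (1,1): upper-left 6x6 block
  rf1 <- flattenReceptiveField(1, spec)
  expect_identical(rf1$rows, 1:6)
  expect_identical(rf1$cols, 1:6)
  ## last neuron of the last map: bottom-right 6x6 block
  rfN <- flattenReceptiveField(flattenSize(spec), spec)
  expect_identical(rfN$rows, 11:16)
  expect_identical(rfN$cols, 21:26)
  ## every field is 6x6 for this architecture (pool + kernel - 1 per axis)
  set.seed(13)
  some <- sample(flattenSize(spec), 30)
  for (i in some) {
    rf <- flattenReceptiveField(i, spec)
    expect_equal(length(rf$rows), 6)
    expect_equal(length(rf$cols), 6)
  }
  expect_error(flattenReceptiveField(0, spec), "1\\.\\.3300")
  ## exhaustive perturbation oracle on a small random input: randomizing
  ## cells outside the field never moves the activation; a targeted bump
  ## inside the field does (weights drawn dense so no dead cells)
  clf <- on
  clf@convW <- matrix(runif(length(clf@convW), 0.5, 1), nrow(clf@convW))
  base <- matrix(runif(16 * 26), 16, 26)
  a0 <- flattenActivations(clf, list(base))
  for (i in sample(flattenSize(spec), 10)) {
    rf <- flattenReceptiveField(i, spec)
    out <- base
    mask <- matrix(TRUE, 16, 26)
    mask[rf$rows, rf$cols] <- FALSE
    out[mask] <- runif(sum(mask))
    expect_equal(flattenActivations(clf, list(out))[1, i], a0[1, i],
                 tolerance = 1e-12)
    inside <- base
    inside[rf$rows[1], rf$cols[1]] <- inside[rf$rows[1], rf$cols[1]] + 5
    expect_gt(abs(flattenActivations(clf, list(inside))[1, i] - a0[1, i]),
              1e-8)
  }
})

test_that("classifier files round-trip with bit-identical predictions", {
  clf <- sharedOnTargetModel()
  X <- lapply(1:5, function(i) encodeOrderK(randomSeq(27), 2))
  path <- withr::local_tempfile(fileext = ".rds")
  writeClassifier(clf, path)
  back <- readClassifier(path)
  expect_identical(predict(back, X), predict(clf, X))
  ## version guard
  obj <- readRDS(path)
  obj$version <- 99L
  saveRDS(obj, path)
  expect_error(readClassifier(path), "version")
})
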