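test_that("the membership kernel has the documented shape", {
  expect_equal(frbn_membership(0, sigma = 1, a = 0, c = 0), 0.5)
  # sigmoid midpoint at d = sigma * sqrt(a)
  expect_equal(frbn_membership(2 * sqrt(1.3), sigma = 2, a = 1.3, c = 0), 0.5)
  expect_equal(frbn_membership(1e6, sigma = 1, a = 5, c = 0), 0)
  expect_equal(frbn_membership(1e6, sigma = 1, a = 5, c = 0.4), 0)
  expect_error(frbn_membership(1, sigma = 0), class = "frbain_validation_error")
  # monotone non-increasing in d over random parameter draws
  set.seed(14)
  for (i in 1:25) {
    sigma <- runif(1, 0.2, 5); a <- runif(1, -2, 4); cc <- runif(1, 0, 0.9)
    d <- sort(runif(50, 0, 10))
    mu <- frbn_membership(d, sigma, a, cc)
    expect_true(all(diff(mu) <= 1e-12))
    expect_true(all(mu >= 0 & mu <= 1))
  }
})

test_that("regularization projects onto the simplex and flags all-zero input", {
  expect_equal(regularize(c(2, 2, 6)), c(0.2, 0.2, 0.6))
  expect_equal(regularize(c(0.2, 0.2, 0.6)), c(0.2, 0.2, 0.6))  # idempotent
  expect_equal(regularize(5), 1)
  expect_error(regularize(c(0, 0)), class = "frbain_degenerate_error")
  expect_error(regularize(c(-1, 2)), class = "frbain_validation_error")
})

test_that("pattern pooling sums or maximizes per class", {
  cls <- c(1, 1, 2)
  expect_equal(pattern_layer(c(0.5, 0.3, 0.2), cls, "sum"), c(0.8, 0.2))
  expect_equal(pattern_layer(c(0.5, 0.3, 0.2), cls, "max"), c(0.5, 0.2))
  # sum pooling conserves the total
  h <- regularize(runif(6))
  expect_equal(sum(pattern_layer(h, rep(1, 6), "sum")), 1)
})

test_that("rule layer enumerates K^K lexicographic product rules", {
  r4 <- rule_index(4)
  expect_equal(nrow(r4), 256)
  expect_equal(r4[1, ], rep(1L, 4))
  expect_equal(r4[2, ], c(1L, 1L, 1L, 2L))      # last index varies fastest
  expect_equal(r4[256, ], rep(4L, 4))
  expect_equal(nrow(rule_index(2)), 4)
  expect_error(rule_index(8), class = "frbain_validation_error")  # cap

  # one-hot input fires only the all-ones tuple
  z <- rule_layer(c(1, 0, 0), rule_index(3))
  expect_equal(z[1], 1)
  expect_equal(sum(z), 1)
  # simplex input: total activation is (sum q)^K = 1
  q <- regularize(runif(3))
  expect_equal(sum(rule_layer(q, rule_index(3))), 1, tolerance = 1e-12)
  # min t-norm variant
  zmin <- rule_layer(c(0.6, 0.4), rule_index(2), tnorm = "min")
  expect_equal(zmin, c(0.6, 0.4, 0.4, 0.4))
})

test_that("T-S head is an affine softmax classifier", {
  L <- 9; K <- 3
  qn <- regularize(runif(L))
  expect_equal(ts_classify(qn, matrix(0, L, K), rep(0, K)), rep(1 / K, K))
  p <- ts_classify(qn, matrix(0, L, 4), c(10, 0, 0, 0))
  expect_gt(p[1], 0.999)
  # independent re-evaluation of the affine map + normalizer
  set.seed(6)
  W <- matrix(rnorm(L * K), L, K); b <- rnorm(K)
  s <- as.numeric(t(W) %*% qn) + b
  expect_equal(ts_classify(qn, W, b), exp(s) / sum(exp(s)), tolerance = 1e-12)
})

test_that("model assembly fixes structure counts from the bank", {
  # K = 4 classes with subclass counts (5, 6, 4, 5) -> 20 nodes, 256 rules
  set.seed(10)
  centers <- list()
  for (k in 1:4) for (l in seq_len(c(5, 6, 4, 5)[k]))
    centers[[length(centers) + 1L]] <-
      rand_signal(12, channels = 2, id = sprintf("z%d%d", k, l),
                  label = paste0("K", k))
  bank <- manual_bank(centers)
  model <- build_model(bank, seed = 1)
  expect_equal(bank_size(model$bank), 20)
  expect_equal(length(model$sigma), 20)
  expect_equal(length(model$class_order), 4)
  expect_equal(nrow(model$rules), 256)
  expect_equal(dim(model$W), c(256, 4))
  # determinism under the seed
  model2 <- build_model(bank, seed = 1)
  expect_identical(model$W, model2$W)
  expect_identical(model$sigma, model2$sigma)
  # K = 2 with 2 centers -> 4 rules
  b2 <- manual_bank(list(sig(1:5, "a", "A"), sig(6:10, "b", "B")))
  expect_equal(nrow(build_model(b2, seed = 1)$rules), 4)
})

test_that("forward pass conserves mass and classifies kernel centers", {
  set.seed(20)
  t <- seq(0, 1, length.out = 25)
  centers <- list(
    signal(cbind(sin(2 * pi * t)), record_id = "zA", label = "A"),
    signal(cbind(8 + sin(6 * pi * t)), record_id = "zB", label = "B"),
    signal(cbind(-8 + cos(4 * pi * t)), record_id = "zC", label = "C"))
  model <- build_model(manual_bank(centers), seed = 2)
  for (k in seq_along(centers)) {
    pr <- forward(centers[[k]], model)
    expect_equal(sum(pr$class_scores), 1, tolerance = 1e-9)
    expect_equal(sum(pr$rule_activations), 1, tolerance = 1e-9)
    expect_equal(sum(pr$pattern_memberships), 1, tolerance = 1e-9)
    # an input equal to a kernel center has maximal membership at that node
    expect_equal(which.max(pr$frbn_memberships), k)
  }
})

test_that("symmetric banks give uniform scores and pooling is order-invariant", {
  tpl <- sig(c(1, 2, 3, 2, 1), "z")
  centers <- list(signal(tpl$values, record_id = "zA", label = "A"),
                  signal(tpl$values, record_id = "zB", label = "B"))
  model <- build_model(manual_bank(centers), seed = 3)
  model$W[] <- 0
  pr <- forward(sig(c(2, 3, 4, 3, 2), "x"), model)
  expect_equal(unname(pr$class_scores), c(0.5, 0.5), tolerance = 1e-9)

  # permuting a class's centers leaves the forward output unchanged
  set.seed(33)
  centers <- list(rand_signal(10, 1, "a1", "A"), rand_signal(10, 1, "a2", "A"),
                  rand_signal(10, 1, "a3", "A"), rand_signal(10, 1, "b1", "B"))
  m1 <- build_model(manual_bank(centers), seed = 4)
  m2 <- m1
  perm <- c(3, 1, 2, 4)                       # permute within class A
  m2$bank$centers <- m1$bank$centers[perm]
  m2$bank$class <- m1$bank$class[perm]
  m2$sigma <- m1$sigma[perm]; m2$a <- m1$a[perm]; m2$c <- m1$c[perm]
  x <- rand_signal(10, 1, "x")
  expect_equal(forward(x, m2)$class_scores, forward(x, m1)$class_scores,
               tolerance = 1e-12)
})

test_that("fuzzify composes DTW distances with the scalar kernel", {
  centers <- list(sig(c(0, 1, 0), "zA", "A"), sig(c(5, 6, 5), "zB", "B"))
  model <- build_model(manual_bank(centers), seed = 5)
  x <- sig(c(0, 1, 1, 0), "x")
  d <- vapply(centers, function(z)
    dtw_distance(x, z, return_path = FALSE)$distance, numeric(1))
  expect_equal(fuzzify(x, model),
               frbn_membership(d, model$sigma, model$a, model$c),
               tolerance = 1e-12)
  # all centers identical -> all memberships equal
  same <- manual_bank(list(sig(1:4, "zA", "A"), sig(1:4, "zB", "B")))
  ms <- build_model(same, seed = 1)
  mus <- fuzzify(sig(c(2, 3, 4, 5), "x"), ms)
  expect_equal(mus[1], mus[2])
})

test_that("model archives round-trip the forward map exactly", {
  set.seed(44)
  centers <- list(rand_signal(9, 2, "a", "A"), rand_signal(13, 2, "a2", "A"),
                  rand_signal(11, 2, "b", "B"))  # unequal center lengths
  model <- build_model(manual_bank(centers), seed = 6)
  dir <- withr::local_tempdir()
  save_model(model, dir)
  model2 <- load_model(dir)
  expect_equal(model2$sigma, model$sigma)
  expect_equal(model2$W, model$W)
  expect_equal(model2$class_order, model$class_order)
  x <- rand_signal(10, 2, "x")
  expect_identical(forward(x, model2)$class_scores,
                   forward(x, model)$class_scores)
  # truncated archive fails to load
  writeLines("{", file.path(dir, "params.json"))
  expect_error(load_model(dir), class = "frbain_io_error")
  expect_error(load_model(withr::local_tempdir()), class = "frbain_io_error")
})
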