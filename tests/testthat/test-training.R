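test_that("the learning-rate schedule decays exactly as configured", {
  ctrl <- train_control()
  expect_equal(lr_schedule(0, ctrl), 0.5)
  expect_equal(lr_schedule(49, ctrl), 0.5)
  expect_equal(lr_schedule(50, ctrl), 0.05)
  expect_equal(lr_schedule(100, ctrl), 0.005)
  expect_equal(lr_schedule(120, ctrl), 0.005)
  # closed form at arbitrary epochs
  for (e in c(0, 7, 99, 101, 499))
    expect_equal(lr_schedule(e, ctrl), 0.5 * 0.1^floor(e / 50))
})

test_that("cross-entropy loss matches closed forms", {
  perfect <- diag(3)
  expect_equal(cross_entropy(perfect, 1:3), 0, tolerance = 1e-10)
  uniform <- matrix(0.25, 2, 4)
  expect_equal(cross_entropy(uniform, c(1, 3)), log(4))
  # batch mean is the mean of individual losses
  p <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  expect_equal(cross_entropy(p, c(1, 2)),
               mean(c(-log(0.7), -log(0.8))))
  # zero probability is clipped, not infinite
  expect_lt(cross_entropy(rbind(c(1, 0)), 2), 28)
})

test_that("precomputed distance table equals per-pair recomputation", {
  gen <- generate_dataset(generator_spec(K = 2, subclasses_per_class = 1,
                                         n_total = 8, seed = 2))
  bank <- build_kernel_bank(gen$dataset, c_range = c(2, 2), seed = 2)
  Dt <- precompute_distances(gen$dataset, bank)
  expect_equal(dim(Dt), c(8, bank_size(bank)))
  for (i in c(1, 5)) for (j in seq_len(ncol(Dt)))
    expect_equal(unname(Dt[i, j]),
                 dtw_distance(gen$dataset$signals[[i]], bank$centers[[j]],
                              return_path = FALSE)$distance,
                 tolerance = 1e-12)
  # a record equal to a center has distance zero to it
  ctr_id <- bank$centers[[1]]$record_id
  i <- match(ctr_id, dataset_ids(gen$dataset))
  expect_equal(unname(Dt[i, 1]), 0)
  # recomputation is deterministic
  expect_identical(Dt, precompute_distances(gen$dataset, bank))
})

test_that("analytic gradients match central finite differences", {
  set.seed(55)
  worst <- 0
  for (rep in 1:8) {
    m <- sample(3:6, 1)
    K <- sample(2:3, 1)
    B <- 7
    cls <- sort(sample(rep(seq_len(K), length.out = m)))
    centers <- lapply(seq_len(m), function(j)
      rand_signal(6, 1, paste0("z", j), label = paste0("K", cls[j])))
    model <- build_model(manual_bank(centers), seed = rep)
    # parameters kept away from the membership clamp boundaries
    model$sigma <- runif(m, 0.8, 2)
    model$a <- runif(m, 1, 2)
    model$c <- runif(m, 0, 0.08)
    model$W <- matrix(rnorm(nrow(model$rules) * K), ncol = K)
    model$r <- rnorm(K)
    Dm <- matrix(runif(B * m, 0, 1.2), B, m) * rep(model$sigma, each = B)
    y <- sample(seq_len(K), B, replace = TRUE)
    barrier <- 0.01
    g <- frbain:::batch_gradients(Dm, y, model, barrier = barrier)
    objective_at <- function(mod) {
      fw <- frbain:::batch_forward(Dm, mod)
      cross_entropy(fw$P, y) - barrier * mean(log(fw$tot))
    }
    h <- 1e-5
    for (par in c("sigma", "a", "c", "r")) {
      for (i in seq_along(model[[par]])) {
        mp <- model; mp[[par]][i] <- mp[[par]][i] + h
        mm <- model; mm[[par]][i] <- mm[[par]][i] - h
        fd <- (objective_at(mp) - objective_at(mm)) / (2 * h)
        rel <- abs(g[[par]][i] - fd) / max(abs(fd), 1e-6)
        worst <- max(worst, rel)
      }
    }
    for (idx in sample(length(model$W), 5)) {
      mp <- model; mp$W[idx] <- mp$W[idx] + h
      mm <- model; mm$W[idx] <- mm$W[idx] - h
      fd <- (objective_at(mp) - objective_at(mm)) / (2 * h)
      worst <- max(worst, abs(g$W[idx] - fd) / max(abs(fd), 1e-6))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("training is deterministic under a fixed seed", {
  gen <- generate_dataset(generator_spec(K = 2, subclasses_per_class = 1,
                                         n_total = 24, seed = 9))
  bank <- build_kernel_bank(gen$dataset, c_range = c(2, 2), seed = 9)
  model <- build_model(bank, seed = 9)
  ctrl <- train_control(max_epochs = 15, seed = 77)
  f1 <- train_model(model, gen$dataset, ctrl)
  f2 <- train_model(model, gen$dataset, ctrl)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$W, f2$model$W)
  expect_identical(f1$model$sigma, f2$model$sigma)
  expect_equal(f1$history$lr,
               0.5 * 0.1^floor((f1$history$epoch - 1) / 50))
})

test_that("training reduces the loss and fits a separable two-class set", {
  gen <- generate_dataset(generator_spec(K = 2, subclasses_per_class = 2,
                                         n_total = 60, seed = 13))
  bank <- build_kernel_bank(gen$dataset, c_range = c(2, 3), seed = 13)
  model <- build_model(bank, seed = 13)
  D <- precompute_distances(gen$dataset, model)
  y <- match(dataset_labels(gen$dataset), model$class_order)
  loss0 <- cross_entropy(frbain:::batch_forward(D, model)$P, y)
  fit <- train_model(model, gen$dataset, train_control(max_epochs = 50, seed = 13),
                     distances = D)
  expect_lt(fit$history$loss[nrow(fit$history)], loss0)
  met <- evaluate_model(fit$model, gen$dataset, distances = D)
  expect_gte(met$accuracy, 0.95)
  expect_true(attr(fit$history, "stop_reason") %in% c("converged", "max_epochs"))
})

test_that("training validates inputs and parameters stay feasible", {
  gen <- generate_dataset(generator_spec(K = 2, subclasses_per_class = 1,
                                         n_total = 12, seed = 3))
  bank <- build_kernel_bank(gen$dataset, c_range = c(2, 2), seed = 3)
  model <- build_model(bank, seed = 3)
  unlabeled <- gen$dataset
  unlabeled$signals[[1]]$label <- NULL
  expect_error(train_model(model, unlabeled, train_control(max_epochs = 1)),
               class = "frbain_validation_error")
  fit <- train_model(model, gen$dataset,
                     train_control(max_epochs = 10, seed = 1))
  expect_true(all(fit$model$sigma > 0))
  expect_true(all(fit$model$c >= 0 & fit$model$c < 1))
})

test_that("metrics match a hand-computed 3-class confusion matrix", {
  truth <- c("a", "a", "a", "b", "b", "c", "c", "c", "c")
  pred  <- c("a", "b", "a", "b", "b", "c", "a", "c", "c")
  met <- metrics_report(truth, pred, c("a", "b", "c"))
  expect_equal(unname(met$confusion["a", ]), c(2L, 1L, 0L))
  expect_equal(met$accuracy, 7 / 9)
  expect_equal(met$per_class$precision, c(2 / 3, 2 / 3, 1))
  expect_equal(met$per_class$recall, c(2 / 3, 1, 3 / 4))
  f1 <- 2 * (2 / 3 * 2 / 3) / (2 / 3 + 2 / 3)
  expect_equal(met$per_class$f1[1], f1)
  expect_equal(met$macro_precision, mean(c(2 / 3, 2 / 3, 1)))

  # perfect classifier: all ones, diagonal confusion
  perf <- metrics_report(truth, truth, c("a", "b", "c"))
  expect_equal(perf$accuracy, 1)
  expect_true(all(perf$per_class$f1 == 1))
  expect_true(all(perf$confusion[upper.tri(perf$confusion)] == 0))

  # one-class predictor on a balanced two-class problem
  expect_warning(
    onec <- metrics_report(c("a", "a", "b", "b"), rep("a", 4), c("a", "b")))
  expect_equal(onec$accuracy, 0.5)
  expect_equal(onec$per_class$recall, c(1, 0))
})
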