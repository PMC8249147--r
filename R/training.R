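## Gradient training of the network parameters {sigma, a, c, W, r}. Kernel
## centers are fixed, so all sample-to-center DTW distances are computed once
## up front and every epoch works on the closed-form layer chain only; no
## gradient flows through the warping itself. The loss is mean categorical
## cross-entropy against the softmax head.

#' Training control parameters
#'
#' Defaults follow the reference regime: initial learning rate 0.5 decayed by
#' a factor 0.1 every 50 epochs (so epochs 0/50/100 run at 0.5/0.05/0.005),
#' at most 500 epochs, stopping early when the epoch mean loss drops below
#' 0.005, stochastic batches with the Adam optimizer.
#'
#' @param initial_lr Initial learning rate (> 0).
#' @param lr_decay_every Epochs between learning-rate decays.
#' @param lr_decay_factor Multiplicative decay factor in (0, 1).
#' @param max_epochs Maximum epochs.
#' @param batch_count Number of batches per epoch (clamped to the sample
#'   count; the last batch may be ragged). The default `NULL` derives the
#'   count from a reference batch size of 54 records, `ceiling(N / 54)`.
#' @param stop_loss Early-stopping threshold on the epoch mean loss.
#' @param optimizer `"sgd"` (plain gradient descent, the default) or
#'   `"adam"`. With the 0.5 learning-rate schedule, Adam's sign-normalized
#'   steps are as large as the admissible range of the bounded offset
#'   parameters and routinely drive nodes into the zero-membership clamp
#'   region, where the gradient vanishes permanently; plain gradient steps
#'   are proportional to the gradient magnitude and remain stable under the
#'   same schedule.
#' @param beta1,beta2,epsilon Adam moment decays and stabilizer.
#' @param barrier Weight of the log-barrier on the total FRBN membership
#'   mass. The classification loss only sees normalized memberships, so it is
#'   flat along a joint shrinkage of all memberships; the barrier
#'   `-barrier * mean(log sum_j mu_j)` pins that direction and keeps the
#'   fuzzification layer from collapsing to all-zero memberships. The early
#'   stopping threshold applies to the cross-entropy alone.
#' @param seed Seed for batch shuffling.
#' @return A list of class `frbain_control`.
#' @export
train_control <- function(initial_lr = 0.5, lr_decay_every = 50,
                          lr_decay_factor = 0.1, max_epochs = 500,
                          batch_count = NULL, stop_loss = 0.005,
                          optimizer = c("sgd", "adam"),
                          beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                          barrier = 0.01, seed = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(initial_lr > 0, lr_decay_every >= 1, lr_decay_factor > 0,
            lr_decay_factor < 1, max_epochs >= 1,
            is.null(batch_count) || batch_count >= 1, stop_loss > 0,
            barrier >= 0)
  structure(list(initial_lr = initial_lr, lr_decay_every = lr_decay_every,
                 lr_decay_factor = lr_decay_factor, max_epochs = max_epochs,
                 batch_count = batch_count, stop_loss = stop_loss,
                 optimizer = optimizer, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, barrier = barrier, seed = seed),
            class = "frbain_control")
}

#' Learning rate at a given epoch
#'
#' `lr(epoch) = initial_lr * factor^floor(epoch / every)` with `epoch`
#' counted from 0, matching a schedule that starts at `initial_lr` and is
#' divided by 10 every `every` epochs.
#'
#' @param epoch Epoch number, 0-based.
#' @param control A [train_control()].
#' @return Learning rate.
#' @export
lr_schedule <- function(epoch, control = train_control()) {
  control$initial_lr *
    control$lr_decay_factor^floor(epoch / control$lr_decay_every)
}

#' Precompute sample-to-center DTW distances
#'
#' The kernel centers are fixed during training, so the N x m distance table
#' is computed once; each epoch then evaluates the closed-form layer chain
#' only.
#'
#' @param dataset A [signal_dataset()].
#' @param bank A [build_kernel_bank()] result (or an `efrbain_model`, whose
#'   DTW options are then used).
#' @param normalize,band DTW options (ignored when `bank` is a model).
#' @return N x m numeric matrix of DTW distances.
#' @export
precompute_distances <- function(dataset, bank, normalize = FALSE,
                                 band = NULL) {
  if (inherits(bank, "efrbain_model")) {
    normalize <- bank$dtw$normalize
    band <- bank$dtw$band
    bank <- bank$bank
  }
  cross_distances(dataset, bank$centers, normalize = normalize, band = band)
}

## Vectorized batch forward pass from a distance block (B x m).
## Returns all intermediates needed for backprop. Rows whose memberships are
## all zero (the signal matches no kernel at the current parameters) either
## raise the degenerate-membership error or, with degenerate = "flag", are
## carried through on a uniform membership and flagged; their clamp mask is
## all-FALSE so they contribute no membership gradient.
batch_forward <- function(Dm, model, degenerate = c("error", "flag")) {
  degenerate <- match.arg(degenerate)
  B <- nrow(Dm); m <- ncol(Dm)
  sig <- matrix(model$sigma, B, m, byrow = TRUE)
  aa <- matrix(model$a, B, m, byrow = TRUE)
  cc <- matrix(model$c, B, m, byrow = TRUE)
  S <- stats::plogis(aa - (Dm / sig)^2)       # pre-offset sigmoid
  mu <- pmin(pmax(S - cc, 0), 1)
  active <- (S - cc) > 0 & (S - cc) < 1       # clamp-inactive mask
  tot <- rowSums(mu)
  dead <- tot <= 0
  if (any(dead)) {
    if (degenerate == "error")
      stop(errorCondition("degenerate membership: a signal matches no kernel",
                          class = c("frbain_degenerate_error",
                                    "frbain_validation_error", "frbain_error")))
    mu[dead, ] <- 1 / m
    tot[dead] <- 1
  }
  H <- mu / tot
  cls <- match(model$bank$class, model$bank$classes)
  K <- length(model$bank$classes)
  Q <- matrix(0, B, K)
  for (k in seq_len(K)) {
    jj <- which(cls == k)
    Q[, k] <- rowSums(H[, jj, drop = FALSE])
  }
  rules <- model$rules
  L <- nrow(rules)
  Z <- matrix(1, B, L)
  for (v in seq_len(ncol(rules))) Z <- Z * Q[, rules[, v], drop = FALSE]
  zt <- rowSums(Z)
  if (any(zt <= 0))
    stop(errorCondition("degenerate rule activations for a signal",
                        class = c("frbain_degenerate_error",
                                  "frbain_validation_error", "frbain_error")))
  QN <- Z / zt
  U <- QN %*% model$W + matrix(model$r, B, K, byrow = TRUE)
  U <- U - apply(U, 1L, max)
  E <- exp(U)
  P <- E / rowSums(E)
  list(S = S, mu = mu, active = active, tot = tot, H = H, Q = Q, Z = Z,
       zt = zt, QN = QN, P = P, cls = cls, degenerate = dead)
}

## Row totals of the raw FRBN memberships; 0 marks a degenerate sample.
membership_totals <- function(Dm, model) {
  B <- nrow(Dm); m <- ncol(Dm)
  sig <- matrix(model$sigma, B, m, byrow = TRUE)
  aa <- matrix(model$a, B, m, byrow = TRUE)
  cc <- matrix(model$c, B, m, byrow = TRUE)
  rowSums(pmin(pmax(stats::plogis(aa - (Dm / sig)^2) - cc, 0), 1))
}

#' Mean categorical cross-entropy loss
#'
#' @param prob Matrix of predicted class probabilities (samples x classes) or
#'   a single probability vector.
#' @param y_idx Integer true-class indices (1-based).
#' @return Mean `-log p[true]` (natural log), probabilities clipped at 1e-12.
#' @export
cross_entropy <- function(prob, y_idx) {
  if (is.vector(prob)) prob <- matrix(prob, nrow = 1)
  if (nrow(prob) != length(y_idx))
    stop_validation("probability rows and label count differ")
  p <- prob[cbind(seq_len(nrow(prob)), y_idx)]
  mean(-log(pmax(p, 1e-12)))
}

## Analytic gradients of the training objective
##   mean CE - barrier * mean(log total-membership)
## w.r.t. {sigma, a, c, W, r}. Dm: B x m distance block, y: 1-based class
## indices. Returns the cross-entropy as `loss` and the full objective as
## `objective`.
batch_gradients <- function(Dm, y, model, fw = NULL, barrier = 0) {
  if (is.null(fw)) fw <- batch_forward(Dm, model)
  B <- nrow(Dm); m <- ncol(Dm); K <- length(model$class_order)
  rules <- model$rules; L <- nrow(rules)
  Y <- matrix(0, B, K); Y[cbind(seq_len(B), y)] <- 1
  dU <- (fw$P - Y) / B                          # B x K
  gr <- colSums(dU)
  gW <- crossprod(fw$QN, dU)                    # L x K
  dQN <- dU %*% t(model$W)                      # B x L
  # qn = z / zt
  dZ <- (dQN - rowSums(dQN * fw$QN)) / fw$zt    # B x L
  # z_t = prod_v q[rules[t,v]]: accumulate leave-one-out products
  dQ <- matrix(0, B, K)
  for (v in seq_len(ncol(rules))) {
    excl <- matrix(1, B, L)
    for (v2 in seq_len(ncol(rules)))
      if (v2 != v) excl <- excl * fw$Q[, rules[, v2], drop = FALSE]
    contrib <- dZ * excl                        # B x L
    for (k in seq_len(K)) {
      sel <- rules[, v] == k
      if (any(sel)) dQ[, k] <- dQ[, k] + rowSums(contrib[, sel, drop = FALSE])
    }
  }
  # q_k = sum_{j in class k} h_j
  dH <- dQ[, fw$cls, drop = FALSE]              # B x m
  # h = mu / tot
  dMu <- (dH - rowSums(dH * fw$H)) / fw$tot
  # log-barrier on the total membership mass: d(-log tot)/dmu_j = -1/tot
  if (barrier > 0) dMu <- dMu - barrier / (B * fw$tot)
  dMu <- dMu * fw$active                        # clamp subgradient
  sig <- matrix(model$sigma, B, m, byrow = TRUE)
  dS <- dMu * fw$S * (1 - fw$S)                 # through the sigmoid
  ga <- colSums(dS)
  gsigma <- colSums(dS * 2 * Dm^2 / sig^3)
  gc <- colSums(-dMu)
  loss <- mean(-log(pmax(fw$P[cbind(seq_len(B), y)], 1e-12)))
  objective <- loss - barrier * mean(log(fw$tot))
  list(loss = loss, objective = objective,
       sigma = gsigma, a = ga, c = gc, W = gW, r = gr)
}

adam_init <- function(model) {
  shapes <- list(sigma = model$sigma * 0, a = model$a * 0, c = model$c * 0,
                 W = model$W * 0, r = model$r * 0)
  list(m = shapes, v = shapes, t = 0L)
}

apply_update <- function(model, grads, lr, control, state) {
  par_names <- c("sigma", "a", "c", "W", "r")
  if (control$optimizer == "adam") {
    state$t <- state$t + 1L
    for (p in par_names) {
      g <- grads[[p]]
      state$m[[p]] <- control$beta1 * state$m[[p]] + (1 - control$beta1) * g
      state$v[[p]] <- control$beta2 * state$v[[p]] + (1 - control$beta2) * g^2
      mhat <- state$m[[p]] / (1 - control$beta1^state$t)
      vhat <- state$v[[p]] / (1 - control$beta2^state$t)
      model[[p]] <- model[[p]] - lr * mhat / (sqrt(vhat) + control$epsilon)
    }
  } else {
    for (p in par_names) model[[p]] <- model[[p]] - lr * grads[[p]]
  }
  # projections keep the membership kernel valid
  model$sigma <- pmax(model$sigma, 1e-6)
  model$c <- pmin(pmax(model$c, 0), 1 - 1e-6)
  list(model = model, state = state)
}

#' Train a network by stochastic gradient descent
#'
#' Per epoch: seeded shuffle, split into `batch_count` batches, update
#' `{sigma, a, c, W, r}` on each batch's cross-entropy gradient (Adam by
#' default), then project `sigma > 0` and the offset into `[0, 1)`. Kernel
#' centers are never updated. Training stops when the epoch mean loss falls
#' below `stop_loss` or at `max_epochs`.
#'
#' @param model An `efrbain_model` from [build_model()].
#' @param dataset Labeled [signal_dataset()] whose labels are all in the
#'   model's class order.
#' @param control A [train_control()].
#' @param distances Optional precomputed N x m distance table
#'   ([precompute_distances()]); computed if missing.
#' @return A list of class `efrbain_fit_raw` with elements `model` (trained)
#'   and `history` (data frame epoch/loss/lr plus `stop_reason` attribute).
#' @export
train_model <- function(model, dataset, control = train_control(),
                        distances = NULL) {
  if (!inherits(model, "efrbain_model")) stop_validation("not an efrbain model")
  if (length(dataset$signals) == 0L) stop_validation("empty training dataset")
  labs <- dataset_labels(dataset)
  if (any(is.na(labs))) stop_validation("all training records must be labeled")
  y <- match(labs, model$class_order)
  if (any(is.na(y)))
    stop_validation("labels outside the model's classes: %s",
                    paste(unique(labs[is.na(y)]), collapse = ", "))
  if (is.null(distances)) distances <- precompute_distances(dataset, model)
  N <- nrow(distances)
  nb <- min(control$batch_count %||% ceiling(N / 54), N)
  state <- adam_init(model)
  losses <- numeric(0); lrs <- numeric(0)
  stop_reason <- "max_epochs"
  K <- length(model$class_order)
  n_degenerate <- 0L
  runner <- function() {
    for (epoch in seq_len(control$max_epochs)) {
      lr <- lr_schedule(epoch - 1L, control)
      perm <- sample.int(N)
      splits <- split(perm, rep(seq_len(nb), each = ceiling(N / nb),
                                length.out = N))
      epoch_loss <- 0
      for (b in splits) {
        # samples with no kernel membership at the current parameters carry
        # no usable gradient: drop them from the update, but charge the
        # uniform-prediction loss so early stopping stays honest
        ok <- membership_totals(distances[b, , drop = FALSE], model) > 0
        if (!all(ok)) {
          n_degenerate <<- n_degenerate + sum(!ok)
          epoch_loss <- epoch_loss + log(K) * sum(!ok)
          b <- b[ok]
          if (!length(b)) next
        }
        g <- batch_gradients(distances[b, , drop = FALSE], y[b], model,
                             barrier = control$barrier)
        upd <- apply_update(model, g, lr, control, state)
        model <<- upd$model
        state <<- upd$state
        epoch_loss <- epoch_loss + g$loss * length(b)
      }
      epoch_loss <- epoch_loss / N
      losses[epoch] <<- epoch_loss
      lrs[epoch] <<- lr
      if (epoch_loss < control$stop_loss) {
        stop_reason <<- "converged"
        break
      }
    }
  }
  with_seed(control$seed, runner())
  if (n_degenerate > 0L)
    warning(sprintf(
      "%d sample-batch evaluations had degenerate (all-zero) memberships and were excluded from gradient updates",
      n_degenerate))
  history <- data.frame(epoch = seq_along(losses), loss = losses, lr = lrs)
  attr(history, "stop_reason") <- stop_reason
  structure(list(model = model, history = history), class = "efrbain_fit_raw")
}

#' Evaluate a model on a labeled dataset
#'
#' One-vs-rest precision, recall and F1 per class from the confusion matrix,
#' their unweighted (macro) means, and overall accuracy. Classes with zero
#' support or zero predictions score 0 with a warning.
#'
#' @param model An `efrbain_model`.
#' @param dataset Labeled [signal_dataset()].
#' @param distances Optional precomputed distance table.
#' @return An object of class `frbain_metrics`: `confusion` (true in rows),
#'   `per_class` data frame, `macro_precision`, `macro_recall`, `macro_f1`,
#'   `accuracy`.
#' @export
evaluate_model <- function(model, dataset, distances = NULL) {
  labs <- dataset_labels(dataset)
  if (any(is.na(labs))) stop_validation("all records must be labeled")
  if (is.null(distances)) distances <- precompute_distances(dataset, model)
  pred <- predict_from_distances(distances, model)
  metrics_report(labs, pred$label, model$class_order)
}

predict_from_distances <- function(distances, model) {
  fw <- batch_forward(distances, model, degenerate = "flag")
  k <- max.col(fw$P, ties.method = "first")
  label <- model$class_order[k]
  prob <- fw$P
  if (any(fw$degenerate)) {
    warning(sprintf("%d record(s) with degenerate membership are unclassifiable",
                    sum(fw$degenerate)))
    label[fw$degenerate] <- NA_character_
    prob[fw$degenerate, ] <- NA_real_
  }
  list(label = label,
       prob = structure(prob, dimnames = list(rownames(distances),
                                              model$class_order)),
       degenerate = fw$degenerate)
}

#' Classification metrics from label vectors
#'
#' @param truth,predicted Character vectors of true and predicted labels.
#'   `NA` predictions (unclassifiable records) count against accuracy and
#'   recall but are excluded from the confusion matrix columns.
#' @param classes Class order for the confusion matrix.
#' @return A `frbain_metrics` object (see [evaluate_model()]).
#' @export
metrics_report <- function(truth, predicted, classes) {
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  tp <- diag(cm)
  support <- as.integer(table(factor(truth, levels = classes)))
  predicted_n <- colSums(cm)
  if (any(support == 0) || any(predicted_n == 0))
    warning("class with zero support or zero predictions; its metrics are 0")
  precision <- ifelse(predicted_n > 0, tp / predicted_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(confusion = cm,
                 per_class = data.frame(class = classes, support = support,
                                        precision = precision, recall = recall,
                                        f1 = f1, row.names = NULL),
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_f1 = mean(f1),
                 accuracy = sum(tp) / length(truth)),
            class = "frbain_metrics")
}

#' @export
print.frbain_metrics <- function(x, digits = 4, ...) {
  cat("Confusion matrix (truth in rows):\n")
  print(x$confusion)
  df <- x$per_class
  df[c("precision", "recall", "f1")] <- round(df[c("precision", "recall", "f1")],
                                              digits)
  print(df, row.names = FALSE)
  cat(sprintf("macro P/R/F1: %.4f / %.4f / %.4f   accuracy: %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1, x$accuracy))
  invisible(x)
}
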