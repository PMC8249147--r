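## The extended fuzzy radial basis adaptive inference network. Layers:
##   1. input: one multichannel signal
##   2. FRBN fuzzification: one node per kernel center; output is a decreasing
##      sigmoid of the squared DTW distance to the center, minus an offset,
##      clamped to [0,1]
##   3. regularization I: joint normalization of all FRBN outputs to a simplex
##   4. pattern layer: per-class pooling (sum or max) of FRBN memberships
##   5. rule layer: product t-norm over all K-tuples of pattern memberships
##      (L = K^K rules, lexicographic tuple order)
##   6. regularization II: normalization of rule activations
##   7. T-S classifier head: affine map to K class scores, softmax decision.

#' Fuzzy radial basis membership
#'
#' The membership of a signal at distance `d` from a kernel center:
#' `clamp(1 / (1 + exp(d^2 / sigma^2 - a)) - c, 0, 1)`. It is maximal at
#' `d = 0` and non-increasing in `d`; overflow saturates at the clamp bounds.
#'
#' @param d Nonnegative distance(s) to the kernel center.
#' @param sigma Smoothing parameter, > 0 (distance units).
#' @param a Shape parameter (sets the membership at `d = 0`).
#' @param c Offset parameter in `[0, 1)`.
#' @return Membership value(s) in `[0, 1]`; vectorized over `d`.
#' @examples
#' frbn_membership(0, sigma = 1, a = 0, c = 0)     # 0.5
#' frbn_membership(2, sigma = 2, a = 1, c = 0)     # sigmoid midpoint: 0.5
#' @export
frbn_membership <- function(d, sigma, a = 1, c = 0) {
  if (any(sigma <= 0)) stop_validation("sigma must be positive")
  pmin(pmax(stats::plogis(a - (d / sigma)^2) - c, 0), 1)
}

#' Normalize nonnegative layer outputs onto the probability simplex
#'
#' Divides each element by the total. The all-zero input is degenerate (the
#' signal matches no kernel) and raises a classed error that callers surface
#' as "unclassifiable".
#'
#' @param v Nonnegative numeric vector with at least one positive element.
#' @return Vector summing to 1.
#' @export
regularize <- function(v) {
  if (any(v < 0)) stop_validation("negative layer output")
  s <- sum(v)
  if (s <= 0)
    stop(errorCondition("degenerate membership: all layer outputs are zero",
                        class = c("frbain_degenerate_error",
                                  "frbain_validation_error", "frbain_error")))
  v / s
}

#' Pattern-layer pooling of FRBN memberships
#'
#' Pools the regularized FRBN memberships per pattern class: `sum` adds the
#' memberships of each class's kernel centers (conserving the total), `max`
#' takes the strongest subclass membership.
#'
#' @param h Numeric vector of regularized FRBN outputs (bank order).
#' @param bank The [build_kernel_bank()] the memberships are aligned to, or a
#'   vector of class indices (1..K) per element of `h`.
#' @param mode `"sum"` or `"max"`.
#' @return Numeric vector of K pattern-class memberships.
#' @export
pattern_layer <- function(h, bank, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  if (inherits(bank, "kernel_bank")) {
    K <- length(bank$classes)
    cls <- match(bank$class, bank$classes)
  } else {
    cls <- as.integer(bank)
    K <- max(cls)
  }
  if (length(h) != length(cls))
    stop_validation("membership vector length %d does not match bank size %d",
                    length(h), length(cls))
  q <- numeric(K)
  for (k in seq_len(K)) {
    jj <- which(cls == k)
    q[k] <- if (mode == "sum") sum(h[jj]) else if (length(jj)) max(h[jj]) else 0
  }
  q
}

#' Rule index for the extended network
#'
#' Enumerates all `L = K^K` K-tuples over `{1..K}` in lexicographic order;
#' rule t fires with the product of the pattern memberships it indexes.
#'
#' @param K Number of pattern classes.
#' @param rule_cap Guard on the rule-layer size.
#' @return Integer matrix with L rows and K columns.
#' @export
rule_index <- function(K, rule_cap = 1e6) {
  if (K < 1) stop_validation("K must be >= 1")
  L <- K^K
  if (L > rule_cap)
    stop_validation(paste0("rule layer would need K^K = %g nodes ",
                           "(cap %g); reduce the number of classes"), L, rule_cap)
  # lexicographic: first index varies slowest
  g <- do.call(expand.grid, rep(list(seq_len(K)), K))[, K:1, drop = FALSE]
  m <- as.matrix(g[do.call(order, as.data.frame(g)), , drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Rule-layer activations (product t-norm)
#'
#' @param q Numeric vector of K pattern-class memberships.
#' @param rules Rule index matrix from [rule_index()].
#' @param tnorm `"product"` (default) or `"min"` fuzzy-AND.
#' @return Numeric vector of L rule activations in tuple order.
#' @export
rule_layer <- function(q, rules, tnorm = c("product", "min")) {
  tnorm <- match.arg(tnorm)
  if (ncol(rules) != length(q))
    stop_validation("rule tuples index %d inputs but q has length %d",
                    ncol(rules), length(q))
  z <- rep(1, nrow(rules))
  if (tnorm == "product") {
    for (v in seq_len(ncol(rules))) z <- z * q[rules[, v]]
  } else {
    for (v in seq_len(ncol(rules))) z <- pmin(z, q[rules[, v]])
  }
  z
}

#' Takagi-Sugeno classifier head
#'
#' Maps the L normalized rule activations through an affine map to K class
#' scores and a softmax to class probabilities.
#'
#' @param qn Numeric vector of L normalized rule activations.
#' @param weights L x K weight matrix.
#' @param bias Length-K bias vector.
#' @return Length-K probability vector (sums to 1).
#' @export
ts_classify <- function(qn, weights, bias) {
  if (nrow(weights) != length(qn) || ncol(weights) != length(bias))
    stop_validation("classifier parameter shapes do not match")
  s <- drop(crossprod(weights, qn)) + bias
  softmax(s)
}

softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Assemble an extended network from a kernel bank
#'
#' Structure is fixed by the bank: m = bank size FRBN nodes, K pattern nodes,
#' `L = K^K` rule nodes. Each node's smoothing parameter is initialized to the
#' median DTW distance from its center to the other centers (1 if there is a
#' single center), the shape parameter to 1 and the offset to 0; classifier
#' weights are drawn small-random from the seed and biases start at zero.
#'
#' @param bank A [build_kernel_bank()] result with K >= 2 classes.
#' @param seed Integer seed for the weight initialization.
#' @param a_init,c_init Initial shape and offset parameters.
#' @param normalize,band DTW options used for all model distances.
#' @param rule_cap Guard on the rule-layer size (see [rule_index()]).
#' @return An object of class `efrbain_model`.
#' @export
build_model <- function(bank, seed = NULL, a_init = 1, c_init = 0,
                        normalize = FALSE, band = NULL, rule_cap = 1e6) {
  if (!inherits(bank, "kernel_bank") || bank_size(bank) == 0L)
    stop_validation("a nonempty kernel bank is required")
  K <- length(bank$classes)
  if (K < 2) stop_validation("at least 2 classes required")
  m <- bank_size(bank)
  rules <- rule_index(K, rule_cap)
  L <- nrow(rules)
  sigma <- rep(1, m)
  if (m > 1) {
    vals <- lapply(bank$centers, `[[`, "values")
    Dc <- .cpp_dtw_matrix(vals, if (is.null(band)) -1L else as.integer(band),
                          normalize)
    diag(Dc) <- NA
    # sigma_j: half the median distance from center j to the other centers --
    # wide enough that every sample keeps nonzero membership, narrow enough
    # that a node resolves its own subclass from its neighbors
    sigma <- apply(Dc, 1L, median, na.rm = TRUE) / 2
    sigma[!is.finite(sigma) | sigma <= 0] <- 1
  }
  W <- with_seed(seed, matrix(rnorm(L * K, sd = 0.01), L, K))
  structure(list(bank = bank,
                 sigma = sigma, a = rep(a_init, m), c = rep(c_init, m),
                 rules = rules, W = W, r = rep(0, K),
                 class_order = bank$classes,
                 pooling = "sum", tnorm = "product",
                 dtw = list(normalize = normalize, band = band),
                 version = 1L),
            class = "efrbain_model")
}

#' @export
print.efrbain_model <- function(x, ...) {
  K <- length(x$class_order)
  cat(sprintf(paste0("<E-FRBAIN model: %d FRBN nodes, %d pattern nodes, ",
                     "%d rule nodes>\n"),
              bank_size(x$bank), K, nrow(x$rules)))
  cat("classes:", paste(x$class_order, collapse = ", "), "\n")
  invisible(x)
}

#' FRBN-layer fuzzification of a signal
#'
#' DTW distance from the signal to every kernel center, passed through each
#' node's [frbn_membership()].
#'
#' @param x A [signal()] (channel count must match the bank).
#' @param model An [build_model()] result.
#' @return Numeric vector of m memberships in bank order.
#' @export
fuzzify <- function(x, model) {
  xv <- as_signal_values(x)
  d <- vapply(model$bank$centers, function(z) {
    dtw_distance(xv, z$values, normalize = model$dtw$normalize,
                 band = model$dtw$band, return_path = FALSE)$distance
  }, numeric(1))
  frbn_membership(d, model$sigma, model$a, model$c)
}

## Forward pass from a precomputed distance row (distances to bank centers).
forward_from_distances <- function(d, model) {
  mu <- frbn_membership(d, model$sigma, model$a, model$c)
  h <- regularize(mu)
  q <- pattern_layer(h, model$bank, mode = model$pooling)
  z <- rule_layer(q, model$rules, tnorm = model$tnorm)
  qn <- regularize(z)
  p <- ts_classify(qn, model$W, model$r)
  k <- which.max(p)                       # ties: earlier class in class_order
  structure(list(label = model$class_order[k],
                 class_scores = stats::setNames(p, model$class_order),
                 frbn_memberships = mu,
                 pattern_memberships = stats::setNames(q, model$class_order),
                 rule_activations = qn),
            class = "efrbain_prediction")
}

#' Forward pass of the network on one signal
#'
#' Composes fuzzification, regularization I, sum pattern pooling, the product
#' rule layer, regularization II and the T-S classifier head. All intermediate
#' layer outputs are returned. The predicted label is the argmax class score
#' with ties broken toward the earlier class in the model's class order.
#'
#' @param x A [signal()].
#' @param model An `efrbain_model`.
#' @return An `efrbain_prediction`: `label`, `class_scores` (sums to 1),
#'   `frbn_memberships`, `pattern_memberships`, `rule_activations`.
#' @export
forward <- function(x, model) {
  d <- vapply(model$bank$centers, function(z) {
    dtw_distance(as_signal_values(x), z$values,
                 normalize = model$dtw$normalize, band = model$dtw$band,
                 return_path = FALSE)$distance
  }, numeric(1))
  forward_from_distances(d, model)
}

#' @export
print.efrbain_prediction <- function(x, ...) {
  cat(sprintf("<prediction: %s>\n", x$label))
  print(round(x$class_scores, 4))
  invisible(x)
}

#' Save / load a fitted network
#'
#' The archive is a directory holding `params.json` (all scalar parameters,
#' versioned), `bank_manifest.csv` and one CSV per kernel-center record under
#' `bank/`. Loading reproduces the forward map exactly.
#'
#' @param model An `efrbain_model`.
#' @param path Archive directory.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop_io("cannot create model directory %s", path)
  bank_dir <- file.path(path, "bank")
  dir.create(bank_dir, showWarnings = FALSE)
  bank <- model$bank
  files <- sprintf("center_%03d.csv", seq_along(bank$centers))
  for (i in seq_along(bank$centers)) {
    v <- bank$centers[[i]]$values
    # full precision so the loaded model's forward map is identical
    txt <- matrix(sprintf("%.17g", v), nrow(v), ncol(v))
    colnames(txt) <- paste0("ch", seq_len(ncol(v)))
    write.csv(as.data.frame(txt), file.path(bank_dir, files[i]),
              row.names = FALSE, quote = FALSE)
  }
  write.csv(data.frame(class = bank$class, subclass = bank$subclass,
                       record_id = vapply(bank$centers, `[[`, character(1),
                                          "record_id"),
                       file = file.path("bank", files)),
            file.path(path, "bank_manifest.csv"), row.names = FALSE,
            quote = FALSE)
  params <- list(format = "efrbain_model", version = model$version,
                 classes = as.list(model$class_order),
                 sigma = model$sigma, a = model$a, c = model$c,
                 W = model$W, r = model$r,
                 pooling = model$pooling, tnorm = model$tnorm,
                 dtw = list(normalize = model$dtw$normalize,
                            band = model$dtw$band))
  jsonlite::write_json(params, file.path(path, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  pj <- file.path(path, "params.json")
  if (!file.exists(pj)) stop_io("not a model archive (missing %s)", pj)
  params <- tryCatch(jsonlite::read_json(pj, simplifyVector = TRUE),
                     error = function(e)
                       stop_io("corrupt model archive: %s", conditionMessage(e)))
  if (!identical(params$format, "efrbain_model") ||
      !identical(as.integer(params$version), 1L))
    stop_io("unsupported model archive version in %s", pj)
  man <- read.csv(file.path(path, "bank_manifest.csv"),
                  colClasses = "character")
  centers <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    s <- read_record_file(file.path(path, man$file[i]), man$record_id[i])
    s$label <- man$class[i]
    centers[[i]] <- s
  }
  classes <- as.character(params$classes)
  bank <- structure(list(centers = centers, class = man$class,
                         subclass = as.integer(man$subclass),
                         classes = classes,
                         per_class_counts = stats::setNames(
                           as.integer(table(factor(man$class,
                                                   levels = classes))),
                           classes),
                         selection = NULL),
                    class = "kernel_bank")
  K <- length(classes)
  W <- matrix(as.numeric(params$W), ncol = K)
  structure(list(bank = bank,
                 sigma = as.numeric(params$sigma), a = as.numeric(params$a),
                 c = as.numeric(params$c),
                 rules = rule_index(K), W = W, r = as.numeric(params$r),
                 class_order = classes,
                 pooling = params$pooling, tnorm = params$tnorm,
                 dtw = list(normalize = isTRUE(params$dtw$normalize),
                            band = params$dtw$band),
                 version = 1L),
            class = "efrbain_model")
}
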