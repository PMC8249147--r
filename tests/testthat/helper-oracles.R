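# Independent oracles and small fixture builders used across the suite.

# single-channel signal from a numeric vector
sig <- function(x, id = "s", label = NULL) {
  signal(matrix(x, ncol = 1), record_id = id, label = label)
}

# multichannel random signal
rand_signal <- function(len, channels = 2, id = "r", label = NULL) {
  signal(matrix(rnorm(len * channels), len, channels),
         record_id = id, label = label)
}

# Brute-force DTW by recursive enumeration of every admissible warping path
# (steps down/right/diagonal from (1,1) to (N,M)); independent of the DP.
dtw_brute <- function(a, b) {
  C <- outer(a, b, function(x, y) abs(x - y))
  N <- length(a); M <- length(b)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(C[1, 1])
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    best + C[i, j]
  }
  rec(N, M)
}

# Exhaustive fuzzy-c-medoids oracle: closed-form optimal memberships for
# every candidate medoid set, minimum objective wins.
fcm_oracle <- function(D, c, fuzzifier = 2) {
  N <- ncol(D)
  bestJ <- Inf; best <- NULL
  for (set in utils::combn(N, c, simplify = FALSE)) {
    dm <- D[set, , drop = FALSE]
    U <- matrix(0, c, N)
    for (j in seq_len(N)) {
      dj <- dm[, j]
      if (any(dj <= 0)) U[which(dj <= 0)[1], j] <- 1
      else {
        w <- (1 / dj)^(2 / (fuzzifier - 1))
        U[, j] <- w / sum(w)
      }
    }
    J <- sum(U^fuzzifier * dm)
    if (J < bestJ - 1e-12) { bestJ <- J; best <- sort(set) }
  }
  list(medoids = best, objective = bestJ)
}

# random symmetric distance matrix from points in the plane
rand_distmat <- function(N, seed) {
  set.seed(seed)
  as.matrix(dist(matrix(runif(2 * N), N)))
}

# a labeled toy dataset with two well-separated shape families
toy_dataset <- function(n_per = 5, len = 30, seed = 1) {
  set.seed(seed)
  t <- seq(0, 1, length.out = len)
  sigs <- list()
  for (i in seq_len(n_per)) {
    sigs[[length(sigs) + 1L]] <-
      signal(cbind(sin(2 * pi * t) + rnorm(len, sd = 0.05),
                   cos(2 * pi * t) + rnorm(len, sd = 0.05)),
             record_id = sprintf("a%d", i), label = "A")
  }
  for (i in seq_len(n_per)) {
    sigs[[length(sigs) + 1L]] <-
      signal(cbind(5 + sin(6 * pi * t) + rnorm(len, sd = 0.05),
                   5 + cos(6 * pi * t) + rnorm(len, sd = 0.05)),
             record_id = sprintf("b%d", i), label = "B")
  }
  signal_dataset(sigs)
}

# a hand-assembled kernel bank (bypasses clustering) for network-layer tests
manual_bank <- function(centers) {
  cls <- vapply(centers, `[[`, character(1), "label")
  class_order <- unique(cls)
  sub <- integer(length(centers))
  for (k in class_order) sub[cls == k] <- seq_len(sum(cls == k))
  structure(list(centers = centers, class = cls, subclass = sub,
                 classes = class_order,
                 per_class_counts = stats::setNames(
                   as.integer(table(factor(cls, levels = class_order))),
                   class_order),
                 selection = NULL),
            class = "kernel_bank")
}
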