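## Relational fuzzy clustering over a precomputed (DTW) distance matrix.
## Centers are medoids -- actual samples -- so they can later serve as kernel
## centers of the radial basis fuzzification layer. The cluster count is
## chosen dynamically by scanning a range of counts and minimizing a validity
## index combining in-cluster coupling and between-cluster separation.

memberships_for_medoids <- function(D, medoids, fuzzifier) {
  c <- length(medoids)
  N <- ncol(D)
  dm <- D[medoids, , drop = FALSE]            # c x N
  U <- matrix(0, c, N)
  expo <- 2 / (fuzzifier - 1)
  for (j in seq_len(N)) {
    dj <- dm[, j]
    zero <- dj <= 0
    if (any(zero)) {
      # sample coincides with a medoid: crisp assignment (standard FCM
      # singularity rule; first zero-distance medoid on ties)
      U[which(zero)[1], j] <- 1
    } else {
      w <- (1 / dj)^expo
      U[, j] <- w / sum(w)
    }
  }
  U
}

fuzzy_objective <- function(D, medoids, U, fuzzifier) {
  sum(U^fuzzifier * D[medoids, , drop = FALSE])
}

#' Fuzzy c-medoids clustering of a distance matrix
#'
#' Alternating optimization of the relational fuzzy clustering objective
#' `sum_i sum_j u_ij^m d(medoid_i, j)`: memberships are the standard inverse
#' -distance update given the medoids, and each medoid is the sample
#' minimizing its cluster's weighted distance sum given the memberships.
#' Medoids are kept distinct. Iteration stops when the objective decreases by
#' less than `tol` or after `max_iter` sweeps.
#'
#' @param D Symmetric nonnegative distance matrix (e.g. [distance_matrix()]).
#' @param c Number of clusters, `1 <= c <= N`.
#' @param fuzzifier Fuzziness exponent m > 1 (default 2).
#' @param tol Convergence tolerance on the objective decrease.
#' @param max_iter Maximum alternating sweeps.
#' @param seed Seed for the initial medoid draw (`NULL` uses the current RNG).
#' @param swap If `TRUE` (default), follow the alternating optimization with a
#'   PAM-style swap refinement: single-medoid swaps (scored with their
#'   closed-form optimal memberships) are applied while they lower the
#'   objective. Alternating optimization alone frequently stalls in swap-
#'   improvable local optima on small relational matrices.
#' @param nstart Number of seeded restarts; the lowest-objective run is kept.
#' @return An object of class `fuzzy_partition`: memberships (c x N, columns
#'   sum to 1), `medoids` (sample indices), `fuzzifier`, `objective`,
#'   `objective_trace` (per accepted iteration), `iterations`, `converged`.
#' @export
fuzzy_c_medoids <- function(D, c, fuzzifier = 2, tol = 1e-6, max_iter = 200,
                            seed = NULL, swap = TRUE, nstart = 1) {
  if (nstart > 1) {
    best <- NULL
    for (r in seq_len(nstart)) {
      p <- fuzzy_c_medoids(D, c, fuzzifier = fuzzifier, tol = tol,
                           max_iter = max_iter,
                           seed = if (is.null(seed)) NULL else seed + r - 1L,
                           swap = swap, nstart = 1)
      if (is.null(best) || p$objective < best$objective) best <- p
    }
    return(best)
  }
  validate_distance_matrix(D)
  N <- ncol(D)
  if (c < 1 || c > N)
    stop_validation("cluster count %d outside 1..%d", c, N)
  if (fuzzifier <= 1) stop_validation("fuzzifier must be > 1")
  medoids <- with_seed(seed, sort(sample.int(N, c)))
  obj <- Inf
  U <- memberships_for_medoids(D, medoids, fuzzifier)
  converged <- FALSE
  iter <- 0L
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    W <- U^fuzzifier                          # c x N weights
    # candidate score of sample s for cluster i: sum_j W[i,j] d(s,j)
    scores <- D %*% t(W)                      # N x c
    new_medoids <- integer(c)
    taken <- rep(FALSE, N)
    for (i in seq_len(c)) {
      ord <- order(scores[, i], seq_len(N))   # deterministic ties: lower index
      pick <- ord[!taken[ord]][1]
      new_medoids[i] <- pick
      taken[pick] <- TRUE
    }
    U <- memberships_for_medoids(D, new_medoids, fuzzifier)
    new_obj <- fuzzy_objective(D, new_medoids, U, fuzzifier)
    medoids <- new_medoids
    trace <- c(trace, new_obj)
    if (is.finite(obj) && obj - new_obj < tol) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (swap && c < N) {
    repeat {
      improved <- FALSE
      for (i in seq_len(c)) {
        for (s in setdiff(seq_len(N), medoids)) {
          cand <- medoids
          cand[i] <- s
          Uc <- memberships_for_medoids(D, cand, fuzzifier)
          Jc <- fuzzy_objective(D, cand, Uc, fuzzifier)
          if (Jc < obj - tol) {
            medoids <- cand
            U <- Uc
            obj <- Jc
            trace <- c(trace, Jc)
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    ord <- order(medoids)
    medoids <- medoids[ord]
    U <- U[ord, , drop = FALSE]
  }
  structure(list(memberships = U, medoids = medoids, fuzzifier = fuzzifier,
                 objective = obj, objective_trace = trace, iterations = iter,
                 converged = converged),
            class = "fuzzy_partition")
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy partition: %d clusters over %d samples, objective %.6g>\n",
              length(x$medoids), ncol(x$memberships), x$objective))
  cat("medoids:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

#' Coupling degree (in-cluster compactness) of a fuzzy partition
#'
#' The fuzzily weighted mean distance to the medoids,
#' `(1/N) sum_i sum_j u_ij^m d(medoid_i, j)`; smaller is more compact.
#'
#' @param partition A [fuzzy_c_medoids()] result.
#' @param D The distance matrix the partition was fit on.
#' @return Nonnegative scalar.
#' @export
coupling_degree <- function(partition, D) {
  validate_distance_matrix(D)
  if (ncol(partition$memberships) != ncol(D))
    stop_validation("partition and distance matrix sizes differ")
  fuzzy_objective(D, partition$medoids, partition$memberships,
                  partition$fuzzifier) / ncol(D)
}

#' Separation degree (between-cluster separation) of a fuzzy partition
#'
#' The minimum pairwise medoid-to-medoid distance. Undefined for a single
#' cluster.
#'
#' @inheritParams coupling_degree
#' @return Positive scalar (0 flags a degenerate duplicate-medoid partition).
#' @export
separation_degree <- function(partition, D) {
  validate_distance_matrix(D)
  med <- partition$medoids
  if (length(med) < 2L)
    stop_validation("separation degree undefined for fewer than 2 clusters")
  M <- D[med, med, drop = FALSE]
  min(M[upper.tri(M)])
}

#' Clustering validity index
#'
#' `GD(c) = alpha * coupling + (1 - alpha) / separation`; smaller values mean
#' better clustering (compact and well separated).
#'
#' @param coupling Coupling degree (compactness), >= 0.
#' @param separation Separation degree, > 0.
#' @param alpha Coupling weight factor in `[0, 1]`.
#' @return Scalar validity score.
#' @export
validity_index <- function(coupling, separation, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop_validation("alpha must be in [0, 1]")
  if (separation <= 0) stop_validation("separation degree must be positive")
  alpha * coupling + (1 - alpha) / separation
}

#' Select the cluster count by validity-index scan
#'
#' Runs [fuzzy_c_medoids()] for each candidate count with seeded restarts
#' (keeping the lowest-objective run), scores each count by the validity
#' index, and returns the partition with minimal score. Ties are broken
#' toward the smaller count; counts with duplicate zero-distance medoids are
#' flagged degenerate and score `Inf`.
#'
#' @inheritParams fuzzy_c_medoids
#' @param c_min,c_max Candidate cluster-count range, `2 <= c_min <= c_max <= N-1`.
#' @param alpha Coupling weight of [validity_index()].
#' @param restarts Seeded restarts per count.
#' @param rescale If `TRUE` (default) the validity scores are computed on
#'   `D` divided by its mean off-diagonal entry, putting the coupling term
#'   and the reciprocal separation on a common scale whatever the distance
#'   units are. The partitions themselves are scale-invariant, so this
#'   affects only the score table.
#' @return List with `best` (the winning `fuzzy_partition`), `best_c`, and
#'   `scores` (data frame with columns c, coupling, separation, gd).
#' @export
select_cluster_count <- function(D, c_min = 2, c_max, alpha = 0.5,
                                 fuzzifier = 2, restarts = 5, tol = 1e-6,
                                 max_iter = 200, seed = NULL, rescale = TRUE) {
  validate_distance_matrix(D)
  N <- ncol(D)
  if (missing(c_max)) c_max <- N - 1L
  if (c_max < c_min) stop_validation("c_max (%d) < c_min (%d)", c_max, c_min)
  if (c_min < 2 || c_max > N - 1)
    stop_validation("cluster-count range must lie in 2..N-1 (N = %d)", N)
  Dv <- if (rescale && mean(D[upper.tri(D)]) > 0)
    D / mean(D[upper.tri(D)]) else D
  cs <- seq.int(c_min, c_max)
  parts <- vector("list", length(cs))
  scores <- data.frame(c = cs, coupling = NA_real_, separation = NA_real_,
                       gd = NA_real_)
  base_seed <- seed %||% 0L
  for (k in seq_along(cs)) {
    best <- NULL
    for (r in seq_len(restarts)) {
      p <- fuzzy_c_medoids(D, cs[k], fuzzifier = fuzzifier, tol = tol,
                           max_iter = max_iter,
                           seed = if (is.null(seed)) NULL
                                  else base_seed + 1000L * cs[k] + r)
      if (is.null(best) || p$objective < best$objective) best <- p
    }
    cd <- coupling_degree(best, Dv)
    sd <- separation_degree(best, Dv)
    scores$coupling[k] <- cd
    scores$separation[k] <- sd
    scores$gd[k] <- if (sd > 0) validity_index(cd, sd, alpha) else {
      warning(sprintf("degenerate partition at c = %d (duplicate medoids)", cs[k]))
      Inf
    }
    parts[[k]] <- best
  }
  if (all(!is.finite(scores$gd)))
    stop_validation("all candidate cluster counts degenerate")
  best_k <- which.min(scores$gd)              # ties: smaller c (first index)
  list(best = parts[[best_k]], best_c = cs[best_k], scores = scores)
}

#' Build the kernel-center bank by per-class clustering
#'
#' For each pattern class the class's records are clustered on their DTW
#' distance matrix with [select_cluster_count()]; the medoid signals become
#' the class's subclass prototypes (kernel centers). The bank is ordered
#' class-major: all centers of class 1, then class 2, and so on.
#'
#' @param dataset Labeled [signal_dataset()].
#' @param alpha Coupling weight of the validity index.
#' @param fuzzifier Fuzziness exponent.
#' @param c_range Either a length-2 vector `c(c_min, c_max)` applied to every
#'   class, or a named list of such vectors per class label. The range is
#'   clamped per class to at most `N_k - 1`; classes too small to cluster
#'   contribute a single medoid (or their lone record) with a warning.
#' @param restarts Seeded restarts per candidate count.
#' @param seed Integer seed controlling all restarts.
#' @param normalize,band DTW options (see [dtw_distance()]).
#' @return An object of class `kernel_bank`: `centers` (list of signals),
#'   `class` (class label per center), `subclass` (index within class),
#'   `classes` (class order), `per_class_counts`, and the per-class validity
#'   score tables in `selection`.
#' @export
build_kernel_bank <- function(dataset, alpha = 0.5, fuzzifier = 2,
                              c_range = c(2, 5), restarts = 5, seed = NULL,
                              normalize = FALSE, band = NULL) {
  labs <- dataset_labels(dataset)
  if (any(is.na(labs))) stop_validation("all records must be labeled")
  classes <- dataset$classes
  centers <- list(); center_class <- character(0); center_sub <- integer(0)
  counts <- integer(length(classes)); names(counts) <- classes
  selection <- vector("list", length(classes)); names(selection) <- classes
  for (k in seq_along(classes)) {
    idx <- which(labs == classes[k])
    rng <- if (is.list(c_range)) c_range[[classes[k]]] else c_range
    if (is.null(rng)) rng <- c(2, 5)
    sub <- dataset_subset(dataset, idx)
    Nk <- length(idx)
    if (Nk == 1L) {
      warning(sprintf("class '%s' has a single record; using it as its center",
                      classes[k]))
      meds_global <- idx
      selection[[k]] <- NULL
    } else {
      c_min <- rng[1]; c_max <- min(rng[2], Nk - 1L)
      D <- distance_matrix(sub, normalize = normalize, band = band)
      if (c_max < c_min) {
        warning(sprintf(
          "class '%s': only %d records; falling back to a single medoid",
          classes[k], Nk))
        p <- fuzzy_c_medoids(D, 1L, fuzzifier = fuzzifier,
                             seed = if (is.null(seed)) NULL else seed + k)
        meds_global <- idx[p$medoids]
        selection[[k]] <- NULL
      } else {
        sel <- select_cluster_count(D, c_min, c_max, alpha = alpha,
                                    fuzzifier = fuzzifier, restarts = restarts,
                                    seed = if (is.null(seed)) NULL
                                           else seed + 17L * k)
        meds_global <- idx[sel$best$medoids]
        selection[[k]] <- sel$scores
      }
    }
    for (l in seq_along(meds_global)) {
      centers[[length(centers) + 1L]] <- dataset$signals[[meds_global[l]]]
      center_class <- c(center_class, classes[k])
      center_sub <- c(center_sub, l)
    }
    counts[k] <- length(meds_global)
  }
  structure(list(centers = centers, class = center_class,
                 subclass = center_sub, classes = classes,
                 per_class_counts = counts, selection = selection),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("<kernel bank: %d centers over %d classes>\n",
              length(x$centers), length(x$classes)))
  print(x$per_class_counts)
  invisible(x)
}

#' Bank size (number of kernel centers)
#' @param bank A [build_kernel_bank()] result.
#' @return Integer.
#' @export
bank_size <- function(bank) length(bank$centers)

#' Save / load a kernel bank directory
#'
#' A bank directory holds one CSV per center plus `bank_manifest.csv`
#' (columns class, subclass, record_id, file) and, when available, a validity
#' score table `validity_<class>.csv` per class.
#'
#' @param bank A [build_kernel_bank()] result.
#' @param path Directory to write to / read from.
#' @return `save_bank` returns `path` invisibly; `load_bank` a `kernel_bank`.
#' @export
save_bank <- function(bank, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop_io("cannot create bank directory %s", path)
  files <- sprintf("center_%03d.csv", seq_along(bank$centers))
  for (i in seq_along(bank$centers)) {
    v <- bank$centers[[i]]$values
    txt <- matrix(sprintf("%.17g", v), nrow(v), ncol(v))
    colnames(txt) <- paste0("ch", seq_len(ncol(v)))
    write.csv(as.data.frame(txt), file.path(path, files[i]),
              row.names = FALSE, quote = FALSE)
  }
  write.csv(data.frame(class = bank$class, subclass = bank$subclass,
                       record_id = vapply(bank$centers, `[[`, character(1),
                                          "record_id"),
                       file = files),
            file.path(path, "bank_manifest.csv"), row.names = FALSE,
            quote = FALSE)
  for (cls in names(bank$selection)) {
    if (!is.null(bank$selection[[cls]]))
      write.csv(bank$selection[[cls]],
                file.path(path, paste0("validity_", make.names(cls), ".csv")),
                row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname save_bank
#' @export
load_bank <- function(path) {
  mf <- file.path(path, "bank_manifest.csv")
  if (!file.exists(mf)) stop_io("not a bank directory (missing %s)", mf)
  man <- read.csv(mf, colClasses = "character")
  centers <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    s <- read_record_file(file.path(path, man$file[i]), man$record_id[i])
    s$label <- man$class[i]
    centers[[i]] <- s
  }
  classes <- unique(man$class)
  structure(list(centers = centers, class = man$class,
                 subclass = as.integer(man$subclass), classes = classes,
                 per_class_counts = stats::setNames(
                   as.integer(table(factor(man$class, levels = classes))),
                   classes),
                 selection = NULL),
            class = "kernel_bank")
}
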