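#' Fit an extended fuzzy radial basis adaptive inference network
#'
#' The full pipeline behind one call: per-class fuzzy c-medoids clustering of
#' the DTW distance matrix with a validity-index scan chooses each class's
#' subclass prototypes ([build_kernel_bank()]); the prototypes become the
#' kernel centers of the network ([build_model()]); and the membership, shape,
#' offset and classifier parameters are learned by stochastic gradient descent
#' on the cross-entropy loss ([train_model()]).
#'
#' @param x A labeled [signal_dataset()].
#' @param alpha Coupling weight of the cluster-validity index, in `[0, 1]`.
#' @param fuzzifier Fuzziness exponent of the clustering (> 1).
#' @param c_range Subclass-count scan range per class (length-2 vector or a
#'   named per-class list); see [build_kernel_bank()].
#' @param restarts Clustering restarts per candidate count.
#' @param normalize,band DTW options applied throughout the model.
#' @param control Training parameters, a [train_control()].
#' @param seed Integer seed driving clustering initialization, weight
#'   initialization and batch shuffling (unless `control` sets its own).
#' @return An object of class `efrbain`: the trained `model`, the training
#'   `history`, the kernel `bank`, per-class validity `selection` tables and
#'   training-set `metrics`.
#' @examples
#' \donttest{
#' gen <- generate_dataset(generator_spec(K = 2, n_total = 40, seed = 7))
#' fit <- efrbain(gen$dataset, c_range = c(2, 3),
#'                control = train_control(max_epochs = 60, batch_count = 5),
#'                seed = 7)
#' print(fit)
#' predict(fit, gen$dataset)[1:5]
#' }
#' @export
efrbain <- function(x, alpha = 0.5, fuzzifier = 2, c_range = c(2, 5),
                    restarts = 5, normalize = FALSE, band = NULL,
                    control = train_control(), seed = 1) {
  if (!inherits(x, "frbain_dataset"))
    stop_validation("x must be a signal_dataset")
  cl <- match.call()
  bank <- build_kernel_bank(x, alpha = alpha, fuzzifier = fuzzifier,
                            c_range = c_range, restarts = restarts,
                            seed = seed, normalize = normalize, band = band)
  model <- build_model(bank, seed = seed, normalize = normalize, band = band)
  if (is.null(control$seed)) control$seed <- seed
  distances <- precompute_distances(x, model)
  fit <- train_model(model, x, control = control, distances = distances)
  metrics <- evaluate_model(fit$model, x, distances = distances)
  structure(list(model = fit$model, history = fit$history, bank = bank,
                 selection = bank$selection, metrics = metrics,
                 control = control, call = cl),
            class = "efrbain")
}

#' @export
print.efrbain <- function(x, ...) {
  cat("Extended fuzzy radial basis adaptive inference network\n\n")
  cat("Call: "); print(x$call)
  K <- length(x$model$class_order)
  cat(sprintf("\nStructure: %d kernel centers (subclasses %s), %d classes, %d rules\n",
              bank_size(x$bank),
              paste(x$bank$per_class_counts, collapse = "+"), K,
              nrow(x$model$rules)))
  h <- x$history
  cat(sprintf("Training: %d epochs, final loss %.4g (%s)\n",
              nrow(h), h$loss[nrow(h)], attr(h, "stop_reason")))
  cat(sprintf("Training accuracy: %.4f\n", x$metrics$accuracy))
  invisible(x)
}

#' @export
summary.efrbain <- function(object, ...) {
  structure(list(fit = object), class = "summary.efrbain")
}

#' @export
print.summary.efrbain <- function(x, ...) {
  print(x$fit)
  cat("\nPer-class subclass counts:\n")
  print(x$fit$bank$per_class_counts)
  cat("\nTraining-set metrics:\n")
  print(x$fit$metrics)
  invisible(x)
}

#' @export
coef.efrbain <- function(object, ...) {
  m <- object$model
  list(sigma = m$sigma, a = m$a, c = m$c, weights = m$W, bias = m$r)
}

#' Predict classes or probabilities for new signals
#'
#' @param object An [efrbain()] fit.
#' @param newdata A [signal_dataset()] or a single [signal()].
#' @param type `"class"` for predicted labels, `"prob"` for the class
#'   probability matrix, `"full"` for a list of per-record
#'   `efrbain_prediction` objects with all layer outputs.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.efrbain <- function(object, newdata,
                            type = c("class", "prob", "full"), ...) {
  type <- match.arg(type)
  model <- object$model
  if (inherits(newdata, "frbain_signal"))
    newdata <- signal_dataset(list(newdata), classes = model$class_order)
  if (!inherits(newdata, "frbain_dataset"))
    stop_validation("newdata must be a signal_dataset or signal")
  if (type == "full")
    return(lapply(newdata$signals, forward, model = model))
  distances <- precompute_distances(newdata, model)
  pred <- predict_from_distances(distances, model)
  if (type == "class") stats::setNames(pred$label, dataset_ids(newdata))
  else pred$prob
}

#' Plot the training loss curve
#'
#' @param x An [efrbain()] fit.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.efrbain <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$loss, type = "l", xlab = "epoch",
       ylab = "mean cross-entropy", main = "E-FRBAIN training loss", ...)
  invisible(x)
}
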