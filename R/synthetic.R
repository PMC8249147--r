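## Synthetic multichannel signal generator. Each pattern class holds several
## subclass templates (smooth random-phase sinusoid mixtures under a
## class-specific envelope); records are drawn from a template by a random
## monotone time warp (shared across channels, as physiological channels share
## one time base) plus i.i.d. Gaussian amplitude noise. Class sizes follow
## given proportions with largest-remainder rounding, so imbalance is exact
## and deterministic.

#' Specification of a synthetic signal dataset
#'
#' @param K Number of pattern classes.
#' @param subclasses_per_class Integer vector `m_k` of subclass template
#'   counts (recycled to length K).
#' @param n_channels Channels per record.
#' @param base_length Template length in timepoints.
#' @param warp_strength Maximum fraction of timepoints duplicated or deleted
#'   by the per-record random warp (>= 0).
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   signal units (templates have unit-scale amplitude).
#' @param class_proportions Nonnegative class proportions summing to 1.
#' @param n_total Total number of records.
#' @param template_separation Required ratio of the smallest inter-template
#'   DTW distance to the largest intra-template perturbation distance at the
#'   spec's warp/noise level (> 0).
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the spec.
#' @return A validated list of class `generator_spec`.
#' @export
generator_spec <- function(K = 3, subclasses_per_class = 2, n_channels = 3,
                           base_length = 60, warp_strength = 0.15,
                           noise_sd = 0.1, class_proportions = rep(1 / K, K),
                           n_total = 300, template_separation = 3, seed = 1) {
  subclasses_per_class <- rep_len(as.integer(subclasses_per_class), K)
  if (K < 2) stop_validation("K must be >= 2")
  if (any(subclasses_per_class < 1))
    stop_validation("subclasses_per_class must all be >= 1")
  if (base_length < 8) stop_validation("base_length must be >= 8")
  if (warp_strength < 0 || noise_sd < 0)
    stop_validation("warp_strength and noise_sd must be >= 0")
  if (length(class_proportions) != K || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-8)
    stop_validation("class_proportions must be K nonnegative values summing to 1")
  if (n_total < K) stop_validation("n_total must be >= K")
  if (template_separation <= 0)
    stop_validation("template_separation must be > 0")
  structure(list(K = K, subclasses_per_class = subclasses_per_class,
                 n_channels = n_channels, base_length = base_length,
                 warp_strength = warp_strength, noise_sd = noise_sd,
                 class_proportions = class_proportions, n_total = n_total,
                 template_separation = template_separation,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

## One candidate template: smooth sinusoid mixture with a template-specific
## fundamental frequency, a class-specific Gaussian envelope/offset and a
## subclass baseline stagger, unit amplitude scale. tid indexes templates
## globally (drives the frequency spread); `spread` widens the frequency and
## baseline gaps on separation-contract retries.
make_one_template <- function(spec, k, l, tid, jitter = 0, spread = 1) {
  T <- spec$base_length
  t <- seq(0, 1, length.out = T)
  f <- (1.5 + 1.1 * (tid - 1)) * spread + jitter  # distinct fundamental
  center <- (k - 0.5) / spec$K                 # class-specific envelope position
  env <- 0.6 + exp(-((t - center) / 0.25)^2)
  base <- 0.5 * k + 0.2 * (l - 1) * spread     # class + subclass baseline
  vals <- matrix(0, T, spec$n_channels)
  for (ch in seq_len(spec$n_channels)) {
    phase <- runif(3, 0, 2 * pi)
    vals[, ch] <- env * (sin(2 * pi * f * t + phase[1]) +
                         0.5 * sin(2 * pi * 2 * f * t + phase[2]) +
                         0.25 * sin(2 * pi * 3 * f * t + phase[3])) +
                  base
  }
  signal(vals, record_id = sprintf("template_c%d_s%d", k, l),
         label = sprintf("C%d", k))
}

#' Build the subclass templates of a generator spec
#'
#' Draws `sum(m_k)` smooth templates and verifies the separation contract:
#' every inter-template DTW distance must be at least `template_separation`
#' times the largest template-to-perturbed-record DTW distance observed at the
#' spec's warp and noise level. Re-draws with jittered frequencies for a
#' bounded number of attempts, then fails.
#'
#' @param spec A [generator_spec()].
#' @param max_tries Re-draw attempts for the separation contract.
#' @return List of template signals; each carries attributes `class` (index),
#'   `subclass` and `template_id`.
#' @export
make_templates <- function(spec, max_tries = 10) {
  with_seed(spec$seed, {
    for (try in seq_len(max_tries)) {
      templates <- list()
      tid <- 0L
      for (k in seq_len(spec$K)) {
        for (l in seq_len(spec$subclasses_per_class[k])) {
          tid <- tid + 1L
          s <- make_one_template(spec, k, l, tid,
                                 jitter = (try - 1) * runif(1, 0.05, 0.3),
                                 spread = 1 + 0.4 * (try - 1))
          attr(s, "class_index") <- k
          attr(s, "subclass") <- l
          attr(s, "template_id") <- tid
          templates[[tid]] <- s
        }
      }
      if (templates_separated(templates, spec)) return(templates)
    }
  })
  stop_validation(paste0("could not achieve the requested template separation",
                         " after %d attempts; lower noise_sd/warp_strength or",
                         " template_separation"), max_tries)
}

templates_separated <- function(templates, spec) {
  vals <- lapply(templates, `[[`, "values")
  Dt <- .cpp_dtw_matrix(vals, -1L, FALSE)
  inter <- if (length(templates) > 1) min(Dt[upper.tri(Dt)]) else Inf
  intra <- 0
  for (s in templates) {
    for (r in 1:3) {
      rec <- sample_record(s, spec$warp_strength, spec$noise_sd)
      intra <- max(intra,
                   dtw_distance(rec, s, return_path = FALSE)$distance)
    }
  }
  intra <- max(intra, 1e-12)
  inter / intra >= spec$template_separation
}

#' Draw one record from a template
#'
#' Applies a random monotone time warp -- up to `warp_strength` of the
#' template's timepoints duplicated and as many deleted, identically across
#' channels -- followed by i.i.d. Gaussian noise on every value. Uses the
#' current RNG stream.
#'
#' @param template A template [signal()].
#' @param warp_strength Maximum warped fraction (>= 0).
#' @param noise_sd Additive noise standard deviation.
#' @param record_id Identifier for the new record.
#' @return A [signal()] labeled like the template.
#' @export
sample_record <- function(template, warp_strength, noise_sd,
                          record_id = template$record_id) {
  v <- template$values
  T <- nrow(v)
  n_ops <- floor(warp_strength * T)
  idx <- seq_len(T)
  if (n_ops > 0) {
    n_dup <- sample.int(n_ops + 1L, 1L) - 1L
    n_del <- sample.int(n_ops + 1L, 1L) - 1L
    if (n_dup > 0) {
      at <- sort(sample.int(length(idx), n_dup))
      idx <- sort(c(idx, idx[at]))
    }
    if (n_del > 0 && length(idx) - n_del >= 2L) {
      drop <- sample.int(length(idx), n_del)
      idx <- idx[-drop]
    }
  }
  out <- v[idx, , drop = FALSE]
  if (noise_sd > 0) out <- out + matrix(rnorm(length(out), sd = noise_sd),
                                        nrow(out), ncol(out))
  signal(out, record_id = record_id, label = template$label)
}

#' Largest-remainder rounding of class counts
#'
#' @param proportions Nonnegative proportions summing to 1.
#' @param n_total Total count to distribute.
#' @return Integer vector summing to `n_total`; ties in the fractional
#'   remainders favor earlier classes.
#' @export
largest_remainder <- function(proportions, n_total) {
  raw <- proportions * n_total
  counts <- floor(raw)
  rem <- raw - counts
  short <- n_total - sum(counts)
  if (short > 0) {
    ord <- order(-rem, seq_along(rem))
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic labeled dataset
#'
#' Class sizes are the largest-remainder rounding of
#' `class_proportions * n_total`; within a class the subclass templates are
#' used round-robin. Fully deterministic given the spec (including its seed).
#'
#' @param spec A [generator_spec()].
#' @return A list of class `generated_dataset`: `dataset` (a
#'   [signal_dataset()] with classes `C1..CK`) and `truth` (data frame
#'   record_id, class, subclass, template_id).
#' @export
generate_dataset <- function(spec) {
  templates <- make_templates(spec)
  counts <- largest_remainder(spec$class_proportions, spec$n_total)
  by_class <- split(seq_along(templates),
                    vapply(templates, attr, integer(1), "class_index"))
  with_seed(spec$seed + 1L, {
    signals <- list(); truth <- list()
    rid <- 0L
    for (k in seq_len(spec$K)) {
      tpl_ids <- by_class[[as.character(k)]]
      for (i in seq_len(counts[k])) {
        rid <- rid + 1L
        tpl <- templates[[tpl_ids[(i - 1L) %% length(tpl_ids) + 1L]]]
        rec <- sample_record(tpl, spec$warp_strength, spec$noise_sd,
                             record_id = sprintf("rec_%05d", rid))
        signals[[rid]] <- rec
        truth[[rid]] <- data.frame(record_id = rec$record_id,
                                   class = tpl$label,
                                   subclass = attr(tpl, "subclass"),
                                   template_id = attr(tpl, "template_id"))
      }
    }
    structure(list(dataset = signal_dataset(signals,
                                            classes = paste0("C", seq_len(spec$K))),
                   truth = do.call(rbind, truth),
                   templates = templates),
              class = "generated_dataset")
  })
}

#' @export
print.generated_dataset <- function(x, ...) {
  cat("<generated dataset>\n")
  print(x$dataset)
  invisible(x)
}
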