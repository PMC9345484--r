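## Per-chunk oculomotor features and the three aggregation schemes:
## averaging (12 columns), statistical-descriptor explosion (119 columns)
## and explosion + per-feature PCA reduction (21 columns).

## the 9 list-valued features and 3 counts
LIST_FEATURES <- c("fixation_duration", "saccade_duration", "blink_duration",
                   "fixation_amplitude", "saccade_amplitude",
                   "fixation_peak_velocity", "saccade_peak_velocity",
                   "fixation_mean_velocity", "saccade_mean_velocity")
COUNT_FEATURES <- c("fixation_count", "saccade_count", "blink_count")

DESCRIPTORS <- c("mean", "median", "sd", "variance", "skewness", "kurtosis",
                 "min", "max", "range", "iqr", "rms", "entropy", "uniformity")

#' Extract the twelve base features of a chunk
#'
#' Durations (ms) of fixations, saccades and blinks; amplitudes (deg) and
#' peak/mean velocities (deg/s) of fixations and saccades; and the three
#' event counts. Events are the chunk's clipped events: durations reflect
#' the clipped span, while amplitude and velocity summaries are those of the
#' detected event (they cannot be recomputed for a partial span without the
#' raw trace).
#'
#' @param chunk_events clipped event table of one chunk (an element of
#'   `oc_chunks$events`).
#' @return object of class `oc_basefeatures`: a list of 9 numeric vectors
#'   plus 3 counts.
#' @export
extract_base_features <- function(chunk_events) {
  ev <- as.data.frame(chunk_events)
  fx <- ev[ev$kind == "fixation", , drop = FALSE]
  sc <- ev[ev$kind == "saccade", , drop = FALSE]
  bl <- ev[ev$kind == "blink", , drop = FALSE]
  structure(list(
    fixation_duration = fx$duration,
    saccade_duration = sc$duration,
    blink_duration = bl$duration,
    fixation_amplitude = fx$amplitude,
    saccade_amplitude = sc$amplitude,
    fixation_peak_velocity = fx$peak_velocity,
    saccade_peak_velocity = sc$peak_velocity,
    fixation_mean_velocity = fx$mean_velocity,
    saccade_mean_velocity = sc$mean_velocity,
    fixation_count = nrow(fx),
    saccade_count = nrow(sc),
    blink_count = nrow(bl)), class = "oc_basefeatures")
}

#' The 13 statistical descriptors of a within-chunk distribution
#'
#' mean, median, standard deviation (sample, n-1), variance, skewness
#' (m3/m2^1.5), excess kurtosis (m4/m2^2 - 3), minimum, maximum, range,
#' interquartile range (quantile type 7), root-mean-square, Shannon entropy
#' (bits) of a 10-equal-width-bin histogram over the within-chunk range, and
#' uniformity (sum of squared bin probabilities). An empty list maps to all
#' zeros (keeping row alignment with the labels); a single value or a
#' constant list has zero dispersion, zero entropy and uniformity one.
#'
#' @param values numeric vector (possibly empty).
#' @return named numeric vector of length 13.
#' @export
describe_distribution <- function(values) {
  out <- stats::setNames(numeric(length(DESCRIPTORS)), DESCRIPTORS)
  n <- length(values)
  if (n == 0L) return(out)
  out["mean"] <- mean(values)
  out["median"] <- median(values)
  out["sd"] <- if (n > 1L) sd(values) else 0
  out["variance"] <- out["sd"]^2
  m2 <- mean((values - out["mean"])^2)
  if (m2 > 0) {
    out["skewness"] <- mean((values - out["mean"])^3) / m2^1.5
    out["kurtosis"] <- mean((values - out["mean"])^4) / m2^2 - 3
  }
  out["min"] <- min(values)
  out["max"] <- max(values)
  out["range"] <- out["max"] - out["min"]
  out["iqr"] <- if (n > 1L) diff(quantile(values, c(0.25, 0.75),
                                          names = FALSE, type = 7)) else 0
  out["rms"] <- sqrt(mean(values^2))
  if (out["range"] > 0) {
    bins <- pmin(floor((values - out["min"]) / out["range"] * 10) + 1L, 10L)
    p <- tabulate(bins, 10L) / n
    out["entropy"] <- -sum(p[p > 0] * log2(p[p > 0]))
    out["uniformity"] <- sum(p^2)
  } else {
    out["entropy"] <- 0
    out["uniformity"] <- 1
  }
  out
}

check_sets <- function(sets) {
  if (length(sets) < 1L) stop("need at least one chunk")
  ok <- vapply(sets, inherits, logical(1), "oc_basefeatures")
  if (!all(ok)) stop("`sets` must be a list of oc_basefeatures")
}

#' Averaging aggregation (12 columns)
#'
#' Replaces each list-valued feature by its within-chunk mean (0 for an
#' empty list) and passes the three counts through.
#'
#' @param sets list of [extract_base_features()] results, one per chunk.
#' @return numeric matrix, chunks x 12, of class `oc_features` with
#'   attribute `scheme = "averaging"`.
#' @export
aggregate_averaging <- function(sets) {
  check_sets(sets)
  rows <- vapply(sets, function(s) {
    c(vapply(LIST_FEATURES,
             function(f) if (length(s[[f]]) > 0L) mean(s[[f]]) else 0,
             numeric(1)),
      vapply(COUNT_FEATURES, function(f) as.numeric(s[[f]]), numeric(1)))
  }, numeric(12L))
  m <- t(rows)
  colnames(m) <- c(LIST_FEATURES, COUNT_FEATURES)
  structure(m, scheme = "averaging", class = c("oc_features", class(m)))
}

#' Feature-explosion aggregation (119 columns)
#'
#' Describes each of the 9 list-valued features by the 13 statistical
#' descriptors: 3 counts + 9 x 13 = 119 columns, named
#' `<feature>__<descriptor>`.
#'
#' @inheritParams aggregate_averaging
#' @return numeric matrix, chunks x 119, class `oc_features`,
#'   `scheme = "explosion"`.
#' @export
aggregate_explosion <- function(sets) {
  check_sets(sets)
  rows <- vapply(sets, function(s) {
    c(vapply(COUNT_FEATURES, function(f) as.numeric(s[[f]]), numeric(1)),
      unlist(lapply(LIST_FEATURES, function(f) describe_distribution(s[[f]]))))
  }, numeric(3L + 9L * 13L))
  m <- t(rows)
  colnames(m) <- c(COUNT_FEATURES,
                   as.vector(t(outer(LIST_FEATURES, DESCRIPTORS,
                                     paste, sep = "__"))))
  structure(m, scheme = "explosion", class = c("oc_features", class(m)))
}

#' Explosion + PCA reduction aggregation (21 columns)
#'
#' Each feature's 13 descriptor columns are standardized (using the mean/SD
#' of `fit_rows`) and reduced to the two leading principal components fitted
#' on `fit_rows` only (leakage-free when `fit_rows` is the training set);
#' all rows are then projected. Components are oriented so their
#' largest-magnitude loading is positive, making the sign deterministic.
#' 3 counts + 9 x 2 = 21 columns.
#'
#' @inheritParams aggregate_averaging
#' @param fit_rows integer row indices used to fit the standardization and
#'   the PCA (default: all rows).
#' @return numeric matrix, chunks x 21, class `oc_features`,
#'   `scheme = "reduced"`, with attribute `explained_variance`: per-feature
#'   percentage of variance captured by the two retained components.
#' @export
aggregate_reduced <- function(sets, fit_rows = NULL) {
  expl <- aggregate_explosion(sets)
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(expl))
  if (length(fit_rows) < 13L)
    stop("need at least 13 fit rows for a stable 13-descriptor PCA")
  counts <- expl[, COUNT_FEATURES, drop = FALSE]
  out <- matrix(NA_real_, nrow(expl), 3L + 2L * length(LIST_FEATURES))
  out[, 1:3] <- counts
  cn <- c(COUNT_FEATURES, character(2L * length(LIST_FEATURES)))
  ev_pct <- stats::setNames(numeric(length(LIST_FEATURES)), LIST_FEATURES)
  for (i in seq_along(LIST_FEATURES)) {
    f <- LIST_FEATURES[i]
    block <- expl[, paste(f, DESCRIPTORS, sep = "__"), drop = FALSE]
    mu <- colMeans(block[fit_rows, , drop = FALSE])
    sg <- apply(block[fit_rows, , drop = FALSE], 2, sd)
    zb <- sweep(block, 2, mu, "-")
    zb <- sweep(zb, 2, ifelse(sg > 0, sg, 1), "/")
    zb[, sg == 0] <- 0
    cols <- 3L + (i - 1L) * 2L + 1:2
    if (all(sg == 0)) {
      message("degenerate descriptor block for ", f,
              "; components set to 0")
      out[, cols] <- 0
      ev_pct[i] <- NA_real_
    } else {
      pc <- prcomp(zb[fit_rows, , drop = FALSE], center = FALSE,
                   scale. = FALSE)
      rot <- pc$rotation[, 1:2, drop = FALSE]
      for (j in 1:2) { # deterministic sign: largest-|loading| positive
        if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
      }
      out[, cols] <- zb %*% rot
      ev_pct[i] <- 100 * sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
    }
    cn[cols] <- paste(f, c("pc1", "pc2"), sep = "__")
  }
  colnames(out) <- cn
  structure(out, scheme = "reduced", explained_variance = ev_pct,
            class = c("oc_features", class(out)))
}

#' Build a feature matrix for labeled chunks
#'
#' Convenience wrapper: extracts base features for the labeled chunks of one
#' or more chunked sessions and applies the requested aggregation scheme.
#'
#' @param chunks an `oc_chunks` object or list of them.
#' @param labeled labeled-chunk table from [binarize_heart_rate()] (rows of
#'   several participants may be concatenated).
#' @param scheme `"averaging"`, `"explosion"` or `"reduced"`.
#' @param fit_rows passed to [aggregate_reduced()].
#' @return `oc_features` matrix with one row per row of `labeled`.
#' @export
build_feature_matrix <- function(chunks, labeled,
                                 scheme = c("averaging", "explosion",
                                            "reduced"),
                                 fit_rows = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(chunks, "oc_chunks")) chunks <- list(chunks)
  names(chunks) <- vapply(chunks, function(ch) ch$table$participant[1],
                          character(1))
  sets <- lapply(seq_len(nrow(labeled)), function(r) {
    ch <- chunks[[labeled$participant[r]]]
    extract_base_features(ch$events[[labeled$index[r] + 1L]])
  })
  switch(scheme,
         averaging = aggregate_averaging(sets),
         explosion = aggregate_explosion(sets),
         reduced = aggregate_reduced(sets, fit_rows))
}
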