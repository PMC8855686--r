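#' Gaussian signal/noise model of retrieval
#'
#' For a node memory that bundles d bipolar neighbor hypervectors at
#' dimension D, the decision score of a stored neighbor decomposes into a
#' unit signal plus d - 1 cross terms, giving N(1, (d-1)/D); the score of an
#' absent probe is pure cross-term noise, N(0, d/D). These two Gaussians
#' drive threshold selection, ROC curves and capacity predictions.
#'
#' @param d (average) memory degree, >= 1 (need not be an integer when
#'   estimated).
#' @param D hypervector dimension, >= 1.
#' @return an object of class \code{capacity_model}: list with \code{d},
#'   \code{D}, \code{signal_mean}, \code{signal_var}, \code{noise_mean},
#'   \code{noise_var}.
#' @export
signal_noise_model <- function(d, D) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 1) {
    stop("`d` must be a number >= 1", call. = FALSE)
  }
  if (!is_count(D)) stop("`D` must be a positive integer", call. = FALSE)
  structure(
    list(d = d, D = as.integer(D),
         signal_mean = 1, signal_var = (d - 1) / D,
         noise_mean = 0, noise_var = d / D),
    class = "capacity_model"
  )
}

#' @export
print.capacity_model <- function(x, ...) {
  cat("<capacity_model> d = ", x$d, ", D = ", x$D,
      "; signal N(1, ", format(x$signal_var),
      "), noise N(0, ", format(x$noise_var), ")\n", sep = "")
  invisible(x)
}

#' Retrieval signal-to-noise ratio in decibels
#'
#' The power ratio of the unit signal to the cross-term noise variance
#' (d - 1)/D of a degree-d memory: \code{10 * log10(D / (d - 1))} dB.
#' Doubling D buys exactly 10*log10(2) ~ 3.01 dB. Degenerate degrees below 2
#' have no cross-term noise and return \code{Inf}.
#'
#' @param d memory degree.
#' @param D hypervector dimension.
#' @return SNR in dB (\code{Inf} for d < 2).
#' @export
snr_db <- function(d, D) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 1) {
    stop("`d` must be a number >= 1", call. = FALSE)
  }
  if (!is_count(D)) stop("`D` must be a positive integer", call. = FALSE)
  if (d < 2) return(Inf)
  10 * log10(D / (d - 1))
}

#' Theoretical ROC curve of thresholded retrieval
#'
#' True-positive rate = P(signal > T) and false-positive rate =
#' P(noise > T) under the model's Gaussians, evaluated with the normal tail
#' function (complementary error function; no lookup tables). Both rates are
#' monotone non-increasing in the threshold. A zero signal variance (d = 1)
#' degenerates to a step at T = 1.
#'
#' @param model a \code{capacity_model}.
#' @param thresholds numeric vector of threshold values.
#' @return a data.frame with columns \code{threshold}, \code{fpr},
#'   \code{tpr}.
#' @export
roc_curve <- function(model, thresholds) {
  stopifnot(inherits(model, "capacity_model"))
  tpr <- if (model$signal_var == 0) {
    as.numeric(thresholds < model$signal_mean)
  } else {
    stats::pnorm(thresholds, model$signal_mean, sqrt(model$signal_var),
                 lower.tail = FALSE)
  }
  fpr <- stats::pnorm(thresholds, model$noise_mean, sqrt(model$noise_var),
                      lower.tail = FALSE)
  data.frame(threshold = thresholds, fpr = fpr, tpr = tpr)
}

#' Equal-error decision threshold
#'
#' The operating point where the threshold sits the same number of standard
#' deviations above the noise mean as below the signal mean:
#' \code{T/sqrt(d/D) = (1 - T)/sqrt((d-1)/D)}, i.e.
#' \code{T = sqrt(d) / (sqrt(d) + sqrt(d - 1))}. Always in (0.5, 1]; tends
#' to 0.5 as d grows. The degenerate d = 1 case (zero signal variance)
#' returns 0.5.
#'
#' @param model a \code{capacity_model}.
#' @return the threshold T.
#' @export
equal_error_threshold <- function(model) {
  stopifnot(inherits(model, "capacity_model"))
  d <- model$d
  if (d <= 1) return(0.5)
  sqrt(d) / (sqrt(d) + sqrt(d - 1))
}

#' Capacity sweep over dimensionality, graph size and dimension dropping
#'
#' Runs the full encode/decode loop over a grid: for every (D, E,
#' noise-fraction) cell and every trial, generate a random graph, encode it,
#' optionally zero a random fraction of the graph hypervector's components,
#' reconstruct by iterative noise cancellation against the true graph, and
#' record whether recovery was exact. Fully seeded: the cell and trial
#' indices derive the per-trial seeds, so the sweep is a pure function of
#' \code{seed}. Per-cell failures (e.g. a divergent reconstruction) count as
#' unsuccessful trials rather than aborting the sweep.
#'
#' @param D,E numeric vectors of dimensions and edge counts (crossed).
#' @param V vertex count (scalar; default 30).
#' @param noise_frac vector of dimension-drop fractions (default 0).
#' @param trials trials per cell (default 20; the full-scale experiments in
#'   the source material use up to 1000).
#' @param seed master seed.
#' @param max_iter reconstruction iteration cap.
#' @param csv optional path; when given the result table is also written as
#'   CSV.
#' @return a data.frame with one row per cell: D, E, V, noise_frac, trials,
#'   seed0, success_rate, mean_iters, mean_mismatches.
#' @export
run_capacity_sweep <- function(D, E, V = 30L, noise_frac = 0, trials = 20L,
                               seed = 1L, max_iter = 30L, csv = NULL) {
  stopifnot(all(D >= 1), all(E >= 1), is_count(V, 2), is_count(trials),
            all(noise_frac >= 0 & noise_frac <= 1))
  grid <- expand.grid(D = D, E = E, noise_frac = noise_frac,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    Dc <- grid$D[cell]; Ec <- grid$E[cell]; nf <- grid$noise_frac[cell]
    seed0 <- as.integer(seed) + 1009L * cell
    succ <- iters <- mism <- numeric(trials)
    for (t in seq_len(trials)) {
      s <- seed0 + t
      ok <- try({
        g <- generate_random_graph(V, Ec, seed = s)
        cb <- generate_codebook(g$nodes, Dc, seed = s + 1L)
        G <- encode_graph(g, cb)
        if (nf > 0) G$vector <- drop_dimensions(G$vector, nf, seed = s + 2L)
        rec <- reconstruct_graph(G, cb, max_iter = max_iter, reference = g)
        succ[t] <- as.numeric(rec$mismatched_edges == 0)
        iters[t] <- rec$iterations
        mism[t] <- rec$mismatched_edges
      }, silent = TRUE)
      if (inherits(ok, "try-error")) {
        succ[t] <- 0; iters[t] <- NA; mism[t] <- NA
      }
    }
    rows[[cell]] <- data.frame(
      D = Dc, E = Ec, V = V, noise_frac = nf, trials = trials, seed0 = seed0,
      success_rate = mean(succ), mean_iters = mean(iters, na.rm = TRUE),
      mean_mismatches = mean(mism, na.rm = TRUE)
    )
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
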