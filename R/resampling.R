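#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] using the asymptotic two-sided
#' p-value (adequate at the subsample sizes this package uses). The
#' statistic D is the supremum absolute difference between the two
#' empirical CDFs.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = min(1, unname(kt$p.value)))
}

#' Resampled Kolmogorov-Smirnov protocol
#'
#' Score distributions compared in this package are typically large and
#' of very unequal size, so a single KS test is dominated by sample size
#' rather than distribution shape. This protocol instead subsamples both
#' distributions to a fixed size, tests, and repeats: each of
#' `iterations` rounds draws `sample_size` observations from each input
#' (without replacement when the input is at least that large, with
#' replacement otherwise), runs the two-sample KS test, and records the
#' p-value; the median p-value over all rounds is the reported outcome.
#' One root seed deterministically derives the per-iteration seeds, so
#' results are exactly reproducible.
#'
#' @param a,b Non-empty numeric samples.
#' @param iterations Number of resampling rounds (default 1000).
#' @param sample_size Observations drawn per side per round (default 1000).
#' @param seed Root seed (integer).
#' @return Object of class `resampled_ks`: `median_p`, `iterations`,
#'   `sample_size`, `per_iteration_p`, `seed`.
#' @export
resampled_ks <- function(a, b, iterations = 1000, sample_size = 1000, seed = 1) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  if (iterations <= 0 || sample_size <= 0) {
    stop("`iterations` and `sample_size` must be positive")
  }
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, iterations)
  draw <- function(x, s) {
    if (length(x) >= s) sample(x, s) else sample(x, s, replace = TRUE)
  }
  p <- vapply(iter_seeds, function(s) {
    set.seed(s)
    ks_two_sample(draw(a, sample_size), draw(b, sample_size))$p.value
  }, 0)
  structure(
    list(median_p = stats::median(p), iterations = as.integer(iterations),
         sample_size = as.integer(sample_size), per_iteration_p = p,
         seed = as.integer(seed)),
    class = "resampled_ks"
  )
}

#' @export
print.resampled_ks <- function(x, ...) {
  cat("Resampled two-sample Kolmogorov-Smirnov test\n")
  cat("  iterations:", x$iterations, " sample size:", x$sample_size,
      " seed:", x$seed, "\n")
  cat("  median p-value:", format(x$median_p, digits = 3), "\n")
  cat("  fraction of iterations with p < 0.05:",
      format(mean(x$per_iteration_p < 0.05), digits = 3), "\n")
  invisible(x)
}
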