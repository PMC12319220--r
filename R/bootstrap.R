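#' Bootstrap optimism-corrected concordance
#'
#' Estimates the optimism of an apparent concordance by replicating the full
#' model-building process on patient-level bootstrap resamples: for each
#' replicate, `build_fn` is run on the resample and the resulting risk scorer
#' is evaluated both on the resample and on the original data; the mean
#' difference is the optimism and the corrected C is apparent minus optimism.
#' Resample indices are drawn up front from the seed, so the first B1
#' replicates of a longer run coincide with a shorter run's.
#'
#' @param data One-row-per-patient dataset with follow-up time and event
#'   columns.
#' @param build_fn Function taking a dataset and returning a scoring function
#'   `function(newdata) -> numeric risk scores` (higher = higher risk), i.e.
#'   the entire development pipeline (selection, estimation) for one sample.
#' @param B Number of bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @param time,event Column names.
#' @return List of class `optimism_result`: `apparent`, `optimism`,
#'   `corrected`, `B`, `n_failed`, `replicates` (per-replicate C in-bootstrap
#'   and on-original). More than 10% failed replicates is fatal.
#' @export
bootstrap_optimism <- function(data, build_fn, B = 200, seed = 1L,
                               time = "residual_time", event = "event") {
  set.seed(seed)
  n <- nrow(data)
  idx <- replicate(B, sample.int(n, n, replace = TRUE), simplify = FALSE)
  scorer <- build_fn(data)
  apparent <- harrell_c(scorer(data), data[[time]], data[[event]])$c
  c_boot <- c_orig <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    res <- tryCatch({
      d_b <- data[idx[[b]], ]
      sc_b <- build_fn(d_b)
      c(harrell_c(sc_b(d_b), d_b[[time]], d_b[[event]])$c,
        harrell_c(sc_b(data), data[[time]], data[[event]])$c)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      c_boot[b] <- res[1]
      c_orig[b] <- res[2]
    }
  }
  failed <- sum(is.na(c_boot))
  if (failed > 0.1 * B) {
    stop(failed, " of ", B, " bootstrap replicates failed (> 10%)")
  }
  optimism <- mean(c_boot - c_orig, na.rm = TRUE)
  structure(
    list(apparent = apparent, optimism = optimism,
         corrected = apparent - optimism, B = B, n_failed = failed,
         replicates = data.frame(c_boot = c_boot, c_orig = c_orig)),
    class = "optimism_result"
  )
}

#' @export
print.optimism_result <- function(x, ...) {
  cat(sprintf("apparent C = %.3f, optimism = %.3f, corrected C = %.3f (B = %d, %d failed)\n",
              x$apparent, x$optimism, x$corrected, x$B, x$n_failed))
  invisible(x)
}

#' Percentile bootstrap CI for a difference in concordance
#'
#' Per replicate, both pipelines are rebuilt on the same patient-level
#' resample and the difference `C_a - C_b` is computed on that resample; the
#' 2.5 and 97.5 percentiles of the replicate differences form the interval.
#'
#' @param data One-row-per-patient dataset.
#' @param build_fn_a,build_fn_b Pipeline builders as in
#'   [bootstrap_optimism()]; the interval is for `C(a) - C(b)`.
#' @param B,seed,time,event As in [bootstrap_optimism()].
#' @return List: `ci` (percentile 95% interval), `delta` (replicate
#'   differences), `apparent_delta` (on the original data), `n_failed`.
#' @export
bootstrap_c_difference <- function(data, build_fn_a, build_fn_b, B = 200,
                                   seed = 1L, time = "residual_time",
                                   event = "event") {
  set.seed(seed)
  n <- nrow(data)
  idx <- replicate(B, sample.int(n, n, replace = TRUE), simplify = FALSE)
  c_of <- function(fn, d) harrell_c(fn(d), d[[time]], d[[event]])$c
  apparent <- c_of(build_fn_a(data), data) - c_of(build_fn_b(data), data)
  delta <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    delta[b] <- tryCatch({
      d_b <- data[idx[[b]], ]
      c_of(build_fn_a(d_b), d_b) - c_of(build_fn_b(d_b), d_b)
    }, error = function(e) NA_real_)
  }
  failed <- sum(is.na(delta))
  if (failed > 0.1 * B) {
    stop(failed, " of ", B, " bootstrap replicates failed (> 10%)")
  }
  ci <- stats::quantile(delta, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(ci = ci, delta = delta, apparent_delta = apparent, n_failed = failed)
}
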