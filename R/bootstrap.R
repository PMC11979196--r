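# Non-parametric case-resampling bootstrap of the fit-index battery.

#' Percentile bootstrap interval
#'
#' Empirical quantiles of the bootstrap draws using the median-unbiased
#' quantile definition (Hyndman-Fan type 8).
#'
#' @param draws Numeric vector of bootstrap draws (>= 2 finite values).
#' @param lower,upper Interval probabilities, default 0.025 and 0.975.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
percentile_interval <- function(draws, lower = 0.025, upper = 0.975) {
  x <- draws[is.finite(draws)]
  if (length(x) < 2L) {
    stop("need at least 2 finite draws for an interval", call. = FALSE)
  }
  q <- stats::quantile(x, probs = c(lower, upper), type = 8, names = FALSE)
  c(lo = q[1], hi = q[2])
}

# One bootstrap replicate: resample raw rows (the observed-case unit), then
# listwise-delete within the replicate, recompute moments and refit both
# models. Returns the index vector or a failure reason.
boot_one <- function(data, spec, estimator, chi_multiplier, divisor) {
  idx <- sample.int(data$n_rows_raw, data$n_rows_raw, replace = TRUE)
  rep_data <- as_cgfi_dataset(data$raw[idx, , drop = FALSE])
  moments <- compute_moments(rep_data, spec, divisor = divisor)
  needs_data <- estimator %in% c("DWLS", "WLS")
  fitted <- suppressWarnings(fit_cfa(
    spec, moments, estimator = estimator,
    data = if (needs_data) rep_data else NULL,
    chi_multiplier = chi_multiplier
  ))
  if (!fitted$converged) stop("replicate fit did not converge", call. = FALSE)
  baseline <- fit_baseline(spec, moments, estimator = estimator,
                           chi_multiplier = chi_multiplier, target = fitted)
  idx_set <- suppressWarnings(fit_index_set(fitted, baseline, moments))
  vapply(names(index_names()), function(f) {
    v <- idx_set[[f]]
    if (is.null(v) || length(v) != 1L) NA_real_ else as.numeric(v)
  }, numeric(1))
}

#' Bootstrap the fit-index battery
#'
#' Draws `B` non-parametric bootstrap replicates (rows resampled with
#' replacement from the raw data; listwise deletion is re-applied within
#' each replicate), refits the target and baseline models, and recomputes
#' every fit index. Replicates that fail (non-convergence, degenerate
#' moments, too few complete rows) are counted and excluded from the
#' summaries; exactly `B` attempts are made, with no retries. Each
#' replicate runs on a seed substream derived from `seed`, so results do
#' not depend on execution order.
#'
#' @param data The original `cgfi_dataset` (raw rows are the resampling
#'   unit).
#' @param spec A `cgfi_model`.
#' @param estimator Estimator name, see [fit_cfa()].
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer master seed.
#' @param chi_multiplier `"N"` or `"N-1"`, see [fit_cfa()].
#' @param divisor Covariance divisor for continuous moments.
#' @return An object of class `cgfi_boot`: `draws` (n_success x 12 matrix),
#'   `summary` (data.frame with mean, sd, q2.5, q97.5 per index),
#'   `n_requested`, `n_success`, `n_failed`, `failures` (reasons), `seed`,
#'   `unstable` (TRUE when more than half the replicates failed).
#' @export
bootstrap_indices <- function(data, spec, estimator = "ML", B = 1000L,
                              seed = 1L, chi_multiplier = c("N", "N-1"),
                              divisor = c("N", "N-1")) {
  stopifnot(inherits(data, "cgfi_dataset"), inherits(spec, "cgfi_model"),
            B >= 1L)
  chi_multiplier <- match.arg(chi_multiplier)
  divisor <- match.arg(divisor)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)

  fields <- names(index_names())
  draws <- matrix(NA_real_, B, length(fields),
                  dimnames = list(NULL, fields))
  ok <- logical(B)
  failures <- character(0)
  for (r in seq_len(B)) {
    set.seed(rep_seeds[r])
    res <- tryCatch(
      boot_one(data, spec, estimator, chi_multiplier, divisor),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      failures <- c(failures, res)
    } else {
      draws[r, ] <- res
      ok[r] <- TRUE
    }
  }
  n_success <- sum(ok)
  if (n_success == 0L) {
    stop("every bootstrap replicate failed; last reason: ",
         utils::tail(failures, 1), call. = FALSE)
  }
  unstable <- n_success < 0.5 * B
  if (unstable) {
    warning("bootstrap unstable: only ", n_success, " of ", B,
            " replicates succeeded", call. = FALSE)
  }
  draws <- draws[ok, , drop = FALSE]
  structure(
    list(draws = draws, summary = summarize_draws(draws),
         n_requested = as.integer(B), n_success = n_success,
         n_failed = as.integer(B) - n_success, failures = failures,
         seed = as.integer(seed), estimator = estimator,
         unstable = unstable),
    class = "cgfi_boot"
  )
}

# Per-index mean, SD (divisor n-1) and percentile 2.5/97.5 bounds. Indices
# that are undefined in every replicate (e.g. AIC under least-squares
# estimators) get mean NaN and NA spread, matching the report convention.
summarize_draws <- function(draws) {
  out <- data.frame(index = colnames(draws), mean = NA_real_, sd = NA_real_,
                    q2.5 = NA_real_, q97.5 = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(draws))) {
    x <- draws[, i]
    x <- x[is.finite(x)]
    if (length(x) == 0L) {
      out$mean[i] <- NaN
      next
    }
    out$mean[i] <- mean(x)
    out$sd[i] <- if (length(x) > 1L) stats::sd(x) else 0
    if (length(x) > 1L) {
      ci <- percentile_interval(x)
      out$q2.5[i] <- ci[["lo"]]
      out$q97.5[i] <- ci[["hi"]]
    } else {
      out$q2.5[i] <- out$q97.5[i] <- x
    }
  }
  out
}

#' @export
print.cgfi_boot <- function(x, ...) {
  cat("Bootstrap of fit indices:", x$n_success, "of", x$n_requested,
      "replicates succeeded (seed", paste0(x$seed, ")"), "\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Export bootstrap draws and summary
#'
#' Writes the successful replicates in long format (`replicate_id`,
#' `index`, `value`; undefined values as "NA") to `path`, and a JSON file
#' (same path with a `_summary.json` suffix) holding the per-index summary
#' plus the failure bookkeeping.
#'
#' @param result A `cgfi_boot`.
#' @param path Output CSV path.
#' @return Invisibly, a list with the two paths written.
#' @export
export_draws <- function(result, path) {
  stopifnot(inherits(result, "cgfi_boot"))
  if (result$n_success < 1L) stop("no successful draws to export",
                                  call. = FALSE)
  long <- data.frame(
    replicate_id = rep(seq_len(result$n_success), each = ncol(result$draws)),
    index = rep(colnames(result$draws), result$n_success),
    value = as.vector(t(result$draws)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE, na = "NA", quote = FALSE)
  json_path <- paste0(sub("\\.csv$", "", path), "_summary.json")
  meta <- list(
    n_requested = result$n_requested, n_success = result$n_success,
    n_failed = result$n_failed, seed = result$seed,
    estimator = result$estimator, unstable = result$unstable,
    summary = result$summary
  )
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(list(draws = path, summary = json_path))
}
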