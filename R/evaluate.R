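#' Simulation performance measures for one method
#'
#' Aggregates per-replicate basic-parameter estimates and confidence
#' intervals against the true log odds ratios: mean bias (averaged over
#' contrasts within a replicate, then over replicates), empirical coverage
#' (percent of intervals containing the truth), mean squared error, mean
#' interval length, and the Monte-Carlo standard error of the mean bias (SD
#' of per-replicate mean bias over the square root of the replicate count).
#'
#' @param estimates Matrix of estimates, one row per replicate, one column
#'   per basic parameter.
#' @param conf.low,conf.high Matching matrices of interval bounds.
#' @param truth Numeric vector of true log odds ratios (one per column).
#' @return A one-row tibble: `n_reps`, `mean_bias`, `coverage` (percent),
#'   `mse`, `mean_ci_length`, `mcse_bias`.
#' @export
nma_performance <- function(estimates, conf.low, conf.high, truth) {
  estimates <- as.matrix(estimates)
  conf.low <- as.matrix(conf.low)
  conf.high <- as.matrix(conf.high)
  if (!all(dim(estimates) == dim(conf.low)) ||
      !all(dim(estimates) == dim(conf.high)) ||
      ncol(estimates) != length(truth)) {
    stop("dimension mismatch between estimates, intervals and truth",
         call. = FALSE)
  }
  truth_m <- matrix(truth, nrow(estimates), length(truth), byrow = TRUE)
  bias_rep <- rowMeans(estimates - truth_m)
  covered <- conf.low <= truth_m & truth_m <= conf.high
  tibble::tibble(
    n_reps = nrow(estimates),
    mean_bias = mean(bias_rep),
    coverage = 100 * mean(rowMeans(covered)),
    mse = mean(rowMeans((estimates - truth_m)^2)),
    mean_ci_length = mean(rowMeans(conf.high - conf.low)),
    mcse_bias = stats::sd(bias_rep) / sqrt(nrow(estimates))
  )
}

fit_one_method <- function(data, method, level) {
  switch(
    method,
    "pl-wald" = ,
    "pl-profile" = ,
    "pl-phi" = stop("internal: PL methods handled by caller"),
    "ml" = {
      fit <- suppressWarnings(nma_fit(data, reference = "1", method = "ml"))
      if (fit$separation || !fit$converged) return(NULL)
      tidy(fit, conf.level = level)
    },
    "iv-common" = nma_iv(data, effects = "common", reference = "1",
                         level = level),
    "iv-random" = nma_iv(data, effects = "random", reference = "1",
                         level = level),
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Run a simulation scenario
#'
#' Generates `n_datasets` replicate networks from a scenario configuration
#' (replicate `j` is seeded with `base_seed + j`, so any replicate is
#' reproducible in isolation and results do not depend on execution order),
#' fits the requested methods to each, and aggregates the performance
#' measures per method. A replicate where a method fails (non-convergence,
#' flagged separation, an error, or any standard error above `1e8`) is
#' excluded for that method and counted in `n_failed`. For penalized-fit
#' methods the Fletcher dispersion estimate is recorded and the percentage
#' of replicates with `phi_hat > 1` is reported.
#'
#' @param scenario Scenario id or configuration (see [nma_simulate()]).
#' @param methods Subset of `"pl-wald"`, `"pl-profile"`, `"pl-phi"`
#'   (dispersion-inflated Wald), `"ml"`, `"iv-common"`, `"iv-random"`.
#' @param n_datasets Number of replicate datasets.
#' @param base_seed Integer; replicate `j` uses seed `base_seed + j`.
#' @param level Nominal interval coverage.
#' @param include_all_zero Keep all-zero-event studies (default `TRUE`);
#'   `FALSE` drops them before fitting, for sensitivity analyses.
#' @return A tibble of class `nma_performance_table`: one row per method
#'   with the measures of [nma_performance()] plus `pct_phi_gt_1` (`NA` for
#'   non-penalized methods) and `n_failed`.
#' @export
nma_run_scenario <- function(scenario,
                             methods = c("pl-wald", "pl-profile", "pl-phi",
                                         "ml", "iv-common", "iv-random"),
                             n_datasets = 1000, base_seed = 1,
                             level = 0.95, include_all_zero = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  cfg <- resolve_scenario(scenario)
  truth <- nma_true_effects(cfg$n_treat)
  n_basic <- length(truth)
  pl_methods <- intersect(methods, c("pl-wald", "pl-profile", "pl-phi"))
  other <- setdiff(methods, pl_methods)

  empty <- function() matrix(NA_real_, n_datasets, n_basic)
  store <- lapply(methods, function(m) {
    list(est = empty(), lo = empty(), hi = empty())
  })
  names(store) <- methods
  phi <- rep(NA_real_, n_datasets)

  for (j in seq_len(n_datasets)) {
    data <- nma_simulate(cfg, seed = base_seed + j)
    if (!include_all_zero) {
      data <- tryCatch(drop_all_zero_studies(data), error = function(e) NULL)
      if (is.null(data)) next
    }
    if (length(pl_methods) > 0) {
      fit <- tryCatch(nma_fit(data, reference = "1", method = "pl"),
                      error = function(e) NULL)
      ok <- !is.null(fit) && fit$converged &&
        all(sqrt(diag(fit$cov)) < 1e8)
      if (ok) {
        disp <- nma_dispersion(fit)
        phi[j] <- disp$phi_hat
        for (m in pl_methods) {
          td <- switch(
            m,
            "pl-wald" = tidy(fit, conf.level = level),
            "pl-profile" = tidy(fit, conf.level = level, ci_type = "profile"),
            "pl-phi" = tidy(nma_inflate(fit, disp), conf.level = level)
          )
          store[[m]]$est[j, ] <- td$estimate
          store[[m]]$lo[j, ] <- td$conf.low
          store[[m]]$hi[j, ] <- td$conf.high
        }
      }
    }
    for (m in other) {
      td <- tryCatch(fit_one_method(data, m, level), error = function(e) NULL)
      if (is.null(td) || any(td$std.error > 1e8)) next
      store[[m]]$est[j, ] <- td$estimate
      store[[m]]$lo[j, ] <- td$conf.low
      store[[m]]$hi[j, ] <- td$conf.high
    }
  }

  out <- purrr::map_dfr(methods, function(m) {
    s <- store[[m]]
    ok <- stats::complete.cases(s$est)
    perf <- if (any(ok)) {
      nma_performance(s$est[ok, , drop = FALSE], s$lo[ok, , drop = FALSE],
                      s$hi[ok, , drop = FALSE], truth)
    } else {
      tibble::tibble(n_reps = 0L, mean_bias = NA_real_, coverage = NA_real_,
                     mse = NA_real_, mean_ci_length = NA_real_,
                     mcse_bias = NA_real_)
    }
    phi_ok <- phi[!is.na(phi)]
    dplyr::bind_cols(
      tibble::tibble(
        scenario = if (is.null(cfg$id)) NA_integer_ else as.integer(cfg$id),
        method = m
      ),
      perf,
      tibble::tibble(
        pct_phi_gt_1 = if (m %in% pl_methods && length(phi_ok) > 0)
          100 * mean(phi_ok > 1) else NA_real_,
        n_failed = n_datasets - sum(ok)
      )
    )
  })
  class(out) <- c("nma_performance_table", class(out))
  out
}

#' Plot a performance table
#'
#' @param object An `nma_performance_table` from [nma_run_scenario()]
#'   (possibly several scenarios row-bound together).
#' @param measure One of `"mean_bias"`, `"coverage"`, `"mse"`,
#'   `"mean_ci_length"`, `"pct_phi_gt_1"`.
#' @param ... Unused.
#' @return A ggplot bar chart of the measure by method (faceted by scenario
#'   when several are present).
#' @method autoplot nma_performance_table
#' @export
autoplot.nma_performance_table <- function(object, measure = "mean_bias",
                                           ...) {
  measure <- match.arg(measure, c("mean_bias", "coverage", "mse",
                                  "mean_ci_length", "pct_phi_gt_1"))
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$method,
                                    y = .data[[measure]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (measure == "coverage") {
    p <- p + ggplot2::geom_hline(yintercept = 95, linetype = "dashed")
  }
  if (length(unique(object$scenario)) > 1) {
    p <- p + ggplot2::facet_wrap(~scenario)
  }
  p
}

#' @importFrom rlang .data
NULL
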