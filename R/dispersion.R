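#' Pearson statistic of a fitted NMA model
#'
#' Computes the Pearson chi-square-type statistic
#' `P = sum (r - n p_hat)^2 / (n p_hat (1 - p_hat))` over all study arms,
#' together with the residual degrees of freedom. The default degrees of
#' freedom are `m = (T - 1) + (N - 1)`; the GLM convention
#' (arms minus fitted parameters, `sum(A_i) - (N + T - 1)`) is available for
#' sensitivity analysis via `df`.
#'
#' @param fit A converged `nma_fit` with interior fitted probabilities
#'   (penalized fits always satisfy this).
#' @param df `"nma"` (default, `m = (T - 1) + (N - 1)`) or `"glm"`.
#' @return A list with `P` (scalar) and `df_m` (integer).
#' @export
nma_pearson <- function(fit, df = c("nma", "glm")) {
  df <- match.arg(df)
  stopifnot(inherits(fit, "nma_fit"))
  p <- fit$p_hat
  if (any(p <= 0 | p >= 1)) {
    stop("fitted probabilities on the boundary; Pearson statistic undefined",
         call. = FALSE)
  }
  r <- fit$data$events
  n <- fit$data$n
  v <- n * p * (1 - p)
  P <- sum((r - n * p)^2 / v)
  n_study <- length(fit$design$studies)
  n_trt <- length(fit$design$treatments)
  df_m <- if (df == "nma") (n_trt - 1L) + (n_study - 1L) else
    nrow(fit$data) - (n_study + n_trt - 1L)
  list(P = P, df_m = as.integer(df_m))
}

#' Fletcher's multiplicative overdispersion estimate
#'
#' Second stage of the multiplicative-heterogeneity adjustment: estimates the
#' overdispersion factor as `phi_hat = max(1, (P / m) / (1 + s_bar))`, where
#' `P` is the Pearson statistic, `m` the residual degrees of freedom, and
#' `s_bar` the mean over arms of
#' `s = (d v / d p) (r - n p_hat) / v = n (1 - 2 p_hat) (r - n p_hat) / v`,
#' a standardized skewness correction. Estimates below 1 are clipped to 1
#' (no underdispersion is modelled). If `1 + s_bar <= 0` the plain Pearson
#' estimator `max(1, P / m)` is used with a warning.
#'
#' @inheritParams nma_pearson
#' @return An object of class `nma_dispersion`: list with `pearson_P`,
#'   `df_m`, `phi_pearson`, `s_bar`, `phi_hat`, `clipped`, `fallback`, and
#'   `cov_inflated` (`phi_hat` times the fit's covariance).
#' @export
nma_dispersion <- function(fit, df = c("nma", "glm")) {
  pe <- nma_pearson(fit, df)
  p <- fit$p_hat
  r <- fit$data$events
  n <- fit$data$n
  v <- n * p * (1 - p)
  s <- n * (1 - 2 * p) * (r - n * p) / v
  s_bar <- mean(s)
  phi_pearson <- pe$P / pe$df_m
  fallback <- FALSE
  if (1 + s_bar <= 0) {
    warning("1 + s_bar <= 0; falling back to the plain Pearson estimator",
            call. = FALSE)
    phi_raw <- phi_pearson
    fallback <- TRUE
  } else {
    phi_raw <- phi_pearson / (1 + s_bar)
  }
  phi_hat <- max(1, phi_raw)
  structure(
    list(pearson_P = pe$P, df_m = pe$df_m, phi_pearson = phi_pearson,
         s_bar = s_bar, phi_hat = phi_hat, clipped = phi_raw < 1,
         fallback = fallback, cov_inflated = phi_hat * fit$cov),
    class = "nma_dispersion"
  )
}

#' Apply a dispersion adjustment to a fitted model
#'
#' Inflates the covariance of a fitted model by the estimated overdispersion
#' factor: point estimates and fitted probabilities are untouched, every
#' standard error is scaled by `sqrt(phi_hat)`, and downstream Wald intervals
#' widen accordingly. This is the "random-effects" penalized-likelihood model
#' in the multiplicative-heterogeneity sense.
#'
#' @param fit An `nma_fit`.
#' @param dispersion Optional `nma_dispersion`; computed from `fit` if
#'   missing.
#' @return The fit with `phi` set to `phi_hat` and `dispersion` attached.
#' @export
nma_inflate <- function(fit, dispersion = NULL) {
  stopifnot(inherits(fit, "nma_fit"))
  if (is.null(dispersion)) dispersion <- nma_dispersion(fit)
  stopifnot(inherits(dispersion, "nma_dispersion"))
  fit$phi <- dispersion$phi_hat
  fit$dispersion <- dispersion
  fit
}

#' @export
print.nma_dispersion <- function(x, ...) {
  cat("<nma_dispersion> Pearson P = ", format(x$pearson_P),
      " on m = ", x$df_m, " df\n",
      "phi_P = P/m = ", format(x$phi_pearson),
      ", s_bar = ", format(x$s_bar), "\n",
      "phi_hat = ", format(x$phi_hat),
      if (x$clipped) "  (clipped at 1)",
      if (x$fallback) "  (plain Pearson fallback)", "\n", sep = "")
  invisible(x)
}

#' @method tidy nma_dispersion
#' @export
tidy.nma_dispersion <- function(x, ...) {
  tibble::tibble(
    pearson_P = x$pearson_P, df_m = x$df_m, phi_pearson = x$phi_pearson,
    s_bar = x$s_bar, phi_hat = x$phi_hat, clipped = x$clipped,
    fallback = x$fallback
  )
}
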