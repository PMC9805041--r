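# Indices of the treatment (basic-parameter) columns of a design.
basic_idx <- function(design) {
  n_study <- length(design$studies)
  seq(n_study + 1, n_study + length(design$treatments) - 1)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the basic parameters of a fitted NMA model
#'
#' Returns one row per basic parameter (each non-reference treatment versus
#' the reference) with the log odds ratio estimate, standard error and
#' confidence interval. Standard errors are the square roots of the diagonal
#' of the inverse information matrix, scaled by `sqrt(phi)` if a dispersion
#' adjustment has been applied via [nma_inflate()].
#'
#' @param x An `nma_fit` object.
#' @param conf.level Nominal two-sided coverage (default 0.95).
#' @param ci_type `"wald"` or `"profile"` (profile-penalized-likelihood;
#'   penalized fits only).
#' @param exponentiate If `TRUE`, report odds ratios instead of log odds
#'   ratios (standard errors stay on the log scale).
#' @param ... Unused.
#' @return A tibble with columns `t1`, `t2`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `conf.level`, `ci_type`.
#' @method tidy nma_fit
#' @export
tidy.nma_fit <- function(x, conf.level = 0.95, ci_type = c("wald", "profile"),
                         exponentiate = FALSE, ...) {
  ci_type <- match.arg(ci_type)
  design <- x$design
  idx <- basic_idx(design)
  est <- unname(x$theta[idx])
  se <- unname(sqrt(x$phi * diag(x$cov)[idx]))
  if (ci_type == "wald") {
    z <- stats::qnorm((1 + conf.level) / 2)
    lo <- est - z * se
    hi <- est + z * se
  } else {
    pcis <- vapply(seq_along(idx), function(j) {
      profile_ci_basic(x, idx[j], conf.level)
    }, numeric(2))
    lo <- pcis[1, ]
    hi <- pcis[2, ]
  }
  out <- tibble::tibble(
    t1 = design$reference,
    t2 = design$treatments[-1],
    estimate = est,
    std.error = se,
    conf.low = lo,
    conf.high = hi,
    conf.level = conf.level,
    ci_type = ci_type
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' One-line model summary
#'
#' @param x An `nma_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the maximized objective, counts, method,
#'   dispersion factor and convergence flags.
#' @method glance nma_fit
#' @export
glance.nma_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_studies = length(x$design$studies),
    n_treatments = length(x$design$treatments),
    n_arms = nrow(x$data),
    n_params = length(x$theta),
    loglik = x$loglik,
    phi = x$phi,
    converged = x$converged,
    iterations = x$iterations,
    separation = isTRUE(x$separation)
  )
}

# Profile-penalized-likelihood CI for the coefficient at column `idx` of the
# design. Bounds solve 2 * (l*_max - l*_profile(d0)) = qchisq(level, 1);
# the profile re-maximizes all other parameters with the coefficient fixed,
# the penalty being recomputed from the full information matrix at each
# constrained iterate. Roots are bisected from the Wald bounds outward
# (bracket doubling up to 8 times), to 1e-6 on the deviance scale.
profile_ci_basic <- function(fit, idx, level = 0.95) {
  if (fit$method != "PL") {
    stop("profile-penalized-likelihood intervals require a PL fit",
         call. = FALSE)
  }
  Z <- fit$design$Z
  r <- fit$data$events
  n <- fit$data$n
  crit <- stats::qchisq(level, df = 1)
  est <- unname(fit$theta[idx])
  se <- sqrt(diag(fit$cov)[idx])
  pll_max <- fit$loglik

  profile_dev <- function(d0) {
    theta0 <- fit$theta
    theta0[idx] <- d0
    res <- firth_newton(Z, r, n, theta0 = theta0, fixed = idx)
    2 * (pll_max - res$pll)
  }

  find_bound <- function(direction) {
    step <- stats::qnorm((1 + level) / 2) * se * direction
    inner <- est
    outer <- est + step
    f_outer <- profile_dev(outer)
    tries <- 0L
    while (f_outer < crit && tries < 8L) {
      inner <- outer
      step <- step * 2
      outer <- outer + step
      f_outer <- profile_dev(outer)
      tries <- tries + 1L
    }
    if (f_outer < crit) {
      stop("profile-likelihood bracket failure at ", direction,
           " side (deviance ", format(f_outer), " < ", format(crit),
           " at offset ", format(outer - est), ")", call. = FALSE)
    }
    stats::uniroot(function(d) profile_dev(d) - crit, lower = min(inner, outer),
                   upper = max(inner, outer), tol = 1e-6)$root
  }

  c(find_bound(-1), find_bound(1))
}

#' Profile-penalized-likelihood confidence interval for one contrast
#'
#' Computes the interval for the log odds ratio of `t2` versus `t1` whose
#' endpoints are the values at which twice the drop from the maximized
#' penalized log-likelihood to the constrained maximum (all other parameters
#' re-maximized) equals the chi-square(1) quantile for `level`. For contrasts
#' not involving the fitted reference, the model is refitted with `t1` as
#' reference so the contrast is a coordinate of the design.
#'
#' @param fit A converged penalized `nma_fit`.
#' @param t1,t2 Treatment labels; the contrast is d(t1 -> t2).
#' @param level Nominal coverage (default 0.95).
#' @return A one-row tibble in the same shape as [tidy.nma_fit()].
#' @export
nma_profile_ci <- function(fit, t1, t2, level = 0.95) {
  stopifnot(inherits(fit, "nma_fit"))
  trts <- fit$design$treatments
  if (!all(c(t1, t2) %in% trts)) stop("unknown treatment label", call. = FALSE)
  if (t1 == t2) stop("t1 and t2 must differ", call. = FALSE)
  f <- if (identical(fit$design$reference, t1)) fit else
    nma_fit(fit$data, reference = t1, method = "pl")
  j <- which(f$design$treatments[-1] == t2)
  idx <- basic_idx(f$design)[j]
  bounds <- profile_ci_basic(f, idx, level)
  tibble::tibble(
    t1 = t1, t2 = t2,
    estimate = unname(f$theta[idx]),
    std.error = unname(sqrt(diag(f$cov)[idx])),
    conf.low = bounds[1], conf.high = bounds[2],
    conf.level = level, ci_type = "profile"
  )
}

#' League table of all pairwise contrasts
#'
#' Expands a fitted model into all `T (T - 1)` ordered treatment contrasts
#' under consistency: d(t1 -> t2) = d(ref -> t2) - d(ref -> t1), with Wald
#' variance Var(d2) + Var(d1) - 2 Cov(d1, d2) from the inverse information
#' (times `phi` if dispersion-adjusted). Profile intervals reparameterize so
#' each contrast is profiled directly.
#'
#' @param fit A converged `nma_fit`.
#' @param ci_type `"wald"` or `"profile"`.
#' @param level Nominal coverage.
#' @param keep_direction `"both"` (default; includes each pair in both
#'   orders, antisymmetric) or `"upper"` (each unordered pair once, sorted
#'   labels).
#' @return A tibble with `t1`, `t2`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `conf.level`, `ci_type`.
#' @export
nma_league <- function(fit, ci_type = c("wald", "profile"), level = 0.95,
                       keep_direction = c("both", "upper")) {
  ci_type <- match.arg(ci_type)
  keep_direction <- match.arg(keep_direction)
  stopifnot(inherits(fit, "nma_fit"))
  trts <- sort(fit$design$treatments)
  pairs <- t(utils::combn(trts, 2))
  idx <- basic_idx(fit$design)
  d_full <- c(0, unname(fit$theta[idx]))
  names(d_full) <- fit$design$treatments
  # covariance of (0, d) with zero row/col for the reference
  V <- matrix(0, length(trts), length(trts))
  dimnames(V) <- list(fit$design$treatments, fit$design$treatments)
  V[-1, -1] <- fit$phi * fit$cov[idx, idx, drop = FALSE]
  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]
    b <- pairs[i, 2]
    est <- d_full[b] - d_full[a]
    se <- sqrt(V[b, b] + V[a, a] - 2 * V[a, b])
    if (ci_type == "wald") {
      z <- stats::qnorm((1 + level) / 2)
      tibble::tibble(t1 = a, t2 = b, estimate = unname(est),
                     std.error = unname(se),
                     conf.low = unname(est - z * se),
                     conf.high = unname(est + z * se),
                     conf.level = level, ci_type = ci_type)
    } else {
      nma_profile_ci(fit, a, b, level)
    }
  })
  if (keep_direction == "both") {
    rev_rows <- rows |>
      dplyr::mutate(
        tmp = .data$t1, t1 = .data$t2, t2 = .data$tmp,
        estimate = -.data$estimate,
        lo = -.data$conf.high, conf.high = -.data$conf.low, conf.low = .data$lo
      ) |>
      dplyr::select(-"tmp", -"lo")
    rows <- dplyr::bind_rows(rows, rev_rows) |>
      dplyr::arrange(.data$t1, .data$t2)
  }
  rows
}

#' Square league matrix of odds-ratio strings
#'
#' Human-readable counterpart of [nma_league()]: a `T x T` character matrix
#' whose `[row, col]` entry is the odds ratio of the column treatment versus
#' the row treatment with its confidence interval.
#'
#' @param league A league tibble from [nma_league()] with both directions.
#' @param digits Significant digits for formatting.
#' @return A character matrix with treatment labels as dimnames.
#' @export
league_matrix <- function(league, digits = 2) {
  trts <- sort(unique(c(league$t1, league$t2)))
  m <- matrix("", length(trts), length(trts), dimnames = list(trts, trts))
  diag(m) <- trts
  for (i in seq_len(nrow(league))) {
    m[league$t1[i], league$t2[i]] <- sprintf(
      "%.*f [%.*f; %.*f]",
      digits, exp(league$estimate[i]),
      digits, exp(league$conf.low[i]),
      digits, exp(league$conf.high[i])
    )
  }
  m
}

#' Forest-style plot of basic parameters
#'
#' @param object An `nma_fit` object.
#' @param conf.level Nominal coverage for the intervals.
#' @param ci_type `"wald"` or `"profile"`.
#' @param ... Unused.
#' @return A ggplot object showing each non-reference treatment's log odds
#'   ratio versus the reference with its confidence interval.
#' @method autoplot nma_fit
#' @export
autoplot.nma_fit <- function(object, conf.level = 0.95,
                             ci_type = c("wald", "profile"), ...) {
  td <- tidy(object, conf.level = conf.level, ci_type = match.arg(ci_type))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$t2)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = sprintf("log odds ratio vs %s (%s %g%% CI)", td$t1[1],
                  td$ci_type[1], 100 * conf.level),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
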