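#' Continuity-corrected log odds ratio for one 2x2 table
#'
#' Observed log odds ratio (arm 2 versus arm 1) and its large-sample
#' variance. If any of the four cells is zero, 0.5 is added to every cell of
#' the table (the conventional reading of the correction) before computing
#' both. Tables with zero events in both arms are uninformative for the
#' classical log odds ratio and are flagged via `all_zero`.
#'
#' @param r1,n1 Events and sample size in the first (baseline) arm.
#' @param r2,n2 Events and sample size in the second arm.
#' @return A one-row tibble with `yi` (logOR), `vi` (variance), `corrected`,
#'   and `all_zero`.
#' @export
logor_cc <- function(r1, n1, r2, n2) {
  stopifnot(n1 > 0, n2 > 0, r1 >= 0, r2 >= 0, r1 <= n1, r2 <= n2)
  cells <- c(r1, n1 - r1, r2, n2 - r2)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c2 <- cells[3]; d2 <- cells[4]
  tibble::tibble(
    yi = log((c2 * b) / (a * d2)),
    vi = 1 / a + 1 / b + 1 / c2 + 1 / d2,
    corrected = corrected,
    all_zero = (r1 + r2) == 0
  )
}

# Per-study contrast records for IV-NMA. Each study contributes its arms'
# contrasts versus the study's first arm, with the shared-baseline covariance
# (the baseline arm's cell reciprocals). Cells of a study with any zero cell
# all get +0.5 first.
iv_contrasts <- function(data) {
  data <- nma_data(data)
  split(seq_len(nrow(data)), factor(data$study, levels = unique(data$study))) |>
    purrr::map(function(rows) {
      r <- data$events[rows]
      n <- data$n[rows]
      trt <- data$treatment[rows]
      all_zero <- sum(r) == 0
      cells_r <- r
      cells_nr <- n - r
      corrected <- any(cells_r == 0 | cells_nr == 0)
      if (corrected) {
        cells_r <- cells_r + 0.5
        cells_nr <- cells_nr + 0.5
      }
      base_var <- 1 / cells_r[1] + 1 / cells_nr[1]
      k <- length(rows) - 1L
      yi <- log(cells_r[-1] / cells_nr[-1]) - log(cells_r[1] / cells_nr[1])
      vi <- base_var + 1 / cells_r[-1] + 1 / cells_nr[-1]
      S <- matrix(base_var, k, k)
      diag(S) <- vi
      list(study = data$study[rows[1]], baseline = trt[1], treatment = trt[-1],
           yi = yi, S = S, corrected = corrected, all_zero = all_zero)
    })
}

#' Inverse-variance network meta-analysis
#'
#' Classical contrast-level NMA by (generalized) weighted least squares of
#' the continuity-corrected study log odds ratios on the basic-parameter
#' design. Studies with at least one zero cell get a 0.5 correction to every
#' cell; studies with zero events in all arms carry no log odds ratio
#' information and are excluded (and reported). Multi-arm studies contribute
#' all contrasts versus their first arm with the shared-baseline within-study
#' covariance. The random-effects variant adds a common heterogeneity
#' variance `tau2` (diagonal) with `tau2 / 2` within-study covariance,
#' estimated by the generalized DerSimonian-Laird moment estimator on the
#' network Q statistic.
#'
#' @param data An `nma_data` tibble.
#' @param effects `"common"` or `"random"`.
#' @param reference Reference treatment (default: lexicographically
#'   smallest).
#' @param level Nominal coverage for the Wald intervals.
#' @return A tibble of basic parameters (`t1`, `t2`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `conf.level`, `ci_type`) with
#'   attributes `tau2` and `excluded` (all-zero-event study ids).
#' @export
nma_iv <- function(data, effects = c("common", "random"), reference = NULL,
                   level = 0.95) {
  effects <- match.arg(effects)
  data <- nma_data(data)
  contrasts <- iv_contrasts(data)
  excluded <- purrr::map_chr(purrr::keep(contrasts, "all_zero"), "study")
  contrasts <- purrr::discard(contrasts, "all_zero")
  if (length(contrasts) == 0) stop("no informative studies left", call. = FALSE)
  kept <- data[data$study %in% purrr::map_chr(contrasts, "study"), , drop = FALSE]
  conn <- nma_connectivity(nma_data(kept))
  if (!conn$connected) {
    stop("network disconnected after excluding all-zero-event studies (",
         paste(excluded, collapse = ", "), ")", call. = FALSE)
  }
  treatments <- sort(unique(kept$treatment))
  if (is.null(reference)) reference <- treatments[1]
  if (!reference %in% treatments) {
    stop("unknown reference treatment: ", reference, call. = FALSE)
  }
  non_ref <- setdiff(treatments, reference)

  y <- unlist(purrr::map(contrasts, "yi"))
  n_con <- length(y)
  X <- matrix(0, n_con, length(non_ref), dimnames = list(NULL, non_ref))
  row <- 1L
  for (ct in contrasts) {
    for (j in seq_along(ct$treatment)) {
      if (ct$treatment[j] != reference) X[row, ct$treatment[j]] <- 1
      if (ct$baseline != reference) X[row, ct$baseline] <- X[row, ct$baseline] - 1
      row <- row + 1L
    }
  }
  blocks <- purrr::map(contrasts, "S")
  assemble_sigma <- function(tau2) {
    mats <- purrr::map(blocks, function(S) {
      k <- nrow(S)
      S + tau2 * (diag(k) / 2 + matrix(0.5, k, k))
    })
    as.matrix(Matrix_bdiag(mats))
  }

  gls <- function(Sigma) {
    W <- solve(Sigma)
    XtW <- crossprod(X, W)
    V <- solve(XtW %*% X)
    list(d = drop(V %*% XtW %*% y), V = V, W = W)
  }

  tau2 <- 0
  fit_c <- gls(assemble_sigma(0))
  if (effects == "random") {
    resid <- y - X %*% fit_c$d
    Q <- drop(crossprod(resid, fit_c$W %*% resid))
    df <- n_con - ncol(X)
    if (df > 0) {
      # E[Q] - df = tau2 * tr(P M): P = W - W X (X'WX)^{-1} X'W, M the
      # heterogeneity structure (1 diagonal, 1/2 within-study off-diagonal)
      W <- fit_c$W
      P <- W - W %*% X %*% solve(crossprod(X, W %*% X)) %*% crossprod(X, W)
      M <- as.matrix(Matrix_bdiag(purrr::map(blocks, function(S) {
        k <- nrow(S)
        diag(k) / 2 + matrix(0.5, k, k)
      })))
      denom <- sum(diag(P %*% M))
      tau2 <- if (denom > 0) max(0, (Q - df) / denom) else 0
    }
  }
  fit <- if (tau2 > 0) gls(assemble_sigma(tau2)) else fit_c
  se <- sqrt(diag(fit$V))
  z <- stats::qnorm((1 + level) / 2)
  out <- tibble::tibble(
    t1 = reference, t2 = non_ref,
    estimate = unname(fit$d), std.error = unname(se),
    conf.low = unname(fit$d - z * se), conf.high = unname(fit$d + z * se),
    conf.level = level, ci_type = "wald"
  )
  attr(out, "tau2") <- tau2
  attr(out, "excluded") <- unname(excluded)
  attr(out, "effects") <- effects
  out
}

# Small block-diagonal helper (dense; contrast systems here are tiny).
Matrix_bdiag <- function(mats) {
  sizes <- vapply(mats, nrow, 1L)
  total <- sum(sizes)
  out <- matrix(0, total, total)
  at <- 0L
  for (m in mats) {
    k <- nrow(m)
    out[at + seq_len(k), at + seq_len(k)] <- m
    at <- at + k
  }
  out
}
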