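test_that("continuity-corrected logOR follows the textbook formulas", {
  x <- logor_cc(1, 10, 3, 10)
  expect_equal(x$yi, log(27 / 7))
  expect_equal(x$vi, 1 + 1 / 9 + 1 / 3 + 1 / 7)
  expect_false(x$corrected)

  z <- logor_cc(0, 10, 2, 10)
  # cells become 0.5, 10.5, 2.5, 8.5
  expect_true(z$corrected)
  expect_equal(z$yi, log((2.5 * 10.5) / (0.5 * 8.5)))
  expect_equal(z$vi, 1 / 0.5 + 1 / 10.5 + 1 / 2.5 + 1 / 8.5)

  expect_equal(logor_cc(4, 12, 4, 12)$yi, 0)
  expect_true(logor_cc(0, 10, 0, 10)$all_zero)
  expect_error(logor_cc(2, 0, 1, 10))
})

test_that("single-study and equal-weight IV estimates collapse correctly", {
  d <- single_2x2()
  iv <- nma_iv(d, "common", reference = "A")
  expect_equal(iv$estimate, logor_cc(1, 10, 3, 10)$yi)

  # two studies of the same comparison with identical vi: plain mean
  d2 <- arm_tbl(c("s1", "s1", "s2", "s2"), c("A", "B", "A", "B"),
                c(1, 3, 2, 5), c(10, 10, 10, 10))
  y1 <- logor_cc(1, 10, 3, 10)
  y2 <- logor_cc(2, 10, 5, 10)
  expect_equal(nma_iv(d2, "common", reference = "A")$estimate,
               weighted.mean(c(y1$yi, y2$yi), 1 / c(y1$vi, y2$vi)))
})

test_that("network IV solves the weighted least-squares normal equations", {
  d <- nma_data(tibble::tibble(
    study = rep(c("s1", "s2", "s3"), each = 2),
    treatment = c("A", "B", "A", "C", "B", "C"),
    events = c(3L, 5L, 4L, 7L, 2L, 6L),
    n = 50L
  ))
  iv <- nma_iv(d, "common", reference = "A")
  cc <- rbind(logor_cc(3, 50, 5, 50), logor_cc(4, 50, 7, 50),
              logor_cc(2, 50, 6, 50))
  X <- matrix(c(1, 0, 0, 1, -1, 1), 3, 2, byrow = TRUE)  # (d_B, d_C)
  W <- diag(1 / cc$vi)
  oracle <- solve(t(X) %*% W %*% X, t(X) %*% W %*% cc$yi)
  expect_equal(iv$estimate, drop(oracle), tolerance = 1e-10)
  expect_equal(iv$std.error, sqrt(diag(solve(t(X) %*% W %*% X))),
               tolerance = 1e-10)
})

test_that("pairwise pooling matches metafor fixed and DL random effects", {
  set.seed(5)
  rows <- purrr::map_dfr(1:6, function(s) {
    tibble::tibble(study = paste0("s", s), treatment = c("A", "B"),
                   events = rbinom(2, 80, c(0.10, 0.22)), n = 80L)
  })
  d <- nma_data(rows)
  cc <- purrr::map_dfr(1:6, function(s) {
    r <- d$events[d$study == paste0("s", s)]
    logor_cc(r[1], 80, r[2], 80)
  })
  fe <- metafor::rma(yi = cc$yi, vi = cc$vi, method = "FE")
  re <- metafor::rma(yi = cc$yi, vi = cc$vi, method = "DL")
  expect_equal(nma_iv(d, "common", reference = "A")$estimate,
               unname(c(fe$beta)), tolerance = 1e-8)
  iv_re <- nma_iv(d, "random", reference = "A")
  expect_equal(iv_re$estimate, unname(c(re$beta)), tolerance = 1e-8)
  expect_equal(attr(iv_re, "tau2"), re$tau2, tolerance = 1e-8)
})

test_that("zero heterogeneity reproduces the common-effect fit", {
  d <- arm_tbl(rep(c("s1", "s2"), each = 2), rep(c("A", "B"), 2),
               c(3, 6, 4, 7), 60)
  iv_c <- nma_iv(d, "common", reference = "A")
  iv_r <- nma_iv(d, "random", reference = "A")
  # near-identical study results: DL truncates tau2 at zero
  expect_equal(attr(iv_r, "tau2"), 0)
  expect_equal(iv_r$estimate, iv_c$estimate)
  expect_equal(iv_r$std.error, iv_c$std.error)
})

test_that("all-zero studies are excluded and disconnection is reported", {
  d <- arm_tbl(rep(c("s1", "s2"), each = 2), c("A", "B", "B", "C"),
               c(1, 2, 0, 0), 30)
  iv <- nma_iv(d, "common", reference = "A")
  expect_equal(attr(iv, "excluded"), "s2")
  expect_equal(nrow(iv), 1)  # C drops out of the estimable set
  d_disc <- arm_tbl(rep(c("s1", "s2", "s3"), each = 2),
                    c("A", "B", "B", "C", "C", "D"),
                    c(1, 2, 0, 0, 2, 3), 30)
  expect_error(nma_iv(d_disc, "common", reference = "A"), "disconnected")
})

test_that("multi-arm studies use the shared-baseline covariance", {
  d <- arm_tbl(rep("s1", 3), c("A", "B", "C"), c(4, 6, 9), 100)
  iv <- nma_iv(d, "common", reference = "A")
  # single multi-arm study: GLS with the exact within-study covariance
  # reproduces the per-contrast logORs (the system is saturated)
  expect_equal(iv$estimate,
               c(logor_cc(4, 100, 6, 100)$yi, logor_cc(4, 100, 9, 100)$yi),
               tolerance = 1e-10)
})

test_that("inverse-variance NMA is more negatively biased than penalized", {
  reps <- 80
  bias <- cached("iv_vs_pl_sc1", {
    pl <- ml <- numeric(0)
    truth <- nma_true_effects(5)
    for (j in seq_len(reps)) {
      d <- nma_simulate(1, seed = 40000 + j)
      pl_fit <- nma_fit(d, "1")
      iv <- tryCatch(nma_iv(d, "common", reference = "1"),
                     error = function(e) NULL)
      if (is.null(iv) || nrow(iv) != 4 || !pl_fit$converged) next
      pl <- c(pl, mean(unname(pl_fit$theta[21:24]) - truth))
      ml <- c(ml, mean(iv$estimate - truth))
    }
    c(pl = mean(pl), iv = mean(ml))
  })
  expect_lt(bias["iv"], bias["pl"])
})
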