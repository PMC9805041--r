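test_that("log-likelihood matches closed forms and the per-arm oracle", {
  one <- arm_tbl(c("s1", "s1"), c("A", "B"), c(0, 0), c(10, 10))
  des <- nma_design(one, "A")
  # eta = 0 everywhere: each arm contributes log C(n,0) + 10 log 0.5
  expect_equal(nma_loglik(c(0, 0), one, des), 20 * log(0.5))

  d <- toy_two_study()
  des <- nma_design(d, "A")
  expect_equal(nma_loglik(rep(0, 4), d, des),
               sum(lchoose(d$n, d$events)) + sum(d$n) * log(0.5))

  set.seed(7)
  for (i in 1:5) {
    theta <- rnorm(4)
    # dbinom's log-pmf already carries the binomial coefficients
    expect_equal(nma_loglik(theta, d, des), loglik_oracle(theta, d, des),
                 tolerance = 1e-12)
  }
  expect_error(nma_loglik(c(0, 0, 0, Inf), d, des), "non-finite")
})

test_that("Fisher information is Z'WZ with binomial weights", {
  d <- single_2x2(50, 100, 50, 100)
  des <- nma_design(d, "A")
  info <- nma_fisher_info(c(0.5, 0.5), d, des)
  # W entries n p (1-p) = 25; hand assembly for Z = [(1,0),(1,1)]
  expect_equal(unname(info), matrix(c(50, 25, 25, 25), 2))

  d2 <- toy_two_study()
  des2 <- nma_design(d2, "A")
  p <- c(0.1, 0.3, 0.05, 0.02)
  w <- d2$n * p * (1 - p)
  hand <- matrix(0, 4, 4)
  for (a in 1:4) hand <- hand + w[a] * tcrossprod(des2$Z[a, ])
  I <- nma_fisher_info(p, d2, des2)
  expect_equal(unname(I), hand)
  expect_equal(I, t(I))
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(4)
    expect_gte(drop(crossprod(x, I %*% x)), 0)
  }
  expect_error(nma_fisher_info(c(0, 0.3, 0.5, 0.2), d2, des2), "inside")
})

test_that("penalized log-likelihood composes likelihood and log-determinant", {
  d <- toy_two_study()
  des <- nma_design(d, "A")
  set.seed(11)
  for (i in 1:5) {
    theta <- rnorm(4) / 2
    p <- plogis(as.vector(des$Z %*% theta))
    expect_equal(
      nma_penalized_loglik(theta, d, des),
      nma_loglik(theta, d, des) +
        0.5 * determinant(nma_fisher_info(p, d, des))$modulus[[1]],
      tolerance = 1e-12
    )
  }
})

test_that("scaling all sample sizes by 4 adds half dim log 4 to the penalty", {
  d <- toy_two_study()
  d4 <- d
  d4$n <- d$n * 4L
  des <- nma_design(d, "A")
  des4 <- nma_design(d4, "A")
  theta <- c(-1, -2, 0.5, 0.3)
  pen <- function(data, design) {
    nma_penalized_loglik(theta, data, design) - nma_loglik(theta, data, design)
  }
  expect_equal(pen(d4, des4) - pen(d, des), 0.5 * 4 * log(4),
               tolerance = 1e-10)
})

test_that("penalized fit of the 2x2 equals the half-cell-corrected logOR", {
  fit <- nma_fit(single_2x2(), reference = "A")
  expect_true(fit$converged)
  # saturated one-study model: Firth = +1/2 per cell, p = (r + 1/2)/(n + 1)
  expect_equal(unname(fit$theta[2]), log((3.5 * 9.5) / (1.5 * 7.5)),
               tolerance = 1e-6)
  expect_equal(fit$p_hat, c(1.5, 3.5) / 11, tolerance = 1e-6)
  # grid-search oracle over the penalized surface
  gm <- grid_maximize_pll(single_2x2(), fit$design,
                          lower = c(-4, -3), upper = c(2, 4))
  expect_equal(unname(fit$theta), gm$theta, tolerance = 1e-4)
})

test_that("three-parameter fits match the grid-search oracle", {
  d <- arm_tbl(rep("s1", 3), c("A", "B", "C"), c(0, 2, 4), c(20, 20, 20))
  fit <- nma_fit(d, reference = "A")
  gm <- grid_maximize_pll(d, fit$design,
                          lower = c(-5, -2, -2), upper = c(1, 4, 5))
  expect_equal(unname(fit$theta), gm$theta, tolerance = 1e-4)
})

test_that("all-zero-event networks get finite symmetric estimates", {
  d <- single_2x2(0, 10, 0, 10)
  fit <- nma_fit(d, reference = "A")
  expect_true(fit$converged)
  expect_equal(unname(fit$theta[2]), 0, tolerance = 1e-8)
  expect_true(all(is.finite(sqrt(diag(fit$cov)))))
  expect_true(all(fit$p_hat > 0 & fit$p_hat <= 0.5))
})

test_that("ML fit recovers the empirical logOR and flags separation", {
  fit <- suppressWarnings(nma_fit(single_2x2(), reference = "A",
                                  method = "ml"))
  expect_equal(unname(fit$theta[2]), log((3 * 9) / (1 * 7)), tolerance = 1e-6)
  expect_false(fit$separation)
  expect_warning(nma_fit(single_2x2(0, 10, 3, 10), method = "ml"),
                 "separation")
  sep <- suppressWarnings(nma_fit(single_2x2(0, 10, 3, 10), method = "ml"))
  expect_true(sep$separation)
})

test_that("the penalty vanishes in the large-count limit", {
  d <- arm_tbl(c("s1", "s1", "s2", "s2"), c("A", "B", "A", "C"),
               c(20000, 30000, 25000, 15000), 100000)
  pl <- nma_fit(d, reference = "A")
  ml <- nma_fit(d, reference = "A", method = "ml")
  expect_lt(max(abs(pl$theta - ml$theta)), 1e-3)
})

test_that("penalized estimates are less biased and shrunk versus ML", {
  set.seed(101)
  reps <- 300
  d_pl <- d_ml <- rep(NA_real_, reps)
  for (i in seq_len(reps)) {
    r1 <- rbinom(1, 30, 0.1)
    r2 <- rbinom(1, 30, plogis(qlogis(0.1) + 1))
    d <- arm_tbl(c("s1", "s1"), c("A", "B"), c(r1, r2), 30)
    d_pl[i] <- unname(nma_fit(d, "A")$theta[2])
    mlfit <- suppressWarnings(nma_fit(d, "A", method = "ml"))
    if (!mlfit$separation) d_ml[i] <- unname(mlfit$theta[2])
  }
  finite <- !is.na(d_ml)
  expect_lt(abs(mean(d_pl) - 1), abs(mean(d_ml[finite]) - 1))
  # shrinkage toward zero holds for the bulk of fixtures, not asserted
  # individually
  expect_gt(mean(abs(d_pl[finite]) <= abs(d_ml[finite]) + 1e-10), 0.9)
})

test_that("relabelling the reference only transforms contrasts consistently", {
  d <- nma_simulate(1, seed = 9)
  fit_a <- nma_fit(d, reference = "1")
  fit_b <- nma_fit(d, reference = "3")
  league_a <- nma_league(fit_a)
  league_b <- nma_league(fit_b)
  expect_equal(league_a$estimate, league_b$estimate, tolerance = 1e-10)
  expect_equal(league_a$std.error, league_b$std.error, tolerance = 1e-10)
})

test_that("fitted probabilities follow the linear predictor", {
  d <- single_2x2()
  fit <- nma_fit(d, "A")
  pp <- predicted_probabilities(fit)
  expect_equal(pp$p_hat, plogis(as.vector(fit$design$Z %*% fit$theta)))
  # alpha = -3, d = 1 gives expit(-2) on the treated arm
  expect_equal(plogis(-3 + 1), 0.119202922, tolerance = 1e-8)
})
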