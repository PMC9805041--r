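# Small fixtures built in code, plus independent oracles used across files.

arm_tbl <- function(study, treatment, events, n) {
  nma_data(tibble::tibble(study = study, treatment = treatment,
                          events = as.integer(events), n = as.integer(n)))
}

# two studies sharing treatment A: {s1: A,B}, {s2: A,C}
toy_two_study <- function() {
  arm_tbl(c("s1", "s1", "s2", "s2"), c("A", "B", "A", "C"),
          c(1, 3, 2, 0), c(10, 10, 50, 50))
}

single_2x2 <- function(r1 = 1, n1 = 10, r2 = 3, n2 = 10) {
  arm_tbl(c("s1", "s1"), c("A", "B"), c(r1, r2), c(n1, n2))
}

# Independent per-arm binomial log-pmf summation oracle
loglik_oracle <- function(theta, data, design) {
  eta <- as.vector(design$Z %*% theta)
  p <- 1 / (1 + exp(-eta))
  sum(dbinom(data$events, data$n, p, log = TRUE))
}

# Coarse-to-fine grid maximization of the penalized log-likelihood for
# models with 2 or 3 parameters; independent of the Newton optimizer.
grid_maximize_pll <- function(data, design, lower, upper, steps = 21,
                              refinements = 6) {
  k <- ncol(design$Z)
  stopifnot(k == length(lower), k <= 3)
  centre <- (lower + upper) / 2
  half <- (upper - lower) / 2
  best <- centre
  for (it in seq_len(refinements)) {
    grids <- lapply(seq_len(k), function(j) {
      seq(best[j] - half[j], best[j] + half[j], length.out = steps)
    })
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, function(th) {
      tryCatch(nma_penalized_loglik(th, data, design),
               error = function(e) -Inf)
    })
    best <- pts[which.max(vals), ]
    half <- half * 2 / (steps - 1)  # shrink window around the best point
  }
  list(theta = unname(best), value = max(vals))
}

# Memoised store for expensive simulation reruns shared across test blocks
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}
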