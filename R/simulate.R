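#' True basic-parameter log odds ratios for a simulated network
#'
#' The simulation design fixes the true log odds ratios of treatments
#' `2..T` versus treatment 1 at equal intervals between 0 and 1:
#' `d_k = k / (T - 1)` for `k = 1, ..., T - 1` (so with five treatments the
#' true values are 0.25, 0.5, 0.75 and 1).
#'
#' @param n_treat Number of treatments (at least 2).
#' @return Numeric vector of length `n_treat - 1`, named by treatment label
#'   (`"2"`, ..., `"T"`).
#' @export
nma_true_effects <- function(n_treat) {
  if (n_treat < 2) stop("need at least 2 treatments", call. = FALSE)
  d <- seq_len(n_treat - 1) / (n_treat - 1)
  names(d) <- as.character(2:n_treat)
  d
}

#' The packaged simulation scenario grid
#'
#' Thirty-three network configurations varying the number of treatments
#' (3/5/8), arm sizes (30-60 or 100-200 participants), studies per
#' comparison (2/4/8), between-study heterogeneity (tau 0 or 0.1), study
#' design (complete two-arm grids or all-arm multi-arm studies), and
#' control-group risk ranges from 0.1%-0.3% up to 5%-10%. Scenario 33 is the
#' extreme-rarity configuration designed to produce many all-zero-event
#' studies.
#'
#' @return A tibble with one row per scenario: `id`, `n_treat`, `n_min`,
#'   `n_max`, `studies_per_comparison`, `design`, `tau`, `risk_min`,
#'   `risk_max`.
#' @export
nma_scenarios <- function() {
  path <- system.file("extdata", "scenarios.yaml", package = "firthnma",
                      mustWork = TRUE)
  purrr::map_dfr(yaml::read_yaml(path), tibble::as_tibble)
}

resolve_scenario <- function(scenario) {
  if (is.numeric(scenario) && length(scenario) == 1) {
    grid <- nma_scenarios()
    row <- grid[grid$id == scenario, ]
    if (nrow(row) != 1) stop("unknown scenario id: ", scenario, call. = FALSE)
    return(as.list(row))
  }
  scenario <- as.list(scenario)
  required <- c("n_treat", "n_min", "n_max", "studies_per_comparison",
                "design", "tau", "risk_min", "risk_max")
  missing_f <- setdiff(required, names(scenario))
  if (length(missing_f) > 0) {
    stop("scenario is missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(scenario$risk_min > 0, scenario$risk_max < 1,
            scenario$risk_min <= scenario$risk_max,
            scenario$n_min <= scenario$n_max)
  scenario
}

#' Simulate one arm-level network dataset
#'
#' Generates a fully-connected network of trials with binary outcomes.
#' Treatments are labelled `"1"` (the reference) to `"T"`. Under the
#' `two_arm_complete` design, `studies_per_comparison` two-arm studies are
#' generated for each of the `T (T - 1) / 2` pairwise comparisons; under
#' `all_arm_multi`, `studies_per_comparison` studies each containing all `T`
#' arms. Per study: a single arm size is drawn uniformly (integers) on
#' `[n_min, n_max]` and shared by all arms; a control-group risk `p1` is
#' drawn uniformly on `[risk_min, risk_max]` whether or not treatment 1 is
#' in the study; study-level log odds ratios versus treatment 1 equal the
#' true values when `tau = 0` and otherwise get a normal random effect with
#' SD `tau` (pairwise correlation 1/2 across contrasts of one study, the
#' consistent homogeneous-heterogeneity structure); arm event counts are
#' binomial with the implied odds. All-zero-event studies are retained.
#'
#' @param scenario A scenario id (row of [nma_scenarios()]) or a list/row
#'   with fields `n_treat`, `n_min`, `n_max`, `studies_per_comparison`,
#'   `design`, `tau`, `risk_min`, `risk_max`.
#' @param seed Optional integer seed for reproducibility.
#' @param return_latent If `TRUE`, attach the per-study latent log odds
#'   ratios (attribute `"latent"`) for calibration checks.
#' @return An `nma_data` tibble with attributes `true_effects` (named
#'   vector, treatments vs `"1"`) and optionally `latent`.
#' @export
nma_simulate <- function(scenario, seed = NULL, return_latent = FALSE) {
  cfg <- resolve_scenario(scenario)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_treat <- as.integer(cfg$n_treat)
  d_true <- nma_true_effects(n_treat)
  treatments <- as.character(seq_len(n_treat))

  study_arms <- switch(
    as.character(cfg$design),
    two_arm_complete = {
      pairs <- utils::combn(treatments, 2, simplify = FALSE)
      rep(pairs, each = cfg$studies_per_comparison)
    },
    all_arm_multi = replicate(cfg$studies_per_comparison, treatments,
                              simplify = FALSE),
    stop("unknown design: ", cfg$design, call. = FALSE)
  )

  n_study <- length(study_arms)
  sizes <- sample(seq(cfg$n_min, cfg$n_max), n_study, replace = TRUE)
  p1 <- stats::runif(n_study, cfg$risk_min, cfg$risk_max)
  tau <- cfg$tau
  # latent study-level logORs vs treatment 1 (delta_1k); shared + own normal
  # components give Var = tau^2, within-study Cov = tau^2 / 2
  latent <- matrix(rep(d_true, each = n_study), nrow = n_study)
  if (tau > 0) {
    shared <- stats::rnorm(n_study, 0, tau / sqrt(2))
    own <- matrix(stats::rnorm(n_study * (n_treat - 1), 0, tau / sqrt(2)),
                  nrow = n_study)
    latent <- latent + shared + own
  }
  colnames(latent) <- names(d_true)

  rows <- purrr::map_dfr(seq_len(n_study), function(i) {
    arms <- study_arms[[i]]
    delta <- c("1" = 0, latent[i, ])
    odds1 <- p1[i] / (1 - p1[i])
    odds <- odds1 * exp(delta[arms])
    p <- odds / (1 + odds)
    tibble::tibble(
      study = sprintf("s%03d", i),
      treatment = arms,
      events = stats::rbinom(length(arms), sizes[i], p),
      n = sizes[i]
    )
  })
  out <- nma_data(rows)
  attr(out, "true_effects") <- d_true
  if (return_latent) attr(out, "latent") <- latent
  if (!is.null(cfg$id)) attr(out, "scenario_id") <- cfg$id
  out
}
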