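#' Simulate a recovery table from known model coefficients
#'
#' Generates per-run recoveries for each compound as the polynomial
#' evaluation of a known coefficient vector at the design's coded points
#' plus homoscedastic Gaussian noise, emulating the replicate scatter of the
#' extraction experiments. The shipped coefficient tables
#' ([quechers_coefficients()]) are the default ground truth in tests, so
#' simulated experiments inhabit the study's actual surface geometry.
#'
#' @param design a \code{\link{ccf_design}}.
#' @param truth named list of \code{recovery_model}s, or a numeric matrix
#'   (terms x compounds), giving the generating coefficient vectors.
#' @param noise_sd standard deviation of the additive recovery noise, in
#'   percentage points (default 2).
#' @param seed integer seed; the table is deterministic given the seed.
#' @param clip_low lower clip for generated recoveries (default 0:
#'   recoveries cannot be negative; no upper clip, since observed
#'   recoveries above 110% do occur).
#' @return A \code{\link{recovery_table}}.
#' @examples
#' des <- ccf_design(chd_factor_space(), 3)
#' tab <- simulate_recoveries(des, quechers_coefficients("acetate"),
#'                            noise_sd = 2, seed = 42)
#' @export
simulate_recoveries <- function(design, truth, noise_sd = 2, seed = NULL,
                                clip_low = 0) {
  stopifnot(inherits(design, "ccf_design"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  space <- attr(design, "space")
  if (is.list(truth) && !is.data.frame(truth)) {
    truth <- vapply(truth, `[[`,
                    numeric(length(truth[[1]]$coefficients)), "coefficients")
  }
  truth <- as.matrix(truth)
  X <- expand_terms(coded_matrix(design), space$name)
  if (nrow(truth) != ncol(X)) {
    stop("coefficient vectors have ", nrow(truth), " terms; basis has ",
         ncol(X))
  }
  mean_resp <- X %*% truth
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0) {
    matrix(stats::rnorm(length(mean_resp), 0, noise_sd), nrow(mean_resp))
  } else 0
  obs <- pmax(mean_resp + noise, clip_low)
  recovery_table(design, obs)
}

#' Simulate paired solvent/matrix calibration series
#'
#' Generates a solvent series with the given slope and a matrix series
#' whose slope is \code{slope_solvent * (1 + me_true/100)}, at
#' \code{n_levels} evenly spaced concentration levels spanning the linear
#' range, with additive Gaussian noise on the responses.
#'
#' @param slope_solvent generating solvent-calibration slope.
#' @param me_true generating matrix effect (%).
#' @param n_levels number of calibration levels (>= 3; default 5).
#' @param noise_sd response noise standard deviation (signal units).
#' @param seed integer seed.
#' @param intercept common baseline response (default 0).
#' @param linear_range concentration range to span (default 0.005--0.1
#'   mg L^-1).
#' @param compound label attached to the series.
#' @return List with elements \code{solvent} and \code{matrix}, each a
#'   \code{\link{calibration_series}}.
#' @examples
#' cal <- simulate_calibration(1e5, me_true = -30, noise_sd = 0)
#' with(cal, compute_matrix_effect(fit_calibration_slope(matrix),
#'                                 fit_calibration_slope(solvent)))
#' @export
simulate_calibration <- function(slope_solvent, me_true, n_levels = 5,
                                 noise_sd = 0, seed = NULL, intercept = 0,
                                 linear_range = c(0.005, 0.1),
                                 compound = "compound") {
  if (n_levels < 3) stop("need at least 3 calibration levels")
  conc <- seq(linear_range[1], linear_range[2], length.out = n_levels)
  slope_matrix <- slope_solvent * (1 + me_true / 100)
  if (!is.null(seed)) set.seed(seed)
  noise <- function() if (noise_sd > 0) stats::rnorm(n_levels, 0, noise_sd)
                      else 0
  list(
    solvent = calibration_series(compound, "solvent", conc,
                                 intercept + slope_solvent * conc + noise(),
                                 linear_range),
    matrix = calibration_series(compound, "matrix", conc,
                                intercept + slope_matrix * conc + noise(),
                                linear_range)
  )
}
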