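#' Predict every compound's recovery at one set of natural-unit conditions
#'
#' Encodes the conditions with the factor space and evaluates each model's
#' full polynomial.
#'
#' @param models named list of \code{recovery_model}s.
#' @param conditions_natural named numeric vector of natural-unit settings.
#' @param space the shared \code{\link{factor_space}}.
#' @return Named numeric vector of predicted recoveries (%), one per
#'   compound.
#' @examples
#' models <- quechers_coefficients("citrate")
#' predict_all(models, c(SW = 3.23, AM = 52.8, EV = 8, WC = 3.8, ET = 1.8),
#'             chd_factor_space())
#' @export
predict_all <- function(models, conditions_natural, space) {
  coded <- encode_factors(space, conditions_natural)
  vapply(models, function(m) unname(predict(m, coded)), numeric(1))
}

#' Optimize extraction conditions toward a target recovery
#'
#' Searches the coded hypercube \eqn{[-1, +1]^k} (no extrapolation beyond
#' the studied ranges) for conditions driving every compound's predicted
#' recovery to the target. The solve is lexicographic: first find settings
#' where the worst-case deviation \eqn{\max_c |pred_c - target|} is within
#' \code{tolerance}; then, among feasible settings, prefer the minimum
#' values of the experimental variables, quantified as the smallest
#' unweighted sum of per-factor scaled positions \eqn{(u - low)/(high -
#' low)}. If no feasible point exists the minimizer of the worst-case
#' deviation is returned with \code{feasible = FALSE}.
#'
#' Because the surfaces are degree-3 polynomials with possible multiple
#' optima, a dense grid scan (\code{n_grid} points per axis) runs first and
#' a Nelder-Mead polish refines the best grid point inside the cube.
#'
#' @param models named list of \code{recovery_model}s sharing one factor
#'   space and basis.
#' @param space the \code{\link{factor_space}}.
#' @param target target recovery (%); default 100.
#' @param tolerance feasibility half-width in recovery points; default 2.5.
#' @param minimize_variables if \code{TRUE} (default) apply the
#'   minimum-variable tie-break among feasible points; if \code{FALSE}
#'   return the minimizer of the worst-case deviation.
#' @param n_grid grid resolution per axis (default 21).
#' @param polish run the simplex refinement after the grid scan.
#' @return An object of class \code{optimization_result}: list with
#'   \code{conditions_coded}, \code{conditions_natural}, \code{predictions}
#'   (recomputed at the returned point), \code{feasible},
#'   \code{objective_value} (worst-case deviation), \code{target},
#'   \code{tolerance}.
#' @export
optimize_conditions <- function(models, space, target = 100, tolerance = 2.5,
                                minimize_variables = TRUE, n_grid = 21,
                                polish = TRUE) {
  if (length(models) < 1) stop("need at least one model")
  k <- nrow(space)
  n_terms <- unique(vapply(models, function(m) length(m$terms), integer(1)))
  if (length(n_terms) != 1) stop("models have inconsistent term bases")
  coef_mat <- vapply(models, `[[`, numeric(n_terms), "coefficients")

  max_dev <- function(coded_mat) {
    X <- expand_terms(coded_mat, space$name)
    pred <- X %*% coef_mat
    apply(abs(pred - target), 1, max)
  }
  scaled_sum <- function(coded_mat) rowSums((coded_mat + 1) / 2)

  # grid scan, chunked over the first factor to bound memory
  axis <- seq(-1, 1, length.out = n_grid)
  rest <- if (k > 1) as.matrix(expand.grid(rep(list(axis), k - 1)))
          else matrix(numeric(0), nrow = 1, ncol = 0)
  best <- list(dev = Inf, cost = Inf, x = NULL, feasible = FALSE)
  for (a in axis) {
    chunk <- cbind(a, rest)
    colnames(chunk) <- space$name
    dev <- max_dev(chunk)
    feas <- dev <= tolerance
    if (minimize_variables && any(feas)) {
      cost <- scaled_sum(chunk[feas, , drop = FALSE])
      i <- which.min(cost)
      if (!best$feasible || cost[i] < best$cost) {
        idx <- which(feas)[i]
        best <- list(dev = dev[idx], cost = cost[i],
                     x = chunk[idx, ], feasible = TRUE)
      }
    } else if (!best$feasible) {
      i <- which.min(dev)
      if (dev[i] < best$dev) {
        best <- list(dev = dev[i], cost = scaled_sum(chunk[i, , drop = FALSE]),
                     x = chunk[i, ], feasible = dev[i] <= tolerance)
      }
    }
  }

  if (polish) {
    box_pen <- function(x) 1e6 * sum(pmax(abs(x) - 1, 0))
    obj <- if (best$feasible && minimize_variables) {
      function(x) {
        d <- max_dev(matrix(x, nrow = 1))
        sum((x + 1) / 2) + 1e3 * max(0, d - tolerance) + box_pen(x)
      }
    } else {
      function(x) max_dev(matrix(x, nrow = 1)) + box_pen(x)
    }
    opt <- if (k == 1) {
      stats::optim(best$x, obj, method = "Brent", lower = -1, upper = 1)
    } else {
      stats::optim(best$x, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))
    }
    cand <- pmin(pmax(opt$par, -1), 1)
    cand_dev <- max_dev(matrix(cand, nrow = 1))
    if (best$feasible && minimize_variables) {
      if (cand_dev <= tolerance &&
          sum((cand + 1) / 2) < best$cost) {
        best <- list(dev = cand_dev, cost = sum((cand + 1) / 2),
                     x = cand, feasible = TRUE)
      }
    } else if (cand_dev < best$dev) {
      best <- list(dev = cand_dev, cost = sum((cand + 1) / 2),
                   x = cand, feasible = cand_dev <= tolerance)
    }
  }

  coded <- stats::setNames(as.numeric(best$x), space$name)
  natural <- decode_factors(space, coded)
  predictions <- vapply(models, function(m) unname(predict(m, coded)),
                        numeric(1))
  structure(list(conditions_coded = coded, conditions_natural = natural,
                 predictions = predictions,
                 feasible = best$feasible,
                 objective_value = max(abs(predictions - target)),
                 target = target, tolerance = tolerance),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("Optimized extraction conditions (target ", x$target, "%, tolerance ",
      x$tolerance, "):\n", sep = "")
  print(round(x$conditions_natural, 3))
  cat("Predicted recoveries (%):\n")
  print(round(x$predictions, 1))
  cat(if (x$feasible) "All compounds within tolerance" else
        "NOT feasible: worst-case deviation",
      round(x$objective_value, 2), "\n")
  invisible(x)
}
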