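#' Build a calibration series
#'
#' A set of concentration/response pairs measured for one compound in one
#' medium (pure extraction solvent or blank soil-matrix extract).
#'
#' @param compound compound name.
#' @param medium \code{"solvent"} or \code{"matrix"}.
#' @param concentration numeric vector (mg L^-1), at least 3 distinct
#'   levels.
#' @param response numeric vector of instrument signals (arbitrary units).
#' @param linear_range declared linear range; levels outside it trigger a
#'   warning. Default 0.005--0.1 mg L^-1.
#' @return An object of class \code{calibration_series}: data frame sorted
#'   by concentration with attributes \code{compound} and \code{medium}.
#' @export
calibration_series <- function(compound, medium = c("solvent", "matrix"),
                               concentration, response,
                               linear_range = c(0.005, 0.1)) {
  medium <- match.arg(medium)
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) != length(response)) {
    stop("concentration and response lengths differ")
  }
  if (length(concentration) < 3) stop("need at least 3 calibration points")
  if (stats::sd(concentration) == 0) {
    stop("zero variance in concentration levels")
  }
  if (any(concentration < linear_range[1] - 1e-12) ||
      any(concentration > linear_range[2] + 1e-12)) {
    warning("calibration levels outside the declared linear range [",
            linear_range[1], ", ", linear_range[2], "] mg/L")
  }
  ord <- order(concentration)
  out <- data.frame(concentration = concentration[ord],
                    response = response[ord])
  attr(out, "compound") <- compound
  attr(out, "medium") <- medium
  class(out) <- c("calibration_series", "data.frame")
  out
}

#' Least-squares slope of a calibration series
#'
#' Unweighted ordinary least squares of response on concentration, with an
#' intercept (a forced-through-zero line would bias the slope under baseline
#' offsets).
#'
#' @param series a \code{\link{calibration_series}}.
#' @return The fitted slope (signal units per mg L^-1).
#' @export
fit_calibration_slope <- function(series) {
  stopifnot(inherits(series, "calibration_series"))
  unname(stats::coef(stats::lm(response ~ concentration, data = series))[2])
}

#' Matrix effect from matrix and solvent calibration slopes
#'
#' \deqn{ME(\%) = \frac{S_m - S_s}{S_s} \cdot 100}
#' where \eqn{S_m} is the calibration slope in blank matrix extract and
#' \eqn{S_s} the slope in pure extraction solvent. Negative values indicate
#' ionization suppression, positive values enhancement; \eqn{|ME| > 20\%}
#' is treated as analytically significant (a fixed rule, not a statistical
#' test).
#'
#' @param slope_matrix,slope_solvent calibration slopes \eqn{S_m}, \eqn{S_s}
#'   (\eqn{S_s \neq 0}).
#' @param threshold significance threshold on \eqn{|ME|}; default 20.
#' @return List with \code{slope_matrix}, \code{slope_solvent},
#'   \code{me_percent}, \code{significant}, \code{direction}
#'   (\code{"suppression"}, \code{"enhancement"} or \code{"none"}).
#' @examples
#' compute_matrix_effect(50, 100)  # -50%, significant suppression
#' @export
compute_matrix_effect <- function(slope_matrix, slope_solvent,
                                  threshold = 20) {
  if (slope_solvent == 0) stop("solvent slope is zero; ME undefined")
  me <- (slope_matrix - slope_solvent) / slope_solvent * 100
  list(slope_matrix = slope_matrix, slope_solvent = slope_solvent,
       me_percent = me, significant = abs(me) > threshold,
       direction = if (me < 0) "suppression" else if (me > 0) "enhancement"
                   else "none")
}

#' Matrix-effect panel across compounds and clean-up combinations
#'
#' Computes the matrix effect for every compound x extraction/clean-up
#' combination present in a long-format calibration data set, pairing the
#' solvent and matrix series of each cell.
#'
#' @param calibration data frame with columns \code{compound},
#'   \code{medium} (\code{solvent}/\code{matrix}), \code{combination}
#'   (e.g. \code{citrate}, \code{citrate-PSA}, \code{acetate-PSA-C18}),
#'   \code{concentration}, \code{response}.
#' @param threshold passed to [compute_matrix_effect()].
#' @return Data frame with one row per compound x combination:
#'   \code{compound}, \code{combination}, \code{slope_solvent},
#'   \code{slope_matrix}, \code{me_percent}, \code{significant},
#'   \code{direction}.
#' @export
me_panel <- function(calibration, threshold = 20) {
  need <- c("compound", "medium", "combination", "concentration", "response")
  missing_cols <- setdiff(need, names(calibration))
  if (length(missing_cols)) {
    stop("calibration data lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cells <- unique(calibration[, c("compound", "combination")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cp <- cells$compound[i]; cb <- cells$combination[i]
    sub <- calibration[calibration$compound == cp &
                         calibration$combination == cb, ]
    slopes <- lapply(c("solvent", "matrix"), function(md) {
      pts <- sub[sub$medium == md, ]
      if (nrow(pts) == 0) {
        stop("no ", md, " calibration series for compound '", cp,
             "' in combination '", cb, "'")
      }
      fit_calibration_slope(calibration_series(cp, md, pts$concentration,
                                               pts$response))
    })
    me <- compute_matrix_effect(slopes[[2]], slopes[[1]], threshold)
    data.frame(compound = cp, combination = cb,
               slope_solvent = me$slope_solvent,
               slope_matrix = me$slope_matrix,
               me_percent = me$me_percent, significant = me$significant,
               direction = me$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
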