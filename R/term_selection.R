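#' Prune model terms below a minimum confidence level
#'
#' Retains the intercept plus every term whose significance letter meets the
#' requested minimum confidence level (95% keeps only \code{a} terms, 90%
#' keeps \code{a}-\code{b}, 80% \code{a}-\code{c}, 70% \code{a}-\code{d};
#' level 0 keeps the full equation). Two evaluation modes:
#' \describe{
#'   \item{\code{truncate}}{(default) dropped terms are deleted and the
#'     remaining coefficients, including \code{b0}, keep their full-fit
#'     values — the simplified equation is evaluated as printed;}
#'   \item{\code{refit}}{the reduced basis is refitted to the observations
#'     by least squares (requires \code{table}).}
#' }
#'
#' @param model a \code{recovery_model} (fitted or read from a coefficient
#'   table).
#' @param min_confidence one of 95, 90, 80, 70, 0 (percent).
#' @param mode \code{"truncate"} or \code{"refit"}.
#' @param table a \code{\link{recovery_table}}; required for
#'   \code{mode = "refit"}.
#' @return An object of class \code{pruned_model}: list with \code{parent},
#'   \code{min_confidence}, \code{mode}, \code{retained} (term labels) and
#'   \code{coefficients} (named vector over the retained terms).
#' @export
prune_model <- function(model, min_confidence,
                        mode = c("truncate", "refit"), table = NULL) {
  stopifnot(inherits(model, "recovery_model"))
  mode <- match.arg(mode)
  keep_letters <- letters_at_level(min_confidence)
  keep <- model$letters %in% keep_letters
  keep[model$terms == "b0"] <- TRUE  # intercept is never pruned
  retained <- model$terms[keep]
  if (mode == "truncate") {
    coef <- model$coefficients[keep]
  } else {
    if (is.null(table)) stop("refit mode needs the recovery table")
    space <- attr(table$design, "space")
    X <- expand_terms(coded_matrix(table$design), space$name)[, keep,
                                                             drop = FALSE]
    y <- table$observations[, model$compound]
    coef <- stats::setNames(drop(qr.coef(qr(X), y)), retained)
  }
  structure(list(parent = model, min_confidence = min_confidence,
                 mode = mode, retained = retained, coefficients = coef),
            class = "pruned_model")
}

#' @export
print.pruned_model <- function(x, ...) {
  cat("Pruned model for ", x$parent$compound, ": ", length(x$retained),
      " of ", length(x$parent$terms), " terms at the ",
      x$min_confidence, "% level (", x$mode, " mode)\n", sep = "")
  invisible(x)
}

#' @export
predict.pruned_model <- function(object, coded, ...) {
  X <- expand_terms(coded, factor_names(object$parent))
  drop(X[, object$retained, drop = FALSE] %*% object$coefficients)
}

#' Deviation range between observed recoveries and a pruned model
#'
#' Per-run absolute differences \eqn{|predicted - observed|}, in recovery
#' percentage points, between the observations and the simplified
#' polynomial; the range (min, max) over runs summarizes how much accuracy
#' term removal costs.
#'
#' @param pruned a \code{\link{prune_model}} result.
#' @param table the \code{\link{recovery_table}} the parent model was fitted
#'   to.
#' @return Named numeric vector \code{c(min, max)}.
#' @export
deviation_range <- function(pruned, table) {
  stopifnot(inherits(pruned, "pruned_model"), inherits(table, "recovery_table"))
  compound <- pruned$parent$compound
  if (!compound %in% table$compounds) {
    stop("table has no compound ", compound)
  }
  pred <- predict(pruned, coded_matrix(table$design))
  dev <- abs(pred - table$observations[, compound])
  c(min = min(dev), max = max(dev))
}

# correlation between model predictions and observations; NA when either
# side is constant (correlation undefined)
prediction_correlation <- function(pred, obs) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  stats::cor(pred, obs)
}

#' Term-removal audit across confidence levels
#'
#' For each compound and each minimum confidence level, prunes the fitted
#' model and reports the deviation range between observed recoveries and the
#' simplified equation together with the correlation R between its
#' predictions and the observations. The level-0 column is the full
#' equation, so its deviation range equals the full-model absolute-residual
#' range. High R with a large maximum deviation flags models whose goodness
#' of fit is driven by a wide response range rather than pointwise accuracy,
#' which is why both numbers are reported side by side.
#'
#' @param models named list of \code{recovery_model}s sharing one design.
#' @param table the common \code{\link{recovery_table}}.
#' @param levels minimum confidence levels to audit (percent).
#' @param mode passed to [prune_model()].
#' @return Data frame with columns \code{compound}, \code{level},
#'   \code{n_terms}, \code{deviation_min}, \code{deviation_max}, \code{R}.
#' @export
selection_report <- function(models, table, levels = c(95, 90, 80, 70, 0),
                             mode = "truncate") {
  stopifnot(length(models) >= 1)
  coded <- coded_matrix(table$design)
  rows <- lapply(models, function(model) {
    obs <- table$observations[, model$compound]
    do.call(rbind, lapply(levels, function(lv) {
      pr <- prune_model(model, lv, mode = mode, table = table)
      pred <- predict(pr, coded)
      dev <- abs(pred - obs)
      data.frame(compound = model$compound, level = lv,
                 n_terms = length(pr$retained),
                 deviation_min = min(dev), deviation_max = max(dev),
                 R = prediction_correlation(pred, obs),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
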