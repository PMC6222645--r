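#' Assemble a recovery table
#'
#' Binds a design to the observed per-run recoveries of one or more
#' compounds.
#'
#' @param design a \code{\link{ccf_design}}.
#' @param observations numeric matrix or data frame (runs x compounds) of
#'   recovery percentages; column names are compound names.
#' @return An object of class \code{recovery_table}: list with elements
#'   \code{design}, \code{observations} (matrix), \code{compounds}.
#' @export
recovery_table <- function(design, observations) {
  stopifnot(inherits(design, "ccf_design"))
  obs <- as.matrix(observations)
  storage.mode(obs) <- "double"
  if (nrow(obs) != nrow(design)) {
    stop("observations have ", nrow(obs), " rows but the design has ",
         nrow(design), " runs")
  }
  if (is.null(colnames(obs))) {
    colnames(obs) <- paste0("compound", seq_len(ncol(obs)))
  }
  if (any(!is.finite(obs))) stop("recoveries must be finite")
  if (any(obs < 0)) stop("recoveries must be non-negative")
  structure(list(design = design, observations = obs,
                 compounds = colnames(obs)),
            class = "recovery_table")
}

#' @export
print.recovery_table <- function(x, ...) {
  cat("Recovery table:", nrow(x$observations), "runs x",
      length(x$compounds), "compounds (",
      paste(x$compounds, collapse = ", "), ")\n")
  invisible(x)
}

#' Map a p-value to the table's confidence-level letter
#'
#' Coefficient significance is annotated with letters: \code{a} for the 95%
#' confidence level (p < 0.05), \code{b} for 90% (p < 0.10), \code{c} for
#' 80% (p < 0.20), \code{d} for 70% (p < 0.30), and \code{""} otherwise.
#'
#' @param p numeric vector of two-sided p-values in [0, 1].
#' @return Character vector of letters (\code{""} for non-significant).
#' @examples
#' significance_letter(c(0.01, 0.07, 0.35))
#' @export
significance_letter <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  as.character(cut(p, breaks = c(-Inf, 0.05, 0.10, 0.20, 0.30, Inf),
                   labels = c("a", "b", "c", "d", ""), right = FALSE))
}

# letters admitted at each minimum confidence level (percent)
letters_at_level <- function(min_confidence) {
  switch(as.character(min_confidence),
         "95" = "a",
         "90" = c("a", "b"),
         "80" = c("a", "b", "c"),
         "70" = c("a", "b", "c", "d"),
         "0"  = c("a", "b", "c", "d", ""),
         stop("min_confidence must be one of 95, 90, 80, 70, 0"))
}

new_recovery_model <- function(compound, terms, coefficients, se, p, letters,
                               R, residual_df, sse, system = NA_character_) {
  structure(list(compound = compound, system = system, terms = terms,
                 coefficients = stats::setNames(coefficients, terms),
                 se = se, p = p, letters = letters, R = R,
                 residual_df = residual_df, sse = sse),
            class = "recovery_model")
}

#' Fit the full polynomial recovery model for one compound
#'
#' Ordinary least-squares fit of the 31-term basis (intercept, linear,
#' two-way, three-way, quadratic; see [term_basis()]) to the observed
#' recoveries of one compound. Standard errors come from the
#' residual-variance-scaled inverse Gram matrix, p-values from two-sided
#' t-tests at \code{n - p} residual degrees of freedom (14 for the 45-run
#' design), and the goodness of fit is reported as the multiple correlation
#' coefficient \eqn{R = \sqrt{1 - SSE/SST}}.
#'
#' @param table a \code{\link{recovery_table}}.
#' @param compound compound name (a column of the table); defaults to the
#'   first compound.
#' @return An object of class \code{recovery_model} with elements
#'   \code{coefficients}, \code{se}, \code{p}, \code{letters} (see
#'   [significance_letter()]), \code{R}, \code{residual_df}, \code{sse}.
#' @examples
#' des <- ccf_design(chd_factor_space(), 3)
#' tab <- simulate_recoveries(des, quechers_coefficients("citrate"),
#'                            noise_sd = 2, seed = 1)
#' fit_full_model(tab, "alloxydim")
#' @export
fit_full_model <- function(table, compound = table$compounds[1]) {
  stopifnot(inherits(table, "recovery_table"))
  if (!compound %in% table$compounds) {
    stop("unknown compound: ", compound)
  }
  y <- table$observations[, compound]
  space <- attr(table$design, "space")
  X <- expand_terms(coded_matrix(table$design), space$name)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more runs (", n, ") than model terms (", p, ")")
  sv <- svd(X, nu = 0, nv = 0)$d
  if (min(sv) / max(sv) < 1e-10) {
    stop("expanded design matrix is rank-deficient")
  }
  qr_x <- qr(X)
  coef <- qr.coef(qr_x, y)
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  sse <- sum(resid^2)
  df <- n - p
  sigma2 <- sse / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df)
  pval[se == 0] <- 0  # exact fit: treat as fully determined
  sst <- sum((y - mean(y))^2)
  R <- if (sst > 0) sqrt(max(0, 1 - sse / sst)) else NA_real_
  new_recovery_model(compound, colnames(X), coef, se, pval,
                     significance_letter(pmin(pmax(pval, 0), 1)),
                     R, df, sse)
}

#' Fit the full model for every compound in a recovery table
#'
#' @inheritParams fit_full_model
#' @return Named list of \code{recovery_model} objects, one per compound.
#' @export
fit_all_models <- function(table) {
  stats::setNames(lapply(table$compounds, function(cp) {
    fit_full_model(table, cp)
  }), table$compounds)
}

#' @export
print.recovery_model <- function(x, ...) {
  cat("Polynomial recovery model for", x$compound)
  if (!is.na(x$system)) cat(" (", x$system, " QuEChERS)", sep = "")
  cat("\n  ", length(x$terms), " terms, R = ", formatC(x$R, digits = 4),
      if (!is.na(x$residual_df)) paste0(", residual df = ", x$residual_df),
      "\n", sep = "")
  flagged <- x$terms[x$letters %in% c("a", "b")]
  if (length(flagged)) {
    cat("  terms at >=90% confidence:", paste(flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict recoveries from a fitted or tabulated model
#'
#' Evaluates the polynomial at coded factor settings: the inner product of
#' the coefficient vector with the expanded feature vector.
#'
#' @param object a \code{recovery_model}.
#' @param coded numeric vector or matrix of coded factor settings.
#' @param ... unused.
#' @return Numeric vector of predicted recoveries (%).
#' @export
predict.recovery_model <- function(object, coded, ...) {
  X <- expand_terms(coded, factor_names(object))
  if (ncol(X) != length(object$coefficients)) {
    stop("coded settings expand to ", ncol(X), " terms; model has ",
         length(object$coefficients))
  }
  drop(X %*% object$coefficients)
}

n_factors <- function(model) {
  # terms = 1 + k + C(k,2) + C(k,3) + k; recover k from the linear block
  sum(!grepl("[:^]", model$terms)) - 1L
}

factor_names <- function(model) {
  model$terms[seq_len(n_factors(model)) + 1L]
}
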