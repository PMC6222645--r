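#' Polynomial term basis for the recovery model
#'
#' The recovery response is modelled as a second-order polynomial in the
#' coded factors augmented with all three-way linear interactions:
#' \deqn{Y = b_0 + \sum_i b_i X_i + \sum_i b_{ii} X_i^2 +
#'   \sum_{i<j} b_{ij} X_i X_j + \sum_{i<j<k} b_{ijk} X_i X_j X_k}
#' For \eqn{k} factors the basis has \eqn{1 + k + C(k,2) + C(k,3) + k}
#' terms; with the study's five factors, 31. Term order is fixed across
#' fitting, printing and serialized coefficient tables: intercept
#' (\code{b0}), linear, two-way, three-way, quadratic, each block in factor
#' order.
#'
#' @param factors character vector of factor names in canonical order.
#' @return Character vector of term labels, e.g. \code{"b0"}, \code{"SW"},
#'   \code{"SW:AM"}, \code{"SW:AM:EV"}, \code{"SW^2"}.
#' @examples
#' term_basis(c("SW", "AM", "EV", "WC", "ET"))  # 31 labels
#' @export
term_basis <- function(factors) {
  factors <- as.character(factors)
  k <- length(factors)
  if (k < 1) stop("need at least one factor")
  two_way <- if (k >= 2) {
    apply(utils::combn(factors, 2), 2, paste, collapse = ":")
  } else character(0)
  three_way <- if (k >= 3) {
    apply(utils::combn(factors, 3), 2, paste, collapse = ":")
  } else character(0)
  c("b0", factors, two_way, three_way, paste0(factors, "^2"))
}

#' Expand coded factor settings into the polynomial feature matrix
#'
#' @param coded numeric vector (one setting) or matrix (one row per setting)
#'   of coded factor values.
#' @param factors factor names; defaults to the column names of \code{coded}
#'   or \code{X1..Xk}.
#' @return Numeric matrix (settings x terms) with columns in
#'   [term_basis()] order; the intercept column is identically 1.
#' @examples
#' expand_terms(c(SW = 1, AM = -1, EV = 0, WC = 0, ET = 0))
#' @export
expand_terms <- function(coded, factors = NULL) {
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1,
                                           dimnames = list(NULL, names(coded)))
  coded <- as.matrix(coded)
  storage.mode(coded) <- "double"
  k <- ncol(coded)
  if (is.null(factors)) {
    factors <- colnames(coded)
    if (is.null(factors)) factors <- paste0("X", seq_len(k))
  }
  if (length(factors) != k) {
    stop("expected ", length(factors), " coded values per setting, got ", k)
  }
  labels <- term_basis(factors)
  n <- nrow(coded)
  X <- matrix(NA_real_, n, length(labels), dimnames = list(NULL, labels))
  X[, 1L] <- 1
  X[, 1L + seq_len(k)] <- coded
  pos <- 1L + k
  if (k >= 2) {
    for (ij in utils::combn(k, 2, simplify = FALSE)) {
      pos <- pos + 1L
      X[, pos] <- coded[, ij[1]] * coded[, ij[2]]
    }
  }
  if (k >= 3) {
    for (ijk in utils::combn(k, 3, simplify = FALSE)) {
      pos <- pos + 1L
      X[, pos] <- coded[, ijk[1]] * coded[, ijk[2]] * coded[, ijk[3]]
    }
  }
  X[, pos + seq_len(k)] <- coded^2
  X
}
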