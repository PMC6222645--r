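#' Generate a face-centred central composite design
#'
#' Builds the three-level face-centred composite design (CCF) used for the
#' recovery experiments: the full \eqn{2^k} factorial portion (all coded
#' coordinates in \{-1, +1\}), \eqn{2k} axial points at axial distance
#' \eqn{\alpha = 1} (one coordinate at -1 or +1, the rest 0), and
#' \code{n_center} replicated center runs (all coordinates 0). For the
#' five-factor study with three center points this gives
#' \eqn{2^5 + 2 \cdot 5 + 3 = 45} runs per extraction system.
#'
#' Run order is deterministic: factorial points in lexicographic -1/+1 order
#' (last factor varying fastest), then axial pairs factor by factor (low face
#' first), then center replicates.
#'
#' @param space a \code{\link{factor_space}}.
#' @param n_center number of replicated center points (>= 1).
#' @return An object of class \code{ccf_design}: a data frame with columns
#'   \code{run_id}, \code{point_type} (\code{factorial}/\code{axial}/
#'   \code{center}) and one coded column per factor; the factor space is
#'   attached as attribute \code{space}.
#' @examples
#' des <- ccf_design(chd_factor_space(), n_center = 3)
#' nrow(des)  # 45
#' table(des$point_type)
#' @export
ccf_design <- function(space, n_center = 3) {
  stopifnot(inherits(space, "factor_space"))
  k <- nrow(space)
  if (k < 1) stop("factor space is empty")
  n_center <- as.integer(n_center)
  if (is.na(n_center) || n_center < 1) stop("n_center must be >= 1")

  # factorial portion, lexicographic with -1 before +1, last factor fastest
  fac <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  fac <- fac[do.call(order, as.data.frame(fac)), , drop = FALSE]
  dimnames(fac) <- NULL

  axial <- matrix(0, nrow = 2 * k, ncol = k)
  for (i in seq_len(k)) {
    axial[2 * i - 1, i] <- -1
    axial[2 * i, i] <- 1
  }
  center <- matrix(0, nrow = n_center, ncol = k)

  coded <- rbind(fac, axial, center)
  colnames(coded) <- space$name
  rownames(coded) <- NULL
  out <- data.frame(
    run_id = seq_len(nrow(coded)),
    point_type = rep(c("factorial", "axial", "center"),
                     c(nrow(fac), nrow(axial), n_center)),
    coded,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  attr(out, "space") <- space
  class(out) <- c("ccf_design", "data.frame")
  out
}

#' Extract the coded design matrix of a CCF design
#'
#' @param design a \code{\link{ccf_design}}.
#' @return Numeric matrix (runs x factors) of coded coordinates.
#' @export
coded_matrix <- function(design) {
  stopifnot(inherits(design, "ccf_design"))
  space <- attr(design, "space")
  as.matrix(as.data.frame(design)[, space$name, drop = FALSE])
}

#' @export
print.ccf_design <- function(x, ...) {
  tab <- table(x$point_type)
  cat("Face-centred composite design:", nrow(x), "runs (",
      tab[["factorial"]], "factorial,", tab[["axial"]], "axial,",
      tab[["center"]], "center )\n")
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("...", nrow(x) - 8, "more runs\n")
  invisible(x)
}

#' Write a design as CSV with coded and natural-unit columns
#'
#' Columns: \code{run_id}, \code{point_type}, one \code{coded_<name>} and one
#' \code{<name>} natural-unit column per factor.
#'
#' @param design a \code{\link{ccf_design}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_design <- function(design, path) {
  space <- attr(design, "space")
  coded <- coded_matrix(design)
  natural <- decode_factors(space, coded)
  out <- data.frame(run_id = design$run_id, point_type = design$point_type,
                    stringsAsFactors = FALSE)
  cd <- as.data.frame(coded)
  names(cd) <- paste0("coded_", space$name)
  nt <- as.data.frame(natural)
  names(nt) <- space$name
  utils::write.csv(cbind(out, cd, nt), path, row.names = FALSE)
  invisible(path)
}
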