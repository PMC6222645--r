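#' Define a factor space for a designed extraction experiment
#'
#' A factor space is an ordered set of experimental variables, each with a
#' natural-unit working range \code{[low, high]}. Variables are coded onto
#' \eqn{[-1, +1]} by \eqn{x = (u - center) / halfrange} with
#' \eqn{center = (low + high)/2} and \eqn{halfrange = (high - low)/2}.
#'
#' @param name character vector of unique factor labels.
#' @param unit character vector of measurement units (recycled if length 1).
#' @param low,high numeric vectors of natural-unit range bounds; \code{low <
#'   high} elementwise.
#' @return An object of class \code{factor_space}: a data frame with columns
#'   \code{name}, \code{unit}, \code{low}, \code{high}, \code{center},
#'   \code{half_range}.
#' @examples
#' factor_space(c("SW", "AM"), c("g", "%"), low = c(2.4, 5), high = c(5.8, 95))
#' @seealso [chd_factor_space()] for the soil-extraction study's five factors.
#' @export
factor_space <- function(name, unit, low, high) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("duplicate factor names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  low <- as.numeric(low)
  high <- as.numeric(high)
  stopifnot(length(low) == length(name), length(high) == length(name))
  if (any(!is.finite(low)) || any(!is.finite(high))) {
    stop("factor bounds must be finite")
  }
  bad <- high <= low
  if (any(bad)) {
    stop("non-positive range width for factor(s): ",
         paste(name[bad], collapse = ", "))
  }
  unit <- rep_len(as.character(unit), length(name))
  out <- data.frame(
    name = name, unit = unit, low = low, high = high,
    center = (low + high) / 2, half_range = (high - low) / 2,
    stringsAsFactors = FALSE
  )
  class(out) <- c("factor_space", "data.frame")
  out
}

#' The five QuEChERS soil-extraction variables
#'
#' Factor space of the extraction study: soil weight (SW, 2.4--5.8 g),
#' acetonitrile proportion of the acetonitrile/methanol extraction mixture
#' (AM, 5--95 %), extraction solvent volume (EV, 8--16 mL), water content
#' (WC, 1.5--4.5 mL) and extraction time (ET, 1--3 min).
#'
#' @return A \code{\link{factor_space}} with the five factors in canonical
#'   order (SW, AM, EV, WC, ET).
#' @export
chd_factor_space <- function() {
  factor_space(
    name = c("SW", "AM", "EV", "WC", "ET"),
    unit = c("g", "%", "mL", "mL", "min"),
    low  = c(2.4, 5, 8, 1.5, 1),
    high = c(5.8, 95, 16, 4.5, 3)
  )
}

#' @export
print.factor_space <- function(x, ...) {
  cat("Factor space with", nrow(x), "factors\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

as_factor_matrix <- function(space, x, what) {
  k <- nrow(space)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != k) {
      stop(what, " length ", length(x), " does not match factor count ", k)
    }
    x <- matrix(x, nrow = 1, dimnames = list(NULL, space$name))
  } else {
    if (ncol(x) != k) {
      stop(what, " has ", ncol(x), " columns but the space has ", k, " factors")
    }
    if (!is.null(colnames(x))) {
      if (!setequal(colnames(x), space$name)) {
        stop(what, " column names do not match factor names")
      }
      x <- x[, space$name, drop = FALSE]
    } else {
      colnames(x) <- space$name
    }
  }
  storage.mode(x) <- "double"
  x
}

#' Code natural-unit factor settings onto the [-1, +1] scale
#'
#' @param space a \code{\link{factor_space}}.
#' @param natural numeric vector (one setting) or matrix/data frame (one row
#'   per setting) of natural-unit values in factor order.
#' @return Coded values with the same shape as the input; a one-row input
#'   vector comes back as a named vector. Values outside the working ranges
#'   are coded by extrapolation with a warning.
#' @examples
#' sp <- chd_factor_space()
#' encode_factors(sp, c(SW = 3.23, AM = 52.8, EV = 8, WC = 3.8, ET = 1.8))
#' @export
encode_factors <- function(space, natural) {
  vec <- is.null(dim(natural)) && !is.data.frame(natural)
  u <- as_factor_matrix(space, natural, "natural values")
  coded <- sweep(sweep(u, 2, space$center, "-"), 2, space$half_range, "/")
  if (any(abs(coded) > 1 + 1e-9)) {
    warning("natural values outside the factor working ranges; ",
            "coded values fall outside [-1, +1] (extrapolation)")
  }
  if (vec) coded[1L, ] else coded
}

#' Decode [-1, +1] settings back to natural units
#'
#' Inverse of [encode_factors()]: \code{decode_factors(space,
#' encode_factors(space, u))} returns \code{u} to numerical precision.
#'
#' @inheritParams encode_factors
#' @param coded numeric vector or matrix of coded values in factor order.
#' @return Natural-unit values with the same shape as the input.
#' @export
decode_factors <- function(space, coded) {
  vec <- is.null(dim(coded)) && !is.data.frame(coded)
  x <- as_factor_matrix(space, coded, "coded values")
  u <- sweep(sweep(x, 2, space$half_range, "*"), 2, space$center, "+")
  if (vec) u[1L, ] else u
}

#' Read or write a factor space as a YAML configuration file
#'
#' The file holds an ordered \code{factors} list, each entry with keys
#' \code{name}, \code{unit}, \code{low}, \code{high}.
#'
#' @param path file path.
#' @return \code{read_factor_space} returns a \code{\link{factor_space}};
#'   \code{write_factor_space} returns \code{path} invisibly.
#' @export
read_factor_space <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$factors)) stop("config has no 'factors' list: ", path)
  f <- cfg$factors
  factor_space(
    name = vapply(f, `[[`, character(1), "name"),
    unit = vapply(f, `[[`, character(1), "unit"),
    low  = vapply(f, function(e) as.numeric(e$low), numeric(1)),
    high = vapply(f, function(e) as.numeric(e$high), numeric(1))
  )
}

#' @rdname read_factor_space
#' @param space a \code{\link{factor_space}} to serialize.
#' @export
write_factor_space <- function(space, path) {
  factors <- lapply(seq_len(nrow(space)), function(i) {
    list(name = space$name[i], unit = space$unit[i],
         low = space$low[i], high = space$high[i])
  })
  yaml::write_yaml(list(factors = factors), path)
  invisible(path)
}
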