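#' Read a coefficient table into recovery models
#'
#' Reads a long-format CSV (columns \code{system}, \code{compound},
#' \code{term}, \code{value}, \code{letter}) holding, per compound, the 31
#' polynomial coefficients in [term_basis()] order plus one \code{R} row
#' with the multiple correlation coefficient. Models built this way carry
#' coefficients, significance letters and R but no standard errors or
#' p-values (those require the raw recoveries).
#'
#' @param path CSV file path.
#' @param factors factor names defining the expected term basis; default
#'   the five extraction variables.
#' @return Named list of \code{recovery_model}s, one per compound.
#' @examples
#' models <- quechers_coefficients("citrate")
#' models$alloxydim$coefficients[["AM"]]  # -4.959
#' @export
read_coefficient_table <- function(path, factors = chd_factor_space()$name) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(letter = "character"))
  need <- c("system", "compound", "term", "value", "letter")
  if (!all(need %in% names(tab))) {
    stop("coefficient table must have columns: ", paste(need, collapse = ", "))
  }
  basis <- term_basis(factors)
  compounds <- unique(tab$compound)
  models <- lapply(compounds, function(cp) {
    sub <- tab[tab$compound == cp, ]
    missing_terms <- setdiff(c(basis, "R"), sub$term)
    if (length(missing_terms)) {
      stop("compound '", cp, "' is missing term(s): ",
           paste(missing_terms, collapse = ", "))
    }
    unknown <- setdiff(sub$term, c(basis, "R"))
    if (length(unknown)) {
      stop("compound '", cp, "' has unknown term label(s): ",
           paste(unknown, collapse = ", "))
    }
    idx <- match(basis, sub$term)
    vals <- sub$value[idx]
    if (any(!is.finite(vals))) stop("malformed coefficient for '", cp, "'")
    new_recovery_model(
      compound = cp, terms = basis, coefficients = vals,
      se = rep(NA_real_, length(basis)), p = rep(NA_real_, length(basis)),
      letters = sub$letter[idx],
      R = sub$value[match("R", sub$term)],
      residual_df = NA_integer_, sse = NA_real_,
      system = sub$system[1]
    )
  })
  stats::setNames(models, compounds)
}

#' @rdname read_coefficient_table
#' @param models named list of \code{recovery_model}s to serialize.
#' @export
write_coefficient_table <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(system = m$system, compound = m$compound,
               term = c(m$terms, "R"),
               value = c(unname(m$coefficients), m$R),
               letter = c(m$letters, ""), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Polynomial models of the two QuEChERS extraction systems
#'
#' Loads the coefficient tables shipped with the package: the fitted
#' 31-term recovery polynomials of the six cyclohexanedione (CHD) residues
#' for the citrate- and acetate-buffered extraction systems, with the
#' published significance letters and R values.
#'
#' @param system \code{"citrate"} or \code{"acetate"}.
#' @return Named list of six \code{recovery_model}s.
#' @export
quechers_coefficients <- function(system = c("citrate", "acetate")) {
  system <- match.arg(system)
  path <- system.file("extdata", paste0("coefficients_", system, ".csv"),
                      package = "quechersrsm")
  read_coefficient_table(path)
}

#' Optimized extraction conditions of the two systems
#'
#' The selected extraction conditions for each system (natural units: SW g,
#' AM %, EV mL, WC mL, ET min), shipped with the package.
#'
#' @param system \code{"citrate"} or \code{"acetate"}.
#' @return Named numeric vector of conditions in canonical factor order.
#' @export
optimized_conditions <- function(system = c("citrate", "acetate")) {
  system <- match.arg(system)
  path <- system.file("extdata", "optimized_conditions.csv",
                      package = "quechersrsm")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  row <- tab[tab$system == system, ]
  unlist(row[, setdiff(names(tab), "system")])
}

#' Read or write a recovery table as CSV
#'
#' Format: \code{run_id} column plus one recovery column per compound; row
#' order must match the design's run order.
#'
#' @param path CSV file path.
#' @param design the \code{\link{ccf_design}} the recoveries belong to.
#' @return \code{read_recovery_table} returns a
#'   \code{\link{recovery_table}}; the writer returns \code{path}
#'   invisibly.
#' @export
read_recovery_table <- function(path, design) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"run_id" %in% names(tab)) stop("recovery CSV needs a run_id column")
  obs <- as.matrix(tab[, setdiff(names(tab), "run_id"), drop = FALSE])
  recovery_table(design, obs)
}

#' @rdname read_recovery_table
#' @param table a \code{\link{recovery_table}} to serialize.
#' @export
write_recovery_table <- function(table, path) {
  out <- data.frame(run_id = table$design$run_id,
                    table$observations, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run the full chemometric pipeline
#'
#' Orchestrates the workflow end to end for one extraction system: build
#' the face-centred design, obtain recoveries (simulated from a coefficient
#' table, or read from file), fit the full polynomial per compound, audit
#' term removal across confidence levels, and optimize the extraction
#' conditions. Outputs are written under \code{out_dir} as CSV (design,
#' recoveries, fitted coefficients, selection report) and JSON (optimized
#' conditions).
#'
#' @param config list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{\code{factors}}{path to a factor-space YAML, or omitted for
#'       the built-in five factors;}
#'     \item{\code{n_center}}{center replicates (default 3);}
#'     \item{\code{truth}}{path to a coefficient CSV used as simulation
#'       ground truth, or \code{"citrate"}/\code{"acetate"} for the shipped
#'       tables;}
#'     \item{\code{recoveries}}{path to an observed recovery CSV
#'       (alternative to \code{truth});}
#'     \item{\code{noise_sd}}{simulation noise (default 2);}
#'     \item{\code{seed}}{simulation seed;}
#'     \item{\code{target}, \code{tolerance}, \code{n_grid}}{optimizer
#'       settings (defaults 100, 2.5, 21);}
#'     \item{\code{levels}, \code{mode}}{selection-report settings.}
#'   }
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the design, recovery table, models,
#'   selection report and optimization result.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || length(config) == 0) {
    stop("config must be a non-empty list or YAML file; see ?run_pipeline")
  }
  known <- c("factors", "n_center", "truth", "recoveries", "noise_sd",
             "seed", "target", "tolerance", "levels", "mode", "n_grid")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "),
         "; valid entries are: ", paste(known, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- if (!is.null(config$factors)) read_factor_space(config$factors)
           else chd_factor_space()
  design <- ccf_design(space, n_center = config$n_center %||% 3)
  write_design(design, file.path(out_dir, "design.csv"))

  table <- if (!is.null(config$recoveries)) {
    read_recovery_table(config$recoveries, design)
  } else if (!is.null(config$truth)) {
    truth <- if (config$truth %in% c("citrate", "acetate")) {
      quechers_coefficients(config$truth)
    } else read_coefficient_table(config$truth)
    simulate_recoveries(design, truth, noise_sd = config$noise_sd %||% 2,
                        seed = config$seed)
  } else {
    stop("config needs either 'recoveries' (observed CSV) or 'truth' ",
         "(simulation coefficients)")
  }
  write_recovery_table(table, file.path(out_dir, "recoveries.csv"))

  models <- fit_all_models(table)
  write_coefficient_table(models, file.path(out_dir, "fitted_models.csv"))

  report <- selection_report(models, table,
                             levels = config$levels %||% c(95, 90, 80, 70, 0),
                             mode = config$mode %||% "truncate")
  utils::write.csv(report, file.path(out_dir, "selection_report.csv"),
                   row.names = FALSE)

  opt <- optimize_conditions(models, space,
                             target = config$target %||% 100,
                             tolerance = config$tolerance %||% 2.5,
                             n_grid = config$n_grid %||% 21)
  jsonlite::write_json(
    list(conditions_natural = as.list(round(opt$conditions_natural, 4)),
         conditions_coded = as.list(round(opt$conditions_coded, 4)),
         predictions = as.list(round(opt$predictions, 1)),
         feasible = opt$feasible,
         objective_value = opt$objective_value),
    file.path(out_dir, "optimized_conditions.json"), auto_unbox = TRUE)

  invisible(list(design = design, table = table, models = models,
                 report = report, optimization = opt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
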