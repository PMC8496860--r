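#' Read and write model parameter files
#'
#' Parameter sets are stored as a flat key-value mapping using the ASCII
#' symbol names of the 45 kinetic constants, plus an optional `knockouts`
#' list of gene names. JSON is the canonical format; YAML is accepted on
#' read (and written when the path ends in `.yaml`/`.yml`). Unknown keys
#' are an error; missing keys fall back to the packaged defaults with a
#' warning. Values are serialized with 9 significant digits.
#'
#' @param path file path; format chosen by extension.
#' @param params a `gal_params` object.
#' @return `read_params()` returns a `gal_params`; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  ko <- as.character(raw$knockouts %||% character())
  raw$knockouts <- NULL
  vals <- unlist(raw)
  unknown <- setdiff(names(vals), .gal_param_names)
  if (length(unknown) > 0) {
    abort(paste0("Unknown parameter key(s) in ", path, ": ",
                 paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(.gal_param_names, names(vals))
  if (length(missing) > 0) {
    warn(paste0("Missing parameter(s) ", paste(missing, collapse = ", "),
                "; packaged defaults substituted."))
    defaults <- reference_parameters()
    vals <- c(vals, stats::setNames(as.numeric(defaults[missing]), missing))
  }
  gal_params(vals, knockouts = ko)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "gal_params"))
  x <- as.list(signif(as.numeric(params), 9))
  names(x) <- names(params)
  ko <- knockouts(params)
  if (length(ko) > 0) x$knockouts <- as.list(ko)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read and write strain induction tables
#'
#' Strain tables are CSV files with header
#' `strain_id,glucose,galactose,on_peak,off_peak,valid`. Duplicate
#' conditions and rows with `on_peak < off_peak` are validation errors.
#' When a grid is supplied, every condition must match a grid condition
#' to within relative 1e-6.
#'
#' @param path CSV file path.
#' @param grid optional [sugar_grid()] to validate conditions against.
#' @param table a strain table tibble.
#' @return `read_strain_table()` returns a strain table tibble.
#' @export
read_strain_table <- function(path, grid = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("glucose", "galactose", "on_peak", "off_peak", "valid")
  if (!all(needed %in% names(tab))) {
    abort(paste0("Strain table must have columns ",
                 paste(needed, collapse = ", "), "."))
  }
  if (is.null(tab$strain_id)) tab$strain_id <- sub("\\.csv$", "", basename(path))
  tab$valid <- as.logical(tab$valid)
  key <- paste(tab$glucose, tab$galactose)
  if (anyDuplicated(key)) {
    abort("Duplicate condition rows in strain table.")
  }
  bad <- which(tab$valid & tab$on_peak < tab$off_peak - 1e-9)
  if (length(bad) > 0) {
    abort(sprintf("on_peak < off_peak at row %d (glucose %g, galactose %g).",
                  bad[1], tab$glucose[bad[1]], tab$galactose[bad[1]]))
  }
  out <- tibble::as_tibble(tab[, c("strain_id", needed)])
  if (!is.null(grid)) match_conditions(out, grid)
  out
}

#' @rdname read_strain_table
#' @export
write_strain_table <- function(table, path) {
  tab <- as.data.frame(table)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 9)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an induction profile or decision front as CSV
#'
#' @param profile an `induction_profile`.
#' @param front a `decision_front`.
#' @param path CSV file path.
#' @export
write_profile <- function(profile, path) {
  tab <- as.data.frame(profile)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 9)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
write_front <- function(front, path) {
  tab <- as.data.frame(front)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 9)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
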