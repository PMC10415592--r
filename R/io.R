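## Tabular writers shared by the pipeline: tab-separated, one header row,
## '.' for missing values, floating point at 6 significant digits.

format_cell <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(is.na(x), ".", format(signif(x, 6L), trim = TRUE,
                                        scientific = FALSE))
  } else {
    out <- ifelse(is.na(x) | !nzchar(as.character(x)), ".", as.character(x))
  }
  out
}

#' Write a data frame as a pipeline TSV
#'
#' Tab-separated with a single header row; missing values become `"."`;
#' numeric columns are printed at 6 significant digits.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  y <- as.data.frame(lapply(x, format_cell), stringsAsFactors = FALSE,
                     check.names = FALSE)
  names(y) <- names(x)
  utils::write.table(y, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_table <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = ".",
                         check.names = FALSE, quote = "")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0L) {
    stop("Missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Read an HGT constraint table
#'
#' Expects tab-separated columns `constraint_id`, `donor_taxa`,
#' `recipient_taxa` (semicolon-separated leaf labels) and `mode`.
#'
#' @param path TSV path.
#' @return Constraint data frame, validated.
#' @export
read_constraints <- function(path) {
  x <- read_tsv_table(path, c("constraint_id", "donor_taxa",
                              "recipient_taxa", "mode"))
  check_constraints(x)
}

#' Read a calibration table
#'
#' Expects columns `clade_name`, `taxa` (semicolon-separated leaf labels or
#' `"root"`), `mean_Ma`, `sd_Ma`, `min_Ma`, `max_Ma`. Calibrations are data
#' that is validated and passed through (for instance to bound simulated
#' root ages); no calibration-density mathematics is performed here.
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_calibrations <- function(path) {
  x <- read_tsv_table(path, c("clade_name", "taxa", "mean_Ma", "sd_Ma",
                              "min_Ma", "max_Ma"))
  bad <- which(!(x$min_Ma < x$max_Ma &
                   x$min_Ma <= x$mean_Ma & x$mean_Ma <= x$max_Ma))
  if (length(bad) > 0L) {
    stop("Invalid calibration row(s) (need min < max and min <= mean <= max): ",
         paste(x$clade_name[bad], collapse = ", "), call. = FALSE)
  }
  x
}

#' Read a clade-definition table
#'
#' Expects columns `clade_name` and `taxa` (semicolon-separated labels).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_clades <- function(path) {
  read_tsv_table(path, c("clade_name", "taxa"))
}

#' Write an ensemble as a Newick tree list
#'
#' One tree per line, the format [load_ensemble()] reads back.
#'
#' @param ensemble A `tree_ensemble`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_treelist <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  lines <- vapply(ensemble$samples, function(s)
    ape::write.tree(s$phy), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a flat key-value ground-truth sidecar
#'
#' One `key<TAB>value` pair per line; used by the simulation subcommands to
#' record ground truth next to their primary outputs.
#'
#' @param values Named list or vector of scalars.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_sidecar <- function(values, path) {
  stopifnot(length(names(values)) == length(values))
  lines <- vapply(seq_along(values), function(i)
    paste(names(values)[i], format_cell(values[[i]]), sep = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}
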