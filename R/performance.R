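#' Assemble the strain x attribute performance matrix
#'
#' Collects per-assay estimates (back-transformed adjusted means, degradation
#' velocities, siderophore percentages) into the single tidy table that feeds
#' the utility scoring: one value per (strain, attribute). Adjusted means
#' fitted on the log1p scale must be back-transformed with `expm1()` before
#' entering the matrix — see [expm1_means()]. Velocities enter as-is, with
#' gated cells contributing 0.
#'
#' @param ... Data frames, each with columns `strain`, `attribute`, `value`
#'   (and optionally `source`).
#' @param attributes Optional character vector declaring the complete
#'   attribute set; any missing (strain, attribute) cell is a completeness
#'   error listing the offenders.
#' @param strains Optional character vector declaring the strain set.
#'
#' @return A tibble of class `performance_matrix` with columns `strain`,
#'   `attribute`, `value`, `source`.
#' @export
build_performance_matrix <- function(..., attributes = NULL, strains = NULL) {
  pieces <- list(...)
  pieces <- purrr::map(pieces, function(p) {
    p <- as_tibble(p)
    if (!all(c("strain", "attribute", "value") %in% names(p))) {
      abort_rhz("Each piece needs columns strain, attribute, value.", "schema_error")
    }
    if (!"source" %in% names(p)) p$source <- NA_character_
    p[c("strain", "attribute", "value", "source")]
  })
  out <- bind_rows(pieces)
  key <- paste(out$strain, out$attribute, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), c("strain", "attribute")]
    abort_rhz(paste0("Duplicate performance cell(s): ",
                     paste(paste(dup$strain, dup$attribute, sep = "/"), collapse = "; ")),
              "integrity_error")
  }
  strains <- strains %||% sort(unique(out$strain))
  attributes <- attributes %||% unique(out$attribute)
  full <- tidyr::expand_grid(strain = strains, attribute = attributes)
  missing_cells <- anti_join(full, out, by = c("strain", "attribute"))
  if (nrow(missing_cells) > 0) {
    abort_rhz(paste0("Missing performance cell(s): ",
                     paste(paste(missing_cells$strain, missing_cells$attribute, sep = "/"),
                           collapse = "; ")),
              "completeness_error")
  }
  out <- inner_join(full, out, by = c("strain", "attribute"))
  class(out) <- c("performance_matrix", class(out))
  out
}

#' Back-transform log1p-scale adjusted means
#'
#' Inverse of the log(x + 1) response transform: `expm1(estimate)`. Applied
#' to [marginal_means()] of a log1p fit so performance values live on the
#' original measurement scale (and are therefore non-negative whenever the
#' fitted mean is non-negative).
#'
#' @param mm A [marginal_means()] tibble (or any tibble with `estimate`).
#' @return The input with `estimate` replaced by `expm1(estimate)` in a
#'   `response` column.
#' @export
expm1_means <- function(mm) {
  mm <- as_tibble(mm)
  mm$response <- expm1(mm$estimate)
  mm
}

#' Write a performance matrix
#'
#' CSV is written wide (strains as rows, attributes as columns); the optional
#' JSON carries the long table with per-cell source provenance.
#'
#' @param x A [build_performance_matrix()] result.
#' @param path CSV output path.
#' @param json_path Optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_performance_matrix <- function(x, path, json_path = NULL) {
  stopifnot(inherits(x, "performance_matrix"))
  wide <- tidyr::pivot_wider(as_tibble(x)[c("strain", "attribute", "value")],
                             names_from = "attribute", values_from = "value")
  readr::write_csv(wide, path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(as_tibble(x), json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a performance matrix written by [write_performance_matrix()]
#'
#' @param path Wide CSV path (strains as rows).
#' @return A `performance_matrix` tibble.
#' @export
read_performance_matrix <- function(path) {
  wide <- readr::read_csv(path, col_types = readr::cols(
    strain = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  long <- tidyr::pivot_longer(wide, -"strain", names_to = "attribute",
                              values_to = "value")
  build_performance_matrix(long)
}
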