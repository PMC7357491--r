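#' Long-format assay tables
#'
#' An `assay_table` is a validated tibble of phenotype measurements in long
#' format, one row per observation. It is the interchange container for every
#' assay the package handles: clearance-halo radii, optical densities, endpoint
#' absorbances, solubilized-phosphate concentrations and colony areas.
#'
#' Required columns are `strain`, `assay`, `condition`, `unit`, `replicate`,
#' `time_h` and `value_kind`, plus either a numeric `value` column or the pair
#' `r1_cm`/`r2_cm` for halo rows (two perpendicular half-diameters of the same
#' colony at the same time). `unit` identifies the experimental unit (plate,
#' tube or well) that carries repeated measures; `time_h` is hours post
#' inoculation (`0` for endpoint assays).
#'
#' Enforced invariants: measurement keys
#' (`strain`, `assay`, `condition`, `unit`, `replicate`, `time_h`,
#' `value_kind`) are unique; values are non-negative for every `value_kind`
#' except `pH`; absorbances and optical densities lie in `[0, 4]`; halo radii
#' are non-negative.
#'
#' @param x A data frame with the columns described above.
#' @param strains Optional character vector declaring the admissible strain
#'   set; any `strain` outside it is an integrity error.
#'
#' @return A tibble with class `assay_table`.
#' @export
#' @examples
#' assay_table(tibble::tibble(
#'   strain = "B02", assay = "cas", condition = "IDM", unit = "t1",
#'   replicate = 1:3, time_h = 0, value = c(0.85, 0.87, 0.86),
#'   value_kind = "absorbance"
#' ))
assay_table <- function(x, strains = NULL) {
  x <- as_tibble(x)
  required <- c("strain", "assay", "condition", "unit", "replicate",
                "time_h", "value_kind")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort_rhz(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      "schema_error"
    )
  }
  has_value <- "value" %in% names(x)
  has_radii <- all(c("r1_cm", "r2_cm") %in% names(x))
  if (!has_value && !has_radii) {
    abort_rhz("Need either a 'value' column or the pair 'r1_cm'/'r2_cm'.",
              "schema_error")
  }
  for (col in intersect(c("replicate", "time_h", "value", "r1_cm", "r2_cm"), names(x))) {
    if (!is.numeric(x[[col]])) {
      abort_rhz(paste0("Column '", col, "' must be numeric."), "schema_error")
    }
  }
  if (any(x$time_h < 0, na.rm = TRUE)) {
    abort_rhz("time_h must be >= 0.", "domain_error")
  }
  if (any(x$replicate < 1, na.rm = TRUE)) {
    abort_rhz("replicate must be a positive integer.", "domain_error")
  }
  if (!is.null(strains)) {
    extra <- setdiff(unique(x$strain), strains)
    if (length(extra) > 0) {
      abort_rhz(paste0("Strain(s) outside the declared set: ",
                       paste(extra, collapse = ", ")), "integrity_error")
    }
  }
  if (has_radii) {
    bad <- which(x$r1_cm < 0 | x$r2_cm < 0)
    if (length(bad) > 0) {
      abort_rhz(paste0("Negative halo radius in row(s): ",
                       paste(head(bad, 5), collapse = ", ")), "domain_error")
    }
  }
  if (has_value) {
    not_ph <- x$value_kind != "pH"
    bad <- which(not_ph & !is.na(x$value) & x$value < 0)
    if (length(bad) > 0) {
      abort_rhz(paste0("Negative value for a non-pH measurement in row(s): ",
                       paste(head(bad, 5), collapse = ", ")), "domain_error")
    }
    od_like <- x$value_kind %in% c("absorbance", "od")
    bad <- which(od_like & !is.na(x$value) & (x$value < 0 | x$value > 4))
    if (length(bad) > 0) {
      abort_rhz(paste0("Absorbance/OD outside [0, 4] in row(s): ",
                       paste(head(bad, 5), collapse = ", ")), "domain_error")
    }
  }
  key <- do.call(paste, c(x[required], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- x[required][duplicated(key), , drop = FALSE]
    dup_txt <- do.call(paste, c(head(dup, 5), sep = "/"))
    abort_rhz(paste0("Duplicate measurement key(s): ",
                     paste(dup_txt, collapse = "; ")), "integrity_error")
  }
  class(x) <- c("assay_table", class(x))
  attr(x, "schema_version") <- "1.0"
  x
}

#' Read an assay table from disk
#'
#' Two layouts are supported. `long_csv` is the canonical interchange format:
#' columns `strain,assay,condition,unit,replicate,time_h,value,value_kind`,
#' with halo tables carrying `r1_cm,r2_cm` (or `d1_cm,d2_cm` diameters, which
#' are halved on read) instead of `value`. `plate_csv` reads a 96-well
#' (8 row x 12 column) optical-density grid, one 8-line block per read time,
#' together with a layout map assigning each well a carbon source; wells
#' mapped to `water` (well A1 by convention) are the blank and are excluded.
#' Numbers use the `.` decimal separator; files are UTF-8.
#'
#' @param path Path to the CSV file.
#' @param layout `"long_csv"` (default) or `"plate_csv"`.
#' @param layout_map For `plate_csv`: path to (or data frame of) a two-column
#'   `well,substrate` map.
#' @param strain_id,unit_id,replicate,assay_id For `plate_csv`: metadata for
#'   the plate being read (a plate holds one strain).
#' @param strains Optional declared strain set, passed to [assay_table()].
#'
#' @return An [assay_table()].
#' @export
read_assay_table <- function(path, layout = c("long_csv", "plate_csv"),
                             layout_map = NULL, strain_id = NULL,
                             unit_id = NULL, replicate = 1L,
                             assay_id = "ecoplate", strains = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    abort_rhz(paste0("File not found: ", path), "io_error")
  }
  if (layout == "long_csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    # Accept diameter columns and halve them: radii are what the area model uses.
    if (all(c("d1_cm", "d2_cm") %in% names(raw))) {
      raw$r1_cm <- as.character(as.numeric(raw$d1_cm) / 2)
      raw$r2_cm <- as.character(as.numeric(raw$d2_cm) / 2)
      raw$d1_cm <- raw$d2_cm <- NULL
    }
    for (col in intersect(c("replicate", "time_h", "value", "r1_cm", "r2_cm"), names(raw))) {
      parsed <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(parsed) & !is.na(raw[[col]]) & raw[[col]] != "NA")
      if (length(bad) > 0) {
        abort_rhz(paste0("Non-numeric value '", raw[[col]][bad[1]], "' in column '",
                         col, "', row ", bad[1], "."), "parse_error")
      }
      raw[[col]] <- parsed
    }
    assay_table(raw, strains = strains)
  } else {
    if (is.null(layout_map)) {
      abort_rhz("plate_csv requires a layout_map (well -> substrate).", "schema_error")
    }
    map <- if (is.character(layout_map)) {
      readr::read_csv(layout_map, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
    } else {
      as_tibble(layout_map)
    }
    if (!all(c("well", "substrate") %in% names(map))) {
      abort_rhz("Layout map needs columns 'well' and 'substrate'.", "schema_error")
    }
    grid <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                            progress = FALSE)
    need <- c("time_h", "row", paste0("c", 1:12))
    missing_cols <- setdiff(need, names(grid))
    if (length(missing_cols) > 0) {
      abort_rhz(paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
                "schema_error")
    }
    long <- tidyr::pivot_longer(grid, cols = all_of(paste0("c", 1:12)),
                                names_to = "col", values_to = "od")
    long$well <- paste0(long$row, sub("^c", "", long$col))
    parsed <- suppressWarnings(as.numeric(long$od))
    bad <- which(is.na(parsed) & !is.na(long$od))
    if (length(bad) > 0) {
      abort_rhz(paste0("Non-numeric OD '", long$od[bad[1]], "' at well ",
                       long$well[bad[1]], "."), "parse_error")
    }
    long$od <- parsed
    long <- inner_join(long, map, by = "well")
    long <- filter(long, .data$substrate != "water")
    out <- tibble(
      strain = strain_id %||% "unknown",
      assay = assay_id,
      condition = long$substrate,
      unit = unit_id %||% "plate1",
      replicate = as.numeric(replicate),
      time_h = as.numeric(long$time_h),
      value = long$od,
      value_kind = "od"
    )
    assay_table(out, strains = strains)
  }
}

#' Write an assay table to disk
#'
#' Writes the canonical long CSV; [read_assay_table()] of the result is the
#' identity on validated tables.
#'
#' @param x An [assay_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(x, path) {
  stopifnot(inherits(x, "assay_table"))
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Halo area from two perpendicular radii
#'
#' Clearance and colony halos are quantified as a rectangle of the two
#' perpendicular half-diameters: `A = r1 * r2` (cm^2). The function is
#' vectorized and symmetric in its arguments, and scales bilinearly:
#' `halo_area(k * r1, r2) = k * halo_area(r1, r2)`.
#'
#' @param r1,r2 Non-negative radii in cm.
#' @return Areas in cm^2.
#' @export
#' @examples
#' halo_area(1.2, 1.25) # 1.5
#' halo_area(1.45, 1.40) # 2.03
halo_area <- function(r1, r2) {
  if (any(r1 < 0, na.rm = TRUE) || any(r2 < 0, na.rm = TRUE)) {
    abort_rhz("Halo radii must be >= 0.", "domain_error")
  }
  r1 * r2
}

#' Add halo areas to a halo assay table
#'
#' Converts `r1_cm`/`r2_cm` rows into a standard `value` column of kind
#' `area_cm2`, so halo tables can flow into the same model-fitting code as
#' every other assay.
#'
#' @param x An [assay_table()] carrying `r1_cm` and `r2_cm`.
#' @return An [assay_table()] with `value` and `value_kind = "area_cm2"`.
#' @export
add_halo_area <- function(x) {
  stopifnot(inherits(x, "assay_table"))
  if (!all(c("r1_cm", "r2_cm") %in% names(x))) {
    abort_rhz("add_halo_area() needs columns 'r1_cm' and 'r2_cm'.", "schema_error")
  }
  x$value <- halo_area(x$r1_cm, x$r2_cm)
  x$value_kind <- "area_cm2"
  assay_table(as_tibble(x))
}

#' Natural log(x + 1) transform
#'
#' The variance-stabilizing transform applied to halo areas and concentrations
#' before model fitting. Uses the natural logarithm; strictly increasing and
#' maps 0 to 0. Values in `(-1, 0)` are tolerated with a warning (they can
#' arise from blank subtraction); values at or below -1 are a domain error.
#'
#' @param x Numeric vector, values > -1.
#' @return `log(x + 1)`, elementwise, order preserved.
#' @export
#' @examples
#' log1p_transform(c(0, exp(1) - 1)) # 0, 1
log1p_transform <- function(x) {
  if (any(x <= -1, na.rm = TRUE)) {
    abort_rhz("log1p_transform() requires values > -1.", "domain_error")
  }
  if (any(x < 0, na.rm = TRUE)) {
    warn("log1p_transform(): negative values (> -1) present; transformed anyway.")
  }
  log1p(x)
}
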