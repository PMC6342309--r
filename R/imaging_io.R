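#' CT slice with attenuation values in Hounsfield units
#'
#' Constructs and validates the package's raw imaging unit: a rectangular
#' 2-D grid of CT attenuation values (HU) plus pixel spacing in mm.
#' Values must lie in the plausible CT range \[-1100, 3100\] (air is about
#' -1000 HU, dense bone/metal up to ~3000 HU).
#'
#' @param values numeric matrix of attenuation values (HU).
#' @param pixel_spacing numeric length-2 vector, (row, col) spacing in mm,
#'   or `NULL` when unknown (areas are then reported in pixel units).
#' @param slice_index integer position of the slice in its volume
#'   (cranio-caudal, 1-based), or `NA`.
#' @return An object of class `hu_slice`.
#' @export
hu_slice <- function(values, pixel_spacing = NULL, slice_index = NA_integer_) {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0L)
    stop_heqct("heqct_validation_error", "slice values must be a non-empty numeric matrix")
  if (anyNA(values))
    stop_heqct("heqct_validation_error", "slice contains NA attenuation values")
  if (any(values < .hu_range[1]) || any(values > .hu_range[2]))
    stop_heqct("heqct_validation_error",
               "attenuation values outside plausible CT range [%d, %d] HU",
               .hu_range[1], .hu_range[2])
  if (!is.null(pixel_spacing)) {
    pixel_spacing <- as.numeric(pixel_spacing)
    if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
        any(pixel_spacing <= 0))
      stop_heqct("heqct_validation_error", "pixel_spacing must be two positive numbers (mm)")
  }
  structure(list(values = values, pixel_spacing = pixel_spacing,
                 slice_index = as.integer(slice_index)),
            class = "hu_slice")
}

#' Binary lung mask paired with a CT slice
#'
#' @param values matrix coercible to logical; `TRUE`/nonzero marks pixels
#'   inside the lung.
#' @param slice an optional [hu_slice()] whose shape the mask must match.
#' @return An object of class `lung_mask` holding a logical matrix.
#' @export
lung_mask <- function(values, slice = NULL) {
  if (!is.matrix(values) || length(values) == 0L)
    stop_heqct("heqct_validation_error", "mask values must be a non-empty matrix")
  m <- matrix(as.logical(values != 0), nrow = nrow(values))
  if (!is.null(slice) && !identical(dim(m), dim(slice$values)))
    stop_heqct("heqct_geometry_error",
               "mask shape (%d x %d) does not match slice shape (%d x %d)",
               nrow(m), ncol(m), nrow(slice$values), ncol(slice$values))
  structure(list(values = m), class = "lung_mask")
}

#' @export
print.hu_slice <- function(x, ...) {
  sp <- if (is.null(x$pixel_spacing)) "unknown spacing"
        else sprintf("%.3g x %.3g mm", x$pixel_spacing[1], x$pixel_spacing[2])
  cat(sprintf("<hu_slice %d x %d, %s, HU range [%g, %g]>\n",
              nrow(x$values), ncol(x$values), sp,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask %d x %d, %d inside pixels>\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

.sorted_csv_paths <- function(path) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0L)
      stop_heqct("heqct_format_error", "no .csv slice files in directory '%s'", path)
    # natural sort on the first integer in each filename, fallback lexicographic
    num <- suppressWarnings(as.integer(gsub("\\D", "", basename(files))))
    files[order(ifelse(is.na(num), Inf, num), basename(files))]
  } else path
}

.read_grid_csv <- function(file) {
  g <- tryCatch(as.matrix(read.csv(file, header = FALSE)),
                error = function(e) stop_heqct("heqct_format_error",
                  "cannot parse CSV grid '%s': %s", file, conditionMessage(e)))
  storage.mode(g) <- "double"
  dimnames(g) <- NULL
  g
}

#' Read a CT volume as an ordered list of HU slices
#'
#' Supported formats: NIfTI (`.nii`/`.nii.gz`; the header's scl_slope /
#' scl_inter rescale is applied by the reader, and pixel spacing is taken
#' from pixdim) and per-slice CSV grids (a directory of numbered `.csv`
#' files or a character vector of files, ordered cranio-caudally).
#' DICOM series are not supported by this build and raise a format error.
#'
#' @param path file, directory, or vector of per-slice CSV files.
#' @param format_hint one of `"auto"`, `"nifti"`, `"csv"`, `"dicom"`.
#' @param pixel_spacing spacing override for CSV input, (row, col) mm.
#' @return List of [hu_slice()] ordered cranio-caudally (ascending slice
#'   index; for NIfTI, ascending third array index).
#' @export
read_volume <- function(path, format_hint = c("auto", "nifti", "csv", "dicom"),
                        pixel_spacing = NULL) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "auto") {
    format_hint <- if (length(path) > 1L) "csv"
      else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
      else if (dir.exists(path) || grepl("\\.csv$", path)) "csv"
      else stop_heqct("heqct_format_error", "cannot infer format of '%s'", path)
  }
  if (format_hint == "dicom")
    stop_heqct("heqct_format_error",
               "DICOM input is not supported; convert the series to NIfTI")
  if (format_hint == "nifti") {
    if (!file.exists(path))
      stop_heqct("heqct_format_error", "file not found: '%s'", path)
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop_heqct("heqct_format_error",
                      "unreadable NIfTI '%s': %s", path, conditionMessage(e)))
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
    if (length(dim(arr)) != 3L)
      stop_heqct("heqct_format_error", "expected a 2-D or 3-D NIfTI volume")
    pd <- RNifti::pixdim(img)
    sp <- if (length(pd) >= 2 && all(pd[1:2] > 0)) pd[1:2] else NULL
    return(lapply(seq_len(dim(arr)[3]), function(k)
      hu_slice(arr[, , k, drop = TRUE], pixel_spacing = sp, slice_index = k)))
  }
  files <- .sorted_csv_paths(path)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop_heqct("heqct_format_error", "file not found: '%s'", missing[1])
  lapply(seq_along(files), function(k)
    hu_slice(.read_grid_csv(files[k]), pixel_spacing = pixel_spacing,
             slice_index = k))
}

#' Read lung masks for a volume
#'
#' Nonzero stored values map to inside-lung. Accepts the same formats as
#' [read_volume()]. If `volume` is supplied, per-slice geometry is checked.
#'
#' @inheritParams read_volume
#' @param volume optional list of [hu_slice()] to validate shapes against.
#' @return List of [lung_mask()], same order as the volume.
#' @export
read_mask <- function(path, format_hint = c("auto", "nifti", "csv", "dicom"),
                      volume = NULL) {
  format_hint <- match.arg(format_hint)
  raw <- read_volume(path, format_hint)
  if (!is.null(volume) && length(raw) != length(volume))
    stop_heqct("heqct_geometry_error",
               "mask has %d slices but volume has %d", length(raw), length(volume))
  lapply(seq_along(raw), function(k)
    lung_mask(raw[[k]]$values,
              slice = if (is.null(volume)) NULL else volume[[k]]))
}

#' Write a numeric grid (HU slice, mask, or binary slice) as a CSV grid
#'
#' @param values a matrix, or an `hu_slice` / `lung_mask` / `binary_slice`.
#' @param file output path.
#' @export
write_grid_csv <- function(values, file) {
  if (inherits(values, c("hu_slice", "lung_mask", "binary_slice")))
    values <- values$values
  write.table(values * 1, file, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

.cohort_types <- function() {
  list(numeric = c("age", "brinkman_index", "lung_area",
                   as.vector(outer(.metric_stems, abs(.hu_thresholds),
                                   paste, sep = "_"))),
       sex_levels = c("female", "male"),
       outcome_levels = c("benign", "cancer"))
}

.validate_cohort <- function(df) {
  if (anyDuplicated(df$patient_id))
    stop_heqct("heqct_validation_error", "patient_id values are not unique")
  df$sex <- tolower(as.character(df$sex))
  if (!all(df$sex %in% c("female", "male")))
    stop_heqct("heqct_validation_error", "sex must be 'male' or 'female'")
  df$outcome <- tolower(as.character(df$outcome))
  if (!all(df$outcome %in% c("benign", "cancer")))
    stop_heqct("heqct_validation_error", "outcome must be 'cancer' or 'benign'")
  for (s in c("laa")) for (t in abs(.hu_thresholds)) {
    col <- paste0(s, "_", t)
    v <- df[[col]]
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop_heqct("heqct_validation_error", "%s outside [0, 100]", col)
  }
  for (s in c("b0", "b1")) for (t in abs(.hu_thresholds)) {
    col <- paste0(s, "_", t)
    v <- df[[col]]
    if (any(v < 0, na.rm = TRUE) ||
        any(abs(v - round(v)) > 1e-8, na.rm = TRUE))
      stop_heqct("heqct_validation_error", "%s must be non-negative integers", col)
  }
  df
}

#' Read a per-patient cohort table
#'
#' Reads a delimited text file with header into the canonical cohort
#' layout: one row per patient with demographics (`age`, `sex`,
#' `brinkman_index`, optional `malignant_tumor_history`, optional
#' `visual_score`), the modelling outcome (`outcome`: cancer/benign),
#' and the emphysema metrics `lung_area`, `laa_*`, `b0_*`, `b1_*` at the
#' -950/-910/-880 HU thresholds (columns named by absolute threshold,
#' e.g. `laa_880`).
#'
#' Source files whose headers differ are mapped through `column_map`, a
#' named character vector `c(canonical = "source header")`. Rows with
#' missing modelling covariates (notably Brinkman index) are retained and
#' flagged in the `modelling_complete` attribute column rather than
#' dropped; model-fitting functions exclude them with a logged count.
#'
#' @param path CSV (or other single-character-delimited) file with header.
#' @param column_map named character vector renaming source headers to
#'   canonical names; `NULL` if the file already uses canonical names.
#' @param sep field separator, default ",".
#' @return A `data.frame` of class `cohort_table`.
#' @export
read_cohort <- function(path, column_map = NULL, sep = ",") {
  if (!file.exists(path))
    stop_heqct("heqct_format_error", "file not found: '%s'", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df))
        stop_heqct("heqct_schema_error",
                   "column_map source header '%s' (for '%s') not in file", src, canon)
      names(df)[names(df) == src] <- canon
    }
  }
  as_cohort(df)
}

#' Coerce a data frame to a validated cohort table
#'
#' @param df data frame using canonical column names (see [read_cohort()]).
#' @return A validated `cohort_table`.
#' @export
as_cohort <- function(df) {
  absent <- setdiff(.canonical_required, names(df))
  if (length(absent))
    stop_heqct("heqct_schema_error", "missing mandatory cohort columns: %s",
               paste(absent, collapse = ", "))
  for (col in .cohort_types()$numeric) df[[col]] <- as.numeric(df[[col]])
  if (!"malignant_tumor_history" %in% names(df))
    df$malignant_tumor_history <- NA_character_
  df <- .validate_cohort(df)
  model_cols <- c("age", "sex", "brinkman_index", "outcome")
  df$modelling_complete <- stats::complete.cases(df[model_cols])
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table (canonical columns) to CSV
#'
#' Inverse of [read_cohort()]: all canonical columns round-trip
#' value-for-value.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  keep <- intersect(c(.canonical_required, .canonical_optional), names(cohort))
  write.csv(as.data.frame(cohort)[keep], path, row.names = FALSE)
  invisible(path)
}
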