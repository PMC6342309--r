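#' Select the three analysis slices of a lung volume
#'
#' The analysis protocol quantifies emphysema on three axial slices
#' representing the upper, middle and lower lung fields. Slices are taken
#' at fractional positions along the cranio-caudal extent of the lung
#' mask (first to last slice containing any inside pixel), rounded to the
#' nearest index. With `fractions = c(0.25, 0.5, 0.75)` and a lung extent
#' over slices 10..29 (0-based) this selects slices 15, 20 and 24.
#'
#' @param volume list of [hu_slice()].
#' @param masks list of [lung_mask()], same length.
#' @param fractions three fractions in \[0, 1\] along the lung extent.
#' @return List of three `list(slice =, mask =, index =)` (index 1-based).
#' @export
select_slices <- function(volume, masks, fractions = c(0.25, 0.5, 0.75)) {
  if (length(volume) != length(masks))
    stop_heqct("heqct_geometry_error", "volume and mask slice counts differ")
  if (length(fractions) != 3L || any(fractions < 0 | fractions > 1))
    stop_heqct("heqct_validation_error", "fractions must be three values in [0, 1]")
  has_lung <- vapply(masks, function(m) any(m$values), logical(1))
  if (sum(has_lung) < 3L)
    stop_heqct("heqct_degenerate_error",
               "need at least 3 lung-bearing slices, found %d", sum(has_lung))
  lo <- min(which(has_lung)); hi <- max(which(has_lung))
  idx <- lo + round(fractions * (hi - lo))
  # guarantee three distinct lung-bearing slices
  idx <- vapply(idx, function(i) {
    cand <- which(has_lung)
    cand[which.min(abs(cand - i))]
  }, numeric(1))
  if (anyDuplicated(idx)) {
    pool <- setdiff(which(has_lung), idx)
    for (j in which(duplicated(idx))) {
      idx[j] <- pool[which.min(abs(pool - idx[j]))]
      pool <- setdiff(pool, idx[j])
    }
    idx <- sort(idx)
  }
  lapply(idx, function(i) list(slice = volume[[i]], mask = masks[[i]],
                               index = as.integer(i)))
}

#' Low-attenuation area percentage over a set of binary slices
#'
#' LAA% = 100 x (total low-attenuation lung pixels) / (total lung
#' pixels), pooled over the supplied slices (the protocol uses three).
#'
#' @param binaries list of [binary_slice()] produced at one threshold,
#'   each carrying its `n_lung_pixels`.
#' @return Percentage in \[0, 100\].
#' @export
laa_percent <- function(binaries) {
  stopifnot(length(binaries) >= 1L)
  n_low <- sum(vapply(binaries, function(b) b$n_low_pixels, numeric(1)))
  n_lung <- sum(vapply(binaries, function(b) as.numeric(b$n_lung_pixels),
                       numeric(1)))
  if (!is.finite(n_lung) || n_lung == 0)
    stop_heqct("heqct_degenerate_error", "no lung pixels in binary slices")
  100 * n_low / n_lung
}

#' Per-patient emphysema metrics: LAA% and Betti numbers per threshold
#'
#' Runs the full quantification for one patient: selects the three
#' analysis slices, thresholds each at every requested HU cutoff, and
#' reports pooled LAA% plus per-patient Betti numbers (summed over the
#' three slices, mirroring the pooled-pixel LAA% definition). Lung area
#' is the inside-mask pixel count over the three slices times the pixel
#' area; when pixel spacing is unknown the area is reported in pixels and
#' `lung_area_mm2` is `NA`.
#'
#' @param volume list of [hu_slice()].
#' @param masks list of [lung_mask()].
#' @param thresholds HU cutoffs (default -950, -910, -880).
#' @param fractions slice-selection fractions, see [select_slices()].
#' @param connectivity passed to [betti_numbers()].
#' @return An `emphysema_metrics` list: `lung_area_mm2`, `lung_area_px`,
#'   `slice_indices`, and per threshold `laa_pct`, `b0`, `b1` (named by
#'   threshold), plus `per_slice` detail.
#' @export
quantify_patient <- function(volume, masks,
                             thresholds = .hu_thresholds,
                             fractions = c(0.25, 0.5, 0.75),
                             connectivity = c(8L, 4L)) {
  sel <- select_slices(volume, masks, fractions)
  spacing <- sel[[1]]$slice$pixel_spacing
  lung_px <- sum(vapply(sel, function(s) sum(s$mask$values), numeric(1)))
  if (lung_px == 0)
    stop_heqct("heqct_degenerate_error", "selected slices contain no lung pixels")
  area_mm2 <- if (is.null(spacing)) NA_real_ else lung_px * prod(spacing)
  tn <- as.character(thresholds)
  laa <- stats::setNames(numeric(length(thresholds)), tn)
  b0 <- b1 <- stats::setNames(integer(length(thresholds)), tn)
  per_slice <- list()
  for (t in seq_along(thresholds)) {
    bins <- lapply(sel, function(s) binarize(s$slice, s$mask, thresholds[t]))
    laa[t] <- laa_percent(bins)
    bp <- lapply(bins, betti_numbers, connectivity = connectivity)
    b0[t] <- sum(vapply(bp, `[[`, integer(1), "b0"))
    b1[t] <- sum(vapply(bp, `[[`, integer(1), "b1"))
    per_slice[[tn[t]]] <- data.frame(
      slice_index = vapply(sel, `[[`, integer(1), "index"),
      n_low = vapply(bins, function(b) b$n_low_pixels, integer(1)),
      n_lung = vapply(bins, function(b) b$n_lung_pixels, integer(1)),
      b0 = vapply(bp, `[[`, integer(1), "b0"),
      b1 = vapply(bp, `[[`, integer(1), "b1"))
  }
  structure(list(lung_area_mm2 = area_mm2, lung_area_px = lung_px,
                 slice_indices = vapply(sel, `[[`, integer(1), "index"),
                 laa_pct = laa, b0 = b0, b1 = b1, per_slice = per_slice),
            class = "emphysema_metrics")
}

#' @export
print.emphysema_metrics <- function(x, ...) {
  cat(sprintf("<emphysema_metrics: slices %s, lung area %s>\n",
              paste(x$slice_indices, collapse = "/"),
              if (is.na(x$lung_area_mm2)) sprintf("%d px", x$lung_area_px)
              else sprintf("%.0f mm^2", x$lung_area_mm2)))
  print(data.frame(threshold_hu = as.numeric(names(x$laa_pct)),
                   laa_pct = round(unname(x$laa_pct), 2),
                   b0 = unname(x$b0), b1 = unname(x$b1)))
  invisible(x)
}

#' Flatten emphysema metrics into one canonical cohort row
#'
#' @param metrics an `emphysema_metrics` object.
#' @param patient_id identifier for the row.
#' @return One-row data frame with `lung_area` and `laa_*`, `b0_*`,
#'   `b1_*` columns matching the cohort-table layout.
#' @export
metrics_row <- function(metrics, patient_id) {
  row <- data.frame(patient_id = patient_id,
                    lung_area = if (is.na(metrics$lung_area_mm2))
                      metrics$lung_area_px else metrics$lung_area_mm2)
  for (t in names(metrics$laa_pct)) {
    th <- as.numeric(t)
    row[[metric_col("laa", th)]] <- unname(metrics$laa_pct[t])
    row[[metric_col("b0", th)]] <- unname(metrics$b0[t])
    row[[metric_col("b1", th)]] <- unname(metrics$b1[t])
  }
  row
}
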