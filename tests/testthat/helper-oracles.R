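# Independent oracles, written against the definitions only (no reuse of
# package internals): BFS flood fill for components/holes, exhaustive
# pair counting for AUC, and a raw NIfTI-1 writer for scaled fixtures.

# BFS connected components of pixels == fg under 4- or 8-connectivity.
flood_fill_components <- function(m, fg, connectivity = 8L) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 4L) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  }
  comps <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (m[r0, c0] != fg || seen[r0, c0]) next
    queue <- matrix(c(r0, c0), ncol = 2)
    seen[r0, c0] <- TRUE
    members <- queue
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        r <- cur[1] + offs[k, 1]; c <- cur[2] + offs[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            m[r, c] == fg && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- rbind(queue, c(r, c))
          members <- rbind(members, c(r, c))
        }
      }
    }
    comps[[length(comps) + 1]] <- members
  }
  comps
}

# (components of the 0 set, holes of the 0 set) by flood fill.
betti_oracle <- function(m, conn0 = 8L, conn1 = 4L) {
  b0 <- length(flood_fill_components(m, 0L, conn0))
  comps1 <- flood_fill_components(m, 1L, conn1)
  touches_border <- vapply(comps1, function(px) {
    any(px[, 1] == 1 | px[, 1] == nrow(m) | px[, 2] == 1 | px[, 2] == ncol(m))
  }, logical(1))
  list(b0 = b0, b1 = sum(!touches_border))
}

# AUC by exhaustive case-control pair enumeration, ties counted 1/2.
auc_oracle <- function(scores, y) {
  cases <- scores[y == 1]; controls <- scores[y == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

random_binary_grid <- function(nr, nc, p0 = 0.4) {
  matrix(as.integer(runif(nr * nc) >= p0), nr, nc)
}

# Minimal NIfTI-1 writer for int16 data with explicit scl_slope/scl_inter,
# so reader-side rescale behaviour can be tested against a file the
# high-level writer cannot produce.
write_scaled_nifti <- function(file, arr, slope, inter, pixdim = c(1, 1, 1)) {
  stopifnot(length(dim(arr)) == 3)
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)
  writeBin(raw(36), con)
  writeBin(as.integer(c(3, dim(arr), 1, 1, 1, 1)), con, size = 2)
  writeBin(raw(14), con)
  writeBin(c(4L, 16L), con, size = 2)          # datatype int16, bitpix 16
  writeBin(0L, con, size = 2)
  writeBin(c(1, pixdim, 0, 0, 0, 0), con, size = 4)
  writeBin(352, con, size = 4)                 # vox_offset
  writeBin(slope, con, size = 4)
  writeBin(inter, con, size = 4)
  writeBin(raw(224), con)
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)
  writeBin(raw(4), con)
  writeBin(as.integer(arr), con, size = 2)
  invisible(file)
}

# Uniform-attenuation volume with full-lung masks, for slice-selection
# and degenerate-input tests.
uniform_volume <- function(n_slices, hu = -700, nr = 8, nc = 8,
                           lung_slices = seq_len(n_slices),
                           spacing = c(1, 1)) {
  vol <- lapply(seq_len(n_slices), function(k)
    hu_slice(matrix(hu, nr, nc), pixel_spacing = spacing, slice_index = k))
  masks <- lapply(seq_len(n_slices), function(k) {
    m <- matrix(k %in% lung_slices, nr, nc)
    lung_mask(m)
  })
  list(volume = vol, masks = masks)
}

# Small complete cohort data frame with canonical columns.
toy_cohort_df <- function(n = 6, seed = 42) {
  set.seed(seed)
  data.frame(
    patient_id = paste0("T", seq_len(n)),
    age = round(runif(n, 50, 80)),
    sex = rep(c("male", "female"), length.out = n),
    brinkman_index = round(runif(n, 0, 1200)),
    malignant_tumor_history = rep(c("yes", "no"), length.out = n),
    outcome = rep(c("cancer", "benign"), length.out = n),
    lung_area = runif(n, 50000, 70000),
    laa_950 = runif(n, 5, 20), laa_910 = runif(n, 25, 40),
    laa_880 = runif(n, 45, 60),
    b0_950 = rpois(n, 7000), b0_910 = rpois(n, 3500), b0_880 = rpois(n, 2000),
    b1_950 = rpois(n, 5000), b1_910 = rpois(n, 7000), b1_880 = rpois(n, 7400))
}
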