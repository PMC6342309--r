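#' Specification of a synthetic lung phantom
#'
#' Describes a three-slice phantom with lung-shaped masks (two ellipses)
#' whose low-attenuation content is planted with known topology: per
#' slice, `n_components` low-attenuation regions of which `n_enclosed`
#' are annuli enclosing a normal-parenchyma island, so the Betti numbers
#' at the construction threshold are (b0, b1) = (n_components,
#' n_enclosed) per slice by construction. Distinct regions are kept
#' pairwise non-adjacent (at least one normal pixel apart, 8-neighbour
#' sense).
#'
#' Attenuation is i.i.d. Gaussian per pixel: normal parenchyma around
#' `background_hu`, planted regions around `hole_hu`. Both means must be
#' at least 3 sd away from `threshold_hu` (defaults give a ~6.7 sd
#' margin, so thresholding recovers the planted geometry essentially
#' always; recovery is asserted after generation and the slice is
#' regenerated, counted, on the rare failure).
#'
#' @param n_components planted low-attenuation regions per slice.
#' @param n_enclosed planted enclosed normal islands per slice
#'   (`<= n_components`; each lives inside its own annular region).
#' @param grid_shape (rows, cols) of each slice.
#' @param background_hu c(mean, sd) for normal parenchyma.
#' @param hole_hu c(mean, sd) for planted low-attenuation regions.
#' @param threshold_hu construction threshold.
#' @param target_laa_fraction optional planted low-attenuation fraction
#'   of the lung; when given, region radii are sized to approximate it,
#'   otherwise radii are drawn from a default range.
#' @param n_slices number of slices (the protocol uses 3).
#' @param pixel_spacing (row, col) mm.
#' @param seed integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_components, n_enclosed = 0L,
                         grid_shape = c(96L, 96L),
                         background_hu = c(mean = -780, sd = 15),
                         hole_hu = c(mean = -980, sd = 15),
                         threshold_hu = -880,
                         target_laa_fraction = NULL,
                         n_slices = 3L,
                         pixel_spacing = c(0.7, 0.7),
                         seed = 1L) {
  if (n_enclosed > n_components)
    stop_heqct("heqct_validation_error",
               "n_enclosed (%d) cannot exceed n_components (%d): each enclosed island needs its own annular region",
               n_enclosed, n_components)
  if (background_hu[2] <= 0 || hole_hu[2] <= 0)
    stop_heqct("heqct_validation_error", "HU noise sd must be positive")
  if (hole_hu[1] + 3 * hole_hu[2] > threshold_hu ||
      background_hu[1] - 3 * background_hu[2] < threshold_hu)
    stop_heqct("heqct_validation_error",
               "hole and background HU means must be >= 3 sd below/above the construction threshold")
  structure(list(n_components = as.integer(n_components),
                 n_enclosed = as.integer(n_enclosed),
                 grid_shape = as.integer(grid_shape),
                 background_hu = background_hu, hole_hu = hole_hu,
                 threshold_hu = threshold_hu,
                 target_laa_fraction = target_laa_fraction,
                 n_slices = as.integer(n_slices),
                 pixel_spacing = pixel_spacing,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.two_ellipse_mask <- function(nr, nc) {
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ell <- function(cr, cc, ar, ac)
    ((r - cr) / ar)^2 + ((c_ - cc) / ac)^2 <= 1
  ell(nr / 2, nc * 0.29, nr * 0.34, nc * 0.15) |
    ell(nr / 2, nc * 0.71, nr * 0.34, nc * 0.15)
}

.dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  sh <- function(dr, dc) {
    res <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    res[rs, cs] <- m[rs - dr, cs - dc]
    res
  }
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- out | sh(dr, dc)
  out
}

.disk <- function(nr, nc, cr, cc, radius) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - cr)^2 + (cc_ - cc)^2 <= radius^2
}

# Plant one slice; returns list(planted0, cores) or NULL if capacity hit.
.plant_slice <- function(spec, mask) {
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  planted0 <- matrix(FALSE, nr, nc)
  cores <- matrix(FALSE, nr, nc)
  blocked <- !mask            # regions must stay inside the lung
  lung_px <- sum(mask)
  k <- spec$n_components
  if (k == 0L) return(list(planted0 = planted0, cores = cores))
  # region sizing
  if (!is.null(spec$target_laa_fraction)) {
    area_each <- spec$target_laa_fraction * lung_px / k
    disk_r <- max(1.2, sqrt(area_each / pi))
    ann_ro <- max(3.6, sqrt(area_each / (pi * (1 - (1 - 2 / 4.5)^2))))
  } else {
    disk_r <- NULL; ann_ro <- NULL
  }
  inside_idx <- which(mask)
  for (i in seq_len(k)) {
    annulus <- i <= spec$n_enclosed
    placed <- FALSE
    for (attempt in seq_len(1000L)) {
      pos <- inside_idx[sample.int(length(inside_idx), 1L)]
      cr <- (pos - 1L) %% nr + 1L
      cc <- (pos - 1L) %/% nr + 1L
      if (annulus) {
        ro <- if (is.null(ann_ro)) runif(1, 4, 6) else ann_ro
        ri <- ro - 2
        outer_d <- .disk(nr, nc, cr, cc, ro)
        core <- .disk(nr, nc, cr, cc, ri - 0.5)
        shape0 <- outer_d & !core
        if (!any(core)) next
      } else {
        rad <- if (is.null(disk_r)) runif(1, 1.5, 3.5) else disk_r
        shape0 <- .disk(nr, nc, cr, cc, rad)
        core <- matrix(FALSE, nr, nc)
        if (!any(shape0)) next
      }
      footprint <- shape0 | core
      if (any(footprint & blocked)) next
      # keep >= 1 normal pixel between regions: nothing within the
      # 8-dilation of existing planted material (or cores) may be reused
      planted0 <- planted0 | shape0
      cores <- cores | core
      blocked <- blocked | .dilate8(footprint)
      placed <- TRUE
      break
    }
    if (!placed)
      stop_heqct("heqct_capacity_error",
                 "could not place region %d of %d in 1000 attempts", i, k)
  }
  list(planted0 = planted0, cores = cores)
}

#' Generate a synthetic lung phantom with known topology
#'
#' Produces the three slices, their masks, and the exact ground truth:
#' per-slice planted Betti pairs and the realized low-attenuation
#' fraction of the lung (planted 0 pixels / lung pixels, pooled over
#' slices). After adding HU noise each slice is re-thresholded at the
#' construction threshold and required to reproduce the planted 0 set
#' and Betti numbers exactly; a slice failing this (possible only through
#' extreme noise draws) is regenerated and counted in `n_regenerated`.
#'
#' @param spec a [phantom_spec()].
#' @return List: `volume` (list of [hu_slice()]), `masks`,
#'   `truth` (`b0_slice`, `b1_slice`, `b0_total`, `b1_total`,
#'   `laa_fraction`, `threshold_hu`), `spec`, `n_regenerated`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  mask_m <- .two_ellipse_mask(nr, nc)
  if (sum(mask_m) < 50L)
    stop_heqct("heqct_validation_error", "grid too small for a lung mask")
  volume <- masks <- vector("list", spec$n_slices)
  n_low <- 0; n_regen <- 0L
  for (s in seq_len(spec$n_slices)) {
    for (try in seq_len(20L)) {
      pl <- .plant_slice(spec, mask_m)
      hu <- matrix(rnorm(nr * nc, spec$background_hu[1], spec$background_hu[2]),
                   nr, nc)
      hu[!mask_m] <- rnorm(sum(!mask_m), -1000, 5)
      hu[pl$planted0] <- rnorm(sum(pl$planted0), spec$hole_hu[1], spec$hole_hu[2])
      hu <- pmin(pmax(hu, .hu_range[1] + 1), .hu_range[2] - 1)
      sl <- hu_slice(hu, pixel_spacing = spec$pixel_spacing, slice_index = s)
      mk <- lung_mask(mask_m, slice = sl)
      bs <- binarize(sl, mk, spec$threshold_hu)
      bp <- betti_numbers(bs)
      ok <- identical(bs$values == 0L, unname(pl$planted0)) &&
        bp$b0 == spec$n_components && bp$b1 == spec$n_enclosed
      if (ok) {
        volume[[s]] <- sl; masks[[s]] <- mk
        n_low <- n_low + sum(pl$planted0)
        break
      }
      n_regen <- n_regen + 1L
      if (try == 20L)
        stop_heqct("heqct_capacity_error",
                   "slice %d failed exact-recovery assertion 20 times", s)
    }
  }
  truth <- list(b0_slice = rep(spec$n_components, spec$n_slices),
                b1_slice = rep(spec$n_enclosed, spec$n_slices),
                b0_total = spec$n_components * spec$n_slices,
                b1_total = spec$n_enclosed * spec$n_slices,
                laa_fraction = n_low / (spec$n_slices * sum(mask_m)),
                threshold_hu = spec$threshold_hu)
  list(volume = volume, masks = masks, truth = truth, spec = spec,
       n_regenerated = n_regen)
}

#' Specification of a synthetic patient cohort
#'
#' Covariates are drawn independently per patient: age from a (clamped)
#' normal, sex from a Bernoulli on male (or an exact male count),
#' Brinkman index from a zero-inflated log-normal (the zero mass is the
#' never-smoker fraction), and the emphysema metrics from a single
#' latent severity factor with per-metric loadings so that the b1
#' columns are mutually correlated and LAA% is monotone across
#' thresholds by construction. The binary outcome follows a logistic
#' model on male sex, age, Brinkman index and b1 at -880 HU; the
#' intercept may be given directly or calibrated so the expected
#' prevalence matches `prevalence`.
#'
#' Defaults reproduce the covariate scales of a nodule-workup cohort:
#' n = 576, age 66.8 +/- 12.4 y, 317/576 male, Brinkman 647 +/- 829,
#' b1 at -880 HU 7470 +/- 2410, cancer prevalence 283/576, and the
#' generative coefficients (-0.438 male, 0.0260/y, 0.000294/Brinkman
#' unit, 0.000104/b1 unit) on the scale typical of unstandardized
#' logistic fits in this setting.
#'
#' @param n_patients cohort size.
#' @param age c(mean, sd) in years.
#' @param sex_male either a probability in (0,1) or an exact integer
#'   count of males (an integer >= 1 is read as a count).
#' @param brinkman list(p_zero, meanlog, sdlog).
#' @param b1 c(mean, sd) of the b1 count at -880 HU.
#' @param coef named generative coefficients: `sex_male`, `age`,
#'   `brinkman_index`, `b1`, and optionally `intercept`.
#' @param prevalence target marginal outcome prevalence used to calibrate
#'   the intercept when `coef["intercept"]` is absent/NA.
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 576L,
                        age = c(mean = 66.8, sd = 12.4),
                        sex_male = 317 / 576,
                        brinkman = list(p_zero = 0.35, meanlog = 6.63, sdlog = 0.74),
                        b1 = c(mean = 7470, sd = 2410),
                        coef = c(intercept = NA, sex_male = -0.438,
                                 age = 0.0260, brinkman_index = 0.000294,
                                 b1 = 0.000104),
                        prevalence = 283 / 576,
                        seed = 1L) {
  if (age[2] <= 0 || b1[2] <= 0 || brinkman$sdlog <= 0)
    stop_heqct("heqct_validation_error", "distribution sd parameters must be positive")
  if (brinkman$p_zero < 0 || brinkman$p_zero >= 1)
    stop_heqct("heqct_validation_error", "brinkman p_zero must be in [0, 1)")
  needed <- c("sex_male", "age", "brinkman_index", "b1")
  if (!all(needed %in% names(coef)))
    stop_heqct("heqct_validation_error", "coef must name %s",
               paste(needed, collapse = ", "))
  structure(list(n_patients = as.integer(n_patients), age = age,
                 sex_male = sex_male, brinkman = brinkman, b1 = b1,
                 coef = coef, prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Table-1-scale marginals for the metric columns not in the generative
# model, plus their loadings on the latent severity factor.
.metric_marginals <- list(
  lung_area = c(mean = 61800, sd = 11900, load = 0),
  laa_950 = c(mean = 25.2, sd = 10.9, load = NA),  # laa uses shared w, below
  laa_910 = c(mean = 41.4, sd = 13.3, load = NA),
  laa_880 = c(mean = 53.3, sd = 13.6, load = NA),
  b0_950 = c(mean = 7770, sd = 3100, load = 0.10),
  b0_910 = c(mean = 3760, sd = 2470, load = -0.40),
  b0_880 = c(mean = 2030, sd = 1850, load = -0.50),
  b1_950 = c(mean = 4930, sd = 3250, load = 0.60),
  b1_910 = c(mean = 7300, sd = 3010, load = 0.75)
)
.laa_severity_loading <- 0.45
.b1_severity_loading <- 0.80

#' Generate a synthetic cohort with known generative model
#'
#' See [cohort_spec()] for the generative process. The returned
#' `cohort_table` carries a hidden-truth attribute `truth` with the
#' generative coefficients (including the calibrated intercept), the
#' per-patient linear predictor, event probability, and the latent
#' severity factor, for use in parameter-recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @return A `cohort_table` with attribute `truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  age <- pmin(pmax(rnorm(n, spec$age[1], spec$age[2]), 20), 100)
  sex <- if (spec$sex_male >= 1) {
    n_male <- as.integer(spec$sex_male)
    if (n_male > n)
      stop_heqct("heqct_validation_error", "male count exceeds cohort size")
    sample(rep(c("male", "female"), c(n_male, n - n_male)))
  } else {
    ifelse(runif(n) < spec$sex_male, "male", "female")
  }
  smoker <- runif(n) >= spec$brinkman$p_zero
  brinkman <- ifelse(smoker,
                     rlnorm(n, spec$brinkman$meanlog, spec$brinkman$sdlog), 0)
  severity <- rnorm(n)
  b1_880 <- round(pmax(0, spec$b1[1] + spec$b1[2] *
                         (.b1_severity_loading * severity +
                          sqrt(1 - .b1_severity_loading^2) * rnorm(n))))
  # shared disturbance w makes LAA% monotone across thresholds a.s.
  w <- .laa_severity_loading * severity +
    sqrt(1 - .laa_severity_loading^2) * rnorm(n)
  laa <- sapply(c("laa_950", "laa_910", "laa_880"), function(v) {
    m <- .metric_marginals[[v]]
    pmin(pmax(m["mean"] + m["sd"] * w, 0), 100)
  })
  laa <- t(apply(laa, 1, cummax))  # guard for astronomically rare inversions
  others <- sapply(setdiff(names(.metric_marginals),
                           c("laa_950", "laa_910", "laa_880")), function(v) {
    m <- .metric_marginals[[v]]
    x <- m["mean"] + m["sd"] * (m["load"] * severity +
                                  sqrt(1 - m["load"]^2) * rnorm(n))
    if (v == "lung_area") pmax(x, 1000) else round(pmax(x, 0))
  })
  cf <- spec$coef
  lp0 <- cf["sex_male"] * (sex == "male") + cf["age"] * age +
    cf["brinkman_index"] * brinkman + cf["b1"] * b1_880
  intercept <- cf["intercept"]
  if (is.na(intercept)) {
    intercept <- stats::uniroot(
      function(c0) mean(stats::plogis(c0 + lp0)) - spec$prevalence,
      interval = c(-50, 50))$root
  }
  prob <- stats::plogis(intercept + lp0)
  outcome <- ifelse(rbinom(n, 1, prob) == 1, "cancer", "benign")
  df <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                   age = age, sex = sex, brinkman_index = brinkman,
                   malignant_tumor_history =
                     ifelse(runif(n) < 146 / 576, "yes", "no"),
                   outcome = outcome,
                   lung_area = others[, "lung_area"],
                   laa_950 = laa[, 1], laa_910 = laa[, 2], laa_880 = laa[, 3],
                   b0_950 = others[, "b0_950"], b0_910 = others[, "b0_910"],
                   b0_880 = others[, "b0_880"],
                   b1_950 = others[, "b1_950"], b1_910 = others[, "b1_910"],
                   b1_880 = b1_880)
  cohort <- as_cohort(df)
  truth <- list(coef = c(intercept = unname(intercept),
                         cf[c("sex_male", "age", "brinkman_index", "b1")]),
                linear_predictor = unname(intercept + lp0),
                prob = unname(prob), severity = severity)
  attr(cohort, "truth") <- truth
  cohort
}

#' Synthetic surrogate for the study cohort
#'
#' A fully synthetic stand-in for a real nodule-workup cohort: covariate
#' marginals at the published summary scales and the outcome generated
#' from the HEQ-model coefficients (see [cohort_spec()] defaults). It is
#' NOT patient data and reproduces the real cohort only in distribution;
#' joint-dependence features of the real data (threshold correlations,
#' heavy tails) are idealized.
#'
#' @param seed integer seed.
#' @param n_patients cohort size.
#' @return A `cohort_table` with hidden truth (see [generate_cohort()]).
#' @export
surrogate_study_cohort <- function(seed = 20190122L, n_patients = 576L) {
  n_male <- round(n_patients * 317 / 576)
  generate_cohort(cohort_spec(n_patients = n_patients, sex_male = n_male,
                              seed = seed))
}
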