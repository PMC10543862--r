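#' Configuration of a synthetic cochlear-spiral measurement cohort
#'
#' Generative parameters for paired measurement sets with the structure the
#' analysis assumes: a planar log-spiral electrode trajectory
#' `r(theta) = r0 * exp(-decay * theta)` (radius shrinking apically, as for
#' a perimodiolar array hugging the modiolus), a hidden 2-D offset of the
#' mid-modiolar axis between the two measurement sets, and independent
#' Gaussian measurement noise per electrode and parameter.
#'
#' The default noise standard deviations are calibrated so that two
#' noise-only replicate sets reproduce interrater limits of agreement of
#' +/- 0.2 mm (EMD) and +/- 10 degrees (aDOI) via
#' `LoA = 1.96 * sqrt(2) * sigma`: `sigma_emd = 0.2 / (1.96 * sqrt(2))`
#' = 0.0722 mm and `sigma_adoi = 10 / (1.96 * sqrt(2))` = 3.61 degrees.
#'
#' @param n_arrays Number of arrays (scans) in the cohort.
#' @param electrodes Electrode numbers measured per array; default E1 plus
#'   the even electrodes E2-E22 of a 22-contact array (12 electrodes).
#' @param adoi_range Angular span (degrees) covered by the measured
#'   electrodes, basal to apical.
#' @param r0 Basal spiral radius, mm.
#' @param decay Per-degree exponential decay of the spiral radius; default
#'   chosen so `r(400 deg) ~ 1.8` mm.
#' @param offset_mean,offset_sd Magnitude of the hidden inter-method axis
#'   offset: `|N(offset_mean, offset_sd)|` mm (folded normal), direction
#'   uniform on the circle.
#' @param sigma_emd,sigma_adoi Measurement-noise SDs per set (mm, degrees).
#' @param array_jitter If `TRUE` (default), each array perturbs the spiral
#'   mildly (log-normal 5% on `r0`, +/- 10 degrees uniform on each end of
#'   `adoi_range`) so arrays differ as patients do.
#' @param seed Integer master seed; all randomness derives from it.
#' @return An object of class `spiral_cohort_config`.
#' @export
spiral_cohort_config <- function(n_arrays = 50,
                                 electrodes = c(1L, seq(2L, 22L, 2L)),
                                 adoi_range = c(20, 420),
                                 r0 = 2.8,
                                 decay = log(2.8 / 1.8) / 400,
                                 offset_mean = 0.3, offset_sd = 0.1,
                                 sigma_emd = 0.2 / (1.96 * sqrt(2)),
                                 sigma_adoi = 10 / (1.96 * sqrt(2)),
                                 array_jitter = TRUE,
                                 seed = 1L) {
  stopifnot(n_arrays >= 1, length(adoi_range) == 2,
            adoi_range[2] >= adoi_range[1],
            sigma_emd >= 0, sigma_adoi >= 0, offset_mean >= 0,
            offset_sd >= 0, r0 > 0)
  if (r0 * exp(-decay * max(adoi_range, 0)) <= 0 || !is.finite(decay))
    cochloc_error("spiral radius must stay positive over adoi_range",
                  "cochloc_config_error")
  electrodes <- sort(unique(as.integer(electrodes)))
  if (any(electrodes < 1) || any(electrodes > 22) || length(electrodes) < 3)
    cochloc_error("electrodes must be >= 3 values within 1..22",
                  "cochloc_config_error")
  structure(
    list(n_arrays = as.integer(n_arrays), electrodes = electrodes,
         adoi_range = as.numeric(adoi_range), r0 = r0, decay = decay,
         offset_mean = offset_mean, offset_sd = offset_sd,
         sigma_emd = sigma_emd, sigma_adoi = sigma_adoi,
         array_jitter = isTRUE(array_jitter), seed = as.integer(seed)),
    class = "spiral_cohort_config")
}

#' True electrode positions of one synthetic array
#'
#' Places the configured electrodes at angles evenly spaced over the
#' array's angular span (with mild per-array jitter of the spiral if
#' configured) and radii from the log-spiral law, and returns their
#' Cartesian coordinates relative to the true mid-modiolar axis.
#' Deterministic given `(config$seed, array_index)`.
#'
#' @param config A [spiral_cohort_config()].
#' @param array_index Array number within the cohort (1-based).
#' @return A [cartesian_electrodes()] object, basal to apical order.
#' @export
generate_true_positions <- function(config, array_index) {
  stopifnot(inherits(config, "spiral_cohort_config"))
  lo <- config$adoi_range[1]
  hi <- config$adoi_range[2]
  r0 <- config$r0
  if (config$array_jitter) {
    with_seed(child_seed(config$seed, array_index, stream = 1L), {
      r0 <- r0 * exp(stats::rnorm(1, 0, 0.05))
      lo <- lo + stats::runif(1, -10, 10)
      hi <- hi + stats::runif(1, -10, 10)
    })
  }
  n <- length(config$electrodes)
  theta <- seq(lo, hi, length.out = n)
  r <- r0 * exp(-config$decay * theta)
  if (any(r <= 0))
    cochloc_error("spiral radius non-positive in adoi_range",
                  "cochloc_config_error")
  rad <- deg2rad(theta)
  cartesian_electrodes(paste0("A", sprintf("%03d", array_index)),
                       config$electrodes, r * cos(rad), r * sin(rad))
}

#' Measure true electrode positions from a (possibly offset) axis
#'
#' Emulates one method's measurement of an array: the electrode coordinates
#' are re-expressed relative to a mid-modiolar axis displaced by
#' `axis_offset` (coordinates minus offset), converted to polar form with
#' multi-turn unwrapping, and independent Gaussian noise is added to each
#' electrode's EMD and aDOI. EMD is clipped at a 1e-3 mm floor; the number
#' of clipped electrodes is recorded in the `n_clipped` attribute.
#'
#' @param true_positions A [cartesian_electrodes()] object.
#' @param axis_offset An [axis_shift()]: the displacement of this method's
#'   axis from the true one, mm.
#' @param sigma_emd,sigma_adoi Noise SDs (mm, degrees).
#' @param seed Integer seed for the noise draws.
#' @param method_label Label for the returned measurement.
#' @return An [electrode_measurement()] with attribute `n_clipped`.
#' @export
measure_with_axis <- function(true_positions, axis_offset,
                              sigma_emd = 0, sigma_adoi = 0,
                              seed = 1L, method_label = "measured") {
  stopifnot(inherits(true_positions, "cartesian_electrodes"),
            inherits(axis_offset, "axis_shift"))
  rel <- cartesian_electrodes(true_positions$array_id,
                              true_positions$electrode,
                              true_positions$x - axis_offset$shift_x,
                              true_positions$y - axis_offset$shift_y)
  if (any(rel$x == 0 & rel$y == 0))
    cochloc_error("axis offset coincides with an electrode position",
                  "cochloc_degenerate_position")
  clean <- to_polar(rel, method_label = method_label)
  n <- length(clean$electrode)
  noisy <- with_seed(seed, {
    list(emd = clean$emd + stats::rnorm(n, 0, sigma_emd),
         adoi = clean$adoi + stats::rnorm(n, 0, sigma_adoi))
  })
  n_clipped <- sum(noisy$emd < 1e-3)
  if (n_clipped > 0) {
    warning(sprintf("%d EMD value(s) clipped at the 1e-3 mm floor", n_clipped))
    noisy$emd <- pmax(noisy$emd, 1e-3)
  }
  # noise can nudge an angle below 0; the floor keeps the measurement valid
  noisy$adoi <- pmax(noisy$adoi, 0)
  out <- electrode_measurement(clean$array_id, method_label, clean$electrode,
                               noisy$emd, noisy$adoi)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Generate a paired synthetic measurement cohort
#'
#' For each array the generator draws true spiral positions, then produces
#' three measurement sets: `manual_rater1` and `manual_rater2` measured
#' from the true axis with independent noise (the interrater pair), and
#' `auto` measured from an axis displaced by a hidden offset (folded-normal
#' magnitude, uniform direction) with its own noise. Per-array covariates
#' (isotropic voxel size and an image-quality sum score) are drawn with the
#' cohort frequencies of a typical DVT series; by default they have no
#' effect on the measurements and exist to exercise confounder checks.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [spiral_cohort_config()].
#' @return A list with `measurements` (table in the [read_measurements()]
#'   schema, three methods), `truth` (data frame `array_id`,
#'   `true_offset_x_mm`, `true_offset_y_mm`, `seed`), `covariates`
#'   (data frame `array_id`, `voxel_size_mm`, `iq_score`), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "spiral_cohort_config"))
  meas <- vector("list", 3 * config$n_arrays)
  truth <- vector("list", config$n_arrays)
  for (i in seq_len(config$n_arrays)) {
    pos <- generate_true_positions(config, i)
    offset <- with_seed(child_seed(config$seed, i, stream = 2L), {
      mag <- abs(stats::rnorm(1, config$offset_mean, config$offset_sd))
      ang <- stats::runif(1, 0, 2 * pi)
      axis_shift(mag * cos(ang), mag * sin(ang))
    })
    meas[[3 * i - 2]] <- measure_with_axis(
      pos, axis_shift(0, 0), config$sigma_emd, config$sigma_adoi,
      seed = child_seed(config$seed, i, stream = 3L),
      method_label = "manual_rater1")
    meas[[3 * i - 1]] <- measure_with_axis(
      pos, axis_shift(0, 0), config$sigma_emd, config$sigma_adoi,
      seed = child_seed(config$seed, i, stream = 4L),
      method_label = "manual_rater2")
    meas[[3 * i]] <- measure_with_axis(
      pos, offset, config$sigma_emd, config$sigma_adoi,
      seed = child_seed(config$seed, i, stream = 5L),
      method_label = "auto")
    truth[[i]] <- data.frame(
      array_id = pos$array_id, true_offset_x_mm = offset$shift_x,
      true_offset_y_mm = offset$shift_y, seed = config$seed,
      stringsAsFactors = FALSE)
  }
  covariates <- with_seed(child_seed(config$seed, 0L, stream = 6L), {
    data.frame(
      array_id = vapply(truth, function(t) t$array_id, character(1)),
      voxel_size_mm = sample(c(0.2, 0.25), config$n_arrays, replace = TRUE,
                             prob = c(0.3, 0.7)),
      iq_score = sample(4:8, config$n_arrays, replace = TRUE,
                        prob = c(0.10, 0.28, 0.26, 0.24, 0.12)),
      stringsAsFactors = FALSE)
  })
  list(measurements = measurements_to_table(meas),
       truth = do.call(rbind, truth),
       covariates = covariates,
       config = config)
}

#' Write a synthetic cohort to disk
#'
#' Writes the measurement CSV plus a truth sidecar JSON
#' (`{array_id, true_offset_x_mm, true_offset_y_mm, seed}` per array) and a
#' covariates CSV next to it.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @param stem File-name stem, default `"cohort"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, stem = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    measurements = file.path(dir, paste0(stem, "_measurements.csv")),
    truth = file.path(dir, paste0(stem, "_truth.json")),
    covariates = file.path(dir, paste0(stem, "_covariates.csv")))
  write_measurements(cohort$measurements, paths[["measurements"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = FALSE, digits = NA)
  utils::write.csv(cohort$covariates, paths[["covariates"]],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
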