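#' Per-array electrode measurement in polar coordinates
#'
#' One method's (or rater's) measurements for the electrodes of a single
#' array: the electrode-to-modiolar-axis distance EMD (mm) and the angular
#' depth of insertion aDOI (degrees from the round window, possibly > 360
#' after a full cochlear turn), indexed by electrode number. Records are
#' stored ordered by increasing electrode number; ascending electrode number
#' is taken as basal-to-apical (E22 most apical).
#'
#' @param array_id Identifier of the electrode array (one per scan/patient).
#' @param method_label Free-text label of the measuring method or rater,
#'   e.g. `"manual_rater1"` or `"auto"`.
#' @param electrode Integer electrode numbers in 1..22, unique.
#' @param emd Numeric EMD in mm, strictly positive and finite.
#' @param adoi Numeric aDOI in degrees, finite, `0 <= adoi < 720`.
#' @param allow_multiturn If `TRUE`, the 720-degree upper bound is waived;
#'   used internally by [to_polar()], whose unwrapping can legitimately
#'   stack more turns when fed a pathological (non-monotone) sequence.
#'
#' @return An object of class `electrode_measurement`: a list with fields
#'   `array_id`, `method_label`, `electrode`, `emd`, `adoi`.
#' @export
#' @examples
#' m <- electrode_measurement("A1", "manual", c(1, 2, 4), c(2.5, 2.4, 2.2),
#'                            c(20, 55, 90))
#' to_cartesian(m)
electrode_measurement <- function(array_id, method_label, electrode, emd, adoi,
                                  allow_multiturn = FALSE) {
  electrode <- as.integer(electrode)
  emd <- as.numeric(emd)
  adoi <- as.numeric(adoi)
  n <- length(electrode)
  if (length(emd) != n || length(adoi) != n)
    cochloc_error("electrode, emd and adoi must have equal length",
                  "cochloc_invalid_measurement")
  if (anyDuplicated(electrode))
    cochloc_error("duplicate electrode numbers within one measurement",
                  "cochloc_invalid_measurement")
  if (any(!is.finite(emd)) || any(emd <= 0))
    cochloc_error("emd must be finite and > 0 for every electrode",
                  "cochloc_invalid_measurement")
  if (any(!is.finite(adoi)) || any(adoi < 0) ||
      (!allow_multiturn && any(adoi >= 720)))
    cochloc_error("adoi must be finite, >= 0 and < 720 degrees",
                  "cochloc_invalid_measurement")
  ord <- order(electrode)
  structure(
    list(array_id = array_id, method_label = method_label,
         electrode = electrode[ord], emd = emd[ord], adoi = adoi[ord]),
    class = "electrode_measurement")
}

#' @export
print.electrode_measurement <- function(x, ...) {
  cat(sprintf("<electrode_measurement> array %s, method %s, %d electrodes\n",
              x$array_id, x$method_label, length(x$electrode)))
  print(data.frame(electrode = x$electrode, emd_mm = x$emd,
                   adoi_deg = x$adoi), row.names = FALSE)
  invisible(x)
}

#' Planar electrode coordinates relative to a candidate mid-modiolar axis
#'
#' Cartesian coordinates of the measured electrodes. The origin is the
#' mid-modiolar axis; the +x axis points toward the round-window reference
#' direction (aDOI = 0 degrees).
#'
#' @param array_id Array identifier.
#' @param electrode Integer electrode numbers, ordered.
#' @param x,y Coordinates in mm, same length as `electrode`.
#' @return An object of class `cartesian_electrodes`.
#' @export
cartesian_electrodes <- function(array_id, electrode, x, y) {
  electrode <- as.integer(electrode)
  if (length(x) != length(electrode) || length(y) != length(electrode))
    cochloc_error("x and y must match electrode in length",
                  "cochloc_invalid_measurement")
  structure(list(array_id = array_id, electrode = electrode,
                 x = as.numeric(x), y = as.numeric(y)),
            class = "cartesian_electrodes")
}

#' Uniform 2-D alteration of the mid-modiolar axis position
#'
#' A translation applied identically to every electrode's Cartesian
#' coordinates, modelling a change in where the mid-modiolar axis was placed.
#' The round-window (0 degree) reference direction is held fixed.
#'
#' @param shift_x,shift_y Translation components in mm, finite.
#' @return An object of class `axis_shift`.
#' @export
axis_shift <- function(shift_x, shift_y) {
  if (!is.finite(shift_x) || !is.finite(shift_y))
    cochloc_error("shift components must be finite", "cochloc_invalid_shift")
  structure(list(shift_x = as.numeric(shift_x), shift_y = as.numeric(shift_y)),
            class = "axis_shift")
}

#' Polar to Cartesian electrode coordinates
#'
#' Maps each electrode's (EMD, aDOI) to planar coordinates
#' `x = EMD * cos(aDOI)`, `y = EMD * sin(aDOI)` (aDOI converted to radians),
#' preserving electrode order. Multi-turn angles map onto the plane
#' periodically; the turn count is recovered on the way back by
#' [unwrap_angles()].
#'
#' @param meas An [electrode_measurement()].
#' @return A [cartesian_electrodes()] object.
#' @export
to_cartesian <- function(meas) {
  stopifnot(inherits(meas, "electrode_measurement"))
  theta <- deg2rad(meas$adoi)
  cartesian_electrodes(meas$array_id, meas$electrode,
                       meas$emd * cos(theta), meas$emd * sin(theta))
}

#' Apply an axis shift to Cartesian electrode coordinates
#'
#' Adds the shift componentwise to every electrode, i.e. translates the
#' electrode cloud relative to the (fixed) axis origin.
#'
#' @param cart A [cartesian_electrodes()] object.
#' @param shift An [axis_shift()].
#' @return A [cartesian_electrodes()] object.
#' @export
apply_shift <- function(cart, shift) {
  stopifnot(inherits(cart, "cartesian_electrodes"),
            inherits(shift, "axis_shift"))
  cartesian_electrodes(cart$array_id, cart$electrode,
                       cart$x + shift$shift_x, cart$y + shift$shift_y)
}

#' Cartesian back to polar measurements with multi-turn unwrapping
#'
#' Computes `EMD = sqrt(x^2 + y^2)` and the raw angle `atan2(y, x)` per
#' electrode, then applies [unwrap_angles()] so the returned aDOI is the
#' multi-turn insertion angle in degrees. An electrode exactly at the origin
#' has no defined angle and raises a degenerate-position error.
#'
#' @param cart A [cartesian_electrodes()] object ordered basal to apical.
#' @param method_label Label for the returned measurement.
#' @param basal_to_apical If `FALSE` the electrode sequence runs apical to
#'   basal and is reversed for unwrapping.
#' @return An [electrode_measurement()].
#' @export
to_polar <- function(cart, method_label = "transformed",
                     basal_to_apical = TRUE) {
  stopifnot(inherits(cart, "cartesian_electrodes"))
  emd <- sqrt(cart$x^2 + cart$y^2)
  if (any(emd == 0))
    cochloc_error("electrode coincides with the axis origin; angle undefined",
                  "cochloc_degenerate_position")
  raw <- rad2deg(atan2(cart$y, cart$x))
  adoi <- unwrap_angles(raw, basal_to_apical = basal_to_apical)
  electrode_measurement(cart$array_id, method_label, cart$electrode, emd, adoi,
                        allow_multiturn = TRUE)
}

#' Multi-turn unwrapping of insertion angles along the array
#'
#' Raw two-argument-arctangent angles are only known modulo 360 degrees; an
#' electrode array inserted deeper than one cochlear turn needs the turn
#' count restored. Two steps:
#' \enumerate{
#'   \item each raw angle is reduced modulo 360 into `[0, 360)` (the
#'     negative-branch correction of the arctangent, generalized);
#'   \item walking basal to apical, a wrap event is a consecutive pair that
#'     transitions from `[270, 360]` to `[0, 90]`; each electrode gains 360
#'     degrees per wrap event occurring earlier in the sequence.
#' }
#' Pathological non-monotone sequences pass through with the literal rule
#' applied.
#'
#' @param raw_adoi Raw angles in degrees, ordered basal to apical (most
#'   basal first) unless `basal_to_apical = FALSE`.
#' @param basal_to_apical If `FALSE`, the input is reversed before and after
#'   unwrapping.
#' @return Unwrapped angles in degrees, same order as the input.
#' @export
#' @examples
#' unwrap_angles(c(-10, 10))            # c(350, 370)
#' unwrap_angles(c(200, 350, 20, 80))   # c(200, 350, 380, 440)
unwrap_angles <- function(raw_adoi, basal_to_apical = TRUE) {
  a <- as.numeric(raw_adoi)
  if (any(!is.finite(a)))
    cochloc_error("raw angles must be finite", "cochloc_invalid_measurement")
  if (!basal_to_apical) a <- rev(a)
  a <- a %% 360
  n <- length(a)
  if (n >= 2) {
    wrap <- (a[-n] >= 270 & a[-n] <= 360) & (a[-1] >= 0 & a[-1] <= 90)
    # electrode i gains 360 deg per wrap event among pairs 1..(i-1)
    a <- a + 360 * c(0, cumsum(wrap))
  }
  if (!basal_to_apical) a <- rev(a)
  a
}

#' Read a per-electrode measurement table from CSV
#'
#' Expected schema: one row per (array, method, electrode) with columns
#' `array_id`, `method`, `electrode`, `emd_mm`, `adoi_deg`; header mandatory,
#' UTF-8, decimal point.
#'
#' @param path CSV file path.
#' @return A data.frame with the five schema columns.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("array_id", "method", "electrode", "emd_mm", "adoi_deg")
  missing <- setdiff(required, names(df))
  if (length(missing))
    cochloc_error(paste("measurement CSV missing columns:",
                        paste(missing, collapse = ", ")),
                  "cochloc_io_error")
  df$array_id <- as.character(df$array_id)
  df$electrode <- as.integer(df$electrode)
  df[required]
}

#' Write a measurement table to CSV
#'
#' @param df Data frame with columns `array_id`, `method`, `electrode`,
#'   `emd_mm`, `adoi_deg`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(df, path) {
  required <- c("array_id", "method", "electrode", "emd_mm", "adoi_deg")
  stopifnot(all(required %in% names(df)))
  utils::write.csv(df[required], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Split a measurement table into per-array measurement objects
#'
#' @param df Measurement table (schema of [read_measurements()]).
#' @param method Optional method label to filter on.
#' @return Named list of [electrode_measurement()] objects, one per
#'   `array_id` (and per method if `method` is `NULL`, named
#'   `"<array_id>.<method>"`).
#' @export
split_measurements <- function(df, method = NULL) {
  if (!is.null(method)) df <- df[df$method == method, , drop = FALSE]
  if (!nrow(df))
    cochloc_error("no rows to split (wrong method label?)", "cochloc_io_error")
  one_method <- length(unique(df$method)) == 1L
  key <- if (one_method) df$array_id else paste(df$array_id, df$method, sep = ".")
  out <- lapply(split(df, key), function(d)
    electrode_measurement(d$array_id[1], d$method[1],
                          d$electrode, d$emd_mm, d$adoi_deg))
  out[unique(key)]
}

#' Flatten measurement objects back into a table
#'
#' @param measurements A list of [electrode_measurement()] objects.
#' @return Data frame in the CSV schema of [read_measurements()].
#' @export
measurements_to_table <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m)
    data.frame(array_id = m$array_id, method = m$method_label,
               electrode = m$electrode, emd_mm = m$emd, adoi_deg = m$adoi,
               stringsAsFactors = FALSE)))
}
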