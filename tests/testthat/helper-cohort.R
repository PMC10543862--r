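# Shared fixture builders. Everything is generated in code; seeds are fixed
# where randomness is involved.

# A 12-electrode spiral measurement (E1 + even electrodes), wrap-free input.
make_spiral_measurement <- function(array_id = "A1", method = "manual",
                                    adoi = seq(20, 420, length.out = 12),
                                    emd = 2.8 * exp(-log(2.8 / 1.8) / 400 * adoi)) {
  electrode_measurement(array_id, method, c(1L, seq(2L, 22L, 2L)), emd, adoi)
}

# A noise-free pair of measurements of the same physical electrodes:
# `reference` seen from the true axis, `moving` from an axis displaced by
# (dx, dy). The restoring shift for `moving` is exactly (dx, dy).
noise_free_pair <- function(dx, dy, seed = 1L, array_index = 1L,
                            jitter = TRUE) {
  cfg <- spiral_cohort_config(n_arrays = 1, sigma_emd = 0, sigma_adoi = 0,
                              array_jitter = jitter, seed = seed)
  pos <- generate_true_positions(cfg, array_index)
  list(
    reference = measure_with_axis(pos, axis_shift(0, 0),
                                  method_label = "manual"),
    moving = measure_with_axis(pos, axis_shift(dx, dy),
                               method_label = "auto"),
    positions = pos)
}

# A noisy pair with a known axis offset, default noise calibration.
noisy_pair <- function(dx, dy, seed = 1L) {
  cfg <- spiral_cohort_config(n_arrays = 1, seed = seed)
  pos <- generate_true_positions(cfg, 1L)
  list(
    reference = measure_with_axis(pos, axis_shift(0, 0),
                                  sigma_emd = cfg$sigma_emd,
                                  sigma_adoi = cfg$sigma_adoi,
                                  seed = seed * 2 + 1,
                                  method_label = "manual"),
    moving = measure_with_axis(pos, axis_shift(dx, dy),
                               sigma_emd = cfg$sigma_emd,
                               sigma_adoi = cfg$sigma_adoi,
                               seed = seed * 2 + 2,
                               method_label = "auto"))
}

# Random valid measurement for property tests: monotone multi-turn angles
# with consecutive gaps below 90 degrees, the spacing regime in which a
# turn crossing is identifiable from the wrapped sequence (real arrays
# space electrodes ~36 degrees apart).
random_measurement <- function(n = 12) {
  start <- runif(1, 0, 60)
  gaps <- runif(n - 1, 5, 85)
  adoi <- start + c(0, cumsum(gaps))
  if (max(adoi) >= 719) adoi <- start + (adoi - start) * (719 - start) / (max(adoi) - start)
  emd <- runif(n, 0.5, 4)
  electrode_measurement("R1", "random", seq_len(n), emd, adoi)
}
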