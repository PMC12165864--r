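# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# An idealised detector: unit QE, no dark, unit ADC, configurable read
# noise. Useful when a test wants the optics or procedure, not the noise
# model, to dominate.
ideal_camera <- function(read_noise_e = 0, dark_e_s = 0, em_gain = 1,
                         full_well_e = 1e6, offset = 100,
                         pnr = FALSE, pitch_um = 1, px = 4096) {
  camera_spec("ideal", pitch_um = pitch_um, pixels_x = px, pixels_y = px,
              qe = 1, read_noise_e = read_noise_e, dark_e_s = dark_e_s,
              em_gain = em_gain, full_well_e = full_well_e,
              adc_gain_e_dn = 1, adc_offset_dn = offset, bit_depth = 16,
              photon_number_resolving = pnr)
}

# A spec-sheet configuration with a chosen effective pixel size (nm).
config_with_pixel <- function(effective_pixel_nm, na = 1.4,
                              camera = ideal_camera()) {
  m <- camera$pitch_um * 1000 / effective_pixel_nm
  microscope_config(camera = camera, m_eff = m, na = na)
}

# Stack of identical frames plus optional iid Gaussian noise, as a plain
# rows x cols x frames array.
noisy_stack <- function(base, n_frames, sd = 0, seed = 1) {
  set.seed(seed)
  a <- array(0, c(dim(base), n_frames))
  for (i in seq_len(n_frames)) {
    a[, , i] <- base + if (sd > 0) matrix(rnorm(length(base), 0, sd),
                                          nrow(base)) else 0
  }
  a
}

# Ideal five-bar profile image: period_px must be even and bars aligned to
# pixels; peaks sit at base + amp, troughs at base.
aligned_bar_image <- function(amp, base = 100, period_px = 10, bars = 5,
                              margin_px = 10, height = 8) {
  half <- period_px / 2
  pat <- rep(c(rep(1, half), rep(0, half)), bars)
  row <- c(rep(0, margin_px), pat, rep(0, margin_px))
  matrix(rep(base + amp * row, each = height), nrow = height)
}
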