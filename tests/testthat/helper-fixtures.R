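# Small-image configurations used by the unit tests (the full-size default
# geometry is exercised by the acceptance suite).

small_config <- function(seed = 42, n_beads = 40, ...) {
  sim_config(seed = seed, image_shape = c(160L, 200L),
             bead_specs = list(
               bead_spec("GFAP", 2.8, 0.03, "q585", n_beads = n_beads)),
             ...)
}

small_duplex_config <- function(seed = 42, ...) {
  sim_config(seed = seed, image_shape = c(200L, 260L),
             bead_specs = list(
               bead_spec("IL6", 4.5, 0.03, "q525", n_beads = 25),
               bead_spec("GFAP", 2.8, 0.03, "q585", n_beads = 40)),
             ...)
}

clean_config <- function(seed = 42, n_beads = 40, shape = c(160L, 200L)) {
  sim_config(seed = seed, image_shape = shape,
             bead_specs = list(
               bead_spec("GFAP", 2.8, 0, "q585", n_beads = n_beads)),
             noise = list(gaussian_sd = 0, poisson_scale = 0),
             debris = list(count = 0, intensity = c(0, 0),
                           radius_px = c(1, 1)),
             fov_scale_sd = 0,
             illumination = list(cx = 0, cy = 0, cxx = 0, cyy = 0))
}

table1_3a <- function() channel_profile(20000, 3000, 7.583, 2.077)
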