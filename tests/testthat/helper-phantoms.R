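# Shared phantom builders. All fixtures are generated in code; grids are
# kept small so the full suite runs in minutes.

# Single-layer phantom with one tensile fiber over a compressive
# background; the standard "living cell" test object.
live_phantom <- function(nx = 16, ny = 16, pitch = 1e-6, noise_rms = 0,
                         seed = 1) {
  span <- (nx - 1) * pitch
  make_phantom(
    nx = nx, ny = ny, pitch = pitch,
    dome = list(height = 3e-6, radius = 0.375 * span, center = NULL),
    sigma_bg = -5e3,
    fibers = list(list(from = c(0.2 * span, 0.3 * span),
                       to = c(0.8 * span, 0.7 * span),
                       width = 1.5e-6, sigma = 40e3)),
    E0 = 20e3, noise_rms = noise_rms, seed = seed)
}

# sigma = 0 everywhere: pure Hertz response ("chemically fixed" analogue).
fixed_phantom <- function(nx = 16, ny = 16, pitch = 1e-6, noise_rms = 0,
                          seed = 1) {
  make_phantom(nx = nx, ny = ny, pitch = pitch, sigma_bg = 0,
               fibers = list(), E0 = 20e3, noise_rms = noise_rms,
               seed = seed)
}

# Two-layer phantom: tensile cortex sigma1 above the interface, distinct
# deep stress sigma2 below; stresses kept low enough that the 3 nN trigger
# is not reached before the full 800 nm depth, and a depth-independent
# sharp tip so layer structure is not confounded with tip-shape depth
# coupling.
two_layer_phantom <- function(nx = 16, ny = 16, pitch = 1e-6,
                              sigma1 = 4e3, sigma2 = 3e3,
                              interface = 150e-9, noise_rms = 0, seed = 1) {
  span <- (nx - 1) * pitch
  make_phantom(
    nx = nx, ny = ny, pitch = pitch, sigma_bg = sigma1, fibers = list(),
    nucleus = list(center = c(span / 2, span / 2), radius = 2 * span,
                   sigma_deep = sigma2, cortex_thickness = interface),
    E0 = 5e3, td = tip_descriptors(30e-9), noise_rms = noise_rms,
    seed = seed)
}

sim_img <- function(ph, ...) simulate_spectrum_image(ph, ...)$img

# tiny 2x2 spectrum image built by hand (used by the io tests)
tiny_image <- function() {
  d <- c(0, 1e-8, 2e-8, 3e-8, 4e-8)
  mk <- function(scale, ix, iy)
    force_curve(d, scale * d, contact_height = 1e-6 * (ix + iy),
                pixel = c(ix, iy))
  curves <- list(mk(0.01, 1, 1), mk(0.02, 2, 1), mk(0.03, 1, 2),
                 mk(0.04, 2, 2))
  topo <- matrix(1e-6 * c(2, 3, 3, 4), 2, 2, byrow = TRUE)
  spectrum_image(curves, topo, pixel_pitch = 0.5e-6, spring_constant = 0.05,
                 force_threshold = 3e-9)
}
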