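#' Photophysical and camera parameters for trace simulation
#'
#' Collects the per-frame photon budgets, bleaching/blinking rates and
#' EMCCD camera model used by [simulate_alex_trace()].  Defaults describe a
#' typical objective-type TIRF measurement at 100-Hz laser alternation:
#' roughly 100 detected photons per green-excitation frame from the FRET
#' pair, EM gain giving 4.55 counts per photon, and an excess-noise factor
#' of 2 for the EM register.
#'
#' @param photons_per_frame_dex mean detected photons per donor-excitation
#'   frame from the FRET pair (DD + DA), before gain.
#' @param photons_per_frame_aex mean detected photons per acceptor-excitation
#'   frame from the acceptor (AA), before gain.
#' @param donor_bleach_rate,acceptor_bleach_rate exponential photobleaching
#'   rates (1/s); 0 disables bleaching.
#' @param blink_on_rate,blink_off_rate dark-state entry/exit rates (1/s) for
#'   the acceptor; 0 disables blinking.
#' @param quench_states character vector of state labels whose donor-excitation
#'   emission is suppressed (contact-mediated quenching), or `NULL`.
#' @param quench_factor multiplicative suppression `q` in `[0, 1]` applied to
#'   the photon budget while in a quenched state.
#' @param background_per_channel mean background counts per frame per channel
#'   (already in camera counts).
#' @param camera_gain counts per detected photon.
#' @param read_noise_sd Gaussian read noise standard deviation (counts).
#' @param excess_noise_factor multiplier on the photon-count variance
#'   approximating the EM-register excess noise.
#' @param shot_noise logical; `FALSE` replaces all stochastic photon and
#'   camera noise by their means (useful for exactness tests).
#' @return an object of class `photophysics_params`.
#' @export
photophysics_params <- function(photons_per_frame_dex = 100,
                                photons_per_frame_aex = 70,
                                donor_bleach_rate = 0.03,
                                acceptor_bleach_rate = 0.10,
                                blink_on_rate = 0,
                                blink_off_rate = 0,
                                quench_states = NULL,
                                quench_factor = 1,
                                background_per_channel = 20,
                                camera_gain = 4.55,
                                read_noise_sd = 10,
                                excess_noise_factor = 2.0,
                                shot_noise = TRUE) {
  rates <- c(photons_per_frame_dex, photons_per_frame_aex,
             donor_bleach_rate, acceptor_bleach_rate,
             blink_on_rate, blink_off_rate, background_per_channel,
             read_noise_sd, excess_noise_factor)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates and counts must be finite and >= 0")
  stop_if_not_scalar_pos(camera_gain, "camera_gain")
  if (quench_factor < 0 || quench_factor > 1)
    stop("quench_factor must lie in [0, 1]")
  structure(list(
    photons_per_frame_dex = photons_per_frame_dex,
    photons_per_frame_aex = photons_per_frame_aex,
    donor_bleach_rate = donor_bleach_rate,
    acceptor_bleach_rate = acceptor_bleach_rate,
    blink_on_rate = blink_on_rate,
    blink_off_rate = blink_off_rate,
    quench_states = quench_states,
    quench_factor = quench_factor,
    background_per_channel = background_per_channel,
    camera_gain = camera_gain,
    read_noise_sd = read_noise_sd,
    excess_noise_factor = excess_noise_factor,
    shot_noise = isTRUE(shot_noise)
  ), class = "photophysics_params")
}

#' Noise-free photophysics (for exactness checks)
#'
#' Convenience wrapper: no shot noise, no read noise, no background and no
#' bleaching, so the apparent FRET efficiency computed downstream equals the
#' true frame-averaged FRET exactly.
#'
#' @param ... overrides passed to [photophysics_params()].
#' @export
noiseless_photophysics <- function(...) {
  defaults <- list(donor_bleach_rate = 0, acceptor_bleach_rate = 0,
                   background_per_channel = 0, read_noise_sd = 0,
                   shot_noise = FALSE)
  args <- utils::modifyList(defaults, list(...))
  do.call(photophysics_params, args)
}
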