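#' Q10 temperature-correction factor
#'
#' Scales a kinetic rate (or, for the permeation class, a conductance) from the
#' temperature at which it was characterised to the simulation temperature,
#' using the standard exponential law \eqn{Q_{10}^{(T_{sim}-T_{orig})/10}}.
#'
#' @param q10 Q10 coefficient (> 0). Typical class values used throughout the
#'   package: 3 for ionic-channel gating, 2.4 for receptor gating, 1.5 for
#'   ionic permeation, 1.3 for transmitter diffusion, 3 for Ca pumps/buffers.
#' @param t_orig Temperature at which the rate was measured (degrees C).
#' @param t_sim Simulation temperature (degrees C).
#' @return Positive scalar multiplier; exactly 1 when `t_sim == t_orig`.
#' @examples
#' q10_factor(3, 27, 37)    # one decade: exactly 3
#' q10_factor(2.4, 23, 30)  # 2.4^0.7
#' @export
q10_factor <- function(q10, t_orig, t_sim) {
  if (!is.numeric(q10) || any(q10 <= 0)) {
    stop("`q10` must be a positive number", call. = FALSE)
  }
  q10^((t_sim - t_orig) / 10)
}

#' Q10 class table
#'
#' Named Q10 coefficients per physical process class. The intracellular Ca
#' diffusion class is cell-type dependent (1.3 for the granule cell, 1.7 for
#' the Golgi cell); both are recorded.
#'
#' @return Named list of Q10 coefficients.
#' @export
q10_classes <- function() {
  list(
    ionic_gating            = 3,
    receptor_gating         = 2.4,
    ionic_permeation        = 1.5,
    transmitter_diffusion   = 1.3,
    ca_pumps_buffers        = 3,
    ca_diffusion_grc        = 1.3,
    ca_diffusion_goc        = 1.7
  )
}
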