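# Synthetic ASL trace generation.
#
# Emulates the structure of a measured FAIR-ASL reactive-hyperemia
# recording: a pre-cuff baseline segment, a gap during cuffing (ASL frames
# are not usable while the cuff manipulates the leg), and a post-release
# hyperemic segment, all sampled every 3.35 s, with additive i.i.d.
# Gaussian noise and an optional linear baseline drift.

#' Generate a synthetic ASL perfusion trace
#'
#' Simulates the model for `subject` under `protocol`, samples it on the ASL
#' grid, drops the cuff-window samples, and adds Gaussian noise of standard
#' deviation `sigma` (plus an optional linear drift).  With `sigma = 0` the
#' result equals the noiseless simulation on the sample grid.
#'
#' @param subject An [rh_subject()] parameter set.
#' @param protocol An [rh_protocol()].
#' @param sigma Noise standard deviation, mL/100mL/min.
#' @param seed Optional integer seed for reproducibility.
#' @param drift_slope Linear baseline drift, (mL/100mL/min)/s (default 0).
#' @param constants An [rh_constants()] list.
#' @param label Free-text label stored in the trace metadata.
#' @return A tibble with `time_s`, `perfusion`, `phase` (no `cuff` rows), and
#'   protocol/subject/meta attributes.
#' @examples
#' \donttest{
#' tr <- rh_generate_trace(rh_subject(), rh_protocol(120), sigma = 0.5, seed = 7)
#' }
#' @export
rh_generate_trace <- function(subject = rh_subject(), protocol = rh_protocol(),
                              sigma = 0.5, seed = NULL, drift_slope = 0,
                              constants = rh_constants(), label = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  sim <- rh_simulate(subject, protocol, constants)
  tr <- sim[sim$phase != "cuff", c("time_s", "perfusion", "phase")]
  if (!is.null(seed)) set.seed(seed)
  if (sigma > 0) tr$perfusion <- tr$perfusion + stats::rnorm(nrow(tr), 0, sigma)
  if (drift_slope != 0)
    tr$perfusion <- tr$perfusion + drift_slope * (tr$time_s - tr$time_s[1])
  attr(tr, "protocol") <- protocol
  attr(tr, "subject") <- subject
  attr(tr, "meta") <- list(label = label, sigma = sigma, seed = seed,
                           drift_slope = drift_slope, synthetic = TRUE)
  tr
}
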