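## Pulsatile inlet waveforms.

#' Generate a periodic inlet flow waveform
#'
#' Produces one cardiac period of volumetric flow from a smooth parametric
#' cardiac template: a periodic von-Mises-shaped systolic bump over a
#' diastolic baseline, with the systolic peak at a configurable fraction of
#' the period. The discrete time average over the period equals
#' \code{meanFlow} to machine precision and the minimum equals
#' \code{meanFlow * (1 - pulsatility)} at the sample grid.
#'
#' @param meanFlow time-averaged volumetric flow (l/s). Defaults for the
#'   three CoW inlets are provided by [cowInflows()].
#' @param period cardiac period (s), default 1.0.
#' @param pulsatility relative excursion below the mean, in [0, 1):
#'   min flow = meanFlow * (1 - pulsatility). 0 gives steady flow;
#'   values >= 1 would imply reverse inlet flow and are rejected.
#' @param nSamples number of samples including the duplicated period
#'   endpoint (>= 50).
#' @param peakTime systolic peak position as a fraction of the period.
#' @param sharpness concentration of the systolic bump (dimensionless).
#' @param label inlet label carried by the waveform.
#' @return A [FlowWaveform-class].
#' @examples
#' wf <- generateInflowWaveform(3.434e-3, period = 1, pulsatility = 0.5)
#' meanFlow(wf)
#' @export
generateInflowWaveform <- function(meanFlow, period = 1.0, pulsatility = 0.5,
                                   nSamples = 201, peakTime = 0.15,
                                   sharpness = 8, label = "") {
  if (meanFlow <= 0) stop("meanFlow must be > 0")
  if (period <= 0) stop("period must be > 0")
  if (pulsatility < 0 || pulsatility >= 1)
    stop("pulsatility must lie in [0, 1): reverse inlet flow is not modelled")
  if (nSamples < 50) stop("need at least 50 samples per period")
  phi <- seq(0, 1, length.out = nSamples)
  g <- exp(sharpness * (cos(2 * pi * (phi - peakTime)) - 1))
  gbar <- mean(g[-nSamples])
  if (pulsatility == 0) {
    flow <- rep(meanFlow, nSamples)
  } else {
    w <- 1 + pulsatility * (g - gbar) / (gbar - min(g))
    flow <- meanFlow * w
    flow <- flow * (meanFlow / mean(flow[-nSamples]))
  }
  flow[nSamples] <- flow[1]
  new("FlowWaveform", period = period, flow = flow, label = label)
}

#' Default inlet waveforms for the three CoW inlets
#'
#' Mean volumetric inflow rates are the phase-contrast-MRI-derived values
#' used as inlet boundary conditions: ICAr 3.434e-3, ICAl 3.065e-3 and
#' BA 2.332e-3 l/s.
#'
#' @param period,pulsatility,nSamples passed to [generateInflowWaveform()].
#' @return named list of three [FlowWaveform-class] objects (ICAl, ICAr, BA).
#' @export
cowInflows <- function(period = 1.0, pulsatility = 0.5, nSamples = 201) {
  means <- c(ICAl = 3.065e-3, ICAr = 3.434e-3, BA = 2.332e-3)
  lapply(setNames(names(means), names(means)), function(lab)
    generateInflowWaveform(means[[lab]], period = period,
                           pulsatility = pulsatility, nSamples = nSamples,
                           label = lab))
}

#' Evaluate a waveform at arbitrary times (periodic linear interpolation)
#'
#' @param waveform a [FlowWaveform-class].
#' @param t times (s); wrapped into the period.
#' @return flow values (l/s).
#' @export
evalWaveform <- function(waveform, t) {
  tw <- t %% waveform@period
  tt <- seq(0, waveform@period, length.out = length(waveform@flow))
  approx(tt, waveform@flow, xout = tw, rule = 2)$y
}
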