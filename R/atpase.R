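# Basal ATPase turnover: linear fits of ADP production and a synthetic
# timecourse generator.

#' Fit the basal ATP turnover rate from an ADP timecourse
#'
#' At 2 mM ATP the reaction is zeroth-order in ATP over the assay window, so
#' ADP accumulates linearly. The turnover rate is the ordinary least-squares
#' slope of ADP (uM) against time (s) divided by the enzyme concentration
#' (uM), in 1/s per motor. The fit requires at least 3 timepoints and checks
#' linearity by demanding that ADP consumption stays below 50% of the
#' starting ATP.
#'
#' @param tc an [ATPaseTimecourse-class].
#' @return list with `rate` (1/s), `se` (standard error of the rate) and the
#'   underlying `fit` (an `lm`).
#' @examples
#' tc <- ATPaseTimecourse(times = seq(0, 1800, 300),
#'                        adp = 0.14 * seq(0, 1800, 300))
#' fitTurnover(tc)$rate
#' @export
fitTurnover <- function(tc) {
  stopifnot(is(tc, "ATPaseTimecourse"))
  validObject(tc)
  if (length(tc@times) < 3L)
    stop("fitTurnover: need at least 3 timepoints")
  if (max(tc@adp) >= 0.5 * tc@atp0)
    stop("fitTurnover: ADP exceeds 50% of starting ATP; the linear ",
         "(zeroth-order) model no longer holds - truncate the timecourse ",
         "to the early linear phase")
  fit <- stats::lm(adp ~ times, data = data.frame(times = tc@times,
                                                  adp = tc@adp))
  # noiseless round-trip inputs fit exactly; summary.lm's perfect-fit
  # warning is expected there and carries no information
  co <- suppressWarnings(summary(fit))$coefficients
  list(rate = unname(co["times", "Estimate"]) / tc@kinesinConc,
       se = unname(co["times", "Std. Error"]) / tc@kinesinConc,
       fit = fit)
}

#' Simulate a basal ATPase timecourse
#'
#' `adp(t) = rate * kinesinConc * t` plus Gaussian sampling noise, clipped to
#' `[0, atp0]`. Defaults follow the assay layout: samples every 5 min
#' starting at 0, 1 uM enzyme, 2 mM ATP.
#'
#' @param rate turnover rate (1/s), >= 0.
#' @param times sampling times (s).
#' @param kinesinConc enzyme concentration (uM).
#' @param atp0 starting ATP (uM).
#' @param noiseSd Gaussian noise SD (uM); 0 for a noiseless line.
#' @param seed integer seed.
#' @return an [ATPaseTimecourse-class].
#' @export
simulateTimecourse <- function(rate, times = seq(0, 1800, by = 300),
                               kinesinConc = 1, atp0 = 2000, noiseSd = 0,
                               seed = 1L) {
  stopifnot(rate >= 0)
  set.seed(as.integer(seed))
  adp <- rate * kinesinConc * times
  if (noiseSd > 0) adp <- adp + stats::rnorm(length(times), 0, noiseSd)
  adp <- pmin(pmax(adp, 0), atp0)
  ATPaseTimecourse(times = times, adp = adp, kinesinConc = kinesinConc,
                   atp0 = atp0)
}

#' Read an ATPase timecourse from CSV
#'
#' Expects columns `time_s` and `adp_uM`.
#'
#' @param path CSV path.
#' @param kinesinConc enzyme concentration (uM).
#' @param atp0 starting ATP (uM).
#' @return an [ATPaseTimecourse-class].
#' @export
readTimecourseCsv <- function(path, kinesinConc = 1, atp0 = 2000) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "adp_uM") %in% names(d)))
    stop("timecourse CSV must have columns time_s, adp_uM: ", path)
  ATPaseTimecourse(times = d$time_s, adp = d$adp_uM,
                   kinesinConc = kinesinConc, atp0 = atp0)
}
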