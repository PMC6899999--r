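#' @import methods
NULL

# ---- MotorParams ------------------------------------------------------------

#' Kinetic parameters of one kinesin variant
#'
#' Generative single-molecule parameters describing how a motor interacts with
#' a stabilised (non-dynamic) microtubule: landing, translocation, detachment
#' from the lattice, and residence at the plus end. Run lengths and dwell
#' times are exponentially distributed with the given means; translocation
#' speed is constant.
#'
#' @slot name variant label, e.g. `"WT"`.
#' @slot velocity mean translocation speed (nm/s); 0 for non-translocating
#'   binders.
#' @slot meanRunLength mean distance travelled before lattice detachment (um).
#' @slot meanEndDwell mean residence time at the microtubule end (s).
#' @slot meanLatticeDwell mean dwell of statically bound lattice events (s);
#'   `NA` if the motor never binds statically.
#' @slot landingRate landing rate (events per um of microtubule per s).
#' @slot fractionStatic proportion of landings that bind without
#'   translocating, in [0, 1].
#' @exportClass MotorParams
setClass("MotorParams", representation(
  name = "character",
  velocity = "numeric",
  meanRunLength = "numeric",
  meanEndDwell = "numeric",
  meanLatticeDwell = "numeric",
  landingRate = "numeric",
  fractionStatic = "numeric"
))

setValidity("MotorParams", function(object) {
  msg <- character()
  if (length(object@velocity) != 1 || is.na(object@velocity) ||
      object@velocity < 0)
    msg <- c(msg, "velocity must be a single nonnegative number (nm/s)")
  if (object@velocity > 0 &&
      (is.na(object@meanRunLength) || object@meanRunLength <= 0))
    msg <- c(msg, "meanRunLength must be > 0 when velocity > 0")
  if (is.na(object@meanEndDwell) || object@meanEndDwell <= 0)
    msg <- c(msg, "meanEndDwell must be > 0")
  if (is.na(object@landingRate) || object@landingRate < 0)
    msg <- c(msg, "landingRate must be >= 0")
  if (is.na(object@fractionStatic) || object@fractionStatic < 0 ||
      object@fractionStatic > 1)
    msg <- c(msg, "fractionStatic must lie in [0, 1]")
  if (!is.na(object@meanLatticeDwell) && object@meanLatticeDwell <= 0)
    msg <- c(msg, "meanLatticeDwell must be > 0 when given")
  if (length(msg)) msg else TRUE
})

#' Construct motor parameters
#'
#' @param name variant label.
#' @param velocity mean translocation speed (nm/s).
#' @param meanRunLength mean run length before lattice detachment (um).
#' @param meanEndDwell mean end-residence time (s).
#' @param meanLatticeDwell mean static lattice dwell (s), or `NA`.
#' @param landingRate landings per um per s.
#' @param fractionStatic fraction of landings that are static binders.
#' @return a [MotorParams-class] object.
#' @examples
#' wt <- MotorParams("WT", velocity = 810, meanRunLength = 3.06,
#'                   meanEndDwell = 0.46)
#' @export
MotorParams <- function(name, velocity, meanRunLength, meanEndDwell,
                        meanLatticeDwell = NA_real_, landingRate = 0.02,
                        fractionStatic = 0) {
  new("MotorParams", name = as.character(name),
      velocity = as.numeric(velocity),
      meanRunLength = as.numeric(meanRunLength),
      meanEndDwell = as.numeric(meanEndDwell),
      meanLatticeDwell = as.numeric(meanLatticeDwell),
      landingRate = as.numeric(landingRate),
      fractionStatic = as.numeric(fractionStatic))
}

setMethod("show", "MotorParams", function(object) {
  cat("MotorParams:", object@name, "\n")
  cat(sprintf("  velocity        %g nm/s\n", object@velocity))
  cat(sprintf("  mean run length %g um\n", object@meanRunLength))
  cat(sprintf("  mean end dwell  %g s\n", object@meanEndDwell))
  if (!is.na(object@meanLatticeDwell))
    cat(sprintf("  lattice dwell   %g s\n", object@meanLatticeDwell))
  cat(sprintf("  landing rate    %g /um/s, fraction static %g\n",
              object@landingRate, object@fractionStatic))
})

# ---- ImagingParams ----------------------------------------------------------

#' Imaging geometry and noise model of the simulated TIRF movie
#'
#' @slot frameInterval time between frames (s); default 1/2.7 (2.7 Hz).
#' @slot pixelSize pixel size (nm).
#' @slot nFrames number of frames.
#' @slot nPixels image width (pixels); `NA` lets the dataset generator size
#'   the image to each microtubule.
#' @slot psfSigma Gaussian width of a point emitter (pixels).
#' @slot signalAmplitude peak intensity of one motor / of the microtubule.
#' @slot backgroundMean mean background intensity.
#' @slot backgroundSd background noise standard deviation.
#' @slot seed integer seed for rendering noise.
#' @exportClass ImagingParams
setClass("ImagingParams", representation(
  frameInterval = "numeric", pixelSize = "numeric", nFrames = "integer",
  nPixels = "integer", psfSigma = "numeric", signalAmplitude = "numeric",
  backgroundMean = "numeric", backgroundSd = "numeric", seed = "integer"
))

setValidity("ImagingParams", function(object) {
  msg <- character()
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  if (object@backgroundSd < 0) msg <- c(msg, "backgroundSd must be >= 0")
  if (object@psfSigma <= 0) msg <- c(msg, "psfSigma must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct imaging parameters
#'
#' Defaults follow a single-molecule TIRF setup imaging GFP-labelled motors
#' on rhodamine-labelled microtubules at 2.7 Hz with a 160 nm camera pixel.
#'
#' @param frameInterval seconds per frame.
#' @param pixelSize nm per pixel.
#' @param nFrames movie length in frames.
#' @param nPixels image width in pixels (`NA` = auto).
#' @param psfSigma point-spread sigma in pixels.
#' @param signalAmplitude spot peak intensity above background.
#' @param backgroundMean,backgroundSd background intensity model.
#' @param seed rendering noise seed.
#' @return an [ImagingParams-class] object.
#' @export
ImagingParams <- function(frameInterval = 1 / 2.7, pixelSize = 160,
                          nFrames = 300, nPixels = NA_integer_,
                          psfSigma = 1.1, signalAmplitude = 400,
                          backgroundMean = 100, backgroundSd = 20,
                          seed = 1L) {
  new("ImagingParams", frameInterval = frameInterval, pixelSize = pixelSize,
      nFrames = as.integer(nFrames), nPixels = as.integer(nPixels),
      psfSigma = psfSigma, signalAmplitude = signalAmplitude,
      backgroundMean = backgroundMean, backgroundSd = backgroundSd,
      seed = as.integer(seed))
}

setMethod("show", "ImagingParams", function(object) {
  cat(sprintf(
    "ImagingParams: %d frames x %s px, %.4g s/frame, %g nm/px, psf %g px\n",
    object@nFrames, ifelse(is.na(object@nPixels), "auto", object@nPixels),
    object@frameInterval, object@pixelSize, object@psfSigma))
})

# ---- MicrotubuleSpec --------------------------------------------------------

#' Geometry of one immobilised, stabilised microtubule
#'
#' Microtubules are GMPCPP-stabilised and static: length does not change over
#' the movie. The minus end sits at `startPixel`; `polarity` says which image
#' side carries the plus end.
#'
#' @slot length microtubule length (um).
#' @slot startPixel image column (1-based) of the left-most microtubule pixel.
#' @slot polarity `"right"` (plus end at the right) or `"left"`.
#' @exportClass MicrotubuleSpec
setClass("MicrotubuleSpec", representation(
  length = "numeric", startPixel = "integer", polarity = "character"
))

setValidity("MicrotubuleSpec", function(object) {
  msg <- character()
  if (object@length <= 0) msg <- c(msg, "length must be > 0 (um)")
  if (object@startPixel < 1L) msg <- c(msg, "startPixel must be >= 1")
  if (!object@polarity %in% c("right", "left"))
    msg <- c(msg, "polarity must be 'right' or 'left'")
  if (length(msg)) msg else TRUE
})

#' @param length microtubule length (um).
#' @param startPixel left-most microtubule column (1-based).
#' @param polarity which side is the plus end, `"right"` or `"left"`.
#' @rdname MicrotubuleSpec-class
#' @export
MicrotubuleSpec <- function(length, startPixel = 8L, polarity = "right") {
  new("MicrotubuleSpec", length = length, startPixel = as.integer(startPixel),
      polarity = polarity)
}

# ---- Kymograph --------------------------------------------------------------

#' Two-channel kymograph
#'
#' A time-position image: rows are frames (time ascending), columns are
#' position along the microtubule axis. Channel 1 (rhodamine) images the
#' microtubule, channel 2 (GFP) the motors.
#'
#' @slot rhodamine frames x pixels intensity matrix (microtubule channel).
#' @slot gfp frames x pixels intensity matrix (motor channel), same shape.
#' @slot frameInterval seconds per frame.
#' @slot pixelSize nm per pixel.
#' @exportClass Kymograph
setClass("Kymograph", representation(
  rhodamine = "matrix", gfp = "matrix",
  frameInterval = "numeric", pixelSize = "numeric"
))

setValidity("Kymograph", function(object) {
  msg <- character()
  if (!all(dim(object@rhodamine) == dim(object@gfp)))
    msg <- c(msg, "rhodamine and gfp channels must share dimensions")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param rhodamine,gfp intensity matrices (frames x pixels).
#' @param frameInterval seconds per frame.
#' @param pixelSize nm per pixel.
#' @rdname Kymograph-class
#' @export
Kymograph <- function(rhodamine, gfp, frameInterval = 1 / 2.7,
                      pixelSize = 160) {
  new("Kymograph", rhodamine = rhodamine, gfp = gfp,
      frameInterval = frameInterval, pixelSize = pixelSize)
}

setMethod("show", "Kymograph", function(object) {
  cat(sprintf(
    "Kymograph: %d frames x %d px (%.4g s/frame, %g nm/px)\n",
    nrow(object@gfp), ncol(object@gfp), object@frameInterval,
    object@pixelSize))
})

#' Channel and geometry accessors
#'
#' @param x a [Kymograph-class].
#' @return the requested channel matrix or geometry scalar.
#' @export
gfpChannel <- function(x) x@gfp

#' @rdname gfpChannel
#' @export
rhodamineChannel <- function(x) x@rhodamine

#' @rdname gfpChannel
#' @export
frameInterval <- function(x) x@frameInterval

#' @rdname gfpChannel
#' @export
pixelSize <- function(x) x@pixelSize

# ---- MicrotubuleExtent ------------------------------------------------------

#' Located microtubule span in a kymograph
#'
#' The end pixels are the final columns at either side whose time-averaged
#' rhodamine signal lies above the background threshold.
#'
#' @slot leftEnd,rightEnd image columns of the two microtubule end pixels.
#' @slot thresholdRho the rhodamine threshold used.
#' @exportClass MicrotubuleExtent
setClass("MicrotubuleExtent", representation(
  leftEnd = "integer", rightEnd = "integer", thresholdRho = "numeric"
))

setValidity("MicrotubuleExtent", function(object) {
  if (object@leftEnd >= object@rightEnd)
    "leftEnd must be < rightEnd" else TRUE
})

#' @param leftEnd,rightEnd end columns (1-based).
#' @param thresholdRho threshold used on the rhodamine channel.
#' @rdname MicrotubuleExtent-class
#' @export
MicrotubuleExtent <- function(leftEnd, rightEnd, thresholdRho = NA_real_) {
  new("MicrotubuleExtent", leftEnd = as.integer(leftEnd),
      rightEnd = as.integer(rightEnd), thresholdRho = thresholdRho)
}

setMethod("show", "MicrotubuleExtent", function(object) {
  cat(sprintf("MicrotubuleExtent: columns %d..%d (threshold %.3g)\n",
              object@leftEnd, object@rightEnd, object@thresholdRho))
})

# ---- EventTrace -------------------------------------------------------------

#' One segmented fluorescence event
#'
#' A connected set of above-threshold GFP pixels with its classification and
#' measurements. Classes: `"translocating"` (unidirectional movement over >= 3
#' frames), `"lattice"` (static binder), `"discarded-crossing"` (overlapping
#' events that cannot be separated). Any non-discarded event whose trace
#' reaches a microtubule end column is additionally end-resident
#' (`endFrames > 0`).
#'
#' @slot pixels n x 2 integer matrix of (frame, column) pixels.
#' @slot frames frames occupied, ascending.
#' @slot centroidCols per-frame intensity-weighted centroid column.
#' @slot peakCols per-frame brightest column.
#' @slot eventClass one of the classes above.
#' @slot censored TRUE if the event touches the first or last movie frame.
#' @slot endFrames length (frames) of the maximal consecutive run spent at an
#'   end column; 0 if never at an end.
#' @slot endSide `"left"`, `"right"` or `NA`.
#' @slot endResidence end-residence time (s), `NA` if not end-resident.
#' @slot endCensored TRUE if the end run touches the movie boundary.
#' @slot velocity translocation speed (nm/s), `NA` unless translocating.
#' @slot runLength run length (um), `NA` unless translocating.
#' @slot runLengthCensored TRUE if the run ends at an end column or at the
#'   movie boundary.
#' @exportClass EventTrace
setClass("EventTrace", representation(
  pixels = "matrix", frames = "integer", centroidCols = "numeric",
  peakCols = "integer", eventClass = "character", censored = "logical",
  endFrames = "integer", endSide = "character", endResidence = "numeric",
  endCensored = "logical", velocity = "numeric", runLength = "numeric",
  runLengthCensored = "logical"
))

setMethod("show", "EventTrace", function(object) {
  cat(sprintf("EventTrace: %s, frames %d..%d (%d px)",
              object@eventClass, min(object@frames), max(object@frames),
              nrow(object@pixels)))
  if (object@endFrames > 0L)
    cat(sprintf(", end-resident %d frame(s) [%s]",
                object@endFrames, object@endSide))
  cat("\n")
})

#' EventTrace accessors
#'
#' @param x an [EventTrace-class].
#' @return the requested slot value.
#' @export
eventClass <- function(x) x@eventClass

#' @rdname eventClass
#' @export
endResidence <- function(x) x@endResidence

#' @rdname eventClass
#' @export
eventVelocity <- function(x) x@velocity

#' @rdname eventClass
#' @export
eventRunLength <- function(x) x@runLength

# ---- ResidenceDataset -------------------------------------------------------

#' Collection of per-event durations for one variant
#'
#' @slot variant variant label.
#' @slot durations uncensored per-event durations (s), all > 0.
#' @slot frameInterval the time quantum of the measurement (s), `NA` for
#'   continuous data.
#' @exportClass ResidenceDataset
setClass("ResidenceDataset", representation(
  variant = "character", durations = "numeric", frameInterval = "numeric"
))

setValidity("ResidenceDataset", function(object) {
  if (length(object@durations) == 0)
    return("durations must be nonempty")
  if (any(!is.finite(object@durations)) || any(object@durations <= 0))
    return("all durations must be finite and > 0")
  TRUE
})

#' ResidenceDataset accessors
#'
#' @param x a [ResidenceDataset-class].
#' @return durations, count, arithmetic mean or SD/sqrt(n).
#' @export
residenceDurations <- function(x) x@durations

#' @rdname residenceDurations
#' @export
residenceN <- function(x) length(x@durations)

#' @rdname residenceDurations
#' @export
residenceMean <- function(x) mean(x@durations)

#' @rdname residenceDurations
#' @export
residenceSem <- function(x) stats::sd(x@durations) / sqrt(length(x@durations))

setMethod("show", "ResidenceDataset", function(object) {
  cat(sprintf("ResidenceDataset '%s': n = %d, mean = %.3g s, sem = %.3g s\n",
              object@variant, residenceN(object), residenceMean(object),
              residenceSem(object)))
})

# ---- KSResult ---------------------------------------------------------------

#' Two-sample Kolmogorov-Smirnov result
#'
#' @slot D supremum absolute difference between the two empirical CDFs.
#' @slot pValue asymptotic p-value.
#' @slot n1,n2 sample sizes.
#' @exportClass KSResult
setClass("KSResult", representation(
  D = "numeric", pValue = "numeric", n1 = "integer", n2 = "integer"
))

setMethod("show", "KSResult", function(object) {
  cat(sprintf("KS two-sample: D = %.4f, p = %.3g (n1 = %d, n2 = %d)\n",
              object@D, object@pValue, object@n1, object@n2))
})

# ---- ATPaseTimecourse -------------------------------------------------------

#' ADP-production timecourse of a basal ATPase assay
#'
#' @slot times sampling times (s), strictly increasing.
#' @slot adp ADP concentration at each time (uM).
#' @slot kinesinConc enzyme concentration (uM).
#' @slot atp0 initial ATP concentration (uM).
#' @exportClass ATPaseTimecourse
setClass("ATPaseTimecourse", representation(
  times = "numeric", adp = "numeric", kinesinConc = "numeric",
  atp0 = "numeric"
))

setValidity("ATPaseTimecourse", function(object) {
  msg <- character()
  if (length(object@times) != length(object@adp))
    msg <- c(msg, "times and adp must have equal length")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@adp < 0) || any(object@adp > object@atp0))
    msg <- c(msg, "adp must lie in [0, atp0]")
  if (object@kinesinConc <= 0) msg <- c(msg, "kinesinConc must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param times sampling times (s).
#' @param adp ADP concentrations (uM).
#' @param kinesinConc enzyme concentration (uM); the assay uses 1 uM.
#' @param atp0 starting ATP (uM); the assay uses 2 mM = 2000 uM.
#' @rdname ATPaseTimecourse-class
#' @export
ATPaseTimecourse <- function(times, adp, kinesinConc = 1, atp0 = 2000) {
  new("ATPaseTimecourse", times = as.numeric(times), adp = as.numeric(adp),
      kinesinConc = kinesinConc, atp0 = atp0)
}

setMethod("show", "ATPaseTimecourse", function(object) {
  cat(sprintf(
    "ATPaseTimecourse: %d points over %g s, [kinesin] = %g uM, ATP0 = %g uM\n",
    length(object@times), max(object@times) - min(object@times),
    object@kinesinConc, object@atp0))
})
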