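# Stochastic simulation of single-motor events and kymograph rendering.

#' Simulate single-motor interaction events on one microtubule
#'
#' Draws a realisation of the kinetic model: motors land on the microtubule
#' as a Poisson process of rate `landingRate * length`, at positions uniform
#' along the lattice. A translocating motor moves plus-ward at constant
#' `velocity` with a detachment hazard `velocity / meanRunLength` (run
#' distances are exponential). A motor whose run carries it to within
#' `endCaptureUm` of the plus end is captured there: it parks at the centre
#' of the end zone and detaches after an exponential dwell of mean
#' `meanEndDwell`. Static binders (`fractionStatic`) dwell at their landing
#' position for an exponential time of mean `meanLatticeDwell`, except that a
#' static binder landing inside the end zone uses the end dwell instead (this
#' is how end-recognising, non-translocating motors such as MCAK acquire end
#' events). Events still bound when the observation window closes are
#' truncated and flagged censored.
#'
#' @param motor a [MotorParams-class].
#' @param mt a [MicrotubuleSpec-class].
#' @param duration observation time (s).
#' @param seed integer seed; identical seeds give identical event lists.
#' @param endCaptureUm distance from the plus end (um) at which the end dwell
#'   begins. Default 0.16 um, i.e. one default camera pixel, so that the end
#'   dwell corresponds to residence in the terminal pixel column.
#' @return a `data.frame` with one row per event and columns `event_id`,
#'   `kind` (`"translocating"`/`"static-lattice"`), `landing_time_s`,
#'   `landing_pos_um`, `detach_time_s`, `reached_end`, `end_arrival_time_s`,
#'   `end_pos_um` (parking position), `velocity_nm_s`, `censored`.
#' @examples
#' wt <- MotorParams("WT", 810, 3.06, 0.46)
#' ev <- simulateEvents(wt, MicrotubuleSpec(8), duration = 60, seed = 1)
#' @export
simulateEvents <- function(motor, mt, duration, seed,
                           endCaptureUm = 0.16) {
  stopifnot(is(motor, "MotorParams"), is(mt, "MicrotubuleSpec"),
            duration > 0)
  validObject(motor)
  if (motor@fractionStatic > 0 && is.na(motor@meanLatticeDwell))
    stop("static events requested (fractionStatic > 0) but meanLatticeDwell ",
         "is absent: parameterisation error")
  set.seed(as.integer(seed))
  L <- mt@length
  n <- stats::rpois(1L, motor@landingRate * L * duration)
  if (n == 0L) {
    return(emptyEventTable())
  }
  t0 <- sort(stats::runif(n, 0, duration))
  pos <- stats::runif(n, 0, L)
  isStatic <- if (motor@velocity <= 0) rep(TRUE, n) else
    stats::runif(n) < motor@fractionStatic
  if (any(isStatic) && is.na(motor@meanLatticeDwell) && motor@velocity <= 0)
    stop("velocity is 0 but meanLatticeDwell is absent: parameterisation error")

  endZone <- max(0, L - endCaptureUm)
  # park at the centre of the terminal position bin of width endCaptureUm,
  # so an end-dwelling motor renders squarely in the terminal pixel column
  endPos <- if (endCaptureUm > 0)
    (max(1, round(L / endCaptureUm)) - 0.5) * endCaptureUm else L
  kind <- ifelse(isStatic, "static-lattice", "translocating")
  reached <- logical(n)
  arrival <- rep(NA_real_, n)
  detach <- numeric(n)

  # draws per event in a fixed order so the realisation is seed-reproducible
  runLen <- stats::rexp(n) * motor@meanRunLength
  endDwell <- stats::rexp(n) * motor@meanEndDwell
  latticeDwell <- if (is.na(motor@meanLatticeDwell)) rep(NA_real_, n) else
    stats::rexp(n) * motor@meanLatticeDwell

  for (i in seq_len(n)) {
    if (isStatic[i]) {
      if (pos[i] >= endZone) {        # end-recognising static binder
        reached[i] <- TRUE
        arrival[i] <- t0[i]
        detach[i] <- t0[i] + endDwell[i]
      } else {
        detach[i] <- t0[i] + latticeDwell[i]
      }
    } else {
      v_um <- motor@velocity / 1000   # nm/s -> um/s
      dToEnd <- max(0, endZone - pos[i])
      if (runLen[i] >= dToEnd) {
        reached[i] <- TRUE
        arrival[i] <- t0[i] + dToEnd / v_um
        detach[i] <- arrival[i] + endDwell[i]
      } else {
        detach[i] <- t0[i] + runLen[i] / v_um
      }
    }
  }
  censored <- detach > duration
  detach <- pmin(detach, duration)
  # still travelling towards the end when the movie closes: not an end event
  cut <- reached & !is.na(arrival) & arrival > duration
  reached[cut] <- FALSE
  arrival[cut] <- NA_real_
  out <- data.frame(
    event_id = seq_len(n),
    kind = kind,
    landing_time_s = t0,
    landing_pos_um = pos,
    detach_time_s = detach,
    reached_end = reached,
    end_arrival_time_s = arrival,
    end_pos_um = ifelse(reached, endPos, NA_real_),
    velocity_nm_s = ifelse(isStatic, 0, motor@velocity),
    censored = censored,
    stringsAsFactors = FALSE
  )
  out
}

emptyEventTable <- function() {
  data.frame(event_id = integer(), kind = character(),
             landing_time_s = numeric(), landing_pos_um = numeric(),
             detach_time_s = numeric(), reached_end = logical(),
             end_arrival_time_s = numeric(), end_pos_um = numeric(),
             velocity_nm_s = numeric(), censored = logical(),
             stringsAsFactors = FALSE)
}

#' Ground-truth motor position at given times
#'
#' Evaluates the piecewise-linear trajectory of one simulated event: constant
#' speed from the landing position until end arrival (if any), parked at the
#' end zone centre during the end dwell, static throughout for lattice
#' binders. Times outside [landing, detach) give `NA`.
#'
#' @param event one row of the table returned by [simulateEvents()].
#' @param times numeric vector of times (s).
#' @return positions (um from the minus end), `NA` when unbound.
#' @export
eventPositionAt <- function(event, times) {
  bound <- times >= event$landing_time_s & times < event$detach_time_s
  p <- rep(NA_real_, length(times))
  if (event$kind == "static-lattice" || event$velocity_nm_s == 0) {
    p[bound] <- if (isTRUE(event$reached_end)) event$end_pos_um else
      event$landing_pos_um
  } else {
    v <- event$velocity_nm_s / 1000
    tt <- times[bound]
    if (isTRUE(event$reached_end)) {
      pre <- tt < event$end_arrival_time_s
      pp <- numeric(length(tt))
      pp[pre] <- event$landing_pos_um + v * (tt[pre] - event$landing_time_s)
      pp[!pre] <- event$end_pos_um
      p[bound] <- pp
    } else {
      p[bound] <- event$landing_pos_um + v * (tt - event$landing_time_s)
    }
  }
  p
}

#' Render simulated events into a noisy two-channel kymograph
#'
#' The rhodamine channel is a uniform intensity over the microtubule's pixel
#' span plus Gaussian background noise. The GFP channel receives, for every
#' frame during which an event is bound (sampled at the frame midpoint), a
#' one-dimensional Gaussian spot of width `psfSigma` centred at the motor
#' position, additive when events overlap, plus background noise. Rendering
#' is deterministic given `imaging@seed`.
#'
#' @param events event table from [simulateEvents()].
#' @param mt the [MicrotubuleSpec-class] the events were simulated on.
#' @param imaging an [ImagingParams-class]; `nPixels` must be set here (use
#'   [generateDataset()] for automatic sizing).
#' @return a [Kymograph-class].
#' @export
renderKymograph <- function(events, mt, imaging) {
  stopifnot(is(mt, "MicrotubuleSpec"), is(imaging, "ImagingParams"))
  validObject(imaging)
  nF <- imaging@nFrames
  dt <- imaging@frameInterval
  pxUm <- imaging@pixelSize / 1000
  mtPx <- max(1L, as.integer(round(mt@length / pxUm)))
  W <- imaging@nPixels
  # keep the microtubule under half of the columns so the median-based
  # background threshold stays on the background
  if (is.na(W)) W <- as.integer(2L * mtPx + 2L * mt@startPixel)
  mtCols <- mt@startPixel:(mt@startPixel + mtPx - 1L)
  if (min(mtCols) < 1L || max(mtCols) > W)
    stop("microtubule span lies outside the image (width ", W, " px)")
  horizon <- nF * dt
  if (nrow(events) && any(events$landing_time_s >= horizon))
    stop("event(s) ", paste(events$event_id[events$landing_time_s >= horizon],
                            collapse = ", "),
         " start after the movie ends; increase nFrames")

  set.seed(imaging@seed)
  noise <- function() {
    if (imaging@backgroundSd > 0)
      matrix(stats::rnorm(nF * W, imaging@backgroundMean,
                          imaging@backgroundSd), nF, W)
    else matrix(imaging@backgroundMean, nF, W)
  }
  rho <- noise()
  rho[, mtCols] <- rho[, mtCols] + imaging@signalAmplitude
  gfp <- noise()

  # position (um from minus end) -> continuous column coordinate
  posToCol <- function(p) {
    if (mt@polarity == "right") (mt@startPixel - 0.5) + p / pxUm
    else (mt@startPixel + mtPx - 0.5) - p / pxUm
  }
  mids <- (seq_len(nF) - 0.5) * dt
  win <- as.integer(ceiling(4 * imaging@psfSigma))
  for (i in seq_len(nrow(events))) {
    p <- eventPositionAt(events[i, ], mids)
    rows <- which(!is.na(p))
    if (!length(rows)) next
    cc <- posToCol(p[rows])
    if (any(cc < 0.5 | cc > W + 0.5))
      stop("event ", events$event_id[i], " renders outside the image")
    base <- floor(cc)
    for (dj in (-win):(win + 1L)) {
      j <- base + dj
      ok <- j >= 1L & j <= W
      if (!any(ok)) next
      amp <- imaging@signalAmplitude *
        exp(-((j[ok] - cc[ok])^2) / (2 * imaging@psfSigma^2))
      gfp[cbind(rows[ok], j[ok])] <- gfp[cbind(rows[ok], j[ok])] + amp
    }
  }
  Kymograph(rhodamine = rho, gfp = gfp, frameInterval = dt,
            pixelSize = imaging@pixelSize)
}

#' Generate a full synthetic dataset of kymographs with ground truth
#'
#' Simulates `nMicrotubules` microtubules (lengths uniform over
#' `mtLengthRange`), renders each into a two-channel kymograph, and collects
#' a ground-truth event table. With `outDir` set, each kymograph is written
#' as a two-page 16-bit TIFF (`kymo_<i>.tif`, page 1 rhodamine, page 2 GFP)
#' and the ground truth as `ground_truth.csv`.
#'
#' @param motor a [MotorParams-class].
#' @param imaging an [ImagingParams-class]; with `nPixels = NA` each image is
#'   sized to `2 * mtPixels + 2 * startPixel` so the microtubule occupies
#'   less than half of the columns (keeps the median-based threshold on the
#'   background).
#' @param nMicrotubules number of microtubules (>= 1).
#' @param seed master seed; per-microtubule event and noise seeds are derived
#'   from it, so identical seeds give identical datasets.
#' @param outDir optional output directory.
#' @param mtLengthRange range (um) for microtubule lengths.
#' @param startPixel left margin of the microtubule in each image.
#' @return invisibly, a list with `kymographs` (list of [Kymograph-class]),
#'   `microtubules` (list of [MicrotubuleSpec-class]), `groundTruth`
#'   (data.frame keyed by `mt_id`, `event_id`) and `files`.
#' @export
generateDataset <- function(motor, imaging, nMicrotubules, seed,
                            outDir = NULL, mtLengthRange = c(6, 10),
                            startPixel = 8L) {
  stopifnot(nMicrotubules >= 1)
  set.seed(as.integer(seed))
  lens <- stats::runif(nMicrotubules, mtLengthRange[1], mtLengthRange[2])
  subSeeds <- sample.int(.Machine$integer.max - 1L, 2L * nMicrotubules)
  pxUm <- imaging@pixelSize / 1000
  duration <- imaging@nFrames * imaging@frameInterval
  kymos <- vector("list", nMicrotubules)
  mts <- vector("list", nMicrotubules)
  gts <- vector("list", nMicrotubules)
  files <- character(0)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  for (i in seq_len(nMicrotubules)) {
    mt <- MicrotubuleSpec(lens[i], startPixel = startPixel)
    mts[[i]] <- mt
    ev <- simulateEvents(motor, mt, duration, seed = subSeeds[2L * i - 1L],
                         endCaptureUm = pxUm)
    img <- imaging
    img@seed <- subSeeds[2L * i]
    if (is.na(img@nPixels)) {
      mtPx <- max(1L, as.integer(round(mt@length / pxUm)))
      img@nPixels <- as.integer(2L * mtPx + 2L * startPixel)
    }
    kymos[[i]] <- renderKymograph(ev, mt, img)
    if (nrow(ev)) {
      gts[[i]] <- data.frame(mt_id = i, ev, stringsAsFactors = FALSE)
    }
    if (!is.null(outDir)) {
      f <- file.path(outDir, sprintf("kymo_%03d.tif", i))
      writeKymographTiff(kymos[[i]], f)
      files <- c(files, f)
    }
  }
  gt <- if (length(gts)) do.call(rbind, gts) else
    data.frame(mt_id = integer(), emptyEventTable())
  if (!is.null(outDir)) {
    csv <- file.path(outDir, "ground_truth.csv")
    writeGroundTruthCsv(gt, csv)
    files <- c(files, csv)
  }
  invisible(list(kymographs = kymos, microtubules = mts, groundTruth = gt,
                 files = files))
}

#' Write / read a two-channel kymograph as 16-bit TIFF
#'
#' Page 1 holds the rhodamine (microtubule) channel, page 2 the GFP (motor)
#' channel; rows are frames, columns are position. Intensities are clamped to
#' [0, 65535]. TIFF carries no acquisition metadata, so `frameInterval` and
#' `pixelSize` must be supplied on reading.
#'
#' @param kymo a [Kymograph-class].
#' @param path output TIFF path.
#' @export
writeKymographTiff <- function(kymo, path) {
  sc <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  tiff::writeTIFF(list(sc(kymo@rhodamine), sc(kymo@gfp)), path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @param path TIFF path written by [writeKymographTiff()].
#' @param frameInterval seconds per frame of the recording.
#' @param pixelSize nm per pixel of the recording.
#' @rdname writeKymographTiff
#' @return `readKymographTiff` returns a [Kymograph-class].
#' @export
readKymographTiff <- function(path, frameInterval = 1 / 2.7,
                              pixelSize = 160) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L)
    stop("expected a two-page TIFF (rhodamine, GFP): ", path)
  Kymograph(rhodamine = pages[[1]] * 65535, gfp = pages[[2]] * 65535,
            frameInterval = frameInterval, pixelSize = pixelSize)
}

#' Write / read the ground-truth event table
#'
#' Column layout: `mt_id,event_id,kind,landing_time_s,landing_pos_um,`
#' `detach_time_s,reached_end,end_arrival_time_s,censored`.
#'
#' @param gt ground-truth data.frame from [generateDataset()].
#' @param path CSV path.
#' @export
writeGroundTruthCsv <- function(gt, path) {
  cols <- c("mt_id", "event_id", "kind", "landing_time_s", "landing_pos_um",
            "detach_time_s", "reached_end", "end_arrival_time_s", "censored")
  utils::write.csv(gt[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruthCsv
#' @return `readGroundTruthCsv` returns the event data.frame.
#' @export
readGroundTruthCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
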