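# Kymograph measurement: thresholding, end location, event segmentation,
# classification, and extraction of end residence, velocity and run length.

#' Analysis configuration
#'
#' Tunable options of the measurement procedure.
#'
#' @param kThreshold threshold multiplier: threshold = median + k x robust SD
#'   (robust SD = 1.4826 x MAD).
#' @param durationConvention `"k"`: an event occupying k frames lasts
#'   `k * frameInterval`; `"k_minus_1"`: `(k - 1) * frameInterval`.
#' @param endWindow half-width (columns) of the end zone around each end
#'   pixel; 0 = the single terminal pixel column.
#' @param endAttribution `"peak"` (default): a frame counts as at-the-end when
#'   the trace's brightest column that frame lies in the end zone; `"any"`:
#'   when any pixel of the trace does. Peak attribution is robust to the
#'   point-spread function lighting the end column while the motor is still
#'   one or two pixels away.
#' @param minTranslocFrames minimum frames of unidirectional movement for the
#'   translocating class (>= 3, i.e. > 750 ms at 2.7 Hz).
#' @param minNetDisplacementPx minimum net centroid displacement (pixels) for
#'   the translocating class; excludes jitter.
#' @return a named list of options.
#' @export
analysisConfig <- function(kThreshold = 3, durationConvention = c("k", "k_minus_1"),
                           endWindow = 0L, endAttribution = c("peak", "any"),
                           minTranslocFrames = 3L, minNetDisplacementPx = 2) {
  list(kThreshold = kThreshold,
       durationConvention = match.arg(durationConvention),
       endWindow = as.integer(endWindow),
       endAttribution = match.arg(endAttribution),
       minTranslocFrames = as.integer(minTranslocFrames),
       minNetDisplacementPx = minNetDisplacementPx)
}

#' Robust background threshold of an intensity image
#'
#' Returns `median(x) + k * 1.4826 * MAD(x)`. On an image whose pixels are
#' mostly background this separates signal from background without being
#' dragged by the bright minority. A zero-spread (constant) image yields the
#' median with a warning, since no signal is separable.
#'
#' @param x numeric array (any shape) of intensities.
#' @param k threshold multiplier (> 0), default 3.
#' @return the threshold intensity (scalar).
#' @examples
#' estimateThreshold(matrix(rnorm(1e4, 100, 10), 100), k = 3)
#' @export
estimateThreshold <- function(x, k = 3) {
  v <- as.numeric(x)
  stopifnot(length(v) > 0, k > 0)
  s <- stats::mad(v)  # includes the 1.4826 consistency constant
  if (s == 0)
    warning("zero spread: no signal separable from background")
  stats::median(v) + k * s
}

#' Locate the microtubule and its end pixels
#'
#' Averages the rhodamine channel over time to a per-column profile,
#' thresholds the profile with [estimateThreshold()], and returns the first
#' and last column of the longest above-threshold run. The end pixel is thus
#' the final pixel at either end of the microtubule with signal above the
#' background threshold. Stabilised microtubules are static, so a single
#' time-averaged extent serves the whole movie.
#'
#' @param kymo a [Kymograph-class].
#' @param k threshold multiplier.
#' @return a [MicrotubuleExtent-class].
#' @export
locateMicrotubule <- function(kymo, k = 3) {
  stopifnot(is(kymo, "Kymograph"))
  profile <- colMeans(kymo@rhodamine)
  thr <- suppressWarnings(estimateThreshold(profile, k))
  above <- profile > thr
  if (!any(above))
    stop("no microtubule detected: no column above threshold ",
         format(thr, digits = 4))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  MicrotubuleExtent(starts[best], ends[best], thresholdRho = thr)
}

#' Detect above-background motor pixels
#'
#' Marks GFP pixels above the channel threshold, restricted to columns within
#' the microtubule extent; everything off the microtubule is forced `FALSE`.
#'
#' @param kymo a [Kymograph-class].
#' @param extent a [MicrotubuleExtent-class].
#' @param k threshold multiplier.
#' @return logical matrix (frames x pixels).
#' @export
detectEventPixels <- function(kymo, extent, k = 3) {
  stopifnot(is(kymo, "Kymograph"), is(extent, "MicrotubuleExtent"))
  if (extent@rightEnd > ncol(kymo@gfp))
    stop("extent lies outside the kymograph")
  thr <- suppressWarnings(estimateThreshold(kymo@gfp, k))
  mask <- kymo@gfp > thr
  keep <- seq_len(ncol(mask)) %in% (extent@leftEnd:extent@rightEnd)
  mask[, !keep] <- FALSE
  mask
}

#' Segment a binary mask into discrete events
#'
#' Connected-component labelling under 8-connectivity: two above-threshold
#' pixels belong to the same event unless separated by at least one
#' non-event pixel along both axes, so diagonal contact connects. This is the
#' operational form of the discreteness rule (events are discrete when
#' separated by >= 1 non-event pixel in time or distance).
#'
#' @param mask logical matrix (frames x pixels).
#' @return list of integer matrices, each n x 2 with columns (frame, column),
#'   ordered by first occupied pixel; empty list for an all-false mask.
#' @export
segmentEvents <- function(mask) {
  stopifnot(is.matrix(mask))
  idx <- which(mask)
  if (!length(idx)) return(list())
  nr <- nrow(mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  n <- length(idx)
  # edges to the 4 forward neighbours (down, right and both diagonals)
  # suffice for an undirected adjacency graph
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    nb <- idx + o[1L] + o[2L] * nr
    valid <- rr + o[1L] >= 1L & rr + o[1L] <= nr & cc + o[2L] <= ncol(mask)
    m <- match(nb, idx)
    ok <- valid & !is.na(m)
    from <- c(from, which(ok)); to <- c(to, m[ok])
  }
  g <- igraph::make_graph(edges = c(rbind(from, to)), n = n,
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  comps <- split(seq_len(n), memb)
  ord <- order(vapply(comps, function(ix) min(idx[ix]), numeric(1)))
  lapply(comps[ord], function(ix) {
    m <- cbind(frame = rr[ix], col = cc[ix])
    m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  })
}

# Per-row pixel runs of a component; used for crossing detection and
# per-frame summaries. Returns list keyed by frame.
rowRuns <- function(pixels) {
  lapply(split(pixels[, 2L], pixels[, 1L]), function(cols) {
    cols <- sort(cols)
    split(cols, cumsum(c(1L, diff(cols) > 1L)))
  })
}

#' Classify one segmented event
#'
#' Applies, in order: (i) the crossing exclusion - a component in which any
#' frame-row holds two or more disjoint pixel runs is two overlapping events
#' that cannot be separated and is discarded (`"discarded-crossing"`);
#' (ii) the translocation criterion - an event spanning at least
#' `minTranslocFrames` frames whose per-frame centroid moves unidirectionally
#' (pauses allowed, no sign reversal) with net displacement >=
#' `minNetDisplacementPx` pixels is `"translocating"`; (iii) all remaining
#' events are `"lattice"` (static binders). Independently of class, frames
#' whose trace sits at an end column are recorded so the event can be scored
#' end-resident; an event touching the first or last movie frame is flagged
#' censored.
#'
#' @param pixels n x 2 (frame, column) matrix of one component.
#' @param extent a [MicrotubuleExtent-class].
#' @param kymo the [Kymograph-class] the component came from (intensities are
#'   needed for centroid and peak columns).
#' @param config an [analysisConfig()] list.
#' @return an [EventTrace-class] with class, per-frame summaries and end
#'   occupancy filled in; measurements are added by [analyseKymograph()].
#' @export
classifyEvent <- function(pixels, extent, kymo, config = analysisConfig()) {
  if (is.null(pixels) || nrow(pixels) == 0L)
    stop("classifyEvent: empty pixel set (contract violation)")
  frames <- sort(unique(pixels[, 1L]))
  runs <- rowRuns(pixels)
  crossing <- any(vapply(runs, length, integer(1)) >= 2L)

  ints <- kymo@gfp[pixels]
  bg <- stats::median(kymo@gfp)
  w <- pmax(ints - bg, 1e-9)
  byFrame <- split(seq_len(nrow(pixels)), pixels[, 1L])
  centroid <- vapply(byFrame, function(ix)
    sum(pixels[ix, 2L] * w[ix]) / sum(w[ix]), numeric(1))
  peak <- vapply(byFrame, function(ix)
    pixels[ix, 2L][which.max(ints[ix])], numeric(1))
  censored <- min(frames) == 1L || max(frames) == nrow(kymo@gfp)

  cls <- "lattice"
  if (crossing) {
    cls <- "discarded-crossing"
  } else if (length(frames) >= config$minTranslocFrames &&
             all(diff(frames) == 1L)) {
    d <- diff(centroid)
    unidir <- all(d >= -1e-9) || all(d <= 1e-9)
    if (unidir &&
        abs(centroid[length(centroid)] - centroid[1L]) >=
          config$minNetDisplacementPx)
      cls <- "translocating"
  }

  endFrames <- 0L; endSide <- NA_character_
  if (cls != "discarded-crossing") {
    occ <- endOccupancy(pixels, peak, frames, extent, config)
    endFrames <- occ$frames; endSide <- occ$side
  }
  new("EventTrace", pixels = pixels, frames = as.integer(frames),
      centroidCols = unname(centroid), peakCols = as.integer(unname(peak)),
      eventClass = cls, censored = censored,
      endFrames = as.integer(endFrames), endSide = endSide,
      endResidence = NA_real_, endCensored = FALSE,
      velocity = NA_real_, runLength = NA_real_, runLengthCensored = FALSE)
}

# Maximal consecutive run of frames at either end column. Returns the longer
# run (first on ties) with its side and start/stop frames.
endOccupancy <- function(pixels, peak, frames, extent, config) {
  w <- config$endWindow
  atEnd <- function(endCol) {
    if (config$endAttribution == "peak") {
      abs(peak - endCol) <= w
    } else {
      vapply(split(pixels[, 2L], pixels[, 1L]), function(cols)
        any(abs(cols - endCol) <= w), logical(1))
    }
  }
  best <- list(frames = 0L, side = NA_character_, first = NA_integer_,
               last = NA_integer_)
  for (side in c("left", "right")) {
    endCol <- if (side == "left") extent@leftEnd else extent@rightEnd
    hit <- atEnd(endCol)
    if (!any(hit)) next
    r <- rle(hit)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    iTrue <- which(r$values)
    k <- iTrue[which.max(r$lengths[iTrue])]
    if (r$lengths[k] > best$frames) {
      best <- list(frames = r$lengths[k], side = side,
                   first = frames[starts[k]], last = frames[stops[k]])
    }
  }
  best
}

#' Measure end-residence time of an end-resident trace
#'
#' Duration of the maximal consecutive run of frames during which the trace
#' occupies the end column, converted to seconds by the duration convention:
#' a run of k frames lasts `k * frameInterval` (or `(k-1) * frameInterval`
#' under `"k_minus_1"`). The value carries attribute `censored = TRUE` when
#' the run touches the movie's final frame, i.e. detachment was not observed.
#'
#' @param trace an [EventTrace-class] with `endFrames > 0`.
#' @param extent the [MicrotubuleExtent-class] used for classification.
#' @param frameInterval seconds per frame.
#' @param config an [analysisConfig()] list.
#' @param nFrames total movie frames (for censoring); default: unknown, no
#'   censor flag.
#' @return end residence (s), with attributes `censored` and `side`.
#' @export
measureEndResidence <- function(trace, extent, frameInterval,
                                config = analysisConfig(), nFrames = NA) {
  if (trace@eventClass == "discarded-crossing")
    stop("measureEndResidence: discarded crossing event (contract violation)")
  occ <- endOccupancy(trace@pixels, trace@peakCols, trace@frames, extent,
                      config)
  if (occ$frames == 0L)
    stop("measureEndResidence: trace never occupies an end column ",
         "(contract violation)")
  k <- occ$frames
  val <- if (config$durationConvention == "k") k * frameInterval
         else (k - 1L) * frameInterval
  cens <- !is.na(nFrames) && occ$last == nFrames
  structure(val, censored = cens, side = occ$side)
}

#' Measure translocation velocity
#'
#' Ordinary least-squares slope of the per-frame centroid position (nm)
#' against time (s), excluding frames spent at an end column; the sign is
#' discarded (speed). A trace with fewer than 2 usable frames is a contract
#' violation.
#'
#' @param trace a `"translocating"` [EventTrace-class].
#' @param extent the [MicrotubuleExtent-class].
#' @param pixelSize nm per pixel.
#' @param frameInterval seconds per frame.
#' @param config an [analysisConfig()] list.
#' @return speed in nm/s.
#' @export
measureVelocity <- function(trace, extent, pixelSize, frameInterval,
                            config = analysisConfig()) {
  use <- !atAnyEnd(trace, extent, config)
  if (sum(use) < 2L)
    stop("measureVelocity: fewer than 2 usable frames (contract violation)")
  x <- trace@frames[use] * frameInterval
  y <- trace@centroidCols[use] * pixelSize
  abs(unname(stats::coef(stats::lm(y ~ x))[2L]))
}

atAnyEnd <- function(trace, extent, config) {
  w <- config$endWindow
  abs(trace@peakCols - extent@leftEnd) <= w |
    abs(trace@peakCols - extent@rightEnd) <= w
}

#' Measure run length
#'
#' Net centroid displacement between the first and last frame of the trace,
#' `|c_last - c_first| * pixelSize`, in um. The value carries attribute
#' `censored = TRUE` when the run terminates at an end column or at the movie
#' boundary (full run not observed).
#'
#' @param trace a `"translocating"` [EventTrace-class].
#' @param extent the [MicrotubuleExtent-class].
#' @param pixelSize nm per pixel.
#' @param nFrames total movie frames.
#' @param config an [analysisConfig()] list.
#' @return run length (um) with attribute `censored`.
#' @export
measureRunLength <- function(trace, extent, pixelSize, nFrames = NA,
                             config = analysisConfig()) {
  if (length(trace@frames) < 2L)
    stop("measureRunLength: fewer than 2 frames (contract violation)")
  n <- length(trace@centroidCols)
  val <- abs(trace@centroidCols[n] - trace@centroidCols[1L]) * pixelSize / 1000
  atEnd <- atAnyEnd(trace, extent, config)
  cens <- atEnd[n] ||
    (!is.na(nFrames) && max(trace@frames) == nFrames) ||
    min(trace@frames) == 1L
  structure(val, censored = cens)
}

#' Analyse one kymograph end to end
#'
#' Composes the measurement chain: locate the microtubule, threshold the GFP
#' channel, segment discrete events, classify each, and measure end
#' residence, velocity and run length. Discarded crossing events are retained
#' in the output with empty measurements. The analysis is deterministic.
#'
#' @param kymo a [Kymograph-class].
#' @param config an [analysisConfig()] list.
#' @return list of completed [EventTrace-class] objects (possibly empty).
#' @export
analyseKymograph <- function(kymo, config = analysisConfig()) {
  extent <- locateMicrotubule(kymo, config$kThreshold)
  mask <- detectEventPixels(kymo, extent, config$kThreshold)
  comps <- segmentEvents(mask)
  nF <- nrow(kymo@gfp)
  lapply(comps, function(px) {
    tr <- classifyEvent(px, extent, kymo, config)
    if (tr@eventClass == "discarded-crossing") return(tr)
    if (tr@endFrames > 0L) {
      er <- measureEndResidence(tr, extent, kymo@frameInterval, config,
                                nFrames = nF)
      tr@endResidence <- as.numeric(er)
      tr@endCensored <- attr(er, "censored")
      tr@endSide <- attr(er, "side")
    }
    if (tr@eventClass == "translocating") {
      tr@velocity <- tryCatch(
        measureVelocity(tr, extent, kymo@pixelSize, kymo@frameInterval,
                        config),
        error = function(e) NA_real_)
      rl <- measureRunLength(tr, extent, kymo@pixelSize, nFrames = nF,
                             config = config)
      tr@runLength <- as.numeric(rl)
      tr@runLengthCensored <- attr(rl, "censored")
    }
    tr
  })
}

#' Tabulate analysed events
#'
#' @param traces list of [EventTrace-class] from [analyseKymograph()].
#' @param mtId microtubule identifier for the `mt_id` column.
#' @return data.frame with columns `mt_id, event_id, class, first_frame,`
#'   `last_frame, end_residence_s, end_side, end_censored, velocity_nm_s,`
#'   `run_length_um, run_censored, censored, discard_reason`.
#' @export
eventsTable <- function(traces, mtId = 1L) {
  if (!length(traces)) {
    return(data.frame(mt_id = integer(), event_id = integer(),
                      class = character(), first_frame = integer(),
                      last_frame = integer(), end_residence_s = numeric(),
                      end_side = character(), end_censored = logical(),
                      velocity_nm_s = numeric(), run_length_um = numeric(),
                      run_censored = logical(), censored = logical(),
                      discard_reason = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(mt_id = mtId, event_id = i, class = tr@eventClass,
               first_frame = min(tr@frames), last_frame = max(tr@frames),
               end_residence_s = tr@endResidence, end_side = tr@endSide,
               end_censored = tr@endCensored, velocity_nm_s = tr@velocity,
               run_length_um = tr@runLength,
               run_censored = tr@runLengthCensored, censored = tr@censored,
               discard_reason = if (tr@eventClass == "discarded-crossing")
                 "crossing" else NA_character_,
               stringsAsFactors = FALSE)
  }))
}

#' Infer which image side is the microtubule plus end
#'
#' Majority vote over the direction of net centroid displacement of
#' translocating events (plus-end-directed motors). `NA` when no
#' translocating event is available.
#'
#' @param traces list of [EventTrace-class].
#' @return `"right"`, `"left"`, or `NA`.
#' @export
inferPlusEnd <- function(traces) {
  d <- vapply(traces, function(tr) {
    if (tr@eventClass != "translocating") return(NA_real_)
    n <- length(tr@centroidCols)
    tr@centroidCols[n] - tr@centroidCols[1L]
  }, numeric(1))
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_character_)
  if (sum(sign(d)) >= 0) "right" else "left"
}
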