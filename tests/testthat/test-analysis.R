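# Measurement chain: thresholding, microtubule location, detection,
# classification and the three measurements.

dt <- 1 / 2.7

test_that("estimateThreshold handles constant, zero and contaminated images", {
  expect_warning(thr <- estimateThreshold(matrix(100, 5, 5)), "zero spread")
  expect_equal(thr, 100)
  expect_warning(thr0 <- estimateThreshold(matrix(0, 4, 4)))
  expect_equal(thr0, 0)
  set.seed(42)
  x <- rnorm(1e4, 100, 10)
  x[sample(1e4, 100)] <- 1000  # 1% bright pixels
  thr <- estimateThreshold(x, k = 3)
  # oracle: direct median/MAD computation on the same array
  expect_equal(thr, median(x) + 3 * mad(x), tolerance = 1e-12)
  expect_gt(thr, 120); expect_lt(thr, 145)
})

test_that("locateMicrotubule finds the longest above-threshold run", {
  rho <- matrix(0, 30, 100); rho[, 10:50] <- 400
  k <- Kymograph(rho, matrix(0, 30, 100))
  ext <- locateMicrotubule(k)
  expect_identical(c(ext@leftEnd, ext@rightEnd), c(10L, 50L))

  rho2 <- matrix(0, 30, 100); rho2[, 5:8] <- 400; rho2[, 20:60] <- 400
  ext2 <- locateMicrotubule(Kymograph(rho2, matrix(0, 30, 100)))
  expect_identical(c(ext2@leftEnd, ext2@rightEnd), c(20L, 60L))

  expect_error(locateMicrotubule(Kymograph(matrix(1, 30, 80) +
                                             matrix(rnorm(2400, 0, 1e-3),
                                                    30),
                                           matrix(0, 30, 80))),
               "no microtubule")
})

test_that("locateMicrotubule recovers simulated microtubule ends within 1 px", {
  m <- MotorParams("WT", 810, 3.06, 0.46, landingRate = 0.01)
  img <- ImagingParams(nFrames = 120)
  ds <- generateDataset(m, img, 4, seed = 31)
  for (j in 1:4) {
    ext <- locateMicrotubule(ds$kymographs[[j]])
    mt <- ds$microtubules[[j]]
    mtPx <- round(mt@length / 0.16)
    expect_lte(abs(ext@leftEnd - mt@startPixel), 1)
    expect_lte(abs(ext@rightEnd - (mt@startPixel + mtPx - 1)), 1)
  }
})

test_that("detectEventPixels restricts to the microtubule and finds spots", {
  # zero-noise single spot: mask true exactly on its above-threshold span
  maskIn <- matrix(FALSE, 20, 60); maskIn[8, 30] <- TRUE
  k <- maskKymograph(maskIn, 10:50)
  ext <- MicrotubuleExtent(10, 50)
  got <- suppressWarnings(detectEventPixels(k, ext))
  expect_identical(which(got), which(maskIn))
  # signal outside the extent only -> all-false mask
  out <- matrix(FALSE, 20, 60); out[5, 55] <- TRUE
  got2 <- suppressWarnings(detectEventPixels(maskKymograph(out, 10:50), ext))
  expect_false(any(got2))
})

test_that("pixel recall is at least 0.9 at signal-to-background 5", {
  m <- MotorParams("WT", 810, 3.06, 0.46, landingRate = 0.008)
  img <- ImagingParams(nFrames = 200, signalAmplitude = 100,
                       backgroundSd = 20)  # amplitude / noise SD = 5
  ds <- generateDataset(m, img, 10, seed = 17)
  hits <- 0L; total <- 0L
  for (j in seq_along(ds$kymographs)) {
    kymo <- ds$kymographs[[j]]
    mt <- ds$microtubules[[j]]
    ext <- locateMicrotubule(kymo)
    mask <- detectEventPixels(kymo, ext, k = 3)
    gt <- ds$groundTruth[ds$groundTruth$mt_id == j, ]
    mids <- (seq_len(img@nFrames) - 0.5) * img@frameInterval
    for (i in seq_len(nrow(gt))) {
      p <- eventPositionAt(gt[i, ], mids)
      rows <- which(!is.na(p))
      cols <- round((mt@startPixel - 0.5) + p[rows] / 0.16)
      ok <- cols >= ext@leftEnd & cols <= ext@rightEnd
      hits <- hits + sum(mask[cbind(rows[ok], cols[ok])])
      total <- total + sum(ok)
    }
  }
  expect_gt(total, 200)
  expect_gte(hits / total, 0.9)
})

test_that("segmentation matches hand-checked discreteness cases", {
  expect_identical(segmentEvents(matrix(FALSE, 4, 4)), list())
  # diagonal contact joins
  m <- matrix(FALSE, 5, 5); m[cbind(c(2, 3), c(2, 3))] <- TRUE
  expect_length(segmentEvents(m), 1L)
  # one all-false row separates
  m2 <- matrix(FALSE, 7, 4); m2[1:2, 2] <- TRUE; m2[5:6, 2] <- TRUE
  expect_length(segmentEvents(m2), 2L)
})

test_that("segmentation equals brute-force flood fill on random masks", {
  for (i in 1:60) {
    mask <- randomMask(sample(2:12, 1), sample(2:12, 1),
                       p = runif(1, 0.1, 0.6), seed = 1000 + i)
    got <- canonicalComponents(segmentEvents(mask))
    want <- canonicalComponents(componentsFromLabels(floodFillLabels(mask)))
    expect_identical(got, want)
  }
})

test_that("classification covers lattice, translocating+end and crossing", {
  ext <- MicrotubuleExtent(5, 20)
  # single pixel away from the ends -> lattice, no end residence
  m1 <- matrix(FALSE, 10, 25); m1[4, 10] <- TRUE
  k1 <- maskKymograph(m1, 5:20)
  tr1 <- classifyEvent(cbind(4L, 10L), ext, k1)
  expect_identical(eventClass(tr1), "lattice")
  expect_identical(tr1@endFrames, 0L)

  # diagonal advancing one column per frame for 6 frames, ending at the
  # right end column -> translocating and end-resident
  m2 <- matrix(FALSE, 12, 25)
  rows <- 3:8; cols <- 15:20
  m2[cbind(rows, cols)] <- TRUE
  k2 <- maskKymograph(m2, 5:20)
  tr2 <- classifyEvent(cbind(rows, cols), ext, k2)
  expect_identical(eventClass(tr2), "translocating")
  expect_identical(tr2@endFrames, 1L)
  expect_identical(tr2@endSide, "right")

  # X of two crossing diagonals -> a row with two disjoint runs -> discarded
  m3 <- matrix(FALSE, 5, 25)
  m3[cbind(1:5, 8:12)] <- TRUE
  m3[cbind(1:5, 12:8)] <- TRUE
  px <- which(m3, arr.ind = TRUE)
  tr3 <- classifyEvent(cbind(px[, 1], px[, 2]), ext,
                       maskKymograph(m3, 5:20))
  expect_identical(eventClass(tr3), "discarded-crossing")
  expect_error(measureEndResidence(tr3, ext, dt), "contract")

  expect_error(classifyEvent(matrix(integer(), 0, 2), ext, k1), "empty")
})

test_that("every component gets exactly one class", {
  classes <- c("translocating", "lattice", "discarded-crossing")
  ext <- MicrotubuleExtent(2, 11)
  for (i in 1:40) {
    mask <- randomMask(8, 12, p = runif(1, 0.1, 0.5), seed = 2000 + i)
    kymo <- maskKymograph(mask, 2:11)
    for (comp in segmentEvents(mask)) {
      tr <- classifyEvent(comp, ext, kymo)
      expect_true(eventClass(tr) %in% classes)
    }
  }
})

test_that("end residence follows the frame-count duration convention", {
  ext <- MicrotubuleExtent(5, 20)
  mk <- function(nframes) {
    m <- matrix(FALSE, 12, 25)
    m[cbind(seq_len(nframes) + 2L, 20L)] <- TRUE
    list(px = cbind(seq_len(nframes) + 2L, 20L),
         kymo = maskKymograph(m, 5:20))
  }
  one <- mk(1)
  tr <- classifyEvent(one$px, ext, one$kymo)
  expect_equal(as.numeric(measureEndResidence(tr, ext, dt)), 1 / 2.7,
               tolerance = 1e-12)
  five <- mk(5)
  tr5 <- classifyEvent(five$px, ext, five$kymo)
  expect_equal(as.numeric(measureEndResidence(tr5, ext, dt)), 5 / 2.7,
               tolerance = 1e-12)
  expect_equal(round(as.numeric(measureEndResidence(tr5, ext, dt)), 3),
               1.852)
  # k_minus_1 convention drops one frame interval
  cfg <- analysisConfig(durationConvention = "k_minus_1")
  expect_equal(as.numeric(measureEndResidence(tr5, ext, dt, cfg)), 4 / 2.7,
               tolerance = 1e-12)
})

test_that("velocity and run length follow the centroid definitions", {
  ext <- MicrotubuleExtent(2, 40)
  # advancing exactly 2 px/frame: 2 * 160 * 2.7 = 864 nm/s
  rows <- 1:6; cols <- seq(10, 20, by = 2)
  m <- matrix(FALSE, 8, 45); m[cbind(rows, cols)] <- TRUE
  tr <- classifyEvent(cbind(rows, cols), ext, maskKymograph(m, 2:40))
  expect_equal(measureVelocity(tr, ext, 160, dt), 864, tolerance = 1e-9)
  # 10-pixel net displacement at 160 nm/px -> 1.6 um
  expect_equal(as.numeric(measureRunLength(tr, ext, 160)), 1.6,
               tolerance = 1e-9)
  # stationary trace passed in error -> velocity 0, run length 0
  rows2 <- 2:7
  m2 <- matrix(FALSE, 10, 45); m2[cbind(rows2, 15L)] <- TRUE
  tr2 <- classifyEvent(cbind(rows2, rep(15L, 6)), ext,
                       maskKymograph(m2, 2:40))
  expect_equal(measureVelocity(tr2, ext, 160, dt), 0, tolerance = 1e-9)
  expect_equal(as.numeric(measureRunLength(tr2, ext, 160)), 0)
  expect_error(measureVelocity(classifyEvent(cbind(1L, 10L), ext,
                                             maskKymograph(m2, 2:40)),
                               ext, 160, dt), "contract")
})

test_that("measurements are invariant under horizontal mirroring", {
  m <- MotorParams("WT", 810, 3.06, 0.46, landingRate = 0.01)
  img <- ImagingParams(nFrames = 150)
  ds <- generateDataset(m, img, 2, seed = 51)
  cfg <- analysisConfig(kThreshold = 4.5)
  for (kymo in ds$kymographs) {
    tab <- eventsTable(analyseKymograph(kymo, cfg))
    flipped <- Kymograph(rhodamineChannel(kymo)[, ncol(gfpChannel(kymo)):1],
                         gfpChannel(kymo)[, ncol(gfpChannel(kymo)):1],
                         frameInterval(kymo), pixelSize(kymo))
    tabF <- eventsTable(analyseKymograph(flipped, cfg))
    expect_equal(sort(tab$end_residence_s), sort(tabF$end_residence_s))
    expect_equal(sort(round(tab$velocity_nm_s, 6)),
                 sort(round(tabF$velocity_nm_s, 6)))
    expect_equal(sort(round(tab$run_length_um, 6)),
                 sort(round(tabF$run_length_um, 6)))
  }
})

test_that("analyseKymograph is deterministic and empty on blank GFP", {
  rho <- matrix(0, 40, 60); rho[, 10:30] <- 400
  blank <- Kymograph(rho, matrix(0, 40, 60))
  expect_length(suppressWarnings(analyseKymograph(blank)), 0L)
  m <- MotorParams("WT", 810, 3.06, 0.46, landingRate = 0.02)
  ds <- generateDataset(m, ImagingParams(nFrames = 100), 1, seed = 8)
  t1 <- eventsTable(analyseKymograph(ds$kymographs[[1]]))
  t2 <- eventsTable(analyseKymograph(ds$kymographs[[1]]))
  expect_identical(t1, t2)
})

test_that("ground-truth events are recovered one-to-one at sparse density", {
  m <- MotorParams("WT", 810, 3.06, 0.46, landingRate = 0.008)
  img <- ImagingParams(nFrames = 250)
  ds <- generateDataset(m, img, 12, seed = 71)
  cfg <- analysisConfig(kThreshold = 4.5)
  matched <- 0L; totalGt <- 0L
  for (j in seq_along(ds$kymographs)) {
    kymo <- ds$kymographs[[j]]
    mt <- ds$microtubules[[j]]
    traces <- analyseKymograph(kymo, cfg)
    gt <- ds$groundTruth[ds$groundTruth$mt_id == j, ]
    mids <- (seq_len(img@nFrames) - 0.5) * img@frameInterval
    for (i in seq_len(nrow(gt))) {
      p <- eventPositionAt(gt[i, ], mids)
      rows <- which(!is.na(p))
      if (length(rows) < 1) next
      totalGt <- totalGt + 1L
      cols <- (mt@startPixel - 0.5) + p[rows] / 0.16
      nOverlap <- sum(vapply(traces, function(tr) {
        shared <- intersect(tr@frames, rows)
        if (length(shared) < 0.5 * length(rows)) return(FALSE)
        all(abs(tr@peakCols[match(shared, tr@frames)] -
                  cols[match(shared, rows)]) <= 2)
      }, logical(1)))
      if (nOverlap == 1L) matched <- matched + 1L
    }
  }
  expect_gt(totalGt, 50)
  expect_gte(matched / totalGt, 0.8)
})

test_that("recovered end dwells increase with the generative dwell", {
  img <- ImagingParams(nFrames = 300)
  rec <- vapply(c(0.5, 1, 2), function(dwell) {
    m <- MotorParams("g", 810, 3.06, dwell, landingRate = 0.008)
    ds <- generateDataset(m, img, 25, seed = 300 + round(10 * dwell))
    durs <- plusEndDurations(analyseDataset(ds))
    dwellMLE(durs, img@frameInterval)
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
  # measured durations are nonnegative multiples of the frame interval
  m <- MotorParams("q", 810, 3.06, 1, landingRate = 0.01)
  ds <- generateDataset(m, img, 3, seed = 99)
  durs <- plusEndDurations(analyseDataset(ds))
  expect_true(all(durs > 0))
  expect_true(all(abs(durs / img@frameInterval -
                        round(durs / img@frameInterval)) < 1e-9))
})
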