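# Orchestration: variant panel, configuration, and the simulate -> analyse ->
# summarise -> compare pipeline with a machine-readable report.

#' Default kinesin variant panel
#'
#' Generative parameters for wild-type Kinesin-1 (rkin430), the alpha4-helix
#' point mutants G262K, N263E, S266R, the triple mutant, the control S266A,
#' and the Kinesin-13 MCAK. Velocities (nm/s), run lengths (um) and end
#' dwells (s) are the compiled single-molecule values for each variant; MCAK
#' does not translocate and is modelled as a static binder
#' (`fractionStatic = 1`) that recognises the microtubule end, with a finite
#' lattice dwell (its depolymerase activity is not modelled).
#'
#' @param landingRate landing rate (events/um/s) applied to every variant;
#'   sparse by default so single events rarely overlap.
#' @return named list of [MotorParams-class].
#' @export
motorPanel <- function(landingRate = 0.02) {
  mk <- function(name, v, rl, ed, ld = NA_real_, fs = 0)
    MotorParams(name, velocity = v, meanRunLength = rl, meanEndDwell = ed,
                meanLatticeDwell = ld, landingRate = landingRate,
                fractionStatic = fs)
  list(
    WT     = mk("WT",     810, 3.06, 0.46),
    G262K  = mk("G262K",  522, 1.29, 0.78),
    N263E  = mk("N263E",  686, 1.05, 0.95),
    S266R  = mk("S266R",  676, 1.54, 1.41),
    Triple = mk("Triple", 646, 0.92, 1.09),
    S266A  = mk("S266A",  548, 1.48, 0.92),
    MCAK   = mk("MCAK",     0, NA_real_, 2.03, ld = 0.8, fs = 1)
  )
}

#' Pipeline configuration
#'
#' @param variants named list of [MotorParams-class] (unique names).
#' @param imaging an [ImagingParams-class].
#' @param nMicrotubules microtubules simulated per variant.
#' @param mtLengthRange microtubule length range (um).
#' @param analysis an [analysisConfig()] list.
#' @param reference reference variant for pairwise comparisons.
#' @param nBoot,bootSeed bootstrap settings for fold-change intervals.
#' @param seed master seed; per-variant seeds are derived from it.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(variants = motorPanel(), imaging = ImagingParams(),
                           nMicrotubules = 4L, mtLengthRange = c(6, 10),
                           analysis = analysisConfig(kThreshold = 4.5),
                           reference = "WT",
                           nBoot = 1e4, bootSeed = 12345, seed = 1L) {
  nms <- names(variants)
  if (is.null(nms) || anyDuplicated(nms))
    stop("variant names must be present and unique")
  if (!reference %in% nms)
    stop("reference variant '", reference, "' is not in the panel")
  structure(list(variants = variants, imaging = imaging,
                 nMicrotubules = as.integer(nMicrotubules),
                 mtLengthRange = mtLengthRange, analysis = analysis,
                 reference = reference, nBoot = nBoot, bootSeed = bootSeed,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised blocks: `motor` (single variant) or `variants` (named list of
#' motor blocks), `imaging`, `dataset` (`n_microtubules`, `mt_length_range`),
#' `analysis` (`k_threshold`, `duration_convention`, `end_window`,
#' `end_attribution`, `min_transloc_frames`), `stats` (`reference`, `n_boot`,
#' `boot_seed`) and `seed`. Every motor/imaging field is addressable by its
#' snake_case name (e.g. `mean_end_dwell`, `frame_interval`).
#'
#' @param path YAML file path.
#' @return a `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  grab <- function(block, key, default) {
    if (!is.null(block[[key]])) block[[key]] else default
  }
  motorFromYaml <- function(m, name) {
    MotorParams(grab(m, "name", name),
                velocity = grab(m, "velocity", 0),
                meanRunLength = grab(m, "mean_run_length", NA_real_),
                meanEndDwell = grab(m, "mean_end_dwell", NA_real_),
                meanLatticeDwell = grab(m, "mean_lattice_dwell", NA_real_),
                landingRate = grab(m, "landing_rate", 0.02),
                fractionStatic = grab(m, "fraction_static", 0))
  }
  variants <- if (!is.null(y$variants)) {
    stats::setNames(
      lapply(names(y$variants),
             function(nm) motorFromYaml(y$variants[[nm]], nm)),
      names(y$variants))
  } else if (!is.null(y$motor)) {
    v <- motorFromYaml(y$motor, grab(y$motor, "name", "motor"))
    stats::setNames(list(v), v@name)
  } else motorPanel()
  im <- y$imaging
  imaging <- ImagingParams(
    frameInterval = grab(im, "frame_interval", 1 / 2.7),
    pixelSize = grab(im, "pixel_size", 160),
    nFrames = grab(im, "n_frames", 300L),
    nPixels = grab(im, "n_pixels", NA_integer_),
    psfSigma = grab(im, "psf_sigma", 1.1),
    signalAmplitude = grab(im, "signal_amplitude", 400),
    backgroundMean = grab(im, "background_mean", 100),
    backgroundSd = grab(im, "background_sd", 20),
    seed = grab(im, "seed", 1L))
  an <- y$analysis
  analysis <- analysisConfig(
    kThreshold = grab(an, "k_threshold", 3),
    durationConvention = grab(an, "duration_convention", "k"),
    endWindow = grab(an, "end_window", 0L),
    endAttribution = grab(an, "end_attribution", "peak"),
    minTranslocFrames = grab(an, "min_transloc_frames", 3L))
  ds <- y$dataset
  st <- y$stats
  pipelineConfig(variants = variants, imaging = imaging,
                 nMicrotubules = grab(ds, "n_microtubules", 4L),
                 mtLengthRange = unlist(grab(ds, "mt_length_range",
                                             c(6, 10))),
                 analysis = analysis,
                 reference = grab(st, "reference",
                                  names(variants)[1L]),
                 nBoot = grab(st, "n_boot", 1e4),
                 bootSeed = grab(st, "boot_seed", 12345),
                 seed = grab(y, "seed", 1L))
}

# Summaries of one variant's analysed events; plus-end residence only when
# polarity is inferable, both ends otherwise.
variantSummary <- function(name, eventsDf, frameInterval) {
  res <- eventsDf[!is.na(eventsDf$end_residence_s) &
                    !eventsDf$end_censored & !eventsDf$censored &
                    (is.na(eventsDf$plus_end) |
                       eventsDf$end_side == eventsDf$plus_end), ,
                  drop = FALSE]
  tra <- eventsDf[eventsDf$class == "translocating" & !eventsDf$censored, ,
                  drop = FALSE]
  run <- tra[!tra$run_censored, , drop = FALSE]
  summ <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(list(n = 0L, mean = NA, sem = NA))
    list(n = length(x), mean = mean(x),
         sem = stats::sd(x) / sqrt(length(x)))
  }
  endDur <- res$end_residence_s
  list(name = name,
       n_events = nrow(eventsDf),
       n_discarded_crossing = sum(eventsDf$class == "discarded-crossing"),
       end_residence = c(summ(endDur),
                         list(dwell_mle = if (length(endDur))
                           dwellMLE(endDur, frameInterval) else NA)),
       velocity = summ(tra$velocity_nm_s),
       run_length = summ(run$run_length_um),
       end_durations = endDur)
}

#' Run the full simulate-analyse-summarise pipeline over a variant panel
#'
#' For every variant: simulate a dataset of kymographs, analyse each
#' kymograph, pool the events, and summarise end residence (raw mean and the
#' dwell MLE of [dwellMLE()]), velocity and run length. End-residence
#' distributions of every non-reference variant are then compared with the
#' reference by two-sample KS, and fold changes of mean end residence (with
#' bootstrap intervals) are reported. Fully reproducible under a fixed
#' master seed.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir optional directory; when given, writes `report.json`,
#'   `events.csv`, `summary.csv` and `ks.csv` (plus per-variant TIFF
#'   datasets when `writeTiffs = TRUE`).
#' @param writeTiffs write the simulated TIFF kymographs and ground truth.
#' @param verbose log stage timings and event counts via `message()`.
#' @return invisibly, the report: a list with `seed`, `reference`,
#'   `variants` (per-variant summaries) and `comparisons`.
#' @export
runPipeline <- function(config, outDir = NULL, writeTiffs = FALSE,
                        verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  set.seed(config$seed)
  vseeds <- sample.int(.Machine$integer.max - 1L, length(config$variants))
  say <- function(...) if (verbose) message(sprintf(...))
  allEvents <- list()
  summaries <- list()
  for (i in seq_along(config$variants)) {
    motor <- config$variants[[i]]
    nm <- names(config$variants)[i]
    t0 <- proc.time()[["elapsed"]]
    dd <- if (writeTiffs && !is.null(outDir))
      file.path(outDir, paste0("dataset_", nm)) else NULL
    ds <- generateDataset(motor, config$imaging, config$nMicrotubules,
                          seed = vseeds[i], outDir = dd,
                          mtLengthRange = config$mtLengthRange)
    evs <- lapply(seq_along(ds$kymographs), function(j) {
      traces <- analyseKymograph(ds$kymographs[[j]], config$analysis)
      df <- eventsTable(traces, mtId = j)
      df$plus_end <- rep(inferPlusEnd(traces), length.out = nrow(df))
      df
    })
    ev <- do.call(rbind, evs)
    ev <- cbind(variant = nm, ev)
    allEvents[[nm]] <- ev
    summaries[[nm]] <- variantSummary(nm, ev,
                                      config$imaging@frameInterval)
    say("[%s] %d microtubules, %d events (%.1f s)", nm,
        config$nMicrotubules, nrow(ev), proc.time()[["elapsed"]] - t0)
  }
  ref <- config$reference
  refDur <- summaries[[ref]]$end_durations
  comparisons <- list()
  for (nm in setdiff(names(config$variants), ref)) {
    dur <- summaries[[nm]]$end_durations
    if (!length(dur) || !length(refDur)) {
      comparisons[[nm]] <- list(variant = nm, reference = ref,
                                note = "insufficient end events")
      next
    }
    ks <- ksTwoSample(dur, refDur)
    fc <- foldChange(dur, refDur, nBoot = config$nBoot,
                     seed = config$bootSeed)
    comparisons[[nm]] <- list(
      variant = nm, reference = ref, ks_D = ks@D, ks_p = ks@pValue,
      n1 = ks@n1, n2 = ks@n2, fold_change = fc$ratio,
      fold_change_ci = fc$ci)
  }
  report <- list(
    seed = config$seed, reference = ref,
    variants = lapply(summaries, function(s)
      s[setdiff(names(s), "end_durations")]),
    comparisons = comparisons)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ev <- do.call(rbind, allEvents)
    utils::write.csv(ev, file.path(outDir, "events.csv"),
                     row.names = FALSE)
    summDf <- do.call(rbind, lapply(summaries, function(s)
      data.frame(variant = s$name, n = s$end_residence$n,
                 mean_s = s$end_residence$mean,
                 sem_s = s$end_residence$sem,
                 dwell_mle_s = s$end_residence$dwell_mle,
                 velocity_nm_s = s$velocity$mean,
                 run_length_um = s$run_length$mean)))
    utils::write.csv(summDf, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    ksDf <- do.call(rbind, lapply(comparisons, function(cp)
      if (is.null(cp$note))
        data.frame(variant = cp$variant, reference = cp$reference,
                   D = cp$ks_D, p = cp$ks_p, n1 = cp$n1, n2 = cp$n2,
                   fold_change = cp$fold_change) else NULL))
    if (!is.null(ksDf))
      utils::write.csv(ksDf, file.path(outDir, "ks.csv"),
                       row.names = FALSE)
  }
  attr(report, "events") <- allEvents
  invisible(report)
}

#' Validate a pipeline report against the shipped schema
#'
#' Structural validation (required fields and their types) against the JSON
#' schema in `inst/schema/report.schema.json`.
#'
#' @param report a report list from [runPipeline()] or parsed from
#'   `report.json`.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validateReport <- function(report) {
  need <- function(ok, what)
    if (!isTRUE(ok)) stop("invalid report: ", what)
  need(is.list(report), "not a list")
  need(all(c("seed", "reference", "variants", "comparisons") %in%
             names(report)),
       "missing top-level field(s)")
  need(is.numeric(report$seed), "seed must be numeric")
  need(is.character(report$reference), "reference must be a string")
  for (v in report$variants) {
    need(all(c("name", "n_events", "end_residence", "velocity",
               "run_length") %in% names(v)),
         paste0("variant block incomplete: ", v$name))
    need(all(c("n", "mean", "sem") %in% names(v$end_residence)),
         paste0("end_residence block incomplete: ", v$name))
  }
  for (cp in report$comparisons) {
    need(all(c("variant", "reference") %in% names(cp)),
         "comparison block incomplete")
    if (is.null(cp$note))
      need(all(c("ks_D", "ks_p", "fold_change") %in% names(cp)),
           paste0("comparison metrics missing: ", cp$variant))
  }
  invisible(TRUE)
}

#' Path to the shipped report JSON schema
#'
#' @return file path of `report.schema.json`.
#' @export
reportSchemaPath <- function() {
  system.file("schema", "report.schema.json", package = "KymoDwell",
              mustWork = TRUE)
}
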