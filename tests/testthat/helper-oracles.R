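# Independent oracles and small builders shared across tests.

# Brute-force 8-connected labelling by queue-based flood fill; the oracle the
# vectorised segmentation is checked against.
floodFillLabels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    if (!mask[r, cl] || lab[r, cl] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r, cl))
    lab[r, cl] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1L] + dr; cc <- p[2L] + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Canonical form of a segmentation: sorted pixel lists, sorted between events.
canonicalComponents <- function(comps) {
  keys <- lapply(comps, function(m) {
    m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    paste(m[, 1L], m[, 2L], sep = ",", collapse = ";")
  })
  unname(sort(unlist(keys)))
}

componentsFromLabels <- function(lab) {
  ids <- setdiff(unique(as.vector(lab)), 0L)
  lapply(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    cbind(frame = w[, 1L], col = w[, 2L])
  })
}

# Noise-free kymograph holding a hand-drawn GFP mask on a uniform
# microtubule spanning mtCols; intensity `amp` on mask pixels.
maskKymograph <- function(maskGfp, mtCols, amp = 400,
                          frameInterval = 1 / 2.7, pixelSize = 160) {
  rho <- matrix(0, nrow(maskGfp), ncol(maskGfp))
  rho[, mtCols] <- amp
  gfp <- maskGfp * amp
  Kymograph(rhodamine = rho, gfp = gfp, frameInterval = frameInterval,
            pixelSize = pixelSize)
}

# Random small mask with given fill probability.
randomMask <- function(nr, nc, p, seed) {
  set.seed(seed)
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# Full measurement chain over a simulated dataset of one motor; returns the
# pooled events table with the per-kymograph inferred plus end attached.
analyseDataset <- function(ds, config = analysisConfig(kThreshold = 4.5)) {
  do.call(rbind, lapply(seq_along(ds$kymographs), function(j) {
    traces <- analyseKymograph(ds$kymographs[[j]], config)
    tab <- eventsTable(traces, mtId = j)
    tab$plus_end <- rep(inferPlusEnd(traces), length.out = nrow(tab))
    tab
  }))
}

# Uncensored plus-end residence durations from a pooled events table.
plusEndDurations <- function(tab) {
  keep <- !is.na(tab$end_residence_s) & !tab$end_censored & !tab$censored &
    (is.na(tab$plus_end) | tab$end_side == tab$plus_end)
  tab$end_residence_s[keep]
}
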