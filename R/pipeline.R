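# Orchestration: configuration, session file I/O (CSV + JSON sidecars),
# per-subject analysis bundles and the two-group comparison report.

#' Analysis configuration
#'
#' All tunable parameters of the pipeline with their default values:
#' 20-500 Hz order-5 band-pass, 6 Hz envelope smoothing, 10 Hz joint
#' angle smoothing, 5 ms minimum burst / 125 ms merge gap, k = 3
#' amplitude clusters, 20 analyzed cycles, alpha 0.05.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `gaitAnalysisConfig`.
#' @export
analysisConfig <- function(...) {
  cfg <- list(
    bandpassLow = 20, bandpassHigh = 500, bandpassOrder = 5,
    envelopeCutoff = 6, envelopeOrder = 4,
    angleCutoff = 10, angleOrder = 4,
    nNodes = 101, nCycles = 20,
    normalizationMode = "max",
    burstMinDuration = 0.005, burstMergeGap = 0.125, kClusters = 3,
    burstInput = "rectified",  # or "envelope"
    secondBurstWindow = c(45, 75), secondBurstMuscles = "RF",
    eventMinPeakHeight = 50, eventMinSeparation = 0.5,
    calWindowS = 10, calMotionThreshold = 5,
    alpha = 0.05, tails = 2,
    cvEstimator = "sample",
    distanceM = 30,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "gaitAnalysisConfig")
}

#' Read / write an analysis configuration
#'
#' Plain-text key-value (YAML) serialization; a round-trip reproduces
#' the configuration exactly.
#'
#' @param path file path.
#' @param config a [analysisConfig()] object.
#' @return `readAnalysisConfig` returns the configuration.
#' @export
writeAnalysisConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeAnalysisConfig
#' @export
readAnalysisConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysisConfig, vals)
}

#' Write an EMG session to CSV with a JSON sidecar
#'
#' CSV columns: `time_s`, one column per muscle label, and `footswitch`
#' when present. The sidecar stores the sampling rate and labels.
#'
#' @param session an [EmgSession-class].
#' @param csvPath,jsonPath output paths.
#' @return invisibly, the CSV path.
#' @export
writeEmgSessionCsv <- function(session, csvPath,
                               jsonPath = sub("\\.csv$", ".json", csvPath)) {
  ch <- channels(session)
  df <- data.frame(time_s = (seq_len(ncol(ch)) - 1) / samplingRate(session))
  for (i in seq_len(nrow(ch))) df[[muscleLabels(session)[i]]] <- ch[i, ]
  if (length(footswitch(session))) df$footswitch <- footswitch(session)
  utils::write.csv(df, csvPath, row.names = FALSE)
  jsonlite::write_json(list(fs = samplingRate(session),
                            muscle_labels = muscleLabels(session),
                            has_footswitch = length(footswitch(session)) > 0),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' Read an EMG session written by [writeEmgSessionCsv()]
#'
#' @param csvPath,jsonPath input paths.
#' @return an [EmgSession-class].
#' @export
readEmgSessionCsv <- function(csvPath,
                              jsonPath = sub("\\.csv$", ".json", csvPath)) {
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  df <- utils::read.csv(csvPath, check.names = FALSE)
  missing <- setdiff(meta$muscle_labels, names(df))
  if (length(missing)) {
    stop("missing muscle channels in CSV: ", paste(missing, collapse = ", "))
  }
  ch <- t(as.matrix(df[meta$muscle_labels]))
  fsw <- if (isTRUE(meta$has_footswitch)) df$footswitch else numeric()
  EmgSession(ch, meta$fs, meta$muscle_labels, fsw)
}

#' Write quaternion streams to CSV with a JSON sidecar
#'
#' CSV columns: `time_s`, then `<site>_w, <site>_x, <site>_y, <site>_z`
#' for each sensor site.
#'
#' @param streams named list of [QuaternionStream-class] objects with a
#'   common sampling rate and length.
#' @param csvPath,jsonPath output paths.
#' @return invisibly, the CSV path.
#' @export
writeQuaternionCsv <- function(streams, csvPath,
                               jsonPath = sub("\\.csv$", ".json", csvPath)) {
  fs <- samplingRate(streams[[1L]])
  n <- nrow(quaternions(streams[[1L]]))
  df <- data.frame(time_s = (seq_len(n) - 1) / fs)
  for (site in names(streams)) {
    q <- quaternions(streams[[site]])
    for (j in seq_len(4L)) {
      df[[paste0(site, "_", c("w", "x", "y", "z")[j])]] <- q[, j]
    }
  }
  utils::write.csv(df, csvPath, row.names = FALSE)
  jsonlite::write_json(list(fs = fs, sites = names(streams)),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' Read quaternion streams written by [writeQuaternionCsv()]
#'
#' @param csvPath,jsonPath input paths.
#' @return named list of [QuaternionStream-class] objects.
#' @export
readQuaternionCsv <- function(csvPath,
                              jsonPath = sub("\\.csv$", ".json", csvPath)) {
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  df <- utils::read.csv(csvPath, check.names = FALSE)
  out <- list()
  for (site in meta$sites) {
    cols <- paste0(site, "_", c("w", "x", "y", "z"))
    if (!all(cols %in% names(df))) stop("missing quaternion columns for ", site)
    q <- as.matrix(df[cols])
    q <- q / sqrt(rowSums(q^2))
    out[[site]] <- QuaternionStream(q, meta$fs, site)
  }
  out
}

#' Write a synthetic session to disk
#'
#' EMG CSV + sidecar, quaternion CSV + sidecar, and the generator ground
#' truth as `truth.json`.
#'
#' @param session a `GaitSession` from [simulateSession()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeEmgSessionCsv(session$emg, file.path(dir, "emg.csv"))
  writeQuaternionCsv(session$imu, file.path(dir, "quaternions.csv"))
  tr <- session$truth
  tr$plan <- unclass(tr$plan)
  tr$bursts <- lapply(tr$bursts, function(b) as.list(b))
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Session manifest
#'
#' @param subjectId subject identifier.
#' @param group `"control"` or `"patient"`.
#' @param condition `"preferred"` or `"slow"` walking velocity.
#' @param emgCsv,quatCsv file paths (JSON sidecars are looked up next to
#'   them).
#' @param distanceM walked distance in meters.
#' @return list of class `SessionManifest`.
#' @export
sessionManifest <- function(subjectId, group = c("control", "patient"),
                            condition = c("preferred", "slow"),
                            emgCsv, quatCsv, distanceM = 30) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  for (p in c(emgCsv, quatCsv)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  structure(list(subjectId = subjectId, group = group,
                 condition = condition, emgCsv = emgCsv, quatCsv = quatCsv,
                 distanceM = distanceM), class = "SessionManifest")
}

# Analyze the EMG side of a session: per-muscle mean normalized
# envelope cycles, per-cycle normalized envelope cycles, burst timing.
analyzeEmg <- function(emg, config) {
  fs <- samplingRate(emg)
  hs <- footswitchHeelStrikes(footswitch(emg))
  if (length(hs) < 2L) stop("footswitch contains fewer than 2 heel strikes")
  nAvail <- length(hs) - 1L
  nUse <- min(nAvail, config$nCycles)
  if (nAvail < config$nCycles) {
    warning("only ", nAvail, " cycles available; config requests ",
            config$nCycles)
  }
  hsUse <- hs[seq_len(nUse + 1L)]
  labs <- muscleLabels(emg)
  meanEnv <- matrix(NA_real_, length(labs), config$nNodes,
                    dimnames = list(labs, NULL))
  cyclesNorm <- list()
  timings <- list()
  for (i in seq_along(labs)) {
    raw <- channels(emg)[i, ]
    bp <- bandpassEmg(raw, fs, config$bandpassLow, config$bandpassHigh,
                      config$bandpassOrder)
    rect <- rectifyEmg(bp)
    env <- pmax(zeroPhaseButter(rect, fs, config$envelopeCutoff,
                                config$envelopeOrder, "low"), 0)
    cyc <- segmentCycles(env, hsUse)
    norm <- amplitudeNormalize(do.call(rbind, lapply(cyc, timeNormalize,
                                                     nNodes = config$nNodes)),
                               config$normalizationMode)
    cyclesNorm[[labs[i]]] <- norm$cycles
    meanEnv[i, ] <- meanCycle(norm$cycles)
    burstSig <- if (config$burstInput == "envelope") env else rect
    train <- cleanBursts(detectActivity(burstSig, fs, labs[i],
                                        config$kClusters),
                         config$burstMinDuration, config$burstMergeGap)
    win <- if (labs[i] %in% config$secondBurstMuscles) {
      config$secondBurstWindow
    } else NULL
    timings[[labs[i]]] <- cycleTiming(train, hsUse, win)
  }
  # co-contraction per cycle, then averaged (pairs with both muscles
  # recorded)
  pairs <- antagonistPairs()
  pairs <- pairs[pairs$a %in% labs & pairs$b %in% labs, , drop = FALSE]
  cci <- matrix(NA_real_, nrow(pairs), config$nNodes,
                dimnames = list(paste0(pairs$a, "-", pairs$b), NULL))
  for (j in seq_len(nrow(pairs))) {
    ca <- cyclesNorm[[pairs$a[j]]]
    cb <- cyclesNorm[[pairs$b[j]]]
    perCycle <- t(vapply(seq_len(nrow(ca)), function(k)
      cciCurve(ca[k, ], cb[k, ]), numeric(config$nNodes)))
    cci[j, ] <- colMeans(perCycle)
  }
  list(meanEnvelopes = meanEnv, cciCurves = cci, burstTimings = timings,
       nCyclesUsed = nUse, heelStrikes = hsUse)
}

# Analyze the IMU side: joint angle mean cycles, gait events, temporal
# parameters.
analyzeImu <- function(imu, config, distanceM = 30) {
  refs <- lapply(imu, calibrateNeutral, windowS = config$calWindowS,
                 motionThreshold = config$calMotionThreshold)
  rel <- lapply(names(imu), function(s)
    relativeOrientation(imu[[s]], refs[[s]]))
  names(rel) <- names(imu)
  eulZ <- lapply(rel, function(s) quatToEuler(s)[, "z"])
  fs <- samplingRate(imu[[1L]])
  signs <- jointSignConventions()
  tracks <- list(
    hip = jointAngle(eulZ$thigh, eulZ$pelvis, fs, "hip", signs[["hip"]],
                     config$angleCutoff, config$angleOrder),
    knee = jointAngle(eulZ$shank, eulZ$thigh, fs, "knee", signs[["knee"]],
                      config$angleCutoff, config$angleOrder),
    ankle = jointAngle(eulZ$foot, eulZ$shank, fs, "ankle", signs[["ankle"]],
                       config$angleCutoff, config$angleOrder)
  )
  gyroZ <- angularVelocityZ(rel$shank)
  events <- detectGaitEvents(gyroZ, fs, config$eventMinPeakHeight,
                             config$eventMinSeparation)
  hs <- heelStrikes(events)
  nUse <- min(length(hs) - 1L, config$nCycles)
  walkTime <- (hs[length(hs)] - hs[1L]) / fs
  tp <- temporalParams(events, distanceM, walkTime, tracks,
                       config$cvEstimator, nCycles = config$nCycles)
  angleCycles <- t(vapply(tracks, function(tr) {
    cyc <- segmentCycles(jointAngles(tr), hs, inclusive = TRUE)
    cyc <- cyc[seq_len(min(length(cyc), config$nCycles))]
    meanCycle(lapply(cyc, timeNormalize, nNodes = config$nNodes))
  }, numeric(config$nNodes)))
  list(angleCycles = angleCycles, events = events, temporal = tp,
       nCyclesUsed = nUse)
}

#' Analyze one subject's session
#'
#' Runs the full per-subject pipeline: EMG conditioning, envelope
#' extraction, cycle segmentation on the heel footswitch, amplitude
#' normalization over the included cycles, co-contraction curves, burst
#' detection and timing, sensor calibration, joint angles, gait events
#' from the shank angular velocity and temporal-spatial parameters. At
#' most `config$nCycles` cycles (the first available) enter the
#' averages; fewer trigger a warning.
#'
#' @param x a `GaitSession` from [simulateSession()] or a
#'   [sessionManifest()].
#' @param config an [analysisConfig()].
#' @return list of class `SubjectBundle`: `meanEnvelopes` (muscle x
#'   nodes), `cciCurves` (pair x nodes), `burstTimings`, `angleCycles`
#'   (joint x nodes), `temporal`, `slopeRatio`, `nCyclesUsed`.
#' @export
runSubject <- function(x, config = analysisConfig()) {
  if (inherits(x, "SessionManifest")) {
    emg <- readEmgSessionCsv(x$emgCsv)
    imu <- readQuaternionCsv(x$quatCsv)
    distanceM <- x$distanceM
    id <- x$subjectId
  } else if (inherits(x, "GaitSession")) {
    emg <- x$emg
    imu <- x$imu
    distanceM <- config$distanceM
    id <- "synthetic"
  } else stop("x must be a GaitSession or SessionManifest")
  e <- analyzeEmg(emg, config)
  k <- analyzeImu(imu, config, distanceM)
  sr <- tryCatch(
    slopeRatio(e$meanEnvelopes["SOL", ], e$meanEnvelopes["LG", ],
               stanceEnd = k$temporal$stancePct),
    error = function(err) NA_real_)
  structure(list(subjectId = id,
                 meanEnvelopes = e$meanEnvelopes,
                 cciCurves = e$cciCurves,
                 burstTimings = e$burstTimings,
                 angleCycles = k$angleCycles,
                 temporal = k$temporal,
                 slopeRatio = sr,
                 nCyclesUsed = e$nCyclesUsed),
            class = "SubjectBundle")
}

#' Compare two groups of subject bundles
#'
#' SPM t-tests over every muscle envelope, co-contraction pair and joint
#' angle waveform; scalar comparisons (with Cohen's d) of the
#' temporal-spatial parameters, per-joint ROM, the SOL/LG slope ratio
#' and the burst on/offset/duration timings.
#'
#' @param bundlesA,bundlesB lists of `SubjectBundle` objects (>= 2 per
#'   group).
#' @param config an [analysisConfig()].
#' @return list of class `GroupComparison` with elements `spm` (named
#'   list of [SpmResult-class]), `scalars` and `burstTests`
#'   (data.frames).
#' @export
runGroupComparison <- function(bundlesA, bundlesB,
                               config = analysisConfig()) {
  if (length(bundlesA) < 2L || length(bundlesB) < 2L) {
    stop("at least two subject bundles per group are required")
  }
  stack <- function(bundles, field, row) {
    do.call(rbind, lapply(bundles, function(b) b[[field]][row, ]))
  }
  spm <- list()
  for (m in rownames(bundlesA[[1L]]$meanEnvelopes)) {
    spm[[paste0("emg.", m)]] <- spmTtest2(
      stack(bundlesA, "meanEnvelopes", m), stack(bundlesB, "meanEnvelopes", m),
      config$alpha, config$tails)
  }
  for (p in rownames(bundlesA[[1L]]$cciCurves)) {
    spm[[paste0("cci.", p)]] <- spmTtest2(
      stack(bundlesA, "cciCurves", p), stack(bundlesB, "cciCurves", p),
      config$alpha, config$tails)
  }
  for (j in rownames(bundlesA[[1L]]$angleCycles)) {
    spm[[paste0("angle.", j)]] <- spmTtest2(
      stack(bundlesA, "angleCycles", j), stack(bundlesB, "angleCycles", j),
      config$alpha, config$tails)
  }
  scalarOf <- function(bundles, fn) vapply(bundles, fn, numeric(1))
  scalarDefs <- list(
    velocity = function(b) b$temporal$velocity,
    cycleTime = function(b) b$temporal$cycleTime,
    cycleTimeCv = function(b) b$temporal$cycleTimeCv,
    stancePct = function(b) b$temporal$stancePct,
    romHip = function(b) b$temporal$rom[["hip"]],
    romKnee = function(b) b$temporal$rom[["knee"]],
    romAnkle = function(b) b$temporal$rom[["ankle"]],
    slopeRatio = function(b) b$slopeRatio
  )
  scalars <- do.call(rbind, lapply(names(scalarDefs), function(nm) {
    a <- scalarOf(bundlesA, scalarDefs[[nm]])
    b <- scalarOf(bundlesB, scalarDefs[[nm]])
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    cmp <- compareScalar(a, b, "t")
    data.frame(variable = nm, meanA = mean(a), meanB = mean(b),
               statistic = cmp$statistic, p = cmp$p.value,
               d = cohensD(mean(a), stats::sd(a), length(a),
                           mean(b), stats::sd(b), length(b)))
  }))
  burstVar <- function(bundles, muscle, what) {
    vapply(bundles, function(b) b$burstTimings[[muscle]]$summary[[what]],
           numeric(1))
  }
  muscles <- names(bundlesA[[1L]]$burstTimings)
  burstTests <- do.call(rbind, lapply(muscles, function(m) {
    do.call(rbind, lapply(c("onsetPct", "offsetPct", "durationPct"),
      function(w) {
        a <- burstVar(bundlesA, m, w)
        b <- burstVar(bundlesB, m, w)
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2L || length(b) < 2L ||
            stats::sd(a) + stats::sd(b) == 0) return(NULL)
        cmp <- compareScalar(a, b, "t")
        data.frame(muscle = m, variable = w, meanA = mean(a),
                   meanB = mean(b), p = cmp$p.value,
                   d = cohensD(mean(a), stats::sd(a), length(a),
                               mean(b), stats::sd(b), length(b)))
      }))
  }))
  structure(list(spm = spm, scalars = scalars, burstTests = burstTests),
            class = "GroupComparison")
}

#' Write a group-comparison report
#'
#' JSON report (cluster tables per waveform, scalar and burst-timing
#' tests) plus CSV exports of the t-curves.
#'
#' @param report a `GroupComparison` from [runGroupComparison()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spmOut <- lapply(report$spm, function(r) {
    list(tCrit = tCrit(r), fwhm = fieldSmoothness(r),
         clusters = spmClusters(r))
  })
  jsonlite::write_json(list(spm = spmOut,
                            scalars = report$scalars,
                            burstTests = report$burstTests),
                       file.path(dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  tmat <- do.call(rbind, lapply(report$spm, tCurve))
  utils::write.csv(data.frame(comparison = names(report$spm), tmat),
                   file.path(dir, "t_curves.csv"), row.names = FALSE)
  invisible(dir)
}
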