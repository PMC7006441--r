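#' @name accessors
#' @title Accessors for gaitSPM containers
#' @description Slot accessors for the S4 containers. Use these rather
#'   than `@` access.
#' @param object a gaitSPM S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))
#' @rdname accessors
#' @export
setGeneric("muscleLabels", function(object) standardGeneric("muscleLabels"))
#' @rdname accessors
#' @export
setGeneric("footswitch", function(object) standardGeneric("footswitch"))
#' @rdname accessors
#' @export
setGeneric("quaternions", function(object) standardGeneric("quaternions"))
#' @rdname accessors
#' @export
setGeneric("sensorSite", function(object) standardGeneric("sensorSite"))
#' @rdname accessors
#' @export
setGeneric("intervals", function(object) standardGeneric("intervals"))
#' @rdname accessors
#' @export
setGeneric("heelStrikes", function(object) standardGeneric("heelStrikes"))
#' @rdname accessors
#' @export
setGeneric("toeOffs", function(object) standardGeneric("toeOffs"))
#' @rdname accessors
#' @export
setGeneric("jointAngles", function(object) standardGeneric("jointAngles"))
#' @rdname accessors
#' @export
setGeneric("tCurve", function(object) standardGeneric("tCurve"))
#' @rdname accessors
#' @export
setGeneric("tCrit", function(object) standardGeneric("tCrit"))
#' @rdname accessors
#' @export
setGeneric("spmClusters", function(object) standardGeneric("spmClusters"))
#' @rdname accessors
#' @export
setGeneric("fieldSmoothness", function(object) standardGeneric("fieldSmoothness"))

#' @rdname accessors
#' @export
setMethod("samplingRate", "EmgSession", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "QuaternionStream", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "BurstTrain", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "GaitEvents", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "JointAngleTrack", function(object) object@fs)

#' @rdname accessors
#' @export
setMethod("channels", "EmgSession", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("muscleLabels", "EmgSession", function(object) object@muscleLabels)
#' @rdname accessors
#' @export
setMethod("footswitch", "EmgSession", function(object) object@footswitch)
#' @rdname accessors
#' @export
setMethod("quaternions", "QuaternionStream", function(object) object@q)
#' @rdname accessors
#' @export
setMethod("sensorSite", "QuaternionStream", function(object) object@sensorSite)
#' @rdname accessors
#' @export
setMethod("intervals", "BurstTrain", function(object) object@intervals)
#' @rdname accessors
#' @export
setMethod("heelStrikes", "GaitEvents", function(object) object@heelStrikes)
#' @rdname accessors
#' @export
setMethod("toeOffs", "GaitEvents", function(object) object@toeOffs)
#' @rdname accessors
#' @export
setMethod("jointAngles", "JointAngleTrack", function(object) object@angle)
#' @rdname accessors
#' @export
setMethod("tCurve", "SpmResult", function(object) object@tCurve)
#' @rdname accessors
#' @export
setMethod("tCrit", "SpmResult", function(object) object@tCrit)
#' @rdname accessors
#' @export
setMethod("spmClusters", "SpmResult", function(object) object@clusters)
#' @rdname accessors
#' @export
setMethod("fieldSmoothness", "SpmResult", function(object) object@fwhm)

setMethod("show", "EmgSession", function(object) {
  cat(sprintf("EmgSession: %d muscles x %d samples at %g Hz%s\n",
              nrow(object@channels), ncol(object@channels), object@fs,
              if (length(object@footswitch)) " (+ footswitch)" else ""))
  cat("  muscles:", paste(object@muscleLabels, collapse = ", "), "\n")
})

setMethod("show", "QuaternionStream", function(object) {
  cat(sprintf("QuaternionStream [%s]: %d samples at %g Hz\n",
              object@sensorSite, nrow(object@q), object@fs))
})

setMethod("show", "BurstTrain", function(object) {
  cat(sprintf("BurstTrain [%s]: %d burst(s) at %g Hz\n",
              object@muscleLabel, nrow(object@intervals), object@fs))
})

setMethod("show", "GaitEvents", function(object) {
  cat(sprintf("GaitEvents: %d heel strikes, %d toe-offs at %g Hz\n",
              length(object@heelStrikes), length(object@toeOffs), object@fs))
})

setMethod("show", "JointAngleTrack", function(object) {
  cat(sprintf("JointAngleTrack [%s]: %d samples at %g Hz, range %.1f..%.1f deg\n",
              object@joint, length(object@angle), object@fs,
              min(object@angle), max(object@angle)))
})

setMethod("show", "SpmResult", function(object) {
  cat(sprintf("SpmResult: df = %g, FWHM = %.2f nodes, t* = %.3f (alpha = %g)\n",
              object@df, object@fwhm, object@tCrit, object@alpha))
  if (nrow(object@clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(object@clusters))) {
      cl <- object@clusters[i, ]
      cat(sprintf("  cluster %d: %g-%g%% cycle, p = %.4g, mean d = %.2f\n",
                  i, cl$start, cl$end, cl$p, cl$meanD))
    }
  }
})
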