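# Accessor generics. Slots are never reached into from user code.

#' @describeIn OCTVolume-class the raw image array `(depth, width, nBScans)`.
#' @param x an object.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
setMethod("volData", "OCTVolume", function(x) x@data)

#' @describeIn OCTVolume-class axial pixel pitch in micrometres per pixel.
#' @export
setGeneric("pitchUm", function(x) standardGeneric("pitchUm"))
setMethod("pitchUm", "OCTVolume", function(x) x@pitchUm)
setMethod("pitchUm", "ThicknessMap", function(x) x@pitchUm)

#' @describeIn OCTVolume-class number of B-scans in the stack.
#' @export
setGeneric("nBScans", function(x) standardGeneric("nBScans"))
setMethod("nBScans", "OCTVolume", function(x) dim(x@data)[3])
setMethod("nBScans", "PhantomTruth", function(x) dim(x@classMasks)[3])

#' @describeIn PhantomTruth-class integer label stack `(depth, width, nBScans)`.
#' @param x an object.
#' @export
setGeneric("classMasks", function(x) standardGeneric("classMasks"))
setMethod("classMasks", "PhantomTruth", function(x) x@classMasks)

#' @describeIn PhantomTruth-class epidermis boundary rows, a list with
#'   matrices `upper` (first epidermis row) and `lower` (first dermis row).
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))
setMethod("boundaries", "PhantomTruth", function(x)
  list(upper = x@upper, lower = x@lower,
       scabTop = x@scabTop, scabBottom = x@scabBottom))

#' @describeIn ThicknessMap-class thickness in pixels (`NA` = undefined A-line).
#' @export
setGeneric("thicknessPx", function(x) standardGeneric("thicknessPx"))
setMethod("thicknessPx", "ThicknessMap", function(x) x@px)
setMethod("thicknessPx", "PhantomTruth", function(x) x@thicknessPx)

#' @describeIn ThicknessMap-class thickness in micrometres.
#' @export
setGeneric("thicknessUm", function(x) standardGeneric("thicknessUm"))
setMethod("thicknessUm", "ThicknessMap", function(x) x@px * x@pitchUm)

#' @describeIn ProbMaps-class 3-channel object probability array.
#' @param x an object.
#' @export
setGeneric("objectProbs", function(x) standardGeneric("objectProbs"))
setMethod("objectProbs", "ProbMaps", function(x) x@object)

#' @describeIn ProbMaps-class contour probability matrix.
#' @export
setGeneric("contourProbs", function(x) standardGeneric("contourProbs"))
setMethod("contourProbs", "ProbMaps", function(x) x@contour)

#' @describeIn MultitaskUNet-class network configuration list.
#' @param x an object.
#' @export
setGeneric("netConfig", function(x) standardGeneric("netConfig"))
setMethod("netConfig", "MultitaskUNet", function(x) x@config)

#' @describeIn MultitaskUNet-class flat named list of parameter arrays.
#' @export
setGeneric("netParams", function(x) standardGeneric("netParams"))
setMethod("netParams", "MultitaskUNet", function(x) x@params)

#' @describeIn MultitaskUNet-class architecture identifier used to guard
#'   checkpoint loading.
#' @export
setGeneric("archHash", function(x) standardGeneric("archHash"))
setMethod("archHash", "MultitaskUNet", function(x) x@archHash)
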