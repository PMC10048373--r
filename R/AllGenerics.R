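#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname accessors
#' @export
setGeneric("xName", function(x) standardGeneric("xName"))

#' @rdname accessors
#' @export
setGeneric("parRegion", function(x) standardGeneric("parRegion"))

#' @rdname accessors
#' @export
setGeneric("parLength", function(x) standardGeneric("parLength"))

#' @rdname accessors
#' @export
setGeneric("parSegments", function(x) standardGeneric("parSegments"))

#' @rdname accessors
#' @export
setGeneric("sexLabel", function(x) standardGeneric("sexLabel"))

#' @rdname accessors
#' @export
setGeneric("xRatio", function(x) standardGeneric("xRatio"))

#' @rdname accessors
#' @export
setGeneric("trackWindows", function(x) standardGeneric("trackWindows"))

#' @rdname accessors
#' @export
setGeneric("normalizedLevels", function(x) standardGeneric("normalizedLevels"))

#' @rdname accessors
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname accessors
#' @export
setGeneric("correspondenceTable",
           function(x) standardGeneric("correspondenceTable"))

#' Compute the genome-wide coverage level of a windowed track
#'
#' @param x a \code{\link{CoverageWindowTrack}}.
#' @param ... passed to methods.
#' @return numeric(1), the normalization denominator (median of window
#'   medians over the selected chromosomes).
#' @export
setGeneric("genomeLevel", function(x, ...) standardGeneric("genomeLevel"))
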