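#' Accessor generics for size-structure containers
#'
#' Small family of accessor generics used across the package's S4 classes.
#' Methods are documented with their classes.
#'
#' @param x An object.
#' @param ... Further arguments passed to methods.
#' @return The corresponding slot value (see the class documentation).
#' @name accessor-generics
NULL

#' @rdname accessor-generics
#' @export
setGeneric("years", function(x, ...) standardGeneric("years"))

#' @rdname accessor-generics
#' @export
setGeneric("binEdges", function(x, ...) standardGeneric("binEdges"))

#' @rdname accessor-generics
#' @export
setGeneric("counts", function(x, ...) standardGeneric("counts"))

#' @rdname accessor-generics
#' @export
setGeneric("composition", function(x, ...) standardGeneric("composition"))

#' @rdname accessor-generics
#' @export
setGeneric("forcing", function(x, ...) standardGeneric("forcing"))

#' @rdname accessor-generics
#' @export
setGeneric("stockMeta", function(x, ...) standardGeneric("stockMeta"))

#' @rdname accessor-generics
#' @export
setGeneric("stockId", function(x, ...) standardGeneric("stockId"))

#' Convert a length composition to per-year proportions
#'
#' @param x A \linkS4class{LengthComposition} (or an object containing one).
#' @param ... Further arguments passed to methods.
#' @return A \linkS4class{LengthComposition} whose rows each sum to 1.
#' @export
setGeneric("toProportions", function(x, ...) standardGeneric("toProportions"))

#' Partition fractions as reported (clamped at zero)
#'
#' @param x A \linkS4class{PartitionResult}.
#' @param ... Further arguments passed to methods.
#' @return Named numeric vector of fractions with negatives clamped to 0,
#'   rounded to three decimals (report convention); the machine-precision
#'   values stay in the object's slots.
#' @export
setGeneric("reportedFractions", function(x, ...)
  standardGeneric("reportedFractions"))
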