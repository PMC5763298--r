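#' Accessors for gdinet objects
#'
#' `nodes()` returns the node identifiers of a network-like object;
#' `edges()` the edge table of a [GMINetwork-class] or [GDINetwork-class];
#' `period()`, `transientLength()` and `attractorStates()` the components
#' of an [Attractor-class]; `regulators()`, `canalyzingValues()`,
#' `canalyzedValues()` and `defaultOutput()` the components of an
#' [NCFRule-class]; `numerator()` and `denominator()` the exact parts of a
#' [Rational-class] or [InfluenceMatrix-class]; `influenceValues()` the
#' influence matrix as plain doubles; `initialStates()` the 0/1 state
#' matrix of an [InitialStateSet-class]; `provenance()` the reproducibility
#' metadata of influence objects.
#'
#' @param x object to access.
#' @return The corresponding component.
#' @name gdinet-accessors
#' @aliases nodes edges period transientLength attractorStates regulators
#'   canalyzingValues canalyzedValues defaultOutput numerator denominator
#'   influenceValues initialStates provenance
#' @examples
#' net <- gmiNetwork(data.frame(source = "a", target = "b", sign = "+"))
#' nodes(net)
#' edges(net)
NULL

#' @rdname gdinet-accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname gdinet-accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname gdinet-accessors
#' @export
setGeneric("period", function(x) standardGeneric("period"))

#' @rdname gdinet-accessors
#' @export
setGeneric("transientLength", function(x) standardGeneric("transientLength"))

#' @rdname gdinet-accessors
#' @export
setGeneric("attractorStates", function(x) standardGeneric("attractorStates"))

#' @rdname gdinet-accessors
#' @export
setGeneric("regulators", function(x) standardGeneric("regulators"))

#' @rdname gdinet-accessors
#' @export
setGeneric("canalyzingValues", function(x) standardGeneric("canalyzingValues"))

#' @rdname gdinet-accessors
#' @export
setGeneric("canalyzedValues", function(x) standardGeneric("canalyzedValues"))

#' @rdname gdinet-accessors
#' @export
setGeneric("defaultOutput", function(x) standardGeneric("defaultOutput"))

#' @rdname gdinet-accessors
#' @export
setGeneric("numerator", function(x) standardGeneric("numerator"))

#' @rdname gdinet-accessors
#' @export
setGeneric("denominator", function(x) standardGeneric("denominator"))

#' @rdname gdinet-accessors
#' @export
setGeneric("influenceValues", function(x) standardGeneric("influenceValues"))

#' @rdname gdinet-accessors
#' @export
setGeneric("initialStates", function(x) standardGeneric("initialStates"))

#' @rdname gdinet-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
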