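#' @rdname CoexExperiment
#' @param x a `CoexExperiment`.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname CoexExperiment
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname CoexExperiment
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @rdname CoexExperiment
#' @export
setGeneric("swapGroups", function(x) standardGeneric("swapGroups"))

#' @rdname InteractionNetwork-class
#' @param x an `InteractionNetwork`.
#' @export
setGeneric("networkSources", function(x) standardGeneric("networkSources"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkTargets", function(x) standardGeneric("networkTargets"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkPairs", function(x) standardGeneric("networkPairs"))
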