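## Generics for accessors; implementations sit next to their classes
## in AllMethods.R.

#' @name uteDixon-accessors
#' @title Accessors for uteDixon S4 objects
#' @description Slot accessors for the imaging and result classes.  Use
#'   these instead of direct slot access.
#' @param object An S4 object from this package.
#' @return The slot contents (arrays for maps, scalars for metadata).
NULL

#' @rdname uteDixon-accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("acquisition", function(object) standardGeneric("acquisition"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("echoTime", function(object) standardGeneric("echoTime"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("fieldStrength", function(object) standardGeneric("fieldStrength"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("waterMap", function(object) standardGeneric("waterMap"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("fatMap", function(object) standardGeneric("fatMap"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("fatFraction", function(object) standardGeneric("fatFraction"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("smoothPhase", function(object) standardGeneric("smoothPhase"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("correctedPhase", function(object) standardGeneric("correctedPhase"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("costTrace", function(object) standardGeneric("costTrace"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("phaseMask", function(object) standardGeneric("phaseMask"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("weightedImages", function(object) standardGeneric("weightedImages"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("ctLikeImages", function(object) standardGeneric("ctLikeImages"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("tissueLabels", function(object) standardGeneric("tissueLabels"))

#' @rdname uteDixon-accessors
#' @export
setGeneric("labelCodes", function(object) standardGeneric("labelCodes"))
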