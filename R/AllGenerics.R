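#' Accessor generics
#'
#' Accessors for the core S4 containers: the estimated mixing and unmixing
#' matrices and source scores of an ICA decomposition, the subject identifiers
#' of multi-subject containers, and the number of estimated components.
#'
#' @param object an object of one of the package's S4 classes.
#' @return `mixing` and `unmixing` return numeric matrices; `icaSources`
#'   returns the samples-by-components source score matrix; `subjectIds`
#'   returns a character vector; `nComponents` returns an integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mixing", function(object) standardGeneric("mixing"))

#' @rdname accessors
#' @export
setGeneric("unmixing", function(object) standardGeneric("unmixing"))

#' @rdname accessors
#' @export
setGeneric("icaSources", function(object) standardGeneric("icaSources"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
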