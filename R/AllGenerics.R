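#' @name ocsim-accessors
#' @title Accessor generics
#' @description Accessors for the core simulation classes.
#' @param x an ocsim object.
#' @param ... passed on to methods.
#' @return the requested component.
NULL

#' @rdname ocsim-accessors
#' @export
setGeneric("nIndiv", function(x) standardGeneric("nIndiv"))

#' @rdname ocsim-accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname ocsim-accessors
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname ocsim-accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname ocsim-accessors
#' @export
setGeneric("lociChrom", function(x) standardGeneric("lociChrom"))

#' @rdname ocsim-accessors
#' @export
setGeneric("lociPosCm", function(x) standardGeneric("lociPosCm"))

#' @rdname ocsim-accessors
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname ocsim-accessors
#' @export
setGeneric("haplotypes", function(x, ...) standardGeneric("haplotypes"))

#' @rdname ocsim-accessors
#' @export
setGeneric("founderLabels", function(x, ...) standardGeneric("founderLabels"))

#' @rdname ocsim-accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname ocsim-accessors
#' @export
setGeneric("tbv", function(x) standardGeneric("tbv"))

#' @rdname ocsim-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname ocsim-accessors
#' @export
setGeneric("alleleFreqs", function(x, ...) standardGeneric("alleleFreqs"))

#' @rdname ocsim-accessors
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))

#' @rdname ocsim-accessors
#' @export
setGeneric("methodTag", function(x) standardGeneric("methodTag"))

#' @rdname ocsim-accessors
#' @export
setGeneric("indivIds", function(x) standardGeneric("indivIds"))

#' @rdname ocsim-accessors
#' @export
setGeneric("inbreedingCoef", function(x) standardGeneric("inbreedingCoef"))

#' @rdname ocsim-accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname ocsim-accessors
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))

#' @rdname ocsim-accessors
#' @export
setGeneric("schemeReport", function(x) standardGeneric("schemeReport"))
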