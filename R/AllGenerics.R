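#' @rdname StudyTable-class
#' @param x,object a \linkS4class{StudyTable} (or other class as documented).
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @rdname StudyTable-class
#' @export
setGeneric("organism", function(x) standardGeneric("organism"))

#' @rdname StudyTable-class
#' @export
setGeneric("idGroups", function(x) standardGeneric("idGroups"))

#' @rdname StudyTable-class
#' @export
setGeneric("geneGroups", function(x) standardGeneric("geneGroups"))

#' @rdname StudyTable-class
#' @export
setGeneric("rowIds", function(x) standardGeneric("rowIds"))

#' @rdname StudyTable-class
#' @export
setGeneric("extraColumns", function(x) standardGeneric("extraColumns"))

#' @rdname HarmonizationLog-class
#' @param x a \linkS4class{HarmonizationLog}.
#' @export
setGeneric("overviewLog", function(x) standardGeneric("overviewLog"))

#' @rdname HarmonizationLog-class
#' @export
setGeneric("detailLog", function(x) standardGeneric("detailLog"))

#' @rdname MechanismNetwork-class
#' @param x a \linkS4class{MechanismNetwork}.
#' @export
setGeneric("seeds", function(x) standardGeneric("seeds"))

#' @rdname MechanismNetwork-class
#' @export
setGeneric("ppiGraph", function(x) standardGeneric("ppiGraph"))

#' @rdname MechanismNetwork-class
#' @export
setGeneric("drugTargets", function(x) standardGeneric("drugTargets"))

#' @rdname SteinerSolution-class
#' @param x a \linkS4class{SteinerSolution}.
#' @export
setGeneric("connectors", function(x) standardGeneric("connectors"))
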