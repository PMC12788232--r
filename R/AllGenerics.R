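#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Bioconductor-style
#' slot access goes through these rather than `@`.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The slot value; see the class documentation for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("muscleLabels", function(x) standardGeneric("muscleLabels"))

#' @rdname accessors
#' @export
setGeneric("nTrialsAveraged", function(x) standardGeneric("nTrialsAveraged"))

#' @rdname accessors
#' @export
setGeneric("synergyWeights", function(x) standardGeneric("synergyWeights"))

#' @rdname accessors
#' @export
setGeneric("synergyCoefficients", function(x) standardGeneric("synergyCoefficients"))

#' @rdname accessors
#' @export
setGeneric("synergyOrder", function(x) standardGeneric("synergyOrder"))

#' @rdname accessors
#' @export
setGeneric("vaf", function(x) standardGeneric("vaf"))

#' @rdname accessors
#' @export
setGeneric("vafReport", function(x) standardGeneric("vafReport"))

#' @rdname accessors
#' @export
setGeneric("vafCurve", function(x) standardGeneric("vafCurve"))

#' @rdname accessors
#' @export
setGeneric("reconstruct", function(x) standardGeneric("reconstruct"))

#' @rdname accessors
#' @export
setGeneric("trueWeights", function(x) standardGeneric("trueWeights"))

#' @rdname accessors
#' @export
setGeneric("trueCoefficients", function(x) standardGeneric("trueCoefficients"))

#' @rdname accessors
#' @export
setGeneric("protocolEffects", function(x) standardGeneric("protocolEffects"))

#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setGeneric("matchPermutation", function(x) standardGeneric("matchPermutation"))

#' @rdname accessors
#' @export
setGeneric("matchSimilarity", function(x) standardGeneric("matchSimilarity"))
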