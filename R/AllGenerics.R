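#' @rdname PeptideSet-class
#' @param x,object A `PeptideSet`.
#' @export
setGeneric("peptideIds", function(x) standardGeneric("peptideIds"))

#' @rdname PeptideSet-class
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname PeptideSet-class
#' @export
setGeneric("peptideLabels", function(x) standardGeneric("peptideLabels"))

#' @rdname PeptideSet-class
#' @export
setGeneric("nPositives", function(x) standardGeneric("nPositives"))

#' @rdname PeptideSet-class
#' @export
setGeneric("nNegatives", function(x) standardGeneric("nNegatives"))

#' @rdname FISTable-class
#' @param x A `FISTable`.
#' @export
setGeneric("fisFeatures", function(x) standardGeneric("fisFeatures"))

#' @rdname FISTable-class
#' @export
setGeneric("fisScores", function(x) standardGeneric("fisScores"))

#' @rdname ModelBundle-class
#' @param x A `ModelBundle`.
#' @export
setGeneric("bundleAlgorithm", function(x) standardGeneric("bundleAlgorithm"))

#' @rdname ModelBundle-class
#' @export
setGeneric("bundleParams", function(x) standardGeneric("bundleParams"))

#' @rdname ModelBundle-class
#' @export
setGeneric("bundleFeatures", function(x) standardGeneric("bundleFeatures"))

#' @rdname ModelBundle-class
#' @export
setGeneric("bundleCutoff", function(x) standardGeneric("bundleCutoff"))
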