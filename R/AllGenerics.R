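#' @import methods
#' @importFrom BiocGenerics start end width strand
#' @importFrom BiocGenerics "start<-" "end<-" "width<-"
NULL

#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @export
setGeneric("biotypes", function(x) standardGeneric("biotypes"))

#' @export
setGeneric("transcriptLengths", function(x) standardGeneric("transcriptLengths"))

#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))

#' @export
setGeneric("transcriptSpans", function(x) standardGeneric("transcriptSpans"))
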