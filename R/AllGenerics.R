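#' @export
setGeneric("activationScores", function(object) standardGeneric("activationScores"))

#' @export
setGeneric("zMatrix", function(object) standardGeneric("zMatrix"))

#' @export
setGeneric("usedGenes", function(object) standardGeneric("usedGenes"))

#' @export
setGeneric("droppedGenes", function(object) standardGeneric("droppedGenes"))

#' @export
setGeneric("anovaTable", function(object) standardGeneric("anovaTable"))

#' @export
setGeneric("tukeyTable", function(object) standardGeneric("tukeyTable"))

#' @export
setGeneric("deTable", function(object) standardGeneric("deTable"))

#' @export
setGeneric("deCalls", function(object, direction = c("up", "down")) standardGeneric("deCalls"))

#' @export
setGeneric("gdaTable", function(object) standardGeneric("gdaTable"))

#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @export
setGeneric("locationTable", function(object) standardGeneric("locationTable"))

#' @export
setGeneric("drugTable", function(object) standardGeneric("drugTable"))

#' @export
setGeneric("termSets", function(object) standardGeneric("termSets"))

#' @export
setGeneric("regulatorEdges", function(object) standardGeneric("regulatorEdges"))

#' @export
setGeneric("panelTable", function(object) standardGeneric("panelTable"))

#' @export
setGeneric("panelMembers", function(object) standardGeneric("panelMembers"))

#' @export
setGeneric("degSets", function(object) standardGeneric("degSets"))

#' @export
setGeneric("depSets", function(object) standardGeneric("depSets"))

#' @export
setGeneric("expectedPanel", function(object) standardGeneric("expectedPanel"))

#' @export
setGeneric("computeActivationScores", function(object, ...)
    standardGeneric("computeActivationScores"))

#' @export
setGeneric("deTest", function(object, ...) standardGeneric("deTest"))
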