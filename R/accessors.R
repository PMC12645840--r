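#' Access the record table of a MutationSet
#'
#' @param x a [MutationSet-class].
#' @return `data.frame` of mutation records.
#' @export
setGeneric("mutData", function(x) standardGeneric("mutData"))

#' @rdname mutData
#' @export
setMethod("mutData", "MutationSet", function(x) x@records)

#' Replace the record table of a MutationSet
#'
#' @param x a [MutationSet-class].
#' @param value replacement `data.frame`.
#' @export
setGeneric("mutData<-", function(x, value) standardGeneric("mutData<-"))

#' @rdname mutData-set
#' @export
setMethod("mutData<-", "MutationSet", function(x, value) {
  x@records <- value
  validObject(x)
  x
})

#' Sample identifiers present in a MutationSet
#' @param x a [MutationSet-class].
#' @return character vector of unique sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "MutationSet", function(x) unique(x@records$sample))

#' Result table of an MFResult
#' @param x an [MFResult-class].
#' @return `data.frame` of grouped counts, depths, frequencies, proportions.
#' @export
setGeneric("mfData", function(x) standardGeneric("mfData"))

#' @rdname mfData
#' @export
setMethod("mfData", "MFResult", function(x) x@data)

#' Grouping columns of an MFResult
#' @param x an [MFResult-class].
#' @export
setGeneric("mfGrouping", function(x) standardGeneric("mfGrouping"))

#' @rdname mfGrouping
#' @export
setMethod("mfGrouping", "MFResult", function(x) x@grouping)

#' Subtype resolution of an MFResult
#' @param x an [MFResult-class].
#' @export
setGeneric("mfResolution", function(x) standardGeneric("mfResolution"))

#' @rdname mfResolution
#' @export
setMethod("mfResolution", "MFResult", function(x) x@resolution)

#' Signature exposures of a SignatureFit
#' @param x a [SignatureFit-class].
#' @param fraction if `TRUE`, return exposures as fractions of their sum.
#' @export
setGeneric("exposures", function(x, fraction = FALSE)
  standardGeneric("exposures"))

#' @rdname exposures
#' @export
setMethod("exposures", "SignatureFit", function(x, fraction = FALSE) {
  if (fraction && sum(x@exposures) > 0) x@exposures / sum(x@exposures)
  else x@exposures
})

setMethod("show", "MutationSet", function(object) {
  rec <- object@records
  cat("MutationSet with", nrow(rec), "records,",
      length(unique(rec$sample)), "sample(s)\n")
  if (nrow(rec)) {
    tab <- table(rec$variation_type)
    cat("  variation types:",
        paste(names(tab), tab, sep = ":", collapse = " "), "\n")
    cat("  flagged (filter_mut):", sum(rec$filter_mut), "\n")
  }
})

setMethod("show", "MFResult", function(object) {
  cat("MFResult:", nrow(object@data), "row(s); grouping:",
      paste(object@grouping, collapse = " x "),
      "; resolution:", object@resolution, "\n")
})

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit (", object@family, ")\n", sep = "")
  cat("  fixed:", paste(object@fixed, collapse = " + "))
  if (length(object@random)) {
    cat("  random:", paste(object@random, collapse = " + "))
  }
  cat("\n  dispersion phi =", format(object@dispersion, digits = 4), "\n")
})

setMethod("show", "BmdResult", function(object) {
  cat("BmdResult: BMD =", format(object@bmd, digits = 4),
      "[BMDL", format(object@bmdl, digits = 4), ", BMDU",
      format(object@bmdu, digits = 4), "] (90% bootstrap interval)\n")
  cat("  Akaike weights:",
      paste(names(object@weights),
            sprintf("%.3f", object@weights), sep = "=", collapse = " "), "\n")
})

setMethod("show", "SpectraComparison", function(object) {
  cat("SpectraComparison: G2 =", format(object@g2, digits = 6),
      "df =", object@df, "(", object@distribution, ") p =",
      format.pval(object@pValue, digits = 4), "\n")
})

setMethod("show", "SignatureFit", function(object) {
  cat("SignatureFit: cosine =", format(object@cosine, digits = 4),
      if (object@robust) "(robust)" else "(NOT robust, < 0.9)", "\n")
  fr <- exposures(object, fraction = TRUE)
  fr <- fr[fr > 0]
  if (length(fr)) {
    cat("  active:", paste(names(fr), sprintf("%.2f", fr),
                           sep = "=", collapse = " "), "\n")
  }
})
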