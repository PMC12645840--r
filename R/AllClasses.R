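#' @import methods
#' @importFrom S4Vectors metadata
NULL

# Canonical column set of a mutation record table, in canonical order.
# Extra (passthrough) columns are kept after these.
.RECORD_COLUMNS <- c(
  "contig", "start", "end", "ref", "alt", "sample",
  "alt_depth", "total_depth", "depth",
  "variation_type", "vaf", "variant_length",
  "context", "subtype", "normalized_ref", "normalized_alt",
  "normalized_subtype", "normalized_context",
  "context_with_mutation", "normalized_context_with_mutation",
  "gc_content", "filter_mut", "filter_reason", "region"
)

.VARIATION_TYPES <- c(
  "no_variant", "snv", "mnv", "insertion", "deletion",
  "complex", "sv", "ambiguous", "uncategorized"
)

# Variation types counted as mutations in frequency numerators.  Ambiguous
# and uncategorized calls still contribute sequencing depth but are not
# confidently typed, so they are excluded from mutation counts.
.MUTATION_TYPES <- c("snv", "mnv", "insertion", "deletion", "complex", "sv")

#' MutationSet: a collection of ECS mutation records
#'
#' Container for per-site mutation records imported from tabular files or
#' single-sample VCFs.  Each row is one record: either a variant call or a
#' sequenced non-variant site.  Records carry depths (`alt_depth`,
#' `total_depth`), a 9-way `variation_type` categorization, the
#' trinucleotide `context`, pyrimidine-strand normalized subtype labels, and
#' filtering flags (`filter_mut`, `filter_reason`).
#'
#' @slot records `data.frame` of records in the canonical column set;
#'   user-supplied extra columns are retained after the canonical ones.
#' @slot metadata named `list` of provenance (input files, options, seeds).
#' @export
setClass("MutationSet",
  slots = c(records = "data.frame", metadata = "list"),
  prototype = prototype(records = data.frame(), metadata = list())
)

setValidity("MutationSet", function(object) {
  rec <- object@records
  need <- c("contig", "start", "end", "ref", "alt", "sample",
            "alt_depth", "total_depth", "variation_type", "filter_mut")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    return(paste("missing record columns:", paste(miss, collapse = ", ")))
  }
  if (nrow(rec)) {
    if (any(!rec$variation_type %in% .VARIATION_TYPES)) {
      return("variation_type outside the 9-way category set")
    }
    bad <- !is.na(rec$alt_depth) & !is.na(rec$total_depth) &
      rec$alt_depth > rec$total_depth
    if (any(bad)) return("alt_depth exceeds total_depth")
    if (any(rec$end <= rec$start - 1L, na.rm = TRUE)) {
      return("end must be > start - 1 (half-open convention)")
    }
  }
  TRUE
})

#' MFResult: grouped mutation counts and frequencies
#'
#' Result of [calculateMF()]: per group (and per subtype, when a resolution
#' is requested) the minimum (`sum_min`) and maximum (`sum_max`) mutation
#' counts, the aggregated sequencing depth (`group_depth`), the mutation
#' frequencies `mf_min`/`mf_max` (mutations per base pair), and subtype
#' proportions (depth-normalized and raw).
#'
#' @slot data `data.frame` with grouping columns, optional `subtype`,
#'   counts, depths, frequencies and proportions.
#' @slot grouping character vector of grouping column names.
#' @slot resolution one of `"none"`, `"type"`, `"6"`, `"12"`, `"96"`, `"192"`.
#' @slot metadata list (depth source, excluded-site counts).
#' @export
setClass("MFResult",
  slots = c(data = "data.frame", grouping = "character",
            resolution = "character", metadata = "list")
)

setValidity("MFResult", function(object) {
  d <- object@data
  if (!length(object@resolution) == 1L ||
      !object@resolution %in% c("none", "type", "6", "12", "96", "192")) {
    return("resolution must be one of none/type/6/12/96/192")
  }
  if (nrow(d)) {
    if (any(d$sum_min < 0) || any(d$sum_max < 0)) return("negative counts")
    if (any(d$sum_min > d$sum_max)) return("sum_min exceeds sum_max")
  }
  TRUE
})

#' ModelFit: a binomial-family regression of mutation frequency
#'
#' Wraps a fitted GLM (binomial or quasibinomial, logit link) or binomial
#' GLMM of per-observation mutation proportions, together with the Pearson
#' dispersion estimate, per-level mean estimates and Pearson residuals.
#'
#' @slot fit the underlying `glm` or `glmerMod` object.
#' @slot family `"binomial"` or `"quasibinomial"`.
#' @slot dispersion Pearson dispersion estimate (phi).
#' @slot fixed,random character vectors of effect names.
#' @slot levelEstimates `data.frame` of per-level mean estimates with SEs.
#' @slot data the modelling data used.
#' @export
setClass("ModelFit",
  slots = c(fit = "ANY", family = "character", dispersion = "numeric",
            fixed = "character", random = "character",
            levelEstimates = "data.frame", data = "data.frame")
)

#' BmdResult: model-averaged benchmark dose
#'
#' Output of [bmdModelAverage()]: the per-family maximum-likelihood fits and
#' AICs, Akaike weights, bootstrap BMD draws, and the model-averaged BMD with
#' its bootstrap confidence bounds (5th/95th percentiles, a 90% interval).
#'
#' @slot fits named list of per-family fits (see [fitDoseResponse()]).
#' @slot aic named numeric vector of per-family AICs.
#' @slot weights named numeric Akaike weights (sum to 1).
#' @slot draws numeric vector of bootstrap BMD draws.
#' @slot bmd,bmdl,bmdu model-averaged BMD (median of draws) and bounds.
#' @slot bmr benchmark-response specification.
#' @slot seed integer seed used for the bootstrap.
#' @slot nBoot number of bootstrap replicates attempted.
#' @slot nFailed number of replicates that failed to produce a BMD.
#' @export
setClass("BmdResult",
  slots = c(fits = "list", aic = "numeric", weights = "numeric",
            draws = "numeric", bmd = "numeric", bmdl = "numeric",
            bmdu = "numeric", bmr = "list", seed = "integer",
            nBoot = "integer", nFailed = "integer")
)

setValidity("BmdResult", function(object) {
  if (length(object@weights) &&
      abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  if (length(object@bmd) == 1L && is.finite(object@bmd)) {
    if (!(object@bmdl <= object@bmd && object@bmd <= object@bmdu)) {
      return("BMDL <= BMD <= BMDU violated")
    }
  }
  TRUE
})

#' SpectraComparison: G-squared contingency comparison of two spectra
#'
#' Holds the R x 2 contingency table of minimum mutation counts, expected
#' counts under homogeneity, the G-squared likelihood-ratio statistic, its
#' degrees of freedom, the reference distribution used (chi-square, or F
#' when N/(R-1) < 20) and the p-value.
#'
#' @slot observed,expected numeric matrices (zero-margin rows dropped).
#' @slot g2 G-squared statistic.
#' @slot df degrees of freedom, (R-1)(T-1).
#' @slot distribution `"chi-square"` or `"F"`.
#' @slot pValue p-value.
#' @slot n total count.
#' @export
setClass("SpectraComparison",
  slots = c(observed = "matrix", expected = "matrix", g2 = "numeric",
            df = "numeric", distribution = "character", pValue = "numeric",
            n = "numeric")
)

#' SignatureFit: non-negative refit of SBS signatures to a 96-channel profile
#'
#' @slot exposures named non-negative vector, mutation counts attributed to
#'   each catalog signature (zero for pruned signatures).
#' @slot reconstructed reconstructed 96-channel profile (catalog x exposures).
#' @slot observed the observed 96-channel counts.
#' @slot cosine cosine similarity between observed and reconstruction;
#'   values > 0.9 indicate a robust reconstruction.
#' @slot robust logical, `cosine > 0.9`.
#' @slot activeSignatures names of signatures retained after pruning.
#' @export
setClass("SignatureFit",
  slots = c(exposures = "numeric", reconstructed = "numeric",
            observed = "numeric", cosine = "numeric", robust = "logical",
            activeSignatures = "character")
)
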