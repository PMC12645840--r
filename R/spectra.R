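#' @importFrom stats dist hclust cutree pchisq pf cophenetic
NULL

#' Compare two mutation spectra with the G-squared statistic
#'
#' Builds an R x 2 contingency table of minimum mutation counts (R
#' subtypes, two groups) and tests for a difference in subtype proportions
#' with the likelihood-ratio statistic
#' `G2 = 2 * sum(Y * log(Y / E))`, where E are the expected counts under
#' homogeneity; cells with zero observed count contribute zero.  Rows with
#' zero margin are dropped before computing degrees of freedom
#' `(R - 1)(T - 1)`.  For large samples G2 is referred to a chi-square
#' distribution; when `N / (R - 1) < 20` (N the total count), `G2 / df` is
#' referred to an F distribution with `df` and `N - df` degrees of freedom
#' for better small-sample behaviour.  Minimum counts are used so the
#' observations are independent mutational events.
#'
#' @param counts numeric matrix (or data.frame) of non-negative integer
#'   counts with R subtype rows and 2 group columns.
#' @return a [SpectraComparison-class].
#' @examples
#' spectraComparison(rbind(c(10, 0), c(0, 10)))  # G2 = 40 log 2
#' @export
spectraComparison <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) != 2L) stop("spectra comparison is defined for two groups")
  if (any(is.na(m)) || any(m < 0) || any(abs(m - round(m)) > 1e-8)) {
    stop("counts must be non-negative integers")
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("subtype_", seq_len(nrow(m)))
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2L) {
    stop("fewer than two subtypes with non-zero margin; ",
         "the comparison is undefined")
  }
  N <- sum(m)
  E <- outer(rowSums(m), colSums(m)) / N
  ratio <- ifelse(m > 0, m * log(m / E), 0)
  g2 <- 2 * sum(ratio)
  g2 <- max(g2, 0)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  if (N / (nrow(m) - 1) >= 20) {
    distn <- "chi-square"
    p <- stats::pchisq(g2, df, lower.tail = FALSE)
  } else {
    distn <- "F"
    df2 <- max(N - df, 1)
    p <- stats::pf(g2 / df, df, df2, lower.tail = FALSE)
  }
  methods::new("SpectraComparison", observed = m, expected = E, g2 = g2,
               df = df, distribution = distn, pValue = p, n = N)
}

#' Build a subtype-count contingency table from an MFResult
#'
#' Extracts the minimum mutation counts of two groups from a
#' subtype-resolved [MFResult-class], as input for [spectraComparison()].
#'
#' @param mf an [MFResult-class] with a single grouping column.
#' @param groups length-2 vector naming the two group levels to compare.
#' @return numeric matrix with one row per subtype and one column per group.
#' @export
spectraTable <- function(mf, groups) {
  stopifnot(methods::is(mf, "MFResult"), length(groups) == 2L)
  if (length(mf@grouping) != 1L) {
    stop("spectraTable() expects an MFResult grouped by a single column")
  }
  d <- mfData(mf)
  g <- d[[mf@grouping]]
  sub <- sort(unique(d$subtype))
  m <- vapply(groups, function(lv) {
    di <- d[g == lv, ]
    di$sum_min[match(sub, di$subtype)]
  }, numeric(length(sub)))
  m[is.na(m)] <- 0
  rownames(m) <- sub
  colnames(m) <- as.character(groups)
  m
}

#' Hierarchically cluster mutation spectra
#'
#' Clusters samples (or groups) by their mutation spectra, represented as
#' subtype counts, frequencies or proportions.  Pairwise distances use
#' [stats::dist()] (default Euclidean) and agglomeration uses
#' [stats::hclust()] (default Ward's minimum-variance method on squared
#' Euclidean distances, `"ward.D2"`).  Leaves are then ordered with the
#' min-height-first rule (see [orderLeaves()]).
#'
#' @param profiles numeric matrix, one row per sample, one column per
#'   subtype.
#' @param distance distance metric name accepted by [stats::dist()].
#' @param linkage linkage method accepted by [stats::hclust()]; `"ward"`
#'   is taken as `"ward.D2"`.
#' @return an `hclust` object with leaf order optimized.
#' @export
clusterSpectra <- function(profiles, distance = "euclidean",
                           linkage = "ward.D2") {
  m <- as.matrix(profiles)
  if (nrow(m) < 2L) stop("need at least two profiles to cluster")
  if (any(!is.finite(m))) stop("profiles contain non-finite values")
  dist_ok <- c("euclidean", "maximum", "manhattan", "canberra", "binary",
               "minkowski")
  if (!distance %in% dist_ok) {
    stop("unknown distance '", distance, "'; options: ",
         paste(dist_ok, collapse = ", "))
  }
  if (identical(linkage, "ward")) linkage <- "ward.D2"
  link_ok <- c("ward.D", "ward.D2", "single", "complete", "average",
               "mcquitty", "median", "centroid")
  if (!linkage %in% link_ok) {
    stop("unknown linkage '", linkage, "'; options: ",
         paste(link_ok, collapse = ", "))
  }
  hc <- stats::hclust(stats::dist(m, method = distance), method = linkage)
  orderLeaves(hc)
}

#' Order dendrogram leaves by the min-height-first rule
#'
#' At every internal node, the subtree containing the smaller minimum merge
#' height is placed first (left); a leaf is considered to have an infinite
#' minimum height, so tighter subtrees come first.  Only the leaf order is
#' changed; the merge topology and heights (hence all cophenetic
#' distances) are untouched.
#'
#' @param hc an `hclust` object.
#' @return the `hclust` object with reordered `$order`.
#' @export
orderLeaves <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  minh <- function(k) {
    # minimum merge height within the subtree rooted at merge row k
    if (k < 0) return(Inf)  # leaf
    min(hc$height[k], minh(hc$merge[k, 1]), minh(hc$merge[k, 2]))
  }
  leaves <- function(k) {
    if (k < 0) return(-k)
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    if (minh(b) < minh(a)) c(leaves(b), leaves(a)) else
      c(leaves(a), leaves(b))
  }
  hc$order <- as.integer(leaves(nrow(hc$merge)))
  hc
}
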