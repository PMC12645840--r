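#' @importFrom pracma lsqnonneg
NULL

#' Cosine similarity between two vectors
#'
#' @param a,b numeric vectors of equal length with nonzero norm.
#' @return `a . b / (|a| |b|)`; in `[0, 1]` for non-negative vectors.
#' @examples
#' cosineSimilarity(c(1, 2, 3), c(4, 5, 6))  # 0.97463
#' @export
cosineSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}

#' Build a group x 96 trinucleotide mutation count matrix
#'
#' Sums SNVs over groups into the 96 canonical pyrimidine-strand channels
#' (minimum counting: each record once).  Non-SNV records, filtered records
#' and SNVs with undefined context are excluded; the number of excluded
#' SNVs is reported via the `"excluded"` attribute.
#'
#' @param x a [MutationSet-class].
#' @param grouping character vector of grouping columns (default sample).
#' @return numeric matrix, rows = groups, 96 columns in canonical order.
#' @export
buildTrinucleotideMatrix <- function(x, grouping = "sample") {
  rec <- mutData(x)
  missg <- setdiff(grouping, names(rec))
  if (length(missg)) {
    stop("grouping column(s) absent: ", paste(missg, collapse = ", "))
  }
  snv <- rec[!rec$filter_mut & rec$variation_type == "snv", , drop = FALSE]
  defined <- !is.na(snv$normalized_context_with_mutation)
  excluded <- sum(!defined)
  snv <- snv[defined, , drop = FALSE]
  key <- interaction(rec[, grouping, drop = FALSE], drop = FALSE,
                     sep = ":", lex.order = TRUE)
  all_groups <- sort(unique(as.character(key)))
  channels <- sbsChannels()
  m <- matrix(0, nrow = length(all_groups), ncol = 96,
              dimnames = list(all_groups, channels))
  if (nrow(snv)) {
    skey <- interaction(snv[, grouping, drop = FALSE], drop = FALSE,
                        sep = ":", lex.order = TRUE)
    tab <- table(as.character(skey), snv$normalized_context_with_mutation)
    m[rownames(tab), colnames(tab)] <- as.matrix(tab)
  }
  if (length(all_groups) && any(rowSums(m) == 0)) {
    warning("group(s) with no SNVs retained with zero counts: ",
            paste(all_groups[rowSums(m) == 0], collapse = ", "))
  }
  attr(m, "excluded") <- excluded
  m
}

#' Read a COSMIC-style SBS signature catalog
#'
#' Parses a tab-separated signature catalog whose first column holds the 96
#' channel labels (`"A[C>A]A"` style) and remaining columns one signature
#' each.  Rows are reordered to the canonical channel order and columns are
#' checked to be non-negative and to sum to 1 (within 1e-6).
#'
#' @param path file path.
#' @return 96 x K numeric matrix with channel rownames.
#' @export
readSignatureCatalog <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  labels <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- labels
  validateSignatureCatalog(m)
}

#' Validate and canonicalize a signature catalog matrix
#'
#' @param m numeric matrix with 96 channel-labelled rows.
#' @return the matrix reordered to canonical channel order.
#' @export
validateSignatureCatalog <- function(m) {
  channels <- sbsChannels()
  if (nrow(m) != 96L || !setequal(rownames(m), channels)) {
    stop("catalog must have exactly the 96 canonical channel rows")
  }
  m <- m[channels, , drop = FALSE]
  if (any(m < 0)) stop("catalog entries must be non-negative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6)) {
    stop("each signature column must sum to 1 (within 1e-6)")
  }
  m
}

#' Write a signature catalog in COSMIC SBS text format
#'
#' @param m 96 x K catalog matrix (see [validateSignatureCatalog()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSignatureCatalog <- function(m, path) {
  m <- validateSignatureCatalog(m)
  df <- data.frame(Type = rownames(m), m, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Synthetic SBS signature catalog
#'
#' Deterministically generates a small catalog of well-separated synthetic
#' signatures for testing and examples.  Like real single-base-substitution
#' signatures, each concentrates most of its mass on a handful of dominant
#' channels within one substitution class (compare SBS4's T[C>A] peaks),
#' with low background elsewhere, so pairwise cosine similarities are low
#' and reconstructions of realistic mutation totals are noise-limited
#' rather than catalog-limited.  This is a synthetic stand-in for a COSMIC
#' catalog download, not a reproduction of any COSMIC signature.
#'
#' @param n_signatures number of signatures (<= 6).
#' @param seed integer seed.
#' @return 96 x `n_signatures` matrix, columns `synthSBS1..K`.
#' @export
syntheticSignatureCatalog <- function(n_signatures = 4, seed = 101) {
  stopifnot(n_signatures >= 1, n_signatures <= 6)
  channels <- sbsChannels()
  sub_of <- substr(channels, 3, 5)
  subs <- snvSubtypes6()
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  m <- sapply(seq_len(n_signatures), function(k) {
    main <- subs[k]
    in_class <- which(sub_of == main)
    peaks <- sample(in_class, 5L)
    w <- rep(0.02, 96)            # low flat background
    w[in_class] <- 0.5            # substitution-class shoulder
    w[peaks] <- c(16, 12, 9, 6, 4)  # dominant channels
    w <- w * stats::runif(96, 0.7, 1.3)
    w / sum(w)
  })
  rownames(m) <- channels
  colnames(m) <- paste0("synthSBS", seq_len(n_signatures))
  m
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Refit a signature catalog to an observed 96-channel profile
#'
#' Estimates signature exposures by non-negative least squares
#' (`min || observed - catalog x ||` subject to `x >= 0`), then prunes the
#' solution backwards for sparsity: at each step the active signature whose
#' removal costs the least reconstruction cosine is dropped (with a refit)
#' as long as the cosine decreases by less than 0.01.  The cosine
#' similarity between the observed profile and the reconstruction is
#' reported; values above 0.9 are considered a robust reconstruction.
#'
#' @param observed non-negative numeric vector of 96 channel counts; if
#'   named, names must match the canonical channels.
#' @param catalog 96 x K signature matrix (see
#'   [validateSignatureCatalog()]).
#' @param prune_threshold maximum cosine loss tolerated when dropping a
#'   signature (default 0.01).
#' @return a [SignatureFit-class].
#' @export
refitSignatures <- function(observed, catalog, prune_threshold = 0.01) {
  catalog <- validateSignatureCatalog(catalog)
  if (length(observed) != 96L) stop("observed must have 96 channels")
  if (!is.null(names(observed))) {
    if (!setequal(names(observed), rownames(catalog))) {
      stop("observed channel labels do not match the catalog rows")
    }
    observed <- observed[rownames(catalog)]
  }
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (sum(observed) == 0) stop("observed profile is all zero")

  nnls_fit <- function(cols) {
    x <- pracma::lsqnonneg(catalog[, cols, drop = FALSE],
                           as.numeric(observed))$x
    names(x) <- cols
    x
  }
  cosine_of <- function(x, cols) {
    rec <- drop(catalog[, cols, drop = FALSE] %*% x)
    if (all(rec == 0)) return(0)
    cosineSimilarity(as.numeric(observed), rec)
  }
  active <- colnames(catalog)
  x <- nnls_fit(active)
  active <- names(x)[x > 0]
  if (!length(active)) active <- colnames(catalog)[1L]
  x <- nnls_fit(active)
  cos_cur <- cosine_of(x, active)
  while (length(active) > 1L) {
    trial <- lapply(active, function(drop_sig) {
      cols <- setdiff(active, drop_sig)
      xt <- nnls_fit(cols)
      list(cols = cols, x = xt, cosine = cosine_of(xt, cols))
    })
    best <- trial[[which.max(vapply(trial, `[[`, numeric(1), "cosine"))]]
    if (cos_cur - best$cosine < prune_threshold) {
      active <- best$cols
      x <- best$x
      cos_cur <- best$cosine
    } else break
  }
  expo <- stats::setNames(numeric(ncol(catalog)), colnames(catalog))
  expo[names(x)] <- x
  recon <- drop(catalog %*% expo)
  cs <- cosineSimilarity(as.numeric(observed), recon)
  methods::new("SignatureFit",
    exposures = expo, reconstructed = recon,
    observed = stats::setNames(as.numeric(observed), rownames(catalog)),
    cosine = cs, robust = cs > 0.9,
    activeSignatures = names(x)[x > 0])
}
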