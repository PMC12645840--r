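#' @import data.table
NULL

.RESOLUTIONS <- c("none", "type", "6", "12", "96", "192")

#' Stranded 192-channel context labels
#'
#' All twelve stranded SNV subtypes within their 16 trinucleotide contexts,
#' formatted like `"A[G>T]C"`.
#' @return character vector of 192 labels.
#' @export
sbsChannels192 <- function() {
  out <- character(0)
  for (s in snvSubtypes12()) {
    for (f5 in .ACGT) for (f3 in .ACGT) {
      out <- c(out, paste0(f5, "[", s, "]", f3))
    }
  }
  out
}

# Per-record subtype label at a resolution.  Mutation records only; SNVs
# with undefined context have no 96/192 label (NA) and are excluded from
# context-resolved tallies.
.subtypeLabels <- function(rec, resolution) {
  switch(resolution,
    none = rep("all", nrow(rec)),
    type = rec$variation_type,
    "6"  = ifelse(rec$variation_type == "snv", rec$normalized_subtype,
                  rec$variation_type),
    "12" = ifelse(rec$variation_type == "snv", rec$subtype,
                  rec$variation_type),
    "96" = ifelse(rec$variation_type == "snv",
                  rec$normalized_context_with_mutation, rec$variation_type),
    "192" = ifelse(rec$variation_type == "snv",
                   rec$context_with_mutation, rec$variation_type),
    stop("unknown resolution: ", resolution)
  )
}

# Depth class of each record's site, from reference base content only.
.depthClass <- function(rec, resolution) {
  base <- substr(rec$ref, 1L, 1L)
  base[!base %in% .ACGT] <- NA_character_
  ctx <- rec$context
  if (resolution %in% c("none", "type")) {
    return(rep("all", nrow(rec)))
  }
  if (resolution == "6") {
    out <- ifelse(base %in% c("C", "T"), base,
                  unname(.complement[base]))
    return(out)
  }
  if (resolution == "12") return(base)
  if (resolution == "96") {
    pyr <- base %in% c("C", "T")
    out <- ctx
    out[!pyr & !is.na(ctx)] <- .revcomp(ctx[!pyr & !is.na(ctx)])
    out[is.na(base)] <- NA_character_
    return(out)
  }
  if (resolution == "192") return(ctx)
  stop("unknown resolution: ", resolution)
}

# Full subtype label set and the depth class each label draws on.
.subtypeUniverse <- function(resolution) {
  nonsnv <- setdiff(.MUTATION_TYPES, "snv")
  if (resolution == "none") {
    return(data.frame(subtype = "all", class = "all"))
  }
  if (resolution == "type") {
    return(data.frame(subtype = .MUTATION_TYPES, class = "all"))
  }
  if (resolution == "6") {
    s <- snvSubtypes6()
    return(data.frame(subtype = c(s, nonsnv),
                      class = c(substr(s, 1, 1), rep("all", length(nonsnv)))))
  }
  if (resolution == "12") {
    s <- snvSubtypes12()
    return(data.frame(subtype = c(s, nonsnv),
                      class = c(substr(s, 1, 1), rep("all", length(nonsnv)))))
  }
  if (resolution == "96") {
    s <- sbsChannels()
    cls <- paste0(substr(s, 1, 1), substr(s, 3, 3), substr(s, 7, 7))
    return(data.frame(subtype = c(s, nonsnv),
                      class = c(cls, rep("all", length(nonsnv)))))
  }
  if (resolution == "192") {
    s <- sbsChannels192()
    cls <- paste0(substr(s, 1, 1), substr(s, 3, 3), substr(s, 7, 7))
    return(data.frame(subtype = c(s, nonsnv),
                      class = c(cls, rep("all", length(nonsnv)))))
  }
  stop("unknown resolution: ", resolution)
}

#' Deduplicate per-site depth
#'
#' When several variants are called at the same (sample, contig, start),
#' only the first record in canonical order keeps its `total_depth` for
#' depth summation; subsequent records contribute zero, preventing
#' double-counting of read depth.  Adds a `depth_contrib` column;
#' `alt_depth` is untouched.
#'
#' @param x a [MutationSet-class].
#' @return the [MutationSet-class] with a `depth_contrib` record column.
#' @export
dedupDepth <- function(x) {
  rec <- mutData(x)
  dt <- data.table::as.data.table(rec)
  ord <- order(dt$sample, dt$contig, dt$start, dt$ref, dt$alt,
               method = "radix")
  dup <- logical(nrow(dt))
  dup[ord] <- duplicated(dt[ord, c("sample", "contig", "start")])
  rec$depth_contrib <- ifelse(dup, 0L, rec$total_depth)
  mutData(x) <- rec
  x
}

#' Calculate Min and Max mutation frequencies
#'
#' Aggregates mutation counts and sequencing depth per group (and per
#' subtype when a resolution is requested) and derives mutation
#' frequencies.  Two counting methods are reported side by side: the
#' minimum method (`sum_min`) counts each mutation record once, attributing
#' recurrent reads to clonal expansion of a single event, while the maximum
#' method (`sum_max`) counts every alt-supporting read as an independent
#' event.  `mf_min` and `mf_max` divide these counts by the summed
#' `total_depth` (mutations per base pair), deduplicated per site so that
#' multi-allelic sites contribute their depth once.  At subtype resolutions
#' the depth denominator is restricted to sites where the subtype can occur
#' (e.g. C:G sites for C-reference subtypes), and depth-normalized and raw
#' subtype proportions are appended.
#'
#' Records flagged by filtering are excluded from mutation counts but their
#' depth remains in denominators.  Ambiguous and uncategorized records are
#' never counted as mutations but contribute depth.
#'
#' @param x a [MutationSet-class].
#' @param grouping character vector of record columns to group by.
#' @param resolution one of `"none"`, `"type"`, `"6"`, `"12"`, `"96"`,
#'   `"192"`.
#' @param precalcDepth optional precalculated depth `data.frame` holding the
#'   grouping columns, `group_depth`, and a `context_class` column at
#'   context-stratified resolutions.  Required when records carry no
#'   per-site depth.
#' @return an [MFResult-class].
#' @export
calculateMF <- function(x, grouping = "sample", resolution = "none",
                        precalcDepth = NULL) {
  resolution <- as.character(resolution)
  resolution <- match.arg(resolution, .RESOLUTIONS)
  rec <- mutData(x)
  missg <- setdiff(grouping, names(rec))
  if (length(missg)) {
    stop("grouping column(s) absent from records: ",
         paste(missg, collapse = ", "))
  }
  dt <- data.table::as.data.table(rec)

  # --- numerators -----------------------------------------------------
  cdt <- dt[!dt$filter_mut & dt$variation_type %in% .MUTATION_TYPES]
  cdt$subtype <- .subtypeLabels(cdt, resolution)
  n_excluded <- sum(is.na(cdt$subtype))
  cdt <- cdt[!is.na(cdt$subtype)]
  counts <- cdt[, list(sum_min = .N,
                       sum_max = sum(as.numeric(alt_depth))),
                by = c(grouping, "subtype")]
  counts$subtype <- as.character(counts$subtype)

  # --- denominators ---------------------------------------------------
  universe <- .subtypeUniverse(resolution)
  groups <- unique(dt[, grouping, with = FALSE])
  if (!is.null(precalcDepth)) {
    depth <- .precalcDepthTable(precalcDepth, grouping, resolution, groups,
                                universe)
  } else {
    if (all(is.na(dt$total_depth))) {
      stop("records carry no depth; supply precalcDepth")
    }
    ddt <- data.table::as.data.table(mutData(dedupDepth(x)))
    ddt$class <- .depthClass(ddt, resolution)
    if (resolution %in% c("96", "192")) {
      n_na <- sum(is.na(ddt$class) & ddt$depth_contrib > 0, na.rm = TRUE)
      if (n_na > 0) {
        message(n_na, " site record(s) with undefined context excluded ",
                "from context-stratified depth")
      }
    }
    total <- ddt[, list(group_depth = sum(as.numeric(depth_contrib),
                                          na.rm = TRUE)),
                 by = grouping]
    total$class <- "all"
    if (resolution %in% c("none", "type")) {
      depth <- total
    } else {
      bycls <- ddt[!is.na(ddt$class),
                   list(group_depth = sum(as.numeric(depth_contrib),
                                          na.rm = TRUE)),
                   by = c(grouping, "class")]
      depth <- data.table::rbindlist(list(bycls, total), use.names = TRUE)
    }
  }

  # --- assemble full grid --------------------------------------------
  grid <- groups[, as.list(universe), by = names(groups)]
  grid <- merge(grid, counts, by = c(grouping, "subtype"), all.x = TRUE)
  grid$sum_min[is.na(grid$sum_min)] <- 0L
  grid$sum_max[is.na(grid$sum_max)] <- 0
  grid <- merge(grid, depth, by.x = c(grouping, "class"),
                by.y = c(grouping, "class"), all.x = TRUE)
  grid$group_depth[is.na(grid$group_depth)] <- NA_real_
  grid$mf_min <- ifelse(!is.na(grid$group_depth) & grid$group_depth > 0,
                        grid$sum_min / grid$group_depth, NA_real_)
  grid$mf_max <- ifelse(!is.na(grid$group_depth) & grid$group_depth > 0,
                        grid$sum_max / grid$group_depth, NA_real_)
  grid$class <- NULL
  data.table::setorderv(grid, c(grouping, "subtype"))
  out <- data.table::setDF(grid)
  if (resolution == "none") out$subtype <- NULL
  res <- methods::new("MFResult", data = out, grouping = grouping,
                      resolution = resolution,
                      metadata = list(
                        depth_source = if (is.null(precalcDepth))
                          "per-site" else "precalculated",
                        context_excluded = n_excluded))
  if (resolution != "none") {
    res <- subtypeProportions(res,
                              normalized = !all(is.na(out$group_depth)))
  }
  res
}

.precalcDepthTable <- function(precalcDepth, grouping, resolution, groups,
                               universe) {
  pd <- data.table::as.data.table(precalcDepth)
  need <- c(grouping, "group_depth")
  class_needed <- !all(universe$class == "all")
  if (class_needed) need <- c(grouping, "context_class", "group_depth")
  missg <- setdiff(need, names(pd))
  if (length(missg)) {
    stop("precalcDepth lacks column(s): ", paste(missg, collapse = ", "),
         " (granularity must match grouping x resolution)")
  }
  if (class_needed) {
    depth <- pd[, list(group_depth = sum(as.numeric(group_depth))),
                by = c(grouping, "context_class")]
    data.table::setnames(depth, "context_class", "class")
    wanted <- setdiff(unique(universe$class), "all")
    have <- merge(groups, depth, by = grouping)
    miss <- setdiff(wanted, unique(have$class))
    if (length(miss)) {
      stop("precalcDepth is missing depth for context class(es): ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    total <- depth[, list(group_depth = sum(group_depth)), by = grouping]
    total$class <- "all"
    depth <- data.table::rbindlist(list(depth, total), use.names = TRUE)
  } else {
    depth <- pd[, list(group_depth = sum(as.numeric(group_depth))),
                by = grouping]
    depth$class <- "all"
  }
  chk <- merge(groups, depth[depth$class == "all"], by = grouping,
               all.x = TRUE)
  if (any(is.na(chk$group_depth))) {
    stop("precalcDepth has no rows for some groups; ",
         "granularity must match the requested grouping")
  }
  depth
}

#' Subtype proportions per group
#'
#' Appends depth-normalized and raw subtype proportions to a
#' subtype-resolved [MFResult-class].  The normalized proportion of subtype
#' s is its minimum mutation frequency divided by the sum of all subtype
#' frequencies in the group, correcting for unequal sequencing depth across
#' subtype contexts; the raw proportion divides the subtype count by the
#' group's total mutation count (`M_total`).  Groups with no mutations get
#' undefined (NA) proportions.
#'
#' @param mf an [MFResult-class] at a subtype resolution.
#' @param normalized compute depth-normalized proportions (requires depth).
#' @return the [MFResult-class] with `proportion` (normalized, when
#'   requested), `proportion_raw` and `M_total` columns.
#' @export
subtypeProportions <- function(mf, normalized = TRUE) {
  stopifnot(methods::is(mf, "MFResult"))
  if (mf@resolution == "none") {
    stop("proportions require a subtype resolution")
  }
  d <- data.table::as.data.table(mf@data)
  grouping <- mf@grouping
  if (normalized && all(is.na(d$group_depth))) {
    stop("normalized proportions need depth; supply precalcDepth to ",
         "calculateMF()")
  }
  d[, M_total := sum(sum_min), by = grouping]
  d[, proportion_raw := ifelse(M_total > 0, sum_min / M_total, NA_real_)]
  if (normalized) {
    d[, proportion := {
      tot <- sum(mf_min, na.rm = TRUE)
      if (is.na(tot) || tot == 0) rep(NA_real_, .N) else {
        p <- mf_min / tot
        p[is.na(p)] <- 0
        p
      }
    }, by = grouping]
  }
  mf@data <- data.table::setDF(d)
  mf
}

#' Per-class sequencing depth from a reference sequence
#'
#' Counts reference positions per subtype-context class over target
#' regions, for apportioning precalculated total depths when per-site
#' records are unavailable: at 6-base resolution the two classes are C:G
#' and T:A positions; at 96/192-base, the trinucleotide context classes.
#'
#' @param reference [Biostrings::DNAStringSet] or FASTA path.
#' @param regions region set (see [makeRegions()]); `NULL` uses the whole
#'   reference.
#' @param resolution `"6"`, `"12"`, `"96"` or `"192"`.
#' @return `data.frame` with `context_class` and `n_sites` (positions whose
#'   class is defined; contig-edge and non-ACGT positions are dropped at
#'   context resolutions).
#' @export
referenceContextCounts <- function(reference, regions = NULL,
                                   resolution = "6") {
  resolution <- match.arg(as.character(resolution),
                          c("6", "12", "96", "192"))
  reference <- .as_reference(reference)
  if (is.null(regions)) {
    regions <- GenomicRanges::GRanges(
      names(reference),
      IRanges::IRanges(1L, Biostrings::width(reference)))
    regions$label <- names(reference)
  } else {
    regions <- .as_regions(regions)
  }
  cls_all <- character(0)
  for (i in seq_along(regions)) {
    ctg <- as.character(GenomicRanges::seqnames(regions))[i]
    pos <- seq(GenomicRanges::start(regions)[i],
               GenomicRanges::end(regions)[i])
    base <- toupper(as.character(Biostrings::subseq(
      rep(reference[ctg], length(pos)), start = pos, width = 1L)))
    fake <- data.frame(ref = base,
                       context = trinucleotideContext(
                         rep(ctg, length(pos)), pos, reference))
    cls_all <- c(cls_all, .depthClass(fake, resolution))
  }
  tab <- table(cls_all, useNA = "no")
  data.frame(context_class = names(tab), n_sites = as.integer(tab),
             row.names = NULL)
}
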