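#' @importFrom GenomicRanges findOverlaps
NULL

.addReason <- function(reason, idx, label) {
  cur <- reason[idx]
  already <- vapply(strsplit(cur, ";", fixed = TRUE),
                    function(r) label %in% r, logical(1))
  reason[idx] <- ifelse(already, cur,
                        ifelse(cur == "", label, paste(cur, label, sep = ";")))
  reason
}

.hasReason <- function(reason, label) {
  vapply(strsplit(reason, ";", fixed = TRUE),
         function(r) label %in% r, logical(1))
}

#' Flag putative germline variants by VAF
#'
#' Variant records whose variant allele fraction strictly exceeds the cutoff
#' are flagged as putative germline (`filter_mut = TRUE`, reason
#' `"germline"`).  A record whose VAF equals the cutoff is not flagged.
#'
#' @param x a [MutationSet-class].
#' @param vaf_cutoff VAF threshold in (0, 1]; default 0.01.
#' @return the updated [MutationSet-class].
#' @export
flagGermlineVaf <- function(x, vaf_cutoff = 0.01) {
  if (!is.numeric(vaf_cutoff) || length(vaf_cutoff) != 1L ||
      is.na(vaf_cutoff) || vaf_cutoff <= 0 || vaf_cutoff > 1) {
    stop("vaf_cutoff must be a single value in (0, 1]")
  }
  rec <- mutData(x)
  hit <- rec$variation_type != "no_variant" & !is.na(rec$vaf) &
    rec$vaf > vaf_cutoff
  rec$filter_mut[hit] <- TRUE
  rec$filter_reason <- .addReason(rec$filter_reason, hit, "germline")
  mutData(x) <- rec
  x
}

#' Flag SNVs inside germline MNVs
#'
#' SNVs whose position falls within the half-open span `[start, end)` of a
#' germline-flagged MNV from the same sample are flagged as probable variant
#' calling artifacts (no-calls within reads supporting the germline MNV can
#' surface as spurious sub-clonal SNVs).  Germline flags must already be
#' assigned (see [flagGermlineVaf()]).
#'
#' @param x a [MutationSet-class].
#' @return the updated [MutationSet-class].
#' @export
flagSnvInGermMnv <- function(x) {
  rec <- mutData(x)
  germ_mnv <- which(rec$variation_type == "mnv" &
                      .hasReason(rec$filter_reason, "germline"))
  if (length(germ_mnv)) {
    snv <- which(rec$variation_type == "snv")
    if (length(snv)) {
      key_m <- rec$sample[germ_mnv]
      hit <- logical(length(snv))
      for (j in seq_along(germ_mnv)) {
        i <- germ_mnv[j]
        hit <- hit | (rec$sample[snv] == rec$sample[i] &
                        rec$contig[snv] == rec$contig[i] &
                        rec$start[snv] >= rec$start[i] &
                        rec$start[snv] < rec$end[i])
      }
      idx <- snv[hit]
      rec$filter_mut[idx] <- TRUE
      rec$filter_reason <- .addReason(rec$filter_reason, idx,
                                      "snv_in_germ_mnv")
    }
  }
  mutData(x) <- rec
  x
}

#' Flag records by the value of a custom column
#'
#' Records whose `column` value is in `values` are flagged with reason
#' `"custom:<column>"`.  Used e.g. to flag pipeline-reported artifacts such
#' as end-repair fill-in artifacts carried in an extra column.
#'
#' @param x a [MutationSet-class].
#' @param column name of an existing record column.
#' @param values character vector of values to flag.
#' @return the updated [MutationSet-class].
#' @export
flagCustom <- function(x, column, values) {
  rec <- mutData(x)
  if (!column %in% names(rec)) {
    stop("column '", column, "' not found; available: ",
         paste(setdiff(names(rec), .RECORD_COLUMNS), collapse = ", "))
  }
  hit <- !is.na(rec[[column]]) & rec[[column]] %in% values
  rec$filter_mut[hit] <- TRUE
  rec$filter_reason <- .addReason(rec$filter_reason, hit,
                                  paste0("custom:", column))
  mutData(x) <- rec
  x
}

#' Restrict records to target regions
#'
#' Removes records outside the supplied target regions.  Single-base records
#' must start within a region; records spanning more than one base must
#' start \emph{and} end within the same region or they are removed.
#' Surviving records are annotated with the region label.
#'
#' @param x a [MutationSet-class].
#' @param regions region set (`GRanges` with `label`, data.frame, or path).
#' @return list with elements `x` (filtered [MutationSet-class]) and
#'   `removed` (number of records removed).
#' @export
applyRegions <- function(x, regions) {
  regions <- .as_regions(regions)
  if (length(regions) == 0L) stop("regions must be non-empty")
  rec <- mutData(x)
  if (!nrow(rec)) return(list(x = x, removed = 0L))
  gr_start <- GenomicRanges::GRanges(rec$contig,
                                     IRanges::IRanges(rec$start, rec$start))
  hit_start <- GenomicRanges::findOverlaps(gr_start, regions,
                                           select = "first")
  span <- rec$end - rec$start  # bases covered by sequence-resolved records
  multi <- span > 1L
  last <- pmax(rec$start, rec$end - 1L)
  gr_last <- GenomicRanges::GRanges(rec$contig,
                                    IRanges::IRanges(last, last))
  hit_last <- GenomicRanges::findOverlaps(gr_last, regions, select = "first")
  keep <- !is.na(hit_start) & (!multi |
    (!is.na(hit_last) & hit_last == hit_start))
  removed <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  rec$region <- regions$label[hit_start[keep]]
  rownames(rec) <- NULL
  mutData(x) <- rec
  list(x = x, removed = removed)
}

#' Remove flagged reads from depth
#'
#' For flagged records other than putative germline, treats the supporting
#' reads as no-calls: `alt_depth` is subtracted from `total_depth` and set
#' to zero.  Germline-flagged records keep both depths so their reads stay
#' in frequency denominators.
#'
#' @param x a [MutationSet-class].
#' @return the updated [MutationSet-class].
#' @export
adjustDepthForFiltered <- function(x) {
  rec <- mutData(x)
  idx <- which(rec$filter_mut & !.hasReason(rec$filter_reason, "germline"))
  if (length(idx)) {
    newtd <- rec$total_depth[idx] - rec$alt_depth[idx]
    if (any(newtd < 0, na.rm = TRUE)) {
      warning("total_depth below zero after subtraction; clamped to 0")
      newtd <- pmax(newtd, 0L)
    }
    rec$total_depth[idx] <- newtd
    rec$vaf[idx] <- ifelse(!is.na(newtd) & newtd > 0, 0, NA_real_)
    rec$alt_depth[idx] <- 0L
  }
  mutData(x) <- rec
  x
}

#' Filter mutation records
#'
#' Applies the filtering rules in a fixed order: germline VAF flagging,
#' SNV-in-germline-MNV flagging, custom-column flagging, region
#' containment, then optional depth adjustment for flagged records.
#' Flagged records are retained by default (their `total_depth` remains
#' available for frequency denominators) and are excluded from mutation
#' counts downstream; `drop = TRUE` removes them entirely.
#'
#' @param x a [MutationSet-class].
#' @param vaf_cutoff germline VAF cutoff, or `NULL` to skip the rule.
#' @param snv_in_germ_mnv flag SNVs inside germline MNVs.
#' @param custom_filter_col,custom_filter_val custom column rule
#'   (both `NULL` to skip).
#' @param regions region set, or `NULL` to skip region containment.
#' @param rm_filtered_mut_from_depth subtract flagged reads from depth
#'   (germline excepted).
#' @param drop remove flagged records from the output.
#' @return list with elements `x` (the filtered [MutationSet-class]) and
#'   `summary` (named counts per reason, plus `region_removed`).
#' @export
filterMut <- function(x, vaf_cutoff = NULL, snv_in_germ_mnv = FALSE,
                      custom_filter_col = NULL, custom_filter_val = NULL,
                      regions = NULL, rm_filtered_mut_from_depth = FALSE,
                      drop = FALSE) {
  summary <- c(germline = 0L, snv_in_germ_mnv = 0L, custom = 0L,
               region_removed = 0L)
  if (!is.null(vaf_cutoff)) {
    x <- flagGermlineVaf(x, vaf_cutoff)
    summary["germline"] <-
      sum(.hasReason(mutData(x)$filter_reason, "germline"))
  }
  if (isTRUE(snv_in_germ_mnv)) {
    x <- flagSnvInGermMnv(x)
    summary["snv_in_germ_mnv"] <-
      sum(.hasReason(mutData(x)$filter_reason, "snv_in_germ_mnv"))
  }
  if (!is.null(custom_filter_col)) {
    x <- flagCustom(x, custom_filter_col, custom_filter_val)
    summary["custom"] <- sum(.hasReason(mutData(x)$filter_reason,
                                        paste0("custom:", custom_filter_col)))
  }
  if (!is.null(regions)) {
    res <- applyRegions(x, regions)
    x <- res$x
    summary["region_removed"] <- res$removed
  }
  if (isTRUE(rm_filtered_mut_from_depth)) {
    x <- adjustDepthForFiltered(x)
  }
  if (isTRUE(drop)) {
    rec <- mutData(x)
    rec <- rec[!rec$filter_mut, , drop = FALSE]
    rownames(rec) <- NULL
    mutData(x) <- rec
  }
  list(x = x, summary = summary)
}
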