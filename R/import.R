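#' @importFrom data.table fread fwrite as.data.table setDF setDT rbindlist
#' @importFrom GenomicRanges GRanges start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom VariantAnnotation readVcf alt ref geno info
#' @importFrom S4Vectors elementNROWS
NULL

.REQUIRED_TABULAR <- c("contig", "start", "ref", "alt", "sample")

# Build the canonical record table from a raw input data.frame: coordinate
# convention, allele case, categorization, depths, VAF, context and subtype
# annotation, canonical sort.  Shared by both importers and the simulator.
.finalizeRecords <- function(df, reference = NULL, regions = NULL,
                             is_0_based = FALSE, source = "input") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(.REQUIRED_TABULAR, names(df))
  if (length(miss)) {
    stop("missing required column(s) in ", source, ": ",
         paste(miss, collapse = ", "))
  }
  n <- nrow(df)
  df$contig <- as.character(df$contig)
  start <- suppressWarnings(as.integer(df$start))
  bad <- which(is.na(start) | start < (if (is_0_based) 0L else 1L))
  if (length(bad)) {
    stop("malformed coordinates in ", source, " at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (is_0_based) start <- start + 1L
  df$start <- start

  df$ref <- toupper(as.character(df$ref))
  alt <- toupper(as.character(df$alt))
  alt[is.na(alt) | alt == ""] <- "."
  df$alt <- alt
  df$sample <- as.character(df$sample)

  df$variation_type <- classifyVariant(df$ref, df$alt)
  is_var <- df$variation_type != "no_variant"

  seq_ref <- .is_acgt_string(df$ref)
  df$end <- ifelse(seq_ref, df$start + nchar(df$ref), df$start + 1L)
  df$end <- as.integer(df$end)

  if (!"alt_depth" %in% names(df)) df$alt_depth <- NA_integer_
  ad <- suppressWarnings(as.integer(df$alt_depth))
  # Table-1 convention: a variant row without alt_depth counts as one read
  ad[is.na(ad) & is_var] <- 1L
  ad[is.na(ad) & !is_var] <- 0L
  ad[!is_var] <- 0L
  df$alt_depth <- ad

  if (!"total_depth" %in% names(df)) df$total_depth <- NA_integer_
  td <- suppressWarnings(as.integer(df$total_depth))
  if ("depth" %in% names(df)) {
    dp <- suppressWarnings(as.integer(df$depth))
    td[is.na(td)] <- dp[is.na(td)]
    df$depth <- dp
  } else {
    df$depth <- NA_integer_
  }
  td <- pmax(td, df$alt_depth)
  df$total_depth <- td

  df$vaf <- ifelse(!is.na(td) & td > 0, df$alt_depth / td, NA_real_)
  df$variant_length <- .variantLength(df$ref, df$alt, df$variation_type)

  if (!is.null(reference)) {
    reference <- .as_reference(reference)
    df$context <- trinucleotideContext(df$contig, df$start, reference)
    mid <- substr(df$context, 2L, 2L)
    mismatch <- !is.na(df$context) & seq_ref &
      mid != substr(df$ref, 1L, 1L)
    if (any(mismatch)) {
      warning(sum(mismatch), " record(s) whose REF disagrees with the ",
              "reference sequence; their context is set to undefined")
      df$context[mismatch] <- NA_character_
    }
  } else if (!"context" %in% names(df)) {
    df$context <- NA_character_
  }

  sub_cols <- c("subtype", "normalized_ref", "normalized_alt",
                "normalized_subtype", "normalized_context",
                "context_with_mutation", "normalized_context_with_mutation")
  for (cc in sub_cols) df[[cc]] <- NA_character_
  snv <- which(df$variation_type == "snv")
  if (length(snv)) {
    ns <- normalizeSubtype(df$ref[snv], df$alt[snv], df$context[snv])
    df$normalized_ref[snv] <- ns$normalized_ref
    df$normalized_alt[snv] <- ns$normalized_alt
    df$subtype[snv] <- ns$subtype
    df$normalized_subtype[snv] <- ns$normalized_subtype
    df$normalized_context[snv] <- ns$normalized_context
    df$context_with_mutation[snv] <- ns$context_with_mutation
    df$normalized_context_with_mutation[snv] <-
      ns$normalized_context_with_mutation
  }
  df$gc_content <- ifelse(is.na(df$context), NA_real_,
    (nchar(gsub("[^GC]", "", df$context))) / 3)

  if (!"filter_mut" %in% names(df)) df$filter_mut <- FALSE
  df$filter_mut <- isTRUE_vec(df$filter_mut)
  if (!"filter_reason" %in% names(df)) df$filter_reason <- ""
  df$filter_reason[is.na(df$filter_reason)] <- ""

  if (!is.null(regions)) {
    df$region <- .regionLabel(df, regions)
  } else if (!"region" %in% names(df)) {
    df$region <- NA_character_
  }

  extras <- setdiff(names(df), .RECORD_COLUMNS)
  df <- df[, c(.RECORD_COLUMNS, extras), drop = FALSE]
  ord <- order(df$sample, df$contig, df$start, df$ref, df$alt,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  toupper(as.character(x)) %in% c("TRUE", "T", "1")
}

.variantLength <- function(ref, alt, type) {
  nr <- nchar(ref)
  na_ <- nchar(alt)
  out <- integer(length(ref))
  out[type == "snv"] <- 1L
  out[type == "mnv"] <- nr[type == "mnv"]
  out[type == "insertion"] <- (na_ - nr)[type == "insertion"]
  out[type == "deletion"] <- (nr - na_)[type == "deletion"]
  out[type == "complex"] <- pmax(nr, na_)[type == "complex"]
  out[type %in% c("sv", "ambiguous", "uncategorized")] <- NA_integer_
  out
}

# Label records with the target region containing their start (1-based).
.regionLabel <- function(df, regions) {
  regions <- .as_regions(regions)
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start, df$start))
  hit <- GenomicRanges::findOverlaps(gr, regions, select = "first")
  lab <- regions$label[hit]
  as.character(lab)
}

#' Import tabular per-site mutation data
#'
#' Reads one or more tab-separated mutation files sharing the required
#' column set (`contig`, `start`, `ref`, `alt`, `sample`; optionally `end`,
#' `alt_depth`, `total_depth`, `depth`, plus arbitrary extra columns) into a
#' single [MutationSet-class].  Variant rows lacking an `alt_depth` column
#' are assumed to be supported by one read.  Declared 0-based start
#' coordinates are shifted to the internal 1-based convention.  When a
#' reference is supplied, trinucleotide contexts and pyrimidine-strand
#' subtype labels are annotated; when regions are supplied, records are
#' labelled with the target containing their start.
#'
#' @param paths character vector of file paths (all are concatenated).
#' @param reference optional [Biostrings::DNAStringSet] or FASTA path.
#' @param regions optional region table (see [readRegions()]) or `GRanges`.
#' @param is_0_based logical; `TRUE` if input starts are 0-based.
#' @param sep field separator (default tab).
#' @return a [MutationSet-class], records in canonical sort order
#'   (sample, contig, start, ref, alt).
#' @export
importTabular <- function(paths, reference = NULL, regions = NULL,
                          is_0_based = FALSE, sep = "\t") {
  if (length(paths) == 0L) stop("no input files given")
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  tabs <- lapply(paths, function(p) {
    data.table::fread(p, sep = sep, header = TRUE, data.table = TRUE,
                      na.strings = c("NA", ""))
  })
  df <- data.table::setDF(data.table::rbindlist(tabs, fill = TRUE))
  rec <- .finalizeRecords(df, reference = reference, regions = regions,
                          is_0_based = is_0_based,
                          source = paste(basename(paths), collapse = "+"))
  methods::new("MutationSet", records = rec,
               metadata = list(source = paths, dialect = "tabular",
                               is_0_based = is_0_based))
}

#' Import single-sample VCF mutation data
#'
#' Reads one or more single-sample VCF files (plain or block-compressed)
#' into a [MutationSet-class].  The sample identifier is taken from the
#' genotype column header, falling back to an INFO `sample` field; if both
#' are present and disagree the file is rejected.  `total_depth` is the sum
#' of the genotype `AD` entries (falling back to `DP`, stored as `depth`);
#' `alt_depth` comes from `VD`.  Multi-allelic rows are split into one
#' record per alternate allele sharing the site depth.  Non-variant records
#' (ALT `"."`) are retained.
#'
#' @inheritParams importTabular
#' @return a [MutationSet-class].
#' @export
importVcf <- function(paths, reference = NULL, regions = NULL) {
  if (length(paths) == 0L) stop("no input files given")
  tabs <- lapply(paths, .parseOneVcf)
  df <- data.table::setDF(data.table::rbindlist(tabs, fill = TRUE))
  rec <- .finalizeRecords(df, reference = reference, regions = regions,
                          is_0_based = FALSE,
                          source = paste(basename(paths), collapse = "+"))
  methods::new("MutationSet", records = rec,
               metadata = list(source = paths, dialect = "vcf"))
}

.parseOneVcf <- function(path) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  nsmp <- ncol(vcf)
  if (!is.null(nsmp) && nsmp > 1L) {
    stop("multi-sample VCF not supported: ", basename(path))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  inf <- VariantAnnotation::info(vcf)

  geno_sample <- if (!is.null(nsmp) && nsmp == 1L) colnames(vcf)[1L] else NULL
  info_sample <- if ("sample" %in% names(inf)) {
    as.character(inf$sample[1L])
  } else NULL
  if (!is.null(geno_sample) && !is.null(info_sample) &&
      !is.na(info_sample) && geno_sample != info_sample) {
    stop("sample identifier conflict in ", basename(path), ": genotype '",
         geno_sample, "' vs INFO '", info_sample, "'")
  }
  smp <- if (!is.null(geno_sample)) geno_sample else info_sample
  if (is.null(smp) || is.na(smp)) {
    stop("no sample identifier (genotype header or INFO/sample) in ",
         basename(path))
  }

  altl <- VariantAnnotation::alt(vcf)
  k <- S4Vectors::elementNROWS(altl)
  k1 <- pmax(k, 1L)  # ALT "." keeps one no-variant record
  idx <- rep(seq_len(nrow(vcf)), k1)
  alt_chr <- rep(".", sum(k1))
  has_alt <- rep(k > 0L, k1)
  alt_chr[has_alt] <- as.character(unlist(altl))
  alt_chr[is.na(alt_chr) | alt_chr == ""] <- "."

  gen <- VariantAnnotation::geno(vcf)
  # site total depth: sum of AD over all alleles (shared by split records)
  td <- rep(NA_integer_, nrow(vcf))
  dp <- rep(NA_integer_, nrow(vcf))
  if ("AD" %in% names(gen)) {
    adm <- gen$AD
    td <- vapply(seq_len(nrow(vcf)), function(i) {
      v <- adm[i, 1L][[1L]]
      if (is.null(v) || all(is.na(v))) NA_integer_
      else as.integer(sum(v, na.rm = TRUE))
    }, integer(1))
  }
  if ("DP" %in% names(gen)) {
    dp <- as.integer(gen$DP[, 1L])
  } else if ("DP" %in% names(inf)) {
    dp <- as.integer(inf$DP)
  }
  vd <- rep(NA_integer_, nrow(vcf))
  if ("VD" %in% names(gen)) {
    vdv <- gen$VD
    vd <- vapply(seq_len(nrow(vcf)), function(i) {
      v <- vdv[i, 1L][[1L]]
      if (is.null(v) || all(is.na(v))) NA_integer_
      else as.integer(v[1L])
    }, integer(1))
  } else if ("VD" %in% names(inf)) {
    vd <- as.integer(inf$VD)
  }

  end_info <- if ("END" %in% names(inf)) as.integer(inf$END) else
    rep(NA_integer_, nrow(vcf))

  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr))[idx],
    start = GenomicRanges::start(rr)[idx],
    ref = as.character(VariantAnnotation::ref(vcf))[idx],
    alt = alt_chr,
    sample = smp,
    alt_depth = vd[idx],
    total_depth = td[idx],
    depth = dp[idx],
    stringsAsFactors = FALSE
  )
  df$alt_depth[df$alt == "."] <- 0L
  filt <- as.character(VariantAnnotation::fixed(vcf)$FILTER)
  if (length(filt)) df$filter <- filt[idx]
  if (any(!is.na(end_info))) {
    # symbolic records carry their span in INFO/END
    sym <- grepl("^<.*>$", df$alt) & !is.na(end_info[idx])
    df$end <- ifelse(sym, end_info[idx] + 1L, NA_integer_)
  }
  df
}

#' Write a MutationSet to the tabular dialect
#'
#' Writes the canonical record table (plus extra columns) as a
#' tab-separated file that [importTabular()] reads back identically.
#'
#' @param x a [MutationSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMutationTable <- function(x, path) {
  stopifnot(methods::is(x, "MutationSet"))
  data.table::fwrite(mutData(x), path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a BED-like target-region table
#'
#' Accepts 3- or 4-column tables (`contig`, `start`, `end`, optional
#' `label`), with or without a header.  BED files use 0-based half-open
#' coordinates (`is_0_based = TRUE`); 1-based tables use inclusive start
#' with half-open end.
#'
#' @param path file path.
#' @param is_0_based `TRUE` for BED convention.
#' @return `GRanges` with a `label` metadata column (1-based, inclusive).
#' @export
readRegions <- function(path, is_0_based = TRUE) {
  tab <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(tab) < 3L) stop("region table needs at least 3 columns")
  names(tab)[1:3] <- c("contig", "start", "end")
  if (ncol(tab) >= 4L) names(tab)[4L] <- "label"
  makeRegions(tab, is_0_based = is_0_based)
}

#' Build a region GRanges from a data.frame
#'
#' @param tab `data.frame` with columns `contig`, `start`, `end` and
#'   optionally `label`.
#' @param is_0_based `TRUE` if (start, end) follow the BED convention;
#'   `FALSE` for 1-based start with half-open end.
#' @return `GRanges` with unique `label` metadata (1-based, inclusive).
#' @export
makeRegions <- function(tab, is_0_based = FALSE) {
  start <- as.integer(tab$start)
  end <- as.integer(tab$end)
  if (is_0_based) start <- start + 1L
  # both conventions leave `end` as the first base after the interval
  end_incl <- end - 1L
  if (any(end_incl < start)) stop("malformed region interval (end <= start)")
  lab <- if ("label" %in% names(tab)) as.character(tab$label) else
    paste0("region_", seq_len(nrow(tab)))
  if (anyDuplicated(lab)) stop("region labels must be unique")
  gr <- GenomicRanges::GRanges(as.character(tab$contig),
                               IRanges::IRanges(start, end_incl))
  gr$label <- lab
  gr
}

.as_regions <- function(regions) {
  if (methods::is(regions, "GRanges")) {
    if (is.null(regions$label)) {
      regions$label <- paste0("region_", seq_along(regions))
    }
    return(regions)
  }
  if (is.data.frame(regions)) return(makeRegions(regions))
  if (is.character(regions) && length(regions) == 1L) {
    return(readRegions(regions))
  }
  stop("regions must be a GRanges, a data.frame, or a file path")
}
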