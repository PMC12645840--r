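#' @importFrom stats rbinom rbeta runif setNames
NULL

#' Generate a random reference panel
#'
#' Builds a deterministic random reference of `n_targets` contigs of
#' `target_length` bases each, emulating a panel of deep-sequencing target
#' regions, together with a region set covering each contig and the
#' per-contig base composition.
#'
#' @param n_targets number of target contigs (default 20).
#' @param target_length bases per target (default 2400).
#' @param seed integer seed; the output is bit-identical for a given seed.
#' @return list with `reference` ([Biostrings::DNAStringSet]), `regions`
#'   (`GRanges` with labels) and `composition` (per-contig A/C/G/T counts).
#' @export
makeReference <- function(n_targets = 20, target_length = 2400, seed = 1) {
  stopifnot(target_length >= 10, n_targets >= 1)
  set.seed(as.integer(seed))
  nm <- sprintf("target_%02d", seq_len(n_targets))
  seqs <- vapply(nm, function(i) {
    paste(sample(.ACGT, target_length, replace = TRUE), collapse = "")
  }, character(1))
  reference <- Biostrings::DNAStringSet(seqs)
  names(reference) <- nm
  regions <- GenomicRanges::GRanges(nm, IRanges::IRanges(1L, target_length))
  regions$label <- nm
  comp <- t(vapply(seqs, function(s) {
    tab <- table(factor(strsplit(s, "")[[1L]], levels = .ACGT))
    as.integer(tab)
  }, integer(4)))
  colnames(comp) <- .ACGT
  rownames(comp) <- nm
  list(reference = reference, regions = regions, composition = comp)
}

#' Per-sample designs along a dose-response curve
#'
#' Builds a simulation design whose group-level true mutation frequencies
#' follow the exponential dose-response curve
#' `mf(x) = mf0 (c - (c-1) exp(-b x^d))`.
#'
#' @param doses dose per group.
#' @param n_per_group samples per dose group.
#' @param mf0 control (dose 0) mutation frequency.
#' @param b,c_,d curve parameters (scale, maximum fold change, shape).
#' @return `data.frame` with `sample`, `dose`, `mf`.
#' @export
doseResponseDesign <- function(doses, n_per_group, mf0 = 2e-7,
                               b = 1, c_ = 3, d = 1) {
  mf <- mf0 * (c_ - (c_ - 1) * exp(-b * doses^d))
  data.frame(
    sample = sprintf("s%02d_d%s", seq_len(length(doses) * n_per_group),
                     rep(doses, each = n_per_group)),
    dose = rep(doses, each = n_per_group),
    mf = rep(mf, each = n_per_group),
    stringsAsFactors = FALSE
  )
}

#' Simulate an ECS mutation dataset with planted ground truth
#'
#' Generates a panel-style deep-sequencing dataset: per-sample, per-site
#' records at a stated depth, with mutations drawn binomially at each
#' sample's true mutation frequency and SNV contexts drawn from a planted
#' 96-channel spectrum.  Optional plants exercise every filtering rule:
#' germline SNVs at VAF around 0.5 (Beta(100, 100)), germline MNVs with
#' spurious sub-clonal SNVs inside their span, custom-labelled artifact
#' rows, clonal multiplets with a stated `alt_depth`, and records outside
#' the target regions.  All randomness comes from one seeded stream; the
#' complete planted truth is returned alongside the records.
#'
#' @param design `data.frame` with columns `sample` and `mf` (true minimum
#'   mutation frequency per sample); extra columns (e.g. `dose`) are
#'   carried into the records.
#' @param panel optional output of [makeReference()]; generated from
#'   `n_targets`/`target_length` when `NULL`.
#' @param n_targets,target_length panel geometry used when `panel` is
#'   `NULL` (defaults 20 targets of 2400 bases, a mutagenesis-panel
#'   layout).
#' @param depth per-site sequencing depth (default 10000).
#' @param spectrum optional length-96 weight vector (canonical channel
#'   order) for SNV contexts; uniform over attainable channels when
#'   `NULL`.
#' @param n_germline germline SNVs planted per dataset.
#' @param n_germ_mnv germline MNVs (3 bp) planted per dataset.
#' @param n_snv_in_germ_mnv sub-clonal SNVs planted inside germline MNV
#'   spans.
#' @param n_artifacts rows labelled `artifact_label` in the `filter`
#'   column.
#' @param artifact_label label used for planted artifacts.
#' @param n_out_of_region variant records planted outside the target
#'   regions (requires `region_margin >= 4`).
#' @param region_margin bases trimmed from each contig end when defining
#'   the target regions, creating out-of-region space (default 0; set
#'   >= 4 when planting out-of-region records).
#' @param n_multiplets planted clonal multiplets (mutations whose
#'   `alt_depth` is `multiplet_alt_depth` instead of 1).
#' @param multiplet_alt_depth reads supporting each planted multiplet.
#' @param per_site if `TRUE` (default) emit a record for every sequenced
#'   site; if `FALSE` emit variant records only (genome-wide sparse
#'   dialect) and rely on the returned depth table.
#' @param seed integer seed.
#' @return list with `records` (tabular-dialect `data.frame`), `mutations`
#'   (a [MutationSet-class] built from the records), `reference`,
#'   `regions`, `depth_table` (per-sample total depth),
#'   `depth_by_class_6` (per-sample C/T-class depth), `sites` (per-site
#'   reference annotation) and `truth` (every planted quantity, including
#'   the seed).
#' @export
simulateDataset <- function(design, panel = NULL, n_targets = 20,
                            target_length = 2400, depth = 10000,
                            spectrum = NULL,
                            n_germline = 0, n_germ_mnv = 0,
                            n_snv_in_germ_mnv = 0, n_artifacts = 0,
                            artifact_label = "EndRepairFillinArtifact",
                            n_out_of_region = 0, region_margin = 0,
                            n_multiplets = 0, multiplet_alt_depth = 10,
                            per_site = TRUE, seed = 1) {
  stopifnot(depth >= 100, all(design$mf < 0.01), all(design$mf >= 0))
  if (n_out_of_region > 0 && region_margin < 4) {
    stop("planting out-of-region records needs region_margin >= 4")
  }
  seed <- as.integer(seed)
  set.seed(seed)
  if (is.null(panel)) {
    panel <- makeReference(n_targets, target_length, seed = seed)
  }
  reference <- panel$reference
  lens <- stats::setNames(Biostrings::width(reference), names(reference))
  regions <- GenomicRanges::GRanges(
    names(reference),
    IRanges::IRanges(1L + region_margin, lens - region_margin))
  regions$label <- names(reference)

  # per-site annotation of all in-region positions
  sites <- do.call(rbind, lapply(names(reference), function(ctg) {
    pos <- seq(1L + region_margin, lens[[ctg]] - region_margin)
    data.frame(contig = ctg, pos = pos, stringsAsFactors = FALSE)
  }))
  sites$ref <- unlist(lapply(names(reference), function(ctg) {
    s <- as.character(reference[[ctg]])
    strsplit(substr(s, 1L + region_margin, lens[[ctg]] - region_margin),
             "")[[1L]]
  }), use.names = FALSE)
  sites$context <- trinucleotideContext(sites$contig, sites$pos, reference)
  pyr <- sites$ref %in% c("C", "T")
  sites$pyr_context <- ifelse(pyr, sites$context,
                              .revcomp(sites$context))
  n_sites <- nrow(sites)

  channels <- sbsChannels()
  ch_ctx <- paste0(substr(channels, 1, 1), substr(channels, 3, 3),
                   substr(channels, 7, 7))
  ch_alt <- substr(channels, 5, 5)
  if (is.null(spectrum)) {
    spectrum <- stats::setNames(rep(1, 96), channels)
  }
  if (length(spectrum) != 96L) stop("spectrum must have 96 weights")
  if (!is.null(names(spectrum))) spectrum <- spectrum[channels]
  # index of candidate sites per pyrimidine-strand context
  ctx_index <- split(seq_len(n_sites), sites$pyr_context)
  attainable <- ch_ctx %in% names(ctx_index)
  spec_use <- ifelse(attainable, spectrum, 0)
  if (sum(spec_use) == 0) stop("no attainable channel has positive weight")
  spec_use <- spec_use / sum(spec_use)

  samples <- as.character(design$sample)
  mut_rows <- list()
  truth_mut <- list()
  planted_hist <- stats::setNames(integer(96), channels)

  for (si in seq_along(samples)) {
    smp <- samples[si]
    mf <- design$mf[si]
    k <- stats::rbinom(1L, size = n_sites * depth, prob = mf)
    if (k == 0) next
    drawn <- sample(96L, k, replace = TRUE, prob = spec_use)
    used <- integer(0)
    rows <- vector("list", k)
    for (j in seq_len(k)) {
      cand <- ctx_index[[ch_ctx[drawn[j]]]]
      cand <- setdiff(cand, used)
      if (!length(cand)) {
        cand <- setdiff(seq_len(n_sites), used)
        if (!length(cand)) stop("more mutations than available sites")
        i <- cand[sample.int(length(cand), 1L)]
        alt <- sample(setdiff(.ACGT, sites$ref[i]), 1L)
      } else {
        i <- cand[sample.int(length(cand), 1L)]
        alt <- if (sites$ref[i] %in% c("C", "T")) ch_alt[drawn[j]] else
          unname(.complement[ch_alt[drawn[j]]])
        planted_hist[drawn[j]] <- planted_hist[drawn[j]] + 1L
      }
      used <- c(used, i)
      rows[[j]] <- data.frame(
        contig = sites$contig[i], start = sites$pos[i],
        ref = sites$ref[i], alt = alt, sample = smp,
        alt_depth = 1L, total_depth = depth, filter = "PASS",
        stringsAsFactors = FALSE)
    }
    mut_rows[[smp]] <- do.call(rbind, rows)
  }
  muts <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame()

  # planted multiplets: promote random mutations to clonal events
  if (n_multiplets > 0 && nrow(muts) > 0) {
    idx <- sample.int(nrow(muts), min(n_multiplets, nrow(muts)))
    muts$alt_depth[idx] <- as.integer(multiplet_alt_depth)
  }

  plant_rows <- list()
  free_site <- function(n, exclude) {
    pool <- setdiff(seq_len(n_sites), exclude)
    pool[sample.int(length(pool), n)]
  }
  used_sites <- if (nrow(muts)) {
    match(paste(muts$contig, muts$start), paste(sites$contig, sites$pos))
  } else integer(0)

  germ <- data.frame()
  if (n_germline > 0) {
    gi <- free_site(n_germline, used_sites)
    used_sites <- c(used_sites, gi)
    gsmp <- samples[((seq_len(n_germline) - 1L) %% length(samples)) + 1L]
    vaf <- stats::rbeta(n_germline, 100, 100)
    germ <- data.frame(
      contig = sites$contig[gi], start = sites$pos[gi],
      ref = sites$ref[gi],
      alt = vapply(sites$ref[gi],
                   function(r) sample(setdiff(.ACGT, r), 1L), character(1)),
      sample = gsmp, alt_depth = as.integer(round(vaf * depth)),
      total_depth = depth, filter = "PASS", stringsAsFactors = FALSE)
    plant_rows$germline <- germ
  }

  germ_mnv <- data.frame()
  snv_in_mnv <- data.frame()
  if (n_germ_mnv > 0) {
    # pick anchor sites with 2 following in-region positions on the same
    # contig, away from other plants
    ok <- which(c(diff(sites$pos, lag = 2) == 2, FALSE, FALSE) &
                  sites$contig == c(sites$contig[-(1:2)], NA, NA))
    ok <- setdiff(ok, c(used_sites, used_sites - 1L, used_sites - 2L))
    ai <- ok[sample.int(length(ok), n_germ_mnv)]
    used_sites <- c(used_sites, ai, ai + 1L, ai + 2L)
    msmp <- samples[((seq_len(n_germ_mnv) - 1L) %% length(samples)) + 1L]
    vaf <- stats::rbeta(n_germ_mnv, 100, 100)
    ref3 <- paste0(sites$ref[ai], sites$ref[ai + 1L], sites$ref[ai + 2L])
    alt3 <- vapply(ref3, function(r) {
      paste(unname(.complement[strsplit(r, "")[[1L]]]), collapse = "")
    }, character(1))
    germ_mnv <- data.frame(
      contig = sites$contig[ai], start = sites$pos[ai],
      ref = ref3, alt = alt3, sample = msmp,
      alt_depth = as.integer(round(vaf * depth)), total_depth = depth,
      filter = "PASS", stringsAsFactors = FALSE)
    plant_rows$germ_mnv <- germ_mnv
    if (n_snv_in_germ_mnv > 0) {
      which_mnv <- ((seq_len(n_snv_in_germ_mnv) - 1L) %% n_germ_mnv) + 1L
      off <- (seq_len(n_snv_in_germ_mnv) - 1L) %/% n_germ_mnv + 1L
      if (any(off > 2L)) stop("at most 2 sub-clonal SNVs per 3-bp MNV")
      ii <- ai[which_mnv] + off
      snv_in_mnv <- data.frame(
        contig = sites$contig[ii], start = sites$pos[ii],
        ref = sites$ref[ii],
        alt = vapply(sites$ref[ii],
                     function(r) sample(setdiff(.ACGT, r), 1L),
                     character(1)),
        sample = germ_mnv$sample[which_mnv],
        alt_depth = pmax(1L, as.integer(round(0.005 * depth))),
        total_depth = depth, filter = "PASS", stringsAsFactors = FALSE)
      plant_rows$snv_in_mnv <- snv_in_mnv
    }
  }

  artifacts <- data.frame()
  if (n_artifacts > 0) {
    ai <- free_site(n_artifacts, used_sites)
    used_sites <- c(used_sites, ai)
    asmp <- samples[((seq_len(n_artifacts) - 1L) %% length(samples)) + 1L]
    artifacts <- data.frame(
      contig = sites$contig[ai], start = sites$pos[ai],
      ref = sites$ref[ai],
      alt = vapply(sites$ref[ai],
                   function(r) sample(setdiff(.ACGT, r), 1L), character(1)),
      sample = asmp, alt_depth = 4L, total_depth = depth,
      filter = artifact_label, stringsAsFactors = FALSE)
    plant_rows$artifacts <- artifacts
  }

  oor <- data.frame()
  if (n_out_of_region > 0) {
    ctg <- names(reference)[((seq_len(n_out_of_region) - 1L) %%
                               length(reference)) + 1L]
    pos <- 2L + (seq_len(n_out_of_region) - 1L) %% (region_margin - 2L)
    rb <- vapply(seq_len(n_out_of_region), function(j) {
      substr(as.character(reference[[ctg[j]]]), pos[j], pos[j])
    }, character(1))
    oor <- data.frame(
      contig = ctg, start = pos, ref = rb,
      alt = vapply(rb, function(r) sample(setdiff(.ACGT, r), 1L),
                   character(1)),
      sample = samples[((seq_len(n_out_of_region) - 1L) %%
                          length(samples)) + 1L],
      alt_depth = 1L, total_depth = depth, filter = "PASS",
      stringsAsFactors = FALSE)
    plant_rows$out_of_region <- oor
  }

  variant <- do.call(rbind, c(list(muts), unname(plant_rows)))
  if (is.null(variant)) {
    variant <- data.frame(contig = character(0), start = integer(0),
                          ref = character(0), alt = character(0),
                          sample = character(0), alt_depth = integer(0),
                          total_depth = integer(0), filter = character(0))
  }

  if (per_site) {
    grid <- data.table::CJ(sample = samples, site = seq_len(n_sites))
    recs <- data.frame(
      contig = sites$contig[grid$site], start = sites$pos[grid$site],
      ref = sites$ref[grid$site], alt = ".", sample = grid$sample,
      alt_depth = 0L, total_depth = depth, filter = "PASS",
      stringsAsFactors = FALSE)
    # replace no-variant rows by variant rows at mutated sites
    vkey <- paste(variant$sample, variant$contig, variant$start)
    rkey <- paste(recs$sample, recs$contig, recs$start)
    recs <- recs[!rkey %in% vkey, , drop = FALSE]
    records <- rbind(recs, variant)
  } else {
    records <- variant
  }
  # carry design covariates (dose, group, ...) onto the records
  extra_cols <- setdiff(names(design), c("mf"))
  records <- merge(records, design[, extra_cols, drop = FALSE],
                   by = "sample", sort = FALSE)

  depth_table <- data.frame(sample = samples,
                            group_depth = as.numeric(n_sites) * depth)
  cls6 <- ifelse(sites$ref %in% c("C", "T"), sites$ref,
                 unname(.complement[sites$ref]))
  cls_tab <- table(cls6)
  depth_by_class_6 <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample = s, context_class = names(cls_tab),
               group_depth = as.numeric(cls_tab) * depth)
  }))

  truth <- list(
    seed = seed, depth = depth, n_sites = n_sites,
    design = design, spectrum = spec_use,
    planted_channel_counts = planted_hist,
    mutations = muts,
    n_mutations_per_sample = stats::setNames(
      vapply(samples, function(s) sum(muts$sample == s), numeric(1)),
      samples),
    germline = germ, germ_mnv = germ_mnv, snv_in_germ_mnv = snv_in_mnv,
    artifacts = artifacts, out_of_region = oor,
    n_germline = n_germline, n_germ_mnv = n_germ_mnv,
    n_germline_flagged = n_germline + n_germ_mnv,
    n_snv_in_germ_mnv = n_snv_in_germ_mnv, n_artifacts = n_artifacts,
    n_out_of_region = n_out_of_region,
    n_multiplets = min(n_multiplets, nrow(muts)),
    multiplet_alt_depth = multiplet_alt_depth)

  ms <- methods::new("MutationSet",
    records = .finalizeRecords(records, reference = reference,
                               regions = regions, source = "simulation"),
    metadata = list(seed = seed, dialect = "simulated"))

  list(records = records, mutations = ms, reference = reference,
       regions = regions, depth_table = depth_table,
       depth_by_class_6 = depth_by_class_6, sites = sites, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the simulation as files: the reference FASTA, a 1-based region
#' table, the combined tabular mutation file, one single-sample VCF per
#' sample (variant records only), the per-sample depth table, and the
#' planted truth as JSON.
#'
#' @param sim output of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @param bgzip if `TRUE`, block-compress the VCFs with
#'   [Rsamtools::bgzip()].
#' @return named list of written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir, bgzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(sim$reference, paths$fasta)
  paths$regions <- file.path(dir, "regions.tsv")
  reg <- data.frame(contig = as.character(
                      GenomicRanges::seqnames(sim$regions)),
                    start = GenomicRanges::start(sim$regions),
                    end = GenomicRanges::end(sim$regions) + 1L,
                    label = sim$regions$label)
  data.table::fwrite(reg, paths$regions, sep = "\t")
  paths$tabular <- file.path(dir, "mutations.tsv")
  data.table::fwrite(sim$records, paths$tabular, sep = "\t", quote = FALSE,
                     na = "NA")
  paths$depth <- file.path(dir, "depth.tsv")
  data.table::fwrite(sim$depth_table, paths$depth, sep = "\t")
  lens <- Biostrings::width(sim$reference)
  vcfs <- character(0)
  for (smp in unique(sim$records$sample)) {
    v <- sim$records[sim$records$sample == smp &
                       sim$records$alt != ".", , drop = FALSE]
    p <- file.path(dir, paste0(smp, ".vcf"))
    .writeSampleVcf(v, p, names(sim$reference), lens, smp)
    if (bgzip) {
      p <- Rsamtools::bgzip(p, overwrite = TRUE)
    }
    vcfs <- c(vcfs, p)
  }
  paths$vcf <- vcfs
  paths$truth <- file.path(dir, "truth.json")
  truth <- sim$truth
  truth$design <- as.list(truth$design)
  jsonlite::write_json(
    truth[c("seed", "depth", "n_sites", "design", "n_germline",
            "n_germ_mnv", "n_snv_in_germ_mnv", "n_artifacts",
            "n_out_of_region", "n_multiplets", "multiplet_alt_depth")],
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

.writeSampleVcf <- function(v, path, contigs, lens, sample_id) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", contigs, ",length=", lens, ">"),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##FILTER=<ID=EndRepairFillinArtifact,Description=\"Planted artifact\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste0("##FORMAT=<ID=VD,Number=1,Type=Integer,",
           "Description=\"Variant depth\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  if (nrow(v)) {
    v <- v[order(match(v$contig, contigs), v$start), , drop = FALSE]
    filt <- if ("filter" %in% names(v)) v$filter else "PASS"
    ad <- paste(v$total_depth - v$alt_depth, v$alt_depth, sep = ",")
    body <- paste(v$contig, v$start, ".", v$ref, v$alt, ".", filt, ".",
                  "GT:AD:VD",
                  paste("0/1", ad, v$alt_depth, sep = ":"), sep = "\t")
  } else {
    body <- character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
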