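# Shared fixtures and independent oracles.  Fixtures are built in code at
# test time; oracles are deliberately naive (nested loops) so they stay
# independent of the package's data.table implementation.

smallPanel <- function(seed = 11, n_targets = 2, target_length = 600) {
  makeReference(n_targets, target_length, seed = seed)
}

# canonical record sort used by the oracles
.oracleOrder <- function(df) {
  df[order(df$sample, df$contig, df$start, df$ref, df$alt), , drop = FALSE]
}

# Brute-force Min/Max counter with per-site depth deduplication.
# groups: named list mapping group label -> logical row index of records.
oracleMF <- function(rec, grouping, resolution = "none") {
  rec <- .oracleOrder(rec)
  mut_types <- c("snv", "mnv", "insertion", "deletion", "complex", "sv")
  lab_of <- function(row) {
    if (resolution == "none") return("all")
    if (resolution == "type") return(row$variation_type)
    if (row$variation_type != "snv") return(row$variation_type)
    if (resolution == "6") return(row$normalized_subtype)
    if (resolution == "12") return(row$subtype)
    if (resolution == "96") return(row$normalized_context_with_mutation)
    if (resolution == "192") return(row$context_with_mutation)
  }
  cls_of_site <- function(row) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    b <- substr(row$ref, 1, 1)
    if (!b %in% c("A", "C", "G", "T")) return(NA_character_)
    if (resolution %in% c("none", "type")) return("all")
    if (resolution == "6") return(if (b %in% c("C", "T")) b else comp[[b]])
    if (resolution == "12") return(b)
    ctx <- row$context
    if (is.na(ctx)) return(NA_character_)
    if (resolution == "96") {
      if (b %in% c("C", "T")) return(ctx)
      rc <- paste(rev(unname(comp[strsplit(ctx, "")[[1]]])), collapse = "")
      return(rc)
    }
    if (resolution == "192") return(ctx)
  }
  cls_of_label <- function(lab) {
    if (resolution %in% c("none", "type")) return("all")
    if (lab %in% mut_types) return("all")
    if (resolution %in% c("6", "12")) return(substr(lab, 1, 1))
    paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
  }
  key_of <- function(i) paste(rec[i, grouping], collapse = "\r")
  keys <- vapply(seq_len(nrow(rec)), key_of, character(1))
  out <- list()
  for (g in unique(keys)) {
    idx <- which(keys == g)
    # depth per class: first record per (sample, contig, start) counts
    seen <- character(0)
    depth_by_class <- list()
    total_depth <- 0
    for (i in idx) {
      sk <- paste(rec$sample[i], rec$contig[i], rec$start[i])
      if (sk %in% seen) next
      seen <- c(seen, sk)
      td <- rec$total_depth[i]
      if (is.na(td)) td <- 0
      total_depth <- total_depth + td
      cl <- cls_of_site(rec[i, ])
      if (!is.na(cl)) {
        depth_by_class[[cl]] <- (depth_by_class[[cl]] %||% 0) + td
      }
    }
    counts <- list()
    for (i in idx) {
      row <- rec[i, ]
      if (row$filter_mut) next
      if (!row$variation_type %in% mut_types) next
      lab <- lab_of(row)
      if (is.na(lab)) next
      cur <- counts[[lab]] %||% c(min = 0, max = 0)
      counts[[lab]] <- c(min = cur[["min"]] + 1,
                         max = cur[["max"]] + row$alt_depth)
    }
    for (lab in names(counts)) {
      cl <- cls_of_label(lab)
      dep <- if (cl == "all") total_depth else depth_by_class[[cl]] %||% 0
      out[[paste(g, lab, sep = "\r")]] <- data.frame(
        key = g, subtype = lab,
        sum_min = counts[[lab]][["min"]], sum_max = counts[[lab]][["max"]],
        group_depth = dep, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random record table for oracle comparisons (valid, self-consistent)
randomRecords <- function(n = 1000, n_samples = 4, seed = 5) {
  set.seed(seed)
  panel <- smallPanel(seed = seed + 1)
  ref <- panel$reference
  lens <- Biostrings::width(ref)
  contig <- sample(names(ref), n, replace = TRUE)
  pos <- vapply(contig, function(ctg) {
    sample(3:(lens[match(ctg, names(ref))] - 3), 1)
  }, integer(1))
  base <- vapply(seq_len(n), function(i) {
    substr(as.character(ref[[contig[i]]]), pos[i], pos[i])
  }, character(1))
  kind <- sample(c("no_variant", "snv", "mnv", "deletion", "insertion"),
                 n, replace = TRUE, prob = c(0.4, 0.35, 0.1, 0.08, 0.07))
  alt <- character(n)
  refa <- base
  for (i in seq_len(n)) {
    if (kind[i] == "no_variant") {
      alt[i] <- "."
    } else if (kind[i] == "snv") {
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), base[i]), 1)
    } else if (kind[i] == "mnv") {
      b2 <- substr(as.character(ref[[contig[i]]]), pos[i] + 1, pos[i] + 1)
      refa[i] <- paste0(base[i], b2)
      alt[i] <- paste0(sample(setdiff(c("A", "C", "G", "T"), base[i]), 1),
                       sample(setdiff(c("A", "C", "G", "T"), b2), 1))
    } else if (kind[i] == "deletion") {
      b2 <- substr(as.character(ref[[contig[i]]]), pos[i] + 1, pos[i] + 1)
      refa[i] <- paste0(base[i], b2)
      alt[i] <- base[i]
    } else {
      alt[i] <- paste0(base[i], sample(c("A", "C", "G", "T"), 1))
    }
  }
  df <- data.frame(
    contig = contig, start = pos, ref = refa, alt = alt,
    sample = sample(paste0("s", seq_len(n_samples)), n, replace = TRUE),
    alt_depth = ifelse(alt == ".", 0L, sample(1:20, n, replace = TRUE)),
    total_depth = sample(500:1500, n, replace = TRUE),
    dose = NA_real_, stringsAsFactors = FALSE)
  df$dose <- c(0, 10, 25, 50)[match(df$sample,
                                    paste0("s", seq_len(n_samples)))]
  # drop coincident duplicates of the same (sample, site, ref, alt)
  df <- df[!duplicated(df[, c("sample", "contig", "start", "ref", "alt")]), ]
  ms <- importTabular(writeTempTable(df), reference = ref)
  list(ms = ms, panel = panel, raw = df)
}

writeTempTable <- function(df) {
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}
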