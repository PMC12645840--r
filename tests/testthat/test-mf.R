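# Min/Max mutation frequency: depth deduplication, oracle equivalence,
# subtype proportions, grouping refinement, context depth.

test_that("per-site depth is deduplicated across co-located variants", {
  df <- data.frame(
    contig = "t1", start = c(100, 100, 100, 200),
    ref = "C", alt = c("A", "G", "T", "A"),
    sample = "s1", alt_depth = 1, total_depth = 1000)
  ms <- dedupDepth(importTabular(writeTempTable(df)))
  rec <- mutData(ms)
  at100 <- rec[rec$start == 100, ]
  expect_equal(sum(at100$depth_contrib), 1000)   # counted once
  expect_equal(sum(rec$depth_contrib), 2000)
  expect_equal(at100$alt_depth, rep(1, 3))       # alt depths untouched
  # single record unchanged
  expect_equal(rec$depth_contrib[rec$start == 200], 1000)
})

test_that("Min counts mutations once, Max counts supporting reads", {
  df <- data.frame(
    contig = "t1", start = c(100, 200), ref = "C", alt = "T",
    sample = "s1", alt_depth = c(7, 1), total_depth = 1000)
  mf <- calculateMF(importTabular(writeTempTable(df)), grouping = "sample")
  d <- mfData(mf)
  expect_equal(d$sum_min, 2)
  expect_equal(d$sum_max, 8)
  expect_equal(d$mf_min, 2 / 2000)
  expect_equal(d$mf_max, 8 / 2000)
})

test_that("calculateMF equals the brute-force oracle at all resolutions", {
  fx <- randomRecords(n = 1000, n_samples = 4, seed = 5)
  groupings <- list("sample", c("sample", "dose"), "dose", "contig",
                    c("sample", "contig"), c("dose", "contig"),
                    "sample", c("contig", "sample"), "dose",
                    c("sample", "dose"))
  set.seed(99)
  for (gi in seq_along(groupings)) {
    g <- groupings[[gi]]
    for (res in c("none", "type", "6", "96")) {
      got <- mfData(calculateMF(fx$ms, grouping = g, resolution = res))
      want <- oracleMF(mutData(fx$ms), g, res)
      gkey <- do.call(paste, c(lapply(got[, g, drop = FALSE],
                                      as.character), sep = "\r"))
      if (res == "none") {
        want_map <- setNames(want$sum_min, want$key)
        max_map <- setNames(want$sum_max, want$key)
        dep_map <- setNames(want$group_depth, want$key)
        expect_equal(got$sum_min, unname(want_map[gkey]),
                     info = paste("min", gi, res))
        expect_equal(got$sum_max, unname(max_map[gkey]),
                     info = paste("max", gi, res))
        expect_equal(got$group_depth, unname(dep_map[gkey]),
                     info = paste("depth", gi, res))
      } else {
        wkey <- paste(want$key, want$subtype, sep = "\r")
        gkey2 <- paste(gkey, got$subtype, sep = "\r")
        min_map <- setNames(want$sum_min, wkey)
        max_map <- setNames(want$sum_max, wkey)
        dep_map <- setNames(want$group_depth, wkey)
        present <- gkey2 %in% wkey
        expect_equal(got$sum_min[present], unname(min_map[gkey2[present]]),
                     info = paste("min", gi, res))
        expect_equal(got$sum_max[present], unname(max_map[gkey2[present]]),
                     info = paste("max", gi, res))
        expect_equal(got$group_depth[present],
                     unname(dep_map[gkey2[present]]),
                     info = paste("depth", gi, res))
        # rows absent from the oracle have zero mutations
        expect_true(all(got$sum_min[!present] == 0))
      }
    }
  }
})

test_that("subtype proportions follow the depth-normalized formula", {
  # worked case: M = (2, 2), D = (100, 300) -> P = (0.75, 0.25)
  mf <- new("MFResult",
            data = data.frame(group = "g", subtype = c("C>A", "C>T"),
                              sum_min = c(2L, 2L), sum_max = c(2, 2),
                              group_depth = c(100, 300),
                              mf_min = c(2 / 100, 2 / 300),
                              mf_max = c(2 / 100, 2 / 300)),
            grouping = "group", resolution = "6", metadata = list())
  d <- mfData(subtypeProportions(mf))
  expect_equal(d$proportion, c(0.75, 0.25))
  expect_equal(d$proportion_raw, c(0.5, 0.5))
  expect_equal(d$M_total, c(4L, 4L))
})

test_that("proportions sum to one and reduce to raw at equal depth", {
  fx <- randomRecords(n = 800, n_samples = 3, seed = 13)
  mf <- calculateMF(fx$ms, grouping = "sample", resolution = "6")
  d <- mfData(mf)
  for (s in unique(d$sample)) {
    ds <- d[d$sample == s, ]
    if (sum(ds$sum_min) == 0) next
    expect_equal(sum(ds$proportion), 1, tolerance = 1e-12)
    expect_equal(sum(ds$proportion_raw), 1, tolerance = 1e-12)
  }
  # equal depths for all subtypes: normalized equals raw exactly
  mfe <- new("MFResult",
             data = data.frame(group = "g",
                               subtype = c("C>A", "C>G", "T>A"),
                               sum_min = c(3L, 1L, 4L), sum_max = c(3, 1, 4),
                               group_depth = 500,
                               mf_min = c(3, 1, 4) / 500,
                               mf_max = c(3, 1, 4) / 500),
             grouping = "group", resolution = "6", metadata = list())
  de <- mfData(subtypeProportions(mfe))
  expect_identical(de$proportion, de$proportion_raw)
  # single nonzero subtype gets proportion 1
  mf1 <- new("MFResult",
             data = data.frame(group = "g", subtype = c("C>A", "C>G"),
                               sum_min = c(5L, 0L), sum_max = c(5, 0),
                               group_depth = c(100, 900),
                               mf_min = c(0.05, 0), mf_max = c(0.05, 0)),
             grouping = "group", resolution = "6", metadata = list())
  expect_equal(mfData(subtypeProportions(mf1))$proportion, c(1, 0))
})

test_that("sum over subtypes matches the unresolved count per group", {
  fx <- randomRecords(n = 600, n_samples = 3, seed = 23)
  base <- mfData(calculateMF(fx$ms, grouping = "sample"))
  for (res in c("type", "6", "12", "96", "192")) {
    d <- mfData(suppressMessages(
      calculateMF(fx$ms, grouping = "sample", resolution = res)))
    agg <- tapply(d$sum_min, d$sample, sum)
    if (res %in% c("96", "192")) {
      # context-undefined SNVs drop out of context-resolved tallies
      expect_true(all(agg[base$sample] <= base$sum_min))
    } else {
      expect_equal(as.vector(agg[base$sample]), base$sum_min)
    }
  }
})

test_that("refining then re-aggregating a grouping is exact", {
  fx <- randomRecords(n = 700, n_samples = 4, seed = 31)
  fine <- mfData(calculateMF(fx$ms, grouping = c("dose", "sample")))
  coarse <- mfData(calculateMF(fx$ms, grouping = "dose"))
  agg_min <- tapply(fine$sum_min, fine$dose, sum)
  agg_dep <- tapply(fine$group_depth, fine$dose, sum)
  expect_equal(as.vector(agg_min[as.character(coarse$dose)]),
               coarse$sum_min)
  expect_equal(as.vector(agg_dep[as.character(coarse$dose)]),
               coarse$group_depth)
})

test_that("mf_max equals mf_min when every alt_depth is one", {
  df <- data.frame(contig = "t1", start = c(50, 80, 120), ref = "C",
                   alt = "T", sample = "s1", alt_depth = 1,
                   total_depth = 100)
  d <- mfData(calculateMF(importTabular(writeTempTable(df)),
                          grouping = "sample"))
  expect_equal(d$mf_min, d$mf_max)
})

test_that("flagged records leave numerators but keep their depth", {
  df <- data.frame(contig = "t1", start = c(100, 200), ref = "C", alt = "T",
                   sample = "s1", alt_depth = c(500, 1), total_depth = 1000)
  ms <- flagGermlineVaf(importTabular(writeTempTable(df)), 0.01)
  d <- mfData(calculateMF(ms, grouping = "sample"))
  expect_equal(d$sum_min, 1)           # germline excluded from counts
  expect_equal(d$group_depth, 2000)    # but still in the denominator
})

test_that("precalculated depths drive MF when sites lack depth", {
  df <- data.frame(contig = "t1", start = c(100, 200), ref = "C", alt = "T",
                   sample = "s1", alt_depth = 1, total_depth = NA)
  ms <- importTabular(writeTempTable(df))
  expect_error(calculateMF(ms, grouping = "sample"), "precalcDepth")
  pd <- data.frame(sample = "s1", group_depth = 5e6)
  d <- mfData(calculateMF(ms, grouping = "sample", precalcDepth = pd))
  expect_equal(d$mf_min, 2 / 5e6)
  # granularity mismatch is an error, not a broadcast
  expect_error(
    calculateMF(ms, grouping = "sample", resolution = "6",
                precalcDepth = pd),
    "context_class")
  pd6 <- data.frame(sample = "s1", context_class = c("C", "T"),
                    group_depth = c(3e6, 2e6))
  d6 <- mfData(calculateMF(ms, grouping = "sample", resolution = "6",
                           precalcDepth = pd6))
  expect_equal(d6$mf_min[d6$subtype == "C>T"], 2 / 3e6)
  expect_error(
    calculateMF(ms, grouping = "sample", resolution = "6",
                precalcDepth = data.frame(sample = "s1",
                                          context_class = "C",
                                          group_depth = 1e6)),
    "context class")
})

test_that("context depth classes tally reference content correctly", {
  # four sites, one per base, each depth 100 -> C:G class 200, T:A 200
  df <- data.frame(contig = "t1", start = 3:6, ref = c("A", "C", "G", "T"),
                   alt = ".", sample = "s1", alt_depth = 0,
                   total_depth = 100)
  ref <- Biostrings::DNAStringSet(c(t1 = "GGACGTAGG"))
  ms <- importTabular(writeTempTable(df), reference = ref)
  d <- mfData(calculateMF(ms, grouping = "sample", resolution = "6"))
  expect_equal(unique(d$group_depth[d$subtype %in% c("C>A", "C>G", "C>T")]),
               200)
  expect_equal(unique(d$group_depth[d$subtype %in% c("T>A", "T>C", "T>G")]),
               200)

  # 96-base class depth equals a per-site tally on a random fixture
  panel <- smallPanel(seed = 3, n_targets = 1, target_length = 2000)
  counts <- referenceContextCounts(panel$reference, resolution = "96")
  seqs <- as.character(panel$reference[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tally <- table(vapply(2:(nchar(seqs) - 1), function(i) {
    ctx <- substr(seqs, i - 1, i + 1)
    mid <- substr(ctx, 2, 2)
    if (mid %in% c("C", "T")) ctx else
      paste(rev(unname(comp[strsplit(ctx, "")[[1]]])), collapse = "")
  }, character(1)))
  expect_equal(counts$n_sites[match(names(tally), counts$context_class)],
               unname(as.integer(tally)))

  # homopolymer: all depth lands in the C:G class
  cc <- referenceContextCounts(
    Biostrings::DNAStringSet(c(h = strrep("C", 50))), resolution = "6")
  expect_equal(cc$context_class, "C")
  expect_equal(cc$n_sites, 50)
})
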