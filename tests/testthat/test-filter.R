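# Filtering rules: germline VAF, SNV-in-germline-MNV, custom column,
# region containment, depth adjustment, and the combined filterMut().

makeFilterFixture <- function() {
  df <- data.frame(
    contig = "t1",
    start = c(100, 101, 150, 200, 250, 300, 101),
    ref = c("C", "ATG", "C", "G", "T", "C", "A"),
    alt = c("T", "TAC", "A", "T", ".", "G", "G"),
    sample = c("s1", "s1", "s1", "s1", "s1", "s1", "s2"),
    alt_depth = c(500, 450, 1, 4, 0, 1, 2),
    total_depth = 1000,
    filter = c("PASS", "PASS", "PASS", "EndRepairFillinArtifact",
               "PASS", "PASS", "PASS"))
  importTabular(writeTempTable(df))
}

test_that("germline VAF flagging is strict and leaves non-variants alone", {
  ms <- flagGermlineVaf(makeFilterFixture(), 0.01)
  rec <- mutData(ms)
  g <- rec[rec$filter_mut, ]
  # 500/1000 and 450/1000 exceed 0.01; the rest do not
  expect_setequal(g$start[g$sample == "s1"], c(100, 101))
  expect_false(any(rec$filter_mut[rec$variation_type == "no_variant"]))
  # boundary: vaf exactly at the cutoff is NOT flagged
  df <- data.frame(contig = "c", start = 10, ref = "A", alt = "G",
                   sample = "s", alt_depth = 10, total_depth = 1000)
  ms2 <- flagGermlineVaf(importTabular(writeTempTable(df)), 0.01)
  expect_false(any(mutData(ms2)$filter_mut))
  expect_error(flagGermlineVaf(ms, 0), "0, 1")
  expect_error(flagGermlineVaf(ms, 1.5), "0, 1")
})

test_that("SNVs inside germline MNVs are flagged per sample, half-open", {
  base <- data.frame(
    contig = "t1", start = c(100, 101, 102, 101),
    ref = c("AT", "C", "C", "C"), alt = c("GC", "T", "T", "T"),
    sample = c("s1", "s1", "s1", "s2"),
    alt_depth = c(480, 2, 2, 2), total_depth = 1000)
  ms <- importTabular(writeTempTable(base))
  ms <- flagGermlineVaf(ms, 0.01)
  ms <- flagSnvInGermMnv(ms)
  rec <- mutData(ms)
  flag_at <- function(smp, pos) {
    any(rec$filter_mut[rec$sample == smp & rec$start == pos &
                         rec$variation_type == "snv"])
  }
  expect_true(flag_at("s1", 101))   # inside [100, 102)
  expect_false(flag_at("s1", 102))  # half-open: end position excluded
  expect_false(flag_at("s2", 101))  # different sample untouched
})

test_that("snv-in-mnv containment matches an interval oracle at all offsets", {
  # germline MNV at [200, 203) (ref length 3); SNVs at every offset
  offs <- -2:4
  df <- data.frame(
    contig = "t1", start = c(200, 200 + offs),
    ref = c("ACG", rep("C", length(offs))),
    alt = c("TGC", rep("T", length(offs))),
    sample = "s1",
    alt_depth = c(490, rep(2, length(offs))), total_depth = 1000)
  ms <- flagSnvInGermMnv(flagGermlineVaf(importTabular(writeTempTable(df)),
                                         0.01))
  rec <- mutData(ms)
  for (o in offs) {
    expected <- (200 + o) >= 200 && (200 + o) < 203
    got <- any(rec$filter_mut[rec$start == 200 + o &
                                rec$variation_type == "snv"])
    expect_identical(got, expected, info = paste("offset", o))
  }
})

test_that("custom-column flagging hits exactly the planted values", {
  ms <- flagCustom(makeFilterFixture(), "filter", "EndRepairFillinArtifact")
  rec <- mutData(ms)
  expect_equal(sum(rec$filter_mut), 1)
  expect_equal(rec$start[rec$filter_mut], 200)
  expect_match(rec$filter_reason[rec$filter_mut], "custom:filter")
  # empty value set flags nothing
  ms0 <- flagCustom(makeFilterFixture(), "filter", character(0))
  expect_equal(sum(mutData(ms0)$filter_mut), 0)
  expect_error(flagCustom(makeFilterFixture(), "nope", "x"), "nope")
  # planted-count check on a larger fixture
  set.seed(9)
  df <- data.frame(contig = "c", start = 1:10 * 10, ref = "A", alt = "G",
                   sample = "s", alt_depth = 1, total_depth = 1000,
                   lab = c(rep("bad", 3), rep("ok", 7)))
  msx <- flagCustom(importTabular(writeTempTable(df)), "lab", "bad")
  expect_equal(sum(mutData(msx)$filter_mut), 3)
})

test_that("region containment removes boundary-straddling records", {
  regions <- makeRegions(data.frame(contig = "t1", start = 100, end = 200,
                                    label = "r1"))
  df <- data.frame(
    contig = c("t1", "t1", "t1", "t2"),
    start = c(150, 198, 120, 50),
    ref = c("C", "CAT", "CA", "A"),
    alt = c("T", "TGC", "C", "G"),
    sample = "s1", alt_depth = 1, total_depth = 100)
  ms <- importTabular(writeTempTable(df))
  res <- applyRegions(ms, regions)
  rec <- mutData(res$x)
  # SNV at 150 kept; 3-bp MNV at 198 spans past end 199 -> removed;
  # 2-bp deletion at 120 inside; off-panel contig removed
  expect_setequal(rec$start, c(150, 120))
  expect_equal(res$removed, 2)
  expect_identical(unique(rec$region), "r1")
})

test_that("depth adjustment spares germline and clamps at zero", {
  ms <- makeFilterFixture()
  ms <- flagGermlineVaf(ms, 0.01)
  ms <- flagCustom(ms, "filter", "EndRepairFillinArtifact")
  before <- mutData(ms)
  germ_before <- sum(before$total_depth[.hasGerm <- grepl(
    "germline", before$filter_reason)])
  ms2 <- adjustDepthForFiltered(ms)
  rec <- mutData(ms2)
  art <- rec[rec$start == 200 & rec$sample == "s1", ]
  expect_equal(art$total_depth, 996)  # 1000 - 4
  expect_equal(art$alt_depth, 0)
  # germline rows keep their depths
  expect_equal(sum(rec$total_depth[grepl("germline", rec$filter_reason)]),
               germ_before)
  # import sanitizes inconsistent depths (alt_depth > total_depth), so
  # subtraction cannot go below zero downstream
  dfc <- data.frame(contig = "c", start = 5, ref = "A", alt = "G",
                    sample = "s", alt_depth = 10, total_depth = 8,
                    lab = "bad")
  msc <- flagCustom(importTabular(writeTempTable(dfc)), "lab", "bad")
  expect_equal(mutData(msc)$total_depth, 10)
  mc <- adjustDepthForFiltered(msc)
  expect_equal(mutData(mc)$total_depth, 0)
  expect_equal(mutData(mc)$alt_depth, 0)
})

test_that("filterMut applies rules in order and reports planted truth", {
  design <- data.frame(sample = paste0("s", 1:3), mf = 2e-6)
  sim <- simulateDataset(design, n_targets = 2, target_length = 700,
                         depth = 2000, n_germline = 2, n_germ_mnv = 1,
                         n_snv_in_germ_mnv = 2, n_artifacts = 4,
                         n_out_of_region = 1, region_margin = 10,
                         seed = 77)
  res <- filterMut(sim$mutations, vaf_cutoff = 0.01, snv_in_germ_mnv = TRUE,
                   custom_filter_col = "filter",
                   custom_filter_val = "EndRepairFillinArtifact",
                   regions = sim$regions,
                   rm_filtered_mut_from_depth = TRUE)
  expect_equal(unname(res$summary["germline"]),
               sim$truth$n_germline_flagged)
  expect_equal(unname(res$summary["snv_in_germ_mnv"]),
               sim$truth$n_snv_in_germ_mnv)
  expect_equal(unname(res$summary["custom"]), sim$truth$n_artifacts)
  expect_equal(unname(res$summary["region_removed"]),
               sim$truth$n_out_of_region)

  # conservation: rows only leave via region removal
  expect_equal(nrow(mutData(res$x)),
               nrow(mutData(sim$mutations)) - res$summary[["region_removed"]])

  # idempotence: same parameters, same result
  res2 <- filterMut(res$x, vaf_cutoff = 0.01, snv_in_germ_mnv = TRUE,
                    custom_filter_col = "filter",
                    custom_filter_val = "EndRepairFillinArtifact",
                    regions = sim$regions,
                    rm_filtered_mut_from_depth = TRUE)
  expect_equal(mutData(res2$x), mutData(res$x))

  # no parameters: identity
  res0 <- filterMut(sim$mutations)
  expect_equal(mutData(res0$x), mutData(sim$mutations))
  expect_true(all(res0$summary == 0))

  # drop removes exactly the flagged rows
  resd <- filterMut(sim$mutations, vaf_cutoff = 0.01, snv_in_germ_mnv = TRUE,
                    custom_filter_col = "filter",
                    custom_filter_val = "EndRepairFillinArtifact",
                    regions = sim$regions, drop = TRUE)
  expect_equal(nrow(mutData(resd$x)),
               nrow(mutData(res$x)) - sum(mutData(res$x)$filter_mut))
  expect_false(any(mutData(resd$x)$filter_mut))
})
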