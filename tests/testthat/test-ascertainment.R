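## compact variant-set builder for filter tests
mk_vs <- function(pos, ref, alt, contig = "c1",
                  hap = "hom_ref", dip = "het",
                  hap_conf = 10, dip_conf = 10,
                  source = "RAD", info = NULL) {
  n <- length(pos)
  type <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP", "InDel")
  variant_set(
    data.frame(contig = rep_len(contig, n), pos = pos, ref = ref,
               alt = alt, type = type, stringsAsFactors = FALSE),
    cbind(single_haploid = rep_len(hap, n),
          pool_diploid = rep_len(dip, n)),
    cbind(single_haploid = rep_len(hap_conf, n),
          pool_diploid = rep_len(dip_conf, n)),
    source = source, info = info)
}

test_that("confidence nulling applies the strictly-lower rule per source", {
  ## RAD: GT_CONF 2.9 nulled, 3.0 kept
  vs <- mk_vs(c(10, 50), "A", "C", hap_conf = c(2.9, 3.0))
  out <- null_low_confidence_calls(vs)
  expect_true(is.na(out$variants$calls[1, "single_haploid"]))
  expect_false(is.na(out$variants$calls[2, "single_haploid"]))
  ## RNA: GQ 30 exactly is retained, 29.9 nulled
  vr <- mk_vs(c(10, 50), "A", "C", source = "RNA",
              hap_conf = 100, dip_conf = c(30, 29.9))
  outr <- null_low_confidence_calls(vr)
  expect_false(is.na(outr$variants$calls[1, "pool_diploid"]))
  expect_true(is.na(outr$variants$calls[2, "pool_diploid"]))
  ## both samples nulled => site removed
  vb <- mk_vs(c(10, 80), "A", "C", hap_conf = c(1, 10),
              dip_conf = c(2, 10))
  outb <- null_low_confidence_calls(vb)
  expect_equal(length(outb$variants), 1)
  expect_equal(nrow(outb$removed), 1)
  expect_equal(outb$removed$pos, 10)
  ## missing confidence counts as sub-threshold and is logged
  vm <- mk_vs(100, "A", "C", hap_conf = NA_real_)
  expect_message(outm <- null_low_confidence_calls(vm), "missing")
  expect_true(is.na(outm$variants$calls[1, "single_haploid"]))
})

test_that("indel vicinity tagging is inclusive over the reference span", {
  ## deletion spanning 200..202; SNPs at inclusive boundary and beyond
  vs <- mk_vs(c(200, 262, 263, 139, 140),
              c("ATG", "A", "A", "A", "A"),
              c("A", "C", "C", "C", "C"))
  led <- tag_indels_and_gap(vs, new_filter_ledger(vs))
  expect_true(led$tags[1, "TypeIndel"])
  expect_true(led$tags[2, "SnpGap"])    # 262 - 202 = 60, inclusive
  expect_false(led$tags[3, "SnpGap"])   # 61 > 60
  expect_false(led$tags[4, "SnpGap"])   # 200 - 139 = 61
  expect_true(led$tags[5, "SnpGap"])    # 200 - 140 = 60
  ## SNP-only contig: no gap tags
  vs2 <- mk_vs(c(100, 300), "A", "G")
  led2 <- tag_indels_and_gap(vs2, new_filter_ledger(vs2))
  expect_equal(sum(led2$tags[, "SnpGap"]), 0)
})

test_that("SNP cluster tagging is symmetric with inclusive window", {
  vs <- mk_vs(c(100, 125), "A", "C")
  led <- tag_snp_clusters(vs, new_filter_ledger(vs))
  expect_true(all(led$tags[, "snpCluster"]))       # distance 25
  vs2 <- mk_vs(c(100, 131), "A", "C")
  led2 <- tag_snp_clusters(vs2, new_filter_ledger(vs2))
  expect_false(any(led2$tags[, "snpCluster"]))     # distance 31
  vs3 <- mk_vs(100, "A", "C")
  led3 <- tag_snp_clusters(vs3, new_filter_ledger(vs3))
  expect_false(any(led3$tags[, "snpCluster"]))
  ## indels never participate in SNP clusters
  vs4 <- mk_vs(c(100, 110), c("A", "AT"), c("C", "A"))
  led4 <- tag_snp_clusters(vs4, new_filter_ledger(vs4))
  expect_false(any(led4$tags[, "snpCluster"]))
})

test_that("masked-interval detection matches the exhaustive oracle", {
  cfg <- ascertainment_config()
  ## 40-base poly-A flanked by random sequence: one homopolymer interval
  set.seed(1)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  sq <- paste0("CGTC", strrep("A", 40), "CGTG")
  m <- detect_masked_intervals(c(x = sq), cfg)
  hp <- m[m$type == "homopolymer", ]
  expect_equal(nrow(hp), 1)
  expect_equal(c(hp$start, hp$end), c(5, 44))
  ## ACGT repeated 25x: no homopolymer; DUST equals the oracle
  sq2 <- strrep("ACGT", 25)
  m2 <- detect_masked_intervals(c(x = sq2), cfg)
  expect_equal(nrow(m2[m2$type == "homopolymer", ]), 0)
  ora2 <- oracle_dust_intervals(sq2)
  lcr2 <- m2[m2$type == "lcr", ]
  expect_equal(lcr2$start, ora2$start)
  expect_equal(lcr2$end, ora2$end)
  ## random 1 kb sequences: interval set equals the brute-force oracle's
  for (s in 1:3) {
    set.seed(s)
    sq3 <- paste0(rnd(400), strrep("AT", 40), rnd(300),
                  strrep("G", 12), rnd(200))
    m3 <- detect_masked_intervals(c(x = sq3), cfg)
    lcr3 <- m3[m3$type == "lcr", ]
    ora3 <- oracle_dust_intervals(sq3)
    expect_equal(lcr3$start, ora3$start, info = paste("seed", s))
    expect_equal(lcr3$end, ora3$end, info = paste("seed", s))
  }
})

test_that("low-complexity and homopolymer interval tagging", {
  mask <- data.frame(contig = "c1", start = c(100, 300), end = c(150, 307),
                     type = c("lcr", "homopolymer"))
  vs <- mk_vs(c(100, 150, 151, 310, 313, 99), "A", "C")
  led <- tag_low_complexity(vs, new_filter_ledger(vs), mask)
  expect_true(led$tags[1, "LowComplexityRegion"])   # interval start
  expect_true(led$tags[2, "LowComplexityRegion"])   # interval end
  expect_false(led$tags[3, "LowComplexityRegion"])  # first base after
  expect_false(led$tags[6, "LowComplexityRegion"])  # last base before
  expect_true(led$tags[4, "Homopolymer"])           # 3 bases from run
  expect_false(led$tags[5, "Homopolymer"])          # 6 > margin 5
  ## empty interval set: zero tags
  led0 <- tag_low_complexity(vs, new_filter_ledger(vs),
                             mask[0, , drop = FALSE])
  expect_equal(sum(led0$tags), 0)
})

test_that("hard-filter thresholds are strict and RNA-only", {
  info <- data.frame(QD = c(1.5, 2.0, NA), FS = c(NA, 60.0, NA),
                     MQ = c(NA, 40.0, NA), MQRankSum = c(NA, -12.5, NA),
                     ReadPosRankSum = c(NA, -8.0, NA),
                     SOR = c(NA, 3.0, NA))
  vs <- mk_vs(c(10, 50, 90), "A", "C", source = "RNA", info = info)
  led <- tag_hard_filter(vs, new_filter_ledger(vs))
  expect_true(led$tags[1, "FailureOnGatkHardFilter"])   # QD 1.5 < 2
  expect_false(led$tags[2, "FailureOnGatkHardFilter"])  # all at threshold
  expect_false(led$tags[3, "FailureOnGatkHardFilter"])  # absent
  ## RAD variant sets are a no-op
  vr <- mk_vs(10, "A", "C", source = "RAD")
  ledr <- tag_hard_filter(vr, new_filter_ledger(vr))
  expect_equal(sum(ledr$tags), 0)
})

test_that("haploid consistency tagging", {
  vs <- mk_vs(c(10, 50, 90), "A", "C",
              hap = c("het", "hom_alt", "hom_ref"))
  calls <- vs$calls
  calls[3, "single_haploid"] <- NA
  vs <- variant_set(vs$variants, calls, vs$conf, vs$source)
  led <- tag_haploid_inconsistency(vs, new_filter_ledger(vs))
  expect_equal(unname(led$tags[, "FailHaploidTest"]),
               c(TRUE, FALSE, FALSE))
  ## missing haploid sample: warning, no tags
  vs2 <- variant_set(vs$variants,
                     matrix(vs$calls[, 2], ncol = 1,
                            dimnames = list(NULL, "pool_diploid")),
                     matrix(vs$conf[, 2], ncol = 1,
                            dimnames = list(NULL, "pool_diploid")),
                     vs$source)
  expect_warning(led2 <- tag_haploid_inconsistency(
    vs2, new_filter_ledger(vs2)), "skipped")
  expect_equal(sum(led2$tags), 0)
})

test_that("single-probe allele compatibility", {
  vs <- mk_vs(c(10, 50, 90, 130), c("A", "G", "C", "T"),
              c("T", "T", "G", "C"))
  led <- tag_allele_compatibility(vs, new_filter_ledger(vs))
  ## A/T tagged, G/T allowed, C/G tagged, T/C == unordered C/T allowed
  expect_equal(unname(led$tags[, "NonSingleProbeType"]),
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("excluded-contig tagging records reasons with set semantics", {
  vs <- mk_vs(c(10, 50, 90, 200), "A", "C",
              contig = c("c1", "c1", "c1", "c2"))
  led <- tag_excluded_contigs(vs, new_filter_ledger(vs),
                              list(transposon = "c1",
                                   similarity = c("c1")))
  expect_equal(sum(led$tags[, "ExcludedContig"]), 3)
  expect_setequal(led$exclusion_reasons[["c1"]],
                  c("transposon", "similarity"))
  ## empty lists: nothing tagged; unknown ids warned and ignored
  led0 <- tag_excluded_contigs(vs, new_filter_ledger(vs), list())
  expect_equal(sum(led0$tags), 0)
  expect_warning(tag_excluded_contigs(vs, new_filter_ledger(vs),
                                      list(transposon = "nope")),
                 "unknown")
})

test_that("flank-length tagging against contig ends", {
  vs <- mk_vs(c(35, 36, 65, 66, 30), "A", "C")
  led <- tag_short_flanks(vs, new_filter_ledger(vs), c(c1 = 100))
  expect_equal(unname(led$tags[, "FlankTooShort"]),
               c(TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("ledger summary accounting and catalog selection", {
  d <- simulate_discovery_dataset(discovery_sim_config(n_contigs = 40,
                                                       seed = 5))
  asc <- ascertain_variants(d$variants, d$reference, mask = d$mask,
                            excluded = d$excluded)
  sm <- summarize_filter_ledger(asc)
  n_total <- sm$count[sm$item == "total_raw_variants"]
  expect_equal(n_total, length(d$variants))
  ## retained + tagged SNPs + indels + removed = total
  v <- asc$variants$variants
  tagged <- rowSums(asc$ledger$tags) > 0
  retained <- sm$count[sm$item == "retained"]
  expect_equal(retained, sum(v$type == "SNP" & !tagged))
  ## retained + variants with >= 1 tag + removed = total (indels always
  ## carry TypeIndel, so every non-retained survivor is tagged)
  expect_equal(retained + sum(tagged) + nrow(asc$removed), n_total)
  cat_df <- select_catalog(asc)
  expect_equal(nrow(cat_df), retained)
  expect_true(all(cat_df$status == "PASS"))
  expect_equal(attr(cat_df, "mean_snps_per_contig"),
               round(nrow(cat_df) /
                       length(unique(cat_df$contig)), 2))
  ## all-clean variant set: retained equals total SNPs
  vs <- mk_vs(c(100, 200, 300), "A", c("C", "G", "C"))
  asc2 <- ascertain_variants(vs, excluded = list(),
                             haploid_sample = NULL)
  sm2 <- summarize_filter_ledger(asc2)
  expect_equal(sm2$count[sm2$item == "retained"], 3)
})

test_that("tagging is order-independent", {
  d <- simulate_discovery_dataset(discovery_sim_config(n_contigs = 25,
                                                       seed = 9))
  nul <- null_low_confidence_calls(d$variants)
  v <- nul$variants
  cfg <- ascertainment_config()
  ops <- list(
    function(l) tag_indels_and_gap(v, l, cfg),
    function(l) tag_snp_clusters(v, l, cfg),
    function(l) tag_low_complexity(v, l, d$mask, cfg),
    function(l) tag_haploid_inconsistency(v, l),
    function(l) tag_allele_compatibility(v, l, cfg),
    function(l) tag_short_flanks(v, l, nchar(d$reference), cfg),
    function(l) tag_excluded_contigs(v, l, d$excluded))
  run_in_order <- function(ord) {
    led <- new_filter_ledger(v)
    for (i in ord) led <- ops[[i]](led)
    led$tags
  }
  set.seed(1)
  ref_tags <- run_in_order(seq_along(ops))
  for (rep in 1:3)
    expect_identical(run_in_order(sample(seq_along(ops))), ref_tags)
})

test_that("gap and cluster tag counts are monotone in window size", {
  d <- simulate_discovery_dataset(discovery_sim_config(
    n_contigs = 30, indel_rate = 0.004, seed = 14))
  v <- null_low_confidence_calls(d$variants)$variants
  gap_counts <- cluster_counts <- c()
  for (w in c(10, 30, 60, 120)) {
    cfg <- ascertainment_config(snp_gap_window = w, cluster_window = w)
    g <- tag_indels_and_gap(v, new_filter_ledger(v), cfg)
    c2 <- tag_snp_clusters(v, new_filter_ledger(v), cfg)
    gap_counts <- c(gap_counts, sum(g$tags[, "SnpGap"]))
    cluster_counts <- c(cluster_counts, sum(c2$tags[, "snpCluster"]))
  }
  expect_true(all(diff(gap_counts) >= 0))
  expect_true(all(diff(cluster_counts) >= 0))
})
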