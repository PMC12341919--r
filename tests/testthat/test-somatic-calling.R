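## Boundary fixtures build read stacks at one site and run the real pileup ->
## control-mask -> filter-cascade path end to end.

ref400 <- random_ref(400, seed = 10)
AT <- 200L
RB <- substring(ref400, AT, AT)
ALTB <- setdiff(c("A", "C", "G", "T"), RB)[1]
REFV <- c(chr1 = ref400)

ctl_pile <- function(n_ref, indel = FALSE, n_alt = 0L, alt_qual = "5") {
  reads <- make_stack(ref400, AT, n_ref, RB, qprefix = "c")
  if (n_alt > 0)
    reads <- rbind(reads, make_stack(ref400, AT, n_alt, ALTB,
                                     qual_at = alt_qual, qprefix = "ca"))
  if (indel) {
    del <- alignment_set(qname = "cd", rname = "chr1", pos = AT - 50L,
                         cigar = "49M2D49M",
                         seq = paste0(substring(ref400, AT - 50L, AT - 2L),
                                      substring(ref400, AT + 1L, AT + 49L)),
                         qual = strrep("G", 98), AS = 88L, NM = 2L,
                         seqlengths = c(chr1 = 400L))
    reads <- rbind(reads, del)
  }
  pileup_table(reads, REFV, count_thresholds(0, 0))
}

mut_pile <- function(n_ref, n_alt, alt_strands = NULL, ref_nm = 0L,
                     alt_nm = 1L, alt_qual = "G", alt_mapq = 60L,
                     third_allele = 0L) {
  reads <- make_stack(ref400, AT, n_ref, RB, nm = rep(ref_nm, n_ref),
                      qprefix = "m")
  if (n_alt > 0)
    reads <- rbind(reads, make_stack(ref400, AT, n_alt, ALTB,
                                     strand = alt_strands,
                                     qual_at = alt_qual, mapq = alt_mapq,
                                     nm = rep(alt_nm, n_alt), qprefix = "ma"))
  if (third_allele > 0) {
    b3 <- setdiff(c("A", "C", "G", "T"), c(RB, ALTB))[1]
    reads <- rbind(reads, make_stack(ref400, AT, third_allele, b3,
                                     nm = 1L, qprefix = "m3"))
  }
  pileup_table(reads, REFV, count_thresholds(10, 30))
}

ctl_all <- structure(list(mode = "diploid",
                          positions = data.table(rname = "chr1", pos = AT)),
                     class = "control_positions")
ctl_all_hap <- structure(list(mode = "haploid",
                              positions = data.table(rname = "chr1", pos = AT)),
                         class = "control_positions")
cfg_dip <- mode_config("diploid")
cfg_hap <- mode_config("haploid")

test_that("control mask applies the printed coverage boundaries exactly", {
  ## diploid: >= 20x in, 19x out
  in20 <- build_control_positions(ctl_pile(20), cfg_dip)$positions
  expect_true(any(in20$rname == "chr1" & in20$pos == AT))
  out19 <- build_control_positions(ctl_pile(19), cfg_dip)$positions
  expect_false(any(out19$rname == "chr1" & out19$pos == AT))
  ## haploid: above 40x means >= 41
  in41 <- build_control_positions(ctl_pile(41), cfg_hap)$positions
  expect_true(any(in41$pos == AT))
  out40 <- build_control_positions(ctl_pile(40), cfg_hap)$positions
  expect_false(any(out40$pos == AT))
})

test_that("any alternate evidence or indel disqualifies a control position", {
  ## one low-quality alt base at lenient counting
  p <- build_control_positions(ctl_pile(50, n_alt = 1L), cfg_dip)$positions
  expect_false(any(p$pos == AT))
  ## indel evidence
  p2 <- build_control_positions(ctl_pile(50, indel = TRUE), cfg_dip)$positions
  expect_false(any(p2$pos == AT))
  expect_true(any(p2$pos == AT - 40L))  # away from the indel footprint
})

test_that("control mask refuses non-lenient pileups", {
  strict <- pileup_table(make_stack(ref400, AT, 30, RB), REFV,
                         count_thresholds(10, 30))
  expect_error(build_control_positions(strict, cfg_dip), "lenient")
})

test_that("alt support boundaries: 2 vs 3 reads, both strands", {
  calls3 <- call_somatic_candidates(
    mut_pile(40, 3, alt_strands = c("+", "+", "-")), ctl_all, cfg_dip)
  expect_equal(nrow(calls3), 1)
  expect_equal(calls3$alt_count, 3L)
  expect_equal(calls3$alt_fwd, 2L)
  expect_equal(calls3$alt_rev, 1L)
  calls2 <- call_somatic_candidates(
    mut_pile(40, 2, alt_strands = c("+", "-")), ctl_all, cfg_dip)
  expect_equal(nrow(calls2), 0)
  ## 3 reads all on one strand fail
  calls_one_strand <- call_somatic_candidates(
    mut_pile(40, 3, alt_strands = c("+", "+", "+")), ctl_all, cfg_dip)
  expect_equal(nrow(calls_one_strand), 0)
  expect_equal(attr(calls_one_strand, "drop_counts")[["alt_support"]], 1L)
})

test_that("mutant coverage caps are inclusive: 70/71 and 120/121", {
  ## diploid: depth 70 passes, 71 fails
  c70 <- call_somatic_candidates(mut_pile(67, 3, c("+", "+", "-")),
                                 ctl_all, cfg_dip)
  expect_equal(c70$depth, 70L)
  expect_equal(nrow(c70), 1)
  c71 <- call_somatic_candidates(mut_pile(68, 3, c("+", "+", "-")),
                                 ctl_all, cfg_dip)
  expect_equal(nrow(c71), 0)
  expect_equal(attr(c71, "drop_counts")[["depth_cap"]], 1L)
  ## haploid: 120 passes, 121 fails
  c120 <- call_somatic_candidates(mut_pile(117, 3, c("+", "+", "-")),
                                  ctl_all_hap, cfg_hap)
  expect_equal(nrow(c120), 1)
  c121 <- call_somatic_candidates(mut_pile(118, 3, c("+", "+", "-")),
                                  ctl_all_hap, cfg_hap)
  expect_equal(nrow(c121), 0)
})

test_that("stringent counting enforces BQ 30 and MAPQ 10 boundaries", {
  ## alt bases at Q29 are not counted at all -> no candidate
  q29 <- call_somatic_candidates(
    mut_pile(40, 3, c("+", "+", "-"), alt_qual = rawToChar(as.raw(29 + 33))),
    ctl_all, cfg_dip)
  expect_equal(nrow(q29), 0)
  q30 <- call_somatic_candidates(
    mut_pile(40, 3, c("+", "+", "-"), alt_qual = rawToChar(as.raw(30 + 33))),
    ctl_all, cfg_dip)
  expect_equal(nrow(q30), 1)
  m9 <- call_somatic_candidates(
    mut_pile(40, 3, c("+", "+", "-"), alt_mapq = 9L), ctl_all, cfg_dip)
  expect_equal(nrow(m9), 0)
  m10 <- call_somatic_candidates(
    mut_pile(40, 3, c("+", "+", "-"), alt_mapq = 10L), ctl_all, cfg_dip)
  expect_equal(nrow(m10), 1)
})

test_that("mismatch filters use the 0.01 boundary on 0.001-resolution input", {
  ## reads of aligned length 100: NM=1 -> exactly 0.01 (passes)
  ok <- call_somatic_candidates(mut_pile(40, 3, c("+", "+", "-"),
                                         ref_nm = 1L, alt_nm = 2L),
                                ctl_all, cfg_dip)
  ## ref_mm = 0.01 passes; delta = 0.01 passes
  expect_equal(nrow(ok), 1)
  expect_equal(ok$ref_mm, 0.01)
  expect_equal(ok$alt_mm - ok$ref_mm, 0.01)
  ## ref reads with NM=2 -> 0.02 > 0.01 fails the reference filter
  bad_ref <- call_somatic_candidates(mut_pile(40, 3, c("+", "+", "-"),
                                              ref_nm = 2L, alt_nm = 2L),
                                     ctl_all, cfg_dip)
  expect_equal(nrow(bad_ref), 0)
  expect_equal(attr(bad_ref, "drop_counts")[["ref_mismatch"]], 1L)
  ## alt 0.02 vs ref 0.00: delta 0.02 fails
  bad_delta <- call_somatic_candidates(mut_pile(40, 3, c("+", "+", "-"),
                                                ref_nm = 0L, alt_nm = 3L),
                                       ctl_all, cfg_dip)
  expect_equal(nrow(bad_delta), 0)
  expect_equal(attr(bad_delta, "drop_counts")[["mismatch_delta"]], 1L)
})

test_that("biallelic and control-membership requirements hold", {
  tri <- call_somatic_candidates(mut_pile(40, 4, c("+", "+", "-", "-"),
                                          third_allele = 2L),
                                 ctl_all, cfg_dip)
  expect_equal(nrow(tri), 0)
  expect_equal(attr(tri, "drop_counts")[["biallelic"]], 1L)
  no_ctl <- structure(list(mode = "diploid",
                           positions = data.table(rname = character(0),
                                                  pos = integer(0))),
                      class = "control_positions")
  masked <- call_somatic_candidates(mut_pile(40, 3, c("+", "+", "-")),
                                    no_ctl, cfg_dip)
  expect_equal(nrow(masked), 0)
  expect_equal(attr(masked, "drop_counts")[["in_control"]], 1L)
})

test_that("emitted calls pass independent brute-force re-verification", {
  pile <- mut_pile(40, 5, c("+", "+", "-", "-", "+"))
  calls <- call_somatic_candidates(pile, ctl_all, cfg_dip)
  expect_equal(nrow(calls), 1)
  expect_true(brute_verify_call(as.list(calls[1]), pile, ctl_all, cfg_dip))
  expect_equal(calls$vaf, 5 / 45)
  expect_match(calls$filter_trace, "in_control.*mismatch_delta")
})

test_that("tightening any threshold never increases the call count", {
  study <- simulate_paired_study(chrom_len = 3e4, n_per_layer = c(L2 = 10),
                                 depth = 60, seed = 12)
  refs <- genome_references(study$genome)
  mp <- partition_alignments(study$mutant$hap, study$mutant$dip)
  cp <- partition_alignments(study$control$hap, study$control$dip)
  cfg <- mode_config("diploid")
  ctl <- build_control_positions(
    pileup_table(cp$diploid, refs$diploid, count_thresholds(0, 0)), cfg)
  pile <- pileup_table(mp$diploid, refs$diploid, count_thresholds(10, 30))
  n_base <- nrow(call_somatic_candidates(pile, ctl, cfg))
  tweak <- function(field, value) { x <- cfg; x[[field]] <- value; x }
  tighter <- list(tweak("min_alt_reads", 5L),
                  tweak("mutant_max_cov", 40L),
                  tweak("max_ref_mismatch", 0.001),
                  tweak("max_mismatch_delta", 0.001))
  for (tcfg in tighter)
    expect_lte(nrow(call_somatic_candidates(pile, ctl, tcfg)), n_base)
})

test_that("reciprocal mutant/control calling yields disjoint sets", {
  study <- simulate_paired_study(chrom_len = 3e4, n_per_layer = c(L2 = 8),
                                 depth = 60, seed = 23)
  fwd <- run_dual_calling(study)
  swapped <- study
  swapped$mutant <- study$control
  swapped$control <- study$mutant
  rev_ <- run_dual_calling(swapped)
  k1 <- paste(fwd$merged$key_rname, fwd$merged$key_pos, fwd$merged$alt)
  k2 <- paste(rev_$merged$key_rname, rev_$merged$key_pos, rev_$merged$alt)
  expect_length(intersect(k1, k2), 0)
  expect_gt(length(k1), 0)
})

test_that("call-set merging collapses, keeps provenance and flags conflicts", {
  cm <- data.table(hap_rname = "chr1", hap_start = 1L, hap_end = 1000L,
                   dip_rname = c("chr1_hapA", "chr1_hapB"), dip_start = 1L)
  mk_calls <- function(rname, pos, alt, mode) {
    structure(data.table(rname = rname, pos = pos, ref = "A", alt = alt,
                         alt_count = 5L, alt_fwd = 3L, alt_rev = 2L,
                         depth = 20L, vaf = 0.25, ref_mm = 0, alt_mm = 0.005,
                         mode = mode, sample_label = "upper",
                         filter_trace = ""),
              class = c("somatic_calls", "data.table", "data.frame"))
  }
  ## disjoint 173 + 25 -> 198
  hap <- mk_calls("chr1", 1:173, "T", "haploid")
  dip <- mk_calls("chr1_hapA", 301:325, "T", "diploid")
  merged <- merge_call_sets(hap, dip, cm)
  expect_equal(nrow(merged), 198)
  expect_false(any(merged$conflict))
  ## identical site+allele collapses with dual provenance
  m2 <- merge_call_sets(mk_calls("chr1", 10L, "T", "haploid"),
                        mk_calls("chr1_hapB", 10L, "T", "diploid"), cm)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$provenance, "diploid,haploid")
  expect_equal(m2$key_pos, 10L)
  ## same site, different alt: both kept, flagged
  m3 <- merge_call_sets(mk_calls("chr1", 10L, "T", "haploid"),
                        mk_calls("chr1_hapA", 10L, "G", "diploid"), cm)
  expect_equal(nrow(m3), 2)
  expect_true(all(m3$conflict))
  ## empty inputs
  m4 <- merge_call_sets(hap[0], dip[0], cm)
  expect_equal(nrow(m4), 0)
})

test_that("coordinate map projects diploid calls and skips divergent blocks", {
  g <- simulate_diploid_genome(1, 2e4, het_rate = 0.01,
                               divergent_spec = c(1000L), seed = 31)
  cm <- build_coord_map(g)
  bl <- g$divergent_blocks
  ## hapA rows cover the whole chromosome; hapB rows exclude the block
  a_rows <- cm[cm$dip_rname == "chr1_hapA", ]
  expect_equal(a_rows$hap_start, 1L)
  expect_equal(a_rows$hap_end, 2e4L)
  b_rows <- cm[cm$dip_rname == "chr1_hapB", ]
  inside_block <- b_rows$hap_start <= bl$start & b_rows$hap_end >= bl$end
  expect_false(any(inside_block))
})

test_that("effective sites count strictly-above-threshold positions", {
  expect_equal(compute_effective_sites(c(10L, 21L, 20L, 25L), 20L), 2L)
  expect_equal(compute_effective_sites(integer(100), 20L), 0L)
  g <- simulate_diploid_genome(1, 3e4, het_rate = 0, seed = 40)
  sim <- simulate_reads(g, NULL, depth = 60, error_rate = 0, seed = 40)
  hap <- emit_truth_alignments(sim, "haploid")
  d <- depth_track(hap, "chr1", c(1L, 3e4L))
  eff <- compute_effective_sites(d, 20L)
  expect_gt(eff, 0.98 * 3e4)
  expect_lte(eff, 3e4)
})
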