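test_that("zero heterozygosity and no blocks give identical haplotypes", {
  g <- simulate_diploid_genome(1, 1e4, het_rate = 0, seed = 5)
  expect_identical(g$hapA, g$hapB)
  expect_equal(nrow(g$het_variants), 0)
  expect_equal(nrow(g$divergent_blocks), 0)
})

test_that("het SNV count matches the binomial model at the default rate", {
  g <- simulate_diploid_genome(1, 1e6, het_rate = 0.016, seed = 42)
  n <- nrow(g$het_variants)
  bounds <- qbinom(c(0.0005, 0.9995), 1e6, 0.016)
  expect_gte(n, bounds[1])
  expect_lte(n, bounds[2])
  ## hapA and hapB differ exactly at the recorded het sites
  a <- strsplit(g$hapA[[1]], "")[[1]]
  b <- strsplit(g$hapB[[1]], "")[[1]]
  expect_identical(which(a != b), g$het_variants$pos)
})

test_that("genome simulation is deterministic and validates inputs", {
  g1 <- simulate_diploid_genome(1, 1e4, 0.02, c(500L), seed = 9)
  g2 <- simulate_diploid_genome(1, 1e4, 0.02, c(500L), seed = 9)
  expect_identical(g1$hapA, g2$hapA)
  expect_identical(g1$het_variants, g2$het_variants)
  g3 <- simulate_diploid_genome(1, 1e4, 0.02, c(500L), seed = 10)
  expect_false(identical(g1$hapA, g3$hapA))
  expect_error(simulate_diploid_genome(1, 1e4, het_rate = 0.2), "het_rate")
  expect_error(simulate_diploid_genome(1, 1e4, divergent_spec = c(9000L)),
               "divergent blocks")
})

test_that("divergent blocks replace hapB with unrelated same-length sequence", {
  g <- simulate_diploid_genome(1, 2e4, het_rate = 0, divergent_spec = c(1000L),
                               seed = 3)
  bl <- g$divergent_blocks
  expect_equal(nrow(bl), 1)
  expect_equal(bl$end - bl$start + 1L, 1000L)
  a <- strsplit(g$hapA[[1]], "")[[1]]
  b <- strsplit(g$hapB[[1]], "")[[1]]
  inside <- bl$start:bl$end
  expect_gt(sum(a[inside] != b[inside]), 600)  # unrelated ~ 75% mismatch
  expect_identical(a[-inside], b[-inside])
})

test_that("implants record the layer VAF expectation", {
  g <- simulate_diploid_genome(1, 5e4, seed = 2)
  imp <- implant_somatic_mutations(
    g, layer_fractions = c(L1 = 0.18, L2 = 0.60, L3 = 0.22),
    n_per_layer = 5, cell_fraction = 1.0, seed = 2)
  expect_equal(nrow(imp), 15)
  expect_equal(imp[imp$layer == "L2", ]$expected_vaf, rep(0.3, 5))
  expect_equal(imp[imp$layer == "L1", ]$expected_vaf, rep(0.09, 5))
  expect_true(all(imp[imp$layer == "L1", ]$expected_vaf < 0.1))
  expect_true(all(imp$ref != imp$alt))
  ## avoid het sites and collisions
  expect_false(any(imp$pos %in% g$het_variants$pos))
  expect_false(any(duplicated(imp$pos)))

  expect_equal(nrow(implant_somatic_mutations(g, n_per_layer = 0, seed = 1)), 0)
  expect_error(implant_somatic_mutations(
    g, layer_fractions = c(L1 = 0.5, L2 = 0.6), n_per_layer = 1, seed = 1),
    "sum to 1")
  small <- simulate_diploid_genome(1, 1e4, het_rate = 0, seed = 1)
  expect_error(implant_somatic_mutations(small, n_per_layer = 4000, seed = 1),
               "only")
})

test_that("error-free reads are exact substrings of their source haplotype", {
  g <- simulate_diploid_genome(1, 2e4, seed = 8)
  sim <- simulate_reads(g, NULL, depth = 10, error_rate = 0, seed = 8)
  r <- sim$reads
  for (i in sample.int(nrow(r), 50)) {
    src <- if (r$haplotype[i] == "A") g$hapA[[r$chrom[i]]] else g$hapB[[r$chrom[i]]]
    expect_identical(r$seq[i], substring(src, r$start[i], r$end[i]))
  }
  expect_equal(unique(r$n_err), 0L)
})

test_that("coverage matches the requested depth", {
  g <- simulate_diploid_genome(1, 1e5, seed = 4)
  sim <- simulate_reads(g, NULL, depth = 60, seed = 4)
  cov <- numeric(1e5)
  r <- sim$reads
  for (i in seq_len(nrow(r))) cov[r$start[i]:r$end[i]] <- cov[r$start[i]:r$end[i]] + 1
  interior <- cov[500:(1e5 - 500)]
  expect_lt(abs(mean(interior) - 60) / 60, 0.05)
})

test_that("observed implant VAF follows the binomial around the layer expectation", {
  g <- simulate_diploid_genome(1, 1e5, seed = 21)
  imp <- implant_somatic_mutations(g, n_per_layer = c(L2 = 50),
                                   cell_fraction = 1.0, seed = 21)
  sim <- simulate_reads(g, imp, depth = 100, seed = 21)
  r <- sim$reads
  vafs <- numeric(nrow(imp))
  in_band <- logical(nrow(imp))
  for (k in seq_len(nrow(imp))) {
    ov <- r$start <= imp$pos[k] & r$end >= imp$pos[k]
    n_ov <- sum(ov)
    carrier <- ov & grepl(paste0("(^|,)", imp$id[k], "($|,)"), r$carried)
    vafs[k] <- sum(carrier) / n_ov
    ## 99% binomial band around the expectation; with 50 implants a small
    ## number of band misses is itself the expected outcome
    band <- qbinom(c(0.005, 0.995), n_ov, imp$expected_vaf[k]) / n_ov
    in_band[k] <- vafs[k] >= band[1] & vafs[k] <= band[2]
  }
  expect_lte(sum(!in_band), 3)   # P(>3 misses | 50 draws at 1%) < 0.002
  ## bias of the mean across >= 50 implants
  expect_lt(abs(mean(vafs) - 0.3), 0.02)
})

test_that("truth alignments carry exact BWA-convention scores", {
  expect_equal(alignment_score(100, 1), 95)   # 1 mismatch: 99 - 4
  expect_equal(alignment_score(100, 0), 100)
  expect_equal(alignment_score(150, 2), 140)

  g <- simulate_diploid_genome(1, 2e4, seed = 6)
  sim <- simulate_reads(g, NULL, depth = 15, seed = 6)
  for (mode in c("haploid", "diploid")) {
    aln <- emit_truth_alignments(sim, mode)
    refs <- genome_references(sim$genome)[[mode]]
    m <- aln[aln$mapped, ]
    for (i in sample.int(nrow(m), 40)) {
      ref_span <- substring(refs[[m$rname[i]]], m$pos[i],
                            m$pos[i] + nchar(m$seq[i]) - 1L)
      nm <- sum(strsplit(m$seq[i], "")[[1]] != strsplit(ref_span, "")[[1]])
      expect_equal(m$NM[i], nm)
      expect_equal(m$AS[i], alignment_score(nchar(m$seq[i]), nm))
    }
  }
})

test_that("diploid-mode MAPQ is 0 exactly on haplotype-identical spans", {
  g <- simulate_diploid_genome(1, 3e4, het_rate = 0.016, seed = 13)
  sim <- simulate_reads(g, NULL, depth = 10, error_rate = 0, seed = 13)
  dip <- emit_truth_alignments(sim, "diploid")
  het <- g$het_variants$pos
  spans_het <- vapply(seq_len(nrow(dip)), function(i)
    any(het >= dip$pos[i] & het <= dip$pos[i] + 149L), logical(1))
  expect_identical(dip$mapq == 60L, spans_het)
  expect_identical(dip$mapq %in% c(0L, 60L), rep(TRUE, nrow(dip)))
})

test_that("divergent-block hapB reads are unmapped in haploid mode only", {
  g <- simulate_diploid_genome(1, 3e4, het_rate = 0, divergent_spec = c(2000L),
                               seed = 17)
  sim <- simulate_reads(g, NULL, depth = 20, error_rate = 0, seed = 17)
  hap <- emit_truth_alignments(sim, "haploid")
  dip <- emit_truth_alignments(sim, "diploid")
  expect_true(all(dip$mapped))
  bl <- g$divergent_blocks
  r <- sim$reads
  blk_b <- r$haplotype == "B" & r$start <= bl$end & r$end >= bl$start
  expect_identical(!hap$mapped, blk_b[match(paste(hap$qname, hap$mate),
                                            paste(r$qname, r$mate))])
  expect_gt(sum(!hap$mapped), 0)
})

test_that("record conservation: each mode emits two records per fragment", {
  g <- simulate_diploid_genome(1, 1e4, seed = 1)
  sim <- simulate_reads(g, NULL, depth = 8, seed = 1)
  n_frag <- length(unique(sim$reads$qname))
  for (mode in c("haploid", "diploid")) {
    aln <- emit_truth_alignments(sim, mode)
    expect_equal(nrow(aln), 2L * n_frag)
  }
  ## every read id appears exactly once per mate in the truth table
  expect_equal(anyDuplicated(sim$reads[, c("qname", "mate")]), 0L)
})

test_that("FASTQ and SAM emission are byte-deterministic given the seed", {
  g <- simulate_diploid_genome(1, 1e4, seed = 30)
  run <- function(seed) {
    sim <- simulate_reads(g, NULL, depth = 5, seed = seed)
    fq <- tempfile(); sam <- tempfile(fileext = ".sam")
    write_fastq(sim, fq)
    write_sam(emit_truth_alignments(sim, "haploid"), sam)
    list(fq1 = readLines(paste0(fq, "_1.fastq")),
         fq2 = readLines(paste0(fq, "_2.fastq")),
         sam = readLines(sam))
  }
  a <- run(7); b <- run(7); c <- run(8)
  expect_identical(a, b)
  expect_false(identical(a$fq1, c$fq1))
})

test_that("base qualities are Q38 with Q20 exactly at error positions", {
  g <- simulate_diploid_genome(1, 2e4, het_rate = 0, seed = 19)
  sim <- simulate_reads(g, NULL, depth = 20, error_rate = 0.01, seed = 19)
  r <- sim$reads
  src <- g$hapA[[1]]   # het_rate 0: both haplotypes identical
  i <- which(r$n_err > 0)[1]
  ref_chars <- strsplit(substring(src, r$start[i], r$end[i]), "")[[1]]
  seq_chars <- strsplit(r$seq[i], "")[[1]]
  qual_chars <- strsplit(r$qual[i], "")[[1]]
  is_err <- seq_chars != ref_chars
  expect_true(all(qual_chars[is_err] == "5"))     # Q20
  expect_true(all(qual_chars[!is_err] == "G"))    # Q38
  expect_equal(sum(is_err), r$n_err[i])
})
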