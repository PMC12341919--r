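#' Simulate a heterozygous diploid genome
#'
#' Generates a pair of haplotype sequences (hapA, hapB) per chromosome that
#' differ at heterozygous SNV sites drawn uniformly at a given rate, plus
#' optional haplotype-divergent blocks where hapB carries sequence unrelated
#' to hapA. Divergent blocks model regions of a heterozygous genome that are
#' representable only in a diploid assembly; block replacement preserves
#' length so hapA and hapB coordinates stay in one-to-one correspondence.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp (>= 10 kb).
#' @param het_rate per-base heterozygous SNV rate outside divergent blocks,
#'   in `[0, 0.05]`. The default 0.016 corresponds to a k-mer-based
#'   genome-wide heterozygosity estimate of ~1.6% for a centuries-old oak.
#' @param divergent_spec integer vector of divergent-block lengths (bp); the
#'   blocks are placed non-overlapping at random positions, distributed
#'   across chromosomes.
#' @param seed integer seed; output is deterministic given the seed.
#' @return An object of class `diploid_genome`: a list with `hapA`, `hapB`
#'   (named character vectors, one sequence per chromosome), `het_variants`
#'   (data.table: chrom, pos, a_allele, b_allele, kind), `divergent_blocks`
#'   (data.table: chrom, start, end; 1-based closed) and `chrom_len`.
#' @export
simulate_diploid_genome <- function(n_chrom = 1L, chrom_len = 1e6, het_rate = 0.016,
                                    divergent_spec = integer(0), seed = 1L) {
  stopifnot(n_chrom >= 1L, chrom_len >= 1e4)
  if (het_rate < 0 || het_rate > 0.05)
    stop("het_rate must lie in [0, 0.05]")
  chrom_len <- as.integer(chrom_len)
  divergent_spec <- as.integer(divergent_spec)
  chroms <- paste0("chr", seq_len(n_chrom))

  .with_seed(seed, {
    ## assign blocks to chromosomes round-robin, then check fit
    block_chrom <- if (length(divergent_spec))
      chroms[((seq_along(divergent_spec) - 1L) %% n_chrom) + 1L] else character(0)
    for (cc in chroms) {
      need <- sum(divergent_spec[block_chrom == cc])
      if (need > chrom_len / 2)
        stop("divergent blocks exceed half the chromosome length on ", cc,
             " (", need, " bp requested, ", chrom_len, " bp available)")
    }

    hapA <- hapB <- setNames(character(n_chrom), chroms)
    het_list <- vector("list", n_chrom)
    blk_list <- vector("list", n_chrom)

    for (i in seq_len(n_chrom)) {
      cc <- chroms[i]
      a <- sample(DNA_BASES, chrom_len, replace = TRUE)
      b <- a

      ## place this chromosome's divergent blocks without overlap
      lens <- divergent_spec[block_chrom == cc]
      blocks <- data.table(chrom = character(0), start = integer(0), end = integer(0))
      if (length(lens)) {
        taken <- integer(0)
        starts <- integer(length(lens))
        for (j in seq_along(lens)) {
          ok <- FALSE
          for (try in 1:1000) {
            s <- sample.int(chrom_len - lens[j] + 1L, 1L)
            span <- s:(s + lens[j] - 1L)
            if (!any(span %in% taken)) { ok <- TRUE; break }
          }
          if (!ok) stop("could not place divergent block of length ", lens[j],
                        " without overlap on ", cc)
          starts[j] <- s
          taken <- c(taken, span)
        }
        blocks <- data.table(chrom = cc, start = starts,
                             end = starts + lens - 1L)
        for (j in seq_along(lens))
          b[blocks$start[j]:blocks$end[j]] <-
            sample(DNA_BASES, lens[j], replace = TRUE)
      }

      in_block <- rep(FALSE, chrom_len)
      if (nrow(blocks))
        for (j in seq_len(nrow(blocks)))
          in_block[blocks$start[j]:blocks$end[j]] <- TRUE

      ## heterozygous SNVs outside blocks
      het_pos <- integer(0)
      if (het_rate > 0) {
        cand <- which(!in_block)
        hit <- runif(length(cand)) < het_rate
        het_pos <- cand[hit]
      }
      het <- data.table(chrom = character(0), pos = integer(0),
                        a_allele = character(0), b_allele = character(0),
                        kind = character(0))
      if (length(het_pos)) {
        a_all <- a[het_pos]
        ## substitute with a uniformly chosen different base
        b_all <- vapply(a_all, function(ba)
          sample(setdiff(DNA_BASES, ba), 1L), character(1), USE.NAMES = FALSE)
        b[het_pos] <- b_all
        het <- data.table(chrom = cc, pos = het_pos,
                          a_allele = a_all, b_allele = b_all, kind = "snv")
      }

      hapA[[cc]] <- paste(a, collapse = "")
      hapB[[cc]] <- paste(b, collapse = "")
      het_list[[i]] <- het
      blk_list[[i]] <- blocks
    }

    out <- list(hapA = hapA, hapB = hapB,
                het_variants = rbindlist(het_list),
                divergent_blocks = rbindlist(blk_list),
                chrom_len = setNames(rep(chrom_len, n_chrom), chroms))
    class(out) <- "diploid_genome"
    out
  })
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat("diploid_genome:", length(x$hapA), "chromosome(s),",
      sum(x$chrom_len), "bp per haplotype\n")
  cat("  het SNVs:", nrow(x$het_variants),
      "| divergent blocks:", nrow(x$divergent_blocks), "\n")
  invisible(x)
}

#' Reference sequence sets for a simulated genome
#'
#' The haploid reference is hapA only (sequence names `<chrom>`); the diploid
#' reference carries both haplotypes as separate contigs named
#' `<chrom>_hapA` / `<chrom>_hapB`.
#'
#' @param genome a `diploid_genome`.
#' @return list with elements `haploid` and `diploid`, each a named character
#'   vector of reference sequences.
#' @export
genome_references <- function(genome) {
  stopifnot(inherits(genome, "diploid_genome"))
  dip <- c(setNames(genome$hapA, paste0(names(genome$hapA), "_hapA")),
           setNames(genome$hapB, paste0(names(genome$hapB), "_hapB")))
  list(haploid = genome$hapA, diploid = dip[order(names(dip))])
}

#' Write a reference set to FASTA
#'
#' @param ref named character vector of sequences.
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), path)
  invisible(path)
}

#' Implant layer-structured somatic mutations
#'
#' Places single-nucleotide somatic mutations on one haplotype each, tagged
#' with the meristem layer (L1/L2/L3) in which they are fixed. The expected
#' variant allele frequency in whole-tissue reads is
#' `layer_fraction * cell_fraction / 2`: the layer contributes
#' `layer_fraction` of the sample DNA, the mutation sits on one of two
#' haplotypes, and `cell_fraction` of the layer's cells carry it.
#'
#' Implant positions avoid heterozygous sites, divergent blocks and each
#' other, so every implant has an unambiguous reference allele shared by
#' both haplotypes.
#'
#' @param genome a `diploid_genome`.
#' @param layer_fractions named numeric, DNA fraction per layer; must sum
#'   to 1. Default `c(L1 = 0.18, L2 = 0.60, L3 = 0.22)`: L2 ~60% (from the
#'   median VAF ~0.3 of mutations shared between leaf and embryonic tissue),
#'   L1 under 20% and L3 over 20%.
#' @param n_per_layer implants per layer (single count, or named vector).
#' @param cell_fraction fraction of cells within the layer carrying each
#'   mutation (1 = fixed in the layer).
#' @param seed integer seed.
#' @return data.table of class `somatic_implants`: id, chrom, pos, ref, alt,
#'   layer, haplotype, cell_fraction, layer_fraction, expected_vaf.
#' @export
implant_somatic_mutations <- function(genome,
                                      layer_fractions = c(L1 = 0.18, L2 = 0.60, L3 = 0.22),
                                      n_per_layer = 10L,
                                      cell_fraction = 1.0,
                                      seed = 1L) {
  stopifnot(inherits(genome, "diploid_genome"),
            cell_fraction >= 0, cell_fraction <= 1)
  if (abs(sum(layer_fractions) - 1) > 1e-8)
    stop("layer fractions must sum to 1")
  layers <- names(layer_fractions)
  if (is.null(layers) || any(!nzchar(layers)))
    stop("layer_fractions must be named")
  if (is.null(names(n_per_layer))) {
    n_per_layer <- setNames(rep(as.integer(n_per_layer), length(layers)), layers)
  } else {
    full <- setNames(integer(length(layers)), layers)
    full[names(n_per_layer)] <- as.integer(n_per_layer)
    n_per_layer <- full
  }
  n_total <- sum(n_per_layer)
  if (n_total == 0L)
    return(structure(
      data.table(id = character(0), chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0), layer = character(0),
                 haplotype = character(0), cell_fraction = numeric(0),
                 layer_fraction = numeric(0), expected_vaf = numeric(0)),
      class = c("somatic_implants", "data.table", "data.frame")))

  .with_seed(seed, {
    picks <- vector("list", length(genome$hapA))
    for (i in seq_along(genome$hapA)) {
      cc <- names(genome$hapA)[i]
      len <- genome$chrom_len[[cc]]
      bad <- rep(FALSE, len)
      hv <- genome$het_variants[chrom == cc]
      if (nrow(hv)) bad[hv$pos] <- TRUE
      bl <- genome$divergent_blocks[chrom == cc]
      if (nrow(bl))
        for (j in seq_len(nrow(bl))) bad[bl$start[j]:bl$end[j]] <- TRUE
      picks[[i]] <- data.table(chrom = cc, pos = which(!bad))
    }
    avail <- rbindlist(picks)
    if (n_total > nrow(avail))
      stop("requested ", n_total, " implants but only ", nrow(avail),
           " positions are free of het sites and divergent blocks")
    sel <- avail[sample.int(nrow(avail), n_total), ]
    layer <- rep(layers, times = n_per_layer[layers])

    achars <- lapply(genome$hapA, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    ref <- mapply(function(cc, p) achars[[cc]][p], sel$chrom, sel$pos)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                  character(1), USE.NAMES = FALSE)
    out <- data.table(
      id = sprintf("som%03d", seq_len(n_total)),
      chrom = sel$chrom, pos = sel$pos, ref = unname(ref), alt = alt,
      layer = layer,
      haplotype = sample(c("A", "B"), n_total, replace = TRUE),
      cell_fraction = cell_fraction,
      layer_fraction = unname(layer_fractions[layer]),
      expected_vaf = unname(layer_fractions[layer]) * cell_fraction / 2)
    setorder(out, chrom, pos)
    structure(out, class = c("somatic_implants", class(out)))
  })
}
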