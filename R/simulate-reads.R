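#' BWA-convention scoring model for truth alignments
#'
#' Ungapped, unclipped alignments are scored as
#' `matches * match_score + mismatches * mismatch_penalty` (+1 / -4, the BWA
#' defaults), so a 100 bp read with one mismatch scores 95. Mapping quality
#' is 60 for uniquely placed reads and 0 for reads whose span is identical
#' between the two haplotypes of a diploid reference.
#'
#' @param match_score score per matching base.
#' @param mismatch_penalty (negative) score per mismatching base.
#' @param mapq_unique MAPQ for uniquely placed reads.
#' @param mapq_ambiguous MAPQ for ambiguously placed reads.
#' @return list of class `scoring_model`.
#' @export
scoring_model <- function(match_score = 1L, mismatch_penalty = -4L,
                          mapq_unique = 60L, mapq_ambiguous = 0L) {
  structure(list(match_score = as.integer(match_score),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 mapq_unique = as.integer(mapq_unique),
                 mapq_ambiguous = as.integer(mapq_ambiguous)),
            class = "scoring_model")
}

#' Alignment score of an ungapped read
#'
#' @param read_len read length in bp.
#' @param n_mismatch number of mismatching bases.
#' @param scoring a [scoring_model()].
#' @return integer alignment score.
#' @export
alignment_score <- function(read_len, n_mismatch, scoring = scoring_model()) {
  as.integer((read_len - n_mismatch) * scoring$match_score +
               n_mismatch * scoring$mismatch_penalty)
}

#' Simulate paired-end short reads from a diploid genome
#'
#' Fragments are drawn uniformly from hapA/hapB with equal probability;
#' read 1 covers the fragment 5' end on the forward strand, read 2 the 3'
#' end on the reverse strand. A fragment whose source haplotype matches an
#' overlapping implant carries the alternate allele with probability
#' `layer_fraction * cell_fraction` (one draw per fragment, so mates agree).
#' Substitution errors occur per base at `error_rate`; erroneous bases are
#' emitted at Q20 and all others at Q38 (Phred+33), so a base-quality >= 30
#' filter separates them.
#'
#' @param genome a `diploid_genome`.
#' @param implants a `somatic_implants` table or NULL.
#' @param depth target fold coverage of the (haploid) genome length.
#' @param read_len read length (bp).
#' @param insert_mean,insert_sd fragment-size distribution (bp), normal,
#'   truncated to `[read_len, chrom_len]`.
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @return object of class `sim_reads`: list with `reads` (data.table, one
#'   row per mate: qname, mate, chrom, haplotype, start, end, strand, seq,
#'   qual, carried, n_err, insert_size), `genome`, `implants`, and scalar
#'   simulation parameters. `seq`/`qual` are stored in reference-forward
#'   orientation; FASTQ emission reverse-complements reverse-strand mates.
#' @export
simulate_reads <- function(genome, implants = NULL, depth = 60, read_len = 150L,
                           insert_mean = 400, insert_sd = 60,
                           error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(genome, "diploid_genome"), depth > 0,
            read_len <= insert_mean, error_rate >= 0, error_rate < 0.5)
  read_len <- as.integer(read_len)
  if (is.null(implants))
    implants <- implant_somatic_mutations(genome, n_per_layer = 0L, seed = 1L)

  .with_seed(seed, {
    per_chrom <- vector("list", length(genome$hapA))
    for (ci in seq_along(genome$hapA)) {
      cc <- names(genome$hapA)[ci]
      len <- genome$chrom_len[[cc]]
      n_frag <- max(1L, as.integer(round(depth * len / (2 * read_len))))
      achars <- strsplit(genome$hapA[[cc]], "", fixed = TRUE)[[1]]
      bchars <- strsplit(genome$hapB[[cc]], "", fixed = TRUE)[[1]]

      hap <- sample(c("A", "B"), n_frag, replace = TRUE)
      ins <- as.integer(round(rnorm(n_frag, insert_mean, insert_sd)))
      ins <- pmin(pmax(ins, read_len), len)
      fstart <- as.integer(floor(runif(n_frag) * (len - ins + 1))) + 1L

      s1 <- fstart                      # mate 1, forward
      s2 <- fstart + ins - read_len     # mate 2, reverse
      off <- 0:(read_len - 1L)
      pos1 <- outer(s1, off, "+")
      pos2 <- outer(s2, off, "+")
      isA <- hap == "A"
      m1 <- matrix("", n_frag, read_len)
      m2 <- matrix("", n_frag, read_len)
      m1[isA, ] <- achars[pos1[isA, , drop = FALSE]]
      m1[!isA, ] <- bchars[pos1[!isA, , drop = FALSE]]
      m2[isA, ] <- achars[pos2[isA, , drop = FALSE]]
      m2[!isA, ] <- bchars[pos2[!isA, , drop = FALSE]]

      ## somatic implants: one carrier draw per (fragment, implant)
      carried1 <- carried2 <- vector("list", 0L)
      car1 <- car2 <- rep("", n_frag)
      imp <- implants[chrom == cc]
      if (nrow(imp)) {
        fend <- fstart + ins - 1L
        for (k in seq_len(nrow(imp))) {
          p <- imp$pos[k]
          ov <- hap == imp$haplotype[k] & fstart <= p & fend >= p
          if (!any(ov)) next
          carrier <- ov & (runif(n_frag) <
                             imp$layer_fraction[k] * imp$cell_fraction[k])
          if (!any(carrier)) next
          w1 <- which(carrier & s1 <= p & p <= s1 + read_len - 1L)
          w2 <- which(carrier & s2 <= p & p <= s2 + read_len - 1L)
          if (length(w1)) {
            m1[cbind(w1, p - s1[w1] + 1L)] <- imp$alt[k]
            car1[w1] <- ifelse(nzchar(car1[w1]),
                               paste0(car1[w1], ",", imp$id[k]), imp$id[k])
          }
          if (length(w2)) {
            m2[cbind(w2, p - s2[w2] + 1L)] <- imp$alt[k]
            car2[w2] <- ifelse(nzchar(car2[w2]),
                               paste0(car2[w2], ",", imp$id[k]), imp$id[k])
          }
        }
      }

      ## substitution errors at reduced base quality
      q1 <- matrix("G", n_frag, read_len)   # Q38 ('G' = 38 + 33)
      q2 <- matrix("G", n_frag, read_len)
      nerr1 <- nerr2 <- integer(n_frag)
      if (error_rate > 0) {
        for (mm in 1:2) {
          mat <- if (mm == 1) m1 else m2
          err <- matrix(runif(n_frag * read_len) < error_rate,
                        n_frag, read_len)
          idx <- which(err)
          if (length(idx)) {
            ## uniformly one of the three other bases
            cur <- mat[idx]
            shift_by <- sample.int(3L, length(idx), replace = TRUE)
            mat[idx] <- DNA_BASES[((match(cur, DNA_BASES) - 1L + shift_by) %% 4L) + 1L]
            if (mm == 1) { m1 <- mat; q1[idx] <- "5"; nerr1 <- rowSums(err) }
            else         { m2 <- mat; q2[idx] <- "5"; nerr2 <- rowSums(err) }
          }
        }
      }

      qn <- sprintf("%s_f%07d", cc, seq_len(n_frag))
      collapse_rows <- function(m) do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
      per_chrom[[ci]] <- data.table(
        qname = rep(qn, 2L),
        mate = rep(1:2, each = n_frag),
        chrom = cc,
        haplotype = rep(hap, 2L),
        start = c(s1, s2),
        end = c(s1, s2) + read_len - 1L,
        strand = rep(c("+", "-"), each = n_frag),
        seq = c(collapse_rows(m1), collapse_rows(m2)),
        qual = c(collapse_rows(q1), collapse_rows(q2)),
        carried = c(car1, car2),
        n_err = c(nerr1, nerr2),
        insert_size = rep(ins, 2L))
    }
    reads <- rbindlist(per_chrom)
    setorder(reads, chrom, qname, mate)
    out <- list(reads = reads, genome = genome, implants = implants,
                read_len = read_len, depth = depth, error_rate = error_rate,
                insert_mean = insert_mean, insert_sd = insert_sd, seed = seed)
    class(out) <- "sim_reads"
    out
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", nrow(x$reads), "reads (",
      nrow(x$reads) / 2, "fragments ),", x$read_len, "bp, depth",
      x$depth, "\n")
  invisible(x)
}

#' Write simulated reads as paired FASTQ
#'
#' Reverse-strand mates are reverse-complemented (and their quality strings
#' reversed) so the FASTQ records are in sequencing orientation.
#'
#' @param sim a `sim_reads` object.
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return invisibly, the two file paths.
#' @export
write_fastq <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_reads"))
  paths <- paste0(prefix, "_", 1:2, ".fastq")
  for (mm in 1:2) {
    r <- sim$reads[mate == mm][order(qname)]
    seqs <- r$seq
    quals <- r$qual
    flip <- r$strand == "-"
    if (any(flip)) {
      seqs[flip] <- revcomp(seqs[flip])
      quals[flip] <- vapply(quals[flip], function(s)
        paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
        character(1), USE.NAMES = FALSE)
    }
    con <- file(paths[mm], "w")
    writeLines(paste0("@", r$qname, "/", mm, "\n", seqs, "\n+\n", quals), con)
    close(con)
  }
  invisible(paths)
}

#' Write the simulation truth table as TSV
#'
#' @param sim a `sim_reads` object.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_truth_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "sim_reads"))
  keep <- c("qname", "mate", "chrom", "haplotype", "start", "end",
            "strand", "carried", "n_err")
  fwrite(sim$reads[, ..keep], path, sep = "\t")
  invisible(path)
}

## positions (per chromosome) where hapA and hapB differ, as a logical vector
.hap_diff_vector <- function(genome, cc) {
  len <- genome$chrom_len[[cc]]
  d <- rep(FALSE, len)
  hv <- genome$het_variants[chrom == cc]
  if (nrow(hv)) d[hv$pos] <- TRUE
  bl <- genome$divergent_blocks[chrom == cc]
  if (nrow(bl))
    for (j in seq_len(nrow(bl))) {
      span <- bl$start[j]:bl$end[j]
      ach <- substring(genome$hapA[[cc]], span, span)
      bch <- substring(genome$hapB[[cc]], span, span)
      d[span] <- d[span] | (ach != bch)
    }
  d
}

#' Emit truth alignments against the haploid or diploid reference
#'
#' Produces the alignments a faithful aligner would report, with
#' BWA-convention scores. In haploid mode every read is placed at its hapA
#' coordinates (hapB reads overlapping a divergent block are emitted
#' unmapped, since their sequence is absent from the haploid reference). In
#' diploid mode each read is placed on its true haplotype contig
#' (`<chrom>_hapA`/`<chrom>_hapB`); MAPQ is `mapq_ambiguous` when the read's
#' reference span is identical between the two haplotypes (the aligner could
#' not distinguish them) and `mapq_unique` otherwise. `NM` is the exact
#' mismatch count of the read sequence against the chosen reference and
#' `AS = matches * match - mismatches * penalty`; alignments are ungapped
#' (`<len>M`) and unclipped by construction.
#'
#' @param sim a `sim_reads` object.
#' @param reference_mode `"haploid"` or `"diploid"`.
#' @param scoring a [scoring_model()].
#' @return data.table of class `alignment_set`, one row per read: qname,
#'   mate, flag, rname, pos, mapq, cigar, seq, qual, AS, NM, strand, mapped,
#'   dup; attribute `seqlengths` names the reference contigs.
#' @export
emit_truth_alignments <- function(sim, reference_mode = c("haploid", "diploid"),
                                  scoring = scoring_model()) {
  stopifnot(inherits(sim, "sim_reads"))
  reference_mode <- match.arg(reference_mode)
  genome <- sim$genome
  L <- sim$read_len
  refs <- genome_references(genome)

  out <- vector("list", length(genome$hapA))
  for (ci in seq_along(genome$hapA)) {
    cc <- names(genome$hapA)[ci]
    r <- sim$reads[chrom == cc]
    n <- nrow(r)
    achars <- strsplit(genome$hapA[[cc]], "", fixed = TRUE)[[1]]
    bchars <- strsplit(genome$hapB[[cc]], "", fixed = TRUE)[[1]]
    dcum <- cumsum(.hap_diff_vector(genome, cc))
    span_diff <- dcum[r$end] - ifelse(r$start > 1L, dcum[r$start - 1L], 0L)

    seqm <- .seq_matrix(r$seq)
    posm <- outer(r$start, 0:(L - 1L), "+")
    isA <- r$haplotype == "A"

    if (reference_mode == "haploid") {
      refm <- matrix(achars[posm], n, L)
      nm <- rowSums(seqm != refm)
      rname <- rep(cc, n)
      mapq <- rep(scoring$mapq_unique, n)
      ## hapB reads overlapping a divergent block: sequence absent from hapA
      mapped <- rep(TRUE, n)
      bl <- genome$divergent_blocks[chrom == cc]
      if (nrow(bl)) {
        inblk <- rep(FALSE, genome$chrom_len[[cc]])
        for (j in seq_len(nrow(bl))) inblk[bl$start[j]:bl$end[j]] <- TRUE
        bcum <- cumsum(inblk)
        ov <- (bcum[r$end] - ifelse(r$start > 1L, bcum[r$start - 1L], 0L)) > 0L
        mapped <- !(r$haplotype == "B" & ov)
      }
    } else {
      refm <- matrix("", n, L)
      refm[isA, ] <- achars[posm[isA, , drop = FALSE]]
      refm[!isA, ] <- bchars[posm[!isA, , drop = FALSE]]
      nm <- rowSums(seqm != refm)
      rname <- paste0(cc, "_hap", r$haplotype)
      mapq <- ifelse(span_diff == 0L, scoring$mapq_ambiguous, scoring$mapq_unique)
      mapped <- rep(TRUE, n)
    }

    as_score <- alignment_score(L, nm, scoring)
    aln <- data.table(
      qname = r$qname, mate = r$mate,
      rname = ifelse(mapped, rname, NA_character_),
      pos = ifelse(mapped, r$start, NA_integer_),
      mapq = ifelse(mapped, as.integer(mapq), 0L),
      cigar = ifelse(mapped, paste0(L, "M"), "*"),
      seq = r$seq, qual = r$qual,
      AS = ifelse(mapped, as_score, NA_integer_),
      NM = ifelse(mapped, as.integer(nm), NA_integer_),
      strand = r$strand, mapped = mapped, dup = FALSE)
    out[[ci]] <- aln
  }
  aln <- rbindlist(out)

  ## SAM flags: paired + mate orientation + first/last; degrade properly when
  ## a mate is unmapped
  mate_tbl <- aln[, .(qname, mate, mapped, strand, pos, rname)]
  other <- mate_tbl[, .(qname, mate = 3L - mate, m_mapped = mapped,
                        m_strand = strand, m_pos = pos, m_rname = rname)]
  aln <- other[aln, on = c("qname", "mate")]
  flag <- 1L +
    ifelse(aln$mapped & aln$m_mapped, 2L, 0L) +
    ifelse(!aln$mapped, 4L, 0L) +
    ifelse(!aln$m_mapped, 8L, 0L) +
    ifelse(aln$mapped & aln$strand == "-", 16L, 0L) +
    ifelse(aln$m_mapped & aln$m_strand == "-", 32L, 0L) +
    ifelse(aln$mate == 1L, 64L, 128L)
  aln[, flag := flag]
  setcolorder(aln, c("qname", "mate", "flag", "rname", "pos", "mapq", "cigar",
                     "seq", "qual", "AS", "NM", "strand", "mapped", "dup"))
  aln[, c("m_mapped", "m_strand", "m_pos", "m_rname") := NULL]
  setorder(aln, qname, mate)
  ref <- refs[[reference_mode]]
  setattr(aln, "seqlengths", setNames(nchar(ref), names(ref)))
  setattr(aln, "class", c("alignment_set", class(aln)))
  aln[]
}
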