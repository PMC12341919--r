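#' Per-read mismatch fraction
#'
#' Edit distance (`NM`) divided by the aligned query length (bases in
#' CIGAR `M`/`=`/`X` operations). The candidate variant base is *not*
#' subtracted: the downstream differential filter (alt mean minus ref mean
#' <= 0.01) absorbs the variant's own 1/read-length contribution for reads
#' of >= 100 bp.
#'
#' @param aln an `alignment_set` (or any data.frame with `cigar` and `NM`).
#' @return numeric vector of mismatch fractions, one per row.
#' @export
per_read_mismatch_fraction <- function(aln) {
  dt <- as.data.table(aln)
  if (any(!dt$mapped %||% TRUE))
    stop("mismatch fraction is defined for mapped reads only")
  if (anyNA(dt$NM))
    stop("edit distance (NM) missing for ", sum(is.na(dt$NM)), " read(s)")
  alen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    dt$cigar, after.soft.clipping = TRUE)
  ## after.soft.clipping removes S; I ops still count toward query span there,
  ## so subtract inserted bases to keep M/=/X only
  ins <- vapply(GenomicAlignments::explodeCigarOpLengths(dt$cigar, ops = "I"),
                sum, integer(1))
  dt$NM / (alen - ins)
}

## Expand mapped alignments into per-base contributions and indel evidence.
## Fast path for ungapped "<len>M" records (the overwhelming majority of
## simulated truth alignments); general CIGARs go through the
## GenomicAlignments range machinery.
.expand_alignments <- function(aln) {
  dt <- as.data.table(aln)[mapped == TRUE]
  if (nrow(dt) == 0L)
    return(list(bases = data.table(rname = character(0), pos = integer(0),
                                   base = character(0), bq = integer(0),
                                   strand = character(0), mapq = integer(0),
                                   mm = numeric(0), qname = character(0),
                                   mate = integer(0)),
                indels = data.table(rname = character(0), pos = integer(0),
                                    qname = character(0), mate = integer(0),
                                    mapq = integer(0))))
  dt[, mm := per_read_mismatch_fraction(dt)]
  slen <- nchar(dt$seq)
  simple <- dt$cigar == paste0(slen, "M")
  parts <- list()

  s <- dt[simple]
  if (nrow(s)) {
    L <- nchar(s$seq)
    pos <- rep(s$pos, L) + sequence(L) - 1L
    base <- unlist(strsplit(s$seq, "", fixed = TRUE), use.names = FALSE)
    bq <- as.integer(charToRaw(paste(s$qual, collapse = ""))) - 33L
    parts$simple <- data.table(
      rname = rep(s$rname, L), pos = pos, base = base, bq = bq,
      strand = rep(s$strand, L), mapq = rep(s$mapq, L),
      mm = rep(s$mm, L), qname = rep(s$qname, L), mate = rep(s$mate, L))
  }

  indels <- data.table(rname = character(0), pos = integer(0),
                       qname = character(0), mate = integer(0),
                       mapq = integer(0))
  g <- dt[!simple]
  if (nrow(g)) {
    rref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      g$cigar, pos = g$pos, ops = c("M", "=", "X"))
    rqry <- GenomicAlignments::cigarRangesAlongQuerySpace(
      g$cigar, ops = c("M", "=", "X"))
    gen_rows <- vector("list", nrow(g))
    ind_rows <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
      rs <- rref[[i]]; qs <- rqry[[i]]
      refpos <- unlist(mapply(seq.int, IRanges::start(rs), IRanges::end(rs),
                              SIMPLIFY = FALSE), use.names = FALSE)
      qrypos <- unlist(mapply(seq.int, IRanges::start(qs), IRanges::end(qs),
                              SIMPLIFY = FALSE), use.names = FALSE)
      sq <- strsplit(g$seq[i], "", fixed = TRUE)[[1]]
      qv <- as.integer(charToRaw(g$qual[i])) - 33L
      gen_rows[[i]] <- data.table(
        rname = g$rname[i], pos = as.integer(refpos), base = sq[qrypos],
        bq = qv[qrypos], strand = g$strand[i], mapq = g$mapq[i],
        mm = g$mm[i], qname = g$qname[i], mate = g$mate[i])
      ## indel footprints: D spans its deleted reference bases; I anchors to
      ## the reference base left of the insertion point
      dmat <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        g$cigar[i], pos = g$pos[i], ops = "D")[[1]]
      imat <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        g$cigar[i], pos = g$pos[i], ops = "I")[[1]]
      ipos <- integer(0)
      if (length(dmat))
        ipos <- c(ipos, unlist(mapply(seq.int, IRanges::start(dmat),
                                      IRanges::end(dmat), SIMPLIFY = FALSE)))
      if (length(imat))
        ipos <- c(ipos, IRanges::start(imat) - 1L)
      if (length(ipos))
        ind_rows[[i]] <- data.table(rname = g$rname[i],
                                    pos = as.integer(unique(ipos)),
                                    qname = g$qname[i], mate = g$mate[i],
                                    mapq = g$mapq[i])
    }
    parts$general <- rbindlist(gen_rows)
    ind_rows <- ind_rows[!vapply(ind_rows, is.null, logical(1))]
    if (length(ind_rows)) indels <- rbindlist(ind_rows)
  }
  list(bases = rbindlist(parts), indels = indels)
}

#' Thresholds for pileup counting
#'
#' @param min_mapq minimum mapping quality for a read to contribute.
#' @param min_bq minimum base quality for a base to contribute.
#' @return list of class `count_thresholds`.
#' @export
count_thresholds <- function(min_mapq = 0L, min_bq = 0L) {
  stopifnot(min_mapq >= 0L, min_bq >= 0L)
  structure(list(min_mapq = as.integer(min_mapq), min_bq = as.integer(min_bq)),
            class = "count_thresholds")
}

#' Genome-wide pileup table
#'
#' bam-readcount-style per-site allele accounting. A read base contributes
#' iff the read's MAPQ >= `min_mapq` and the base quality >= `min_bq`;
#' deleted bases never contribute to depth. Per allele, forward/reverse
#' strand counts and the means of base quality and per-read mismatch
#' fraction are aggregated; per site, `indel_ev` counts reads (passing the
#' MAPQ threshold) with an inserted or deleted segment touching the
#' position (insertions anchored to the base on their left). Overlapping
#' mates contribute independently, mirroring bam-readcount's default.
#'
#' @param aln an `alignment_set`.
#' @param ref named character vector of reference sequences.
#' @param thresholds a [count_thresholds()].
#' @return object of class `pileup`: list with `alleles` (data.table:
#'   rname, pos, base, count, fwd, rev, mean_bq, mean_mm), `sites`
#'   (data.table: rname, pos, ref, depth, indel_ev) and `thresholds`.
#' @export
pileup_table <- function(aln, ref, thresholds = count_thresholds()) {
  ex <- .expand_alignments(aln)
  b <- ex$bases[mapq >= thresholds$min_mapq & bq >= thresholds$min_bq]
  alleles <- b[, .(count = .N, fwd = sum(strand == "+"),
                   rev = sum(strand == "-"), mean_bq = mean(bq),
                   mean_mm = mean(mm)),
               by = .(rname, pos, base)]
  sites <- alleles[, .(depth = sum(count)), by = .(rname, pos)]
  ind <- ex$indels[mapq >= thresholds$min_mapq,
                   .(indel_ev = uniqueN(paste(qname, mate))),
                   by = .(rname, pos)]
  sites <- merge(sites, ind, by = c("rname", "pos"), all = TRUE)
  sites[is.na(depth), depth := 0L]
  sites[is.na(indel_ev), indel_ev := 0L]
  sites[, ref := .ref_base_at(ref, rname, pos)]
  setcolorder(sites, c("rname", "pos", "ref", "depth", "indel_ev"))
  setorder(sites, rname, pos)
  setorder(alleles, rname, pos, base)
  structure(list(alleles = alleles, sites = sites, thresholds = thresholds),
            class = "pileup")
}

.ref_base_at <- function(ref, rname, pos) {
  out <- character(length(rname))
  for (cc in unique(rname)) {
    w <- rname == cc
    if (!cc %in% names(ref))
      stop("reference sequence '", cc, "' not found")
    out[w] <- substring(ref[[cc]], pos[w], pos[w])
  }
  out
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup:", nrow(x$sites), "sites (MAPQ >=", x$thresholds$min_mapq,
      ", BQ >=", x$thresholds$min_bq, ")\n")
  invisible(x)
}

#' Count alleles at a single site
#'
#' @param aln an `alignment_set` of reads overlapping the site.
#' @param rname,pos reference name and 1-based position.
#' @param ref_base expected reference base; validated against `ref`.
#' @param ref named character vector of reference sequences.
#' @param thresholds a [count_thresholds()].
#' @return list of class `pileup_site` with `rname`, `pos`, `ref`, `depth`,
#'   `indel_ev` and `alleles` (data.table as in [pileup_table()]).
#' @export
count_site <- function(aln, rname, pos, ref_base, ref,
                       thresholds = count_thresholds()) {
  true_ref <- substring(ref[[rname]], pos, pos)
  if (!identical(toupper(ref_base), toupper(true_ref)))
    stop("ref_base '", ref_base, "' disagrees with reference base '",
         true_ref, "' at ", rname, ":", pos)
  pt <- pileup_table(aln, ref, thresholds)
  want_rn <- rname; want_pos <- pos
  al <- pt$alleles[J(want_rn, want_pos), on = c("rname", "pos"), nomatch = NULL]
  st <- pt$sites[J(want_rn, want_pos), on = c("rname", "pos"), nomatch = NULL]
  structure(list(rname = rname, pos = pos, ref = true_ref,
                 depth = if (nrow(st)) st$depth else 0L,
                 indel_ev = if (nrow(st)) st$indel_ev else 0L,
                 alleles = al),
            class = "pileup_site")
}

#' Per-position depth track
#'
#' @param aln an `alignment_set`.
#' @param rname reference name.
#' @param region integer length-2 vector `c(start, end)` (1-based closed).
#' @param thresholds a [count_thresholds()].
#' @return integer vector of depth per position over the region (deleted
#'   bases do not count).
#' @export
depth_track <- function(aln, rname, region, thresholds = count_thresholds()) {
  stopifnot(length(region) == 2L, region[1] <= region[2])
  ex <- .expand_alignments(aln)
  sel <- ex$bases$mapq >= thresholds$min_mapq &
    ex$bases$bq >= thresholds$min_bq &
    ex$bases$rname == rname
  b <- ex$bases[which(sel)]
  n <- region[2] - region[1] + 1L
  out <- integer(n)
  bb <- b[which(b$pos >= region[1] & b$pos <= region[2])]
  if (nrow(bb)) {
    tab <- bb[, .N, by = pos]
    out[tab$pos - region[1] + 1L] <- tab$N
  }
  out
}

#' Write a pileup as a bam-readcount-style TSV
#'
#' One row per site: chrom, pos, ref, depth, indel_ev, then one
#' `base:count:fwd:rev:mean_bq:mean_mm` block per observed allele.
#'
#' @param pileup a `pileup` object.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_pileup_tsv <- function(pileup, path) {
  al <- pileup$alleles[, .(blocks = paste(
    sprintf("%s:%d:%d:%d:%.2f:%.4f", base, count, fwd, rev, mean_bq, mean_mm),
    collapse = "\t")), by = .(rname, pos)]
  m <- merge(pileup$sites, al, by = c("rname", "pos"), all.x = TRUE)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s", m$rname, m$pos, m$ref,
                   m$depth, m$indel_ev,
                   ifelse(is.na(m$blocks), "", m$blocks))
  writeLines(lines, path)
  invisible(path)
}
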