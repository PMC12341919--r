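#' Write an alignment set as SAM
#'
#' Emits a valid SAM file (header `@HD`/`@SQ`, tags `AS:i`/`NM:i`) from an
#' `alignment_set`. Mate fields (RNEXT/PNEXT/TLEN) are reconstructed by
#' pairing records on (qname, mate). Unmapped mates are written with
#' `RNAME *`, `POS 0`, `CIGAR *`.
#'
#' @param aln an `alignment_set` (see [emit_truth_alignments()]).
#' @param path output SAM path.
#' @param seqlengths named integer vector of reference lengths; defaults to
#'   the `seqlengths` attribute of `aln`.
#' @return invisibly, `path`.
#' @export
write_sam <- function(aln, path, seqlengths = attr(aln, "seqlengths")) {
  stopifnot(is.data.frame(aln), !is.null(seqlengths))
  dt <- as.data.table(aln)
  mate_info <- dt[, .(qname, mate = 3L - mate, m_rname = rname, m_pos = pos,
                      m_mapped = mapped)]
  dt <- mate_info[dt, on = c("qname", "mate")]

  rnext <- rep("*", nrow(dt))
  pnext <- rep(0L, nrow(dt))
  tlen <- rep(0L, nrow(dt))
  has_mate <- !is.na(dt$m_mapped) & dt$m_mapped
  rnext[has_mate] <- ifelse(!is.na(dt$rname[has_mate]) &
                              dt$rname[has_mate] == dt$m_rname[has_mate],
                            "=", dt$m_rname[has_mate])
  pnext[has_mate] <- dt$m_pos[has_mate]
  both <- has_mate & dt$mapped & dt$rname == dt$m_rname
  if (any(both)) {
    L <- nchar(dt$seq[both])
    lo <- pmin(dt$pos[both], dt$m_pos[both])
    hi <- pmax(dt$pos[both] + L - 1L, dt$m_pos[both] + L - 1L)
    sz <- hi - lo + 1L
    tlen[both] <- ifelse(dt$pos[both] <= dt$m_pos[both], sz, -sz)
  }

  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  opt <- ifelse(dt$mapped,
                sprintf("AS:i:%d\tNM:i:%d", dt$AS, dt$NM), "")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  dt$qname, dt$flag,
                  ifelse(dt$mapped, dt$rname, "*"),
                  ifelse(dt$mapped, dt$pos, 0L),
                  ifelse(dt$mapped, dt$mapq, 0L),
                  dt$cigar, rnext, pnext, tlen, dt$seq, dt$qual)
  body <- ifelse(nzchar(opt), paste0(body, "\t", opt), body)
  con <- file(path, "w")
  writeLines(c(hdr, body), con)
  close(con)
  invisible(path)
}

#' Read a SAM/BAM file into an alignment set
#'
#' SAM input is converted to BAM with Rsamtools and scanned back with the
#' `AS`/`NM` tags; secondary and supplementary records are kept (callers
#' such as [partition_alignments()] drop them explicitly).
#'
#' @param path SAM or BAM file.
#' @return data.table of class `alignment_set` (see
#'   [emit_truth_alignments()] for the columns).
#' @export
read_sam <- function(path) {
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else {
    tmp <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = tmp, overwrite = TRUE,
                     indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("AS", "NM"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  n <- length(x$qname)
  flag <- as.integer(x$flag)
  mapped <- bitwAnd(flag, 4L) == 0L
  aln <- data.table(
    qname = x$qname,
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                  ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)),
    flag = flag,
    rname = ifelse(mapped, as.character(x$rname), NA_character_),
    pos = ifelse(mapped, x$pos, NA_integer_),
    mapq = as.integer(x$mapq),
    cigar = ifelse(mapped, x$cigar, "*"),
    seq = as.character(x$seq),
    qual = as.character(x$qual),
    AS = if (is.null(x$tag$AS)) NA_integer_ else as.integer(x$tag$AS),
    NM = if (is.null(x$tag$NM)) NA_integer_ else as.integer(x$tag$NM),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapped = mapped,
    dup = bitwAnd(flag, 1024L) > 0L)
  setattr(aln, "seqlengths", hdr)
  setattr(aln, "class", c("alignment_set", class(aln)))
  aln[]
}

#' Construct an alignment set from per-read fields
#'
#' Convenience constructor used in tests and examples; fills SAM flags from
#' mate/strand/mapped and validates CIGAR-vs-sequence consistency for
#' mapped, unclipped records.
#'
#' @param qname,mate,rname,pos,mapq,cigar,seq,qual,AS,NM,strand,mapped,dup
#'   per-read vectors (recycled where scalar).
#' @param seqlengths named integer vector of reference lengths.
#' @return an `alignment_set` data.table.
#' @export
alignment_set <- function(qname, mate = 1L, rname = NA_character_,
                          pos = NA_integer_, mapq = 60L, cigar = "*",
                          seq = "", qual = "", AS = NA_integer_,
                          NM = NA_integer_, strand = "+", mapped = TRUE,
                          dup = FALSE, seqlengths = NULL) {
  n <- length(qname)
  aln <- data.table(
    qname = qname, mate = as.integer(rep_len(mate, n)),
    flag = 0L,
    rname = rep_len(rname, n), pos = as.integer(rep_len(pos, n)),
    mapq = as.integer(rep_len(mapq, n)), cigar = rep_len(cigar, n),
    seq = rep_len(seq, n), qual = rep_len(qual, n),
    AS = as.integer(rep_len(AS, n)), NM = as.integer(rep_len(NM, n)),
    strand = rep_len(strand, n), mapped = rep_len(mapped, n),
    dup = rep_len(dup, n))
  aln[, flag := 1L + ifelse(!mapped, 4L, 0L) +
        ifelse(strand == "-" & mapped, 16L, 0L) +
        ifelse(mate == 1L, 64L, 128L) +
        ifelse(dup, 1024L, 0L)]
  if (!is.null(seqlengths)) setattr(aln, "seqlengths", seqlengths)
  setattr(aln, "class", c("alignment_set", class(aln)))
  aln[]
}
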