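#' Assign one read to the haploid or diploid reference
#'
#' Implements the three-step hierarchy used for dual-reference calling:
#' if the alignment scores differ, the read goes to the reference with the
#' higher score; if the scores tie, to the reference with the higher MAPQ;
#' if both tie, to the diploid assembly. A read mapped against only one
#' reference is assigned there (`reason = "only_mapped_one"`). A MAPQ of
#' 255 ("unavailable" by SAM convention) loses a tie against any numeric
#' MAPQ; two 255s tie.
#'
#' @param hap,dip one-row data.frames / lists with fields `mapped`, `AS`
#'   (alignment score) and `mapq`, or `NULL` when the read is absent from
#'   that input.
#' @return list with `assigned_to` (`"haploid"`/`"diploid"`) and `reason`
#'   (`"score"`, `"mapq"`, `"default"`, `"only_mapped_one"`).
#' @export
assign_read <- function(hap, dip) {
  hm <- !is.null(hap) && isTRUE(as.logical(hap$mapped %||% TRUE))
  dm <- !is.null(dip) && isTRUE(as.logical(dip$mapped %||% TRUE))
  if (!hm && !dm)
    stop("read unmapped against both references; pre-filter such reads")
  if (hm && !dm) return(list(assigned_to = "haploid", reason = "only_mapped_one"))
  if (!hm && dm) return(list(assigned_to = "diploid", reason = "only_mapped_one"))
  h_as <- as.integer(hap$AS); d_as <- as.integer(dip$AS)
  if (is.na(h_as) || is.na(d_as))
    stop("mapped reads must carry an alignment score (AS)")
  if (h_as != d_as)
    return(list(assigned_to = if (h_as > d_as) "haploid" else "diploid",
                reason = "score"))
  hq <- .effective_mapq(hap$mapq); dq <- .effective_mapq(dip$mapq)
  if (hq != dq)
    return(list(assigned_to = if (hq > dq) "haploid" else "diploid",
                reason = "mapq"))
  list(assigned_to = "diploid", reason = "default")
}

## MAPQ 255 = unavailable: treated below every numeric value in comparisons
.effective_mapq <- function(q) {
  q <- as.integer(q)
  ifelse(is.na(q) | q == 255L, -1L, q)
}

#' Does an alignment carry clipping?
#'
#' @param cigar character vector of CIGAR strings.
#' @return logical: `TRUE` where the CIGAR contains a soft (`S`) or hard
#'   (`H`) clip operation.
#' @export
is_clipped <- function(cigar) {
  grepl("[SH]", cigar) & cigar != "*"
}

#' Partition reads between the haploid and diploid reference
#'
#' Applies [assign_read()] to every (qname, mate) present in either input,
#' after dropping secondary/supplementary records, then removes duplicates
#' and reads clipped in either alignment from the outputs (a read clipped
#' against one reference is distrusted against both). The decision log
#' covers every mapped read; the two output sets are disjoint by
#' (qname, mate).
#'
#' @param hap_aln,dip_aln `alignment_set`s of the same read set against the
#'   haploid and diploid references.
#' @return list of class `partition` with `haploid` and `diploid`
#'   (`alignment_set` subsets of the respective inputs) and `decisions`
#'   (data.table: qname, mate, hap_AS, dip_AS, hap_mapq, dip_mapq,
#'   assigned_to, reason, excluded in {"", "clipped", "duplicate"}).
#' @export
partition_alignments <- function(hap_aln, dip_aln) {
  hap <- .primary_only(as.data.table(hap_aln))
  dip <- .primary_only(as.data.table(dip_aln))
  for (nm in c("hap", "dip")) {
    d <- get(nm)
    dups <- d[, .N, by = .(qname, mate)][N > 1L]
    if (nrow(dups))
      stop("stream '", nm, "' has ", nrow(dups),
           " (qname, mate) pairs occurring more than once after ",
           "primary-alignment filtering, e.g. ", dups$qname[1])
  }

  h <- hap[, .(qname, mate, hap_AS = AS, hap_mapq = mapq,
               hap_mapped = mapped, hap_clip = is_clipped(cigar),
               hap_dup = dup)]
  d <- dip[, .(qname, mate, dip_AS = AS, dip_mapq = mapq,
               dip_mapped = mapped, dip_clip = is_clipped(cigar),
               dip_dup = dup)]
  m <- merge(h, d, by = c("qname", "mate"), all = TRUE)
  m[is.na(hap_mapped), hap_mapped := FALSE]
  m[is.na(dip_mapped), dip_mapped := FALSE]
  m <- m[hap_mapped | dip_mapped]          # decision subjects

  if (any(m$hap_mapped & m$dip_mapped &
            (is.na(m$hap_AS) | is.na(m$dip_AS))))
    stop("mapped reads without an alignment score (AS) cannot be assigned")

  ## vectorised three-step hierarchy
  hq <- .effective_mapq(m$hap_mapq); dq <- .effective_mapq(m$dip_mapq)
  only_h <- m$hap_mapped & !m$dip_mapped
  only_d <- !m$hap_mapped & m$dip_mapped
  both <- m$hap_mapped & m$dip_mapped
  assigned <- character(nrow(m)); reason <- character(nrow(m))
  assigned[only_h] <- "haploid"; reason[only_h] <- "only_mapped_one"
  assigned[only_d] <- "diploid"; reason[only_d] <- "only_mapped_one"
  sc <- both & m$hap_AS != m$dip_AS
  assigned[sc] <- ifelse(m$hap_AS[sc] > m$dip_AS[sc], "haploid", "diploid")
  reason[sc] <- "score"
  mq <- both & !sc & hq != dq
  assigned[mq] <- ifelse(hq[mq] > dq[mq], "haploid", "diploid")
  reason[mq] <- "mapq"
  df <- both & !sc & !mq
  assigned[df] <- "diploid"; reason[df] <- "default"

  clip <- (m$hap_mapped & !is.na(m$hap_clip) & m$hap_clip) |
    (m$dip_mapped & !is.na(m$dip_clip) & m$dip_clip)
  dupf <- (m$hap_mapped & !is.na(m$hap_dup) & m$hap_dup) |
    (m$dip_mapped & !is.na(m$dip_dup) & m$dip_dup)
  excluded <- ifelse(dupf, "duplicate", ifelse(clip, "clipped", ""))

  decisions <- data.table(
    qname = m$qname, mate = m$mate,
    hap_AS = m$hap_AS, dip_AS = m$dip_AS,
    hap_mapq = m$hap_mapq, dip_mapq = m$dip_mapq,
    assigned_to = assigned, reason = reason, excluded = excluded)

  keep <- decisions[excluded == ""]
  hap_keys <- keep[assigned_to == "haploid", .(qname, mate)]
  dip_keys <- keep[assigned_to == "diploid", .(qname, mate)]
  hap_out <- hap[hap_keys, on = c("qname", "mate"), nomatch = NULL][mapped == TRUE]
  dip_out <- dip[dip_keys, on = c("qname", "mate"), nomatch = NULL][mapped == TRUE]
  for (o in list(hap_out, dip_out))
    setattr(o, "class", c("alignment_set", "data.table", "data.frame"))
  setattr(hap_out, "seqlengths", attr(hap_aln, "seqlengths"))
  setattr(dip_out, "seqlengths", attr(dip_aln, "seqlengths"))
  structure(list(haploid = hap_out, diploid = dip_out, decisions = decisions),
            class = "partition")
}

## drop secondary (0x100) and supplementary (0x800) records
.primary_only <- function(aln) {
  aln[bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L]
}

#' @export
print.partition <- function(x, ...) {
  cat("partition:", nrow(x$haploid), "reads -> haploid,",
      nrow(x$diploid), "-> diploid,",
      sum(x$decisions$excluded != ""), "excluded\n")
  print(x$decisions[excluded == "", .N, by = .(assigned_to, reason)])
  invisible(x)
}

#' Write a decision log as TSV
#'
#' @param partition result of [partition_alignments()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_decision_log <- function(partition, path) {
  fwrite(partition$decisions, path, sep = "\t")
  invisible(path)
}
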