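## Shared fixtures and independent oracles. Oracles deliberately re-derive
## results by naive enumeration, never by calling the code paths they check.

library(data.table)

## one-position read stack: n reads of length `len` all covering `at`,
## with chosen base/qual at that position and reference elsewhere
make_stack <- function(ref_seq, at, n, base_at, qual_at = "G", mapq = 60L,
                       strand = NULL, len = 100L, rname = "chr1",
                       qprefix = "r", nm = NULL, start = NULL) {
  stopifnot(nchar(ref_seq) >= at)
  if (is.null(start)) start <- max(1L, at - as.integer(len / 2))
  start <- rep_len(as.integer(start), n)
  if (is.null(strand)) strand <- rep(c("+", "-"), length.out = n)
  seqs <- quals <- character(n)
  for (i in seq_len(n)) {
    s <- substring(ref_seq, start[i], start[i] + len - 1L)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    qs <- rep("G", len)                       # Q38
    ch[at - start[i] + 1L] <- base_at
    qs[at - start[i] + 1L] <- qual_at
    seqs[i] <- paste(ch, collapse = "")
    quals[i] <- paste(qs, collapse = "")
  }
  ref_chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  if (is.null(nm))
    nm <- vapply(seq_len(n), function(i) {
      rc <- ref_chars[start[i]:(start[i] + len - 1L)]
      sum(strsplit(seqs[i], "", fixed = TRUE)[[1]] != rc)
    }, integer(1))
  alignment_set(
    qname = paste0(qprefix, seq_len(n)), mate = 1L, rname = rname,
    pos = start, mapq = mapq, cigar = paste0(len, "M"), seq = seqs,
    qual = quals, AS = alignment_score(len, nm), NM = as.integer(nm),
    strand = rep_len(strand, n), mapped = TRUE,
    seqlengths = setNames(nchar(ref_seq), rname))
}

random_ref <- function(len, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
}

## ---- independent assignment oracle: literal per-read rule application ----
brute_assign_one <- function(h_mapped, d_mapped, h_as, d_as, h_mq, d_mq) {
  if (h_mapped && !d_mapped) return(c("haploid", "only_mapped_one"))
  if (!h_mapped && d_mapped) return(c("diploid", "only_mapped_one"))
  if (h_as != d_as) {
    if (h_as > d_as) return(c("haploid", "score"))
    return(c("diploid", "score"))
  }
  hq <- if (is.na(h_mq) || h_mq == 255) -1 else h_mq
  dq <- if (is.na(d_mq) || d_mq == 255) -1 else d_mq
  if (hq != dq) {
    if (hq > dq) return(c("haploid", "mapq"))
    return(c("diploid", "mapq"))
  }
  c("diploid", "default")
}

brute_assign_all <- function(hap_aln, dip_aln) {
  h <- as.data.frame(hap_aln); h <- h[h$mapped, , drop = FALSE]
  d <- as.data.frame(dip_aln); d <- d[d$mapped, , drop = FALSE]
  hk <- paste(h$qname, h$mate); dk <- paste(d$qname, d$mate)
  keys <- union(hk, dk)
  hi <- match(keys, hk); di <- match(keys, dk)
  assigned <- reason <- character(length(keys))
  for (j in seq_along(keys)) {
    r <- brute_assign_one(!is.na(hi[j]), !is.na(di[j]),
                          if (!is.na(hi[j])) h$AS[hi[j]] else NA,
                          if (!is.na(di[j])) d$AS[di[j]] else NA,
                          if (!is.na(hi[j])) h$mapq[hi[j]] else NA,
                          if (!is.na(di[j])) d$mapq[di[j]] else NA)
    assigned[j] <- r[1]; reason[j] <- r[2]
  }
  data.frame(key = keys, assigned_to = assigned, reason = reason)
}

## ---- independent pileup oracle: read-by-read recount (ungapped reads) ----
brute_recount <- function(aln, rname_q, pos_q, min_mapq = 0, min_bq = 0) {
  a <- as.data.frame(aln)
  ## cheap overlap prefilter; the counted logic below stays per-read
  a <- a[a$mapped & !is.na(a$pos) &
           a$pos <= pos_q & a$pos + nchar(a$seq) - 1L >= pos_q, , drop = FALSE]
  counts <- list()
  depth <- 0L
  for (i in seq_len(nrow(a))) {
    if (!a$mapped[i] || is.na(a$rname[i]) || a$rname[i] != rname_q) next
    len <- nchar(a$seq[i])
    if (!grepl("^[0-9]+M$", a$cigar[i])) next
    if (a$pos[i] > pos_q || a$pos[i] + len - 1L < pos_q) next
    if (a$mapq[i] < min_mapq) next
    off <- pos_q - a$pos[i] + 1L
    bq <- as.integer(charToRaw(substring(a$qual[i], off, off))) - 33L
    if (bq < min_bq) next
    b <- substring(a$seq[i], off, off)
    if (is.null(counts[[b]])) counts[[b]] <- c(n = 0L, fwd = 0L, rev = 0L)
    counts[[b]]["n"] <- counts[[b]]["n"] + 1L
    if (a$strand[i] == "+") counts[[b]]["fwd"] <- counts[[b]]["fwd"] + 1L
    else counts[[b]]["rev"] <- counts[[b]]["rev"] + 1L
    depth <- depth + 1L
  }
  list(depth = depth, counts = counts)
}

## ---- independent call re-verification from raw stringent pileup ----
brute_verify_call <- function(call, mutant_pileup, control, cfg) {
  al <- mutant_pileup$alleles
  st <- mutant_pileup$sites
  a <- al[al$rname == call$rname & al$pos == call$pos, ]
  s <- st[st$rname == call$rname & st$pos == call$pos, ]
  if (nrow(s) == 0) return(FALSE)
  in_ctrl <- any(control$positions$rname == call$rname &
                   control$positions$pos == call$pos)
  ref_rows <- a[a$base == s$ref, ]
  alt_rows <- a[a$base == call$alt, ]
  if (nrow(ref_rows) != 1 || nrow(alt_rows) != 1) return(FALSE)
  in_ctrl &&
    s$depth <= cfg$mutant_max_cov &&
    s$indel_ev == 0 &&
    nrow(a) == 2 &&
    alt_rows$count >= cfg$min_alt_reads &&
    alt_rows$fwd >= 1 && alt_rows$rev >= 1 &&
    ref_rows$mean_mm <= cfg$max_ref_mismatch &&
    (alt_rows$mean_mm - ref_rows$mean_mm) <= cfg$max_mismatch_delta
}

## a mock flank aligner returning a fixed footprint (for boundary tests)
fixed_aligner <- function(rname, start, end) {
  function(query, targets) list(rname = rname, start = start, end = end)
}
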