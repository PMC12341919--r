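#' Seed-based exact flank aligner
#'
#' Default pluggable aligner for [classify_read_mapping()]. Takes evenly
#' spaced exact seeds from the query, matches each against the target set
#' with `Biostrings::matchPattern`, keeps seeds with a single hit, chains
#' co-linear hits (equal diagonal within `colinear_gap`), and reports the
#' footprint of the best chain. Exact seeding is sufficient for synthetic
#' data, where homologous sequence is identical up to divergent blocks;
#' production use can plug in any function with the same contract.
#'
#' @param seed_len seed length (bp).
#' @param step distance between seed starts (bp).
#' @param colinear_gap maximum diagonal scatter within one chain (bp).
#' @return a function `(query, targets)` returning
#'   `list(rname, start, end)` for the best chain, or `NULL` when no seed
#'   matches uniquely; `targets` is a named character vector.
#' @export
exact_seed_aligner <- function(seed_len = 60L, step = 250L,
                               colinear_gap = 10000L) {
  force(seed_len); force(step); force(colinear_gap)
  function(query, targets) {
    qlen <- nchar(query)
    if (qlen < seed_len) return(NULL)
    offs <- unique(c(seq(1L, qlen - seed_len + 1L, by = step),
                     qlen - seed_len + 1L))
    hits <- list()
    for (o in offs) {
      pat <- substring(query, o, o + seed_len - 1L)
      for (tn in names(targets)) {
        m <- Biostrings::matchPattern(pat, Biostrings::DNAString(targets[[tn]]))
        if (length(m) == 1L)
          hits[[length(hits) + 1L]] <- data.table(
            rname = tn, t_start = IRanges::start(m),
            t_end = IRanges::end(m), q_off = o)
        ## multi-hit seeds are ambiguous and discarded
      }
    }
    if (!length(hits)) return(NULL)
    h <- rbindlist(hits)
    ## ambiguous seeds hitting several targets once each: drop them too
    amb <- h[, .N, by = q_off][N > 1L, q_off]
    h <- h[!q_off %in% amb]
    if (!nrow(h)) return(NULL)
    h[, diag := t_start - q_off]
    best <- NULL
    for (tn in unique(h$rname)) {
      ht <- h[rname == tn][order(diag)]
      grp <- cumsum(c(1L, diff(ht$diag) > colinear_gap))
      for (gg in unique(grp)) {
        chain <- ht[grp == gg]
        if (is.null(best) || nrow(chain) > best$n)
          best <- list(rname = tn, start = min(chain$t_start),
                       end = max(chain$t_end), n = nrow(chain))
      }
    }
    list(rname = best$rname, start = best$start, end = best$end)
  }
}

#' Classify a diploid-aligned read as properly or improperly mapped
#'
#' Flank-based mismap detection: the read's diploid-assembly footprint is
#' extended by `flank_bp` on each side (a ~4.1 kb window for a 100-150 bp
#' read with 2 kb flanks, clipped at contig ends), the window sequence is
#' aligned to the haploid assembly, and its haploid footprint gives the
#' read's expected position range. If the window's best haploid alignment
#' spans less than `min_span` (4 kb) the verdict is `undefined`. Otherwise
#' the read is `proper` when its direct haploid alignment starts inside the
#' expected interval and `improper` when it lies elsewhere or the read
#' failed to map to the haploid assembly at all.
#'
#' @param read_dip one-row `alignment_set` (or list) with the read's
#'   diploid-reference alignment (`rname`, `pos`, `seq` or `end`).
#' @param dip_ref,hap_ref named character vectors of diploid / haploid
#'   reference sequences.
#' @param hap_read the same read's haploid-reference alignment (one-row
#'   `alignment_set` or list), or `NULL` if unmapped there.
#' @param flank_aligner function `(query, targets) -> list(rname, start,
#'   end) | NULL`; defaults to [exact_seed_aligner()].
#' @param flank_bp flank width (bp) added on each side of the read.
#' @param min_span minimum haploid span (bp) of the window alignment for a
#'   defined verdict.
#' @return list of class `mismap_verdict`: `verdict` in
#'   `{"proper", "improper", "undefined"}`, `expected_interval`
#'   (list(rname, start, end) or NULL), `observed` (list(rname, pos) or
#'   NULL).
#' @export
classify_read_mapping <- function(read_dip, dip_ref, hap_ref, hap_read = NULL,
                                  flank_aligner = exact_seed_aligner(),
                                  flank_bp = 2000L, min_span = 4000L) {
  rn <- read_dip$rname
  if (!rn %in% names(dip_ref))
    stop("diploid contig '", rn, "' not in dip_ref")
  read_len <- if (!is.null(read_dip$seq) && nzchar(read_dip$seq))
    nchar(read_dip$seq) else (read_dip$end - read_dip$pos + 1L)
  tlen <- nchar(dip_ref[[rn]])
  w_start <- max(1L, read_dip$pos - flank_bp)
  w_end <- min(tlen, read_dip$pos + read_len - 1L + flank_bp)
  window <- substring(dip_ref[[rn]], w_start, w_end)

  res <- flank_aligner(window, hap_ref)
  verdict <- function(v, exp_int, obs)
    structure(list(verdict = v, expected_interval = exp_int, observed = obs),
              class = "mismap_verdict")
  obs <- if (!is.null(hap_read) && isTRUE(as.logical(hap_read$mapped %||% TRUE)))
    list(rname = hap_read$rname, pos = hap_read$pos) else NULL
  if (is.null(res) || (res$end - res$start + 1L) < min_span)
    return(verdict("undefined", NULL, obs))
  exp_int <- list(rname = res$rname, start = res$start, end = res$end)
  if (is.null(obs))
    return(verdict("improper", exp_int, NULL))
  ok <- obs$rname == exp_int$rname &&
    obs$pos >= exp_int$start && obs$pos <= exp_int$end
  verdict(if (ok) "proper" else "improper", exp_int, obs)
}

#' Classify every read of a diploid alignment set
#'
#' @param dip_aln diploid-reference `alignment_set` (mapped reads only are
#'   classified).
#' @param hap_aln haploid-reference `alignment_set` of the same reads.
#' @param dip_ref,hap_ref named character vectors of reference sequences.
#' @inheritParams classify_read_mapping
#' @return data.table: qname, mate, verdict, exp_rname, exp_start, exp_end,
#'   obs_rname, obs_pos.
#' @export
classify_read_mappings <- function(dip_aln, hap_aln, dip_ref, hap_ref,
                                   flank_aligner = exact_seed_aligner(),
                                   flank_bp = 2000L, min_span = 4000L) {
  dip <- as.data.table(dip_aln)[mapped == TRUE]
  hap <- as.data.table(hap_aln)
  setkey(hap, qname, mate)
  out <- vector("list", nrow(dip))
  for (i in seq_len(nrow(dip))) {
    hr <- hap[.(dip$qname[i], dip$mate[i]), nomatch = NULL]
    hr <- if (nrow(hr) && hr$mapped[1]) as.list(hr[1]) else NULL
    v <- classify_read_mapping(as.list(dip[i]), dip_ref, hap_ref, hr,
                               flank_aligner, flank_bp, min_span)
    out[[i]] <- data.table(
      qname = dip$qname[i], mate = dip$mate[i], verdict = v$verdict,
      exp_rname = v$expected_interval$rname %||% NA_character_,
      exp_start = v$expected_interval$start %||% NA_integer_,
      exp_end = v$expected_interval$end %||% NA_integer_,
      obs_rname = v$observed$rname %||% NA_character_,
      obs_pos = v$observed$pos %||% NA_integer_)
  }
  rbindlist(out)
}

#' Configuration of the germline short-read vs long-read cross-check
#'
#' @param min_depth_factor,max_depth_factor admissible depth window as
#'   multiples of sample mean coverage.
#' @param min_vaf minimum variant allele frequency.
#' @param require_pass require `FILTER == "PASS"`.
#' @param min_hifi_support minimum long-read alternate observations for a
#'   variant to count as reproduced.
#' @return list of class `germline_check_config`.
#' @export
germline_check_config <- function(min_depth_factor = 0.5,
                                  max_depth_factor = 2.0,
                                  min_vaf = 0.3, require_pass = TRUE,
                                  min_hifi_support = 5L) {
  stopifnot(min_depth_factor > 0, max_depth_factor > 0, min_vaf >= 0,
            min_vaf <= 1)
  structure(list(min_depth_factor = min_depth_factor,
                 max_depth_factor = max_depth_factor, min_vaf = min_vaf,
                 require_pass = require_pass,
                 min_hifi_support = as.integer(min_hifi_support)),
            class = "germline_check_config")
}

#' Cross-check short-read germline variants against long-read pileups
#'
#' A variant enters the check iff its depth lies within
#' `[min_depth_factor, max_depth_factor] * sample_mean_depth` (inclusive),
#' its VAF is at least `min_vaf`, and (when required) its FILTER is PASS.
#' An eligible variant is `reproduced` iff the long-read pileup shows at
#' least `min_hifi_support` reads carrying its alternate allele. The
#' returned table carries a `not_reproduced_by_bin` attribute: the
#' fraction of eligible variants not reproduced, stratified by 0.05-wide
#' VAF bins.
#'
#' @param variants data.frame with columns rname, pos, ref, alt, depth,
#'   vaf, filter.
#' @param sample_mean_depth mean short-read coverage of the sample.
#' @param hifi_pileup a `pileup` of long reads over the same reference.
#' @param cfg a [germline_check_config()].
#' @return data.table: the input plus `eligible`, `hifi_alt` and
#'   `reproduced` columns.
#' @export
crosscheck_germline_variants <- function(variants, sample_mean_depth,
                                         hifi_pileup,
                                         cfg = germline_check_config()) {
  v <- as.data.table(variants)
  need <- c("rname", "pos", "ref", "alt", "depth", "vaf", "filter")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("variants table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(v$vaf) || anyNA(v$filter))
    stop("variants carry missing VAF/FILTER annotations")
  v[, eligible := depth >= cfg$min_depth_factor * sample_mean_depth &
      depth <= cfg$max_depth_factor * sample_mean_depth &
      vaf >= cfg$min_vaf &
      (!cfg$require_pass | filter == "PASS")]
  al <- hifi_pileup$alleles[, .(rname, pos, base, count)]
  v <- al[v, on = c(rname = "rname", pos = "pos", base = "alt")]
  setnames(v, "base", "alt")
  v[is.na(count), count := 0L]
  setnames(v, "count", "hifi_alt")
  v[, reproduced := eligible & hifi_alt >= cfg$min_hifi_support]
  v[eligible == FALSE, reproduced := NA]
  ev <- v[eligible == TRUE]
  bins <- if (nrow(ev)) {
    ev[, vaf_bin := sprintf("[%.2f,%.2f)", floor(vaf / 0.05) * 0.05,
                            floor(vaf / 0.05) * 0.05 + 0.05)]
    ev[, .(n = .N, frac_not_reproduced = mean(!reproduced)), by = vaf_bin][order(vaf_bin)]
  } else data.table(vaf_bin = character(0), n = integer(0),
                    frac_not_reproduced = numeric(0))
  setattr(v, "not_reproduced_by_bin", bins)
  v[]
}
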