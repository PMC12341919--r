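#' Mode-specific calling configuration
#'
#' Thresholds of the dual-reference caller. Against the diploid assembly
#' the control mask requires coverage >= 20x and the mutant sample is
#' capped at <= 70x; against the haploid assembly the control requires
#' coverage above 40x (i.e. >= 41) and the mutant cap is <= 120x (doubled,
#' since the haploid reference carries both haplotypes' reads at one
#' locus). The mutant pileup is counted at MAPQ of at least 10 and base
#' quality of at least 30; a call needs at least 3 alternate reads with
#' support on both strands, reference-read mean mismatch at most 0.01, and
#' alternate-minus-reference mean mismatch at most 0.01.
#'
#' @param mode `"haploid"` or `"diploid"`.
#' @param max_control_alt maximum non-reference base observations tolerated
#'   at a control position (default 0: any alternate evidence under the
#'   lenient thresholds disqualifies the position).
#' @return list of class `mode_config`.
#' @export
mode_config <- function(mode = c("diploid", "haploid"), max_control_alt = 0L) {
  mode <- match.arg(mode)
  structure(list(
    mode = mode,
    control_min_cov = if (mode == "diploid") 20L else 41L,
    mutant_max_cov = if (mode == "diploid") 70L else 120L,
    control_min_mapq = 0L, control_min_bq = 0L,
    mutant_min_mapq = 10L, mutant_min_bq = 30L,
    min_alt_reads = 3L, require_both_strands = TRUE,
    max_ref_mismatch = 0.01, max_mismatch_delta = 0.01,
    max_control_alt = as.integer(max_control_alt)),
    class = "mode_config")
}

#' Build the set of control positions
#'
#' Positions where the control sample is confidently homozygous-reference:
#' depth at lenient thresholds (MAPQ >= 0, BQ >= 0) at or above the
#' mode's control minimum, no indel evidence, and at most
#' `max_control_alt` (default zero) non-reference base observations. The
#' lenient counting exists to let *any* alternate evidence in the control
#' disqualify a position, which minimises false somatic calls.
#'
#' @param control_pileup a `pileup` of the control sample; must have been
#'   computed at the lenient thresholds (checked from metadata).
#' @param cfg a [mode_config()].
#' @return list of class `control_positions` with `mode` and `positions`
#'   (data.table: rname, pos).
#' @export
build_control_positions <- function(control_pileup, cfg) {
  stopifnot(inherits(control_pileup, "pileup"), inherits(cfg, "mode_config"))
  th <- control_pileup$thresholds
  if (th$min_mapq != cfg$control_min_mapq || th$min_bq != cfg$control_min_bq)
    stop("control pileup was computed at MAPQ >= ", th$min_mapq, ", BQ >= ",
         th$min_bq, " but the control mask requires the lenient thresholds ",
         "MAPQ >= ", cfg$control_min_mapq, ", BQ >= ", cfg$control_min_bq)
  s <- control_pileup$sites
  a <- control_pileup$alleles
  nonref <- merge(a, s[, .(rname, pos, ref)], by = c("rname", "pos"))
  nonref <- nonref[base != ref, .(nonref = sum(count)), by = .(rname, pos)]
  s2 <- merge(s, nonref, by = c("rname", "pos"), all.x = TRUE)
  s2[is.na(nonref), nonref := 0L]
  keep <- s2[depth >= cfg$control_min_cov & indel_ev == 0L &
               nonref <= cfg$max_control_alt, .(rname, pos)]
  setorder(keep, rname, pos)
  structure(list(mode = cfg$mode, positions = keep),
            class = "control_positions")
}

#' @export
print.control_positions <- function(x, ...) {
  cat("control_positions (", x$mode, "): ", nrow(x$positions),
      " positions\n", sep = "")
  invisible(x)
}

#' Write control positions as BED (0-based half-open)
#'
#' @param control a `control_positions` object.
#' @param path output BED path.
#' @return invisibly, `path`.
#' @export
write_control_bed <- function(control, path) {
  p <- control$positions
  writeLines(sprintf("%s\t%d\t%d", p$rname, p$pos - 1L, p$pos), path)
  invisible(path)
}

#' Call somatic SNV candidates with the stringent filter cascade
#'
#' A site is emitted iff all of the following hold: the position is in the
#' control set; depth does not exceed the mode's mutant cap; exactly two
#' base alleles are observed (reference plus one alternate) with no indel
#' evidence; the alternate has at least `min_alt_reads` supporting reads on
#' both strands; reference-read mean mismatch fraction <= 0.01; and the
#' alternate-minus-reference mean mismatch difference is <= 0.01. Failing
#' sites are dropped silently; the attribute `drop_counts` tallies the
#' first filter each candidate (site with alternate evidence) failed.
#'
#' @param mutant_pileup a `pileup` of the mutant sample computed at the
#'   mode's stringent thresholds (checked from metadata).
#' @param control a `control_positions` object of the same mode.
#' @param cfg a [mode_config()].
#' @param sample_label label recorded on each call (e.g. `"upper"`).
#' @return data.table of class `somatic_calls`: rname, pos, ref, alt,
#'   alt_count, alt_fwd, alt_rev, depth, vaf, ref_mm, alt_mm, mode,
#'   sample_label, filter_trace.
#' @export
call_somatic_candidates <- function(mutant_pileup, control, cfg,
                                    sample_label = "mutant") {
  stopifnot(inherits(mutant_pileup, "pileup"),
            inherits(control, "control_positions"),
            inherits(cfg, "mode_config"))
  if (control$mode != cfg$mode)
    stop("control set mode '", control$mode, "' does not match cfg mode '",
         cfg$mode, "'")
  th <- mutant_pileup$thresholds
  if (th$min_mapq != cfg$mutant_min_mapq || th$min_bq != cfg$mutant_min_bq)
    stop("mutant pileup was computed at MAPQ >= ", th$min_mapq, ", BQ >= ",
         th$min_bq, " but the caller requires MAPQ >= ", cfg$mutant_min_mapq,
         ", BQ >= ", cfg$mutant_min_bq)

  s <- mutant_pileup$sites
  a <- merge(mutant_pileup$alleles, s[, .(rname, pos, ref, depth, indel_ev)],
             by = c("rname", "pos"))
  a[, is_ref := base == ref]
  site <- a[, .(
    n_alleles = .N,
    ref_count = sum(count[is_ref]),
    ref_mm = if (any(is_ref)) mean_mm[is_ref][1] else NA_real_,
    alt = if (any(!is_ref)) base[!is_ref][which.max(count[!is_ref])] else NA_character_,
    alt_count = if (any(!is_ref)) max(count[!is_ref]) else 0L,
    alt_fwd = if (any(!is_ref)) fwd[!is_ref][which.max(count[!is_ref])] else 0L,
    alt_rev = if (any(!is_ref)) rev[!is_ref][which.max(count[!is_ref])] else 0L,
    alt_mm = if (any(!is_ref)) mean_mm[!is_ref][which.max(count[!is_ref])] else NA_real_,
    depth = depth[1], indel_ev = indel_ev[1], ref = ref[1]),
    by = .(rname, pos)]

  cand <- site[!is.na(alt)]
  ctrl_key <- control$positions
  in_ctrl <- if (nrow(ctrl_key))
    !is.na(ctrl_key[cand, on = c("rname", "pos"), which = TRUE])
  else rep(FALSE, nrow(cand))

  checks <- list(
    in_control = in_ctrl,
    depth_cap = cand$depth <= cfg$mutant_max_cov,
    no_indel = cand$indel_ev == 0L,
    biallelic = cand$n_alleles == 2L & cand$ref_count > 0L,
    alt_support = cand$alt_count >= cfg$min_alt_reads &
      (!cfg$require_both_strands | (cand$alt_fwd >= 1L & cand$alt_rev >= 1L)),
    ref_mismatch = !is.na(cand$ref_mm) & cand$ref_mm <= cfg$max_ref_mismatch,
    mismatch_delta = !is.na(cand$ref_mm) & !is.na(cand$alt_mm) &
      (cand$alt_mm - cand$ref_mm) <= cfg$max_mismatch_delta)

  pass_all <- Reduce(`&`, checks)
  ## first-failure accounting for dropped candidates
  drop_counts <- integer(length(checks)); names(drop_counts) <- names(checks)
  failed <- !pass_all
  remaining <- failed
  for (nm in names(checks)) {
    hit <- remaining & !checks[[nm]]
    drop_counts[[nm]] <- sum(hit)
    remaining <- remaining & !hit
  }

  calls <- cand[pass_all, .(rname, pos, ref, alt, alt_count, alt_fwd, alt_rev,
                            depth, vaf = alt_count / depth, ref_mm, alt_mm)]
  set(calls, j = "mode", value = cfg$mode)
  set(calls, j = "sample_label", value = sample_label)
  set(calls, j = "filter_trace", value = paste(names(checks), collapse = ";"))
  setorder(calls, rname, pos)
  setattr(calls, "drop_counts", drop_counts)
  setattr(calls, "class", c("somatic_calls", class(calls)))
  calls[]
}

#' Merge haploid- and diploid-mode call sets
#'
#' Diploid-mode calls are projected onto haploid coordinates through the
#' coordinate map; a haploid call and a diploid call at the same mapped
#' site with the same alternate allele collapse into one record whose
#' `provenance` lists both modes. Calls at one mapped site with
#' *different* alternate alleles are both kept and flagged
#' `conflict = TRUE`. Unmappable diploid calls are retained as-is.
#'
#' @param hap_calls,dip_calls `somatic_calls` tables (either may be empty).
#' @param coord_map data.table with columns hap_rname, hap_start, hap_end,
#'   dip_rname, dip_start describing collinear blocks (see
#'   [build_coord_map()]).
#' @return data.table of class `merged_calls`: key_rname, key_pos (haploid
#'   coordinates where mappable), ref, alt, provenance, conflict, vaf per
#'   mode, sorted by haploid coordinate.
#' @export
merge_call_sets <- function(hap_calls, dip_calls, coord_map) {
  hap <- as.data.table(hap_calls)
  dip <- as.data.table(dip_calls)
  empty_cols <- function() data.table(
    key_rname = character(0), key_pos = integer(0), ref = character(0),
    alt = character(0), provenance = character(0), conflict = logical(0),
    vaf_haploid = numeric(0), vaf_diploid = numeric(0))
  if (nrow(hap) == 0L && nrow(dip) == 0L)
    return(structure(empty_cols(), class = c("merged_calls", "data.table",
                                             "data.frame")))
  h <- if (nrow(hap)) hap[, .(key_rname = rname, key_pos = pos, ref, alt,
                              vaf_haploid = vaf)] else NULL
  d <- NULL
  if (nrow(dip)) {
    d <- copy(dip)
    cm <- as.data.table(coord_map)
    d[, `:=`(key_rname = NA_character_, key_pos = NA_integer_)]
    for (i in seq_len(nrow(cm))) {
      w <- d$rname == cm$dip_rname[i] &
        d$pos >= cm$dip_start[i] &
        d$pos <= cm$dip_start[i] + (cm$hap_end[i] - cm$hap_start[i])
      if (any(w)) {
        d$key_rname[w] <- cm$hap_rname[i]
        d$key_pos[w] <- cm$hap_start[i] + (d$pos[w] - cm$dip_start[i])
      }
    }
    d[is.na(key_rname), `:=`(key_rname = rname, key_pos = pos)]
    d <- d[, .(key_rname, key_pos, ref, alt, vaf_diploid = vaf)]
  }
  all_calls <- rbindlist(list(
    if (!is.null(h)) h[, .(key_rname, key_pos, ref, alt, vaf_haploid,
                           vaf_diploid = NA_real_, mode = "haploid")],
    if (!is.null(d)) d[, .(key_rname, key_pos, ref, alt,
                           vaf_haploid = NA_real_, vaf_diploid, mode = "diploid")]))
  merged <- all_calls[, .(
    ref = ref[1],
    provenance = paste(sort(unique(mode)), collapse = ","),
    vaf_haploid = if (any(!is.na(vaf_haploid))) max(vaf_haploid, na.rm = TRUE) else NA_real_,
    vaf_diploid = if (any(!is.na(vaf_diploid))) max(vaf_diploid, na.rm = TRUE) else NA_real_),
    by = .(key_rname, key_pos, alt)]
  merged[, conflict := .N > 1L, by = .(key_rname, key_pos)]
  setcolorder(merged, c("key_rname", "key_pos", "ref", "alt", "provenance",
                        "conflict", "vaf_haploid", "vaf_diploid"))
  setorder(merged, key_rname, key_pos, alt)
  structure(merged, class = c("merged_calls", class(merged)))
}

#' Coordinate map between a simulated haploid and diploid reference
#'
#' Both haplotype contigs of the simulated diploid reference are collinear
#' with the haploid (hapA) chromosome, except within divergent blocks,
#' where hapB sequence has no haploid counterpart; those intervals are
#' excluded from the hapB mapping.
#'
#' @param genome a `diploid_genome`.
#' @return data.table with columns hap_rname, hap_start, hap_end,
#'   dip_rname, dip_start.
#' @export
build_coord_map <- function(genome) {
  stopifnot(inherits(genome, "diploid_genome"))
  rows <- list()
  for (cc in names(genome$hapA)) {
    len <- genome$chrom_len[[cc]]
    rows[[length(rows) + 1L]] <- data.table(
      hap_rname = cc, hap_start = 1L, hap_end = len,
      dip_rname = paste0(cc, "_hapA"), dip_start = 1L)
    bl <- genome$divergent_blocks[chrom == cc][order(start)]
    segs <- if (nrow(bl)) {
      bounds <- data.table(s = c(1L, bl$end + 1L),
                           e = c(bl$start - 1L, len))
      bounds[s <= e]
    } else data.table(s = 1L, e = len)
    for (j in seq_len(nrow(segs)))
      rows[[length(rows) + 1L]] <- data.table(
        hap_rname = cc, hap_start = segs$s[j], hap_end = segs$e[j],
        dip_rname = paste0(cc, "_hapB"), dip_start = segs$s[j])
  }
  rbindlist(rows)
}

#' Count effective sites from a control depth track
#'
#' Effective sites are positions whose control-sample depth is strictly
#' above the minimum coverage ("above 20x"); they form the denominator of
#' per-site mutation rates.
#'
#' @param depth integer vector of per-position depth.
#' @param min_cov coverage threshold (strict).
#' @return integer count of positions with `depth > min_cov`.
#' @export
compute_effective_sites <- function(depth, min_cov = 20L) {
  sum(depth > min_cov)
}

#' Write somatic calls as VCF 4.2
#'
#' @param calls a `somatic_calls` table.
#' @param path output VCF path.
#' @param seqlengths optional named integer vector for `##contig` lines.
#' @return invisibly, `path`.
#' @export
write_calls_vcf <- function(calls, path, seqlengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(seqlengths))
             sprintf("##contig=<ID=%s,length=%d>", names(seqlengths),
                     as.integer(seqlengths)),
           "##INFO=<ID=MODE,Number=1,Type=String,Description=\"Reference mode\">",
           "##INFO=<ID=ALTFWD,Number=1,Type=Integer,Description=\"Alt forward reads\">",
           "##INFO=<ID=ALTREV,Number=1,Type=Integer,Description=\"Alt reverse reads\">",
           "##INFO=<ID=REFMM,Number=1,Type=Float,Description=\"Ref-read mean mismatch\">",
           "##INFO=<ID=ALTMM,Number=1,Type=Float,Description=\"Alt-read mean mismatch\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  dt <- as.data.table(calls)
  body <- if (nrow(dt)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tMODE=%s;ALTFWD=%d;ALTREV=%d;REFMM=%.4f;ALTMM=%.4f;VAF=%.4f;DP=%d",
    dt$rname, dt$pos, dt$ref, dt$alt, dt$mode, dt$alt_fwd, dt$alt_rev,
    dt$ref_mm, dt$alt_mm, dt$vaf, dt$depth) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
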