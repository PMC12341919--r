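#' Simulate a paired mutant/control study
#'
#' Builds one heterozygous diploid genome, implants layer-structured
#' somatic mutations into the "mutant" sample only, simulates paired short
#' reads for mutant and control from the same genome, and emits truth
#' alignments for both samples against both references. The control is a
#' biological replicate of the same individual without the somatic
#' implants (the two-branch design: each branch serves as the other's
#' control).
#'
#' @inheritParams simulate_diploid_genome
#' @inheritParams implant_somatic_mutations
#' @inheritParams simulate_reads
#' @param seed integer master seed; genome, implants and the two read sets
#'   use derived sub-seeds.
#' @return list of class `paired_study`: `genome`, `implants`, `mutant`,
#'   `control` (each a list with `sim`, `hap` and `dip` alignment sets),
#'   and `coord_map`.
#' @export
simulate_paired_study <- function(n_chrom = 1L, chrom_len = 1e5,
                                  het_rate = 0.016,
                                  divergent_spec = integer(0),
                                  layer_fractions = c(L1 = 0.18, L2 = 0.60, L3 = 0.22),
                                  n_per_layer = 0L, cell_fraction = 1.0,
                                  depth = 60, read_len = 150L,
                                  insert_mean = 400, insert_sd = 60,
                                  error_rate = 0.001, seed = 1L) {
  seed <- as.integer(seed)
  genome <- simulate_diploid_genome(n_chrom, chrom_len, het_rate,
                                    divergent_spec, seed = seed)
  implants <- implant_somatic_mutations(genome, layer_fractions, n_per_layer,
                                        cell_fraction, seed = seed + 1L)
  mut_sim <- simulate_reads(genome, implants, depth, read_len, insert_mean,
                            insert_sd, error_rate, seed = seed + 2L)
  ctl_sim <- simulate_reads(genome, NULL, depth, read_len, insert_mean,
                            insert_sd, error_rate, seed = seed + 3L)
  wrap <- function(sim) list(
    sim = sim,
    hap = emit_truth_alignments(sim, "haploid"),
    dip = emit_truth_alignments(sim, "diploid"))
  structure(list(genome = genome, implants = implants,
                 mutant = wrap(mut_sim), control = wrap(ctl_sim),
                 coord_map = build_coord_map(genome)),
            class = "paired_study")
}

#' Run dual-reference somatic calling on a paired study
#'
#' The full pipeline: partition each sample's reads between the haploid
#' and diploid reference by the score/MAPQ/default hierarchy, pile up the
#' control at lenient thresholds and the mutant at stringent thresholds in
#' each mode, build the control-position mask, apply the filter cascade,
#' and merge the two modes' calls through the coordinate map.
#'
#' @param study a `paired_study` (or an equivalent list with the same
#'   fields).
#' @param sample_label label for the mutant sample on emitted calls.
#' @return list of class `dual_calling`: `hap_calls`, `dip_calls`,
#'   `merged`, `control_hap`, `control_dip`, `mutant_partition`,
#'   `control_partition`.
#' @export
run_dual_calling <- function(study, sample_label = "mutant") {
  refs <- genome_references(study$genome)
  mp <- partition_alignments(study$mutant$hap, study$mutant$dip)
  cp <- partition_alignments(study$control$hap, study$control$dip)

  res <- list(mutant_partition = mp, control_partition = cp)
  for (mode in c("haploid", "diploid")) {
    cfg <- mode_config(mode)
    ref <- refs[[mode]]
    ctl_aln <- if (mode == "haploid") cp$haploid else cp$diploid
    mut_aln <- if (mode == "haploid") mp$haploid else mp$diploid
    ctl_pile <- pileup_table(ctl_aln, ref,
                             count_thresholds(cfg$control_min_mapq,
                                              cfg$control_min_bq))
    mut_pile <- pileup_table(mut_aln, ref,
                             count_thresholds(cfg$mutant_min_mapq,
                                              cfg$mutant_min_bq))
    ctl_set <- build_control_positions(ctl_pile, cfg)
    calls <- call_somatic_candidates(mut_pile, ctl_set, cfg, sample_label)
    if (mode == "haploid") {
      res$control_hap <- ctl_set; res$hap_calls <- calls
    } else {
      res$control_dip <- ctl_set; res$dip_calls <- calls
    }
  }
  res$merged <- merge_call_sets(res$hap_calls, res$dip_calls, study$coord_map)
  structure(res, class = "dual_calling")
}

#' @export
print.dual_calling <- function(x, ...) {
  cat("dual_calling:", nrow(x$hap_calls), "haploid-mode calls,",
      nrow(x$dip_calls), "diploid-mode calls,",
      nrow(x$merged), "merged\n")
  invisible(x)
}

#' Compare calls against implanted truth
#'
#' A merged call recovers an implant when it lies at the implant's haploid
#' coordinate with the implant's alternate allele.
#'
#' @param merged a `merged_calls` table.
#' @param implants a `somatic_implants` table.
#' @return list with `recovered` (logical per implant), `recall`,
#'   `n_false` (calls matching no implant).
#' @export
score_against_truth <- function(merged, implants) {
  m <- as.data.table(merged)
  imp <- as.data.table(implants)
  if (nrow(imp) == 0L)
    return(list(recovered = logical(0), recall = NA_real_,
                n_false = nrow(m)))
  key <- paste(m$key_rname, m$key_pos, m$alt)
  truth <- paste(imp$chrom, imp$pos, imp$alt)
  recovered <- truth %in% key
  list(recovered = recovered, recall = mean(recovered),
       n_false = sum(!key %in% truth))
}
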