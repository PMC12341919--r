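#' Estimate meristem-layer DNA fractions from shared-mutation VAFs
#'
#' Mutations shared between leaf and embryonic tissue mark the
#' sub-epidermal meristem layer L2, since embryos derive from L2. A fixed,
#' single-haplotype L2 mutation is observed at VAF = l2_fraction / 2, so
#' the central VAF of such shared mutations yields the L2 DNA fraction
#' directly: `l2_fraction = 2 * central VAF`. The remainder is split
#' between the epidermal L1 and the ground-tissue L3 with L1 contributing
#' less than L3, giving `l1_upper_bound = (1 - l2_fraction) / 2` and an
#' expected L1-fixed VAF below `l1_upper_bound / 2`.
#'
#' @param shared_vafs numeric vector of VAFs of layer-shared mutations,
#'   each in (0, 0.5].
#' @param center `"median"` (default) or `"mean"` summary of the VAFs.
#' @param vaf_threshold_haploid,vaf_threshold_diploid VAF thresholds used
#'   by [classify_l2_calls()] to retain likely-L2 (transmissible) calls;
#'   defaults 0.2 against the haploid reference (where one L2 haplotype is
#'   ~30% of reads) and 0.4 against the diploid reference (where coverage
#'   is split per haplotype, doubling observed VAF).
#' @return list of class `layer_model` with the fields above.
#' @export
estimate_layer_model <- function(shared_vafs, center = c("median", "mean"),
                                 vaf_threshold_haploid = 0.2,
                                 vaf_threshold_diploid = 0.4) {
  center <- match.arg(center)
  if (length(shared_vafs) == 0L)
    stop("at least one shared-mutation VAF is required")
  if (any(shared_vafs <= 0 | shared_vafs > 0.5))
    stop("shared VAFs must lie in (0, 0.5]")
  v <- if (center == "median") median(shared_vafs) else mean(shared_vafs)
  l2 <- 2 * v
  rest <- 1 - l2
  structure(list(
    median_shared_vaf = v,
    l2_fraction = l2,
    l1_plus_l3_fraction = rest,
    l1_upper_bound = rest / 2,
    expected_l1_vaf_upper = rest / 4,
    vaf_threshold_haploid = vaf_threshold_haploid,
    vaf_threshold_diploid = vaf_threshold_diploid),
    class = "layer_model")
}

#' @export
print.layer_model <- function(x, ...) {
  cat(sprintf(
    "layer_model: L2 %.0f%% of sample DNA (central shared VAF %.3f)\n",
    100 * x$l2_fraction, x$median_shared_vaf))
  cat(sprintf("  L1+L3 %.0f%%, L1 < %.0f%%, expected L1-fixed VAF < %.2f\n",
              100 * x$l1_plus_l3_fraction, 100 * x$l1_upper_bound,
              x$expected_l1_vaf_upper))
  invisible(x)
}

#' Retain likely-L2 (transmissible) somatic calls
#'
#' A call is kept iff its VAF reaches the mode-specific threshold:
#' `vaf >= vaf_threshold_haploid` for haploid-mode calls,
#' `vaf >= vaf_threshold_diploid` for diploid-mode calls.
#'
#' @param calls a `somatic_calls` table (needs `vaf` and `mode`).
#' @param model a `layer_model`.
#' @return the retained subset, same class as the input.
#' @export
classify_l2_calls <- function(calls, model) {
  dt <- as.data.table(calls)
  if (nrow(dt) == 0L) return(calls)
  thr <- ifelse(dt$mode == "haploid", model$vaf_threshold_haploid,
                model$vaf_threshold_diploid)
  out <- dt[dt$vaf >= thr]
  setattr(out, "class", class(calls))
  out
}

#' Per-site, annual and generational mutation rates
#'
#' `raw_rate = n / effective_sites` (per bp),
#' `annual_rate = raw_rate / age_years` (per bp per year),
#' `generational_rate = annual_rate * generation_years` (per bp per
#' generation).
#'
#' @param n number of mutations.
#' @param effective_sites callable site count (bp); must be positive.
#' @param age_years age of the individual (years).
#' @param generation_years assumed generation time (years).
#' @return list of class `mutation_rate_estimate`.
#' @export
mutation_rate <- function(n, effective_sites, age_years = 234,
                          generation_years = 50) {
  if (effective_sites <= 0) stop("effective_sites must be positive")
  stopifnot(n >= 0, age_years > 0, generation_years > 0)
  raw <- n / effective_sites
  annual <- raw / age_years
  structure(list(
    n_mutations = n, effective_sites = effective_sites,
    age_years = age_years, generation_years = generation_years,
    raw_rate = raw, annual_rate = annual,
    generational_rate = annual * generation_years),
    class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, sigfigs = 2, ...) {
  cat(sprintf("mutation rates (n = %d over %.3g bp):\n",
              x$n_mutations, x$effective_sites))
  cat(sprintf("  raw          %s per bp\n", signif(x$raw_rate, sigfigs)))
  cat(sprintf("  annual       %s per bp per year (age %g y)\n",
              signif(x$annual_rate, sigfigs), x$age_years))
  cat(sprintf("  generational %s per bp per generation (%g y)\n",
              signif(x$generational_rate, sigfigs), x$generation_years))
  invisible(x)
}

.SPECTRUM_CLASSES <- data.table::data.table(
  class = c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"),
  label = c("C:G>A:T", "C:G>G:C", "C:G>T:A", "T:A>A:T", "T:A>C:G", "T:A>G:C"))

#' Mutation spectrum over the six pyrimidine substitution classes
#'
#' Purine-reference substitutions are folded onto the pyrimidine strand
#' (e.g. G>A becomes C>T), and counts are reported per class with
#' both-strand labels (C:G>T:A etc.). Counts always sum to the number of
#' input SNVs.
#'
#' @param ref,alt character vectors of reference and alternate bases
#'   (single A/C/G/T each), or a `somatic_calls`/`merged_calls` table via
#'   `calls`.
#' @param calls optional calls table with `ref` and `alt` columns.
#' @return data.table of class `spectrum_table`: class, label, count.
#' @export
mutation_spectrum <- function(ref = NULL, alt = NULL, calls = NULL) {
  if (!is.null(calls)) {
    ref <- calls$ref; alt <- calls$alt
  }
  stopifnot(length(ref) == length(alt))
  ok <- ref %in% DNA_BASES & alt %in% DNA_BASES
  if (any(!ok))
    stop("ambiguous or non-ACGT base(s) in spectrum input: ",
         paste(unique(c(ref[!ok], alt[!ok])), collapse = ", "))
  if (any(ref == alt)) stop("ref and alt must differ")
  folded <- fold_to_pyrimidine(ref, alt)
  cls <- paste0(folded$ref, ">", folded$alt)
  out <- copy(.SPECTRUM_CLASSES)
  tab <- table(factor(cls, levels = out$class))
  out[, count := as.integer(tab[class])]
  structure(out, class = c("spectrum_table", class(out)))
}

#' Fold substitutions onto the pyrimidine strand
#'
#' Applied twice, folding equals folding applied once (it fixes
#' pyrimidine-reference substitutions).
#'
#' @param ref,alt single-base character vectors.
#' @return list with folded `ref` and `alt` vectors.
#' @export
fold_to_pyrimidine <- function(ref, alt) {
  pur <- ref %in% c("A", "G")
  list(ref = ifelse(pur, unname(.comp[ref]), ref),
       alt = ifelse(pur, unname(.comp[alt]), alt))
}
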