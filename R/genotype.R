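#' Expected variant allele fraction of a fully clonal mutation
#'
#' Computes the VAF expected for a mutation present in every tumor cell,
#' given the number of mutated alleles per tumor cell (multiplicity), the
#' total tumor copy number at the locus, and the tumor cell fraction of the
#' sample:
#' \deqn{VAF_{exp} = \frac{n_{mut}\,\rho}{2(1-\rho) + n_{tot}\,\rho}}
#' The denominator counts alleles per cell averaged over the admixture of
#' diploid normal cells (2 copies) and tumor cells (`n_tot` copies).
#'
#' @param n_mut integer vector, number of mutated alleles per tumor cell
#'   (>= 1, <= `n_tot`).
#' @param n_tot integer vector, total tumor copy number at the locus (>= 1).
#' @param purity numeric vector, tumor cell fraction rho in (0, 1].
#' @return Numeric vector of expected VAFs in (0, 1].
#' @examples
#' expected_vaf(1, 2, 1.0)  # pure-tumor diploid heterozygous: 0.5
#' expected_vaf(1, 2, 0.5)  # half-pure sample: 0.25
#' @export
expected_vaf <- function(n_mut, n_tot, purity) {
  n <- max(length(n_mut), length(n_tot), length(purity))
  n_mut <- rep_len(n_mut, n); n_tot <- rep_len(n_tot, n)
  purity <- rep_len(purity, n)
  if (any(!is.finite(purity)) || any(purity <= 0) || any(purity > 1))
    stop("'purity' must lie in (0, 1]; a sample with no tumor content has no expected VAF")
  if (any(n_tot < 1) || any(n_mut < 1))
    stop("'n_mut' and 'n_tot' must be >= 1")
  if (any(n_mut > n_tot))
    stop("'n_mut' cannot exceed 'n_tot'")
  (n_mut * purity) / (2 * (1 - purity) + n_tot * purity)
}

#' Relative variant allele fraction (rVAF)
#'
#' The observed VAF divided by the VAF expected for a fully clonal mutation
#' with the given multiplicity, local total copy number and tumor cell
#' fraction. Truncal mutations have rVAF near 1; subclonal mutations fall
#' below 1. Sampling noise can push rVAF above 1 — the raw value is returned
#' uncapped; use [cellular_prevalence()] for a \[0, 1\]-clamped version
#' suitable as a cellular-prevalence estimate.
#'
#' @param vaf_obs observed VAF (alt reads / total reads), in \[0, 1\].
#' @inheritParams expected_vaf
#' @return Numeric vector of raw rVAF values (>= 0, uncapped).
#' @seealso [cellular_prevalence()], [expected_vaf()]
#' @examples
#' rvaf(0.25, n_mut = 1, n_tot = 2, purity = 0.5)  # 1: clonal
#' @export
rvaf <- function(vaf_obs, n_mut = 1L, n_tot = 2L, purity) {
  if (any(vaf_obs < 0 | vaf_obs > 1, na.rm = TRUE))
    stop("'vaf_obs' must lie in [0, 1]")
  vaf_obs / expected_vaf(n_mut, n_tot, purity)
}

#' Clamped cellular prevalence from rVAF
#'
#' @inheritParams rvaf
#' @return `pmin(rvaf, 1)`: the rVAF clamped to \[0, 1\].
#' @export
cellular_prevalence <- function(vaf_obs, n_mut = 1L, n_tot = 2L, purity) {
  pmin(rvaf(vaf_obs, n_mut, n_tot, purity), 1)
}

#' Estimate mutation multiplicity from an observed VAF
#'
#' Picks the number of mutated alleles m in 1..`n_tot` whose clonal expected
#' VAF is nearest to the observed VAF; ties break toward the smaller m.
#'
#' @inheritParams rvaf
#' @return Integer vector of estimated multiplicities.
#' @examples
#' estimate_multiplicity(0.5, n_tot = 2, purity = 1)    # 1
#' estimate_multiplicity(0.95, n_tot = 2, purity = 1)   # 2
#' @export
estimate_multiplicity <- function(vaf_obs, n_tot, purity) {
  n <- max(length(vaf_obs), length(n_tot), length(purity))
  vaf_obs <- rep_len(vaf_obs, n); n_tot <- rep_len(as.integer(n_tot), n)
  purity <- rep_len(purity, n)
  vapply(seq_len(n), function(i) {
    m <- seq_len(n_tot[i])
    d <- abs(vaf_obs[i] - expected_vaf(m, n_tot[i], purity[i]))
    m[which.min(d)]  # which.min returns the first minimum: smaller m wins ties
  }, integer(1))
}

#' Tumor mutational burden
#'
#' Mutations per megabase of sequenced target. With `coding_only = TRUE`
#' (the default) only amino-acid-changing effects (missense, nonsense,
#' frameshift, splice) are counted, matching exome pipelines that discard
#' synonymous calls before burden analysis.
#'
#' @param mutations data frame of mutation observations; needs an `effect`
#'   column when `coding_only = TRUE`. If `patient_id`/`timepoint` columns
#'   are present the burden is computed per sample.
#' @param target_size_mb sequenced target size in megabases (default 50,
#'   a typical whole-exome capture).
#' @param coding_only count only amino-acid-changing mutations?
#' @return Data frame with columns `patient_id`, `timepoint` (when grouped),
#'   `n_mutations`, `target_size_mb`, `tmb`.
#' @export
compute_tmb <- function(mutations, target_size_mb = 50, coding_only = TRUE) {
  if (!is.numeric(target_size_mb) || length(target_size_mb) != 1 ||
      !is.finite(target_size_mb) || target_size_mb <= 0)
    stop("'target_size_mb' must be a single positive number")
  if (coding_only) {
    if (!"effect" %in% names(mutations))
      stop("'mutations' needs an 'effect' column when coding_only = TRUE")
    mutations <- mutations[mutations$effect %in% CODING_EFFECTS, , drop = FALSE]
  }
  grouped <- all(c("patient_id", "timepoint") %in% names(mutations))
  if (grouped) {
    if (nrow(mutations)) {
      out <- aggregate(list(n_mutations = rep_len(1L, nrow(mutations))),
                       by = list(patient_id = mutations$patient_id,
                                 timepoint = mutations$timepoint),
                       FUN = sum)
      out <- out[order(out$patient_id, match(out$timepoint, TIMEPOINTS)), ]
      rownames(out) <- NULL
    } else {
      out <- data.frame(patient_id = character(), timepoint = character(),
                        n_mutations = integer())
    }
  } else {
    out <- data.frame(n_mutations = nrow(mutations))
  }
  out$target_size_mb <- target_size_mb
  out$tmb <- out$n_mutations / target_size_mb
  out
}

#' Pyrimidine-context substitution spectrum
#'
#' Collapses single-nucleotide substitutions onto the six classes with a
#' pyrimidine reference base (C>A, C>G, C>T, T>A, T>C, T>G); purine-reference
#' substitutions are reverse-complemented (e.g. G>A counts as C>T). Indels
#' and records with non-ACGT alleles are skipped with a warning.
#'
#' @param mutations data frame with `ref` and `alt` columns (single-base
#'   strings for SNVs).
#' @return Named integer vector of length 6; counts sum to the number of
#'   usable SNVs.
#' @export
substitution_spectrum <- function(mutations) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- setNames(integer(6), classes)
  if (!nrow(mutations)) return(out)
  ref <- toupper(as.character(mutations$ref))
  alt <- toupper(as.character(mutations$alt))
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & ref != alt
  if (any(!is_snv))
    warning(sum(!is_snv), " record(s) skipped: not ACGT single-base substitutions")
  ref <- ref[is_snv]; alt <- alt[is_snv]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  tab <- table(factor(paste0(ref, ">", alt), levels = classes))
  out[] <- as.integer(tab)
  out
}
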