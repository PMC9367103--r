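#' Call gain/loss states from allele-specific copy-number segments
#'
#' @param segments data frame with `n_major` and `n_minor` columns (plus any
#'   identifying columns, carried through).
#' @param baseline total copy number treated as neutral (default 2; supply 4
#'   for genome-doubled samples).
#' @return The input with `total_cn` and `state`
#'   (`"loss"`/`"neutral"`/`"gain"`) appended.
#' @export
call_gain_loss <- function(segments, baseline = 2L) {
  stopifnot(all(c("n_major", "n_minor") %in% names(segments)))
  total <- segments$n_major + segments$n_minor
  if (any(total < 0 | segments$n_major < 0 | segments$n_minor < 0))
    stop("negative copy numbers")
  segments$total_cn <- total
  segments$state <- ifelse(total < baseline, "loss",
                    ifelse(total > baseline, "gain", "neutral"))
  segments
}

#' Cohort-level change in CNA fraction between two timepoints
#'
#' For each bin, the fraction of patients carrying a gain (resp. loss) at
#' the later timepoint minus the same fraction at the earlier timepoint.
#' Only patients present at both timepoints contribute (inner join; dropped
#' patients are recorded in the `dropped_patients` attribute).
#'
#' @param calls_t1,calls_t2 data frames as returned by [call_gain_loss()]
#'   with `patient_id`, `bin` and `state` columns.
#' @return Data frame `bin`, `delta_gain`, `delta_loss` (both in \[-1, 1\]),
#'   `n_patients`.
#' @export
cohort_fraction_delta <- function(calls_t1, calls_t2) {
  req <- c("patient_id", "bin", "state")
  stopifnot(all(req %in% names(calls_t1)), all(req %in% names(calls_t2)))
  common <- intersect(unique(calls_t1$patient_id), unique(calls_t2$patient_id))
  if (!length(common)) stop("no patients shared between the two timepoints")
  dropped <- setdiff(union(unique(calls_t1$patient_id),
                           unique(calls_t2$patient_id)), common)
  c1 <- calls_t1[calls_t1$patient_id %in% common, ]
  c2 <- calls_t2[calls_t2$patient_id %in% common, ]
  bins <- union(unique(c1$bin), unique(c2$bin))
  frac <- function(calls, state) {
    hit <- unique(calls[calls$state == state, c("patient_id", "bin")])
    counts <- table(factor(hit$bin, levels = bins))
    as.numeric(counts) / length(common)
  }
  out <- data.frame(
    bin = bins,
    delta_gain = frac(c2, "gain") - frac(c1, "gain"),
    delta_loss = frac(c2, "loss") - frac(c1, "loss"),
    n_patients = length(common),
    stringsAsFactors = FALSE
  )
  attr(out, "dropped_patients") <- dropped
  out
}

#' Per-patient total copy-number trajectory at a gene locus
#'
#' Looks the gene up in each patient/timepoint segment set. When the locus
#' spans several segments the length-weighted majority segment's copy number
#' is used; samples without an overlapping segment are reported `NA`, never
#' imputed.
#'
#' @param segments data frame with `patient_id`, `timepoint`, `chrom`,
#'   `start`, `end` (0-based half-open), `n_major`, `n_minor`.
#' @param gene_chrom,gene_start,gene_end the gene locus (same coordinate
#'   convention).
#' @return Data frame with one row per patient: `patient_id`, `cn_pre`,
#'   `cn_post_a`, `cn_post_b`.
#' @export
gene_cn_trajectory <- function(segments, gene_chrom, gene_start, gene_end) {
  stopifnot(gene_end > gene_start)
  patients <- unique(segments$patient_id)
  lookup <- function(pid, tp) {
    s <- segments[segments$patient_id == pid & segments$timepoint == tp &
                    segments$chrom == gene_chrom &
                    segments$start < gene_end & segments$end > gene_start, ]
    if (!nrow(s)) return(NA_integer_)
    overlap <- pmin(s$end, gene_end) - pmax(s$start, gene_start)
    i <- which.max(overlap)
    as.integer(s$n_major[i] + s$n_minor[i])
  }
  out <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  for (tp in TIMEPOINTS)
    out[[paste0("cn_", tp)]] <- vapply(patients, lookup, integer(1), tp = tp)
  out
}

#' Paired signed-rank test on copy-number (or burden) trajectories
#'
#' Two-sided Wilcoxon signed-rank test on per-patient paired differences;
#' the exact distribution is used up to 25 pairs, the normal approximation
#' above. Incomplete pairs are dropped. When every difference is zero the
#' test is degenerate and p = 1 is returned with a flag.
#'
#' @param t1,t2 paired numeric vectors (same patients, same order).
#' @return List with `statistic`, `p_value`, `n_pairs`, `degenerate`.
#' @export
paired_cn_test <- function(t1, t2) {
  ok <- !is.na(t1) & !is.na(t2)
  t1 <- t1[ok]; t2 <- t2[ok]
  if (length(t1) < 2) stop("need at least 2 complete pairs")
  d <- t2 - t1
  if (all(d == 0))
    return(list(statistic = NA_real_, p_value = 1, n_pairs = length(d),
                degenerate = TRUE))
  exact <- length(d) <= 25 && !any(d == 0) && !any(duplicated(abs(d[d != 0])))
  wt <- suppressWarnings(wilcox.test(t2, t1, paired = TRUE, exact = exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = length(d), degenerate = FALSE)
}
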