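#' Threshold-based somatic variant calling on read counts
#'
#' Emulates a conventional somatic-calling gate on a count table: a variant
#' is called in a sample iff it has coverage, its observed VAF is at least
#' `min_vaf` (default 5%) and it is supported by at least `min_alt` alt
#' reads (default 3, standing in for the caller-intersect confirmation that
#' cannot be re-run on count tables). The failing gate is recorded per
#' observation.
#'
#' @param observations data frame with `alt_reads` and `ref_reads` columns;
#'   a `mutation_id` column is built from `chrom:pos:ref:alt` if absent.
#' @param min_vaf minimum observed VAF, in \[0, 1\].
#' @param min_alt minimum number of alt reads.
#' @return The input with columns `vaf_obs`, `called` (logical) and `reason`
#'   (`"pass"`, `"below_vaf"`, `"below_alt_reads"`, `"no_coverage"`)
#'   appended.
#' @export
call_variants <- function(observations, min_vaf = 0.05, min_alt = 3L) {
  stopifnot(is.data.frame(observations),
            all(c("alt_reads", "ref_reads") %in% names(observations)))
  alt <- observations$alt_reads
  ref <- observations$ref_reads
  if (any(alt < 0 | ref < 0, na.rm = TRUE)) stop("negative read counts")
  if (!"mutation_id" %in% names(observations)) {
    observations$mutation_id <- with(observations,
                                     paste(chrom, pos, ref, alt, sep = ":"))
  }
  depth <- alt + ref
  vaf <- ifelse(depth > 0, alt / depth, NA_real_)
  called <- !is.na(vaf) & vaf >= min_vaf & alt >= min_alt
  reason <- ifelse(depth == 0, "no_coverage",
            ifelse(!is.na(vaf) & vaf < min_vaf, "below_vaf",
            ifelse(alt < min_alt, "below_alt_reads", "pass")))
  observations$vaf_obs <- vaf
  observations$called <- called
  observations$reason <- reason
  observations
}

#' Scan an uncalled sample for trace reads
#'
#' A variant that fails formal calling but is supported by at least one alt
#' read leaves a "trace": evidence that the subclone carrying it is present
#' below the detection limit. Trace reads are counted as-is, uncapped.
#'
#' @param alt_reads alt read count(s) at the locus.
#' @param called logical: was the variant formally called in this sample?
#' @param depth total depth; zero depth yields `NA` (not assessable).
#' @return Data frame with `trace_present` (logical) and `trace_reads`.
#' @export
trace_scan <- function(alt_reads, called, depth = NULL) {
  n <- max(length(alt_reads), length(called))
  alt_reads <- rep_len(alt_reads, n); called <- rep_len(called, n)
  present <- !called & alt_reads >= 1
  if (!is.null(depth)) {
    depth <- rep_len(depth, n)
    present[depth == 0] <- NA
  }
  data.frame(trace_present = present,
             trace_reads = ifelse(is.na(present), NA_integer_, alt_reads))
}

#' Classify per-mutation longitudinal trajectories between two samples
#'
#' For each mutation observed in a pair of samples from the same patient:
#' called in both = `persistent`; called only in the later sample =
#' `emerging` (the earlier sample is then rescanned for trace reads,
#' distinguishing `pre_existing_trace` from `no_trace`); called only in the
#' earlier sample = `disappearing` (the later sample is rescanned,
#' `residual_trace` vs `no_trace`). Mutations called in neither sample are
#' `absent` and dropped from the output unless `keep_absent = TRUE`.
#'
#' @param obs_t1,obs_t2 mutation observation tables (read counts) for the
#'   earlier and later sample; matched on `mutation_id`.
#' @param min_vaf,min_alt calling thresholds, see [call_variants()].
#' @param keep_absent keep never-called mutations in the output?
#' @return Data frame with one row per mutation: `mutation_id`, `status`,
#'   `trace_flag` (`pre_existing_trace` / `residual_trace` / `no_trace` /
#'   `not_applicable`), `trace_reads_prior`, `trace_reads_post`, `vaf_t1`,
#'   `vaf_t2`.
#' @export
classify_trajectories <- function(obs_t1, obs_t2, min_vaf = 0.05, min_alt = 3L,
                                  keep_absent = FALSE) {
  c1 <- call_variants(obs_t1, min_vaf, min_alt)
  c2 <- call_variants(obs_t2, min_vaf, min_alt)
  ids <- union(c1$mutation_id, c2$mutation_id)
  i1 <- match(ids, c1$mutation_id)
  i2 <- match(ids, c2$mutation_id)
  # a mutation absent from one table is treated as uncovered there
  called1 <- ifelse(is.na(i1), FALSE, c1$called[i1])
  called2 <- ifelse(is.na(i2), FALSE, c2$called[i2])
  alt1 <- ifelse(is.na(i1), 0L, c1$alt_reads[i1])
  alt2 <- ifelse(is.na(i2), 0L, c2$alt_reads[i2])
  dep1 <- ifelse(is.na(i1), 0L, c1$alt_reads[i1] + c1$ref_reads[i1])
  dep2 <- ifelse(is.na(i2), 0L, c2$alt_reads[i2] + c2$ref_reads[i2])

  status <- ifelse(called1 & called2, "persistent",
            ifelse(!called1 & called2, "emerging",
            ifelse(called1 & !called2, "disappearing", "absent")))

  trace_flag <- rep("not_applicable", length(ids))
  trace_reads_prior <- rep(NA_integer_, length(ids))
  trace_reads_post <- rep(NA_integer_, length(ids))

  em <- status == "emerging"
  if (any(em)) {
    tr <- trace_scan(alt1[em], called1[em], dep1[em])
    trace_flag[em] <- ifelse(is.na(tr$trace_present), "not_applicable",
                      ifelse(tr$trace_present, "pre_existing_trace", "no_trace"))
    trace_reads_prior[em] <- tr$trace_reads
  }
  dis <- status == "disappearing"
  if (any(dis)) {
    tr <- trace_scan(alt2[dis], called2[dis], dep2[dis])
    trace_flag[dis] <- ifelse(is.na(tr$trace_present), "not_applicable",
                       ifelse(tr$trace_present, "residual_trace", "no_trace"))
    trace_reads_post[dis] <- tr$trace_reads
  }

  out <- data.frame(
    mutation_id = ids, status = status, trace_flag = trace_flag,
    trace_reads_prior = trace_reads_prior, trace_reads_post = trace_reads_post,
    vaf_t1 = ifelse(is.na(i1), NA_real_, c1$vaf_obs[i1]),
    vaf_t2 = ifelse(is.na(i2), NA_real_, c2$vaf_obs[i2]),
    stringsAsFactors = FALSE
  )
  if (!keep_absent) out <- out[out$status != "absent", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize trace rates over a set of trajectory tables
#'
#' Counts emerging and disappearing mutations and the fraction of each with
#' trace-read support, per patient and for the cohort. Fractions over zero
#' mutations are reported as `NA`, never 0.
#'
#' @param trajectories data frame as returned by [classify_trajectories()],
#'   with an added `patient_id` column (and optionally `transition`).
#' @return Data frame with one row per patient plus a `"cohort"` row:
#'   `n_emerging`, `n_emerging_trace`, `frac_emerging_trace`,
#'   `n_disappearing`, `n_disappearing_trace`, `frac_disappearing_trace`.
#' @export
summarize_trace_rates <- function(trajectories) {
  stopifnot("patient_id" %in% names(trajectories))
  tally <- function(d) {
    em <- d$status == "emerging"
    di <- d$status == "disappearing"
    n_em <- sum(em); n_di <- sum(di)
    n_em_tr <- sum(em & d$trace_flag == "pre_existing_trace")
    n_di_tr <- sum(di & d$trace_flag == "residual_trace")
    data.frame(
      n_emerging = n_em, n_emerging_trace = n_em_tr,
      frac_emerging_trace = if (n_em > 0) n_em_tr / n_em else NA_real_,
      n_disappearing = n_di, n_disappearing_trace = n_di_tr,
      frac_disappearing_trace = if (n_di > 0) n_di_tr / n_di else NA_real_
    )
  }
  per <- do.call(rbind, lapply(split(trajectories, trajectories$patient_id), tally))
  per <- cbind(patient_id = rownames(per), per)
  cohort <- tally(trajectories)
  cohort <- cbind(patient_id = "cohort", cohort)
  out <- rbind(per, cohort)
  rownames(out) <- NULL
  out
}
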