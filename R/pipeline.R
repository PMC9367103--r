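#' Pipeline run configuration
#'
#' Validates the end-to-end run configuration. Exactly one input source must
#' be given: either paths to mutation/segment/purity tables, or a
#' [sim_config()] describing a synthetic cohort to generate.
#'
#' @param mutations,segments,purity file paths (TSV; see
#'   [read_mutation_table()], [read_segments()]).
#' @param measurements optional TSV of clinical diameters (see
#'   [assess_response()]; columns for both treatment intervals may be given
#'   as `interval` = `pre_post_a` / `post_a_post_b` rows).
#' @param simulate optional [sim_config()] replacing the file inputs.
#' @param min_vaf,min_alt somatic-calling gates ([call_variants()]).
#' @param min_cellularity samples below this tumor cell fraction are
#'   ineligible for subclonal analysis (default 0.20).
#' @param k_max,n_restarts clustering controls ([clone_mixture()]).
#' @param tmb_target_size_mb,tmb_coding_only burden controls
#'   ([compute_tmb()]).
#' @param seed integer seed governing every stochastic stage of the run.
#' @param out_dir optional output directory; when given, tables and the
#'   manifest are written there.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(mutations = NULL, segments = NULL, purity = NULL,
                       measurements = NULL, simulate = NULL,
                       min_vaf = 0.05, min_alt = 3L, min_cellularity = 0.20,
                       k_max = 6L, n_restarts = 10L,
                       tmb_target_size_mb = 50, tmb_coding_only = TRUE,
                       seed = 1L, out_dir = NULL) {
  have_paths <- !is.null(mutations)
  have_sim <- !is.null(simulate)
  if (have_paths == have_sim)
    stop("exactly one of file inputs ('mutations' etc.) or 'simulate' must be given")
  if (have_paths && (is.null(segments) || is.null(purity)))
    stop("file input needs 'mutations', 'segments' and 'purity' paths")
  if (have_sim && !inherits(simulate, "sim_config"))
    stop("'simulate' must be a sim_config()")
  stopifnot(min_vaf >= 0, min_vaf <= 1, min_alt >= 0,
            min_cellularity >= 0, min_cellularity <= 1,
            k_max >= 1, tmb_target_size_mb > 0)
  structure(list(
    mutations = mutations, segments = segments, purity = purity,
    measurements = measurements, simulate = simulate,
    min_vaf = min_vaf, min_alt = as.integer(min_alt),
    min_cellularity = min_cellularity,
    k_max = as.integer(k_max), n_restarts = as.integer(n_restarts),
    tmb_target_size_mb = tmb_target_size_mb, tmb_coding_only = tmb_coding_only,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [run_config()]; a `simulate` block
#' is passed to [sim_config()] (its `directed_cna_events` entry, if present,
#' is coerced to a data frame).
#'
#' @param path YAML file path.
#' @return A validated `"run_config"`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$directed_cna_events))
      sim$directed_cna_events <-
        do.call(rbind, lapply(sim$directed_cna_events, as.data.frame))
    y$simulate <- do.call(sim_config, sim)
  }
  do.call(run_config, y)
}

#' Annotate observations with rVAF given segments and purity
#'
#' Looks up, for every observation, the overlapping copy-number segment of
#' its sample (total copy number; multiplicity estimated from the observed
#' VAF via [estimate_multiplicity()]) and the sample purity, then computes
#' the raw rVAF and the clamped cellular prevalence. Observations without a
#' covering segment fall back to `n_tot = 2`, `n_mut = 1` with a warning.
#'
#' @param observations mutation observation table.
#' @param segments segment table (`patient_id`, `timepoint`, `chrom`,
#'   `start`, `end`, `n_major`, `n_minor`).
#' @param purity purity table (`patient_id`, `timepoint`, `purity`).
#' @return The observations with `vaf_obs`, `n_tot`, `n_mut`, `purity`,
#'   `rvaf`, `prevalence` appended.
#' @export
annotate_rvaf <- function(observations, segments, purity) {
  obs <- observations
  depth <- obs$alt_reads + obs$ref_reads
  obs$vaf_obs <- ifelse(depth > 0, obs$alt_reads / depth, NA_real_)
  key_obs <- paste(obs$patient_id, obs$timepoint)
  key_pur <- paste(purity$patient_id, purity$timepoint)
  obs$purity <- purity$purity[match(key_obs, key_pur)]
  if (any(is.na(obs$purity)))
    stop("missing purity for sample(s): ",
         paste(unique(key_obs[is.na(obs$purity)]), collapse = ", "))
  n_tot <- rep(NA_integer_, nrow(obs))
  key_seg <- paste(segments$patient_id, segments$timepoint)
  for (k in unique(key_obs)) {
    oi <- which(key_obs == k)
    seg <- segments[key_seg == k, ]
    if (!nrow(seg)) next
    for (i in oi) {
      hit <- seg$chrom == obs$chrom[i] & seg$start < obs$pos[i] &
        seg$end >= obs$pos[i]
      if (any(hit)) {
        j <- which(hit)[1]
        n_tot[i] <- seg$n_major[j] + seg$n_minor[j]
      }
    }
  }
  if (anyNA(n_tot)) {
    warning(sum(is.na(n_tot)),
            " observation(s) without copy-number overlap; assuming n_tot = 2")
    n_tot[is.na(n_tot)] <- 2L
  }
  n_tot <- pmax(n_tot, 1L)
  obs$n_tot <- n_tot
  obs$n_mut <- ifelse(is.na(obs$vaf_obs), 1L,
                      estimate_multiplicity(pmin(obs$vaf_obs, 1), n_tot, obs$purity))
  # multiplicity is a property of the mutated locus, not of the biopsy:
  # share one estimate across a mutation's samples with the same local copy
  # number, taken from its most informative (highest purity x depth) sample
  if ("mutation_id" %in% names(obs)) {
    grp <- paste(obs$mutation_id, obs$n_tot)
    info <- obs$purity * pmax(depth, 0)
    for (g in unique(grp[duplicated(grp)])) {
      i <- which(grp == g)
      i_ok <- i[!is.na(obs$vaf_obs[i])]
      if (length(i_ok)) obs$n_mut[i] <- obs$n_mut[i_ok[which.max(info[i_ok])]]
    }
  }
  obs$rvaf <- ifelse(is.na(obs$vaf_obs), NA_real_,
                     rvaf(obs$vaf_obs, obs$n_mut, obs$n_tot, obs$purity))
  obs$prevalence <- pmin(obs$rvaf, 1)
  obs
}

#' Pair samples for longitudinal comparison with the cellularity fallback
#'
#' Builds the ordered sample pairs analysed per patient: `pre -> post_a` and
#' `post_a -> post_b` when all three samples are eligible (tumor cell
#' fraction >= `min_cellularity`); when the intermediate sample is
#' ineligible but `pre` and `post_b` are, the direct `pre -> post_b`
#' fallback pair is used instead. One eligibility decision per sample is
#' recorded.
#'
#' @param purity purity table (`patient_id`, `timepoint`, `purity`).
#' @param min_cellularity eligibility threshold (default 0.20).
#' @return List with `pairs` (data frame `patient_id`, `t1`, `t2`,
#'   `fallback`) and `eligibility` (per-sample decisions).
#' @export
pair_samples <- function(purity, min_cellularity = 0.20) {
  elig <- purity
  elig$eligible <- purity$purity >= min_cellularity
  pairs <- list()
  for (pid in unique(purity$patient_id)) {
    e <- setNames(rep(FALSE, 3), TIMEPOINTS)
    sub <- elig[elig$patient_id == pid, ]
    e[sub$timepoint] <- sub$eligible
    if (e["pre"] && e["post_a"])
      pairs[[length(pairs) + 1L]] <- data.frame(
        patient_id = pid, t1 = "pre", t2 = "post_a", fallback = FALSE)
    if (e["post_a"] && e["post_b"])
      pairs[[length(pairs) + 1L]] <- data.frame(
        patient_id = pid, t1 = "post_a", t2 = "post_b", fallback = FALSE)
    if (!e["post_a"] && e["pre"] && e["post_b"])
      pairs[[length(pairs) + 1L]] <- data.frame(
        patient_id = pid, t1 = "pre", t2 = "post_b", fallback = TRUE)
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(patient_id = character(), t1 = character(),
                    t2 = character(), fallback = logical()),
       eligibility = elig)
}

#' Run the full longitudinal subclone-tracking pipeline
#'
#' Orchestrates every stage on a cohort (read from files or simulated):
#' rVAF annotation, threshold calling, cellularity-gated sample pairing
#' (with the pre -> post_b fallback), per-pair trajectory classification
#' with trace rescanning, per-patient clonal clustering (merge + prune +
#' fishplot table), TMB per sample, cohort CNA fraction deltas, and — when
#' clinical measurements are supplied — response classification and paired
#' TMB comparison by response group. For simulated cohorts a
#' truth-vs-inferred scorecard is added. The run is deterministic given the
#' config seed; a manifest records a hash of the configuration.
#'
#' @param config a [run_config()].
#' @return A list of class `"cohort_report"`; see the vignette for the
#'   component tables. When `config$out_dir` is set, tables and
#'   `manifest.json` are also written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    truth <- cohort$truth
  } else {
    cohort <- read_cohort_paths(config)
    truth <- NULL
  }
  obs <- annotate_rvaf(cohort$observations, cohort$segments, cohort$purity)
  obs <- call_variants(obs, config$min_vaf, config$min_alt)

  pairing <- pair_samples(cohort$purity, config$min_cellularity)

  # trajectories per eligible pair
  traj <- list()
  for (i in seq_len(nrow(pairing$pairs))) {
    pr <- pairing$pairs[i, ]
    o1 <- obs[obs$patient_id == pr$patient_id & obs$timepoint == pr$t1, ]
    o2 <- obs[obs$patient_id == pr$patient_id & obs$timepoint == pr$t2, ]
    if (!nrow(o1) || !nrow(o2)) next
    tr <- classify_trajectories(o1, o2, config$min_vaf, config$min_alt)
    if (nrow(tr)) {
      tr$patient_id <- pr$patient_id
      tr$transition <- paste(pr$t1, pr$t2, sep = "->")
      tr$fallback <- pr$fallback
      traj[[length(traj) + 1L]] <- tr
    }
  }
  trajectories <- if (length(traj)) do.call(rbind, traj) else NULL
  trace_summary <- if (!is.null(trajectories))
    summarize_trace_rates(trajectories) else NULL

  # per-patient clustering over eligible timepoints (>= 2 needed)
  clusters <- list()
  fishplots <- list()
  elig <- pairing$eligibility
  for (pid in unique(obs$patient_id)) {
    tps <- elig$timepoint[elig$patient_id == pid & elig$eligible]
    tps <- TIMEPOINTS[TIMEPOINTS %in% tps]
    if (length(tps) < 2) next
    po <- obs[obs$patient_id == pid & obs$timepoint %in% tps, ]
    # cluster mutations ever called in this patient
    called_ids <- unique(po$mutation_id[po$called])
    if (length(called_ids) < 2) next
    po <- po[po$mutation_id %in% called_ids, ]
    prev <- matrix(0, length(called_ids), length(tps),
                   dimnames = list(called_ids, tps))
    dep <- prev
    idx <- cbind(match(po$mutation_id, called_ids), match(po$timepoint, tps))
    prev[idx] <- ifelse(is.na(po$prevalence), 0, po$prevalence)
    # effective depth on the prevalence scale: raw depth x expected clonal
    # VAF, so that successes equal alt reads and the binomial kernel carries
    # the right sampling variance for the purity/CN-corrected prevalence
    dep[idx] <- pmax(1, round((po$alt_reads + po$ref_reads) *
                                expected_vaf(po$n_mut, po$n_tot, po$purity)))
    fit <- clone_mixture(prev, dep, k_max = min(config$k_max, length(called_ids)),
                         n_restarts = config$n_restarts,
                         seed = config$seed + match(pid, unique(obs$patient_id)))
    fit <- merge_singletons(fit)
    pruned <- prune_small_clusters(fit)
    clusters[[pid]] <- list(model = fit, display = pruned$display,
                            removed = pruned$removed)
    fishplots[[pid]] <- build_fishplot_table(pruned$display)
  }

  # burden per sample (called mutations only, as in exome pipelines)
  called_obs <- obs[obs$called, ]
  tmb <- compute_tmb(called_obs, config$tmb_target_size_mb,
                     config$tmb_coding_only)
  spectrum <- lapply(split(called_obs, called_obs$timepoint),
                     substitution_spectrum)

  # cohort CNA dynamics over all three transitions
  seg_calls <- call_gain_loss(cohort$segments)
  if (!"bin" %in% names(seg_calls))
    seg_calls$bin <- paste0(seg_calls$chrom, ":", seg_calls$start)
  cna_delta <- list()
  for (tr in list(c("pre", "post_a"), c("post_a", "post_b"), c("pre", "post_b"))) {
    c1 <- seg_calls[seg_calls$timepoint == tr[1], ]
    c2 <- seg_calls[seg_calls$timepoint == tr[2], ]
    if (nrow(c1) && nrow(c2))
      cna_delta[[paste(tr, collapse = "->")]] <- cohort_fraction_delta(c1, c2)
  }

  # clinical response (optional)
  response <- NULL
  tmb_by_group <- NULL
  if (!is.null(config$measurements)) {
    meas <- read.delim(config$measurements, stringsAsFactors = FALSE)
    response <- assess_response(meas)
    resp_flag <- setNames(response$responder, response$patient_id)
    tmb_wide <- .tmb_wide(tmb)
    if (!is.null(tmb_wide))
      tmb_by_group <- compare_tmb_by_group(tmb_wide$pre, tmb_wide$post_a,
                                           resp_flag)
  }

  scorecard <- if (!is.null(truth))
    score_against_truth(truth, obs, clusters) else NULL

  manifest <- list(
    package = "clonetracer",
    version = as.character(utils::packageVersion("clonetracer")),
    seed = config$seed,
    config_hash = .config_hash(config),
    n_patients = length(unique(obs$patient_id)),
    n_observations = nrow(obs),
    eligibility = pairing$eligibility
  )

  report <- structure(list(
    observations = obs,
    pairing = pairing,
    trajectories = trajectories,
    trace_summary = trace_summary,
    clusters = clusters,
    fishplot_tables = fishplots,
    tmb = tmb,
    spectrum = spectrum,
    cna_delta = cna_delta,
    response = response,
    tmb_by_group = tmb_by_group,
    scorecard = scorecard,
    manifest = manifest,
    config = config
  ), class = "cohort_report")

  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

read_cohort_paths <- function(config) {
  list(
    observations = read_mutation_table(config$mutations, "tsv"),
    segments = read_segments(config$segments),
    purity = read.delim(config$purity, stringsAsFactors = FALSE)
  )
}

.tmb_wide <- function(tmb) {
  if (!all(c("patient_id", "timepoint", "tmb") %in% names(tmb))) return(NULL)
  wide <- list()
  for (tp in TIMEPOINTS) {
    sub <- tmb[tmb$timepoint == tp, ]
    wide[[tp]] <- setNames(sub$tmb, sub$patient_id)
  }
  wide
}

.config_hash <- function(config) {
  clean <- config[!vapply(config, is.null, logical(1))]
  clean$simulate <- if (!is.null(clean$simulate)) unclass(clean$simulate)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(clean, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Score inferred results against simulation truth
#'
#' For each simulated patient: recall of truly present mutations (CCF above
#' the detection limit) among called variants, the true and inferred number
#' of clones, and the fraction of truly pre-existing "emerging" mutations.
#'
#' @param truth the `truth` component of a `"sim_cohort"`.
#' @param obs annotated, called observation table.
#' @param clusters per-patient clustering results from [run_pipeline()].
#' @return Data frame, one row per patient.
#' @export
score_against_truth <- function(truth, obs, clusters) {
  rows <- lapply(truth, function(tr) {
    pid <- tr$patient_id
    po <- obs[obs$patient_id == pid, ]
    present <- tr$ccf > 0
    ids <- paste0(pid, ":", rownames(tr$ccf))
    recall <- vapply(TIMEPOINTS, function(tp) {
      truly <- ids[present[, tp]]
      if (!length(truly)) return(NA_real_)
      called <- po$mutation_id[po$timepoint == tp & po$called]
      mean(truly %in% called)
    }, numeric(1))
    n_clones_true <- nrow(tr$tree$clones)
    n_clusters <- if (pid %in% names(clusters))
      clusters[[pid]]$model$n_clusters else NA_integer_
    data.frame(patient_id = pid,
               recall_pre = recall["pre"], recall_post_a = recall["post_a"],
               recall_post_b = recall["post_b"],
               n_clones_true = n_clones_true, n_clusters = n_clusters)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mutation_tsv(report$observations, file.path(out_dir, "observations.tsv"))
  if (!is.null(report$trajectories))
    write.table(report$trajectories, file.path(out_dir, "trajectories.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$trace_summary))
    write.table(report$trace_summary, file.path(out_dir, "trace_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$tmb, file.path(out_dir, "tmb.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$cna_delta))
    write.table(report$cna_delta[[nm]],
                file.path(out_dir, paste0("cna_delta_", gsub("->", "_", nm), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (pid in names(report$fishplot_tables))
    write.table(report$fishplot_tables[[pid]],
                file.path(out_dir, paste0("fishplot_", pid, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$scorecard))
    write.table(report$scorecard, file.path(out_dir, "scorecard.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Longitudinal subclone-tracking report\n")
  cat(sprintf("  %d patients, %d observations (%d called)\n",
              x$manifest$n_patients, nrow(x$observations),
              sum(x$observations$called)))
  if (!is.null(x$trajectories)) {
    tab <- table(x$trajectories$status)
    cat("  trajectories:",
        paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  }
  if (length(x$clusters))
    cat(sprintf("  clustering: %d patient(s), cluster counts %s\n",
                length(x$clusters),
                paste(vapply(x$clusters, function(cl) cl$model$n_clusters,
                             integer(1)), collapse = "/")))
  if (!is.null(x$tmb_by_group)) {
    cat("  TMB by response group:\n")
    print(x$tmb_by_group, row.names = FALSE)
  }
  invisible(x)
}
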