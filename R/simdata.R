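#' Simulation configuration for a synthetic longitudinal cohort
#'
#' Bundles and validates the parameters of the cohort generator. The defaults
#' describe an exome-like longitudinal design: three biopsies per patient
#' (pretreatment and after each of two sequential drug regimens), ~150x mean
#' depth, a truncal clone plus 2-6 subclones carrying a handful of coding
#' mutations each, tumor cell fractions declining over treatment within the
#' 0.2-0.9 range, and treatment dynamics in which small subclones can go
#' extinct while truncal mutations persist.
#'
#' @param n_patients number of patients.
#' @param n_subclones_range integer pair: min/max number of subclones beside
#'   the truncal clone.
#' @param mutations_per_clone_range integer pair: mutations assigned to each
#'   clone (truncal included).
#' @param depth_mean mean sequencing depth (reads); per-locus depth is
#'   Poisson-distributed around it.
#' @param purity_by_timepoint length-3 numeric: mean tumor cell fraction at
#'   `pre`, `post_a`, `post_b`.
#' @param purity_jitter half-width of the uniform per-sample jitter around
#'   the timepoint mean purity (clamped to \[0.05, 0.95\]).
#' @param extinction_prob_small_clone probability that a subclone below 0.1
#'   prevalence goes extinct at each treatment transition.
#' @param expansion_sd log-scale standard deviation of the multiplicative
#'   prevalence perturbation per transition.
#' @param error_rate per-base sequencing error rate used to draw false alt
#'   reads at wild-type loci (default 0).
#' @param directed_cna_events `NULL` or a data frame with columns
#'   `bin`, `timepoint`, `type` (`"gain"`/`"loss"`), `prob`: copy-number
#'   events injected at a timepoint with a given per-patient probability
#'   (persisting at later timepoints).
#' @param genome_bins data frame of genomic bins (`bin`, `chrom`, `start`,
#'   `end`, 0-based half-open) used both as copy-number segments and as the
#'   loci mutations are placed in; defaults to [default_genome_bins()].
#' @param seed integer seed making the whole cohort reproducible.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 10L,
                       n_subclones_range = c(2L, 6L),
                       mutations_per_clone_range = c(5L, 20L),
                       depth_mean = 150,
                       purity_by_timepoint = c(pre = 0.65, post_a = 0.45, post_b = 0.35),
                       purity_jitter = 0.15,
                       extinction_prob_small_clone = 0.3,
                       expansion_sd = 0.5,
                       error_rate = 0,
                       directed_cna_events = NULL,
                       genome_bins = default_genome_bins(),
                       seed = 1L) {
  stopifnot(n_patients >= 1, depth_mean > 0,
            length(n_subclones_range) == 2, length(mutations_per_clone_range) == 2,
            length(purity_by_timepoint) == 3)
  if (n_subclones_range[1] > n_subclones_range[2] ||
      mutations_per_clone_range[1] > mutations_per_clone_range[2])
    stop("ranges must be ordered (min <= max)")
  if (mutations_per_clone_range[1] < 1) stop("each clone needs >= 1 mutation")
  probs <- c(extinction_prob_small_clone, error_rate, purity_jitter)
  if (any(probs < 0) || extinction_prob_small_clone > 1 || error_rate > 1)
    stop("probabilities must lie in [0, 1]")
  if (any(purity_by_timepoint <= 0) || any(purity_by_timepoint > 1))
    stop("'purity_by_timepoint' values must lie in (0, 1]")
  req <- c("bin", "chrom", "start", "end")
  if (!is.data.frame(genome_bins) || !all(req %in% names(genome_bins)))
    stop("'genome_bins' must be a data frame with columns bin, chrom, start, end")
  if (anyDuplicated(genome_bins$bin)) stop("'genome_bins' bin names must be unique")
  if (!is.null(directed_cna_events)) {
    ev_req <- c("bin", "timepoint", "type", "prob")
    if (!is.data.frame(directed_cna_events) ||
        !all(ev_req %in% names(directed_cna_events)))
      stop("'directed_cna_events' needs columns bin, timepoint, type, prob")
    bad <- setdiff(directed_cna_events$bin, genome_bins$bin)
    if (length(bad))
      stop("directed CNA event references unknown bin(s): ",
           paste(bad, collapse = ", "))
    if (!all(directed_cna_events$timepoint %in% TIMEPOINTS))
      stop("event timepoints must be one of: ", paste(TIMEPOINTS, collapse = ", "))
    if (!all(directed_cna_events$type %in% c("gain", "loss")))
      stop("event type must be 'gain' or 'loss'")
    if (any(directed_cna_events$prob < 0 | directed_cna_events$prob > 1))
      stop("event probabilities must lie in [0, 1]")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    n_subclones_range = as.integer(n_subclones_range),
    mutations_per_clone_range = as.integer(mutations_per_clone_range),
    depth_mean = depth_mean,
    purity_by_timepoint = setNames(as.numeric(purity_by_timepoint), TIMEPOINTS),
    purity_jitter = purity_jitter,
    extinction_prob_small_clone = extinction_prob_small_clone,
    expansion_sd = expansion_sd,
    error_rate = error_rate,
    directed_cna_events = directed_cna_events,
    genome_bins = genome_bins,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default genomic bins for the simulator
#'
#' A compact arm-level bin set (hg19-like coordinates, 0-based half-open)
#' covering chromosomes recurrently altered in breast cancer, plus two
#' gene-sized bins (`MYC`, `ERBB2`) so per-gene copy-number trajectories can
#' be exercised. Synthetic convenience coordinates, not an annotation source.
#'
#' @return Data frame with columns `bin`, `chrom`, `start`, `end`, `gene`.
#' @export
default_genome_bins <- function() {
  b <- rbind(
    c("1p",  "1", 0,         125000000),
    c("1q",  "1", 125000000, 249250000),
    c("2q",  "2", 93300000,  243199000),
    c("3q",  "3", 91000000,  198022000),
    c("6p",  "6", 0,         61000000),
    c("6q",  "6", 61000000,  171115000),
    c("8p",  "8", 0,         45600000),
    c("8q",  "8", 45600000,  146364000),
    c("11q", "11", 53700000, 135006000),
    c("16q", "16", 36600000, 90354000),
    c("17p", "17", 0,        24000000),
    c("17q", "17", 24000000, 81195000),
    c("19p", "19", 0,        26500000),
    c("19q", "19", 26500000, 59129000),
    c("MYC",   "8", 128748000, 128753000),
    c("ERBB2", "17", 37844000, 37886000)
  )
  data.frame(bin = b[, 1], chrom = b[, 2],
             start = as.numeric(b[, 3]), end = as.numeric(b[, 4]),
             gene = ifelse(b[, 1] %in% c("MYC", "ERBB2"), b[, 1],
                           paste0("G", b[, 1])),
             stringsAsFactors = FALSE)
}

#' Simulate a clonal tree with treatment-driven prevalence dynamics
#'
#' Builds one truncal clone (cellular prevalence 1 at every timepoint) and a
#' random nested set of subclones. Subclone prevalences evolve across the
#' three timepoints by a multiplicative log-normal perturbation
#' (`exp(rnorm(0, expansion_sd))`), and subclones below 0.1 prevalence go
#' extinct with probability `extinction_prob_small_clone` at each transition.
#' Prevalences are inclusive (a clone's prevalence counts its descendants),
#' so at every timepoint the prevalences of a clone's children sum to at most
#' its own; violations after perturbation are repaired by proportional
#' rescaling of the children.
#'
#' @param config a [sim_config()].
#' @return A list of class `"clonal_tree"`: `clones` (data frame
#'   `subclone_id`, `parent_id`; parent 0 marks the root), `prevalence`
#'   (clones x timepoints matrix), `mutations` (data frame assigning each
#'   mutation to one clone, with locus, alleles, gene and effect).
#' @export
simulate_clonal_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_sub <- if (diff(config$n_subclones_range) == 0) config$n_subclones_range[1] else
    sample(config$n_subclones_range[1]:config$n_subclones_range[2], 1)
  n_clones <- n_sub + 1L
  parent <- integer(n_clones)  # clone 1 = truncal, parent 0
  for (i in seq_len(n_sub) + 1L)
    parent[i] <- if (i == 2L) 1L else sample(seq_len(i - 1L), 1)

  prev <- matrix(0, n_clones, 3, dimnames = list(NULL, TIMEPOINTS))
  prev[1, ] <- 1
  # initial prevalences, parents before children (ids are topologically ordered)
  for (i in seq_len(n_sub) + 1L)
    prev[i, "pre"] <- prev[parent[i], "pre"] * runif(1, 0.05, 0.6)
  prev[, "pre"] <- .enforce_nesting(prev[, "pre"], parent)

  for (t in 2:3) {
    p <- prev[, t - 1]
    for (i in seq_len(n_sub) + 1L) {
      if (p[i] <= 0) { prev[i, t] <- 0; next }
      if (p[i] < 0.1 && runif(1) < config$extinction_prob_small_clone) {
        prev[i, t] <- 0
      } else {
        prev[i, t] <- min(1, p[i] * exp(rnorm(1, 0, config$expansion_sd)))
      }
    }
    prev[1, t] <- 1
    prev[, t] <- .enforce_nesting(prev[, t], parent)
  }

  mpc <- config$mutations_per_clone_range
  n_mut_clone <- if (diff(mpc) == 0) rep(mpc[1], n_clones) else
    sample(mpc[1]:mpc[2], n_clones, replace = TRUE)
  bins <- config$genome_bins
  total <- sum(n_mut_clone)
  bin_idx <- sample(nrow(bins), total, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  mutations <- data.frame(
    mutation_id = sprintf("M%04d", seq_len(total)),
    subclone_id = rep(seq_len(n_clones), n_mut_clone),
    chrom = bins$chrom[bin_idx],
    pos = floor(runif(total, bins$start[bin_idx], bins$end[bin_idx])) + 1L,
    ref = ref, alt = alt,
    gene = (bins$gene %||% bins$bin)[bin_idx],
    bin = bins$bin[bin_idx],
    effect = sample(EFFECT_LEVELS, total, replace = TRUE,
                    prob = c(0.60, 0.10, 0.10, 0.05, 0.15)),
    stringsAsFactors = FALSE
  )
  structure(list(
    clones = data.frame(subclone_id = seq_len(n_clones), parent_id = parent),
    prevalence = prev,
    mutations = mutations
  ), class = "clonal_tree")
}

# Scale children down where sibling prevalences exceed the parent's
# (inclusive-prevalence pigeonhole); applied root-to-leaf.
.enforce_nesting <- function(p, parent) {
  for (i in order(seq_along(p))) {
    kids <- which(parent == i)
    if (!length(kids)) next
    s <- sum(p[kids])
    if (s > p[i] && s > 0) p[kids] <- p[kids] * (p[i] / s)
  }
  p
}

#' Cellular prevalence of each mutation implied by a clonal tree
#'
#' Under the infinite-sites assumption each mutation belongs to one clone and
#' is carried by that clone and all its descendants, so its cancer cell
#' fraction at a timepoint equals the clone's inclusive prevalence.
#'
#' @param tree a `"clonal_tree"`.
#' @return Matrix mutations x timepoints of true CCFs.
#' @export
mutation_ccf <- function(tree) {
  stopifnot(inherits(tree, "clonal_tree"))
  m <- tree$prevalence[tree$mutations$subclone_id, , drop = FALSE]
  rownames(m) <- tree$mutations$mutation_id
  m
}

#' Simulate per-bin allele-specific copy number for one patient
#'
#' Baseline is diploid (major 1, minor 1) in every bin at every timepoint.
#' Each directed event fires with its probability; when it fires, the bin
#' gains (+1 major) or loses (-1, floored at total 1) from the event's
#' timepoint onward.
#'
#' @param config a [sim_config()].
#' @return Data frame of segments: `timepoint`, `bin`, `chrom`, `start`,
#'   `end`, `n_major`, `n_minor`.
#' @export
simulate_copy_number <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bins <- config$genome_bins
  seg <- expand.grid(timepoint = TIMEPOINTS, bin = bins$bin,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  seg <- merge(seg, bins[c("bin", "chrom", "start", "end")], by = "bin", sort = FALSE)
  seg$n_major <- 1L
  seg$n_minor <- 1L
  ev <- config$directed_cna_events
  if (!is.null(ev)) {
    for (j in seq_len(nrow(ev))) {
      if (runif(1) >= ev$prob[j]) next
      affected <- seg$bin == ev$bin[j] &
        match(seg$timepoint, TIMEPOINTS) >= match(ev$timepoint[j], TIMEPOINTS)
      if (ev$type[j] == "gain") {
        seg$n_major[affected] <- seg$n_major[affected] + 1L
      } else {
        # drop the minor allele first; never go below total 1 (mutations must
        # keep at least one carrying copy)
        has_minor <- affected & seg$n_minor > 0
        seg$n_minor[has_minor] <- seg$n_minor[has_minor] - 1L
        only_major <- affected & !has_minor & seg$n_major > 1
        seg$n_major[only_major] <- seg$n_major[only_major] - 1L
      }
    }
  }
  seg[order(match(seg$timepoint, TIMEPOINTS), seg$chrom, seg$start),
      c("timepoint", "bin", "chrom", "start", "end", "n_major", "n_minor")]
}

#' Simulate read counts for one mutation in one sample
#'
#' Total depth is Poisson(`depth_mean`); alt reads are binomial with success
#' probability `ccf * expected_vaf(n_mut, n_tot, purity)`, optionally plus
#' sequencing error (`error_rate` chance per read of a false alt call).
#'
#' @param ccf cancer cell fraction of the mutation in \[0, 1\].
#' @param n_mut,n_tot,purity see [expected_vaf()].
#' @param depth_mean mean depth (> 0).
#' @param n number of independent draws.
#' @param error_rate per-read false-alt probability.
#' @return Data frame with `alt_reads`, `ref_reads` (one row per draw).
#' @export
simulate_reads <- function(ccf, n_mut = 1L, n_tot = 2L, purity,
                           depth_mean = 150, n = 1L, error_rate = 0) {
  if (any(ccf < 0 | ccf > 1)) stop("'ccf' must lie in [0, 1]")
  p <- ccf * expected_vaf(n_mut, n_tot, purity)
  p <- pmin(1, p + error_rate * (1 - p))
  depth <- rpois(n, depth_mean)
  alt <- rbinom(n, depth, rep_len(p, n))
  data.frame(alt_reads = alt, ref_reads = depth - alt)
}

#' Simulate a synthetic longitudinal cohort with known clonal ground truth
#'
#' Draws, for each patient, a clonal tree with treatment dynamics
#' ([simulate_clonal_tree()]), per-bin copy number
#' ([simulate_copy_number()]), per-timepoint purity, and binomial read counts
#' at every patient mutation in every one of the three samples
#' ([simulate_reads()]). The returned truth component lets downstream stages
#' be scored against the generating model.
#'
#' @param config a [sim_config()]; `config$seed` makes the cohort
#'   reproducible.
#' @return A list of class `"sim_cohort"`: `observations` (long mutation
#'   table: `patient_id`, `timepoint`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `effect`, `alt_reads`, `ref_reads`, `mutation_id`), `segments`
#'   (BED-like, per patient/timepoint), `purity` (per sample), `truth`
#'   (per-patient trees, CCFs, mutation assignments) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  obs_list <- seg_list <- pur_list <- truth <- vector("list", config$n_patients)
  for (pi in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", pi)
    tree <- simulate_clonal_tree(config)
    seg <- simulate_copy_number(config)
    purity <- pmin(0.95, pmax(0.05, config$purity_by_timepoint +
      runif(3, -config$purity_jitter, config$purity_jitter)))
    ccf <- mutation_ccf(tree)
    per_tp <- vector("list", 3)
    for (ti in seq_along(TIMEPOINTS)) {
      tp <- TIMEPOINTS[ti]
      seg_tp <- seg[seg$timepoint == tp, ]
      n_tot <- (seg_tp$n_major + seg_tp$n_minor)[match(tree$mutations$bin, seg_tp$bin)]
      reads <- do.call(rbind, lapply(seq_len(nrow(tree$mutations)), function(mi)
        simulate_reads(ccf[mi, tp], n_mut = 1L, n_tot = n_tot[mi],
                       purity = purity[ti], depth_mean = config$depth_mean,
                       error_rate = config$error_rate)))
      per_tp[[ti]] <- data.frame(
        patient_id = pid, timepoint = tp,
        tree$mutations[c("chrom", "pos", "ref", "alt", "gene", "effect")],
        alt_reads = reads$alt_reads, ref_reads = reads$ref_reads,
        mutation_id = paste0(pid, ":", tree$mutations$mutation_id),
        stringsAsFactors = FALSE
      )
    }
    obs_list[[pi]] <- do.call(rbind, per_tp)
    seg$patient_id <- pid
    seg_list[[pi]] <- seg[c("patient_id", "timepoint", "chrom", "start", "end",
                            "n_major", "n_minor", "bin")]
    pur_list[[pi]] <- data.frame(patient_id = pid, timepoint = TIMEPOINTS,
                                 purity = as.numeric(purity))
    truth[[pi]] <- list(patient_id = pid, tree = tree, ccf = ccf)
  }
  structure(list(
    observations = do.call(rbind, obs_list),
    segments = do.call(rbind, seg_list),
    purity = do.call(rbind, pur_list),
    truth = truth,
    config = config
  ), class = "sim_cohort")
}
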