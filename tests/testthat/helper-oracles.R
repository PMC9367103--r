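# Independent oracle implementations used to check the package's code paths.
# These deliberately re-derive results by brute force / closed form and must
# not call the functions they validate.

# Closed-form probability that a mutation leaves a trace (>= 1 alt read while
# failing the VAF/alt-read calling gates) under Poisson depth and binomial
# alt sampling at success probability p.
oracle_trace_prob <- function(p, depth_mean = 150, min_vaf = 0.05, min_alt = 3,
                              d_max = NULL) {
  if (is.null(d_max)) d_max <- ceiling(depth_mean + 10 * sqrt(depth_mean))
  total <- 0
  for (D in 1:d_max) {
    a <- 1:D
    called <- (a / D >= min_vaf) & (a >= min_alt)
    trace <- !called
    total <- total + dpois(D, depth_mean) * sum(dbinom(a[trace], D, p))
  }
  total
}

# Brute-force trajectory classification for one mutation given raw counts in
# two samples (independent of classify_trajectories).
oracle_classify_one <- function(alt1, ref1, alt2, ref2,
                                min_vaf = 0.05, min_alt = 3) {
  is_called <- function(a, r) {
    d <- a + r
    d > 0 && a / d >= min_vaf && a >= min_alt
  }
  c1 <- is_called(alt1, ref1)
  c2 <- is_called(alt2, ref2)
  if (c1 && c2) return(list(status = "persistent", flag = "not_applicable"))
  if (!c1 && !c2) return(list(status = "absent", flag = "not_applicable"))
  if (c2) {
    flag <- if (alt1 + ref1 == 0) "not_applicable"
            else if (alt1 >= 1) "pre_existing_trace" else "no_trace"
    return(list(status = "emerging", flag = flag))
  }
  flag <- if (alt2 + ref2 == 0) "not_applicable"
          else if (alt2 >= 1) "residual_trace" else "no_trace"
  list(status = "disappearing", flag = flag)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
# (no ties in |d|, no zeros assumed).
oracle_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Independent re-implementation of the clonal-tree draw sequence up to the
# prevalence dynamics (the generator draws prevalences before mutations, so
# under the same seed the prevalence matrix must agree draw for draw).
oracle_tree_prevalence <- function(config) {
  rng <- function(nr) if (diff(nr) == 0) nr[1] else sample(nr[1]:nr[2], 1)
  n_sub <- rng(config$n_subclones_range)
  n_clones <- n_sub + 1L
  parent <- integer(n_clones)
  for (i in seq_len(n_sub) + 1L)
    parent[i] <- if (i == 2L) 1L else sample(seq_len(i - 1L), 1)
  nest <- function(p) {
    for (i in seq_along(p)) {
      kids <- which(parent == i)
      if (length(kids) && sum(p[kids]) > p[i] && sum(p[kids]) > 0)
        p[kids] <- p[kids] * p[i] / sum(p[kids])
    }
    p
  }
  prev <- matrix(0, n_clones, 3)
  prev[1, ] <- 1
  for (i in seq_len(n_sub) + 1L)
    prev[i, 1] <- prev[parent[i], 1] * runif(1, 0.05, 0.6)
  prev[, 1] <- nest(prev[, 1])
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
    prev[, t] <- nest(prev[, t])
  }
  prev
}

# Did any subclone cross a prevalence boundary between consecutive timepoints?
crossed_boundary <- function(prev, boundary) {
  if (nrow(prev) < 2) return(FALSE)
  sub <- prev[-1, , drop = FALSE]
  any((sub[, -3, drop = FALSE] < boundary) != (sub[, -1, drop = FALSE] < boundary))
}

# Small well-separated three-cluster prevalence/depth dataset (the recovery
# benchmark design: one truncal cluster and two dynamic subclones).
make_three_cluster_data <- function(n_per = 30, depth_mean = 150) {
  centers <- rbind(c(1.0, 1.0, 1.0), c(0.6, 0.1, 0.4), c(0.2, 0.5, 0.05))
  truth <- rep(1:3, each = n_per)
  dep <- matrix(rpois(3 * n_per * 3, depth_mean), 3 * n_per, 3)
  dep[dep == 0] <- 1
  alt <- matrix(rbinom(length(dep), as.vector(dep),
                       as.vector(centers[truth, ])), 3 * n_per, 3)
  list(prevalence = alt / dep, depth = dep, truth = truth, centers = centers)
}
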