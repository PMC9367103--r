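#' Cluster mutations by cellular prevalence across timepoints
#'
#' Fits a finite binomial-mixture model to a mutations x timepoints matrix of
#' clamped rVAF values (cellular prevalences) with matching sequencing
#' depths: cluster k is characterised by a prevalence `theta[k, t]` per
#' timepoint, and mutation i contributes a binomial likelihood with
#' `prevalence[i, t] * depth[i, t]` successes in `depth[i, t]` trials.
#' Expectation-maximization is run for each candidate number of clusters
#' K = 1..`k_max` with `n_restarts` random restarts; the number of clusters
#' is selected by the Bayesian information criterion (ties toward smaller K).
#' This is a deterministic, desk-scale stand-in for Dirichlet-process
#' samplers such as PyClone, adequate for short prevalence vectors.
#'
#' @param prevalence numeric matrix (mutations x timepoints) of cellular
#'   prevalences in \[0, 1\] (rVAF clamped to \[0, 1\]).
#' @param depth numeric matrix, same shape: per-mutation, per-timepoint
#'   sequencing depth.
#' @param k_max largest number of clusters considered.
#' @param n_restarts random EM restarts per K.
#' @param seed integer seed for the restarts (optional).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `"clone_mixture"` with components
#'   `assignments` (named integer vector), `prevalence` (K x T matrix of
#'   cluster prevalences), `n_clusters`, `fit_score` (BIC of the selected
#'   model), `logLik`, `bic_by_k`, `mixing`, `posterior`, `sizes`, and the
#'   input data.
#' @seealso [merge_singletons()], [prune_small_clusters()],
#'   [build_fishplot_table()]
#' @export
clone_mixture <- function(prevalence, depth, k_max = 10L, n_restarts = 10L,
                          seed = NULL, max_iter = 500L, tol = 1e-8) {
  prevalence <- as.matrix(prevalence)
  depth <- as.matrix(depth)
  if (!all(dim(prevalence) == dim(depth)))
    stop("'prevalence' and 'depth' must have the same dimensions")
  if (nrow(prevalence) < 1) stop("need at least one mutation")
  if (all(depth == 0)) stop("all-zero depth matrix")
  if (any(prevalence < 0 | prevalence > 1))
    stop("'prevalence' values must lie in [0, 1]")
  if (is.null(rownames(prevalence)))
    rownames(prevalence) <- paste0("m", seq_len(nrow(prevalence)))
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(prevalence); tp <- ncol(prevalence)
  x <- prevalence * depth          # fractional successes are fine for EM
  k_max <- min(k_max, n)

  fits <- vector("list", k_max)
  bics <- numeric(k_max)
  for (k in seq_len(k_max)) {
    best <- NULL
    for (r in seq_len(if (k == 1) 1L else n_restarts)) {
      fit <- .em_binom_mixture(x, depth, k, max_iter, tol)
      if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
    # free parameters: K*T cluster prevalences + (K-1) mixing weights
    bics[k] <- -2 * best$logLik + (k * tp + (k - 1)) * log(n)
    fits[[k]] <- best
  }
  k_best <- which.min(round(bics, 8))  # ties toward smaller K by which.min
  fit <- fits[[k_best]]

  assignments <- apply(fit$posterior, 1, which.max)
  names(assignments) <- rownames(prevalence)
  # relabel clusters by decreasing mean prevalence for stable reporting
  ord <- order(-rowMeans(fit$theta))
  relabel <- match(seq_len(k_best), ord)
  assignments <- relabel[assignments]
  names(assignments) <- rownames(prevalence)
  theta <- fit$theta[ord, , drop = FALSE]
  dimnames(theta) <- list(paste0("C", seq_len(k_best)),
                          colnames(prevalence) %||% paste0("t", seq_len(tp)))

  structure(list(
    assignments = assignments,
    prevalence = theta,
    n_clusters = k_best,
    fit_score = bics[k_best],
    logLik = fit$logLik,
    bic_by_k = bics,
    mixing = fit$pi[ord],
    posterior = fit$posterior[, ord, drop = FALSE],
    sizes = as.integer(table(factor(assignments, levels = seq_len(k_best)))),
    data = list(prevalence = prevalence, depth = depth),
    merged = NULL, flagged_singletons = integer(0),
    call = match.call()
  ), class = "clone_mixture")
}

.em_binom_mixture <- function(x, depth, k, max_iter, tol) {
  n <- nrow(x); tp <- ncol(x)
  eps <- 1e-6
  # init: cluster prevalences from k distinct random mutations, jittered
  init_rows <- sample(n, k, replace = n < k)
  # note argument order: pmin/pmax take dims from their first argument
  theta <- pmin(pmax((x / pmax(depth, 1))[init_rows, , drop = FALSE] +
                       matrix(runif(k * tp, -0.02, 0.02), k, tp), eps), 1 - eps)
  pi_k <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step: log binomial kernel per mutation x cluster
    logp <- matrix(0, n, k)
    for (j in seq_len(k)) {
      th <- pmin(1 - eps, pmax(eps, theta[j, ]))
      logp[, j] <- x %*% log(th) + (depth - x) %*% log(1 - th) + log(pi_k[j])
    }
    m <- apply(logp, 1, max)
    post <- exp(logp - m)
    rs <- rowSums(post)
    post <- post / rs
    ll <- sum(m + log(rs))
    # M-step
    nk <- colSums(post)
    pi_k <- nk / n
    theta <- (t(post) %*% x) / pmax(t(post) %*% depth, .Machine$double.eps)
    theta <- pmin(pmax(theta, eps), 1 - eps)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(theta = theta, pi = pi_k, posterior = post, logLik = ll)
}

#' Merge single-mutation clusters into their nearest cluster
#'
#' Single-mutation "clusters" are usually noise. Each singleton is compared
#' to every non-singleton cluster by the standardized distance between the
#' mutation's observed prevalence vector and the cluster mean, where the
#' per-timepoint scale is the binomial standard error of the cluster mean at
#' the mutation's depth. The singleton is merged into the cluster minimizing
#' that distance, but only when every per-timepoint z-score lies within
#' \[-1, +1\]; otherwise it is retained and flagged.
#'
#' @param model a `"clone_mixture"` fit.
#' @return The model with singletons reassigned; `model$merged` records the
#'   moves and `model$flagged_singletons` the retained outliers. Cluster
#'   prevalences of merge targets are left unchanged.
#' @export
merge_singletons <- function(model) {
  stopifnot(inherits(model, "clone_mixture"))
  sizes <- tabulate(model$assignments, nbins = model$n_clusters)
  singletons <- which(sizes == 1L)
  nonsing <- which(sizes > 1L)
  if (!length(singletons) || !length(nonsing)) return(model)
  asg <- model$assignments
  prev <- model$data$prevalence
  dep <- model$data$depth
  merged <- list()
  flagged <- integer(0)
  for (s in singletons) {
    mut <- which(asg == s)
    z <- t(vapply(nonsing, function(k) {
      se <- sqrt(model$prevalence[k, ] * (1 - model$prevalence[k, ]) /
                   pmax(dep[mut, ], 1))
      (prev[mut, ] - model$prevalence[k, ]) / pmax(se, .Machine$double.eps)
    }, numeric(ncol(prev))))
    dist <- sqrt(rowSums(z^2))
    best <- which.min(dist)
    if (all(abs(z[best, ]) <= 1)) {
      asg[mut] <- nonsing[best]
      merged[[length(merged) + 1L]] <- data.frame(
        mutation = names(asg)[mut], from = s, to = nonsing[best])
    } else {
      flagged <- c(flagged, s)
    }
  }
  # drop now-empty clusters and relabel
  keep <- sort(unique(asg))
  relabel <- match(seq_len(model$n_clusters), keep)
  model$assignments <- setNames(relabel[asg], names(asg))
  model$prevalence <- model$prevalence[keep, , drop = FALSE]
  rownames(model$prevalence) <- paste0("C", seq_along(keep))
  model$mixing <- model$mixing[keep] / sum(model$mixing[keep])
  model$posterior <- model$posterior[, keep, drop = FALSE]
  model$n_clusters <- length(keep)
  model$sizes <- as.integer(table(factor(model$assignments,
                                         levels = seq_len(model$n_clusters))))
  model$merged <- if (length(merged)) do.call(rbind, merged) else NULL
  model$flagged_singletons <- relabel[flagged]
  model
}

#' Remove small clusters from display output
#'
#' Clusters with fewer than `min_size` mutations are excluded from the
#' display model but retained, untouched, in the removed list: the analysis
#' stays complete while plots stay readable.
#'
#' @param model a `"clone_mixture"` (typically after [merge_singletons()]).
#' @param min_size smallest cluster size kept for display.
#' @return List with `display` (the model restricted to clusters >=
#'   `min_size`; retained clusters' prevalences unchanged) and `removed`
#'   (data frame of pruned mutations with their cluster id and prevalences).
#' @export
prune_small_clusters <- function(model, min_size = 3L) {
  stopifnot(inherits(model, "clone_mixture"))
  sizes <- tabulate(model$assignments, nbins = model$n_clusters)
  small <- which(sizes < min_size)
  removed <- data.frame(mutation = character(), cluster = integer())
  if (length(small)) {
    drop_mut <- model$assignments %in% small
    removed <- data.frame(mutation = names(model$assignments)[drop_mut],
                          cluster = unname(model$assignments[drop_mut]))
    keep <- setdiff(seq_len(model$n_clusters), small)
    relabel <- match(seq_len(model$n_clusters), keep)
    model$assignments <- model$assignments[!drop_mut]
    model$assignments <- setNames(relabel[model$assignments],
                                  names(model$assignments))
    model$prevalence <- model$prevalence[keep, , drop = FALSE]
    if (length(keep)) rownames(model$prevalence) <- paste0("C", seq_along(keep))
    model$mixing <- model$mixing[keep]
    model$posterior <- model$posterior[!drop_mut, keep, drop = FALSE]
    model$n_clusters <- length(keep)
    model$sizes <- as.integer(table(factor(model$assignments,
                                           levels = seq_len(model$n_clusters))))
    model$data$prevalence <- model$data$prevalence[!drop_mut, , drop = FALSE]
    model$data$depth <- model$data$depth[!drop_mut, , drop = FALSE]
  }
  list(display = model, removed = removed)
}

#' Long-format cluster trajectory table with parent guesses
#'
#' Emits one row per cluster per timepoint with the cluster prevalence, plus
#' a parent guess by the containment heuristic: cluster A can be the parent
#' of B if A's prevalence is at least B's at every timepoint; among the
#' candidates, the one with the smallest total prevalence (the tightest
#' container) is chosen. Clusters contained by no other cluster are roots
#' (`parent = NA`); clusters tied with their best candidate at every
#' timepoint are marked `"ambiguous"`. Suitable as input for fishplot-style
#' visualisation; note the heuristic cannot distinguish a new subclone
#' carrying all truncal mutations from one that lost some.
#'
#' @param model a (typically pruned) `"clone_mixture"`.
#' @return Data frame `cluster`, `timepoint`, `prevalence`, `n_mutations`,
#'   `parent`.
#' @export
build_fishplot_table <- function(model) {
  stopifnot(inherits(model, "clone_mixture"))
  theta <- model$prevalence
  k <- nrow(theta)
  parent <- rep(NA_character_, k)
  for (b in seq_len(k)) {
    dominates <- vapply(seq_len(k), function(a)
      a != b && all(theta[a, ] >= theta[b, ]), logical(1))
    cand <- which(dominates)
    if (!length(cand)) next
    best <- cand[which.min(rowSums(theta[cand, , drop = FALSE]))]
    if (all(theta[best, ] == theta[b, ])) parent[b] <- "ambiguous"
    else parent[b] <- rownames(theta)[best]
  }
  out <- expand.grid(cluster = rownames(theta), timepoint = colnames(theta),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$prevalence <- theta[cbind(match(out$cluster, rownames(theta)),
                                match(out$timepoint, colnames(theta)))]
  out$n_mutations <- model$sizes[match(out$cluster, rownames(theta))]
  out$parent <- parent[match(out$cluster, rownames(theta))]
  out[order(match(out$cluster, rownames(theta))), , drop = FALSE]
}

#' @export
print.clone_mixture <- function(x, ...) {
  cat("Binomial-mixture clonal clustering\n")
  cat(sprintf("  %d mutations x %d timepoints, %d cluster(s) selected by BIC (%.1f)\n",
              nrow(x$data$prevalence), ncol(x$data$prevalence),
              x$n_clusters, x$fit_score))
  cat("  cluster prevalences:\n")
  print(round(x$prevalence, 3))
  invisible(x)
}

#' @export
summary.clone_mixture <- function(object, ...) {
  out <- list(
    n_mutations = nrow(object$data$prevalence),
    n_clusters = object$n_clusters,
    sizes = object$sizes,
    prevalence = object$prevalence,
    mixing = object$mixing,
    logLik = object$logLik,
    bic = object$fit_score,
    bic_by_k = object$bic_by_k,
    flagged_singletons = object$flagged_singletons
  )
  class(out) <- "summary.clone_mixture"
  out
}

#' @export
print.summary.clone_mixture <- function(x, ...) {
  cat(sprintf("Clonal clustering of %d mutations: %d cluster(s)\n",
              x$n_mutations, x$n_clusters))
  tab <- cbind(size = x$sizes, mixing = round(x$mixing, 3),
               round(x$prevalence, 3))
  print(tab)
  cat(sprintf("logLik %.2f, BIC %.1f (by K: %s)\n", x$logLik, x$bic,
              paste(round(x$bic_by_k, 1), collapse = ", ")))
  invisible(x)
}

#' @export
coef.clone_mixture <- function(object, ...) object$prevalence

#' @export
logLik.clone_mixture <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- object$n_clusters * ncol(object$prevalence) +
    object$n_clusters - 1
  attr(val, "nobs") <- nrow(object$data$prevalence)
  class(val) <- "logLik"
  val
}

#' Assign new mutations to fitted clusters
#'
#' @param object a `"clone_mixture"` fit.
#' @param prevalence,depth matrices of new observations (mutations x
#'   timepoints, same timepoints as the fit); defaults to the training data.
#' @param ... unused.
#' @return Integer vector of cluster assignments (maximum posterior).
#' @export
predict.clone_mixture <- function(object, prevalence = NULL, depth = NULL, ...) {
  if (is.null(prevalence)) {
    prevalence <- object$data$prevalence
    depth <- object$data$depth
  }
  prevalence <- as.matrix(prevalence); depth <- as.matrix(depth)
  eps <- 1e-6
  x <- prevalence * depth
  k <- object$n_clusters
  logp <- matrix(0, nrow(x), k)
  for (j in seq_len(k)) {
    th <- pmin(1 - eps, pmax(eps, object$prevalence[j, ]))
    logp[, j] <- x %*% log(th) + (depth - x) %*% log(1 - th) +
      log(object$mixing[j])
  }
  asg <- apply(logp, 1, which.max)
  setNames(as.integer(asg), rownames(prevalence))
}

#' @export
residuals.clone_mixture <- function(object, ...) {
  object$data$prevalence - object$prevalence[object$assignments, , drop = FALSE]
}

#' Simulate prevalence observations from a fitted clonal mixture
#'
#' Draws binomial alt counts at the fitted cluster prevalences using the
#' training depths and returns the implied prevalence matrices.
#'
#' @param object a `"clone_mixture"`.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return List of `nsim` prevalence matrices.
#' @export
simulate.clone_mixture <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dep <- object$data$depth
  th <- object$prevalence[object$assignments, , drop = FALSE]
  lapply(seq_len(nsim), function(i) {
    alt <- matrix(rbinom(length(dep), as.vector(dep), as.vector(th)),
                  nrow(dep), ncol(dep), dimnames = dimnames(dep))
    alt / pmax(dep, 1)
  })
}

#' Parallel-coordinate plot of cluster prevalences
#'
#' @param x a `"clone_mixture"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.clone_mixture <- function(x, ...) {
  theta <- x$prevalence
  matplot(t(theta), type = "b", lty = 1, pch = 19,
          xaxt = "n", ylim = c(0, 1),
          xlab = "timepoint", ylab = "cellular prevalence",
          main = "Cluster prevalence trajectories", ...)
  axis(1, at = seq_len(ncol(theta)), labels = colnames(theta))
  legend("topright", legend = paste0(rownames(theta), " (n=", x$sizes, ")"),
         col = seq_len(nrow(theta)), lty = 1, pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}
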