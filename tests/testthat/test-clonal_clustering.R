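test_that("identical prevalence vectors collapse to one cluster", {
  prev <- matrix(0.6, 20, 3)
  dep <- matrix(150, 20, 3)
  fit <- clone_mixture(prev, dep, k_max = 5, seed = 1)
  expect_equal(fit$n_clusters, 1)
  expect_true(all(abs(fit$prevalence - 0.6) < 0.01))
  expect_error(clone_mixture(prev, dep * 0), "all-zero")
})

test_that("two well-separated groups are recovered with accurate prevalences", {
  set.seed(2)
  centers <- rbind(c(1, 1, 1), c(0.6, 0.1, 0.4))
  truth <- rep(1:2, each = 30)
  dep <- matrix(rpois(180, 150), 60, 3)
  alt <- matrix(rbinom(180, as.vector(dep), as.vector(centers[truth, ])), 60, 3)
  ks <- integer(5)
  for (s in 1:5) {
    fit <- clone_mixture(alt / dep, dep, k_max = 5, seed = s)
    ks[s] <- fit$n_clusters
    if (fit$n_clusters == 2)
      expect_lt(max(abs(fit$prevalence - centers)), 0.05)
  }
  expect_equal(as.integer(names(which.max(table(ks)))), 2)
})

test_that("BIC selects the true number of noiseless well-separated clusters", {
  for (k_true in 1:4) {
    centers <- matrix(seq(0.95, 0.1, length.out = 12), 4, 3)[seq_len(k_true), ,
                                                             drop = FALSE]
    prev <- centers[rep(seq_len(k_true), each = 25), , drop = FALSE]
    dep <- matrix(1000, nrow(prev), 3)
    fit <- clone_mixture(prev, dep, k_max = 6, seed = k_true)
    expect_equal(fit$n_clusters, k_true)
  }
})

test_that("mutation order does not change the clustering (up to relabeling)", {
  set.seed(6)
  d <- make_three_cluster_data()
  fit1 <- clone_mixture(d$prevalence, d$depth, k_max = 5, seed = 10)
  perm <- sample(nrow(d$prevalence))
  fit2 <- clone_mixture(d$prevalence[perm, ], d$depth[perm, ], k_max = 5,
                        seed = 10)
  expect_equal(fit1$n_clusters, fit2$n_clusters)
  # clusters are relabeled by decreasing mean prevalence, so the prevalence
  # matrices must agree and assignments must map consistently
  expect_equal(fit1$prevalence, fit2$prevalence, tolerance = 1e-6)
  expect_equal(unname(fit2$assignments[order(perm)]),
               unname(fit1$assignments))
})

test_that("singleton merge follows the standardized-distance rule", {
  # two tight clusters plus one singleton sitting exactly on a cluster mean
  prev <- rbind(matrix(0.9, 10, 3), matrix(0.3, 10, 3), rep(0.9, 3))
  dep <- matrix(150, 21, 3)
  fit <- clone_mixture(prev, dep, k_max = 4, seed = 3)
  if (fit$n_clusters == 3) {   # singleton isolated by the fit
    merged <- merge_singletons(fit)
    expect_lt(merged$n_clusters, fit$n_clusters)
    m21 <- merged$assignments[21]
    expect_equal(unname(merged$prevalence[m21, 1]), 0.9, tolerance = 0.02)
  }
  # model without singleton clusters is untouched
  fit2 <- clone_mixture(prev[1:20, ], dep[1:20, ], k_max = 3, seed = 3)
  expect_identical(merge_singletons(fit2)$assignments, fit2$assignments)
})

test_that("merge targets equal brute-force nearest-cluster search on random configurations", {
  set.seed(50)
  for (rep_i in 1:50) {
    k <- sample(2:4, 1)
    centers <- matrix(runif(k * 3, 0.05, 0.95), k, 3)
    sizes <- sample(5:10, k, replace = TRUE)
    prev <- centers[rep(seq_len(k), sizes), , drop = FALSE] +
      matrix(rnorm(sum(sizes) * 3, 0, 0.01), sum(sizes), 3)
    single <- pmin(0.95, pmax(0.05, centers[sample(k, 1), ] + rnorm(3, 0, 0.05)))
    prev <- pmin(pmax(rbind(prev, single), 0.01), 0.99)
    dep <- matrix(150, nrow(prev), 3)
    n <- nrow(prev)

    # hand-built model: known clusters, last mutation a singleton
    model <- structure(list(
      assignments = setNames(c(rep(seq_len(k), sizes), k + 1L),
                             paste0("m", seq_len(n))),
      prevalence = rbind(centers, prev[n, ]),
      n_clusters = k + 1L,
      mixing = rep(1 / (k + 1), k + 1),
      posterior = matrix(1 / (k + 1), n, k + 1),
      sizes = c(sizes, 1L),
      data = list(prevalence = prev, depth = dep),
      fit_score = NA_real_, logLik = NA_real_, bic_by_k = NA_real_,
      merged = NULL, flagged_singletons = integer(0)
    ), class = "clone_mixture")

    # brute force: standardized distance to every non-singleton cluster
    z <- t(vapply(seq_len(k), function(j) {
      se <- sqrt(centers[j, ] * (1 - centers[j, ]) / 150)
      (prev[n, ] - centers[j, ]) / se
    }, numeric(3)))
    best <- which.min(sqrt(rowSums(z^2)))
    acceptable <- all(abs(z[best, ]) <= 1)

    merged <- merge_singletons(model)
    if (acceptable) {
      expect_equal(merged$n_clusters, k)
      expect_equal(unname(merged$assignments[n]), best)
    } else {
      expect_equal(merged$n_clusters, k + 1L)
      expect_true(length(merged$flagged_singletons) >= 1)
    }
  }
})

test_that("pruning removes small clusters from display but keeps them in the ledger", {
  d <- make_three_cluster_data(n_per = 10)
  fit <- clone_mixture(d$prevalence, d$depth, k_max = 4, seed = 4)
  pr <- prune_small_clusters(fit, min_size = 3)
  expect_equal(nrow(pr$removed), 0)
  # force a small cluster by pruning at an absurd threshold
  pr2 <- prune_small_clusters(fit, min_size = 15)
  expect_equal(length(pr2$display$assignments) + nrow(pr2$removed),
               length(fit$assignments))
  if (pr2$display$n_clusters > 0 && pr2$display$n_clusters < fit$n_clusters) {
    kept_names <- rownames(pr2$display$prevalence)
    expect_true(all(pr2$display$prevalence %in% fit$prevalence))
  }
})

test_that("merging never increases, and pruning never alters retained prevalences", {
  set.seed(61)
  d <- make_three_cluster_data(n_per = 12)
  fit <- clone_mixture(d$prevalence, d$depth, k_max = 6, seed = 7)
  merged <- merge_singletons(fit)
  expect_lte(merged$n_clusters, fit$n_clusters)
  pruned <- prune_small_clusters(merged, min_size = 3)
  retained_old <- merged$prevalence[merged$sizes >= 3, , drop = FALSE]
  expect_equal(unname(pruned$display$prevalence), unname(retained_old))
})

test_that("fishplot table parents follow the containment heuristic", {
  model <- structure(list(
    assignments = setNames(rep(1:3, c(5, 4, 3)), paste0("m", 1:12)),
    prevalence = matrix(c(1, 1, 1,  0.4, 0.3, 0.2,  0.3, 0.05, 0.1), 3, 3,
                        byrow = TRUE,
                        dimnames = list(c("C1", "C2", "C3"),
                                        c("pre", "post_a", "post_b"))),
    n_clusters = 3L, sizes = c(5L, 4L, 3L),
    mixing = c(0.4, 0.35, 0.25),
    data = list(prevalence = matrix(0, 1, 3), depth = matrix(1, 1, 3))
  ), class = "clone_mixture")
  tab <- build_fishplot_table(model)
  expect_equal(nrow(tab), 9)
  expect_true(is.na(tab$parent[tab$cluster == "C1"][1]))       # root
  expect_equal(tab$parent[tab$cluster == "C2"][1], "C1")
  expect_equal(tab$parent[tab$cluster == "C3"][1], "C2")       # tightest container

  # brute-force containment on random nested prevalence sets
  set.seed(17)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    theta <- matrix(runif(k * 3), k, 3,
                    dimnames = list(paste0("C", 1:k), c("pre", "post_a", "post_b")))
    model$prevalence <- theta
    model$n_clusters <- k
    model$sizes <- rep(2L, k)
    tab <- build_fishplot_table(model)
    for (b in 1:k) {
      dom <- setdiff(which(apply(theta, 1, function(a) all(a >= theta[b, ]))), b)
      got <- tab$parent[tab$cluster == paste0("C", b)][1]
      if (!length(dom)) {
        expect_true(is.na(got))
      } else {
        want <- dom[which.min(rowSums(theta[dom, , drop = FALSE]))]
        if (all(theta[want, ] == theta[b, ])) expect_equal(got, "ambiguous")
        else expect_equal(got, paste0("C", want))
      }
    }
  }
})

test_that("model methods expose coefficients, residuals, prediction and simulation", {
  set.seed(12)
  d <- make_three_cluster_data(n_per = 15)
  fit <- clone_mixture(d$prevalence, d$depth, k_max = 5, seed = 5)
  expect_identical(coef(fit), fit$prevalence)
  expect_equal(dim(residuals(fit)), dim(d$prevalence))
  expect_lt(mean(abs(residuals(fit))), 0.1)
  expect_identical(unname(predict(fit)), unname(fit$assignments))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(d$prevalence))
  expect_output(print(fit), "Binomial-mixture")
  expect_output(print(summary(fit)), "cluster")
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_true(is.finite(as.numeric(ll)))
})
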