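test_that("config validation catches bad parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_subclones_range = c(5, 2)), "ordered")
  expect_error(sim_config(extinction_prob_small_clone = 1.5), "probabilities")
  expect_error(sim_config(purity_by_timepoint = c(0.5, 0, 0.3)))
  expect_error(sim_config(directed_cna_events = data.frame(
    bin = "NOPE", timepoint = "pre", type = "loss", prob = 1)), "unknown bin")
  expect_error(sim_config(directed_cna_events = data.frame(
    bin = "MYC", timepoint = "mid", type = "loss", prob = 1)), "timepoint")
})

test_that("truncal clone keeps prevalence 1 and dynamics vanish in the no-noise limit", {
  cfg <- sim_config(expansion_sd = 0, extinction_prob_small_clone = 0)
  set.seed(11)
  for (i in 1:20) {
    tree <- simulate_clonal_tree(cfg)
    expect_equal(unname(tree$prevalence[1, ]), c(1, 1, 1))
    # no-dynamics limit: every subclone identical across the three timepoints
    expect_equal(tree$prevalence[, "post_a"], tree$prevalence[, "pre"])
    expect_equal(tree$prevalence[, "post_b"], tree$prevalence[, "pre"])
  }
})

test_that("sibling prevalences never exceed the parent (nesting invariant)", {
  cfg <- sim_config(expansion_sd = 0.5, extinction_prob_small_clone = 0.3)
  set.seed(202)
  for (i in 1:1000) {
    tree <- simulate_clonal_tree(cfg)
    parent <- tree$clones$parent_id
    for (p in seq_len(nrow(tree$clones))) {
      kids <- which(parent == p)
      if (!length(kids)) next
      sums <- colSums(tree$prevalence[kids, , drop = FALSE])
      expect_true(all(sums <= tree$prevalence[p, ] + 1e-9))
    }
    expect_true(all(tree$prevalence >= 0))
  }
})

test_that("detection-boundary crossing fraction matches an independent re-simulation", {
  cfg <- sim_config(expansion_sd = 0.5, extinction_prob_small_clone = 0.3)
  boundary <- 0.05 / expected_vaf(1, 2, 0.7)  # CCF at the 5% VAF limit
  n_trees <- 1000
  crossings <- logical(n_trees)
  for (i in seq_len(n_trees)) {
    set.seed(1000 + i)
    tree <- simulate_clonal_tree(cfg)
    crossings[i] <- crossed_boundary(tree$prevalence, boundary)
  }
  oracle <- logical(n_trees)
  for (i in seq_len(n_trees)) {
    set.seed(1000 + i)
    oracle[i] <- crossed_boundary(oracle_tree_prevalence(cfg), boundary)
  }
  expect_identical(crossings, oracle)
  expect_gt(mean(crossings), 0)  # dynamics do move clones across the limit
})

test_that("read emission follows the expected-VAF model", {
  set.seed(5)
  expect_true(all(simulate_reads(0, purity = 0.8, n = 200)$alt_reads == 0))
  # diploid heterozygous pure-tumor limit
  r <- simulate_reads(1, 1, 2, purity = 1, depth_mean = 1e6, n = 10)
  expect_true(all(abs(r$alt_reads / (r$alt_reads + r$ref_reads) - 0.5) < 0.002))
  # analytic mean VAF on a grid, within 3 standard errors
  grid <- expand.grid(ccf = c(0.1, 0.5, 1), n_mut = 1:2, n_tot = 2:3,
                      rho = c(0.4, 0.8))
  grid <- grid[grid$n_mut <= grid$n_tot, ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- g$ccf * expected_vaf(g$n_mut, g$n_tot, g$rho)
    r <- simulate_reads(g$ccf, g$n_mut, g$n_tot, g$rho,
                        depth_mean = 100, n = 1e5)
    vaf <- r$alt_reads / (r$alt_reads + r$ref_reads)
    se <- sd(vaf) / sqrt(length(vaf))
    expect_lt(abs(mean(vaf) - p), 3 * se + 1e-6)
  }
  expect_error(simulate_reads(1.2, purity = 0.5), "ccf")
})

test_that("copy number baseline is diploid and directed events obey their rule", {
  cfg0 <- sim_config()
  set.seed(3)
  seg <- simulate_copy_number(cfg0)
  expect_true(all(seg$n_major + seg$n_minor == 2))

  ev <- data.frame(bin = "MYC", timepoint = "post_b", type = "loss", prob = 1)
  cfg1 <- sim_config(n_patients = 10, directed_cna_events = ev)
  set.seed(3)
  for (i in 1:10) {
    seg <- simulate_copy_number(cfg1)
    myc <- seg[seg$bin == "MYC", ]
    expect_equal(myc$n_major[myc$timepoint == "post_b"] +
                   myc$n_minor[myc$timepoint == "post_b"], 1)
    expect_equal(myc$n_major[myc$timepoint == "pre"] +
                   myc$n_minor[myc$timepoint == "pre"], 2)
  }

  # probabilistic event frequency within 3 binomial SDs
  ev3 <- data.frame(bin = "8q", timepoint = "post_a", type = "gain", prob = 0.3)
  cfg3 <- sim_config(directed_cna_events = ev3)
  set.seed(9)
  hits <- vapply(1:1000, function(i) {
    seg <- simulate_copy_number(cfg3)
    any(seg$bin == "8q" & seg$timepoint == "post_a" &
          seg$n_major + seg$n_minor == 3)
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
})

test_that("cohort simulation is deterministic and writes byte-identical files", {
  cfg <- sim_config(n_patients = 2, seed = 99)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$observations, co2$observations)
  expect_identical(co1$segments, co2$segments)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co1, d1)
  write_cohort(co2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("cohort round-trips through disk and truth lists every mutation once", {
  cfg <- sim_config(n_patients = 2, seed = 4)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$observations), nrow(co$observations))
  expect_equal(back$observations$alt_reads, co$observations$alt_reads)
  expect_equal(back$observations$pos, co$observations$pos)
  # truth covers each simulated mutation exactly once
  truth_ids <- unlist(lapply(back$truth, function(tr)
    paste0(tr$patient_id, ":", tr$mutations$mutation_id)))
  expect_identical(sort(unique(co$observations$mutation_id)),
                   sort(truth_ids))
})
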