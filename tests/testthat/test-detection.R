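obs_row <- function(alt, ref, id = "m1") {
  data.frame(mutation_id = id, alt_reads = alt, ref_reads = ref)
}

test_that("calling applies the VAF and alt-read gates and records reasons", {
  expect_true(call_variants(obs_row(10, 90))$called)      # VAF 0.10
  low <- call_variants(obs_row(3, 147))                   # VAF 0.02
  expect_false(low$called)
  expect_equal(low$reason, "below_vaf")
  few <- call_variants(obs_row(2, 18))                    # VAF 0.10 but 2 reads
  expect_false(few$called)
  expect_equal(few$reason, "below_alt_reads")
  nocov <- call_variants(obs_row(0, 0))
  expect_false(nocov$called)
  expect_equal(nocov$reason, "no_coverage")
  expect_error(call_variants(obs_row(-1, 5)), "negative")
})

test_that("calling sweep matches brute-force evaluation of both predicates", {
  sweep <- call_variants(obs_row(0:20, 100 - (0:20), sprintf("m%02d", 0:20)))
  brute <- vapply(0:20, function(a) (a / 100 >= 0.05) && (a >= 3), logical(1))
  expect_identical(sweep$called, brute)
})

test_that("raising min_vaf never enlarges the called set (monotone filter)", {
  set.seed(8)
  obs <- obs_row(rbinom(300, 150, 0.06), 150, sprintf("m%03d", 1:300))
  obs$ref_reads <- pmax(150 - obs$alt_reads, 0)
  prev <- NULL
  for (v in c(0.01, 0.03, 0.05, 0.1, 0.2)) {
    called <- call_variants(obs, min_vaf = v)$called
    if (!is.null(prev)) expect_true(all(prev | !called))  # called  subset of prev
    prev <- called
  }
})

test_that("trace detection is exclusive with calling and calibrated to the binomial tail", {
  expect_true(trace_scan(2, called = FALSE)$trace_present)
  expect_equal(trace_scan(2, called = FALSE)$trace_reads, 2)
  expect_false(trace_scan(0, called = FALSE)$trace_present)
  expect_false(trace_scan(10, called = TRUE)$trace_present)
  expect_true(is.na(trace_scan(0, called = FALSE, depth = 0)$trace_present))

  set.seed(21)
  ccf <- 0.03; rho <- 0.7
  r <- simulate_reads(ccf, 1, 2, rho, depth_mean = 150, n = 1e4)
  cv <- call_variants(cbind(r, mutation_id = sprintf("m%05d", seq_len(nrow(r)))))
  tr <- trace_scan(cv$alt_reads, cv$called, cv$alt_reads + cv$ref_reads)
  p_emp <- mean(tr$trace_present, na.rm = TRUE)
  p_oracle <- oracle_trace_prob(ccf * expected_vaf(1, 2, rho))
  se <- sqrt(p_oracle * (1 - p_oracle) / 1e4)
  expect_lt(abs(p_emp - p_oracle), 3 * se)
})

test_that("trace probability rises with CCF below the detection limit", {
  probs <- vapply(c(0.002, 0.005, 0.01, 0.02, 0.03),
                  function(ccf) oracle_trace_prob(ccf * expected_vaf(1, 2, 0.7)),
                  numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("P(called) is non-decreasing in CCF at fixed depth", {
  set.seed(13)
  ccfs <- c(0.02, 0.05, 0.1, 0.2, 0.5, 1)
  p_called <- vapply(ccfs, function(ccf) {
    r <- simulate_reads(ccf, 1, 2, 0.6, depth_mean = 150, n = 4000)
    mean(call_variants(cbind(r, mutation_id = seq_len(nrow(r))))$called)
  }, numeric(1))
  expect_true(all(diff(p_called) > -0.02))  # Monte-Carlo slack
})

test_that("trajectory classification matches the brute-force oracle on 200 mutations", {
  set.seed(77)
  n <- 200
  # counts spanning all regimes: zero, trace-level, borderline, clearly called
  alt1 <- sample(c(0, 0, 1, 2, 3, 5, 10, 40), n, replace = TRUE)
  alt2 <- sample(c(0, 0, 1, 2, 3, 5, 10, 40), n, replace = TRUE)
  ref1 <- sample(c(0, 50, 100, 150), n, replace = TRUE,
                 prob = c(0.05, 0.3, 0.35, 0.3))
  ref2 <- sample(c(0, 50, 100, 150), n, replace = TRUE,
                 prob = c(0.05, 0.3, 0.35, 0.3))
  ids <- sprintf("m%03d", 1:n)
  got <- classify_trajectories(obs_row(alt1, ref1, ids), obs_row(alt2, ref2, ids),
                               keep_absent = TRUE)
  got <- got[match(ids, got$mutation_id), ]
  for (i in seq_len(n)) {
    want <- oracle_classify_one(alt1[i], ref1[i], alt2[i], ref2[i])
    expect_identical(got$status[i], want$status, info = ids[i])
    expect_identical(got$trace_flag[i], want$flag, info = ids[i])
  }
})

test_that("trajectory examples behave as documented", {
  t1 <- obs_row(c(10, 2, 10, 0), 140, sprintf("m%d", 1:4))
  t2 <- obs_row(c(12, 30, 2, 1), 140, sprintf("m%d", 1:4))
  tr <- classify_trajectories(t1, t2)
  tr <- tr[match(sprintf("m%d", 1:3), tr$mutation_id), ]
  expect_identical(tr$status, c("persistent", "emerging", "disappearing"))
  expect_identical(tr$trace_flag[2], "pre_existing_trace")
  expect_equal(tr$trace_reads_prior[2], 2)
  expect_identical(tr$trace_flag[3], "residual_trace")
  # m4 never called: excluded by default
  expect_false("m4" %in% tr$mutation_id)
})

test_that("trace-rate summary matches a hand tally and conserves totals", {
  traj <- data.frame(
    patient_id = c("A", "A", "A", "B", "B", "C"),
    status = c("emerging", "emerging", "disappearing", "persistent",
               "disappearing", "persistent"),
    trace_flag = c("pre_existing_trace", "no_trace", "residual_trace",
                   "not_applicable", "no_trace", "not_applicable")
  )
  s <- summarize_trace_rates(traj)
  a <- s[s$patient_id == "A", ]
  expect_equal(a$n_emerging, 2)
  expect_equal(a$n_emerging_trace, 1)
  expect_equal(a$frac_emerging_trace, 0.5)
  cohort <- s[s$patient_id == "cohort", ]
  expect_equal(cohort$n_emerging, sum(s$n_emerging[s$patient_id != "cohort"]))
  expect_equal(cohort$n_disappearing, 2)
  # no emerging mutations for C: fraction undefined, not zero
  expect_true(is.na(s$frac_emerging_trace[s$patient_id == "C"]))
})

test_that("most emerging mutations with true prior presence carry a pre-existing trace", {
  co <- simulate_cohort(sim_config(n_patients = 15, seed = 31))
  obs <- call_variants(co$observations)
  flags <- character(0)
  for (pid in unique(obs$patient_id)) {
    tru <- co$truth[[which(vapply(co$truth, `[[`, "", "patient_id") == pid)]]
    for (tps in list(c("pre", "post_a"), c("post_a", "post_b"))) {
      o1 <- obs[obs$patient_id == pid & obs$timepoint == tps[1], ]
      o2 <- obs[obs$patient_id == pid & obs$timepoint == tps[2], ]
      tr <- classify_trajectories(o1, o2)
      ccf_t1 <- tru$ccf[, tps[1]]
      names(ccf_t1) <- paste0(pid, ":", rownames(tru$ccf))
      em <- tr[tr$status == "emerging" & ccf_t1[tr$mutation_id] > 0, ]
      flags <- c(flags, em$trace_flag)
    }
  }
  expect_gt(length(flags), 10)
  expect_gt(mean(flags == "pre_existing_trace"), 0.5)
})
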