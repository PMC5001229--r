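test_that("effective sizes match brute-force footprint enumeration", {
  set.seed(5)
  cfg <- sim_config(n_genes = 10, seed = 5)
  tx <- make_transcriptome(cfg)
  for (ev in tx$events) {
    got <- effective_sizes(ev, 40L)
    want <- brute_effective_sizes(ev, 40L)
    expect_equal(got$eff_inc, want$eff_inc, info = ev$event_id)
    expect_equal(got$eff_exc, want$eff_exc, info = ev$event_id)
    expect_equal(got$eff_shared, want$eff_shared, info = ev$event_id)
  }
})

test_that("junction-overhang filtering matches brute force and trims junction reads", {
  set.seed(6)
  toy <- toy_event("cassette", rand_dna(120), rand_dna(90), rand_dna(120))
  for (o in c(1L, 5L, 10L)) {
    got <- effective_sizes(toy$event, 40L, overhang = o)
    want <- brute_effective_sizes(toy$event, 40L, overhang = o)
    expect_equal(got$eff_inc, want$eff_inc)
    expect_equal(got$eff_exc, want$eff_exc)
    expect_equal(got$eff_shared, want$eff_shared)
  }
  e1 <- effective_sizes(toy$event, 40L, overhang = 1L)
  e8 <- effective_sizes(toy$event, 40L, overhang = 8L)
  expect_lt(e8$eff_exc, e1$eff_exc)   # exclusion reads are all junctional
})

test_that("an event too short to yield diagnostic reads is flagged untestable", {
  set.seed(7)
  toy <- toy_event("cassette", rand_dna(20), rand_dna(5), rand_dna(20))
  eff <- effective_sizes(toy$event, 75L)
  expect_false(eff$testable)
  expect_match(eff$reason, "no .*-specific read positions")
})

test_that("symmetric counts give a posterior mean of exactly one half", {
  eff <- data.frame(eff_inc = 120, eff_exc = 120, eff_shared = 200)
  post <- psi_posterior(57, 57, 31, eff)
  expect_equal(post$mean, 0.5, tolerance = 1e-12)
  expect_true(post$ci[1] < 0.5 && post$ci[2] > 0.5)
})

test_that("pure exclusion counts with equal effective sizes recover the Beta(1, n+1) posterior", {
  eff <- data.frame(eff_inc = 100, eff_exc = 100, eff_shared = 0)
  post <- psi_posterior(0, 100, 0, eff)
  expect_lt(abs(post$mean - 1 / 102), 1e-6)
  ## grid posterior matches the Beta(1, 101) density where it has mass
  dens <- post$mass / exp(psikit:::.psi_grid(1001L)$logw)
  lo <- post$psi <= 0.1
  expect_lt(max(abs(dens[lo] - dbeta(post$psi[lo], 1, 101))), 1e-4)
})

test_that("all-zero counts return the uniform prior, flagged low-information", {
  eff <- data.frame(eff_inc = 50, eff_exc = 80, eff_shared = 10)
  post <- psi_posterior(0, 0, 0, eff)
  expect_true(post$low_information)
  expect_equal(post$mean, 0.5, tolerance = 1e-9)
  expect_equal(post$ci, c(0.025, 0.975), tolerance = 1e-3)
  expect_equal(sum(post$mass), 1, tolerance = 1e-9)
})

test_that("grid posterior mean and log Bayes factor track the quadrature oracle", {
  set.seed(11)
  for (i in 1:25) {
    cf <- random_count_config()
    post <- psi_posterior(cf$ctrl$n_inc, cf$ctrl$n_exc, cf$ctrl$n_shared,
                          cf$eff)
    expect_lt(abs(post$mean - oracle_post_mean(cf$ctrl, cf$eff)), 1e-3)
    bf <- bayes_factor(cf$ctrl, cf$trt, cf$eff)
    expect_lt(abs(bf$log_bf - oracle_log_bf(cf$ctrl, cf$trt, cf$eff)), 0.01)
  }
})

test_that("the posterior mean is monotone in the inclusion count", {
  eff <- data.frame(eff_inc = 200, eff_exc = 150, eff_shared = 100)
  total <- 300L
  means <- vapply(seq(0L, total, by = 20L), function(ni)
    psi_posterior(ni, total - ni, 50, eff)$mean, 0)
  expect_true(all(diff(means) > 0))
})

test_that("swapping condition labels negates delta PSI and preserves the Bayes factor", {
  set.seed(13)
  for (i in 1:5) {
    cf <- random_count_config()
    ab <- bayes_factor(cf$ctrl, cf$trt, cf$eff)
    ba <- bayes_factor(cf$trt, cf$ctrl, cf$eff)
    expect_equal(ab$delta_psi, -ba$delta_psi, tolerance = 1e-12)
    expect_equal(ab$log_bf, ba$log_bf, tolerance = 1e-10)
  }
})

test_that("identical counts in both conditions favor the shared model", {
  eff <- data.frame(eff_inc = 200, eff_exc = 200, eff_shared = 200)
  n <- list(n_inc = 200, n_exc = 200, n_shared = 200)
  bf <- bayes_factor(n, n, eff)
  expect_lt(bf$bayes_factor, 5)
  expect_false(bf$passes)
})

test_that("the call rule requires both the Bayes factor and delta PSI thresholds", {
  expect_true(passes_call(5.1, 0.06))
  expect_false(passes_call(5.1, 0.04))
  expect_false(passes_call(4.9, 0.06))
  expect_true(passes_call(5.1, -0.06))
  expect_false(passes_call(5.0, 0.06))    # strict inequality
  expect_false(passes_call(5.1, 0.05))
})

test_that("call summaries partition passing events by sign and type", {
  cfg <- sim_config(n_genes = 40, seed = 17, frac_affected = 0.5,
                    delta_psi_effects = c(0.3), depth_per_event = 800)
  tx <- make_transcriptome(cfg)
  truth <- make_truth(tx, cfg)
  eff <- effective_sizes_table(tx, cfg$read_length)
  cts <- simulate_counts(tx, truth, cfg, eff)
  calls <- call_events(cts, eff)
  s <- calls$summary
  expect_equal(s$n_up + s$n_down, s$n_passing)
  expect_equal(sum(unlist(s$by_type)), s$n_passing)
  expect_equal(s$n_tested + nrow(calls$skipped), length(tx$events))
  expect_identical(calls$calls$passes,
                   passes_call(calls$calls$bayes_factor, calls$calls$delta_psi))
})

test_that("no counts in a condition skips the event with a reason", {
  cfg <- sim_config(n_genes = 3, seed = 19)
  tx <- make_transcriptome(cfg)
  truth <- make_truth(tx, cfg)
  eff <- effective_sizes_table(tx, cfg$read_length)
  cts <- simulate_counts(tx, truth, cfg, eff)
  cts <- cts[!(cts$event_id == eff$event_id[1] & cts$condition == "treated"), ]
  calls <- call_events(cts, eff)
  expect_true(eff$event_id[1] %in% calls$skipped$event_id)
  expect_equal(calls$summary$n_tested, 2L)
})
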