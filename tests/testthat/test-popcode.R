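# Shared fixtures for the encode/decode experiments (built once per file).
bank <- build_candidate_bank()
pops <- default_populations()

test_that("tuning curves peak at the preferred value with Gaussian falloff", {
  pop <- tuning_population(0, 1, sd = 0.1, n_detectors = 11, gain = 40)
  f <- tuning_response(pop, pop$preferred[6])
  expect_equal(f[6], 40)
  f_off <- tuning_response(pop, pop$preferred[6] + 0.1)
  expect_equal(f_off[6], 40 * exp(-0.5))
  # symmetric about the stimulated detector
  expect_equal(f[5], f[7])
  expect_equal(f[2], f[10])
})

test_that("Poisson encoding is unbiased around the tuning curve", {
  pop <- pops$gamma
  f <- tuning_response(pop, 0.065)
  draws <- withr::with_seed(31, {
    rowMeans(vapply(1:2000, function(i) encode_spikes(pop, 0.065),
                    numeric(length(f))))
  })
  se <- sqrt(f / 2000)
  active <- f > 1
  expect_true(all(abs(draws[active] - f[active]) < 3 * se[active] + 1e-9))

  silent <- tuning_population(0, 1, 0.1, gain = 0)
  expect_true(all(encode_spikes(silent, 0.5) == 0))
  expect_error(decode_mle(silent, rep(0, 33)), "gain")
})

test_that("ML decoding recovers the stimulus", {
  pop <- pops$theta
  stim <- 0.0027
  grid_step <- diff(pop$range) / 999
  noise_free <- decode_mle(pop, round(tuning_response(pop, stim)))
  expect_lt(abs(noise_free - stim), grid_step + 1e-12)

  est <- withr::with_seed(41, {
    vapply(1:2000, function(i) decode_mle(pop, encode_spikes(pop, stim)),
           numeric(1))
  })
  expect_lt(abs(mean(est) - stim), 0.005 * diff(pop$range))

  lone <- rep(0, length(pop$preferred))
  lone[10] <- 4
  expect_lt(abs(decode_mle(pop, lone) - pop$preferred[10]), 2 * pop$sd)
})

test_that("decoding precision grows with gain", {
  sd_at_gain <- function(gain, seed) {
    pop <- tuning_population(0.2, 0.45, 0.01625, gain = gain)
    withr::with_seed(seed, {
      sd(vapply(1:300, function(i) decode_mle(pop, encode_spikes(pop, 0.33)),
                numeric(1)))
    })
  }
  expect_lt(sd_at_gain(100, 51), sd_at_gain(20, 52))
})

test_that("the candidate bank covers the 9 x 5 x 5 hypothesis grid", {
  expect_equal(nrow(bank), 225)
  expect_equal(length(unique(bank$ttc)), 9)
  expect_equal(length(unique(bank$gravity)), 5)
  expect_equal(length(unique(bank$size)), 5)

  std <- bank[bank$gravity == 9.807 & bank$size == 0.074 & bank$ttc == 2, ]
  expect_equal(nrow(std), 1)
  expect_gt(std$theta, 0.0024)
  expect_lt(std$theta, 0.0031)
  expect_gt(std$gamma, 0.045)
  expect_lt(std$gamma, 0.085)
  expect_gt(std$gamma_dot, 0.2)
  expect_lt(std$gamma_dot, 0.45)

  # size has no effect on the kinematic angles, only on retinal size
  pair <- bank[bank$ttc == 2 & bank$gravity == 9.807 &
                 bank$size %in% c(0.0703, 0.0777), ]
  expect_equal(pair$gamma[1], pair$gamma[2])
  expect_equal(pair$gamma_dot[1], pair$gamma_dot[2])
  expect_false(pair$theta[1] == pair$theta[2])
})

test_that("an uninformative margin collapses identification to chance", {
  ex <- run_prior_experiment(n_trials_per_ttc = 60, priors = NULL,
                             margin = Inf, bank = bank, pops = pops,
                             seed = 61)
  expect_equal(ex$chance, 1 / 9)
  expect_lt(abs(ex$accuracy - 1 / 9), binom_3se(1 / 9, 540))
  ex_p <- run_prior_experiment(n_trials_per_ttc = 60,
                               priors = prior_spec(), margin = Inf,
                               bank = bank, pops = pops, seed = 62)
  expect_lt(abs(ex_p$accuracy - 1 / 9), binom_3se(1 / 9, 540))
})

test_that("correct priors beat substantially wrong gravity priors", {
  correct <- run_prior_experiment(n_trials_per_ttc = 60,
                                  priors = prior_spec(), bank = bank,
                                  pops = pops, seed = 71)
  for (g in c(8.826, 10.787)) { # +-10% gravity priors
    wrong <- run_prior_experiment(n_trials_per_ttc = 60,
                                  priors = prior_spec(gravity = g),
                                  bank = bank, pops = pops, seed = 71)
    expect_gt(correct$accuracy, wrong$accuracy)
  }
})

test_that("the 'contains' scoring rule upper-bounds the draw rule", {
  draw <- run_prior_experiment(n_trials_per_ttc = 60,
                               priors = prior_spec(), bank = bank,
                               pops = pops, scoring = "draw", seed = 81)
  contains <- run_prior_experiment(n_trials_per_ttc = 60,
                                   priors = prior_spec(), bank = bank,
                                   pops = pops, scoring = "contains",
                                   seed = 81)
  expect_gte(contains$accuracy, draw$accuracy)
})

test_that("tidy and glance summarize an experiment", {
  ex <- run_prior_experiment(n_trials_per_ttc = 20, priors = prior_spec(),
                             bank = bank, pops = pops, seed = 91)
  td <- tidy(ex)
  expect_equal(nrow(td), 9)
  expect_named(td, c("ttc", "n_trials", "accuracy"))
  gl <- glance(ex)
  expect_equal(gl$decoder, "with_priors")
  expect_equal(gl$chance, 1 / 9)
  expect_equal(gl$accuracy,
               sum(td$accuracy * td$n_trials) / sum(td$n_trials))
})
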