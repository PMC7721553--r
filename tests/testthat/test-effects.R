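test_that("display rounding matches the published convention", {
  expect_equal(display_round(5980, 100), 6000)
  expect_equal(display_round(1080, 100), 1100)
  expect_equal(display_round(-237.6, 100), -200)
  # ties away from zero
  expect_equal(display_round(150, 100), 200)
  expect_equal(display_round(-150, 100), -200)
  expect_equal(display_round(50, 100), 100)
  expect_equal(display_round(0, 100), 0)
})

test_that("display rounding agrees with a brute-force nearest-multiple search", {
  oracle <- function(x, res) {
    ks <- seq(floor(x / res) - 2, ceiling(x / res) + 2)
    cand <- ks * res
    d <- abs(cand - x)
    best <- cand[d == min(d)]
    if (length(best) > 1) best <- best[which.max(abs(best))]  # tie away from 0
    best
  }
  set.seed(99)
  xs <- c(stats::runif(200, -5000, 5000), seq(-250, 250, by = 50))
  for (res in c(100, 0.1, 7)) {
    got <- display_round(xs, res)
    want <- vapply(xs, oracle, numeric(1), res = res)
    expect_equal(got, want, tolerance = 1e-12, label = paste("resolution", res))
  }
  # idempotence
  expect_equal(display_round(display_round(xs, 100), 100),
               display_round(xs, 100))
})

test_that("central deltas reproduce the published Table 2/3 arithmetic", {
  d <- intervention_deltas(netherlands_2016(), "central")
  pick <- function(iv, oc) d$delta[d$intervention == iv & d$outcome == oc]
  expect_equal(pick("smarter", "spontaneous"), 5980)      # 0.130 * 46000
  expect_equal(display_round(pick("smarter", "spontaneous"), 100), 6000)
  expect_equal(pick("lifestyle", "gestational_diabetes"), 237.6)  # 0.044 * 5400
  expect_equal(display_round(pick("lifestyle", "gestational_diabetes"), 100), 200)
  expect_equal(pick("lifestyle", "IUI"), 1080)
  expect_equal(pick("mindfulness", "ICSI"), 123.3)        # 0.009 * 13700
  # the combined program's obese-subset complications use the 5400 denominator
  expect_equal(d$denominator_n[d$intervention == "combined" &
                                 d$outcome == "gestational_diabetes"], 5400)
  expect_equal(d$denominator_n[d$intervention == "combined" &
                                 d$outcome == "IUGR"], 46000)
})

test_that("outcomes without evidence are structurally absent, not zero rows", {
  d <- intervention_deltas(netherlands_2016(), "central")
  expect_identical(nrow(d[d$intervention == "smoking" &
                            d$outcome == "spontaneous", ]), 0L)
  expect_identical(nrow(d[d$intervention == "mindfulness" &
                            d$outcome == "IUI", ]), 0L)
})

test_that("a zero-rate intervention yields exactly zero deltas", {
  cfg <- tiny_config()
  cfg$effects$least <- 0
  cfg$effects$central <- 0
  cfg$effects$most <- 0
  d <- intervention_deltas(cfg, "central")
  expect_true(all(d$delta == 0))
})

test_that("deltas are linear in the rate and in the denominator", {
  cfg <- tiny_config()
  d1 <- intervention_deltas(cfg, "central")$delta
  for (k in c(0.25, 0.5, 2)) {
    scaled_rate <- cfg
    scaled_rate$effects$central <- cfg$effects$central * k
    scaled_rate$effects$most <- pmax(scaled_rate$effects$central,
                                     cfg$effects$most)
    scaled_rate$effects$least <- pmin(scaled_rate$effects$central,
                                      cfg$effects$least)
    expect_equal(intervention_deltas(scaled_rate, "central")$delta, k * d1)
  }
  scaled_pop <- cfg
  scaled_pop$population$n_couples <- cfg$population$n_couples * 3
  expect_equal(intervention_deltas(scaled_pop, "central")$delta, 3 * d1)
})

test_that("scenario deltas are monotone when rate triples are ordered", {
  for (seed in 1:20) {
    cfg <- generate_config(seed, n_interventions = 3)
    dl <- intervention_deltas(cfg, "least")$delta
    dc <- intervention_deltas(cfg, "central")$delta
    dm <- intervention_deltas(cfg, "most")$delta
    expect_true(all(dl <= dc + 1e-12) && all(dc <= dm + 1e-12),
                label = paste("seed", seed))
  }
})

test_that("avoided cycles cannot exceed baseline cycles", {
  cfg <- tiny_config()
  # baseline IVF cycles = 0.3*1000*2 = 600; a 70% whole-cohort reduction
  # would avoid 700 cycles
  cfg$effects$central <- 0.7
  cfg$effects$most <- 0.7
  cfg$effects$least <- 0.7
  expect_error(intervention_deltas(cfg, "central"),
               class = "preconbia_validation_error")
})

test_that("unknown interventions are a usage error", {
  expect_error(intervention_deltas(netherlands_2016(),
                                   interventions = "nope"),
               class = "preconbia_usage_error")
})

test_that("composing two programs over-counts unless overlap is corrected", {
  cfg <- netherlands_2016()
  naive <- compose_interventions(cfg, "smarter", "lifestyle", overlap = 0)
  ivf_naive <- naive$delta[naive$outcome == "IVF"]
  # naive addition (2162 + 610.2) over-counts the published combined
  # program's own rate (0.055 * 46000 = 2530)
  d <- intervention_deltas(cfg, "central")
  ivf_combined <- d$delta[d$intervention == "combined" & d$outcome == "IVF"]
  expect_equal(ivf_naive, 2162 + 610.2)
  expect_gt(ivf_naive, ivf_combined)
  full_overlap <- compose_interventions(cfg, "smarter", "lifestyle", overlap = 1)
  expect_equal(full_overlap$delta[full_overlap$outcome == "IVF"], 2162)
})
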