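test_that("scenario propagation reproduces the published bounds", {
  scn <- run_scenarios(netherlands_2016())
  costs <- scn$costs
  pick <- function(iv, s, col) costs[[col]][costs$intervention == iv &
                                              costs$scenario == s]
  expect_equal(pick("smarter", "most", "total"), 101200000)   # 2200 * 46000
  expect_equal(pick("smoking", "least", "total"), -64000)     # -20 * 3200
  expect_equal(pick("mindfulness", "central", "total"), 4932000)
  expect_identical(nrow(costs), 15L)  # 5 interventions x 3 scenarios
})

test_that("degenerate benefit triples give three identical scenario columns", {
  cfg <- tiny_config()
  cfg$benefits_printed$least <- 250
  cfg$benefits_printed$most <- 250
  scn <- run_scenarios(cfg)
  wide <- tidyr::pivot_wider(scn$costs[c("intervention", "scenario", "total")],
                             names_from = "scenario", values_from = "total")
  expect_equal(wide$least, wide$central)
  expect_equal(wide$most, wide$central)
})

test_that("scenario totals are ordered least <= central <= most", {
  for (seed in 1:20) {
    cfg <- generate_config(seed, n_interventions = 4)
    for (mode in c("printed", "computed")) {
      w <- tidyr::pivot_wider(
        run_scenarios(cfg, mode)$costs[c("intervention", "scenario", "total")],
        names_from = "scenario", values_from = "total")
      expect_true(all(w$least <= w$central + 1e-9) &&
                    all(w$central <= w$most + 1e-9),
                  label = paste("seed", seed, mode))
    }
  }
})

test_that("uniform PSA means converge to the interval midpoint", {
  cfg <- netherlands_2016()
  psa <- run_psa(cfg, n_draws = 20000, seed = 3, distribution = "uniform")
  s <- psa$summary
  # smoking: uniform on [-20, 170] per couple -> mean 75, sd 190/sqrt(12)
  m <- s$mean[s$intervention == "smoking"] / 3200
  se <- (190 / sqrt(12)) / sqrt(20000)
  expect_lt(abs(m - 75), 3 * se)
  expect_true(all(s$q2.5 >= tapply(psa$draws$total, psa$draws$intervention, min)[s$intervention]))
  expect_true(all(s$q97.5 <= tapply(psa$draws$total, psa$draws$intervention, max)[s$intervention]))
})

test_that("triangular PSA means converge to (a + c + b) / 3", {
  psa <- run_psa(netherlands_2016(), n_draws = 20000, seed = 5,
                 distribution = "triangular")
  m <- psa$summary$mean[psa$summary$intervention == "smarter"] / 46000
  mu <- (100 + 513 + 2200) / 3
  sd_tri <- sqrt((100^2 + 513^2 + 2200^2 - 100 * 513 - 100 * 2200 -
                    513 * 2200) / 18)
  expect_lt(abs(m - mu), 3 * sd_tri / sqrt(20000))
  # all draws stay inside the scenario interval
  d <- psa$draws[psa$draws$intervention == "smarter", ]
  expect_true(all(d$per_couple >= 100 & d$per_couple <= 2200))
})

test_that("PSA is reproducible and leaves the caller's RNG untouched", {
  cfg <- netherlands_2016()
  set.seed(123)
  before <- .Random.seed
  p1 <- run_psa(cfg, n_draws = 500, seed = 7)
  expect_identical(.Random.seed, before)
  p2 <- run_psa(cfg, n_draws = 500, seed = 7)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$summary, p2$summary)
  p3 <- run_psa(cfg, n_draws = 500, seed = 8)
  expect_false(identical(p1$draws$total, p3$draws$total))
})

test_that("adding an intervention does not perturb the other streams", {
  cfg <- netherlands_2016()
  keep <- c("smarter", "lifestyle")
  sub <- cfg
  sub$interventions <- cfg$interventions[cfg$interventions$intervention %in% keep, ]
  sub$effects <- cfg$effects[cfg$effects$intervention %in% keep, ]
  sub$costs <- cfg$costs[cfg$costs$intervention %in% keep, ]
  sub$benefits_printed <- cfg$benefits_printed[
    cfg$benefits_printed$intervention %in% keep, ]
  sub$art_printed <- cfg$art_printed[cfg$art_printed$intervention %in% keep, ]
  sub$printed <- NULL
  sub$anomalies <- NULL
  full <- run_psa(cfg, n_draws = 1000, seed = 11)
  part <- run_psa(sub, n_draws = 1000, seed = 11)
  for (id in keep) {
    expect_identical(part$draws$total[part$draws$intervention == id],
                     full$draws$total[full$draws$intervention == id],
                     label = id)
  }
})

test_that("degenerate triples collapse the PSA to a point mass", {
  cfg <- tiny_config()
  cfg$benefits_printed$least <- 250
  cfg$benefits_printed$most <- 250
  for (dist in c("uniform", "triangular")) {
    psa <- run_psa(cfg, n_draws = 200, seed = 1, distribution = dist)
    expect_equal(unique(psa$draws$per_couple), 250)
    expect_equal(psa$summary$sd, 0)
  }
})

test_that("unordered benefit triples are rejected", {
  cfg <- tiny_config()
  cfg$benefits_printed$least <- 999
  expect_error(run_psa(cfg, n_draws = 10, seed = 1),
               class = "preconbia_domain_error")
})
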