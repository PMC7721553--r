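test_that("per-couple benefit follows the avoided-cost-minus-program identity", {
  deltas <- tibble::tibble(outcome_class = "cycles", outcome = "IVF", delta = 100)
  costs <- tibble::tibble(component = c("cycle", "program"),
                          item = c("IVF", NA), unit_cost = c(3000, 50))
  expect_equal(per_couple_benefit(deltas, costs, 1000), 250)  # 300 - 50

  # zero deltas, zero program cost
  zero <- tibble::tibble(outcome_class = "cycles", outcome = "IVF", delta = 0)
  costs0 <- tibble::tibble(component = "cycle", item = "IVF", unit_cost = 3000)
  expect_equal(per_couple_benefit(zero, costs0, 10), 0)

  # a program costing more than it saves gives a legal negative benefit
  costly <- tibble::tibble(component = c("cycle", "program"),
                           item = c("IVF", NA), unit_cost = c(3000, 500))
  expect_equal(per_couple_benefit(deltas, costly, 1000), -200)

  expect_error(per_couple_benefit(deltas, costs, 0),
               class = "preconbia_domain_error")
})

test_that("total saving is the exact per-couple times group-size product", {
  expect_equal(total_saving(513, 46000), 23598000)
  expect_equal(total_saving(41, 3200), 131200)
  expect_equal(total_saving(0, 123456), 0)
  expect_equal(total_saving(-20, 3200), -64000)
})

test_that("currency conversion is a rounded exact product", {
  expect_equal(eur_to_usd(1163, 1.1867), 1380.13)
  expect_equal(eur_to_usd(100, 1.19), 119)
  expect_equal(eur_to_usd(0, 1.5), 0)
  # default rate reproduces all five published USD amounts to within 6 cents
  eur <- c(41, 360, 513, 586, 1163)
  usd <- c(48.66, 427.23, 608.80, 695.43, 1380.18)
  expect_true(all(abs(eur_to_usd(eur) - usd) < 0.06))
})

test_that("total/group-size recovers the per-couple benefit to machine precision", {
  for (seed in 1:10) {
    cfg <- generate_config(seed, n_interventions = 3)
    res <- cost_results(cfg, "central", "computed")
    expect_equal(res$total / res$group_size, res$per_couple,
                 tolerance = 1e-12)
  }
})

test_that("per-couple benefit is monotone in costs and deltas", {
  cfg <- netherlands_2016()
  base <- cost_results(cfg, "central", "computed")
  # non-decreasing in every unit cost
  for (path in c("costs.smarter.cycle.IVF", "costs.smarter.cycle.IUI",
                 "costs.smarter.complication.IUGR",
                 "costs.lifestyle.complication.preterm")) {
    up <- cost_results(perturb_config(cfg, path, 100), "central", "computed")
    expect_true(all(up$per_couple >= base$per_couple - 1e-9), label = path)
  }
  # non-decreasing in every delta (via the effect rate)
  up <- cost_results(perturb_config(cfg, "effects.smarter.IVF.central", 0.01) |>
                       perturb_config("effects.smarter.IVF.most", 0.01),
                     "central", "computed")
  expect_true(all(up$per_couple >= base$per_couple - 1e-9))
  expect_gt(up$per_couple[up$intervention == "smarter"],
            base$per_couple[base$intervention == "smarter"])
  # strictly decreasing in the program cost
  dearer <- cost_results(perturb_config(cfg, "costs.smarter.program", 10),
                         "central", "computed")
  expect_equal(dearer$per_couple[dearer$intervention == "smarter"],
               base$per_couple[base$intervention == "smarter"] - 10)
})

test_that("the computed mode is calibrated to the published central benefits", {
  cfg <- netherlands_2016()
  computed <- cost_results(cfg, "central", "computed")
  expect_equal(computed$per_couple, cfg$benefits_printed$central,
               tolerance = 1e-12)
  expect_identical(unique(computed$source), "computed-from-deltas")
})

test_that("printed mode multiplies the published per-couple triples through", {
  cfg <- netherlands_2016()
  res <- cost_results(cfg, "most", "printed")
  expect_equal(res$total[res$intervention == "smarter"], 2200 * 46000)
  expect_equal(res$art_only[res$intervention == "smarter"], 26.2e6)
  expect_identical(unique(res$source), "printed-benefit")
})
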