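test_that("rendered tables use the published display conventions", {
  scn <- run_scenarios(netherlands_2016())
  md <- render_tables(scn, "markdown")
  expect_named(md, c("table2", "table3", "table4"))
  expect_match(md[["table2"]], "\\+6,000 \\(\\+13\\.0\\)")   # spontaneous gain
  expect_match(md[["table2"]], "-10,800 \\(-23\\.4\\)")      # avoided IUI cycles
  expect_match(md[["table2"]], "-100 \\(-0\\.9\\)")          # mindfulness ICSI
  expect_match(md[["table3"]], "-200 \\(-4\\.4\\)")          # gestational diabetes
  expect_match(md[["table4"]], "€24 M", fixed = TRUE)
  expect_match(md[["table4"]], "€4.9 M (€-2.6 M, €6.9 M)", fixed = TRUE)
  expect_match(md[["table4"]], "€0.131 M", fixed = TRUE)     # unrounded 41*3200
})

test_that("no-evidence outcomes render as em-dashes", {
  scn <- run_scenarios(netherlands_2016())
  md <- render_tables(scn, "markdown")
  smoking_row <- grep("Smoking", strsplit(md[["table2"]], "\n")[[1]], value = TRUE)
  expect_match(smoking_row, "— \\| -300")  # no spontaneous-pregnancy evidence
  mindful_t3 <- grep("Mindfulness", strsplit(md[["table3"]], "\n")[[1]], value = TRUE)
  expect_identical(length(unlist(gregexpr("—", mindful_t3))), 4L)
})

test_that("an intervention with no complication evidence renders a dash-only row", {
  cfg <- tiny_config()   # only an IVF cycles effect
  scn <- run_scenarios(cfg)
  t3 <- render_tables(scn, "markdown")[["table3"]]
  row <- grep("Demo", strsplit(t3, "\n")[[1]], value = TRUE)
  expect_false(grepl("[0-9]", row))
  expect_match(row, "—")
})

test_that("csv and json renderings are parseable and deterministic", {
  scn <- run_scenarios(netherlands_2016())
  csv <- render_tables(scn, "csv")
  parsed <- utils::read.csv(text = csv[["table4"]])
  expect_identical(nrow(parsed), 5L)
  expect_true("total_saving" %in% names(parsed))

  js <- render_tables(scn, "json")
  parsed_js <- jsonlite::fromJSON(js[["tables"]])
  expect_named(parsed_js, c("table2", "table3", "table4"))
  expect_identical(nrow(parsed_js$table2), 5L)

  expect_identical(render_tables(scn, "markdown"),
                   render_tables(run_scenarios(netherlands_2016()), "markdown"))
})

test_that("tidiers and plots expose the result objects", {
  scn <- run_scenarios(netherlands_2016())
  td <- tidy(scn)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 15L)
  g <- glance(scn)
  expect_identical(g$best_intervention, "combined")
  expect_s3_class(autoplot(scn), "ggplot")

  psa <- run_psa(netherlands_2016(), n_draws = 200, seed = 1)
  expect_identical(nrow(tidy(psa)), 5L)
  expect_s3_class(autoplot(psa), "ggplot")

  audit <- audit_printed(netherlands_2016())
  expect_s3_class(tidy(audit), "tbl_df")
  expect_identical(sum(glance(audit)[, c("n_match", "n_mismatch", "n_flagged",
                                         "n_not_recomputable")] |> unlist()),
                   nrow(audit))
})
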