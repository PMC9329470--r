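test_that("run configuration round-trips through YAML", {
  cfg <- run_config(n = 99, seed = 7, net = silnet_config(max_epochs = 3L),
                    bootstrap_B = 50L)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, tmp)
  cfg2 <- read_run_config(tmp)
  expect_equal(cfg2$n, 99L)
  expect_equal(cfg2$seed, 7L)
  expect_equal(cfg2$net$max_epochs, 3L)
  expect_equal(cfg2$bootstrap_B, 50L)
  expect_equal(cfg2$population$spacing, cfg$population$spacing)
})

test_that("the demo pipeline runs end to end and is reproducible", {
  cfg <- run_config(n = 120, seed = 3, net = silnet_config(max_epochs = 4L),
                    bootstrap_B = 100L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res <- run_demo(d1, cfg)
  expect_true(file.exists(file.path(d1, "report.md")))
  expect_true(file.exists(file.path(d1, "cohort.csv")))
  expect_true(file.exists(file.path(d1, "predictions.csv")))
  expect_true(file.exists(file.path(d1, "metrics.json")))
  expect_equal(nrow(res$predictions), 120)
  report <- readLines(file.path(d1, "report.md"))
  expect_true(any(grepl("delta R2 \\(Silhouette - BMI\\)", report)))
  expect_true(any(grepl("config hash: [0-9a-f]+", report)))
  run_demo(d2, cfg)
  expect_identical(report, readLines(file.path(d2, "report.md")))
})

test_that("the command-line wrapper is present and parseable", {
  cli <- system.file("cli", "silfat.R", package = "silfat")
  expect_true(nzchar(cli) && file.exists(cli))
  expect_silent(parse(cli))
})
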