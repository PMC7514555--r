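test_that("bundled fixtures load with their documented shapes", {
  g <- load_dataset("guinea_complete")
  expect_length(g$times, 72)
  expect_equal(min(g$times), 12)
  expect_equal(max(g$times), 376)
  expect_equal(sum(g$times), 7187)
  expect_null(g$censoring)

  ff <- load_dataset("guinea_ff36")
  expect_length(ff$times, 36)
  expect_true(all(ff$times %in% g$times))

  r1 <- load_dataset("guinea_R1")
  expect_length(r1$times, 18)
  expect_equal(r1$times[1:3], c(12, 24, 32))
  expect_equal(r1$times[18], 143)
  expect_equal(r1$censoring$k, 2L)
  expect_equal(r1$censoring$n, 36L)
  expect_identical(r1$censoring$R, c(18L, rep(0L, 17)))
  expect_identical(load_dataset("guinea_R2")$censoring$R, rep(1L, 18))
  expect_identical(load_dataset("guinea_R3")$censoring$R,
                   c(rep(0L, 17), 18L))
  # all censored subsamples are drawn from the first-failure minima
  for (nm in c("guinea_R1", "guinea_R2", "guinea_R3")) {
    expect_true(all(load_dataset(nm)$times %in% ff$times))
  }
})

test_that("dataset loading reports malformed files", {
  empty <- tempfile()
  writeLines(character(0), empty)
  expect_error(load_dataset(empty), "no data")
  bad <- tempfile()
  writeLines(c("12", "oops", "15"), bad)
  expect_error(load_dataset(bad), "line 2")
  neg <- tempfile()
  writeLines(c("12", "-3"), neg)
  expect_error(load_dataset(neg), "line 2")
  expect_error(load_dataset("/nonexistent/file.txt"), "not found")
  # single-column csv with header is tolerated
  csv <- tempfile(fileext = ".csv")
  writeLines(c("time", "1.5", "2.5"), csv)
  expect_equal(load_dataset(csv)$times, c(1.5, 2.5))
  unlink(c(empty, bad, neg, csv))
})

test_that("first-failure grouping returns group minima", {
  g <- load_dataset("guinea_complete")
  expect_equal(first_failure_grouping(g, k = 1)$times, sort(g$times))
  expect_equal(first_failure_grouping(g, k = 72)$times, 12)
  ff <- first_failure_grouping(g, k = 2, seed = 3)
  expect_length(ff$times, 36)
  expect_true(all(ff$times %in% g$times))
  expect_true(12 %in% ff$times)   # the global minimum is always a minimum
  expect_error(first_failure_grouping(g, k = 5), "divide")
})

test_that("the fit subcommand reports estimates and both interval families", {
  out <- utils::capture.output(
    res <- pffcens_main(c("fit", "--data", "guinea_R1", "--output", "json")))
  js <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(js$schema_version, "1")
  expect_equal(js$estimates$alpha, 1.174, tolerance = 1e-3)
  expect_named(js$intervals, c("normal", "log_normal"))
  # explicit scheme flags override nothing here but must parse
  out2 <- utils::capture.output(
    pffcens_main(c("fit", "--data", "guinea_R1", "--k", "2", "--n", "36",
                   "--scheme", "(18,0*17)", "--ci", "log")))
  expect_true(any(grepl("log_normal", out2)))
})

test_that("the gof subcommand reproduces the complete-data fit report", {
  out <- utils::capture.output(
    pffcens_main(c("gof", "--data", "guinea_complete", "--output", "json")))
  js <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(js$ks, 0.152, tolerance = 1e-3)
  expect_equal(js$neg_loglik, 395.649, tolerance = 1e-5)
})

test_that("the bayes subcommand runs both engines", {
  out <- utils::capture.output(
    pffcens_main(c("bayes", "--data", "guinea_R1", "--method", "lindley",
                   "--a", "0", "--b", "0", "--output", "json")))
  js <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(js$method, "lindley")
  expect_true(js$estimates$entropy > 5 && js$estimates$entropy < 7)
  out <- utils::capture.output(
    pffcens_main(c("bayes", "--data", "guinea_R1", "--method", "is",
                   "--M", "1000", "--seed", "7", "--a", "0", "--b", "0",
                   "--output", "json")))
  js <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(js$M, 1000)
  expect_length(js$hpd$target, 3)
  expect_error(pffcens_main(c("bayes", "--data", "guinea_R1",
                              "--method", "is")),
               "--seed")
})

test_that("the simulate subcommand writes a readable sample", {
  path <- tempfile(fileext = ".csv")
  utils::capture.output(
    pffcens_main(c("simulate", "--alpha", "2", "--lambda", "1",
                   "--k", "2", "--n", "20", "--scheme", "(8,0*11)",
                   "--seed", "12", "--out", path)))
  s <- read_pff(path)
  expect_length(s$times, 12)
  expect_identical(s$times,
                   simulate_pff(censoring_scheme(2, 20, c(8L, rep(0L, 11))),
                                iwd_params(2, 1), seed = 12)$times)
  expect_error(pffcens_main(c("simulate", "--alpha", "2", "--n", "20",
                              "--scheme", "(5,0*11)")),
               "--seed")
  unlink(path)
})

test_that("config files supply defaults that flags override", {
  cfg <- tempfile()
  writeLines(c("data=guinea_R1", "output=json"), cfg)
  out <- utils::capture.output(pffcens_main(c("fit", "--config", cfg)))
  js <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(js$command, "fit")
  unlink(cfg)
})
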