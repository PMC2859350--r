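test_that("a minimal well-formed CSV is read and validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,device,replicate,value",
               "1,A,1,120", "1,A,2,122", "1,B,1,118", "1,B,2,121"), f)
  d <- read_agreement_csv(f)
  expect_s3_class(d, "agreement_data")
  expect_equal(d$n, 1L)
  expect_equal(d$m, 2L)
  expect_true(d$balanced)
  expect_equal(d$devices, c("A", "B"))
})

test_that("column mapping and device order are honoured", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,instrument,rep,sbp,age",
               "1,manual,1,120,54", "1,manual,2,122,54",
               "1,omron,1,118,54", "1,omron,2,121,54",
               "2,manual,1,141,61", "2,manual,2,139,61",
               "2,omron,1,135,61", "2,omron,2,137,61"), f)
  d <- read_agreement_csv(f, column_map = c(subject = "id",
                                            device = "instrument",
                                            replicate = "rep",
                                            value = "sbp"),
                          device_order = c("omron", "manual"))
  expect_equal(d$devices, c("omron", "manual"))
  expect_equal(d$covariates, "age")
  expect_error(read_agreement_csv(f, column_map = c(value = "missing")),
               "absent")
})

test_that("written data round-trips field for field", {
  sc <- simulation_scenario(n = 12, m = 3, beta_diff = 2.174)
  d <- generate_dataset(sc, seed = 301)
  f <- withr::local_tempfile(fileext = ".csv")
  write_agreement_csv(d, f)
  d2 <- read_agreement_csv(f, device_order = d$devices)
  expect_equal(d2$data$value, d$data$value)
  expect_equal(d2$data$subject, d$data$subject)
  expect_equal(d2$n, d$n)
  expect_equal(d2$m, d$m)
  expect_equal(d2$balanced, d$balanced)
})

test_that("validation rejects malformed inputs", {
  base <- data.frame(subject = c(1, 1, 1), device = c("A", "B", "C"),
                     replicate = 1, value = c(1, 2, 3))
  expect_error(agreement_data(base), "exactly 2 device")
  one_dev <- data.frame(subject = 1, device = "A", replicate = 1, value = 1)
  expect_error(agreement_data(one_dev), "exactly 2 device")
  bad_val <- data.frame(subject = c(1, 1), device = c("A", "B"),
                        replicate = 1, value = c(1, NA))
  expect_error(agreement_data(bad_val), "row")
  expect_error(agreement_data(data.frame(subject = 1, value = 2)),
               "missing required column")
})

test_that("unbalanced data are accepted but flagged", {
  df <- data.frame(subject = c("a", "a", "a", "b", "b"),
                   device = c("A", "A", "B", "A", "B"),
                   replicate = c(1, 2, 1, 1, 1),
                   value = rnorm(5, 100))
  d <- agreement_data(df)
  expect_false(d$balanced)
  expect_true(is.na(d$m))
})

test_that("wide-format data melt into the long layout", {
  wide <- data.frame(id = 1:4,
                     a1 = c(10, 11, 12, 13), a2 = c(10.5, 11.2, 12.1, 13.4),
                     b1 = c(9.8, 11.1, 12.3, 12.9), b2 = c(10.1, 11, 12, 13))
  d <- wide_to_long(wide, "id", list(A = c("a1", "a2"), B = c("b1", "b2")))
  expect_equal(d$n, 4L)
  expect_equal(d$m, 2L)
  expect_true(d$balanced)
  expect_equal(d$data$value[d$data$device == "A" & d$data$replicate == 1],
               wide$a1)
})

test_that("JSON reports carry the full result schema and round-trip numerically", {
  pars <- case_example_params()
  res <- tdi_upper_bound(pars, 0.90)
  f <- withr::local_tempfile(fileext = ".json")
  write_report(list(total = res), f, meta = list(seed = 1))
  parsed <- jsonlite::read_json(f)
  r <- parsed$results$total
  expect_true(all(c("p", "p1", "kappa_hat", "upper_bound", "confidence",
                    "kind", "df_convention") %in% names(r)))
  expect_equal(r$kappa_hat, res$kappa_hat, tolerance = 1e-12)
  expect_equal(r$upper_bound, res$upper_bound, tolerance = 1e-12)
  expect_equal(r$df_convention, "no_interaction")
})

test_that("reports reject empty collections and write CSV", {
  expect_error(write_report(list(), withr::local_tempfile()), "non-empty")
  pars <- case_example_params()
  res <- tdi_upper_bound(pars, 0.90)
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(list(total = res, table = data.frame(a = 1:2, b = c(3, 4))),
               f, format = "csv")
  rows <- read.csv(f)
  expect_true("kappa_hat" %in% rows$field)
  expect_equal(as.numeric(rows$value[rows$field == "kappa_hat"]),
               res$kappa_hat, tolerance = 1e-12)
})
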