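make_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, na = "NA")
  path
}

test_that("read_responses parses a simple table and infers the mask", {
  path <- make_csv(tibble::tibble(group = c("A", "A", "B"),
                                  i1 = c(0, 1, 2), i2 = c(2, 1, 0)))
  ds <- read_responses(path)
  expect_s3_class(ds, "response_dataset")
  expect_equal(nrow(ds$responses), 3)
  expect_equal(ncol(ds$responses), 2)
  expect_true(all(ds$admin))
})

test_that("all-missing group/item cells become design missingness", {
  df <- tibble::tibble(group = c(rep("Raine", 3), rep("TEDS", 3)),
                       cbcl1 = c(0, 1, 2, NA, NA, NA),
                       cbcl2 = c(1, 1, 0, NA, NA, NA),
                       sdq1 = c(0, 2, 1, 1, 0, 2))
  ds <- response_dataset(df, items = c("cbcl1", "cbcl2", "sdq1"))
  expect_false(ds$admin["TEDS", "cbcl1"])
  expect_false(ds$admin["TEDS", "cbcl2"])
  expect_true(ds$admin["TEDS", "sdq1"])
  expect_true(all(ds$admin["Raine", ]))
})

test_that("out-of-range codes are rejected with row/column context", {
  df <- tibble::tibble(group = "A", i1 = 3)
  expect_error(response_dataset(df, items = "i1", C = 2), "i1.*allowed 0..2")
  expect_error(response_dataset(tibble::tibble(group = "A", i1 = 1.5),
                                items = "i1"), "non-integer")
  # explicit mask contradicting observed data is also an error
  df2 <- tibble::tibble(group = c("A", "B"), i1 = c(1, 2), i2 = c(0, 1))
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2,
                 dimnames = list(c("A", "B"), c("i1", "i2")))
  expect_error(response_dataset(df2, items = c("i1", "i2"),
                                admin_mask = mask), "contradict")
})

test_that("complete-case filtering counts and respects the design", {
  df <- tibble::tibble(group = rep("A", 5),
                       i1 = c(0, 1, NA, 2, 1), i2 = c(1, 1, 0, 2, 0))
  mask <- matrix(TRUE, 1, 2, dimnames = list("A", c("i1", "i2")))
  ds <- response_dataset(df, items = c("i1", "i2"), admin_mask = mask)
  out <- complete_case_filter(ds)
  expect_equal(nrow(out$responses), 4)
  expect_equal(attr(out, "n_removed"), 1)

  # no missing data: identity
  full <- complete_case_filter(out)
  expect_equal(attr(full, "n_removed"), 0)
  expect_equal(full$responses, out$responses)

  # missing-by-design does not disqualify: person 3 in group B lacks i1
  # only because B was never administered i1
  df3 <- tibble::tibble(group = c("A", "A", "B"),
                        i1 = c(0, 1, NA), i2 = c(1, NA, 2))
  ds3 <- response_dataset(df3, items = c("i1", "i2"))
  out3 <- complete_case_filter(ds3)
  expect_equal(attr(out3, "n_removed"), 1)
  expect_equal(as.character(out3$persons$group), c("A", "B"))

  # idempotence
  expect_equal(complete_case_filter(out3)$responses, out3$responses)
  expect_error(
    complete_case_filter(response_dataset(
      tibble::tibble(group = "A", i1 = NA_integer_, i2 = 1),
      items = c("i1", "i2"),
      admin_mask = matrix(TRUE, 1, 2,
                          dimnames = list("A", c("i1", "i2"))))),
    "no complete cases")
})

test_that("one-per-family selection is uniform, seeded, reproducible", {
  df <- tibble::tibble(group = rep("A", 6),
                       fam = rep(c("f1", "f2", "f3"), each = 2),
                       i1 = c(0, 1, 2, 0, 1, 2), i2 = c(1, 1, 0, 0, 2, 2))
  ds <- response_dataset(df, items = c("i1", "i2"), family = "fam")
  sel <- select_one_per_family(ds, seed = 4)
  expect_equal(nrow(sel$responses), 3)
  expect_equal(sort(unique(sel$persons$family)), c("f1", "f2", "f3"))

  # same seed twice: identical; different seeds can differ
  sel2 <- select_one_per_family(ds, seed = 4)
  expect_identical(sel$responses, sel2$responses)

  # all singletons: identity
  df$fam <- paste0("f", 1:6)
  dss <- response_dataset(df, items = c("i1", "i2"), family = "fam")
  expect_equal(nrow(select_one_per_family(dss, seed = 1)$responses), 6)

  # missing family IDs: error unless singleton policy set
  df$fam[1] <- NA
  dsn <- response_dataset(df, items = c("i1", "i2"), family = "fam")
  expect_error(select_one_per_family(dsn, seed = 1), "family IDs")
  expect_equal(nrow(select_one_per_family(dsn, seed = 1,
                                          singletons = "keep")$responses), 6)
})

test_that("filter then select commutes with select-within-complete-cases", {
  sim <- simulate_cohorts(
    local({
      cfg <- fixture_truth(n = 60, k = 4)
      cfg$twin_frac <- 0.5
      cfg
    }), seed = 9)
  ds <- sim$data
  # plant some person-level missingness on administered items
  set.seed(21)
  holes <- cbind(sample.int(nrow(ds$responses), 10), sample.int(4, 10, TRUE))
  ds$responses[holes] <- NA_integer_
  a <- select_one_per_family(complete_case_filter(ds), seed = 5)
  b_pool <- complete_case_filter(ds)
  b <- complete_case_filter(select_one_per_family(b_pool, seed = 5))
  expect_identical(a$responses, b$responses)
})

test_that("write/read round-trips the canonical CSV dialect bit-exactly", {
  sim <- simulate_cohorts(fixture_truth(n = 25, k = 5), seed = 3)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(sim$data, p1)
  ds2 <- read_responses(p1, group = "group", family = "family")
  write_responses(ds2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(ds2$responses, sim$data$responses)
  expect_identical(ds2$admin, sim$data$admin)
})

test_that("observed sum-score statistics match hand and brute-force values", {
  df <- tibble::tibble(group = rep("A", 3), i1 = c(0, 1, 2), i2 = c(2, 2, 2))
  ds <- response_dataset(df, items = c("i1", "i2"))
  s <- observed_sum_stats(ds, "A")
  expect_equal(s$mean, 3)
  expect_equal(s$sd, 1)
  expect_equal(s$ts, 4)

  # all-identical scores: SD 0
  dfc <- tibble::tibble(group = rep("A", 3), i1 = c(1, 1, 1))
  expect_equal(observed_sum_stats(response_dataset(dfc, "i1"), "A")$sd, 0)

  # 10-person fixture vs independent recomputation
  sim <- simulate_cohorts(fixture_truth(n = 10, k = 5), seed = 8)
  s10 <- observed_sum_stats(sim$data, "G1", items = c("it01", "it02", "it03"))
  rows <- sim$data$persons$group == "G1"
  raw <- sim$data$responses[rows, c("it01", "it02", "it03")]
  sums <- apply(raw, 1, sum)
  expect_equal(s10$mean, sum(sums) / length(sums))
  expect_equal(s10$sd, sqrt(sum((sums - mean(sums))^2) / (length(sums) - 1)))

  # SD needs n >= 2
  df1 <- tibble::tibble(group = "A", i1 = 1)
  expect_error(observed_sum_stats(response_dataset(df1, "i1"), "A"),
               "at least 2")
})
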