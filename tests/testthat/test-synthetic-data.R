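test_that("the default design reproduces the study group sizes", {
  d <- study_design(observables = "total_macrophages")
  ds <- generate_cohort(params_mild(), design = d, seed = 1)
  expect_equal(nrow(ds), 42L)  # 10 untreated + 17 phx + 15 sham
  counts <- table(ds$group)
  expect_equal(unname(counts[c("untreated", "phx", "sham")]),
               c(10L, 17L, 15L), ignore_attr = TRUE)
  phx <- subset(ds, group == "phx")
  expect_equal(unname(table(phx$day)), c(5L, 4L, 4L, 4L),
               ignore_attr = TRUE)
  sham <- subset(ds, group == "sham")
  expect_equal(unname(table(sham$day)), c(3L, 3L, 3L, 6L),
               ignore_attr = TRUE)
})

test_that("noiseless cohorts reproduce the mapped curves exactly", {
  p <- params_mild()
  m <- observable_mapping(total_macrophages = c(150, 2),
                          angiogenesis = c(50, 0.1))
  ds <- generate_cohort(p, m, noise = noise_model(0), seed = 1)
  sim <- simulate_phx(p, duration = 21)
  at <- sample_at_days(sim$curves, c(4, 8, 14, 21))

  phx_vol <- subset(ds, group == "phx" & observable == "volume")
  for (d in c(4, 8, 14, 21)) {
    expect_true(all(phx_vol$value[phx_vol$day == d] ==
                      100 * at$volume[at$day == d]))
  }
  phx_tm <- subset(ds, group == "phx" & observable == "total_macrophages")
  expect_equal(unique(phx_tm$value[phx_tm$day == 8]),
               150 * at$total_macrophages[at$day == 8] + 2)

  # sham and untreated animals carry mapped homeostatic values
  sham <- subset(ds, group == "sham")
  expect_true(all(sham$value[sham$observable == "volume"] == 100))
  expect_true(all(sham$value[sham$observable == "kupffer"] == 100 * 0.06))
  ut <- subset(ds, group == "untreated")
  expect_true(all(ut$value[ut$observable == "angiogenesis"] == 0.1))
})

test_that("cohort generation is seeded and restores the RNG state", {
  p <- params_mild()
  set.seed(1234)
  before <- .Random.seed
  d1 <- generate_cohort(p, noise = noise_model(0.15), seed = 7)
  expect_identical(.Random.seed, before)
  d2 <- generate_cohort(p, noise = noise_model(0.15), seed = 7)
  d3 <- generate_cohort(p, noise = noise_model(0.15), seed = 8)
  expect_identical(d1, d2)
  expect_true(any(d1$value != d3$value))
})

test_that("off-grid sampling days are refused", {
  d <- study_design(days = c(4, 8.31, 14, 21))
  expect_error(generate_cohort(params_mild(), design = d, seed = 1),
               "grid")
})

test_that("summaries use the n-1 denominator and mark n = 1 cells", {
  ds <- data.frame(group = "phx", day = 4,
                   animal = c("a", "b", "c"),
                   observable = c("volume", "volume", "kupffer"),
                   value = c(70, 80, 6))
  s <- summarize_dataset(ds)
  vol <- s[s$observable == "volume", ]
  expect_equal(vol$mean, 75)
  expect_equal(vol$sd, sqrt(50), tolerance = 1e-10)  # 7.0711
  ku <- s[s$observable == "kupffer", ]
  expect_equal(ku$mean, 6)
  expect_true(is.na(ku$sd))
  expect_equal(ku$n, 1L)
})

test_that("noiseless summaries equal the generating curve with zero SD", {
  p <- params_mild()
  ds <- generate_cohort(p, noise = noise_model(0), seed = 2)
  s <- summarize_dataset(ds)
  many <- s[s$n > 1L, ]
  expect_true(all(many$sd == 0))
  sim <- simulate_phx(p, duration = 21)
  at <- sample_at_days(sim$curves, 8)
  expect_equal(s$mean[s$group == "phx" & s$day == 8 &
                        s$observable == "volume"],
               100 * at$volume)
})

test_that("cell means converge to the generating curve at large n", {
  p <- params_mild()
  d <- study_design(phx_n = rep(10000, 4), sham_n = rep(10000, 4),
                    untreated_n = 10000, observables = "volume")
  ds <- generate_cohort(p, design = d, noise = noise_model(0.15),
                        seed = 12)
  s <- summarize_dataset(ds)
  sim <- simulate_phx(p, duration = 21)
  at <- sample_at_days(sim$curves, c(4, 8, 14, 21))
  for (day in c(4, 8, 14, 21)) {
    truth <- 100 * at$volume[at$day == day]
    cell <- s[s$group == "phx" & s$day == day, ]
    se <- 0.15 * truth / sqrt(cell$n)
    expect_lt(abs(cell$mean - truth), 3 * se)
    expect_lt(abs(cell$mean - truth) / truth, 0.01)
  }
})

test_that("dataset CSV round-trips and malformed rows are reported", {
  ds <- generate_cohort(params_mild(), noise = noise_model(0.1), seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, f)
  back <- read_dataset_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("group,day,observable,value",
               "phx,4,volume,75",
               "phx,8,vollume,80"), bad)
  expect_error(read_dataset_csv(bad), "row.*2")
})
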