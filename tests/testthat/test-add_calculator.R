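test_that("two full post-placement days at 27.5 C accrue exactly 55 ADD", {
  tl <- cadaver_timeline("2015-06-01", "2015-06-01")
  temps <- const_temps(27.5)
  expect_equal(accumulated_degree_days(tl, temps, "2015-06-03"), 55)
})

test_that("daily contributions follow the frozen/storage/half-day rules", {
  temps <- const_temps(27.5)
  # frozen day contributes zero
  tl <- cadaver_timeline("2015-06-01", "2015-06-05",
                         frozen_intervals = list(c("2015-06-02", "2015-06-03")))
  expect_equal(daily_contribution("2015-06-02", tl, temps, "2015-06-10"), 0)
  # interior post-placement day contributes its full daily mean
  expect_equal(daily_contribution("2015-06-07", tl, temps, "2015-06-10"), 27.5)
  # interior storage day contributes the storage temperature
  expect_equal(daily_contribution("2015-06-04", tl, temps, "2015-06-10"), 3)
  # placement day (death == placement) with mean 20 contributes half: 10
  tl2 <- cadaver_timeline("2015-06-01", "2015-06-01")
  expect_equal(daily_contribution("2015-06-01", tl2, const_temps(20),
                                  "2015-06-05"), 10)
  # sampling day contributes its morning half only
  expect_equal(daily_contribution("2015-06-05", tl2, const_temps(20),
                                  "2015-06-05"), 10)
})

test_that("the storage/placement fixture matches the half-day oracle", {
  # death D0, placement D2, sampling D5; post-placement means 20,22,24,26
  tl <- cadaver_timeline("2015-06-01", "2015-06-03")
  temps <- data.frame(date = as.Date(c("2015-06-03", "2015-06-04",
                                       "2015-06-05", "2015-06-06")),
                      mean_c = c(20, 22, 24, 26))
  got <- accumulated_degree_days(tl, temps, "2015-06-06")
  expect_equal(got, oracle_add(tl, temps, "2015-06-06"))
  # frozen value: 4 storage halves (6) + 10 + 22 + 24 + 13
  expect_equal(got, 75)
})

test_that("an interval frozen through sampling accrues zero", {
  tl <- cadaver_timeline("2015-06-01", "2015-06-08",
                         frozen_intervals = list(c("2015-06-01", "2015-06-08")))
  expect_equal(accumulated_degree_days(tl, const_temps(30), "2015-06-08"), 0)
})

test_that("ADD is additive, monotone and scales with temperature", {
  tl <- cadaver_timeline("2015-06-01", "2015-06-04",
                         frozen_intervals = list(c("2015-06-02", "2015-06-02")))
  set.seed(9)
  temps <- const_temps(0, days = 30)
  temps$mean_c <- round(runif(30, 2, 35), 1)
  add_at <- function(d, tmp = temps) accumulated_degree_days(tl, tmp, d)
  dates <- seq(as.Date("2015-06-04"), by = "day", length.out = 20)
  vals <- vapply(dates, add_at, numeric(1))
  # strictly increasing (all rates positive post-placement)
  expect_true(all(diff(vals) > 0))
  # additivity: ADD(death -> t2) = ADD(death -> t1) + increments over (t1, t2]
  t1 <- dates[5]; t2 <- dates[12]
  inc <- 0
  for (d in as.list(seq(t1, t2, by = "day"))) {
    inc <- inc + daily_contribution(d, tl, temps, t2)
  }
  inc <- inc - daily_contribution(t1, tl, temps, t1)  # remove t1's am half
  expect_equal(add_at(t2), add_at(t1) + inc, tolerance = 1e-12)
  # doubling every daily mean doubles the post-placement contribution
  doubled <- temps; doubled$mean_c <- 2 * temps$mean_c
  zeroed <- temps; zeroed$mean_c <- 0
  storage_part <- add_at(t2, zeroed)  # storage/frozen accrual alone
  expect_equal(add_at(t2, doubled) - storage_part,
               2 * (add_at(t2) - storage_part), tolerance = 1e-12)
})

test_that("implementation equals the brute-force half-day oracle on random timelines", {
  set.seed(31)
  for (i in 1:60) {
    death <- as.Date("2015-01-01") + sample(0:100, 1)
    placement <- death + sample(0:6, 1)
    sample_date <- placement + sample(0:20, 1)
    frozen <- list()
    if (placement > death && runif(1) < 0.5) {
      f0 <- death + sample(0:as.integer(placement - death), 1)
      f1 <- min(f0 + sample(0:3, 1), placement)
      frozen <- list(c(f0, f1))
    }
    tl <- cadaver_timeline(death, placement, frozen,
                           storage_temp_c = sample(c(3, 4), 1))
    temps <- data.frame(date = seq(death, sample_date + 2, by = "day"))
    temps$mean_c <- round(runif(nrow(temps), -5, 35), 1)
    for (clamp in c(TRUE, FALSE)) {
      expect_equal(
        accumulated_degree_days(tl, temps, sample_date, clamp_negative = clamp),
        oracle_add(tl, temps, sample_date, clamp_negative = clamp),
        tolerance = 1e-9)
    }
  }
})

test_that("negative means clamp to zero by default but not when disabled", {
  tl <- cadaver_timeline("2015-06-01", "2015-06-01")
  temps <- const_temps(-4)
  expect_equal(accumulated_degree_days(tl, temps, "2015-06-03"), 0)
  expect_equal(accumulated_degree_days(tl, temps, "2015-06-03",
                                       clamp_negative = FALSE), -8)
})

test_that("gaps in the temperature record are reported, not imputed", {
  tl <- cadaver_timeline("2015-06-01", "2015-06-01")
  temps <- const_temps(20, days = 2)
  expect_error(accumulated_degree_days(tl, temps, "2015-06-05"),
               "no temperature record")
})

test_that("timelines and temperature series round-trip through their formats", {
  tl <- cadaver_timeline("2015-06-01", "2015-06-05",
                         frozen_intervals = list(c("2015-06-02", "2015-06-03")),
                         storage_temp_c = 3)
  p <- withr::local_tempfile(fileext = ".json")
  write_cadaver_timeline(tl, p)
  expect_equal(read_cadaver_timeline(p), tl)

  temps <- const_temps(21.5, days = 5)
  pt <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(date = format(temps$date), mean_c = temps$mean_c), pt,
            row.names = FALSE)
  expect_equal(read_daily_temperature(pt), temps)

  # invalid timelines rejected
  expect_error(cadaver_timeline("2015-06-05", "2015-06-01"), "death_date")
  expect_error(cadaver_timeline("2015-06-01", "2015-06-03",
                                list(c("2015-06-02", "2015-06-09"))),
               "frozen")
})
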