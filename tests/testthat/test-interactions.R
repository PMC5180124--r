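test_that("observed proportions divide kin-category rate sums by total strength", {
  # worked example: non-kin rate sum 0.02 of total 0.05 -> 0.4
  rates <- tibble::tibble(
    infant_id = "I1", period = "LATE",
    male_id = c("M1", "M2", "M3"),
    rate = c(0.03, 0.015, 0.005),
    kin = factor(c("FATHER", "NON_KIN", "NON_KIN"), levels = kin_levels)
  )
  obs <- observed_proportions(rates)
  expect_equal(obs$observed_prop[obs$kin == "NON_KIN"], 0.4)
  expect_equal(obs$observed_prop[obs$kin == "FATHER"], 0.6)
  expect_equal(unique(obs$total_strength), 0.05)

  # all interaction with the father only
  solo <- rates |> dplyr::mutate(rate = c(0.02, 0, 0))
  obs2 <- observed_proportions(solo)
  expect_equal(obs2$observed_prop[obs2$kin == "FATHER"], 1)

  # three-male fixture against hand arithmetic, maternal kin in the total
  mixed <- tibble::tibble(
    infant_id = "I2", period = "LATE",
    male_id = c("M1", "M2", "M3"),
    rate = c(0.01, 0.02, 0.01),
    kin = factor(c("FATHER", "MATERNAL_KIN", "NON_KIN"),
                 levels = kin_levels)
  )
  obs3 <- observed_proportions(mixed)
  expect_equal(obs3$observed_prop[obs3$kin == "FATHER"], 0.01 / 0.04)
  expect_equal(obs3$observed_prop[obs3$kin == "MATERNAL_KIN"], 0.5)
  expect_equal(sum(obs3$observed_prop), 1, tolerance = 1e-12)

  # zero-strength infants are excluded
  none <- rates |> dplyr::mutate(rate = 0)
  expect_identical(nrow(observed_proportions(none)), 0L)
})

test_that("expected proportions come from community demography at the reference date", {
  # ten adult males, one the father, nine non-kin -> 0.9
  roster <- tibble::tibble(
    id = c(sprintf("M%02d", 1:10), "F1", "I1"),
    sex = c(rep("M", 10), "F", "F"),
    birth_date = as.Date(c(rep("1980-01-01", 10), "1985-01-01", "2010-01-01")),
    death_date = as.Date(NA)
  ) |>
    dplyr::mutate(adult_from = add_months(birth_date, 144))
  ped <- tibble::tibble(child_id = "I1", mother_id = "F1", father_id = "M01")
  e <- expected_proportions("I1", as.Date("2010-01-01"), roster, ped)
  expect_equal(e$expected_prop[e$kin == "NON_KIN"], 0.9)
  expect_equal(e$expected_prop[e$kin == "FATHER"], 0.1)
  expect_equal(sum(e$expected_prop), 1, tolerance = 1e-12)

  # father dead before the reference date -> FATHER expectation 0
  roster2 <- roster
  roster2$death_date[roster2$id == "M01"] <- as.Date("2009-06-01")
  e2 <- expected_proportions("I1", as.Date("2010-01-01"), roster2, ped)
  expect_equal(e2$expected_prop[e2$kin == "FATHER"], 0)
  expect_equal(e2$expected_prop[e2$kin == "NON_KIN"], 1)

  roster3 <- roster |> dplyr::mutate(death_date = as.Date("2000-01-01"))
  expect_error(expected_proportions("I1", as.Date("2010-01-01"), roster3, ped),
               "No adult males")
})

test_that("interaction rates match the per-sample brute-force tally", {
  fx <- random_sample_fixture(3)
  rates <- interaction_rates(fx$point_samples, fx$roster, fx$pedigree)
  for (m in fx$males) {
    got <- rates$rate[rates$male_id == m]
    want <- oracle_rate(fx$point_samples, "I1", m)
    if (length(got) == 0) got <- 0
    expect_equal(got, want, info = m)
  }
  # direct ratio example: 5 play minutes of 500 co-present minutes
  expect_equal(5 / 500, 0.01)
})

test_that("the sign-flip permutation test is exact, symmetric and degenerate-safe", {
  expect_equal(permutation_test(c(0, 0, 0))$p, 1)
  expect_error(permutation_test(1), "at least 2")

  # n = 3: exhaustive enumeration over the 8 sign patterns
  x <- c(0.3, -0.1, 0.25)
  res <- permutation_test(x, B = 10000)
  expect_identical(res$method, "exhaustive")
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  p_manual <- mean(abs(signs %*% x) / 3 >= abs(mean(x)) - 1e-12)
  expect_equal(res$p, p_manual)

  # order invariance and two-sidedness (global sign flip)
  res_perm <- permutation_test(rev(x), B = 10000)
  expect_equal(res_perm$p, res$p)
  res_neg <- permutation_test(-x, B = 10000)
  expect_equal(res_neg$p, res$p)

  # Monte-Carlo with a seed is reproducible and close to exact for n <= 12
  y <- withr::with_seed(8, stats::rnorm(12, 0.3, 1))
  exact <- permutation_test(y, B = 2^12, exact = TRUE)
  mc1 <- permutation_test(y, B = 10000, seed = 4, exact = FALSE)
  mc2 <- permutation_test(y, B = 10000, seed = 4, exact = FALSE)
  expect_identical(mc1$p, mc2$p)
  tol <- 3 * sqrt(exact$p * (1 - exact$p) / 10000)
  expect_lt(abs(mc1$p - exact$p), max(tol, 1e-3))
})

test_that("interaction summaries wire rates, filters and expectations together", {
  cfg <- sim_config(n_adult_males = 8, n_mothers = 6, years = 5,
                    follow_days_per_month = 0, family_days_per_month = 1,
                    family_minutes = 120, unknown_paternity = 0,
                    interaction_rate = 5e-3, seed = 55)
  b <- simulate_study(cfg)
  s <- interaction_summaries(b)
  expect_true(all(s$observed$expected_prop >= 0 &
                    s$observed$expected_prop <= 1))
  sums <- s$observed |>
    dplyr::group_by(infant_id, period) |>
    dplyr::summarise(o = sum(observed_prop), e = sum(expected_prop),
                     .groups = "drop")
  expect_true(all(abs(sums$e - 1) < 1e-12))
  expect_true(all(abs(sums$o - 1) < 1e-12))
  tests <- interaction_tests(s, b$pedigree, B = 2000, seed = 2)
  expect_setequal(tests$kin, c("FATHER", "NON_KIN"))
  expect_true(all(tests$p >= 0 & tests$p <= 1))
})
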