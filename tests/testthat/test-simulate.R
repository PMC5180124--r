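test_that("identical seeds give byte-identical output bundles", {
  cfg <- sim_config(n_adult_males = 5, n_mothers = 4, years = 4,
                    follow_days_per_month = 1, family_days_per_month = 1,
                    family_minutes = 60, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(simulate_study(cfg), d1, config = cfg)
  write_bundle(simulate_study(cfg), d2, config = cfg)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), info = f)
  }
})

test_that("simulator output passes datamodel validation", {
  b <- simulate_study(sim_config(n_adult_males = 6, n_mothers = 5, years = 5,
                                 follow_days_per_month = 2,
                                 family_days_per_month = 1,
                                 family_minutes = 90, seed = 21))
  expect_silent(validate_bundle(b))
  expect_gt(nrow(b$follows), 0)
  expect_gt(nrow(b$point_samples), 0)
})

test_that("config validation rejects infeasible demography and null-violating bias", {
  expect_error(sim_config(n_adult_males = 0), "adult male")
  expect_error(sim_config(father_bias = 0.5), "father_bias")
  expect_error(sim_config(gregariousness = c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("with a null paternity link the sire lottery matches its closed form", {
  # P(next sire == prior father) under independent rank-skewed lotteries
  # is sum(w^2) / sum(w)^2
  w <- exp(-0.4 * (0:9))
  p_expected <- sum(w^2) / sum(w)^2
  hits <- 0L; n_cases <- 0L
  for (i in 1:200) {
    cfg <- sim_config(n_adult_males = 10, n_mothers = 6, years = 10,
                      unknown_paternity = 0, rank_skew = 0.4,
                      follow_days_per_month = 0, family_days_per_month = 0,
                      dominance_per_month = 0, seed = derive_seed(400, i))
    com <- simulate_community(cfg)
    tf <- com$latent$true_father
    con <- com$conceptions
    if (nrow(con) == 0) next
    same <- tf[con$prior_infant_id] == con$sire_id
    hits <- hits + sum(same); n_cases <- n_cases + nrow(con)
  }
  p_hat <- hits / n_cases
  se <- sqrt(p_expected * (1 - p_expected) / n_cases)
  expect_gt(n_cases, 300)
  expect_lt(abs(p_hat - p_expected), 4 * se)
})

test_that("a zero interaction rate yields zero interaction strength for every infant", {
  cfg <- sim_config(n_adult_males = 6, n_mothers = 5, years = 5,
                    interaction_rate = 0, early_interaction_rate = 0,
                    follow_days_per_month = 0, family_days_per_month = 1,
                    family_minutes = 90, seed = 31)
  b <- simulate_study(cfg)
  expect_true(all(b$point_samples$behavior == "NONE"))
  rates <- interaction_rates(b$point_samples, b$roster, b$pedigree)
  expect_true(all(rates$rate == 0))
})

test_that("father bias in co-party membership decays with infant age", {
  # with a 6-month half-life, the father/non-kin contrast in bin 0 should
  # exceed the bin-6 contrast on average across replicates
  contrast_by_bin <- function(tab) {
    tab |>
      dplyr::group_by(age_bin, kin) |>
      dplyr::summarise(m = mean(z), .groups = "drop") |>
      tidyr::pivot_wider(names_from = kin, values_from = m) |>
      dplyr::mutate(d = FATHER - NON_KIN)
  }
  d0 <- c(); d6 <- c()
  for (i in 1:15) {
    b <- simulate_study(calib_assoc_config(derive_seed(500, i),
                                           father_bias = 3))
    tab <- build_within_period_dataset(b)
    cb <- contrast_by_bin(tab)
    d0 <- c(d0, cb$d[cb$age_bin == 0]); d6 <- c(d6, cb$d[cb$age_bin == 6])
  }
  expect_gt(mean(d0, na.rm = TRUE), mean(d6, na.rm = TRUE))
  expect_gt(mean(d0, na.rm = TRUE), 0.5)
})

test_that("under the null fathers and non-kin with equal exposure are exchangeable", {
  # the association proportion dilutes pairs present for only part of a
  # window; the null symmetry of the estimator therefore holds among
  # pairs with full-window exposure, compared pairwise within windows
  ds <- c()
  for (i in 1:10) {
    b <- simulate_study(calib_assoc_config(derive_seed(600, i)))
    windows <- kinbias:::father_offspring_windows(b)
    recs <- association_records(b, windows)
    mi <- kinbias:::mi_pair_table(b$roster, b$pedigree)
    recs <- recs |>
      dplyr::left_join(mi |> dplyr::select(infant_id, infant_birth,
                                           presence_end),
                       by = "infant_id") |>
      dplyr::filter(infant_birth <= start, presence_end >= end)
    paired <- recs |>
      dplyr::group_by(window_id) |>
      dplyr::summarise(
        d = mean(z[infant_id == anchor_infant_id[1]]) -
          mean(z[kin == "NON_KIN" & infant_id != anchor_infant_id[1]]),
        .groups = "drop"
      ) |>
      dplyr::filter(is.finite(d))
    ds <- c(ds, mean(paired$d))
  }
  expect_lt(abs(mean(ds)), 0.1)
})
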