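balanced_assoc_table <- function(seed = 101, reps = 4, noise = 0.3,
                                 effect = 0) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      kin = c("FATHER", "NON_KIN"), bin = 0:6, rep = seq_len(reps)
    )
    grid |>
      dplyr::mutate(
        male_id = sprintf("M%d", ((rep - 1) %% 3) + 1),
        mother_id = sprintf("F%d", ((rep + 1) %% 3) + 1),
        infant_id = sprintf("I%d", rep),
        age_bin = factor(bin, levels = 0:6),
        kin = factor(kin, levels = c("FATHER", "NON_KIN")),
        z = stats::rnorm(dplyr::n(), sd = noise) +
          effect * (kin == "FATHER") * (bin <= 2),
        proportion = NA_real_, follow_minutes = NA_real_,
        window_id = NA_character_, anchor_infant_id = NA_character_
      )
  })
}

test_that("without random effects the model reproduces the cell means exactly", {
  tab <- balanced_assoc_table()
  fit <- fit_association_lmm(tab, random_effects = FALSE)
  cells <- tab |>
    dplyr::group_by(kin, age_bin) |>
    dplyr::summarise(m = mean(z), .groups = "drop")
  pred <- stats::predict(fit$fit, newdata = cells)
  expect_equal(unname(pred), cells$m, tolerance = 1e-6)
})

test_that("a singular mixed fit agrees with the fixed-effects-only fit", {
  tab <- balanced_assoc_table(seed = 11)
  mixed <- suppressWarnings(fit_association_lmm(tab))
  plain <- fit_association_lmm(tab, random_effects = FALSE)
  if (mixed$singular) {
    expect_equal(lme4::fixef(mixed$fit), stats::coef(plain$fit),
                 tolerance = 1e-6)
  } else {
    # variance was estimated positive: coefficients still close
    expect_equal(lme4::fixef(mixed$fit), stats::coef(plain$fit),
                 tolerance = 0.1)
  }
})

test_that("within-bin contrasts carry a family-wise adjustment", {
  tab <- balanced_assoc_table(seed = 21, reps = 6, effect = 1)
  fit <- suppressWarnings(fit_association_lmm(tab))
  ct <- tukey_within_bin(fit)
  expect_identical(nrow(ct), 7L)
  expect_true(all(ct$p_adjusted >= ct$p_unadjusted - 1e-10))
  # the injected early-bin effect is detected where it was injected
  expect_true(all(ct$p_adjusted[ct$age_bin %in% 0:2] < 0.05))

  # degenerate family: a single bin reduces to the unadjusted comparison
  tab1 <- tab |> dplyr::filter(age_bin == 0)
  fit1 <- suppressWarnings(fit_association_lmm(tab1))
  ct1 <- tukey_within_bin(fit1)
  expect_identical(nrow(ct1), 1L)
  expect_equal(ct1$p_adjusted, ct1$p_unadjusted, tolerance = 1e-6)
})

test_that("same-sire bookkeeping reports exact counts and the integer percentage", {
  n <- 27
  ped <- tibble::tibble(
    child_id = sprintf("P%02d", 1:n),
    mother_id = sprintf("F%02d", 1:n),
    father_id = sprintf("M%02d", rep(1:9, 3))
  )
  con <- tibble::tibble(
    mother_id = sprintf("F%02d", 1:n),
    prior_infant_id = sprintf("P%02d", 1:n),
    conception_date = as.Date("2011-01-01") + 1:n,
    next_infant_id = sprintf("N%02d", 1:n),
    # exactly six repeat sires
    sire_id = c(ped$father_id[1:6], sprintf("M%02d", rep(10:16, 3)))
  )
  s <- paternity_case_summary(con, ped)
  expect_identical(s$n_known, 27L)
  expect_identical(s$n_same_sire, 6L)
  expect_identical(s$pct_same_sire, 22)

  # unknown paternities drop out of the accounting
  con2 <- con
  con2$sire_id[7:11] <- NA
  s2 <- paternity_case_summary(con2, ped)
  expect_identical(s2$n_known, 22L)
  expect_identical(s2$n_same_sire, 6L)
})

test_that("complete separation triggers the bias-reduced refit", {
  withr::with_seed(31, {
    cases <- tibble::tibble(
      mother_id = sprintf("F%d", 1:14),
      prior_infant_id = sprintf("P%d", 1:14),
      father_id = sprintf("M%d", rep(1:7, 2)),
      conception_date = as.Date("2011-01-01") + 1:14,
      z = c(stats::rnorm(7, -2, 0.3), stats::rnorm(7, 2, 0.3)),
      rank = sample(1:8, 14, replace = TRUE)
    ) |>
      dplyr::mutate(same_sire = as.integer(z > 0))
  })
  expect_warning(fit <- fit_paternity_model(cases), "Firth|separation")
  expect_identical(fit$method, "firth")
  expect_true(all(is.finite(fit$wald$estimate)))
  expect_true(all(is.finite(fit$wald$se)))
  expect_gt(fit$wald$estimate[fit$wald$term == "z"], 0)
})

test_that("the Firth fallback matches plain likelihood on well-behaved data", {
  withr::with_seed(41, {
    n <- 400
    x <- stats::rnorm(n)
    y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.8 * x))
    X <- cbind(1, x)
    firth <- kinbias:::kb_firth_logit(X, y)
    glm_fit <- stats::glm(y ~ x, family = stats::binomial())
  })
  # penalization vanishes asymptotically
  expect_equal(unname(firth$coefficients), unname(stats::coef(glm_fit)),
               tolerance = 0.05)
})

test_that("tidy and glance return the reporting tables", {
  tab <- balanced_assoc_table(seed = 51)
  fit <- suppressWarnings(fit_association_lmm(tab))
  td <- tidy(fit)
  expect_true(all(c("term", "f_value", "den_df", "p_value") %in% names(td)))
  expect_true("kin:age_bin" %in% td$term)
  expect_identical(glance(fit)$nobs, nrow(tab))
  tf <- tidy(fit, effects = "fixed")
  expect_true(all(c("estimate", "std_error") %in% names(tf)))
})
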