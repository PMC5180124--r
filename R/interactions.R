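# Infant-adult male interaction rates, observed vs expected kin-category
# proportions, and the one-sample sign-flip permutation test.
#
# Infancy is split into two periods: EARLY (birth to 6 months, when
# infanticide risk peaks and infants are in near-constant contact with the
# mother) and LATE (6 months to 3.5 years).  The dyadic interaction rate is
#   (point-sample minutes grooming or playing with a male) /
#   (point-sample minutes in the same party as that male),
# and per-infant rates are summed over adult males into a total interaction
# strength.  Maternal-kin and unknown-paternity dyads count toward the
# total strength but are excluded from the father/non-kin contrasts.

# EARLY/LATE infancy period of each point sample (NA beyond infancy)
kb_sample_period <- function(point_samples, roster, early_months = 6L,
                             max_months = 42L) {
  birth <- roster$birth_date[match(point_samples$infant_id, roster$id)]
  b_early <- add_months_u(birth, early_months)
  b_max <- add_months_u(birth, max_months)
  ifelse(point_samples$date < b_early, "EARLY",
         ifelse(point_samples$date < b_max, "LATE", NA))
}

#' Dyadic infant-male interaction rates from family-follow point samples
#'
#' @param point_samples point-sample tibble (see [read_point_samples()]).
#' @param roster,pedigree community tables.
#' @param early_months infant age (months) below which a sample is EARLY.
#' @param max_months infancy end in months (samples beyond are dropped).
#' @return tibble with one row per (infant, period, adult male) that was
#'   ever co-present: `interaction_minutes`, `co_present_minutes`, `rate`
#'   (0 with `flagged = TRUE` when the denominator is 0) and `kin`.
#' @export
interaction_rates <- function(point_samples, roster, pedigree,
                              early_months = 6L, max_months = 42L) {
  empty <- tibble(
    infant_id = character(), period = character(), male_id = character(),
    interaction_minutes = numeric(), co_present_minutes = numeric(),
    rate = numeric(), flagged = logical(),
    kin = factor(character(), levels = kin_levels)
  )
  if (nrow(point_samples) == 0) return(empty)

  period <- kb_sample_period(point_samples, roster, early_months, max_months)
  ps <- point_samples[!is.na(period), ]
  period <- period[!is.na(period)]
  if (nrow(ps) == 0) return(empty)

  # per-male co-presence scan over the padded membership strings;
  # denominators count adult males alive on the sample date
  padded <- paste0(";", ps$member_ids, ";")
  males <- roster |> filter(sex == "M")
  kf <- factor(paste(ps$infant_id, period, sep = "\r"))
  ki <- as.integer(kf)
  ng <- nlevels(kf)
  soc <- ps$behavior %in% c("GROOM", "PLAY") & !is.na(ps$partner_id)
  co_g <- matrix(0, ng, nrow(males), dimnames = list(levels(kf), NULL))
  int_g <- matrix(0, ng, nrow(males))
  for (j in seq_len(nrow(males))) {
    m <- males$id[[j]]
    eligible <- males$adult_from[[j]] <= ps$date &
      (is.na(males$death_date[[j]]) | males$death_date[[j]] >= ps$date)
    present <- eligible &
      stringr::str_detect(padded, stringr::fixed(paste0(";", m, ";")))
    co_g[, j] <- tabulate(ki[present], nbins = ng)
    int_g[, j] <- tabulate(ki[soc & present & ps$partner_id == m],
                           nbins = ng)
  }
  keep <- which(co_g > 0 | int_g > 0, arr.ind = TRUE)
  if (nrow(keep) == 0) return(empty)
  parts <- strsplit(rownames(co_g)[keep[, 1]], "\r", fixed = TRUE)
  res <- tibble(
    infant_id = vapply(parts, `[[`, "", 1),
    period = vapply(parts, `[[`, "", 2),
    male_id = males$id[keep[, 2]],
    co_present_minutes = co_g[keep],
    interaction_minutes = int_g[keep]
  )
  res |>
    mutate(
      flagged = co_present_minutes == 0,
      rate = ifelse(flagged, 0, interaction_minutes / co_present_minutes),
      kin = classify_kin(male_id, infant_id, pedigree)
    ) |>
    select(infant_id, period, male_id, interaction_minutes,
           co_present_minutes, rate, flagged, kin)
}

#' Observed kin-category proportions of total interaction strength
#'
#' The total strength of an infant's interactions with adult males is the
#' sum of its dyadic rates across all adult males (all kin categories
#' included).  The observed proportion for a category is the category's
#' rate sum divided by the total strength.
#'
#' @param rates tibble with `infant_id`, `period`, `male_id`, `rate`,
#'   `kin` (e.g. from [interaction_rates()]).
#' @return tibble with one row per (infant, period, kin category) carrying
#'   `observed_prop` and `total_strength`; infants with zero total strength
#'   are excluded.
#' @export
observed_proportions <- function(rates) {
  strength <- rates |>
    group_by(infant_id, period) |>
    summarise(total_strength = sum(rate), .groups = "drop") |>
    filter(total_strength > 0)
  rates |>
    inner_join(strength, by = c("infant_id", "period")) |>
    group_by(infant_id, period, kin, total_strength) |>
    summarise(rate_sum = sum(rate), .groups = "drop") |>
    mutate(observed_prop = rate_sum / total_strength) |>
    select(infant_id, period, kin, observed_prop, total_strength)
}

#' Expected kin-category proportions from community demography
#'
#' The expected proportion for a category is the fraction of adult males
#' alive (and adult) on the reference date that belong to it: with 10
#' adult males of whom 9 are non-kin to the infant, the expected non-kin
#' proportion is 0.9.
#'
#' @param infant_id infant id (scalar).
#' @param reference_date date at which community demography is taken.
#' @param roster,pedigree community tables.
#' @return tibble with one row per kin category (`kin`, `n_males`,
#'   `expected_prop`); errors when no adult males are alive.
#' @export
expected_proportions <- function(infant_id, reference_date, roster, pedigree) {
  males <- adult_males_on(roster, reference_date)
  if (nrow(males) == 0) {
    abort(paste0("No adult males alive on ", reference_date, "."))
  }
  cats <- classify_kin(males$id, infant_id, pedigree)
  counts <- table(factor(cats, levels = kin_levels))
  tibble(
    infant_id = infant_id,
    kin = factor(kin_levels, levels = kin_levels),
    n_males = as.integer(counts),
    expected_prop = as.integer(counts) / nrow(males)
  )
}

#' Per-infant interaction summaries for both infancy periods
#'
#' Applies the observation-time filters (at least `early_min_hours` of
#' family-follow point samples in early infancy, `late_min_hours` in late
#' infancy; boundary inclusive), computes per-infant observed kin-category
#' proportions and the demography-based expected proportions.  The
#' reference date for expected demography is the period start: the
#' infant's birth for EARLY, its six-month anniversary for LATE
#' (`reference = "mid_period"` uses the period midpoint instead).
#'
#' @param bundle a `kb_bundle`.
#' @param early_min_hours,late_min_hours observation filters in hours.
#' @param reference `"period_start"` (default) or `"mid_period"`.
#' @return list with `rates` (dyadic), `observed` (per infant/period/
#'   category with expected values joined) and `hours` (per infant/period
#'   observed minutes with the filter verdict).
#' @export
interaction_summaries <- function(bundle, early_min_hours = 10,
                                  late_min_hours = 60,
                                  reference = c("period_start", "mid_period")) {
  reference <- match.arg(reference)
  rates <- interaction_rates(bundle$point_samples, bundle$roster,
                             bundle$pedigree)

  period <- kb_sample_period(bundle$point_samples, bundle$roster, 6L, 42L)
  hours <- tibble(infant_id = bundle$point_samples$infant_id[!is.na(period)],
                  period = period[!is.na(period)]) |>
    dplyr::count(infant_id, period, name = "observed_minutes") |>
    mutate(kept = ifelse(period == "EARLY",
                         observed_minutes >= early_min_hours * 60,
                         observed_minutes >= late_min_hours * 60))

  kept <- hours |> filter(kept) |> select(infant_id, period)
  rates_kept <- rates |> semi_join(kept, by = c("infant_id", "period"))
  obs <- observed_proportions(rates_kept)

  # expected demography at the period reference date
  ref_tab <- kept |>
    mutate(
      infant_birth = bundle$roster$birth_date[match(infant_id,
                                                    bundle$roster$id)],
      reference_date = dplyr::case_when(
        reference == "period_start" & period == "EARLY" ~ infant_birth,
        reference == "period_start" & period == "LATE" ~
          add_months_u(infant_birth, 6L),
        reference == "mid_period" & period == "EARLY" ~
          add_months_u(infant_birth, 3L),
        TRUE ~ add_months_u(infant_birth, 24L)
      )
    )
  males <- bundle$roster |> filter(sex == "M")
  grid <- tidyr::expand_grid(
    ref_tab |> select(infant_id, period, reference_date),
    male_id = males$id
  ) |>
    mutate(
      adult_from = males$adult_from[match(male_id, males$id)],
      death_date = males$death_date[match(male_id, males$id)],
      birth_date = males$birth_date[match(male_id, males$id)]
    ) |>
    filter(adult_from <= reference_date, birth_date <= reference_date,
           is.na(death_date) | death_date >= reference_date)
  if (nrow(grid) == 0) abort("No adult males alive at a reference date.")
  kin_tab <- grid |>
    distinct(male_id, infant_id) |>
    mutate(kin = classify_kin(male_id, infant_id, bundle$pedigree))
  expected <- grid |>
    left_join(kin_tab, by = c("male_id", "infant_id")) |>
    group_by(infant_id, period) |>
    mutate(.n_alive = dplyr::n()) |>
    group_by(infant_id, period, kin, .n_alive, .drop = FALSE) |>
    summarise(n_males = dplyr::n(), .groups = "drop") |>
    filter(!is.na(.n_alive)) |>
    mutate(expected_prop = n_males / .n_alive) |>
    select(infant_id, period, kin, n_males, expected_prop)

  observed <- expected |>
    left_join(obs, by = c("infant_id", "period", "kin")) |>
    mutate(observed_prop = dplyr::coalesce(observed_prop, 0)) |>
    semi_join(obs |> distinct(infant_id, period),
              by = c("infant_id", "period"))

  list(rates = rates, observed = observed, hours = hours)
}

#' One-sample sign-flip permutation test
#'
#' Tests whether per-case differences (e.g. observed minus expected
#' proportions across infants) are centred on zero.  The null is generated
#' by independent sign flips of each difference; the statistic is the
#' mean; the two-sided p-value is the fraction of permuted |mean| values
#' at least as large as the observed |mean|.  When all `2^n` sign patterns
#' fit within `B` the test enumerates them exhaustively (exact); otherwise
#' `B` random sign patterns are drawn.
#'
#' @param differences numeric vector (length >= 2).
#' @param B number of iterations (default 10000).
#' @param seed integer seed for the Monte-Carlo draw (required unless the
#'   test is exhaustive).
#' @param exact `NULL` (auto), `TRUE` (force enumeration) or `FALSE`
#'   (force Monte-Carlo).
#' @return one-row tibble: `n`, `mean_diff`, `p`, `B`, `method`.
#' @export
permutation_test <- function(differences, B = 10000, seed = NULL,
                             exact = NULL) {
  x <- as.numeric(differences)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) abort("Need at least 2 differences for the permutation test.")
  obs <- mean(x)
  do_exact <- exact %||% (n <= 20 && 2^n <= B)
  tol <- 1e-12
  if (do_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    means <- as.vector(signs %*% x) / n
    p <- mean(abs(means) >= abs(obs) - tol)
    method <- "exhaustive"
    B_used <- nrow(signs)
  } else {
    if (is.null(seed)) abort("`seed` is required for the Monte-Carlo test.")
    means <- withr::with_seed(as.integer(seed), {
      signs <- matrix(sample(c(-1, 1), n * B, replace = TRUE), nrow = B)
      as.vector(signs %*% x) / n
    })
    p <- sum(abs(means) >= abs(obs) - tol) / B
    method <- "monte-carlo"
    B_used <- B
  }
  tibble(n = n, mean_diff = obs, p = p, B = B_used, method = method)
}

#' Observed-vs-expected permutation tests by kin category
#'
#' For each requested kin category, collects the per-infant differences
#' `observed_prop - expected_prop` in the given period and runs the
#' one-sample sign-flip permutation test.  Infants whose paternity is
#' unknown are excluded from both contrasts; infants whose father was dead
#' or not adult at the reference date (expected father proportion 0) are
#' excluded from the FATHER contrast.
#'
#' @param summaries output of [interaction_summaries()].
#' @param pedigree pedigree tibble (to identify known-paternity infants).
#' @param period `"LATE"` (default) or `"EARLY"`.
#' @param categories kin categories to test.
#' @param B,seed passed to [permutation_test()].
#' @return tibble with one row per category: `kin`, `n`, `mean_diff`, `p`,
#'   `B`, `method`.
#' @export
interaction_tests <- function(summaries, pedigree, period = "LATE",
                              categories = c("FATHER", "NON_KIN"),
                              B = 10000, seed = 1L) {
  obs <- summaries$observed |>
    filter(period == !!period) |>
    mutate(father_known = !is.na(
      pedigree$father_id[match(infant_id, pedigree$child_id)]
    ))
  out <- vector("list", length(categories))
  for (i in seq_along(categories)) {
    cat_i <- categories[[i]]
    d <- obs |>
      filter(kin == cat_i, father_known)
    if (cat_i == "FATHER") d <- d |> filter(expected_prop > 0)
    diffs <- d$observed_prop - d$expected_prop
    res <- permutation_test(diffs, B = B, seed = seed + i)
    out[[i]] <- res |> mutate(kin = cat_i, .before = 1)
  }
  purrr::list_rbind(out)
}
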