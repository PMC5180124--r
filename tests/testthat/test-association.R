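make_follow_row <- function(focal, date, start, end, members) {
  tibble::tibble(focal_id = focal, date = as.Date(date),
                 start_min = as.integer(start), end_min = as.integer(end),
                 member_ids = paste(members, collapse = ";"))
}

test_that("association proportion handles empty and full overlap", {
  f <- dplyr::bind_rows(
    make_follow_row("M1", "2010-01-01", 0, 300, c("M1")),
    make_follow_row("M1", "2010-01-01", 300, 600, c("M1", "F1"))
  )
  r <- association_proportion(f, "M1", "F1", "I1",
                              "2010-01-01", "2010-01-31")
  expect_equal(r$proportion, 0)          # infant never present
  expect_equal(r$follow_minutes, 600)

  f2 <- dplyr::bind_rows(
    make_follow_row("M1", "2010-01-01", 0, 300, c("M1", "F1", "I1")),
    make_follow_row("M1", "2010-01-02", 100, 400, c("M1", "F1", "I1"))
  )
  r2 <- association_proportion(f2, "M1", "F1", "I1",
                               "2010-01-01", "2010-01-31")
  expect_equal(r2$proportion, 1)

  # zero follow minutes in the window -> flagged
  r3 <- association_proportion(f2, "M1", "F1", "I1",
                               "2011-01-01", "2011-01-31")
  expect_true(r3$flagged)
  expect_true(is.na(r3$proportion))
})

test_that("association proportions equal the per-minute brute-force oracle", {
  for (seed in 1:20) {
    fx <- random_follow_fixture(seed)
    for (m in fx$males) {
      for (k in seq_along(fx$mothers)) {
        got <- association_proportion(fx$follows, m, fx$mothers[k],
                                      fx$infants[k], fx$window[1],
                                      fx$window[2])
        want <- oracle_association(fx$follows, m, fx$mothers[k],
                                   fx$infants[k], fx$window[1],
                                   fx$window[2])
        expect_equal(got$co_minutes, want$co)
        expect_equal(got$follow_minutes, want$denom)
        expect_equal(got$proportion, want$proportion)
      }
    }
  }
})

test_that("z-standardization has the textbook fixed points", {
  recs <- tibble::tibble(
    male_id = "M1", window_id = "w1",
    proportion = c(0.1, 0.2, 0.3)
  )
  z <- standardize_association(recs)
  expect_equal(z$z[z$proportion == 0.3], 1)  # sample sd is exactly 0.1
  expect_false(any(z$degenerate))

  flat <- tibble::tibble(male_id = "M1", window_id = "w1",
                         proportion = rep(0.25, 4))
  zf <- standardize_association(flat)
  expect_true(all(zf$z == 0))
  expect_true(all(zf$degenerate))

  expect_error(standardize_association(flat[0, ]), "Empty")
})

test_that("z-scores are mean-0, sd-1 within every standardization set", {
  b <- simulate_study(calib_assoc_config(77, father_bias = 2))
  windows <- kinbias:::father_offspring_windows(b)
  recs <- association_records(b, windows)
  stats <- recs |>
    dplyr::filter(!degenerate) |>
    dplyr::group_by(male_id, window_id) |>
    dplyr::summarise(m = mean(z), s = sd(z), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(n > 1)
  expect_gt(nrow(stats), 10)
  expect_lt(max(abs(stats$m)), 1e-9)
  expect_lt(max(abs(stats$s - 1)), 1e-9)
})

test_that("the 30-hour window filter is boundary-inclusive at minute precision", {
  roster <- toy_roster()
  ped <- toy_pedigree()
  birth <- as.Date("2010-01-01")
  roster$birth_date[roster$id == "I1"] <- birth
  # M1 (father of I1) followed exactly 1800 min in bin 0, M4 1799 min;
  # spread over three 600-minute days so no single segment is oversized
  f <- dplyr::bind_rows(
    make_follow_row("M1", "2010-02-01", 0, 600, c("M1", "F1", "I1")),
    make_follow_row("M1", "2010-02-02", 0, 600, c("M1", "F2", "I2")),
    make_follow_row("M1", "2010-02-03", 0, 600, c("M1")),
    make_follow_row("M4", "2010-02-01", 0, 600, c("M4", "F1", "I1")),
    make_follow_row("M4", "2010-02-02", 0, 600, c("M4")),
    make_follow_row("M4", "2010-02-03", 0, 599, c("M4"))
  )
  bundle <- structure(list(roster = roster, pedigree = ped, follows = f),
                      class = "kb_bundle")
  windows <- tibble::tibble(
    window_id = c("w_M1", "w_M4"), male_id = c("M1", "M4"),
    start = birth, end = add_months(birth, 6) - 1
  )
  recs <- association_records(bundle, windows, min_minutes = 1800)
  expect_setequal(unique(recs$male_id), "M1")
  recs_lo <- association_records(bundle, windows, min_minutes = 1799)
  expect_setequal(unique(recs_lo$male_id), c("M1", "M4"))
})

test_that("within-period windows need both a father row and a non-kin row", {
  roster <- toy_roster()
  ped <- toy_pedigree()
  birth <- as.Date("2010-01-01")
  roster$birth_date[roster$id == "I1"] <- birth
  # kill I2 before I1's birth: no non-kin MI pair is ever present
  roster$death_date[roster$id == "I2"] <- as.Date("2009-12-01")
  roster$death_date[roster$id == "F2"] <- as.Date("2009-12-01")
  f <- dplyr::bind_rows(
    make_follow_row("M1", "2010-02-01", 0, 600, c("M1", "F1", "I1")),
    make_follow_row("M1", "2010-02-02", 0, 600, c("M1", "F1", "I1")),
    make_follow_row("M1", "2010-02-03", 0, 600, c("M1"))
  )
  bundle <- structure(list(roster = roster, pedigree = ped, follows = f),
                      class = "kb_bundle")
  expect_identical(nrow(build_within_period_dataset(bundle)), 0L)
})

test_that("between-period rows may come from disjoint calendar periods", {
  # father followed with his 2010 offspring; the only non-kin infant in the
  # same age bin was observed twelve years earlier
  roster <- tibble::tibble(
    id = c("F1", "F2", "M1", "M2", "I1", "I2"),
    sex = c("F", "F", "M", "M", "M", "F"),
    birth_date = as.Date(c("1980-01-01", "1980-01-01", "1980-01-01",
                           "1980-01-01", "2010-01-01", "1998-05-15")),
    death_date = as.Date(NA)
  ) |>
    dplyr::mutate(adult_from = add_months(birth_date, 144))
  ped <- tibble::tibble(
    child_id = c("I1", "I2"), mother_id = c("F1", "F2"),
    father_id = c("M1", "M2")
  )
  days10 <- as.Date("2010-01-05") + 0:5
  days98 <- as.Date("1998-05-20") + 0:5
  f <- dplyr::bind_rows(
    purrr::map(days10, \(d) make_follow_row("M1", d, 0, 400,
                                            c("M1", "F1", "I1"))) |>
      dplyr::bind_rows(),
    purrr::map(days98, \(d) make_follow_row("M1", d, 0, 400,
                                            c("M1", "F2", "I2"))) |>
      dplyr::bind_rows()
  )
  bundle <- structure(list(roster = roster, pedigree = ped, follows = f),
                      class = "kb_bundle")
  within <- build_within_period_dataset(bundle, min_hours = 30)
  expect_identical(nrow(within), 0L)  # never co-observed in one period
  between <- build_between_period_dataset(bundle, min_hours = 30)
  expect_identical(sort(as.character(unique(between$kin))),
                   c("FATHER", "NON_KIN"))
  expect_true(all(between$age_bin == 0))
  # father absent from bins where no non-kin infant was ever observed
  expect_false(any(between$age_bin != 0))
})

test_that("within- and between-period datasets coincide when all infants share a birth date", {
  roster <- tibble::tibble(
    id = c("F1", "F2", "F3", "M1", "M2", "M3", "I1", "I2", "I3"),
    sex = c("F", "F", "F", "M", "M", "M", "M", "F", "M"),
    birth_date = as.Date(c(rep("1985-01-01", 3), rep("1982-01-01", 3),
                           rep("2010-01-01", 3))),
    death_date = as.Date(NA)
  ) |>
    dplyr::mutate(adult_from = add_months(birth_date, 144))
  ped <- tibble::tibble(
    child_id = c("I1", "I2", "I3"), mother_id = c("F1", "F2", "F3"),
    father_id = c("M1", "M2", "M3")
  )
  withr::with_seed(99, {
    dates <- as.Date("2010-01-01") + sort(sample(0:1200, 90))
    rows <- purrr::map(dates, function(d) {
      present <- c("F1;I1", "F2;I2", "F3;I3")[stats::runif(3) < 0.5]
      pres_ids <- unlist(strsplit(present, ";"))
      dplyr::bind_rows(
        make_follow_row("M1", d, 0, 400, c("M1", pres_ids)),
        make_follow_row("M2", d, 0, 400, c("M2", pres_ids)),
        make_follow_row("M3", d, 0, 400, c("M3", pres_ids))
      )
    }) |> dplyr::bind_rows()
  })
  bundle <- structure(list(roster = roster, pedigree = ped, follows = rows),
                      class = "kb_bundle")
  w <- build_within_period_dataset(bundle, min_hours = 1)
  b <- build_between_period_dataset(bundle, min_hours = 1)
  key <- function(x) x |>
    dplyr::arrange(male_id, infant_id, age_bin, kin) |>
    dplyr::select(male_id, infant_id, age_bin, kin, z)
  expect_equal(key(w), key(b), tolerance = 1e-12)
})
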