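# Dyadic male x mother-infant association proportions and their per-male
# z-standardization inside infant-anchored six-month windows.
#
# The association index for a male and an MI pair over a calendar window is
#   (minutes the MI pair was in the male's party) / (minutes the male was
#   followed), counting a minute only when mother AND infant are both
#   recorded in the male's party segment.  Each male's proportions are then
#   z-standardized across all MI pairs present in the community during the
#   same window, which controls for temporal changes in demography and
#   community-level gregariousness.

far_future <- as.Date("9999-12-31")

# MI pairs (mother, infant, dates) derivable from pedigree + roster
mi_pair_table <- function(roster, pedigree) {
  pedigree |>
    filter(child_id %in% roster$id, mother_id %in% roster$id) |>
    transmute(
      mother_id,
      infant_id = child_id,
      infant_birth = roster$birth_date[match(child_id, roster$id)],
      infant_death = dplyr::coalesce(roster$death_date[match(child_id, roster$id)],
                                     far_future),
      mother_death = dplyr::coalesce(roster$death_date[match(mother_id, roster$id)],
                                     far_future)
    ) |>
    filter(!is.na(infant_birth)) |>
    mutate(presence_end = pmin(add_months(infant_birth, 42L) - 1L,
                               infant_death, mother_death))
}

#' Dyadic association proportions with per-male z-standardization
#'
#' For each requested (male, window), computes the association proportion
#' of the male with every MI pair present in the community during that
#' window (infant alive and under 42 months, mother alive; by default
#' throughout the window, see `presence`), then z-standardizes the
#' proportions within the (male, window) set.  Males followed for fewer than `min_minutes` in a
#' window are dropped.  Degenerate standardization sets (a single pair, or
#' zero variance) get `z = 0` and `degenerate = TRUE`.
#'
#' @param bundle a `kb_bundle` (needs `roster`, `pedigree`, `follows`).
#' @param windows tibble with columns `window_id`, `male_id`, `start`,
#'   `end` and optionally `bin`, `anchor_infant_id`.
#' @param min_minutes minimum follow minutes for a male in a window
#'   (boundary inclusive); default 1800 = 30 h.
#' @param presence `"full_window"` (default): an MI pair enters a window's
#'   standardization set only when present throughout the window, so that
#'   every proportion in the set has equal exposure; `"any_day"`: pairs
#'   present for at least one day are included, with their proportions
#'   mechanically diluted by the unexposed fraction of the window.
#' @param widen_kin passed to [classify_kin()].
#' @return a tibble of association records: one row per (male, window,
#'   MI pair) with `follow_minutes`, `co_minutes`, `proportion`, `z`,
#'   `degenerate`, `kin`.
#' @export
association_records <- function(bundle, windows, min_minutes = 1800,
                                presence = c("full_window", "any_day"),
                                widen_kin = FALSE) {
  presence <- match.arg(presence)
  stopifnot(all(c("window_id", "male_id", "start", "end") %in% names(windows)))
  if (!"bin" %in% names(windows)) windows$bin <- NA_integer_
  if (!"anchor_infant_id" %in% names(windows)) {
    windows$anchor_infant_id <- NA_character_
  }
  empty <- tibble(
    window_id = character(), male_id = character(), start = as.Date(character()),
    end = as.Date(character()), bin = integer(), anchor_infant_id = character(),
    mother_id = character(), infant_id = character(), follow_minutes = numeric(),
    co_minutes = numeric(), proportion = numeric(), z = numeric(),
    degenerate = logical(), kin = factor(character(), levels = kin_levels)
  )
  if (nrow(windows) == 0 || nrow(bundle$follows) == 0) return(empty)

  mi <- mi_pair_table(bundle$roster, bundle$pedigree)
  segs <- follow_segments(bundle$follows)
  members <- segment_members(segs)

  # minutes followed per male-day
  daily_denom <- segs |>
    group_by(focal_id, date) |>
    summarise(minutes = sum(minutes), .groups = "drop")

  # minutes with both members of an MI pair present, per male-day
  cand <- members |>
    inner_join(mi |> select(mother_id, infant_id),
               by = c(member = "mother_id"), relationship = "many-to-many") |>
    rename(mother_id = member)
  daily_co <- cand |>
    semi_join(members, by = c("seg_uid", infant_id = "member")) |>
    group_by(focal_id, date, mother_id, infant_id) |>
    summarise(co_minutes = sum(minutes), .groups = "drop")

  # window-level denominators with the observation-time filter
  mw <- windows |>
    inner_join(daily_denom,
               by = dplyr::join_by(male_id == focal_id,
                                   start <= date, end >= date)) |>
    group_by(window_id, male_id) |>
    summarise(follow_minutes = sum(minutes), .groups = "drop") |>
    filter(follow_minutes >= min_minutes)
  if (nrow(mw) == 0) return(empty)

  # MI pairs present in each retained window
  win_pairs <- if (presence == "full_window") {
    windows |>
      semi_join(mw, by = c("window_id", "male_id")) |>
      inner_join(mi, by = dplyr::join_by(end <= presence_end,
                                         start >= infant_birth),
                 relationship = "many-to-many")
  } else {
    windows |>
      semi_join(mw, by = c("window_id", "male_id")) |>
      inner_join(mi, by = dplyr::join_by(start <= presence_end,
                                         end >= infant_birth),
                 relationship = "many-to-many")
  }
  if (nrow(win_pairs) == 0) return(empty)

  win_co <- windows |>
    semi_join(mw, by = c("window_id", "male_id")) |>
    inner_join(daily_co,
               by = dplyr::join_by(male_id == focal_id,
                                   start <= date, end >= date),
               relationship = "many-to-many") |>
    group_by(window_id, male_id, mother_id, infant_id) |>
    summarise(co_minutes = sum(co_minutes), .groups = "drop")

  recs <- win_pairs |>
    left_join(mw, by = c("window_id", "male_id")) |>
    left_join(win_co, by = c("window_id", "male_id", "mother_id", "infant_id")) |>
    mutate(co_minutes = dplyr::coalesce(co_minutes, 0),
           proportion = co_minutes / follow_minutes) |>
    select(window_id, male_id, start, end, bin, anchor_infant_id,
           mother_id, infant_id, follow_minutes, co_minutes, proportion)

  recs <- standardize_association(recs)

  kin_tab <- recs |>
    distinct(male_id, infant_id) |>
    mutate(kin = classify_kin(male_id, infant_id, bundle$pedigree,
                              widen = widen_kin))
  recs |>
    left_join(kin_tab, by = c("male_id", "infant_id"))
}

#' z-standardize association proportions within (male, window) sets
#'
#' `z = (p - mean(P)) / sd(P)` where `P` are one male's proportions across
#' all MI pairs present in the community in the same window (sample sd,
#' n - 1 denominator).  When the set has a single pair or zero variance the
#' z-score is set to 0 and flagged `degenerate`.
#'
#' @param records tibble with `male_id`, `window_id`, `proportion`.
#' @return `records` with `z` and `degenerate` columns added/replaced.
#' @export
standardize_association <- function(records) {
  if (nrow(records) == 0) abort("Empty standardization set.")
  records |>
    group_by(male_id, window_id) |>
    mutate(
      .n = dplyr::n(),
      .sd = sd(proportion),
      degenerate = .n < 2 | is.na(.sd) | .sd == 0,
      z = ifelse(degenerate, 0, (proportion - mean(proportion)) / .sd)
    ) |>
    ungroup() |>
    select(-.n, -.sd)
}

#' Association proportion for one male and one MI pair
#'
#' Direct computation of the dyadic association index over a calendar
#' window: co-presence minutes (mother and infant both in the male's party
#' segment) over the male's follow minutes.
#'
#' @param follows follows tibble.
#' @param male_id,mother_id,infant_id ids.
#' @param start,end inclusive window dates.
#' @return a one-row tibble with `co_minutes`, `follow_minutes`,
#'   `proportion` (`NA` and `flagged = TRUE` when the male has zero follow
#'   minutes in the window).
#' @export
association_proportion <- function(follows, male_id, mother_id, infant_id,
                                   start, end) {
  start <- as.Date(start); end <- as.Date(end)
  segs <- follow_segments(follows) |>
    filter(focal_id == !!male_id, date >= start, date <= end)
  denom <- sum(segs$minutes)
  if (denom == 0) {
    return(tibble(co_minutes = NA_real_, follow_minutes = 0,
                  proportion = NA_real_, flagged = TRUE))
  }
  both <- vapply(segs$member_ids, function(m) {
    ids <- strsplit(m, ";", fixed = TRUE)[[1]]
    (mother_id %in% ids) && (infant_id %in% ids)
  }, logical(1), USE.NAMES = FALSE)
  co <- sum(segs$minutes[both])
  tibble(co_minutes = co, follow_minutes = denom, proportion = co / denom,
         flagged = FALSE)
}

# windows anchored at each known-father infant's birth, one per age bin,
# restricted to that infant's father
father_offspring_windows <- function(bundle, bins = 0:6) {
  offspring <- bundle$pedigree |>
    filter(!is.na(father_id), child_id %in% bundle$roster$id) |>
    transmute(anchor_infant_id = child_id, male_id = father_id,
              birth = bundle$roster$birth_date[match(child_id, bundle$roster$id)])
  if (nrow(offspring) == 0) {
    return(tibble(window_id = character(), male_id = character(),
                  anchor_infant_id = character(), bin = integer(),
                  start = as.Date(character()), end = as.Date(character())))
  }
  offspring |>
    mutate(w = purrr::map(birth, infant_windows, bins = bins)) |>
    tidyr::unnest(w) |>
    transmute(
      window_id = paste0(anchor_infant_id, "_b", bin, "_", male_id),
      male_id, anchor_infant_id, bin, start, end
    )
}

#' Within-period comparison dataset
#'
#' For each father and each of his offspring, windows start at the
#' offspring's birth and advance in six-month steps.  Within each window
#' the father's z-standardized association with the mother of his offspring
#' (kin `FATHER`) is set against his associations with mothers of non-kin
#' infants in the *same* calendar window (kin `NON_KIN`); rows from other
#' kin categories, unknown-paternity dyads, and the father's other-aged own
#' offspring enter the standardization but not the comparison.  A
#' (father, window) contributes only when the father was followed at least
#' `min_hours` in the window and has both a `FATHER` row and at least one
#' `NON_KIN` row.
#'
#' @param bundle a `kb_bundle`.
#' @param min_hours observation-time filter in hours (boundary inclusive).
#' @return tibble with columns `male_id`, `mother_id`, `infant_id`,
#'   `age_bin` (factor 0-6), `kin` (factor FATHER/NON_KIN), `z`,
#'   `proportion`, `follow_minutes`, `window_id`, `anchor_infant_id`.
#' @export
build_within_period_dataset <- function(bundle, min_hours = 30,
                                        presence = "full_window") {
  windows <- father_offspring_windows(bundle)
  recs <- association_records(bundle, windows, min_minutes = min_hours * 60,
                              presence = presence)
  if (nrow(recs) == 0) return(kb_empty_analysis_table())

  rows <- recs |>
    filter((kin == "FATHER" & infant_id == anchor_infant_id) |
             kin == "NON_KIN")
  keep <- rows |>
    group_by(window_id) |>
    filter(any(kin == "FATHER") & any(kin == "NON_KIN")) |>
    ungroup()
  kb_as_analysis_table(keep)
}

#' Between-period comparison dataset
#'
#' Compares a father's z-standardized association with the mother of his
#' offspring in a given age bin to his associations with mothers of
#' non-kin infants occupying the *same age bin during their own lives*,
#' whatever the calendar period.  Non-kin rows therefore come from windows
#' anchored at each non-kin infant's birth.  Only (father, bin)
#' combinations with both a `FATHER` and at least one `NON_KIN` row are
#' retained.  The same `min_hours` filter applies to every window.
#'
#' @inheritParams build_within_period_dataset
#' @return tibble in the same shape as [build_within_period_dataset()].
#' @export
build_between_period_dataset <- function(bundle, min_hours = 30,
                                         presence = "full_window") {
  father_win <- father_offspring_windows(bundle)
  father_recs <- association_records(bundle, father_win,
                                     min_minutes = min_hours * 60,
                                     presence = presence)
  father_rows <- father_recs |>
    filter(kin == "FATHER", infant_id == anchor_infant_id)

  fathers <- unique(father_win$male_id)
  mi <- mi_pair_table(bundle$roster, bundle$pedigree)
  if (length(fathers) == 0 || nrow(mi) == 0) return(kb_empty_analysis_table())

  # candidate (father, non-kin infant) pairs
  cand <- tidyr::expand_grid(male_id = fathers, infant_id = mi$infant_id) |>
    mutate(kin = classify_kin(male_id, infant_id, bundle$pedigree)) |>
    filter(kin == "NON_KIN") |>
    select(male_id, infant_id)
  if (nrow(cand) == 0) return(kb_empty_analysis_table())

  nk_windows <- cand |>
    left_join(mi |> select(infant_id, infant_birth), by = "infant_id") |>
    mutate(w = purrr::map(infant_birth, infant_windows)) |>
    tidyr::unnest(w) |>
    transmute(
      window_id = paste0(infant_id, "_b", bin, "_", male_id),
      male_id, anchor_infant_id = infant_id, bin, start, end
    )
  nk_recs <- association_records(bundle, nk_windows,
                                 min_minutes = min_hours * 60,
                                 presence = presence)
  nk_rows <- nk_recs |>
    filter(kin == "NON_KIN", infant_id == anchor_infant_id)

  rows <- dplyr::bind_rows(father_rows, nk_rows)
  if (nrow(rows) == 0) return(kb_empty_analysis_table())
  keep <- rows |>
    group_by(male_id, bin) |>
    filter(any(kin == "FATHER") & any(kin == "NON_KIN")) |>
    ungroup()
  kb_as_analysis_table(keep)
}

kb_empty_analysis_table <- function() {
  tibble(
    male_id = character(), mother_id = character(), infant_id = character(),
    age_bin = factor(integer(), levels = 0:6),
    kin = factor(character(), levels = c("FATHER", "NON_KIN")),
    z = numeric(), proportion = numeric(), follow_minutes = numeric(),
    window_id = character(), anchor_infant_id = character()
  )
}

kb_as_analysis_table <- function(rows) {
  rows |>
    transmute(
      male_id, mother_id, infant_id,
      age_bin = factor(bin, levels = 0:6),
      kin = factor(as.character(kin), levels = c("FATHER", "NON_KIN")),
      z, proportion, follow_minutes, window_id, anchor_infant_id
    )
}

#' Per-bin sample sizes of an association analysis table
#'
#' Counts, for each age bin, the number of distinct males and distinct MI
#' pairs contributing rows — the bookkeeping shape of the study's
#' sample-size table.
#'
#' @param table output of [build_within_period_dataset()] or
#'   [build_between_period_dataset()].
#' @return tibble with `age_bin`, `n_males`, `n_pairs`.
#' @export
association_sample_sizes <- function(table) {
  table |>
    group_by(age_bin) |>
    summarise(
      n_males = dplyr::n_distinct(male_id),
      n_pairs = dplyr::n_distinct(paste(mother_id, infant_id)),
      .groups = "drop"
    )
}
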