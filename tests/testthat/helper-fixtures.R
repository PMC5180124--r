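# Fixtures and independent oracles used across the test files.
# Oracles deliberately use brute-force enumeration (per-minute grids,
# maternal-ancestor chain intersection) rather than the package's own
# algorithms.

# --- small hand-built community ----------------------------------------

toy_roster <- function() {
  tibble::tibble(
    id = c("G1", "G2", "F1", "F2", "M1", "M2", "M3", "M4", "I1", "I2"),
    sex = c("F", "F", "F", "F", "M", "M", "M", "M", "M", "F"),
    birth_date = as.Date(c(
      "1960-01-01", "1962-01-01", "1985-01-01", "1986-01-01",
      "1984-01-01", "1985-06-01", "1986-01-01", "1987-01-01",
      "2010-01-01", "2010-03-01"
    )),
    death_date = as.Date(NA)
  ) |>
    dplyr::mutate(adult_from = kinbias::add_months(birth_date, 144))
}

# M1: father of I1.  M2: son of G1 = maternal uncle of I1 (F1's brother).
# M3: son of G2's daughter F2 -> maternal cousin of I2? (see pedigree)
# M4: unrelated.
toy_pedigree <- function() {
  tibble::tibble(
    child_id = c("F1", "F2", "M2", "M3", "I1", "I2"),
    mother_id = c("G1", "G2", "G1", "F2", "F1", "F2"),
    father_id = c(NA, NA, NA, NA, "M1", NA)
  )
}

# --- independent kin oracle: maternal-ancestor chain intersection ------

oracle_kin <- function(male_id, infant_id, pedigree) {
  mo <- stats::setNames(as.character(pedigree$mother_id), pedigree$child_id)
  fa <- stats::setNames(as.character(pedigree$father_id), pedigree$child_id)
  chain <- function(id) {
    out <- character()
    cur <- unname(mo[id])
    while (!is.na(cur)) {
      out <- c(out, cur)
      cur <- unname(mo[cur])
    }
    out
  }
  f <- unname(fa[infant_id])
  if (!is.na(f) && f == male_id) return("FATHER")
  cm <- chain(male_id)   # male's maternal ancestors, nearest first
  ci <- chain(infant_id)
  common <- intersect(cm, ci)
  if (length(common) > 0) {
    # first common maternal ancestor and the depth on each side
    anc <- common[[which.min(match(common, cm))]]
    dm <- match(anc, cm)
    di <- match(anc, ci)
    named <- (dm == 1 && di == 1) ||  # maternal brother
      (dm == 1 && di == 2) ||         # maternal uncle
      (dm == 2 && di == 2)            # maternal cousin
    if (named) return("MATERNAL_KIN")
  }
  if (is.na(f)) "UNKNOWN" else "NON_KIN"
}

random_pedigree <- function(seed, n = 30) {
  withr::with_seed(seed, {
    ids <- sprintf("X%02d", seq_len(n))
    # generation layers guarantee acyclic mother links
    gen <- sort(sample(1:3, n, replace = TRUE))
    mother <- rep(NA_character_, n)
    father <- rep(NA_character_, n)
    sexes <- sample(c("M", "F"), n, replace = TRUE)
    for (i in which(gen > 1)) {
      elders <- which(gen < gen[i] & sexes == "F")
      if (length(elders) > 0) {
        mother[i] <- ids[[if (length(elders) == 1) elders else
          sample(elders, 1)]]
      }
      males <- which(gen < gen[i] & sexes == "M")
      if (length(males) > 0 && stats::runif(1) < 0.7) {
        father[i] <- ids[[if (length(males) == 1) males else
          sample(males, 1)]]
      }
    }
    list(
      pedigree = tibble::tibble(child_id = ids, mother_id = mother,
                                father_id = father),
      males = ids[sexes == "M"],
      ids = ids
    )
  })
}

# --- random follow fixtures and the per-minute association oracle ------

random_follow_fixture <- function(seed, n_males = 2, n_pairs = 2,
                                  n_days = 3) {
  withr::with_seed(seed, {
    males <- sprintf("M%d", seq_len(n_males))
    mothers <- sprintf("F%d", seq_len(n_pairs))
    infants <- sprintf("I%d", seq_len(n_pairs))
    dates <- as.Date("2010-03-01") + 0:(n_days - 1)
    rows <- list()
    for (m in males) for (d in dates) {
      n_seg <- sample(2:4, 1)
      bounds <- sort(sample(1:300, n_seg + 1))
      for (s in seq_len(n_seg)) {
        present <- c(mothers, infants)[stats::runif(2 * n_pairs) < 0.5]
        # infant sometimes recorded without its mother and vice versa
        rows[[length(rows) + 1]] <- tibble::tibble(
          focal_id = m, date = d,
          start_min = bounds[s], end_min = bounds[s + 1],
          member_ids = paste(c(m, present), collapse = ";")
        )
      }
    }
    list(
      follows = dplyr::bind_rows(rows),
      males = males, mothers = mothers, infants = infants,
      window = c(min(dates), max(dates))
    )
  })
}

# brute force: expand every segment to its minutes and count
oracle_association <- function(follows, male_id, mother_id, infant_id,
                               start, end) {
  denom <- 0L
  co <- 0L
  for (r in seq_len(nrow(follows))) {
    row <- follows[r, ]
    if (row$focal_id != male_id) next
    if (row$date < start || row$date > end) next
    for (minute in seq(row$start_min, row$end_min - 1L)) {
      denom <- denom + 1L
      ids <- strsplit(row$member_ids, ";", fixed = TRUE)[[1]]
      if (mother_id %in% ids && infant_id %in% ids) co <- co + 1L
    }
  }
  list(co = co, denom = denom,
       proportion = if (denom > 0) co / denom else NA_real_)
}

# --- random point-sample fixtures and the per-sample rate oracle -------

random_sample_fixture <- function(seed, n_males = 3, n_minutes = 120) {
  withr::with_seed(seed, {
    males <- sprintf("M%d", seq_len(n_males))
    birth <- as.Date("2010-01-01")
    date <- as.Date("2011-06-01")  # late infancy
    rows <- lapply(seq_len(n_minutes), function(k) {
      present <- males[stats::runif(n_males) < 0.5]
      beh <- "NONE"; partner <- NA_character_
      if (length(present) > 0 && stats::runif(1) < 0.15) {
        beh <- sample(c("GROOM", "PLAY"), 1)
        partner <- if (length(present) == 1) present else sample(present, 1)
      }
      tibble::tibble(
        infant_id = "I1", date = date, minute = k - 1L,
        behavior = beh, partner_id = partner,
        member_ids = paste(c("I1", "F1", present), collapse = ";")
      )
    })
    roster <- tibble::tibble(
      id = c("F1", "I1", males),
      sex = c("F", "F", rep("M", n_males)),
      birth_date = c(as.Date("1990-01-01"), birth,
                     rep(as.Date("1990-01-01"), n_males)),
      death_date = as.Date(NA)
    ) |>
      dplyr::mutate(adult_from = kinbias::add_months(birth_date, 144))
    pedigree <- tibble::tibble(child_id = "I1", mother_id = "F1",
                               father_id = males[[1]])
    list(point_samples = dplyr::bind_rows(rows), roster = roster,
         pedigree = pedigree, males = males)
  })
}

oracle_rate <- function(point_samples, infant_id, male_id) {
  denom <- 0L
  num <- 0L
  for (r in seq_len(nrow(point_samples))) {
    row <- point_samples[r, ]
    if (row$infant_id != infant_id) next
    ids <- strsplit(row$member_ids, ";", fixed = TRUE)[[1]]
    if (!male_id %in% ids) next
    denom <- denom + 1L
    if (row$behavior %in% c("GROOM", "PLAY") && !is.na(row$partner_id) &&
        row$partner_id == male_id) {
      num <- num + 1L
    }
  }
  if (denom == 0) 0 else num / denom
}

# --- scaled-down study conditions used for replicate experiments -------
# (problem sizes chosen once for desk-scale Monte-Carlo studies; the
# biological parameters under test are set per-experiment)

calib_assoc_config <- function(seed, father_bias = 1) {
  kinbias::sim_config(
    n_adult_males = 10, n_mothers = 8, years = 5,
    father_bias = father_bias, father_interaction_bias = 1,
    paternity_link = 0, unknown_paternity = 0,
    follow_days_per_month = 1, follow_minutes = 720,
    family_days_per_month = 0, dominance_per_month = 0,
    seed = seed
  )
}

calib_interact_config <- function(seed) {
  kinbias::sim_config(
    n_adult_males = 10, n_mothers = 12, years = 5,
    father_bias = 1, father_interaction_bias = 1, paternity_link = 0,
    unknown_paternity = 0, interaction_rate = 0.01,
    follow_days_per_month = 0, family_days_per_month = 1,
    family_minutes = 120, dominance_per_month = 0,
    seed = seed
  )
}

calib_paternity_config <- function(seed, paternity_link = 0,
                                   father_bias = 1) {
  kinbias::sim_config(
    n_adult_males = 10, n_mothers = 20, years = 9,
    father_bias = father_bias, father_interaction_bias = 1,
    paternity_link = paternity_link, unknown_paternity = 0,
    follow_days_per_month = 1, follow_minutes = 360,
    family_days_per_month = 0, dominance_per_month = 4,
    seed = seed
  )
}

derive_seed <- function(base, i) as.integer((base * 131 + i * 7919) %% 2147483629)
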