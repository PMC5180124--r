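# Synthetic fission-fusion community and observation-protocol simulator.
#
# The generator emulates the study conditions of a long-term East African
# chimpanzee site: a community with ~12 adult males and ~12 mothers, focal
# follows of adult males recording party composition in piecewise-constant
# 30-minute segments, family follows recording infant behaviour at 1-minute
# point samples, a dominance-interaction log driven by a fixed latent
# hierarchy, and genetically assigned paternities drawn from a rank-skewed
# lottery.  Father bias acts multiplicatively on the odds that a
# mother-infant (MI) pair shares the father's party, decaying with infant
# age with a configurable half-life.

#' Simulation configuration
#'
#' Builds and validates the configuration object used by
#' [simulate_community()], [simulate_follows()] and [simulate_study()].
#'
#' @param n_adult_males number of adult males (the study community had
#'   9-14).
#' @param n_mothers number of mothers with dependent infants (12-25 adult
#'   females in the study community).
#' @param years simulated study span in years.
#' @param gregariousness length-2 numeric range; each mother's baseline
#'   probability of sharing a party (per 30-minute segment) is drawn
#'   uniformly from it.  The default `c(0.3, 0.6)` mirrors mothers spending
#'   roughly 40-70% of their time alone.
#' @param father_bias multiplier (>= 1) on the odds that an MI pair shares
#'   the father's party at infant age 0; 1 is the null of no paternal bias.
#' @param bias_halflife half-life, in months of infant age, of the exponent
#'   of the father bias: the odds multiplier at age `a` is
#'   `father_bias ^ (2 ^ (-a / bias_halflife))`.
#' @param interaction_rate per-minute probability that an infant grooms or
#'   plays with a given co-present adult male in late infancy.
#' @param father_interaction_bias multiplier (>= 1) on `interaction_rate`
#'   for fathers in late infancy; 1 is the null.
#' @param early_interaction_rate per-minute interaction probability for all
#'   males in early infancy (near zero: young infants rarely interact with
#'   adult males).
#' @param male_presence baseline probability that a given adult male shares
#'   the family party during a family-follow block.
#' @param paternity_link log-odds coefficient linking the father's
#'   z-standardized association with the mother (over the infant's first 18
#'   months) to his odds of siring her next offspring.  Default 0: the next
#'   sire is drawn from the rank lottery regardless of association.
#' @param rank_skew decay rate of the paternity lottery weights across
#'   ordinal ranks: weight of rank r is `exp(-rank_skew * (r - 1))`.
#' @param elo_noise scale of the latent-strength difference in the
#'   dominance-outcome logistic; larger values give noisier hierarchies.
#' @param unknown_paternity probability that an infant's paternity is
#'   unassigned in the released pedigree.
#' @param maternal_kin_rate probability (capped at 1) that a mother has an
#'   adult maternal brother in the community, making him a maternal uncle
#'   of her infants.
#' @param interbirth_years,interbirth_sd mean and sd (years) of the
#'   interbirth interval, truncated to \[3, 6.5\] years.
#' @param gestation_days gestation length; conception = birth - gestation.
#' @param follow_days_per_month focal-follow days per adult male per month
#'   (0 disables male follows).
#' @param follow_minutes length of a focal-follow day in minutes.
#' @param segment_minutes party composition is piecewise-constant over
#'   segments of this many minutes.
#' @param family_days_per_month family-follow days per infant per month
#'   (0 disables family follows).
#' @param family_minutes length of a family-follow day in minutes.
#' @param dominance_per_month decided dominance interactions per month.
#' @param start_date calendar date of the start of the simulated study.
#' @param seed master integer seed; identical seeds give byte-identical
#'   output bundles.  Internal stages use fixed derived streams so each
#'   stage is independently reproducible.
#' @return a validated list with class `"kb_sim_config"`.
#' @export
sim_config <- function(n_adult_males = 12,
                       n_mothers = 12,
                       years = 8,
                       gregariousness = c(0.3, 0.6),
                       father_bias = 3,
                       bias_halflife = 6,
                       interaction_rate = 5e-4,
                       father_interaction_bias = 3,
                       early_interaction_rate = 2e-5,
                       male_presence = 0.15,
                       paternity_link = 0,
                       rank_skew = 0.4,
                       elo_noise = 1.25,
                       unknown_paternity = 0.1,
                       maternal_kin_rate = 1,
                       interbirth_years = 4.5,
                       interbirth_sd = 0.7,
                       gestation_days = 230,
                       follow_days_per_month = 4,
                       follow_minutes = 720,
                       segment_minutes = 30,
                       family_days_per_month = 1,
                       family_minutes = 240,
                       dominance_per_month = 6,
                       start_date = as.Date("2000-01-01"),
                       seed = 1L) {
  cfg <- list(
    n_adult_males = as.integer(n_adult_males), n_mothers = as.integer(n_mothers),
    years = years, gregariousness = gregariousness, father_bias = father_bias,
    bias_halflife = bias_halflife, interaction_rate = interaction_rate,
    father_interaction_bias = father_interaction_bias,
    early_interaction_rate = early_interaction_rate,
    male_presence = male_presence, paternity_link = paternity_link,
    rank_skew = rank_skew, elo_noise = elo_noise,
    unknown_paternity = unknown_paternity,
    maternal_kin_rate = maternal_kin_rate,
    interbirth_years = interbirth_years, interbirth_sd = interbirth_sd,
    gestation_days = as.integer(gestation_days),
    follow_days_per_month = as.integer(follow_days_per_month),
    follow_minutes = as.integer(follow_minutes),
    segment_minutes = as.integer(segment_minutes),
    family_days_per_month = as.integer(family_days_per_month),
    family_minutes = as.integer(family_minutes),
    dominance_per_month = as.integer(dominance_per_month),
    start_date = as.Date(start_date), seed = as.integer(seed)
  )
  if (cfg$n_adult_males < 1) abort("Infeasible demography: need >= 1 adult male.")
  if (cfg$n_mothers < 1) abort("Infeasible demography: need >= 1 mother.")
  probs <- c(cfg$gregariousness, cfg$male_presence, cfg$interaction_rate,
             cfg$early_interaction_rate, cfg$unknown_paternity)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (cfg$father_bias < 1 || cfg$father_interaction_bias < 1) {
    abort("`father_bias` and `father_interaction_bias` must be >= 1 (1 = null).")
  }
  if (cfg$years * 12 < 42) abort("Study span must cover at least 42 months.")
  if (cfg$follow_minutes %% cfg$segment_minutes != 0 ||
      cfg$family_minutes %% cfg$segment_minutes != 0) {
    abort("Follow lengths must be multiples of `segment_minutes`.")
  }
  structure(cfg, class = "kb_sim_config")
}

# fixed derived seed streams so each stage is independently reproducible
seed_stream <- function(seed, k) {
  as.integer((as.numeric(seed) %% 100000L) * 7919 + k * 104729) %% 2147483629L
}

# odds-scale father bias exponent at a given infant age in months
father_decay <- function(age_months, halflife) 2^(-age_months / halflife)

study_end <- function(config) {
  add_months(config$start_date, as.integer(round(config$years * 12))) - 1L
}

#' Simulate community demography, pedigree and conceptions
#'
#' Draws the roster (adult males with a fixed latent dominance hierarchy,
#' mothers with per-mother gregariousness, their matriline links and
#' infants born across the study span), assigns each infant a sire by a
#' rank-skewed lottery, masks a configurable fraction of paternities as
#' unknown, and builds the conception table of consecutive-infant cases.
#' With a non-null `paternity_link` the next-infant sires are redrawn by
#' [simulate_study()] once association data exist.
#'
#' @param config a [sim_config()].
#' @return a list with class `"kb_community"`: `roster`, `pedigree`,
#'   `conceptions` tibbles plus a `latent` list (true fathers, hierarchy,
#'   gregariousness) used by [simulate_follows()].
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "kb_sim_config"))
  withr::with_seed(seed_stream(config$seed, 1L), {
    start <- config$start_date
    end <- study_end(config)
    span_months <- as.integer(round(config$years * 12))
    n_m <- config$n_adult_males
    n_f <- config$n_mothers

    male_ids <- sprintf("M%02d", seq_len(n_m))
    male_birth <- start - round(runif(n_m, 15, 35) * 365.25)
    strength <- setNames(seq(n_m, 1), male_ids)  # M01 strongest

    gma_ids <- sprintf("G%02d", seq_len(n_f))
    mother_ids <- sprintf("F%02d", seq_len(n_f))
    mother_birth <- start - round(runif(n_f, 13, 30) * 365.25)
    gma_birth <- mother_birth - round(runif(n_f, 15, 25) * 365.25)
    gma_death <- start - round(runif(n_f, 1, 5) * 365.25)
    greg <- setNames(runif(n_f, config$gregariousness[1],
                           config$gregariousness[2]), mother_ids)

    # maternal-kin links: a male may be a mother's maternal brother, which
    # makes him the maternal uncle of her infants
    kin_link <- runif(n_f) < min(1, config$maternal_kin_rate)
    male_mother <- setNames(rep(NA_character_, n_m), male_ids)
    free_males <- male_ids
    for (i in seq_len(n_f)) {
      if (kin_link[i] && length(free_males) > 0) {
        pick <- if (length(free_males) == 1) free_males else
          sample(free_males, 1)
        male_mother[pick] <- gma_ids[i]
        free_males <- setdiff(free_males, pick)
      }
    }

    # births: first birth uniform over the span that leaves a full infancy,
    # later births at truncated-normal interbirth intervals
    ibi_days <- function(n) {
      d <- rnorm(n, config$interbirth_years, config$interbirth_sd)
      round(pmin(pmax(d, 3), 6.5) * 365.25)
    }
    first_window <- as.integer(end - 1278L - start)  # 42 months ~ 1278 days
    births <- vector("list", n_f)
    for (i in seq_len(n_f)) {
      b <- start + sample.int(max(first_window, 1L), 1L) - 1L
      bs <- b
      repeat {
        b <- b + ibi_days(1)
        if (b > end) break
        bs <- c(bs, b)
      }
      births[[i]] <- bs
    }
    infants <- tibble(
      mother_id = rep(mother_ids, lengths(births)),
      birth_date = as.Date(unlist(births), origin = "1970-01-01")
    ) |>
      arrange(birth_date) |>
      mutate(infant_id = sprintf("I%02d", dplyr::row_number()),
             sex = sample(c("M", "F"), dplyr::n(), replace = TRUE))

    # rank-skewed paternity lottery
    lottery_w <- exp(-config$rank_skew * (rank(-strength) - 1))
    sire <- vapply(seq_len(nrow(infants)), function(i) {
      sample(male_ids, 1, prob = lottery_w)
    }, character(1))
    unknown_mask <- runif(nrow(infants)) < config$unknown_paternity
    infants$father_id <- sire
    true_father <- setNames(sire, infants$infant_id)

    roster <- dplyr::bind_rows(
      tibble(id = gma_ids, sex = "F", birth_date = gma_birth,
             death_date = gma_death),
      tibble(id = mother_ids, sex = "F", birth_date = mother_birth,
             death_date = as.Date(NA)),
      tibble(id = male_ids, sex = "M", birth_date = male_birth,
             death_date = as.Date(NA)),
      tibble(id = infants$infant_id, sex = infants$sex,
             birth_date = infants$birth_date, death_date = as.Date(NA))
    ) |>
      mutate(adult_from = default_adult_from(birth_date))

    pedigree <- dplyr::bind_rows(
      tibble(child_id = mother_ids, mother_id = gma_ids,
             father_id = NA_character_),
      tibble(child_id = male_ids, mother_id = unname(male_mother),
             father_id = NA_character_) |>
        filter(!is.na(mother_id)),
      tibble(child_id = infants$infant_id, mother_id = infants$mother_id,
             father_id = ifelse(unknown_mask, NA_character_,
                                infants$father_id))
    )

    conceptions <- infants |>
      group_by(mother_id) |>
      arrange(birth_date, .by_group = TRUE) |>
      mutate(prior_infant_id = dplyr::lag(infant_id)) |>
      ungroup() |>
      filter(!is.na(prior_infant_id)) |>
      transmute(
        mother_id,
        prior_infant_id,
        conception_date = birth_date - config$gestation_days,
        next_infant_id = infant_id,
        sire_id = as.character(ifelse(
          unknown_mask[match(infant_id, infants$infant_id)],
          NA_character_, father_id))
      ) |>
      arrange(conception_date)

    structure(
      list(
        roster = roster, pedigree = pedigree, conceptions = conceptions,
        latent = list(strength = strength, gregariousness = greg,
                      true_father = true_father,
                      unknown_mask = setNames(unknown_mask,
                                              infants$infant_id)),
        config = config
      ),
      class = "kb_community"
    )
  })
}

#' Simulate focal follows, family follows and the dominance log
#'
#' Party membership during male focal follows is resampled in
#' piecewise-constant segments: the odds that an MI pair shares a given
#' male's party are the mother's baseline gregariousness odds, multiplied
#' by `father_bias ^ (2 ^ (-age / bias_halflife))` when the male is the
#' infant's father.  During family follows, co-present adult males interact
#' (groom/play) with the infant at the configured per-minute rates, with
#' the father multiplier applying in late infancy only.  Dominance
#' interactions are decided by a logistic contest on the fixed latent
#' hierarchy.
#'
#' @param community a `kb_community` from [simulate_community()].
#' @param config the same [sim_config()].
#' @return list of tibbles `follows`, `point_samples`, `dominance`.
#' @export
simulate_follows <- function(community, config) {
  stopifnot(inherits(community, "kb_community"))
  withr::with_seed(seed_stream(config$seed, 2L), {
    start <- config$start_date
    span_months <- as.integer(round(config$years * 12))
    male_ids <- names(community$latent$strength)
    greg <- community$latent$gregariousness
    true_father <- community$latent$true_father
    seg_min <- config$segment_minutes

    mi <- community$pedigree |>
      filter(child_id %in% names(true_father)) |>
      transmute(
        mother_id, infant_id = child_id,
        infant_birth = community$roster$birth_date[
          match(child_id, community$roster$id)],
        father = unname(true_father[child_id]),
        g = unname(greg[mother_id])
      ) |>
      mutate(end42 = add_months(infant_birth, 42L) - 1L)

    month_starts <- add_months(start, 0:(span_months - 1L))

    follows <- kb_sim_male_follows(config, male_ids, mi, month_starts)
    point_samples <- kb_sim_family_follows(config, male_ids, mi, month_starts)
    dominance <- kb_sim_dominance(config, community, month_starts)

    list(follows = follows, point_samples = point_samples,
         dominance = dominance)
  })
}

kb_sim_male_follows <- function(config, male_ids, mi, month_starts) {
  empty <- tibble(focal_id = character(), date = as.Date(character()),
                  start_min = integer(), end_min = integer(),
                  member_ids = character())
  fdpm <- config$follow_days_per_month
  if (fdpm <= 0) return(empty)
  seg_min <- config$segment_minutes
  k_seg <- config$follow_minutes %/% seg_min

  sched <- tidyr::expand_grid(focal_id = male_ids, month = month_starts)
  day_off <- t(vapply(seq_len(nrow(sched)),
                      function(i) sort(sample.int(28L, fdpm)) - 1L,
                      integer(fdpm)))
  days <- tibble(
    focal_id = rep(sched$focal_id, each = fdpm),
    date = rep(sched$month, each = fdpm) + as.vector(t(day_off))
  ) |>
    mutate(day_uid = dplyr::row_number())

  day_pairs <- dplyr::inner_join(
    days, mi, by = dplyr::join_by(between(date, infant_birth, end42))
  )
  seg_pairs <- day_pairs[rep(seq_len(nrow(day_pairs)), each = k_seg), ]
  seg_pairs$seg_idx <- rep.int(seq_len(k_seg) - 1L, nrow(day_pairs))
  age_m <- as.numeric(seg_pairs$date - seg_pairs$infant_birth) / 30.4375
  logit_p <- qlogis(seg_pairs$g) +
    father_decay(age_m, config$bias_halflife) * log(config$father_bias) *
      (seg_pairs$focal_id == seg_pairs$father)
  present <- runif(nrow(seg_pairs)) < plogis(logit_p)
  seg_pres <- seg_pairs[present, c("day_uid", "seg_idx", "mother_id",
                                   "infant_id")]
  seg_pres$seg_uid <- (seg_pres$day_uid - 1L) * k_seg + seg_pres$seg_idx + 1L
  members <- seg_pres |>
    mutate(pair_str = paste(mother_id, infant_id, sep = ";")) |>
    group_by(seg_uid) |>
    summarise(others = paste(pair_str, collapse = ";"), .groups = "drop")

  segs <- days[rep(seq_len(nrow(days)), each = k_seg), ]
  segs$seg_idx <- rep.int(seq_len(k_seg) - 1L, nrow(days))
  segs$seg_uid <- (segs$day_uid - 1L) * k_seg + segs$seg_idx + 1L
  segs |>
    left_join(members, by = "seg_uid") |>
    transmute(
      focal_id, date,
      start_min = seg_idx * seg_min,
      end_min = (seg_idx + 1L) * seg_min,
      member_ids = ifelse(is.na(others), focal_id,
                          paste(focal_id, others, sep = ";"))
    )
}

kb_sim_family_follows <- function(config, male_ids, mi, month_starts) {
  empty <- tibble(infant_id = character(), date = as.Date(character()),
                  minute = integer(), behavior = character(),
                  partner_id = character(), member_ids = character())
  fdpm <- config$family_days_per_month
  if (fdpm <= 0 || nrow(mi) == 0) return(empty)
  seg_min <- config$segment_minutes
  n_blocks_day <- config$family_minutes %/% seg_min
  end <- study_end(config)

  # one row per (infant, age-month) follow day within the study span
  sched <- tidyr::expand_grid(row = seq_len(nrow(mi)), age_month = 0:41) |>
    mutate(
      infant_id = mi$infant_id[row], mother_id = mi$mother_id[row],
      infant_birth = mi$infant_birth[row], father = mi$father[row]
    ) |>
    mutate(month_start = add_months(infant_birth, age_month)) |>
    filter(month_start + 27L <= end)
  if (nrow(sched) == 0) return(empty)
  sched <- sched[rep(seq_len(nrow(sched)), each = fdpm), ]
  sched$date <- sched$month_start + (sample.int(28L, nrow(sched),
                                                replace = TRUE) - 1L)
  sched$day_uid <- seq_len(nrow(sched))

  blocks <- sched[rep(seq_len(nrow(sched)), each = n_blocks_day), ]
  blocks$block_idx <- rep.int(seq_len(n_blocks_day) - 1L, nrow(sched))
  blocks$block_uid <- seq_len(nrow(blocks))

  # adult-male co-presence per block
  bm <- blocks[rep(seq_len(nrow(blocks)), each = length(male_ids)),
               c("block_uid", "infant_id", "father", "infant_birth", "date")]
  bm$male_id <- rep.int(male_ids, nrow(blocks))
  age_m <- as.numeric(bm$date - bm$infant_birth) / 30.4375
  logit_p <- qlogis(config$male_presence) +
    father_decay(age_m, config$bias_halflife) * log(config$father_bias) *
      (bm$male_id == bm$father)
  bm$present <- runif(nrow(bm)) < plogis(logit_p)
  bm_pres <- bm[bm$present, ]

  # interaction minutes per (block, co-present male)
  early <- bm_pres$date < add_months_u(bm_pres$infant_birth, 6L)
  lambda <- ifelse(early, config$early_interaction_rate,
                   config$interaction_rate *
                     ifelse(bm_pres$male_id == bm_pres$father,
                            config$father_interaction_bias, 1))
  n_int <- rbinom(nrow(bm_pres), seg_min, lambda)
  has_int <- which(n_int > 0)
  inter <- if (length(has_int)) {
    rows <- rep(has_int, n_int[has_int])
    offs <- unlist(lapply(has_int, function(i) sample.int(seg_min, n_int[i])),
                   use.names = FALSE) - 1L
    tibble(
      block_uid = bm_pres$block_uid[rows],
      partner_id = bm_pres$male_id[rows],
      minute_in_block = offs,
      behavior = sample(c("GROOM", "PLAY"), length(rows), replace = TRUE)
    ) |>
      distinct(block_uid, minute_in_block, .keep_all = TRUE)
  } else {
    tibble(block_uid = integer(), partner_id = character(),
           minute_in_block = integer(), behavior = character())
  }

  male_str <- bm_pres |>
    group_by(block_uid) |>
    summarise(males = paste(male_id, collapse = ";"), .groups = "drop")
  blocks <- blocks |>
    left_join(male_str, by = "block_uid") |>
    mutate(member_ids = ifelse(
      is.na(males), paste(infant_id, mother_id, sep = ";"),
      paste(infant_id, mother_id, males, sep = ";")
    ))

  samples <- blocks[rep(seq_len(nrow(blocks)), each = seg_min),
                    c("block_uid", "infant_id", "date", "block_idx",
                      "member_ids")]
  samples$minute_in_block <- rep.int(seq_len(seg_min) - 1L, nrow(blocks))
  samples |>
    left_join(inter, by = c("block_uid", "minute_in_block")) |>
    transmute(
      infant_id, date,
      minute = block_idx * seg_min + minute_in_block,
      behavior = ifelse(is.na(behavior), "NONE", behavior),
      partner_id,
      member_ids
    )
}

kb_sim_dominance <- function(config, community, month_starts) {
  empty <- tibble(date = as.Date(character()), winner_id = character(),
                  loser_id = character())
  n_ev_m <- config$dominance_per_month
  male_ids <- names(community$latent$strength)
  if (n_ev_m <= 0 || length(male_ids) < 2) return(empty)
  s <- community$latent$strength
  n_ev <- n_ev_m * length(month_starts)
  i <- sample.int(length(male_ids), n_ev, replace = TRUE)
  j <- sample.int(length(male_ids) - 1L, n_ev, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)
  p_i <- plogis((s[i] - s[j]) / config$elo_noise)
  i_wins <- runif(n_ev) < p_i
  tibble(
    date = rep(month_starts, each = n_ev_m) +
      (sample.int(28L, n_ev, replace = TRUE) - 1L),
    winner_id = ifelse(i_wins, male_ids[i], male_ids[j]),
    loser_id = ifelse(i_wins, male_ids[j], male_ids[i])
  ) |>
    arrange(date)
}

#' Simulate a complete study bundle
#'
#' Runs [simulate_community()] and [simulate_follows()] and assembles the
#' full observation bundle.  With a non-null `paternity_link` (gamma), the
#' sires of next-born infants are redrawn with the prior father's lottery
#' odds multiplied by `exp(gamma * z)`, where `z` is the father-mother
#' z-standardized association over the prior infant's first 18 months as
#' computed by the package's own association machinery on the simulated
#' follows; the follows are then re-simulated (same random stream) so that
#' paternal party bias reflects the final pedigree.
#'
#' @param config a [sim_config()].
#' @return a `kb_bundle`: `roster`, `pedigree`, `conceptions`, `follows`,
#'   `point_samples`, `dominance` tibbles plus the `config`.  The
#'   generator's latent state is attached as attribute `"latent"` for
#'   validation studies.
#' @export
simulate_study <- function(config = sim_config()) {
  community <- simulate_community(config)
  obs <- simulate_follows(community, config)

  if (config$paternity_link != 0 && nrow(community$conceptions) > 0) {
    community <- kb_redraw_sires(community, obs, config)
    obs <- simulate_follows(community, config)
  }

  bundle <- structure(
    list(
      roster = community$roster, pedigree = community$pedigree,
      conceptions = community$conceptions, follows = obs$follows,
      point_samples = obs$point_samples, dominance = obs$dominance,
      config = config
    ),
    class = "kb_bundle"
  )
  attr(bundle, "latent") <- community$latent
  bundle
}

# Redraw next-infant sires with log-odds gamma * z on the prior father's
# lottery weight; processed in conception-date order so that a redrawn sire
# propagates to later cases of the same mother.
kb_redraw_sires <- function(community, obs, config) {
  con <- community$conceptions
  true_father <- community$latent$true_father
  mask <- community$latent$unknown_mask
  strength <- community$latent$strength
  male_ids <- names(strength)
  lottery_w <- exp(-config$rank_skew * (rank(-strength) - 1))

  tmp_bundle <- structure(
    list(roster = community$roster, pedigree = community$pedigree,
         follows = obs$follows),
    class = "kb_bundle"
  )
  prior_birth <- community$roster$birth_date[
    match(con$prior_infant_id, community$roster$id)]
  windows <- tidyr::expand_grid(
    w = seq_len(nrow(con)), male_id = male_ids
  ) |>
    mutate(
      window_id = paste0("pw", w, "_", male_id),
      anchor_infant_id = con$prior_infant_id[w],
      start = prior_birth[w],
      end = add_months(prior_birth[w], 18L) - 1L,
      bin = NA_integer_
    ) |>
    select(-w)
  recs <- association_records(tmp_bundle, windows, min_minutes = 60)
  z_tab <- recs |>
    filter(infant_id == anchor_infant_id) |>
    select(male_id, anchor_infant_id, z)

  withr::with_seed(seed_stream(config$seed, 3L), {
    for (r in seq_len(nrow(con))) {
      f_prior <- unname(true_father[con$prior_infant_id[r]])
      zi <- z_tab$z[z_tab$male_id == f_prior &
                      z_tab$anchor_infant_id == con$prior_infant_id[r]]
      zi <- if (length(zi) == 1 && is.finite(zi)) zi else 0
      w <- lottery_w
      w[male_ids == f_prior] <- w[male_ids == f_prior] *
        exp(config$paternity_link * zi)
      new_sire <- sample(male_ids, 1, prob = w)
      nid <- con$next_infant_id[r]
      true_father[nid] <- new_sire
      masked <- unname(mask[nid])
      con$sire_id[r] <- if (masked) NA_character_ else new_sire
      community$pedigree$father_id[community$pedigree$child_id == nid] <-
        if (masked) NA_character_ else new_sire
    }
  })
  community$conceptions <- con
  community$latent$true_father <- true_father
  community
}
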