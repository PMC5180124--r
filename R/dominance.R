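# Elo-rating dominance hierarchy from a decided-interaction log.
#
# The common animal-dominance parameterization: expected score of the
# winner E_w = 1 / (1 + 10^((R_l - R_w)/400)); the winner gains
# k * (1 - E_w) and the loser loses the same amount, so the rating sum is
# conserved at every update.  Higher ratings mean higher positions; the
# ordinal rank at a date is the rating order among adult males alive then.

#' Single Elo update
#'
#' @param rating_winner,rating_loser current ratings.
#' @param k k-factor (> 0), the maximum rating change per interaction.
#' @return named numeric vector `c(winner =, loser =)` of updated ratings.
#' @examples
#' elo_update(1000, 1000, k = 100)  # winner 1050, loser 950
#' @export
elo_update <- function(rating_winner, rating_loser, k = 100) {
  stopifnot(is.finite(rating_winner), is.finite(rating_loser), k > 0)
  e_w <- 1 / (1 + 10^((rating_loser - rating_winner) / 400))
  delta <- k * (1 - e_w)
  c(winner = rating_winner + delta, loser = rating_loser - delta)
}

#' Elo rating history from a dominance-interaction log
#'
#' Replays the decided interactions in date order (ties in date keep log
#' order) from a common start rating.  Males enter at `start_rating` on
#' their first appearance.
#'
#' @param dominance tibble with `date`, `winner_id`, `loser_id`.
#' @param start_rating starting rating for every male (default 1000).
#' @param k_factor k-factor for every update (default 100).
#' @return an object of class `"kb_elo"`: list with `history` (one row per
#'   interaction: date, ids, post-update ratings), `ratings` (final named
#'   vector), `first_seen` (named date vector) and the parameters.
#' @export
elo_history <- function(dominance, start_rating = 1000, k_factor = 100) {
  dom <- dominance |> arrange(date)
  ids <- unique(c(dom$winner_id, dom$loser_id))
  ratings <- setNames(rep(start_rating, length(ids)), ids)
  n <- nrow(dom)
  hist <- tibble(
    seq = seq_len(n), date = dom$date,
    winner_id = dom$winner_id, loser_id = dom$loser_id,
    rating_winner = NA_real_, rating_loser = NA_real_
  )
  for (i in seq_len(n)) {
    w <- dom$winner_id[[i]]; l <- dom$loser_id[[i]]
    upd <- elo_update(ratings[[w]], ratings[[l]], k_factor)
    ratings[[w]] <- upd[["winner"]]
    ratings[[l]] <- upd[["loser"]]
    hist$rating_winner[[i]] <- upd[["winner"]]
    hist$rating_loser[[i]] <- upd[["loser"]]
  }
  first_seen <- dom |>
    tidyr::pivot_longer(c(winner_id, loser_id), values_to = "id") |>
    group_by(id) |>
    summarise(first_seen = min(date), .groups = "drop")
  structure(
    list(
      history = hist,
      ratings = ratings,
      first_seen = setNames(first_seen$first_seen, first_seen$id),
      start_rating = start_rating, k_factor = k_factor
    ),
    class = "kb_elo"
  )
}

#' Ordinal male ranks at a date
#'
#' Replays the Elo history up to (and including) `date` and ranks the
#' adult males alive on that date by rating (rank 1 = highest).  Males
#' without any interaction yet sit at the start rating.  Ties are broken
#' deterministically by earlier first-interaction date, then id order.
#'
#' @param elo a `"kb_elo"` object from [elo_history()].
#' @param date query date.
#' @param roster roster tibble (defines who is an adult male alive then).
#' @return tibble with `male_id`, `rating`, `rank`.
#' @export
ordinal_ranks_at <- function(elo, date, roster) {
  date <- as.Date(date)
  males <- adult_males_on(roster, date)
  if (nrow(males) == 0) abort(paste0("No adult males alive on ", date, "."))

  ratings <- setNames(rep(elo$start_rating, nrow(males)), males$id)
  h <- elo$history |> filter(date <= !!date)
  if (nrow(h) > 0) {
    for (i in seq_len(nrow(h))) {
      w <- h$winner_id[[i]]; l <- h$loser_id[[i]]
      if (w %in% names(ratings)) ratings[[w]] <- h$rating_winner[[i]]
      if (l %in% names(ratings)) ratings[[l]] <- h$rating_loser[[i]]
    }
  }
  first_seen <- elo$first_seen[names(ratings)]
  first_seen[is.na(first_seen)] <- far_future
  ord <- order(-unname(ratings), unname(first_seen), names(ratings))
  tibble(
    male_id = names(ratings)[ord],
    rating = unname(ratings)[ord],
    rank = seq_along(ord)
  )
}
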