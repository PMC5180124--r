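# Kin classification of adult males relative to infants.
#
# An adult male is classified, relative to a given infant, as the infant's
# FATHER, as MATERNAL_KIN (adult maternal brother, maternal uncle or
# maternal cousin of the infant, i.e. kin through mother-links up to
# grandmother sharing), as NON_KIN, or as UNKNOWN when the infant's
# paternity is unassigned and no maternal relation is established.
# FATHER takes precedence over any coincidental maternal relation.

#' Kin category levels
#'
#' Factor levels used for male-infant kin categories, in precedence order.
#' @export
kin_levels <- c("FATHER", "MATERNAL_KIN", "NON_KIN", "UNKNOWN")

# named lookup child -> mother / father from a pedigree tibble
mother_lookup <- function(pedigree) {
  setNames(as.character(pedigree$mother_id), pedigree$child_id)
}
father_lookup <- function(pedigree) {
  setNames(as.character(pedigree$father_id), pedigree$child_id)
}

# follow mother-links to the matriline root (used by widen = TRUE)
matriline_root <- function(ids, mo) {
  root <- ids
  repeat {
    nxt <- unname(mo[root])
    step <- !is.na(nxt)
    if (!any(step)) break
    root[step] <- nxt[step]
  }
  root
}

#' Classify an adult male relative to an infant
#'
#' Pure function of (male, infant, pedigree).  A male is the infant's
#' `FATHER` when the pedigree lists him as such; `MATERNAL_KIN` when he is
#' an adult maternal brother (shares the infant's mother), maternal uncle
#' (son of the infant's maternal grandmother) or maternal cousin (his
#' mother and the infant's mother share a mother); `UNKNOWN` when the
#' infant's paternity is unassigned and no maternal relation holds; and
#' `NON_KIN` otherwise.  `FATHER` takes precedence over any coincidental
#' maternal relation.
#'
#' @param male_id,infant_id character vectors (recycled to common length).
#' @param pedigree tibble with columns `child_id`, `mother_id`, `father_id`.
#' @param roster optional roster tibble; when supplied, both ids must be
#'   present and the male must have `sex == "M"`, otherwise an error names
#'   the offending id.
#' @param widen logical; when `TRUE`, any male sharing the infant's
#'   matriline root (arbitrary depth of mother-links) is `MATERNAL_KIN`.
#'   Default `FALSE`: only the three named relations count, deeper
#'   matrilineal relatives fall to `NON_KIN`.
#' @return a factor with levels [kin_levels].
#' @examples
#' ped <- tibble::tibble(
#'   child_id = c("I1", "F1"), mother_id = c("F1", "G1"),
#'   father_id = c("M1", NA)
#' )
#' classify_kin("M1", "I1", ped)  # FATHER
#' @export
classify_kin <- function(male_id, infant_id, pedigree, roster = NULL,
                         widen = FALSE) {
  n <- max(length(male_id), length(infant_id))
  male_id <- rep_len(as.character(male_id), n)
  infant_id <- rep_len(as.character(infant_id), n)

  if (!is.null(roster)) {
    missing_ids <- setdiff(unique(c(male_id, infant_id)), roster$id)
    if (length(missing_ids) > 0) {
      abort(paste0("Unknown id(s) not in roster: ",
                   paste(missing_ids, collapse = ", ")))
    }
    sex_of <- setNames(roster$sex, roster$id)
    not_male <- unique(male_id[sex_of[male_id] != "M"])
    if (length(not_male) > 0) {
      abort(paste0("Id(s) passed as males are not male in the roster: ",
                   paste(not_male, collapse = ", ")))
    }
  }

  mo <- mother_lookup(pedigree)
  fa <- father_lookup(pedigree)

  fa_i <- unname(fa[infant_id])
  mo_i <- unname(mo[infant_id])
  mo_m <- unname(mo[male_id])
  gm_i <- unname(mo[mo_i])
  gm_m <- unname(mo[mo_m])

  is_father <- !is.na(fa_i) & fa_i == male_id
  brother <- !is.na(mo_m) & !is.na(mo_i) & mo_m == mo_i
  uncle <- !is.na(mo_m) & !is.na(gm_i) & mo_m == gm_i
  cousin <- !is.na(gm_m) & !is.na(gm_i) & gm_m == gm_i & !brother & !uncle
  maternal <- brother | uncle | cousin
  if (widen) {
    root_i <- matriline_root(infant_id, mo)
    root_m <- matriline_root(male_id, mo)
    linked_m <- !is.na(mo_m) | male_id %in% pedigree$child_id
    linked_i <- !is.na(mo_i)
    maternal <- maternal |
      (linked_m & linked_i & root_m == root_i & root_m != male_id)
  }

  out <- ifelse(is_father, "FATHER",
         ifelse(maternal, "MATERNAL_KIN",
         ifelse(is.na(fa_i), "UNKNOWN", "NON_KIN")))
  factor(out, levels = kin_levels)
}

# kin category for each row of a (male_id, infant_id) tibble
kin_categories <- function(pairs, pedigree, widen = FALSE) {
  pairs |>
    mutate(kin = classify_kin(.data$male_id, .data$infant_id, pedigree,
                              widen = widen))
}
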