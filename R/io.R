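# Readers, writers and validation for the six tabular inputs.
#
# All files are plain CSV; lines starting with '#' are treated as comments
# (output files carry one such provenance line).  Dates are ISO-8601.
# member_ids columns hold semicolon-joined individual ids.

kb_col_types <- list(
  roster = readr::cols(
    id = readr::col_character(), sex = readr::col_character(),
    birth_date = readr::col_date(), death_date = readr::col_date(),
    adult_from = readr::col_date()
  ),
  pedigree = readr::cols(
    child_id = readr::col_character(), mother_id = readr::col_character(),
    father_id = readr::col_character()
  ),
  follows = readr::cols(
    focal_id = readr::col_character(), date = readr::col_date(),
    start_min = readr::col_integer(), end_min = readr::col_integer(),
    member_ids = readr::col_character()
  ),
  point_samples = readr::cols(
    infant_id = readr::col_character(), date = readr::col_date(),
    minute = readr::col_integer(), behavior = readr::col_character(),
    partner_id = readr::col_character(), member_ids = readr::col_character()
  ),
  dominance = readr::cols(
    date = readr::col_date(), winner_id = readr::col_character(),
    loser_id = readr::col_character()
  ),
  conceptions = readr::cols(
    mother_id = readr::col_character(), prior_infant_id = readr::col_character(),
    conception_date = readr::col_date(), next_infant_id = readr::col_character(),
    sire_id = readr::col_character()
  )
)

kb_read_one <- function(path, what) {
  readr::read_csv(path, col_types = kb_col_types[[what]], comment = "#",
                  progress = FALSE, show_col_types = FALSE)
}

#' Read a roster table
#'
#' `roster.csv` lists every individual with `id`, `sex` (M/F), `birth_date`,
#' `death_date` (empty = still alive) and `adult_from` (empty = derived as
#' birth date + 12 years, the adulthood threshold).
#'
#' @param path path to `roster.csv`.
#' @return a tibble with `adult_from` filled in.
#' @export
read_roster <- function(path) {
  out <- kb_read_one(path, "roster")
  out |>
    mutate(adult_from = dplyr::coalesce(adult_from,
                                        default_adult_from(birth_date)))
}

#' @rdname read_roster
#' @export
read_pedigree <- function(path) kb_read_one(path, "pedigree")

#' @rdname read_roster
#' @export
read_follows <- function(path) kb_read_one(path, "follows")

#' @rdname read_roster
#' @export
read_point_samples <- function(path) kb_read_one(path, "point_samples")

#' @rdname read_roster
#' @export
read_dominance <- function(path) kb_read_one(path, "dominance")

#' @rdname read_roster
#' @export
read_conceptions <- function(path) kb_read_one(path, "conceptions")

kb_files <- c(
  roster = "roster.csv", pedigree = "pedigree.csv", follows = "follows.csv",
  point_samples = "point_samples.csv", dominance = "dominance.csv",
  conceptions = "conceptions.csv"
)

#' Read a full observation-data bundle from a directory
#'
#' Reads the six CSV tables (`roster.csv`, `pedigree.csv`, `follows.csv`,
#' `point_samples.csv`, `dominance.csv`, `conceptions.csv`), validates all
#' structural invariants, and returns them as a bundle.
#'
#' @param dir directory containing the six files.
#' @param validate run [validate_bundle()] (default `TRUE`).
#' @return a list of six tibbles with class `"kb_bundle"`.
#' @export
read_bundle <- function(dir, validate = TRUE) {
  paths <- setNames(file.path(dir, kb_files), names(kb_files))
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(paste0("Missing input file(s): ",
                 paste(kb_files[missing], collapse = ", ")))
  }
  bundle <- list(
    roster = read_roster(paths[["roster"]]),
    pedigree = read_pedigree(paths[["pedigree"]]),
    follows = read_follows(paths[["follows"]]),
    point_samples = read_point_samples(paths[["point_samples"]]),
    dominance = read_dominance(paths[["dominance"]]),
    conceptions = read_conceptions(paths[["conceptions"]])
  )
  class(bundle) <- "kb_bundle"
  if (validate) validate_bundle(bundle)
  bundle
}

#' Write an observation-data bundle to a directory
#'
#' Writes the six CSV tables, each prefixed with a comment line recording
#' the package version and configuration hash for provenance.
#'
#' @param bundle a `kb_bundle` (see [read_bundle()], [simulate_study()]).
#' @param dir output directory (created if needed).
#' @param config optional configuration object; its [rlang::hash()] is
#'   recorded in the header comment.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hash <- if (is.null(config)) "none" else rlang::hash(config)
  header <- sprintf("# kinbias %s; config_hash=%s",
                    as.character(utils::packageVersion("kinbias")), hash)
  for (nm in names(kb_files)) {
    path <- file.path(dir, kb_files[[nm]])
    writeLines(header, path)
    readr::write_csv(bundle[[nm]], path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  invisible(dir)
}

# --- validation ---------------------------------------------------------

kb_violation <- function(file, row, field, message) {
  tibble(file = file, row = as.integer(row), field = field, message = message)
}

#' Validate an observation-data bundle
#'
#' Checks every structural invariant of the input tables: roster date
#' ordering and sex codes, pedigree mother existence and acyclicity,
#' non-overlapping sorted follow intervals containing the focal, point
#' samples whose groom/play records name a partner present in the party,
#' and dominance/conception referential integrity.  On any violation an
#' error lists the file, row and field of (up to) the first ten offending
#' records.
#'
#' @param bundle a `kb_bundle`.
#' @return the bundle, invisibly, when valid.
#' @export
validate_bundle <- function(bundle) {
  v <- list()
  roster <- bundle$roster
  ped <- bundle$pedigree

  bad_sex <- which(!roster$sex %in% c("M", "F"))
  if (length(bad_sex)) v <- c(v, list(kb_violation(
    "roster.csv", bad_sex, "sex", "sex must be 'M' or 'F'")))
  bad_adult <- which(!is.na(roster$adult_from) &
                       roster$birth_date >= roster$adult_from)
  if (length(bad_adult)) v <- c(v, list(kb_violation(
    "roster.csv", bad_adult, "adult_from", "birth_date must precede adult_from")))
  bad_death <- which(!is.na(roster$death_date) &
                       roster$death_date < roster$birth_date)
  if (length(bad_death)) v <- c(v, list(kb_violation(
    "roster.csv", bad_death, "death_date", "death_date precedes birth_date")))

  no_mother <- which(!ped$mother_id %in% roster$id)
  if (length(no_mother)) v <- c(v, list(kb_violation(
    "pedigree.csv", no_mother, "mother_id", "mother not in roster")))
  no_child <- which(!ped$child_id %in% roster$id)
  if (length(no_child)) v <- c(v, list(kb_violation(
    "pedigree.csv", no_child, "child_id", "child not in roster")))
  # acyclicity of mother-links
  mo <- mother_lookup(ped)
  for (i in seq_along(ped$child_id)) {
    seen <- character()
    cur <- ped$child_id[[i]]
    while (!is.na(cur)) {
      if (cur %in% seen) {
        v <- c(v, list(kb_violation("pedigree.csv", i, "mother_id",
                                    "individual is its own ancestor")))
        break
      }
      seen <- c(seen, cur)
      cur <- unname(mo[cur])
    }
  }

  fol <- bundle$follows
  if (nrow(fol) > 0) {
    bad_len <- which(fol$end_min <= fol$start_min)
    if (length(bad_len)) v <- c(v, list(kb_violation(
      "follows.csv", bad_len, "end_min", "end_min must exceed start_min")))
    focal_in <- map2_lgl_(fol$focal_id, fol$member_ids,
                          function(f, m) f %in% strsplit(m, ";", fixed = TRUE)[[1]])
    if (any(!focal_in)) v <- c(v, list(kb_violation(
      "follows.csv", which(!focal_in), "member_ids", "focal not in member_ids")))
    ovl <- fol |>
      mutate(.row = dplyr::row_number()) |>
      arrange(focal_id, date, start_min) |>
      group_by(focal_id, date) |>
      mutate(.overlap = start_min < dplyr::lag(end_min, default = -1L)) |>
      ungroup() |>
      filter(.data$.overlap)
    if (nrow(ovl)) v <- c(v, list(kb_violation(
      "follows.csv", ovl$.row, "start_min",
      paste0("overlapping intervals on ", ovl$date, " for focal ", ovl$focal_id))))
  }

  ps <- bundle$point_samples
  if (nrow(ps) > 0) {
    bad_beh <- which(!ps$behavior %in% c("GROOM", "PLAY", "OTHER", "NONE"))
    if (length(bad_beh)) v <- c(v, list(kb_violation(
      "point_samples.csv", bad_beh, "behavior", "unknown behavior code")))
    soc <- ps$behavior %in% c("GROOM", "PLAY")
    no_part <- which(soc & is.na(ps$partner_id))
    if (length(no_part)) v <- c(v, list(kb_violation(
      "point_samples.csv", no_part, "partner_id",
      "groom/play sample without partner")))
    with_part <- which(soc & !is.na(ps$partner_id))
    if (length(with_part)) {
      ok <- map2_lgl_(ps$partner_id[with_part], ps$member_ids[with_part],
                      function(p, m) p %in% strsplit(m, ";", fixed = TRUE)[[1]])
      if (any(!ok)) v <- c(v, list(kb_violation(
        "point_samples.csv", with_part[!ok], "partner_id",
        "partner not in member_ids")))
    }
  }

  dom <- bundle$dominance
  if (nrow(dom) > 0) {
    bad <- which(dom$winner_id == dom$loser_id |
                   !dom$winner_id %in% roster$id | !dom$loser_id %in% roster$id)
    if (length(bad)) v <- c(v, list(kb_violation(
      "dominance.csv", bad, "winner_id", "invalid contestant pair")))
  }

  con <- bundle$conceptions
  if (nrow(con) > 0) {
    bad <- which(!con$mother_id %in% roster$id)
    if (length(bad)) v <- c(v, list(kb_violation(
      "conceptions.csv", bad, "mother_id", "mother not in roster")))
  }

  violations <- if (length(v)) dplyr::bind_rows(v) else
    kb_violation(character(), integer(), character(), character())
  if (nrow(violations) > 0) {
    shown <- utils::head(violations, 10)
    msg <- paste0(
      "Bundle validation failed (", nrow(violations), " violation(s)):\n",
      paste0("  ", shown$file, " row ", shown$row, " [", shown$field, "]: ",
             shown$message, collapse = "\n")
    )
    abort(msg, class = "kb_validation_error", violations = violations)
  }
  invisible(bundle)
}

# small vapply helper (avoids importing purrr::map2_lgl name clash in checks)
map2_lgl_ <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), logical(1))
}

# long format of follow segments: one row per (segment, member)
follow_segments <- function(follows) {
  follows |>
    mutate(seg_uid = dplyr::row_number(), minutes = end_min - start_min)
}

segment_members <- function(segments) {
  parts <- strsplit(segments$member_ids, ";", fixed = TRUE)
  idx <- rep.int(seq_along(parts), lengths(parts))
  tibble(
    seg_uid = segments$seg_uid[idx],
    focal_id = segments$focal_id[idx],
    date = segments$date[idx],
    minutes = segments$minutes[idx],
    member = unlist(parts, use.names = FALSE)
  )
}

#' @export
print.kb_bundle <- function(x, ...) {
  cat("<kb_bundle>\n")
  for (nm in names(kb_files)) {
    cat(sprintf("  %-14s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
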