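# broom-style tidy()/glance() methods for the fitted-model classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the association mixed-model fit
#'
#' @param x a `"kb_assoc_fit"`.
#' @param effects `"anova"` (default: one row per fixed term with its
#'   F-test) or `"fixed"` (one row per coefficient).
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.kb_assoc_fit <- function(x, effects = c("anova", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "anova") return(x$anova)
  s <- coef(summary(x$fit))
  out <- tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"]
  )
  if ("df" %in% colnames(s)) out$df <- s[, "df"]
  tcol <- intersect(c("t value"), colnames(s))
  if (length(tcol)) out$statistic <- s[, tcol]
  pcol <- intersect(c("Pr(>|t|)"), colnames(s))
  if (length(pcol)) out$p_value <- s[, pcol]
  out
}

#' @rdname tidy.kb_assoc_fit
#' @export
glance.kb_assoc_fit <- function(x, ...) {
  tibble(
    nobs = nrow(x$data),
    n_males = dplyr::n_distinct(x$data$male_id),
    n_mothers = dplyr::n_distinct(x$data$mother_id),
    n_infants = dplyr::n_distinct(x$data$infant_id),
    sigma = stats::sigma(x$fit),
    random_effects = x$random_effects,
    singular = x$singular
  )
}

#' Tidy the paternity model fit
#'
#' @param x a `"kb_paternity_fit"`.
#' @param ... unused.
#' @return a tibble with one row per fixed term (Wald chi-square tests).
#' @export
tidy.kb_paternity_fit <- function(x, ...) x$wald

#' @rdname tidy.kb_paternity_fit
#' @export
glance.kb_paternity_fit <- function(x, ...) {
  tibble(
    n_known = x$n_known,
    n_pass = x$n_pass,
    n_same_sire = sum(x$cases$same_sire),
    method = x$method
  )
}

#' @export
print.kb_assoc_fit <- function(x, ...) {
  cat("<kb_assoc_fit> z-standardized association ~ kin * age_bin",
      if (x$random_effects) "+ (1|male) + (1|mother) + (1|infant)" else "",
      "\n")
  print(x$anova)
  invisible(x)
}

#' @export
print.kb_paternity_fit <- function(x, ...) {
  cat("<kb_paternity_fit> same_sire ~ z + rank (", x$method, ")\n", sep = "")
  cat("cases: ", x$n_pass, " of ", x$n_known, " known-paternity cases\n",
      sep = "")
  print(x$wald)
  invisible(x)
}
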