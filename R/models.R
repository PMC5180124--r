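# The three statistical models fitted on pipeline outputs:
#  * a Gaussian mixed model of z-standardized association with fixed
#    effects kin category, infant age bin and their interaction, and
#    crossed random intercepts for male, mother and infant (fitted for the
#    within-period and the between-period dataset);
#  * Tukey-style within-bin contrasts of FATHER vs NON_KIN;
#  * a binomial mixed model of whether the same male sires the mother's
#    next offspring, with the father-mother z-association over the prior
#    infant's first 18 months and the father's ordinal Elo rank at
#    conception as predictors and mother/father random intercepts.
# Estimation is delegated to lme4/lmerTest (REML + Satterthwaite) and
# emmeans; the module owns model construction, filters, contrasts and
# reporting.

kb_prepare_lmm_data <- function(table, include_sex = FALSE, roster = NULL) {
  data <- table |>
    mutate(
      kin = factor(as.character(kin), levels = c("FATHER", "NON_KIN")),
      age_bin = droplevels(factor(age_bin, levels = 0:6))
    )
  if (include_sex) {
    if (is.null(roster)) abort("`roster` is required when `include_sex = TRUE`.")
    data$infant_sex <- factor(roster$sex[match(data$infant_id, roster$id)])
  }
  data
}

#' Fit the Gaussian mixed model of z-standardized association
#'
#' Response: z-standardized association; fixed effects: kin category
#' (FATHER vs NON_KIN), age bin (0-6) and their interaction, optionally
#' infant sex; crossed random intercepts for male, mother and infant.
#' Gaussian errors, identity link, REML estimation with Satterthwaite
#' denominator degrees of freedom for the type-III F-tests.  Singular fits
#' (a variance component estimated at zero) are returned with a warning.
#'
#' @param table analysis table from [build_within_period_dataset()] or
#'   [build_between_period_dataset()].
#' @param include_sex include infant sex as a fixed covariate (default
#'   `FALSE`, mirroring its exclusion after a non-significant test).
#' @param roster roster tibble, required when `include_sex = TRUE`.
#' @param random_effects set `FALSE` to drop all random intercepts and fit
#'   the fixed-effects-only linear model.
#' @param reml use REML (default) or ML.
#' @return an object of class `"kb_assoc_fit"` with elements `fit`,
#'   `anova` (term, F, num/den df, p), `data`, `singular`.
#' @export
fit_association_lmm <- function(table, include_sex = FALSE, roster = NULL,
                                random_effects = TRUE, reml = TRUE) {
  data <- kb_prepare_lmm_data(table, include_sex, roster)
  if (nrow(data) == 0) abort("Empty analysis table.")
  # a single observed age bin degenerates to the plain two-group model
  one_bin <- nlevels(data$age_bin) < 2
  fixed <- if (one_bin) "z ~ kin" else "z ~ kin * age_bin"
  if (include_sex) fixed <- paste(fixed, "+ infant_sex")
  contr <- if (one_bin) list(kin = "contr.sum") else
    list(kin = "contr.sum", age_bin = "contr.sum")

  if (random_effects) {
    # random factors need at least two sampled levels to be estimable
    re_terms <- c("male_id", "mother_id", "infant_id")
    re_terms <- re_terms[vapply(re_terms, function(v)
      dplyr::n_distinct(data[[v]]) > 1, logical(1))]
    if (length(re_terms) == 0) {
      return(fit_association_lmm(table, include_sex, roster,
                                 random_effects = FALSE, reml = reml))
    }
    form <- as.formula(paste(
      fixed, "+", paste0("(1 | ", re_terms, ")", collapse = " + ")))
    msgs <- character()
    fit <- withCallingHandlers(
      lmerTest::lmer(form, data = data, REML = reml, contrasts = contr,
                     control = lme4::lmerControl(calc.derivs = FALSE)),
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
      }
    )
    singular <- lme4::isSingular(fit)
    if (singular) {
      warn("Singular fit: one or more variance components estimated at 0.")
    }
    an <- suppressMessages(anova(fit, type = 3))
    anova_tbl <- tibble(
      term = rownames(an),
      num_df = an$NumDF, den_df = an$DenDF,
      f_value = an$`F value`, p_value = an$`Pr(>F)`
    )
  } else {
    form <- as.formula(fixed)
    fit <- stats::lm(form, data = data, contrasts = contr)
    an <- stats::anova(fit)
    anova_tbl <- tibble(
      term = rownames(an), num_df = an$Df,
      den_df = stats::df.residual(fit),
      f_value = an$`F value`, p_value = an$`Pr(>F)`
    ) |>
      filter(term != "Residuals")
    singular <- FALSE
  }
  structure(
    list(fit = fit, anova = anova_tbl, data = data,
         random_effects = random_effects, singular = singular,
         include_sex = include_sex),
    class = "kb_assoc_fit"
  )
}

#' Tukey-style within-bin contrasts of FATHER vs NON_KIN
#'
#' One FATHER - NON_KIN contrast per age bin, with single-step
#' family-wise adjustment over the (up to 7) within-bin comparisons — the
#' multivariate-t generalization of the Tukey procedure for this
#' non-pairwise family.  Unadjusted p-values are reported alongside.
#' Empty bins are omitted.  Satterthwaite degrees of freedom are used for
#' mixed fits.
#'
#' @param x a `"kb_assoc_fit"`.
#' @param adjust multiplicity adjustment passed to emmeans (default
#'   `"mvt"`).
#' @param seed seed for the quasi-Monte-Carlo multivariate-t integral, so
#'   adjusted p-values are reproducible.
#' @return tibble with `age_bin`, `estimate`, `se`, `df`, `t_ratio`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
tukey_within_bin <- function(x, adjust = "mvt", seed = 1L) {
  stopifnot(inherits(x, "kb_assoc_fit"))
  has_bin <- "age_bin" %in% all.vars(stats::formula(x$fit))
  if (has_bin) {
    emm <- suppressMessages(emmeans::emmeans(
      x$fit, ~ kin | age_bin,
      lmer.df = "satterthwaite", lmerTest.limit = 1e5
    ))
    ct <- emmeans::contrast(emm, method = "pairwise", by = "age_bin")
  } else {
    emm <- suppressMessages(emmeans::emmeans(
      x$fit, ~ kin, lmer.df = "satterthwaite", lmerTest.limit = 1e5
    ))
    ct <- emmeans::contrast(emm, method = "pairwise")
  }
  unadj <- as.data.frame(summary(ct, by = NULL, adjust = "none"))
  adj <- withr::with_seed(as.integer(seed),
                          as.data.frame(summary(ct, by = NULL,
                                                adjust = adjust)))
  tibble(
    age_bin = if (has_bin) unadj$age_bin else
      factor(levels(x$data$age_bin)[1], levels = 0:6),
    estimate = unadj$estimate, se = unadj$SE, df = unadj$df,
    t_ratio = unadj$t.ratio,
    p_unadjusted = unadj$p.value,
    p_adjusted = pmin(1, adj$p.value)
  )
}

#' Build paternity cases from conceptions, associations and ranks
#'
#' One case per (mother, prior infant) with known prior paternity and
#' known next-offspring sire.  The predictor `z` is the prior father's
#' z-standardized association with the mother over the prior infant's
#' first 18 months (standardized against all MI pairs present in that
#' window); fathers followed fewer than `min_hours` in the window are
#' filtered out.  `rank` is the father's ordinal Elo rank at the
#' conception of the next offspring (fathers dead or not adult at
#' conception are dropped).  The response `same_sire` indicates whether
#' the prior father sired the next offspring.
#'
#' @param bundle a `kb_bundle`.
#' @param min_hours focal observation filter over the 18 months
#'   (default 90).
#' @param start_rating,k_factor Elo parameters (see [elo_history()]).
#' @return tibble of cases with attributes `n_known` (cases with known
#'   prior father and next sire) and `n_pass` (cases surviving all
#'   filters).
#' @export
paternity_cases <- function(bundle, min_hours = 90, start_rating = 1000,
                            k_factor = 100) {
  con <- bundle$conceptions
  ped <- bundle$pedigree
  empty <- tibble(
    mother_id = character(), prior_infant_id = character(),
    father_id = character(), conception_date = as.Date(character()),
    same_sire = integer(), z = numeric(), rank = integer()
  )
  if (nrow(con) == 0) {
    attr(empty, "n_known") <- 0L; attr(empty, "n_pass") <- 0L
    return(empty)
  }

  cases <- con |>
    mutate(father_id = ped$father_id[match(prior_infant_id, ped$child_id)]) |>
    filter(!is.na(father_id), !is.na(sire_id)) |>
    mutate(same_sire = as.integer(sire_id == father_id))
  n_known <- nrow(cases)
  if (n_known == 0) {
    attr(empty, "n_known") <- 0L; attr(empty, "n_pass") <- 0L
    return(empty)
  }

  prior_birth <- bundle$roster$birth_date[
    match(cases$prior_infant_id, bundle$roster$id)]
  windows <- cases |>
    mutate(
      window_id = paste0("pat_", prior_infant_id),
      male_id = father_id,
      anchor_infant_id = prior_infant_id,
      start = prior_birth,
      end = add_months(prior_birth, 18L) - 1L,
      bin = NA_integer_
    ) |>
    select(window_id, male_id, anchor_infant_id, start, end, bin)
  recs <- association_records(bundle, windows, min_minutes = min_hours * 60)
  z_tab <- recs |>
    filter(infant_id == anchor_infant_id) |>
    transmute(prior_infant_id = anchor_infant_id, male_id, z)

  elo <- elo_history(bundle$dominance, start_rating = start_rating,
                     k_factor = k_factor)
  rank_of <- function(male, date) {
    ranks <- tryCatch(ordinal_ranks_at(elo, date, bundle$roster),
                      error = function(e) NULL)
    if (is.null(ranks)) return(NA_integer_)
    r <- ranks$rank[ranks$male_id == male]
    if (length(r) == 1) r else NA_integer_
  }

  out <- cases |>
    inner_join(z_tab, by = c("prior_infant_id", father_id = "male_id")) |>
    mutate(rank = purrr::map2_int(father_id, conception_date, rank_of)) |>
    filter(!is.na(rank)) |>
    select(mother_id, prior_infant_id, father_id, conception_date,
           same_sire, z, rank)
  attr(out, "n_known") <- n_known
  attr(out, "n_pass") <- nrow(out)
  out
}

#' Same-sire bookkeeping across known-paternity cases
#'
#' Counts the cases in which the mother's next offspring was sired by the
#' same male, among all cases where both paternities are known, and
#' reports the nearest-integer percentage.
#'
#' @param conceptions conceptions tibble.
#' @param pedigree pedigree tibble.
#' @return one-row tibble: `n_known`, `n_same_sire`, `pct_same_sire`.
#' @export
paternity_case_summary <- function(conceptions, pedigree) {
  known <- conceptions |>
    mutate(father_id = pedigree$father_id[match(prior_infant_id,
                                                pedigree$child_id)]) |>
    filter(!is.na(father_id), !is.na(sire_id))
  n_same <- sum(known$sire_id == known$father_id)
  tibble(
    n_known = nrow(known),
    n_same_sire = n_same,
    pct_same_sire = if (nrow(known) > 0)
      round(100 * n_same / nrow(known)) else NA_real_
  )
}

#' Fit the binomial model of association and subsequent paternity
#'
#' `same_sire ~ z + rank` with random intercepts for mother and father,
#' binomial errors and logit link (Laplace approximation).  Wald chi-square
#' tests are reported per fixed term.  Under complete separation (or a
#' failed mixed fit) the model is refitted with the package's bias-reduced
#' (Firth-penalized) fixed-effects logistic regression, with a warning.
#'
#' @param cases case table from [paternity_cases()].
#' @param random_effects set `FALSE` for the fixed-effects-only logistic
#'   fit.
#' @return object of class `"kb_paternity_fit"` with `fit`, `wald`
#'   (term, estimate, se, chisq, df, p), `cases`, counts and the
#'   estimation method used.
#' @export
fit_paternity_model <- function(cases, random_effects = TRUE) {
  if (nrow(cases) < 3) abort("Too few paternity cases to fit the model.")
  method <- if (random_effects) "glmer" else "glm"
  y <- cases$same_sire
  if (all(y == 0) || all(y == 1)) {
    warn("All-0 or all-1 response: refitting with Firth penalization.")
    method <- "firth"
  }

  fit <- NULL
  if (method == "glmer") {
    fit <- tryCatch(
      suppressMessages(lme4::glmer(
        same_sire ~ z + rank + (1 | mother_id) + (1 | father_id),
        data = cases, family = binomial(),
        control = lme4::glmerControl(calc.derivs = FALSE,
                                     check.conv.grad = "ignore",
                                     check.conv.hess = "ignore",
                                     check.conv.singular = "ignore")
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) method <- "glm"
  }
  if (method == "glm") {
    fit <- stats::glm(same_sire ~ z + rank, data = cases, family = binomial())
  }

  coefs <- if (method == "glmer") {
    s <- coef(summary(fit)); s[, c("Estimate", "Std. Error"), drop = FALSE]
  } else if (method == "glm") {
    s <- coef(summary(fit)); s[, c("Estimate", "Std. Error"), drop = FALSE]
  } else NULL

  separated <- !is.null(coefs) &&
    (any(abs(coefs[, 1]) > 10 & coefs[, 2] > 25) || any(!is.finite(coefs)))
  if (separated) {
    warn(paste0("Apparent complete separation; refitting with the ",
                "bias-reduced (Firth) logistic regression."))
    method <- "firth"
  }
  if (method == "firth") {
    X <- model.matrix(~ z + rank, data = cases)
    fit <- kb_firth_logit(X, y)
    coefs <- cbind(fit$coefficients, fit$se)
    rownames(coefs) <- colnames(X)
  }

  wald <- tibble(
    term = rownames(coefs),
    estimate = coefs[, 1], se = coefs[, 2],
    chisq = (coefs[, 1] / coefs[, 2])^2, df = 1,
    p_value = pchisq((coefs[, 1] / coefs[, 2])^2, df = 1, lower.tail = FALSE)
  ) |>
    filter(term != "(Intercept)")

  structure(
    list(fit = fit, wald = wald, cases = cases, method = method,
         n_known = attr(cases, "n_known") %||% nrow(cases),
         n_pass = attr(cases, "n_pass") %||% nrow(cases)),
    class = "kb_paternity_fit"
  )
}

# Firth-penalized logistic regression (Jeffreys-prior score adjustment):
# the bias-reduced fallback used under complete separation.
kb_firth_logit <- function(X, y, max_iter = 200, tol = 1e-8) {
  # drop aliased columns (e.g. a constant rank covariate); their
  # coefficients are reported as NA
  qrX <- qr(X)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  dropped <- setdiff(seq_len(ncol(X)), keep)
  if (length(dropped) > 0) {
    full_names <- colnames(X)
    sub <- kb_firth_logit(X[, keep, drop = FALSE], y, max_iter, tol)
    coefs <- setNames(rep(NA_real_, length(full_names)), full_names)
    ses <- coefs
    coefs[full_names[keep]] <- sub$coefficients
    ses[full_names[keep]] <- sub$se
    return(list(coefficients = coefs, se = ses,
                iterations = sub$iterations))
  }
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- plogis(eta)
    W <- pmax(p * (1 - p), 1e-10)
    XtWX <- crossprod(X * W, X)
    XtWX_inv <- tryCatch(solve(XtWX), error = function(e)
      solve(XtWX + diag(1e-8 * (1 + max(diag(XtWX))), ncol(X))))
    # hat diagonal of W^1/2 X (X'WX)^-1 X' W^1/2
    h <- rowSums((X %*% XtWX_inv) * X) * W
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- as.vector(XtWX_inv %*% U)
    # damped Newton: cap the step so separation geometry cannot diverge
    if (max(abs(step)) > 2) step <- step * (2 / max(abs(step)))
    beta <- beta + step
    if (max(abs(U)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  W <- pmax(plogis(eta) * (1 - plogis(eta)), 1e-10)
  XtWX <- crossprod(X * W, X)
  XtWX_inv <- tryCatch(solve(XtWX), error = function(e)
    solve(XtWX + diag(1e-8 * (1 + max(diag(XtWX))), ncol(X))))
  se <- sqrt(pmax(diag(XtWX_inv), 0))
  list(coefficients = setNames(as.vector(beta), colnames(X)),
       se = setNames(se, colnames(X)), iterations = it)
}
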