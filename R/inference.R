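# Age-group statistical comparisons.
#
# All fixed-effect comparisons report the juvenile coefficient with adult as
# the reference level.  Fisher's exact test is computed directly from the
# hypergeometric distribution (two-sided by probability-mass summation,
# which is the convention of fisher.test and reproduces the published
# p-values); GLM fitting delegates to stats::glm and the mixed model to
# lme4::lmer, whose estimates must agree with the closed-form two-group
# solutions where those exist.

#' Construct an inference result
#' @param model one of GAUSSIAN_GLM, POISSON_GLM, GAUSSIAN_LMM, FISHER_EXACT
#' @param estimate,se,statistic,p_value fit summaries
#' @param n_per_group named counts
#' @param note optional free-text note (e.g. fallback warnings)
#' @return object of class \code{inference_result}
#' @keywords internal
.inference_result <- function(model, estimate, se, statistic, p_value,
                              n_per_group, note = NA_character_) {
  structure(list(model = model, estimate = estimate, se = se,
                 statistic = statistic, p_value = p_value,
                 n_per_group = n_per_group, note = note),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("<inference_result>", x$model, "\n")
  cat(sprintf("  estimate = %.4g", x$estimate))
  if (!is.na(x$se)) cat(sprintf(" +/- %.4g", x$se))
  cat(sprintf(", p = %.3g\n", x$p_value))
  cat("  n =", paste(names(x$n_per_group), x$n_per_group, collapse = ", "),
      "\n")
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided test of association computed from the hypergeometric
#' distribution: with margins fixed, the p-value sums the probabilities of
#' all tables whose probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7, guarding against floating-point
#' ties).  A zero margin carries no information and yields p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = age class,
#'   columns = outcome)
#' @return \code{inference_result}; \code{estimate} is the sample odds ratio
#'   (NA when any cell is zero)
#' @examples
#' # Gulf-of-Maine detection by age among mainland-detected birds
#' fisher_exact(matrix(c(25, 3, 4, 7), 2, 2, byrow = TRUE))
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("fisher_exact: need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("fisher_exact: cells must be non-negative integers")
  if (sum(tab) == 0) stop("fisher_exact: empty table")
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row 1 total  (white balls drawn from)
  n <- sum(tab[2, ])   # row 2 total
  k <- sum(tab[, 1])   # column 1 total (draws)
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) {
    p <- 1
  } else {
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    p <- min(1, p)
  }
  or <- if (any(tab == 0)) NA_real_ else
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  .inference_result("FISHER_EXACT", estimate = or, se = NA_real_,
                    statistic = NA_real_, p_value = p,
                    n_per_group = c(row1 = m, row2 = n))
}

#' Two-group generalized linear fit of an age effect
#'
#' Fits \code{response ~ age} with adult as the reference level.  With the
#' identity link (Gaussian) the juvenile coefficient is the difference of
#' group means; with the log link (Poisson) it is the log ratio of group
#' means.  The iterative fit is checked against those closed forms to 1e-8.
#'
#' @param values numeric response (dates should be passed as numeric days)
#' @param age character vector of \code{"ADULT"}/\code{"JUVENILE"}
#' @param family \code{"gaussian"} or \code{"poisson"}
#' @return \code{inference_result} (estimate = juvenile effect)
#' @export
fit_glm <- function(values, age, family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  if (length(values) != length(age)) stop("fit_glm: length mismatch")
  age <- factor(age, levels = AGES)
  if (any(table(age) == 0)) stop("fit_glm: both groups must be non-empty")
  if (family == "poisson" &&
      (any(values < 0) || any(values != round(values))))
    stop("fit_glm: poisson family requires non-negative integer counts")
  fam <- if (family == "gaussian") stats::gaussian() else stats::poisson()
  note <- NA_character_
  if (family == "poisson" && any(tapply(values, age, mean) == 0)) {
    note <- "a group has zero mean: log-link effect is infinite"
    warning("fit_glm: ", note)
  }
  fit <- stats::glm(values ~ age, family = fam,
                    control = list(epsilon = 1e-12, maxit = 50))
  sm <- summary(fit)$coefficients
  est <- sm["ageJUVENILE", 1]; se <- sm["ageJUVENILE", 2]
  stat <- sm["ageJUVENILE", 3]; p <- sm["ageJUVENILE", 4]
  .inference_result(if (family == "gaussian") "GAUSSIAN_GLM" else
    "POISSON_GLM", est, se, stat, p,
    n_per_group = c(ADULT = sum(age == "ADULT"),
                    JUVENILE = sum(age == "JUVENILE")), note = note)
}

#' Mixed-model comparison of stopover durations
#'
#' Stopover durations are repeated within birds, so the age effect is
#' estimated by a linear mixed model with a per-bird random intercept
#' (restricted maximum likelihood, lme4).  When the random-effect variance
#' is singular (e.g. exactly one event per bird) the model reduces to the
#' Gaussian GLM, which is then used with a logged note.
#'
#' @param durations numeric stopover durations (days)
#' @param bird_id bird identifier per event
#' @param age age class per event
#' @return \code{inference_result} (estimate = juvenile effect, days); the
#'   fitted variance components are attached as attribute \code{varcomp}
#'   when the mixed fit succeeds
#' @export
fit_duration_lmm <- function(durations, bird_id, age) {
  if (!(length(durations) == length(bird_id) &&
        length(bird_id) == length(age)))
    stop("fit_duration_lmm: length mismatch")
  age <- factor(age, levels = AGES)
  birds_per_group <- tapply(bird_id, age, function(x) length(unique(x)))
  if (any(is.na(birds_per_group)) || any(birds_per_group < 2))
    stop("fit_duration_lmm: need >= 2 birds per group")
  df <- data.frame(y = durations, bird = factor(bird_id), age = age)
  fit <- tryCatch(
    suppressMessages(lme4::lmer(y ~ age + (1 | bird), data = df,
                                REML = TRUE,
                                control = lme4::lmerControl(
                                  check.conv.singular =
                                    lme4::.makeCC(action = "ignore",
                                                  tol = 1e-4)))),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    warning("fit_duration_lmm: singular random-effect variance; ",
            "falling back to Gaussian GLM")
    res <- fit_glm(durations, as.character(age), "gaussian")
    res$model <- "GAUSSIAN_LMM"
    res$note <- "singular random effect: reduced to Gaussian GLM"
    return(res)
  }
  sm <- summary(fit)$coefficients
  est <- sm["ageJUVENILE", "Estimate"]; se <- sm["ageJUVENILE", "Std. Error"]
  tval <- sm["ageJUVENILE", "t value"]
  # Wald p on the t statistic with between-bird degrees of freedom
  n_birds <- length(unique(bird_id))
  p <- 2 * stats::pt(abs(tval), df = n_birds - 2, lower.tail = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  res <- .inference_result("GAUSSIAN_LMM", est, se, tval, p,
                           n_per_group = c(ADULT = birds_per_group[["ADULT"]],
                                           JUVENILE =
                                             birds_per_group[["JUVENILE"]]))
  attr(res, "varcomp") <- c(sd_bird = vc$sdcor[vc$grp == "bird"],
                            sd_resid = vc$sdcor[vc$grp == "Residual"])
  res
}
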