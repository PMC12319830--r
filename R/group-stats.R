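#' @title Group-level inference helpers
#' @name group_stats
#' @description One-sample tests on Fisher-z values, factorial mixed models
#'   with a participant random intercept, and the Dice set-overlap
#'   coefficient used for ROI comparison.
NULL

#' One-sample t test
#'
#' Classical one-sample t statistic of a set of values (typically Fisher-z
#' normalised correlations, one per participant) against a null mean.
#'
#' @param values numeric vector (n >= 2, finite).
#' @param mu0 null mean (default 0).
#' @param alternative as [stats::t.test()] (default two-sided).
#' @return List with \code{t}, \code{df}, \code{p}, \code{mean},
#'   \code{alternative}.
#' @export
one_sample_t <- function(values, mu0 = 0,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values) >= 2, all(is.finite(values)))
  if (stats::sd(values) == 0) {
    if (all(values == mu0))
      return(list(t = 0, df = length(values) - 1L, p = 1, mean = mu0,
                  alternative = alternative))
    stop("values have zero variance but differ from mu0: t is infinite")
  }
  tt <- stats::t.test(values, mu = mu0, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = unname(tt$estimate), alternative = alternative)
}

#' Factorial linear mixed model with participant random intercept
#'
#' Fits \code{response ~ factorA * factorB + (1 | participant)} (or the
#' corresponding one-factor model), returns per-effect F tests
#' (Satterthwaite denominator degrees of freedom) and Bonferroni-corrected
#' pairwise post-hoc contrasts for each requested factor. A constant
#' response is degenerate for the model; it is returned directly as
#' zero-size effects (F = 0, p = 1) without fitting.
#'
#' @param table data frame with a \code{participant} column, the factor
#'   columns, and the response column.
#' @param response name of the response column.
#' @param factors character vector of one or two factor column names.
#' @param posthoc factors to compute pairwise contrasts for (default: those
#'   in \code{factors} with more than 2 levels, plus 2-level factors too;
#'   i.e. all).
#' @return An object of class \code{mixed_test}: list with \code{anova}
#'   (data frame: effect, F, df1, df2, p) and \code{contrasts} (named list
#'   of data frames from emmeans, Bonferroni adjusted).
#' @export
factorial_mixed_test <- function(table, response, factors, posthoc = factors) {
  stopifnot(is.data.frame(table), "participant" %in% names(table),
            response %in% names(table), all(factors %in% names(table)),
            length(factors) %in% 1:2)
  if (length(unique(table$participant)) < 2)
    stop("mixed model needs at least 2 participants")
  y <- table[[response]]
  if (!all(is.finite(y))) stop("non-finite response values")
  for (f in factors) table[[f]] <- factor(table[[f]])
  if (any(vapply(factors, function(f) nlevels(table[[f]]) < 2, logical(1))))
    stop("each factor needs at least 2 observed levels (rank-deficient design)")

  effects <- if (length(factors) == 2)
    c(factors, paste(factors, collapse = ":")) else factors
  if (stats::sd(y) == 0) {
    an <- data.frame(effect = effects, F = 0, df1 = NA_real_, df2 = NA_real_,
                     p = 1, stringsAsFactors = FALSE)
    return(structure(list(anova = an, contrasts = list(), degenerate = TRUE),
                     class = "mixed_test"))
  }

  fml <- stats::as.formula(paste(
    response, "~", paste(factors, collapse = " * "), "+ (1 | participant)"))
  fit <- lmerTest::lmer(fml, data = table)
  av <- stats::anova(fit)   # Satterthwaite type III
  an <- data.frame(effect = rownames(av), F = av[["F value"]],
                   df1 = av[["NumDF"]], df2 = av[["DenDF"]],
                   p = av[["Pr(>F)"]], stringsAsFactors = FALSE)

  contrasts <- list()
  for (f in intersect(posthoc, factors)) {
    em <- emmeans::emmeans(fit, stats::as.formula(paste("~", f)))
    contrasts[[f]] <- as.data.frame(
      emmeans::contrast(em, method = "pairwise", adjust = "bonferroni"))
  }
  structure(list(anova = an, contrasts = contrasts, model = fit,
                 degenerate = FALSE),
            class = "mixed_test")
}

#' @export
print.mixed_test <- function(x, ...) {
  cat("Linear mixed model (participant random intercept)\n")
  print(x$anova, row.names = FALSE)
  for (f in names(x$contrasts)) {
    cat("Pairwise contrasts (Bonferroni):", f, "\n")
    print(x$contrasts[[f]], row.names = FALSE)
  }
  invisible(x)
}

#' Dice coefficient of overlap between two sets
#'
#' \code{2 |A intersect B| / (|A| + |B|)}, used to compare region-of-interest
#' definitions (sets of voxel or vertex identifiers).
#'
#' @param a,b vectors of location identifiers (duplicates ignored).
#' @return Dice coefficient in \code{[0, 1]}; both sets empty is undefined
#'   and raises an error.
#' @export
dice <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) + length(b) == 0)
    stop("Dice coefficient undefined for two empty sets")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
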