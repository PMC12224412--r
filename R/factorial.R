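#' Factorial linear models on second-order correlations
#'
#' Fits an ordinary least-squares model with factors, interactions, and
#' covariates (e.g. `rho ~ group * model + fluency`, the
#' group-by-model ANCOVA with a reading-fluency covariate, or the
#' three-way group x model x gradient ANOVA over fusiform subregions)
#' and reports F-tests by Type II sums of squares — each term tested
#' after every other term at its level, which does not depend on term
#' order and is the appropriate decomposition for mildly unbalanced
#' group sizes.
#'
#' @param data Data frame with the response, factors, and covariates.
#' @param formula Model formula; character predictors are converted to
#'   factors.
#' @return An object of class `lexrsa_factorial`; see [tidy()] for the
#'   F-table and [glance()] for the model summary.
#' @export
fit_factorial <- function(data, formula) {
  data <- as.data.frame(data)
  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "lexrsa_error_schema"
    )
  }
  for (v in vars[-1]) {
    if (is.character(data[[v]]) || is.logical(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2) {
      abort(paste0("Factor `", v, "` needs at least 2 levels."), class = "lexrsa_error_parameter")
    }
  }
  y <- data[[vars[1]]]
  if (!is.numeric(y)) abort("Response must be numeric.", class = "lexrsa_error_schema")
  if (var(y, na.rm = TRUE) == 0) {
    abort("Degenerate model: response is constant.", class = "lexrsa_error_degenerate")
  }
  fit <- lm(formula, data = data)
  if (nrow(data) <= length(coef(fit))) {
    abort("Need more observations than model coefficients.", class = "lexrsa_error_design")
  }
  al <- alias(fit)
  if (!is.null(al$Complete)) {
    abort(paste0("Aliased term(s): ", paste(rownames(al$Complete), collapse = ", ")),
      class = "lexrsa_error_design"
    )
  }
  an <- car::Anova(fit, type = 2)
  tab <- tibble::tibble(
    term = rownames(an),
    sumsq = an[["Sum Sq"]],
    df = an[["Df"]],
    statistic = an[["F value"]],
    df_residual = an["Residuals", "Df"],
    p_value = an[["Pr(>F)"]]
  )
  tab <- tab[tab$term != "Residuals", ]
  structure(list(fit = fit, anova = tab, formula = formula), class = "lexrsa_factorial")
}

#' @export
print.lexrsa_factorial <- function(x, ...) {
  cat("<lexrsa_factorial> Type II F-tests for", deparse(x$formula), "\n")
  print(x$anova)
  invisible(x)
}

#' @describeIn fit_factorial F-table: `term`, `sumsq`, `df`,
#'   `statistic`, `df_residual`, `p_value`.
#' @param x,object A `lexrsa_factorial` object.
#' @param ... Unused.
#' @export
tidy.lexrsa_factorial <- function(x, ...) x$anova

#' @describeIn fit_factorial One-row model summary (`r.squared`,
#'   `sigma`, `df_residual`, `nobs`).
#' @export
glance.lexrsa_factorial <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    df_residual = x$fit$df.residual,
    nobs = length(x$fit$residuals)
  )
}

#' Tukey-adjusted pairwise comparisons of cell means
#'
#' Post hoc contrasts between the cells of one or more factors of a
#' fitted factorial model, using the model's residual variance and the
#' studentized-range (Tukey HSD) adjustment. With only two cells the
#' adjusted p-value coincides with the unadjusted pairwise t-test.
#'
#' @param object A [fit_factorial()] object.
#' @param specs Factor specification passed to [emmeans::emmeans()],
#'   e.g. `~ model` or `~ gradient * model`.
#' @return A tibble of pairwise contrasts: `contrast`, `estimate`,
#'   `std_error`, `df`, `statistic`, `p_value` (Tukey-adjusted).
#' @export
tukey_posthoc <- function(object, specs) {
  stopifnot(inherits(object, "lexrsa_factorial"))
  emm <- emmeans::emmeans(object$fit, specs)
  if (nrow(summary(emm)) < 2) {
    abort("Need at least 2 cells to compare.", class = "lexrsa_error_parameter")
  }
  prs <- summary(graphics::pairs(emm, adjust = "tukey"))
  tibble::tibble(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate,
    std_error = prs$SE,
    df = prs$df,
    statistic = prs$t.ratio,
    p_value = prs$p.value
  )
}
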