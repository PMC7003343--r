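tTestP <- function(x, g) {
  xs <- split(x, g)
  if (length(xs) != 2L) return(NA_real_)
  a <- xs[[1L]]; b <- xs[[2L]]
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

categoricalP <- function(v, g) {
  tab <- table(g, v)
  if (ncol(tab) < 2L) return(list(p = 1, test = "chisq"))
  exp <- suppressWarnings(stats::chisq.test(tab)$expected)
  if (any(exp < 5) || any(tab == 0))
    list(p = stats::fisher.test(tab)$p.value, test = "fisher")
  else
    list(p = suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value,
         test = "chisq")
}

#' Between-class comparison of cohort covariates
#'
#' Per covariate: Student's t-test (equal variances) for continuous
#' variables, with the Mann-Whitney U p-value reported alongside;
#' chi-square for categorical variables, switching to Fisher's exact test
#' when any expected cell count is below 5.
#'
#' @param records cohort data.frame with columns label, age_years,
#'   max_diameter_cm, enhancement_type, subtype, regimen.
#' @return data.frame with columns variable, test, p_value (and
#'   p_mannwhitney for the continuous rows).
#' @export
cohortStats <- function(records) {
  g <- factor(records$label)
  if (nlevels(g) != 2L) stop("both classes must be present")
  rows <- list()
  for (v in c("age_years", "max_diameter_cm")) {
    if (!v %in% names(records)) next
    x <- records[[v]]
    mw <- suppressWarnings(stats::wilcox.test(x ~ g)$p.value)
    rows[[v]] <- data.frame(variable = v, test = "t",
                            p_value = tTestP(x, g), p_mannwhitney = mw)
  }
  for (v in c("enhancement_type", "subtype", "regimen")) {
    if (!v %in% names(records)) next
    r <- categoricalP(records[[v]], g)
    rows[[v]] <- data.frame(variable = v, test = r$test, p_value = r$p,
                            p_mannwhitney = NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
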