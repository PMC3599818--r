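# Maternal-age analysis: a first-order linear model of genome-wide maternal
# crossover count in maternal age with mother identity as a factor, and
# per-chromosome comparisons between younger and older mothers.

#' Fit the maternal-age effect on crossover count
#'
#' Least-squares fit of `count ~ age + mother`, a first-order model in
#' maternal age at childbirth with maternal ID as a factor and no
#' interactions. The mother factor absorbs between-mother rate differences,
#' so the age coefficient is identified by within-mother age variation;
#' consequently at least two mothers must have two or more children and age
#' must vary within at least one mother.
#'
#' @param records data.frame with columns `childId`, `motherId`,
#'   `motherAgeYears` (integer, floored) and `count` (genome-wide maternal
#'   crossover count for the child's meiosis).
#' @return list with `slope` (crossovers per year), `se`, `p` (two-sided),
#'   `r2`, `adjR2`, `nChildren`, `nMothers` and the `fit` object.
#' @export
fitAgeEffect <- function(records) {
  need <- c("motherId", "motherAgeYears", "count")
  stopifnot(all(need %in% names(records)))
  records <- records[complete.cases(records[, need]), ]
  bad <- records$motherAgeYears < 12 | records$motherAgeYears > 60
  if (any(bad))
    warning(sum(bad), " record(s) with implausible mother age (12-60)")
  nk <- table(records$motherId)
  if (sum(nk >= 2) < 2)
    stop("need at least two mothers with two or more children each; ",
         "age and mother identity are otherwise confounded")
  varies <- tapply(records$motherAgeYears, records$motherId,
                   function(a) length(unique(a)) > 1)
  if (!any(varies))
    stop("maternal age is constant within every mother; the age effect is ",
         "confounded with the mother factor")
  df <- data.frame(count = records$count, age = records$motherAgeYears,
                   mother = factor(records$motherId))
  fit <- lm(count ~ age + mother, data = df)
  cf <- summary(fit)$coefficients
  if (!"age" %in% rownames(cf) || is.na(coef(fit)["age"]))
    stop("age coefficient could not be estimated (collinear design)")
  othersNA <- names(coef(fit))[is.na(coef(fit)) & names(coef(fit)) != "age"]
  if (length(othersNA))
    stop("rank-deficient design; collinear columns: ",
         paste(othersNA, collapse = ", "))
  s <- summary(fit)
  list(slope = unname(cf["age", "Estimate"]),
       se = unname(cf["age", "Std. Error"]),
       p = unname(cf["age", "Pr(>|t|)"]),
       r2 = s$r.squared, adjR2 = s$adj.r.squared,
       nChildren = nrow(df), nMothers = nlevels(df$mother), fit = fit)
}

#' Per-chromosome age-group comparison of maternal crossover counts
#'
#' Splits children into mothers aged at most `ageThreshold` at birth versus
#' older, and tests per chromosome for a reduction in the older group with a
#' one-sided Welch t-test (alternative: mean of the older group is lower).
#' Raw p-values are reported together with Bonferroni adjustment across the
#' 23 chromosomes (1-22 and X).
#'
#' @param records data.frame with columns `childId`, `motherAgeYears`,
#'   `chrom` and `count` (per-chromosome maternal crossover count).
#' @param ageThreshold age split (default 30: groups age <= 30 and > 30).
#' @param nChromosomes Bonferroni multiplier (default 23).
#' @return data.frame per chromosome: group sizes, means and standard
#'   errors, `p` (one-sided) and `pBonferroni`. Chromosomes where either
#'   group has fewer than two observations are skipped with a warning.
#' @export
chromosomeAgeGroups <- function(records, ageThreshold = 30,
                                nChromosomes = 23) {
  need <- c("motherAgeYears", "chrom", "count")
  stopifnot(all(need %in% names(records)))
  older <- records$motherAgeYears > ageThreshold
  if (!any(older) || all(older))
    stop("both age groups must be non-empty")
  out <- list()
  sem <- function(x) sd(x) / sqrt(length(x))
  for (ch in unique(records$chrom)) {
    a <- records$count[records$chrom == ch & !older]  # younger (<= threshold)
    b <- records$count[records$chrom == ch & older]
    if (length(a) < 2 || length(b) < 2) {
      warning("chromosome ", ch, " skipped: a group has < 2 observations")
      next
    }
    tt <- t.test(b, a, alternative = "less")   # Welch by default
    out[[length(out) + 1]] <- data.frame(
      chrom = ch, nYounger = length(a), nOlder = length(b),
      meanYounger = mean(a), meanOlder = mean(b),
      seYounger = sem(a), seOlder = sem(b),
      p = tt$p.value, pBonferroni = min(1, tt$p.value * nChromosomes),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no chromosome had enough observations")
  res <- do.call(rbind, out)
  res[order(.chromRank(res$chrom)), , drop = FALSE]
}
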