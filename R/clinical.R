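# Clinical baseline statistics (Shapiro-Wilk normality gate routing to
# Welch t or Mann-Whitney U, chi-square for categorical variables) and the
# optometric NSBVD subtype rules.

#' Welch's t-test from summaries or raw samples
#'
#' `t = (meanA - meanB) / sqrt(sdA^2/nA + sdB^2/nB)` with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p-value. Either
#' supply raw samples (`a`, `b`) or the group summaries.
#'
#' @param a,b raw samples (used when given).
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a = NULL, b = NULL, meanA = mean(a), sdA = sd(a),
                    nA = length(a), meanB = mean(b), sdB = sd(b),
                    nB = length(b)) {
  if (nA < 2 || nB < 2) stop("need n >= 2 per group")
  if (sdA < 0 || sdB < 0) stop("negative SD")
  va <- sdA^2 / nA; vb <- sdB^2 / nB
  if (va + vb == 0) {
    if (meanA == meanB) return(list(t = 0, df = nA + nB - 2, p = 1))
    warning("zero variance with unequal means: t is infinite")
    return(list(t = sign(meanA - meanB) * Inf, df = nA + nB - 2, p = 0))
  }
  t <- (meanA - meanB) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (nA - 1) + vb^2 / (nB - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Mann-Whitney U test with standardized statistic
#'
#' U statistic with midrank tie handling; the standardized statistic Z uses
#' the tie-corrected variance and a 0.5 continuity correction. The p-value
#' is two-tailed: exact by enumeration of all group assignments when
#' `nA + nB <= 12` and the data are untied, otherwise from the normal
#' approximation.
#'
#' @param a,b numeric samples.
#' @return List with `U` (number of (a, b) pairs with a > b, ties counted
#'   half), `Z`, `p`, and `method`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  nA <- length(a); nB <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  mu <- nA * nB / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / ((nA + nB) * (nA + nB - 1))
  sigma2 <- nA * nB / 12 * ((nA + nB + 1) - tie_term)
  sigma <- sqrt(sigma2)
  if (sigma == 0) {
    Z <- 0
  } else {
    cc <- if (abs(U - mu) > 0.5) 0.5 else abs(U - mu)  # continuity correction
    Z <- sign(U - mu) * (abs(U - mu) - cc) / sigma
  }
  has_ties <- any(ties > 1)
  if (nA + nB <= 12 && !has_ties) {
    combos <- combn(nA + nB, nA)
    rr <- rank(c(a, b))
    Us <- apply(combos, 2, function(ix) sum(rr[ix]) - nA * (nA + 1) / 2)
    p <- mean(abs(Us - mu) >= abs(U - mu))
    method <- "exact"
  } else {
    p <- if (sigma == 0) 1 else 2 * pnorm(-abs(Z))
    method <- "normal"
  }
  list(U = U, Z = Z, p = min(1, p), method = method)
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Without continuity correction (so identical margins give exactly
#' `chi^2 = 0`, `p = 1`); `df = 1`.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return List with `chisq`, `df`, `p`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table")
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq <- sum((tab - E)^2 / E)
  list(chisq = chisq, df = 1, p = pchisq(chisq, 1, lower.tail = FALSE))
}

#' Shapiro-Wilk normality gate
#'
#' Routes a continuous variable to the parametric (Welch t) or
#' non-parametric (Mann-Whitney U) comparison: `"non_normal"` when the
#' Shapiro-Wilk p-value is below `alpha` in either group (degenerate
#' constant samples are non-normal by convention).
#'
#' @param a,b numeric samples, `n >= 3` each.
#' @param alpha gate significance level.
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  pvals <- vapply(list(a, b), function(x) {
    if (length(unique(x)) == 1) return(0)   # degenerate: not normal
    shapiro.test(x)$p.value
  }, 0)
  if (any(pvals < alpha)) "non_normal" else "normal"
}

#' Reference baseline summaries for a 15 + 15 vergence cohort
#'
#' Per-variable group means and SDs (patients vs controls) characteristic
#' of an NSBVD case-control sample: patients show a receded near point of
#' convergence and reduced positive fusional vergence, with demographics
#' matched. Phoria is signed (exophoria negative). Used as generator
#' parameters by [simulate_clinical_table()] and as the worked baseline
#' example.
#'
#' @return Data frame with columns `variable`, `mean_nsbvd`, `sd_nsbvd`,
#'   `mean_control`, `sd_control`.
#' @export
reference_baseline_summaries <- function() {
  data.frame(
    variable = c("age", "distance_phoria", "near_phoria", "ac_a",
                 "npc", "pfv", "nfv"),
    mean_nsbvd = c(27.33, -0.93, -5.53, 3.97, 6.33, 18.20, 18.67),
    sd_nsbvd = c(3.89, 2.93, 6.43, 1.91, 2.71, 6.71, 6.92),
    mean_control = c(26.47, -1.20, -3.23, 4.25, 4.33, 26.00, 18.73),
    sd_control = c(4.05, 0.99, 1.83, 0.46, 0.75, 3.36, 1.83),
    stringsAsFactors = FALSE
  )
}

#' Simulate a clinical table from the reference summaries
#'
#' Draws each continuous variable from a normal distribution with the
#' group's reference mean and SD (near point of convergence truncated at
#' 0.5 cm); sex is fixed at 7 males / 8 females per group.
#'
#' @param n_per_group subjects per group.
#' @param seed RNG seed.
#' @param summaries summary table as from [reference_baseline_summaries()].
#' @return Data frame, one row per subject, with `group`, `sex` and the
#'   optometric variables.
#' @export
simulate_clinical_table <- function(n_per_group = 15, seed = 1,
                                    summaries = reference_baseline_summaries()) {
  run_with_seed(seed, {
    groups <- rep(c("nsbvd", "control"), each = n_per_group)
    n_m <- round(n_per_group * 7 / 15)
    sex <- rep(c(rep("male", n_m), rep("female", n_per_group - n_m)), 2)
    out <- data.frame(group = groups, sex = sex, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(summaries))) {
      v <- summaries$variable[i]
      x <- c(rnorm(n_per_group, summaries$mean_nsbvd[i], summaries$sd_nsbvd[i]),
             rnorm(n_per_group, summaries$mean_control[i], summaries$sd_control[i]))
      if (v == "npc") x <- pmax(x, 0.5)
      out[[v]] <- x
    }
    out
  })
}

#' Baseline group comparison table
#'
#' One row per variable: categorical variables (sex) are compared with the
#' chi-square test; continuous variables pass through the Shapiro-Wilk gate
#' and are compared with Welch's t (normal) or the Mann-Whitney U test
#' (non-normal). Group summaries are reported as mean (SD).
#'
#' @param table clinical data frame with a `group` column (`"control"` /
#'   `"nsbvd"`), optionally `sex`, and numeric optometric columns.
#' @param alpha significance level for flagging.
#' @return A `verge_baseline` data frame: variable, group summaries, test
#'   used, statistic, p, significance flag.
#' @export
compare_baseline <- function(table, alpha = 0.05) {
  if (!all(c("control", "nsbvd") %in% table$group)) {
    stop("both groups must be present")
  }
  pat <- table[table$group == "nsbvd", , drop = FALSE]
  ctl <- table[table$group == "control", , drop = FALSE]
  rows <- list()
  if ("sex" %in% names(table)) {
    tab <- rbind(table(factor(pat$sex, c("male", "female"))),
                 table(factor(ctl$sex, c("male", "female"))))
    res <- chi_square(tab)
    rows[[length(rows) + 1]] <- data.frame(
      variable = "sex",
      nsbvd = paste0(tab[1, 1], "/", tab[1, 2]),
      control = paste0(tab[2, 1], "/", tab[2, 2]),
      test = "chi_square", statistic = res$chisq, p = res$p,
      significant = res$p < alpha, stringsAsFactors = FALSE)
  }
  num_vars <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], "group")
  for (v in num_vars) {
    a <- pat[[v]]; b <- ctl[[v]]
    gate <- normality_gate(a, b)
    if (gate == "normal") {
      res <- welch_t(a, b)
      test <- "welch_t"; stat <- res$t
    } else {
      res <- mann_whitney(a, b)
      test <- "mann_whitney"; stat <- res$Z
    }
    rows[[length(rows) + 1]] <- data.frame(
      variable = v,
      nsbvd = sprintf("%.2f (%.2f)", mean(a), sd(a)),
      control = sprintf("%.2f (%.2f)", mean(b), sd(b)),
      test = test, statistic = stat, p = res$p,
      significant = res$p < alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("verge_baseline", class(out))
  out
}

#' Optometric subtype rule set
#'
#' The diagnostic criteria for the six NSBVD subtypes as a data-driven rule
#' table: each row is one constraint, written as an R expression over the
#' subject's measures (`near_phoria`, `distance_phoria` signed with
#' exophoria negative; `ac_a`; `npc` in cm; `near_pfv`, `distance_pfv`,
#' `near_nfv`, `distance_nfv` in prism diopters). A subtype is assigned when
#' every constraint of its rows holds; a subtype with any constraint whose
#' measures are missing is not evaluable and is skipped.
#'
#' @return Data frame with columns `subtype`, `constraint` (expression
#'   text), `fields` (comma-separated measures used).
#' @export
nsbvd_criteria <- function() {
  rule <- function(subtype, constraint, fields) {
    data.frame(subtype = subtype, constraint = constraint, fields = fields,
               stringsAsFactors = FALSE)
  }
  rbind(
    # Convergence insufficiency: marked near exophoria exceeding distance
    # exophoria, receded NPC, weak near positive fusional reserve.
    rule("CI", "-near_phoria > 6", "near_phoria"),
    rule("CI", "-near_phoria >= -distance_phoria + 4", "near_phoria,distance_phoria"),
    rule("CI", "npc > 6", "npc"),
    rule("CI", "near_pfv < 15 | near_pfv < 2 * (-near_phoria)", "near_pfv,near_phoria"),
    # Convergence excess: near esophoria with high AC/A and weak near NFV.
    rule("CE", "near_phoria > 2", "near_phoria"),
    rule("CE", "ac_a > 5", "ac_a"),
    rule("CE", "near_nfv < 12", "near_nfv"),
    # Divergence insufficiency: distance esophoria 2-8 prism diopters and
    # weak distance negative fusional reserve.
    rule("DI", "distance_phoria >= 2 & distance_phoria <= 8", "distance_phoria"),
    rule("DI", "distance_nfv < 4", "distance_nfv"),
    # Divergence excess: distance exophoria exceeding near, weak distance PFV.
    rule("DE", "-distance_phoria > 6", "distance_phoria"),
    rule("DE", "-distance_phoria > -near_phoria", "distance_phoria,near_phoria"),
    rule("DE", "distance_pfv < 10", "distance_pfv"),
    # Simple exophoria.
    rule("simple_exophoria", "-distance_phoria > 4", "distance_phoria"),
    rule("simple_exophoria", "-near_phoria > 7", "near_phoria"),
    rule("simple_exophoria", "ac_a >= 3 & ac_a <= 5", "ac_a"),
    rule("simple_exophoria", "distance_pfv < 10 & near_pfv < 15", "distance_pfv,near_pfv"),
    # Simple esophoria.
    rule("simple_esophoria", "distance_phoria > 2", "distance_phoria"),
    rule("simple_esophoria", "near_phoria > 2", "near_phoria"),
    rule("simple_esophoria", "ac_a >= 3 & ac_a <= 5", "ac_a"),
    rule("simple_esophoria", "distance_nfv < 4 & near_nfv < 12", "distance_nfv,near_nfv")
  )
}

#' Classify a subject's NSBVD subtype(s)
#'
#' Evaluates the [nsbvd_criteria()] rule table on one subject's optometric
#' measures. Phoria values are signed (exophoria negative, esophoria
#' positive); rules compare magnitudes in the deviation's direction. A
#' subtype whose constraints reference missing measures is not evaluable
#' and is excluded (reported via the `"skipped"` attribute).
#'
#' @param measures named list or vector of optometric values (see
#'   [nsbvd_criteria()] for names).
#' @param rules rule table (editable); defaults to the shipped criteria.
#' @return Character vector of matching subtypes (possibly empty), with
#'   attribute `skipped` naming subtypes that could not be evaluated.
#' @export
classify_subtype <- function(measures, rules = nsbvd_criteria()) {
  env <- list2env(as.list(measures))
  matched <- character(0); skipped <- character(0)
  for (st in unique(rules$subtype)) {
    rr <- rules[rules$subtype == st, , drop = FALSE]
    fields <- unique(unlist(strsplit(rr$fields, ",")))
    have <- vapply(fields, function(f) {
      exists(f, envir = env) && !is.na(get(f, envir = env))
    }, TRUE)
    if (!all(have)) {
      skipped <- c(skipped, st)
      next
    }
    ok <- vapply(rr$constraint, function(ex) {
      isTRUE(eval(parse(text = ex), envir = env))
    }, TRUE)
    if (all(ok)) matched <- c(matched, st)
  }
  attr(matched, "skipped") <- skipped
  matched
}
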