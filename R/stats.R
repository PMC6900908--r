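#' Paired t-test on per-subject differences
#'
#' Classical one-sample t on the within-subject differences:
#' `t = mean(d) / (sd(d)/sqrt(n))`, `df = n - 1`, two-sided p.
#'
#' @param differences Numeric vector of per-subject differences (post - pre
#'   or a condition contrast), length >= 2, non-zero variance.
#' @return A `stat_result` list: `statistic`, `df`, `p`, `effect_size`
#'   (paired Cohen's d, magnitude), `mean`, `sd`, `n`.
#' @export
paired_t <- function(differences) {
  n <- length(differences)
  if (n < 2) stop("need at least two paired differences")
  if (stats::sd(differences) == 0) {
    if (all(differences == 0))
      return(structure(list(statistic = 0, df = n - 1, p = 1,
                            effect_size = 0, mean = 0,
                            sd = 0, n = n), class = "stat_result"))
    stop("degenerate sample: zero variance with non-zero mean")
  }
  ht <- stats::t.test(differences)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 effect_size = abs(mean(differences)) / stats::sd(differences),
                 mean = mean(differences), sd = stats::sd(differences), n = n),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g, d = %.3f\n",
              x$df, x$statistic, x$p, x$effect_size))
  invisible(x)
}

#' Paired Cohen's d
#'
#' Standardized mean of the within-subject differences,
#' `d = |mean(d)| / sd(d)`; identically equal to `|t|/sqrt(n)` for the
#' paired t-test on the same sample.
#'
#' @param differences Numeric vector of per-subject differences.
#' @return Non-negative effect size.
#' @export
cohens_d_paired <- function(differences) {
  if (stats::sd(differences) == 0) {
    if (all(differences == 0)) return(0)
    stop("degenerate sample: zero variance with non-zero mean")
  }
  abs(mean(differences)) / stats::sd(differences)
}

#' Paired Cohen's d from a reported t statistic
#'
#' `d = |t| / sqrt(n)` -- the identity used to recover effect sizes from
#' published paired t values.
#'
#' @param t The t statistic.
#' @param n Sample size (pairs).
#' @return Non-negative effect size.
#' @export
cohens_d_from_t <- function(t, n) abs(t) / sqrt(n)

#' Partial eta squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`, equivalently `SS_effect / (SS_effect +
#' SS_error)`.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Value in `[0, 1)`.
#' @export
partial_eta_squared <- function(F, df1, df2) {
  if (any(F < 0)) stop("F must be non-negative")
  F * df1 / (F * df1 + df2)
}

#' One-way ANOVA across stimulation conditions
#'
#' By default conditions are treated as independent groups (between-subjects
#' decomposition), which with k groups of 15 subjects yields df (k-1, 15k-k)
#' -- matching the (2, 42) and (3, 56) layout of the condition comparisons.
#' `repeated = TRUE` instead removes the subject stratum (values in each group
#' must then be ordered by subject), the decomposition appropriate to the
#' within-subject design.
#'
#' @param groups List of numeric vectors, one per condition, each of length
#'   two or more.
#' @param repeated Use the repeated-measures error term (default `FALSE`).
#' @return A `stat_result` with `statistic` (F), `df` = c(df1, df2), `p`,
#'   `effect_size` (partial eta squared).
#' @export
one_way_anova <- function(groups, repeated = FALSE) {
  stopifnot(length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least two values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (repeated) {
    sizes <- unique(vapply(groups, length, integer(1)))
    if (length(sizes) != 1)
      stop("repeated-measures ANOVA needs equal group sizes")
    subj <- factor(rep(seq_len(sizes), times = length(groups)))
    fit <- stats::aov(y ~ g + subj)
    tab <- summary(fit)[[1]]
    i <- match("g", trimws(rownames(tab)))
    r <- match("Residuals", trimws(rownames(tab)))
  } else {
    fit <- stats::aov(y ~ g)
    tab <- summary(fit)[[1]]
    i <- 1L; r <- nrow(tab)
  }
  Fv <- tab[i, "F value"]; df1 <- tab[i, "Df"]; df2 <- tab[r, "Df"]
  structure(list(statistic = unname(Fv), df = c(df1 = df1, df2 = df2),
                 p = unname(tab[i, "Pr(>F)"]),
                 effect_size = unname(tab[i, "Sum Sq"] /
                                        (tab[i, "Sum Sq"] + tab[r, "Sum Sq"])),
                 n = length(y)),
            class = "stat_result")
}

#' Two-way ANOVA: channel by stimulation phase
#'
#' Fixed-effects factorial decomposition of per-channel power with subjects as
#' replicates within cells. For the full 19-channel, two-phase, 15-subject
#' design the effect dfs are 18 (channel), 1 (stimulation) and 18
#' (interaction) with 532 error df.
#'
#' @param data Data frame with columns `power`, `channel`, `phase`, `subject`;
#'   every channel-by-phase cell needs at least two replicates.
#' @return Named list of `stat_result`s: `channel`, `stimulation`,
#'   `interaction`, each with partial eta squared attached.
#' @export
two_way_anova <- function(data) {
  stopifnot(all(c("power", "channel", "phase") %in% names(data)))
  data$channel <- factor(data$channel)
  data$phase <- factor(data$phase)
  cells <- table(data$channel, data$phase)
  if (any(cells < 2)) stop("incomplete design: every cell needs >= 2 replicates")
  fit <- stats::aov(power ~ channel * phase, data = data)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  res <- match("Residuals", rn)
  pull <- function(nm) {
    i <- match(nm, rn)
    structure(list(statistic = unname(tab[i, "F value"]),
                   df = c(df1 = tab[i, "Df"], df2 = tab[res, "Df"]),
                   p = unname(tab[i, "Pr(>F)"]),
                   effect_size = unname(tab[i, "Sum Sq"] /
                                          (tab[i, "Sum Sq"] + tab[res, "Sum Sq"])),
                   n = nrow(data)),
              class = "stat_result")
  }
  list(channel = pull("channel"), stimulation = pull("phase"),
       interaction = pull("channel:phase"))
}

#' Bonferroni adjustment
#'
#' `min(1, p * family_size)` for each p-value. The family size is explicit
#' because post hoc families here are defined by design (3 pairwise
#' comparisons among three conditions; 6 among four; 19 channels), not by
#' the length of the vector at hand.
#'
#' @param p Numeric vector of raw p-values.
#' @param family_size Number of comparisons in the family (>= 1); defaults to
#'   `length(p)`.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, family_size = length(p)) {
  stopifnot(family_size >= 1)
  pmin(1, p * family_size)
}
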