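## Bias / medical-implication analysis of the ArI error: per-group
## Shapiro-Wilk normality checks, Kruskal-Wallis omnibus, Dunn's post-hoc
## rank test with Bonferroni correction, and Cohen's d effect sizes of each
## diagnosis group against the exclusive normal-findings reference, binned
## none/small/moderate/large at 0.2/0.5/0.8.

#' Cohen's d standardized mean difference
#'
#' Classical pooled-standard-deviation form:
#' `(mean(a) - mean(b)) / sqrt(((na-1)*var(a) + (nb-1)*var(b)) / (na+nb-2))`.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return Cohen's d (sign follows `mean(a) - mean(b)`).
#' @export
cohensD <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("cohensD needs at least 2 values per group")
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) stop("effect size undefined: zero pooled standard deviation")
  (mean(a) - mean(b)) / sp
}

#' Bin an effect size by magnitude
#'
#' `|d|` in [0, 0.2) is "none", [0.2, 0.5) "small", [0.5, 0.8) "moderate",
#' and >= 0.8 "large".
#'
#' @param d Cohen's d value(s).
#' @return Character vector of bins.
#' @export
effectSizeBin <- function(d) {
  cut(abs(d), breaks = c(0, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("none", "small", "moderate", "large")) |> as.character()
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics on the joint ranks after a Kruskal-Wallis
#' omnibus, with the tie correction
#' `sigma2 = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))`, two-sided p-values
#' and Bonferroni adjustment over all pairs (adjusted p capped at 1,
#' never below the raw p).
#'
#' @param values numeric vector of observations.
#' @param groups factor/character of group membership, same length.
#' @return data.frame with columns group1, group2, z, p, p_adj.
#' @export
dunnTest <- function(values, groups) {
  groups <- as.character(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  g <- unique(groups)
  if (length(g) < 2) stop("Dunn test needs at least 2 groups")
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  pairs <- utils::combn(g, 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(sigma2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
             p = as.numeric(p),
             p_adj = pmin(1, as.numeric(p) * ncol(pairs)),
             stringsAsFactors = FALSE)
}

#' Group bias analysis of the ArI error
#'
#' Given per-record ArI errors grouped by a metadata category, runs the
#' full comparison chain: Shapiro-Wilk normality per group, Kruskal-Wallis
#' omnibus across groups, Dunn's post-hoc test with Bonferroni correction,
#' and Cohen's d (with magnitude bin) of each group against the reference
#' group. A group's `significant` flag comes from its Bonferroni-adjusted
#' Dunn p-value against the reference at level `alpha`. Groups with fewer
#' than `minN` values are excluded with a warning.
#'
#' @param errorsByGroup named list of numeric ArI-error vectors.
#' @param reference name of the reference group (default "NormalFinding").
#' @param alpha significance level (default 0.05).
#' @param minN minimum group size (default 3).
#' @return list with `groups` (per-group data.frame: n, shapiro_p,
#'   cohens_d, effect_bin, p_adj_vs_reference, significant), `omnibus`
#'   (Kruskal-Wallis statistic, df, p), `posthoc` (full Dunn table).
#' @export
groupBiasAnalysis <- function(errorsByGroup, reference = "NormalFinding",
                              alpha = 0.05, minN = 3) {
  sizes <- vapply(errorsByGroup, length, 0L)
  small <- names(errorsByGroup)[sizes < minN]
  if (length(small)) {
    warning("excluding group(s) below minimum size: ",
            paste(small, collapse = ", "))
    errorsByGroup <- errorsByGroup[sizes >= minN]
  }
  if (length(errorsByGroup) < 2)
    stop("need at least 2 groups of size >= ", minN)
  if (!reference %in% names(errorsByGroup))
    stop("reference group '", reference, "' not present")
  values <- unlist(errorsByGroup, use.names = FALSE)
  groups <- rep(names(errorsByGroup), vapply(errorsByGroup, length, 0L))
  kw <- kruskal.test(values, factor(groups))
  ph <- dunnTest(values, groups)
  ref <- errorsByGroup[[reference]]
  gnames <- setdiff(names(errorsByGroup), reference)
  rows <- lapply(gnames, function(gn) {
    x <- errorsByGroup[[gn]]
    d <- tryCatch(cohensD(x, ref), error = function(e) NA_real_)
    sp <- if (length(x) >= 3 && length(x) <= 5000 && sd(x) > 0)
      shapiro.test(x)$p.value else NA_real_
    hit <- (ph$group1 == gn & ph$group2 == reference) |
           (ph$group2 == gn & ph$group1 == reference)
    padj <- ph$p_adj[hit][1]
    data.frame(group = gn, n = length(x), shapiro_p = sp, cohens_d = d,
               effect_bin = if (is.na(d)) NA_character_ else effectSizeBin(d),
               p_adj_vs_reference = padj,
               significant = !is.na(padj) && padj < alpha,
               stringsAsFactors = FALSE)
  })
  list(groups = do.call(rbind, rows),
       reference = reference,
       omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       posthoc = ph)
}

#' Correlation between arousal index and ArI error
#'
#' Pearson correlation (with two-sided p-value) between the reference
#' arousal index and the absolute ArI error across records; used to ask
#' whether prediction errors grow with sleep fragmentation.
#'
#' @param reports data.frame of [evaluateRecord()] rows (needs `ari_true`
#'   and `ari_error`), or a [SleepEvalReport-class].
#' @param groupFilter optional logical/index vector selecting records.
#' @return `list(r, p, n)`.
#' @export
ariErrorCorrelation <- function(reports, groupFilter = NULL) {
  if (is(reports, "SleepEvalReport")) reports <- reportRecords(reports)
  if (!is.null(groupFilter)) reports <- reports[groupFilter, , drop = FALSE]
  if (nrow(reports) < 3) stop("need at least 3 records for the correlation")
  if (sd(reports$ari_true) == 0 || sd(reports$ari_error) == 0)
    stop("correlation undefined: zero variance")
  ct <- cor.test(reports$ari_true, reports$ari_error, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(reports))
}

#' Decade age bins for bias analysis
#'
#' @param age numeric ages in years.
#' @param breaks bin boundaries (default 18, 30, 40, ..., 80, Inf).
#' @return Character vector of bin labels ("18-29", ..., "80+").
#' @export
ageBins <- function(age, breaks = c(18, seq(30, 80, by = 10), Inf)) {
  labs <- paste0(breaks[-length(breaks)], "-", breaks[-1] - 1)
  labs[length(labs)] <- paste0(breaks[length(breaks) - 1], "+")
  as.character(cut(age, breaks = breaks, right = FALSE, labels = labs))
}
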