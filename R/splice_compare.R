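# Group-wise PSI comparison: per-group summaries, dPSI with the pooled SD
# used for small samples, two-way factorial ANOVA per bin, and Holm
# (sequential Bonferroni) multiple-testing correction.

#' Group-wise PSI summaries
#'
#' Mean and sample SD (n - 1 denominator) of PSI per counting bin for every
#' genotype-by-muscle group. Missing PSI values are excluded from n; a
#' single-sample group gets `sd_psi = 0` and is flagged. Cells with no
#' non-missing PSI are dropped with a warning.
#'
#' @param table A `psi_table` from [build_psi_table()].
#' @return data.frame `bin_id`, `genotype`, `muscle`, `n`, `mean_psi`,
#'   `sd_psi`, `single_sample`.
#' @export
summarize_groups <- function(table) {
  stopifnot(inherits(table, "psi_table"))
  d <- merge(table$psi, table$metadata, by = "sample_id")
  d <- d[!is.na(d$psi), , drop = FALSE]
  full_cells <- length(table$bin_order) *
    nrow(unique(table$metadata[, c("genotype", "muscle")]))
  agg <- stats::aggregate(psi ~ bin_id + genotype + muscle, data = d,
                          FUN = function(x) c(n = length(x), mean = mean(x),
                                              sd = if (length(x) > 1)
                                                stats::sd(x) else 0))
  out <- data.frame(bin_id = agg$bin_id, genotype = agg$genotype,
                    muscle = agg$muscle,
                    n = as.integer(agg$psi[, "n"]),
                    mean_psi = agg$psi[, "mean"],
                    sd_psi = agg$psi[, "sd"],
                    stringsAsFactors = FALSE)
  out$single_sample <- out$n == 1L
  if (nrow(out) < full_cells)
    warning(full_cells - nrow(out),
            " group cell(s) had no non-missing PSI and were dropped")
  out <- out[order(match(out$bin_id, table$bin_order), out$muscle,
                   out$genotype), ]
  rownames(out) <- NULL
  out
}

#' Pooled standard deviation of two groups
#'
#' Degrees-of-freedom-weighted pooled SD under an equal-variance
#' assumption, appropriate for small samples (n < 30):
#' \deqn{SD = \sqrt{\frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}}}
#'
#' @param n1,n2 Group sizes, `n1 + n2 > 2`.
#' @param s1,s2 Group sample SDs, non-negative.
#' @return The pooled SD.
#' @export
#' @examples
#' pooled_sd(4, 0.2, 3, 0.1)
pooled_sd <- function(n1, s1, n2, s2) {
  if (any(n1 + n2 <= 2)) stop("pooled SD requires n1 + n2 > 2")
  if (any(s1 < 0) || any(s2 < 0)) stop("SDs must be non-negative")
  sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
}

#' Per-muscle dPSI between genotypes
#'
#' For each bin and muscle, dPSI = mean mutant PSI minus mean wild-type
#' PSI, so a negative value means higher inclusion in wild type. The pooled
#' SD of the two groups is attached. Bins lacking a matching pair of group
#' summaries in a muscle are skipped with a warning.
#'
#' @param summaries Output of [summarize_groups()].
#' @param mutant,reference Genotype labels (defaults `"mdm"`, `"WT"`).
#' @return data.frame `bin_id`, `muscle`, `dpsi`, `sd_pooled`, `n_mut`,
#'   `n_ref`.
#' @export
delta_psi <- function(summaries, mutant = "mdm", reference = "WT") {
  mut <- summaries[summaries$genotype == mutant, , drop = FALSE]
  ref <- summaries[summaries$genotype == reference, , drop = FALSE]
  m <- merge(mut, ref, by = c("bin_id", "muscle"),
             suffixes = c("_mut", "_ref"))
  skipped <- nrow(mut) + nrow(ref) - 2L * nrow(m)
  if (skipped > 0L)
    warning(skipped, " unmatched group summar(ies) skipped in delta_psi")
  if (nrow(m) == 0L)
    return(data.frame(bin_id = character(), muscle = character(),
                      dpsi = numeric(), sd_pooled = numeric(),
                      n_mut = integer(), n_ref = integer()))
  sdp <- ifelse(m$n_mut + m$n_ref > 2,
                pooled_sd(m$n_ref, m$sd_psi_ref, m$n_mut, m$sd_psi_mut),
                NA_real_)
  out <- data.frame(bin_id = m$bin_id, muscle = m$muscle,
                    dpsi = m$mean_psi_mut - m$mean_psi_ref,
                    sd_pooled = sdp,
                    n_mut = m$n_mut, n_ref = m$n_ref,
                    stringsAsFactors = FALSE)
  out[order(out$bin_id, out$muscle), ]
}

#' Two-way factorial ANOVA on one bin's PSI
#'
#' Fits `psi ~ genotype * muscle` on the non-missing PSI values of a bin
#' and returns Type III F tests computed with sum-to-zero contrasts
#' (unbalanced designs allowed). Requires at least two levels of each
#' factor among the non-missing observations.
#'
#' @param table A `psi_table`.
#' @param bin_id Bin to test.
#' @return data.frame with one row per effect (`genotype`, `muscle`,
#'   `genotype:muscle`): `F`, `p`, `df`, plus the residual df as an
#'   attribute `"df_residual"`; `NULL` when the bin has no testable data.
#' @export
anova_two_way <- function(table, bin_id) {
  stopifnot(inherits(table, "psi_table"))
  d <- merge(table$psi[table$psi$bin_id == bin_id, , drop = FALSE],
             table$metadata, by = "sample_id")
  d <- d[!is.na(d$psi), , drop = FALSE]
  if (nrow(d) == 0L) return(NULL)
  d$genotype <- factor(d$genotype)
  d$muscle <- factor(d$muscle)
  if (nlevels(d$genotype) < 2L || nlevels(d$muscle) < 2L)
    stop("bin ", bin_id, ": both factors need >= 2 observed levels")
  fit <- stats::lm(psi ~ genotype * muscle, data = d,
                   contrasts = list(genotype = "contr.sum",
                                    muscle = "contr.sum"))
  a <- car::Anova(fit, type = 3)
  eff <- c("genotype", "muscle", "genotype:muscle")
  rows <- match(eff, rownames(a))
  out <- data.frame(bin_id = bin_id, effect = eff,
                    df = a$Df[rows],
                    F = a$`F value`[rows],
                    p = a$`Pr(>F)`[rows],
                    stringsAsFactors = FALSE)
  attr(out, "df_residual") <- a$Df[rownames(a) == "Residuals"]
  out
}

#' Holm (sequential Bonferroni) step-down correction
#'
#' Sorts the p-values ascending and sets
#' `p_adj(i) = max_{j <= i} min(1, (m - j + 1) p(j))`, rejecting while
#' `p_adj <= alpha`. Uniformly more powerful than single-step Bonferroni at
#' the same family-wise error rate. Missing p-values propagate as missing
#' and do not count toward the family size m.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\]; may contain `NA`.
#' @param alpha Significance level (default 0.05).
#' @param m Family size; defaults to the number of non-missing p-values,
#'   but can be set larger when the tested bins are a subset of a wider
#'   family.
#' @return data.frame `p`, `p_adjusted`, `significant`, in input order.
#' @export
#' @examples
#' sequential_bonferroni(c(0.01, 0.04, 0.03))
sequential_bonferroni <- function(p_values, alpha = 0.05, m = NULL) {
  p <- as.numeric(p_values)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  ok <- which(!is.na(p))
  k <- length(ok)
  if (is.null(m)) m <- k
  if (m < k) stop("family size m cannot be smaller than the number of tests")
  adj <- rep(NA_real_, length(p))
  if (k > 0L) {
    o <- ok[order(p[ok])]
    stepwise <- pmin(1, (m - seq_len(k) + 1) * p[o])
    adj[o] <- cummax(stepwise)
  }
  data.frame(p = p, p_adjusted = adj,
             significant = !is.na(adj) & adj <= alpha)
}

#' Genotype comparison of splicing across all bins
#'
#' Convenience wrapper running the full comparison: per-group summaries,
#' per-muscle dPSI with pooled SD, a per-bin two-way ANOVA genotype test,
#' and Holm correction across the tested bins.
#'
#' @param table A `psi_table`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param family_size Multiple-testing family size m; defaults to the
#'   number of bins that could be tested.
#' @param mutant,reference Genotype labels.
#' @return data.frame with one row per bin and muscle: `bin_id`, `muscle`,
#'   `dpsi`, `sd_pooled`, `p_value` (genotype main effect, shared across
#'   the muscles of a bin), `p_adjusted`, `significant`.
#' @export
compare_splicing <- function(table, alpha = 0.05, family_size = NULL,
                             mutant = "mdm", reference = "WT") {
  summ <- summarize_groups(table)
  dp <- delta_psi(summ, mutant = mutant, reference = reference)
  bins <- unique(dp$bin_id)
  pvals <- vapply(bins, function(b) {
    res <- tryCatch(anova_two_way(table, b), error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    res$p[res$effect == "genotype"]
  }, numeric(1))
  holm <- sequential_bonferroni(pvals, alpha = alpha, m = family_size)
  idx <- match(dp$bin_id, bins)
  dp$p_value <- pvals[idx]
  dp$p_adjusted <- holm$p_adjusted[idx]
  dp$significant <- holm$significant[idx]
  dp
}
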