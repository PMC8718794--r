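#' Housekeeping-gene normalisation of a count matrix
#'
#' Per-sample scale factor = geometric mean of that sample's
#' housekeeping counts divided by the across-sample geometric mean of
#' those values; every count is divided by its sample's factor, then
#' log2(x + 1) transformed. Any zero housekeeping count is an error (a
#' zero reference makes the geometric mean degenerate), reported with
#' gene and sample.
#'
#' @param m A `count_matrix` (or a list with `counts`, `groups`,
#'   `housekeeping`).
#' @return Object of class `normalized_counts`: `log2` and `linear`
#'   (genes x samples matrices), `factors` (per-sample scale factors),
#'   `groups`, `housekeeping`.
#' @export
normalize_counts <- function(m) {
  counts <- m$counts
  hk <- m$housekeeping
  if (!length(hk) || !all(hk %in% rownames(counts)))
    stop_invalid("housekeeping genes must be present in the matrix")
  if (is.null(m$groups) || length(unique(m$groups)) != 2 ||
      any(table(m$groups) < 2))
    stop_invalid("need two groups with >= 2 samples each")
  hk_counts <- counts[hk, , drop = FALSE]
  zero <- which(hk_counts == 0, arr.ind = TRUE)
  if (nrow(zero))
    stop(errorCondition(
      sprintf("zero housekeeping count: gene %s, sample %s",
              rownames(hk_counts)[zero[1, 1]], colnames(counts)[zero[1, 2]]),
      class = c("alternans_normalization_error", "error", "condition")))
  gm <- exp(colMeans(log(hk_counts)))
  factors <- gm / exp(mean(log(gm)))
  linear <- sweep(counts, 2, factors, "/")
  structure(list(log2 = log2(linear + 1), linear = linear, factors = factors,
                 groups = m$groups, housekeeping = hk),
            class = "normalized_counts")
}

#' Welch's unequal-variance t-test
#'
#' Returns the Welch t statistic, Welch-Satterthwaite degrees of
#' freedom, and the two-sided p value. Zero variance in both groups with
#' equal means gives p = 1 by convention.
#'
#' @param values_a,values_b Numeric vectors (each >= 2 values).
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_test(c(10, 12, 14), c(20, 22, 24))
welch_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop_invalid("each group needs >= 2 values")
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(t = 0, df = length(values_a) + length(values_b) - 2, p = 1))
    return(list(t = sign(mean(values_a) - mean(values_b)) * Inf,
                df = length(values_a) + length(values_b) - 2, p = 0))
  }
  ht <- t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment `p(i) * m * c(m) / i` with `c(m) = sum_{k=1}^m
#' 1/k`, monotonised and capped at 1 -- valid under arbitrary dependence
#' between tests, which is why it suits correlated transcript panels.
#'
#' @param p_values Vector of raw p values in \[0, 1\].
#' @return Adjusted p values in the input order.
#' @export
#' @examples
#' adjust_by(c(0.01, 0.02, 0.9))  # 0.055 0.055 1.000
adjust_by <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_invalid("p values must lie in [0, 1]")
  p.adjust(p_values, method = "BY")
}

#' Differential-expression calls on a normalised count table
#'
#' Per-gene Welch t-test on log2 normalised expression (group 2 vs group
#' 1), Benjamini-Yekutieli adjustment across all tested genes, direction
#' by sign of the mean log2 difference, and a significance call at
#' `alpha` with no fold-change cutoff. If `negative_controls` are given,
#' genes are first filtered to those detected above background (mean
#' count > mean + 2 SD of the negative-control counts); this 2-SD rule
#' is a stand-in for proprietary panel background thresholds.
#'
#' @param m A `count_matrix` or `normalized_counts`.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param negative_controls Optional character vector of negative-control
#'   gene names used for background filtering (excluded from testing).
#' @return A data.frame of class `deg_table`: `gene`, `log2fc`
#'   (group2 - group1), `t`, `df`, `p`, `p_adj`, `direction`,
#'   `significant`; summary counts in `attr(, "summary")`.
#' @export
call_degs <- function(m, alpha = 0.05, negative_controls = NULL) {
  norm <- if (inherits(m, "normalized_counts")) m else normalize_counts(m)
  x <- norm$log2
  if (!is.null(negative_controls)) {
    nc <- intersect(negative_controls, rownames(x))
    if (length(nc)) {
      raw_nc <- (2^x[nc, , drop = FALSE]) - 1
      thr <- mean(raw_nc) + 2 * sd(raw_nc)
      keep <- rowMeans((2^x) - 1) > thr
      keep[nc] <- FALSE
      x <- x[keep, , drop = FALSE]
    }
  }
  g <- norm$groups
  lv <- levels(g)
  a_idx <- g == lv[1]; b_idx <- g == lv[2]
  res <- lapply(rownames(x), function(gene) {
    va <- x[gene, a_idx]; vb <- x[gene, b_idx]
    if (any(is.na(va)) && all(is.na(va)) || any(is.na(vb)) && all(is.na(vb)))
      return(NULL)
    w <- welch_test(vb, va)           # group2 vs group1 orientation
    data.frame(gene = gene, log2fc = mean(vb) - mean(va),
               t = w$t, df = w$df, p = w$p)
  })
  dropped <- rownames(x)[vapply(res, is.null, logical(1))]
  if (length(dropped))
    warning("genes with a fully missing group excluded: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, res)
  out$p_adj <- adjust_by(out$p)
  out$direction <- ifelse(out$log2fc >= 0, "up", "down")
  out$significant <- out$p_adj < alpha
  attr(out, "summary") <- list(n_tested = nrow(out),
                               n_significant = sum(out$significant),
                               n_up = sum(out$significant & out$direction == "up"),
                               n_down = sum(out$significant & out$direction == "down"),
                               alpha = alpha,
                               orientation = sprintf("%s vs %s", lv[2], lv[1]))
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @export
print.deg_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("DEG table (%s): %d tested, %d significant (%d up, %d down) at adjusted p < %g\n",
              s$orientation, s$n_tested, s$n_significant, s$n_up, s$n_down, s$alpha))
  NextMethod()
}

#' Group-mean expression ratio of two genes
#'
#' Ratio of the group-mean linear-scale normalised expression of
#' `gene_a` to `gene_b` in one group (e.g. a TNNI3/TNNI1 maturation
#' index).
#'
#' @param norm A `normalized_counts` (or `count_matrix`).
#' @param gene_a,gene_b Gene names.
#' @param group Group label.
#' @return Dimensionless ratio.
#' @export
expression_ratio <- function(norm, gene_a, gene_b, group) {
  if (inherits(norm, "count_matrix")) norm <- normalize_counts(norm)
  x <- norm$linear
  if (!all(c(gene_a, gene_b) %in% rownames(x)))
    stop_invalid("both genes must be present")
  sel <- norm$groups == group
  if (!any(sel)) stop_invalid(sprintf("no samples in group '%s'", group))
  den <- mean(x[gene_b, sel])
  if (den == 0) stop_invalid("zero denominator expression")
  mean(x[gene_a, sel]) / den
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct_target - mean(Ct of the two reference genes)`
#' (the arithmetic mean in Ct space equals geometric-mean normalisation
#' on the linear scale); `ddCt = mean dCt(condition) - mean
#' dCt(reference group)`; fold change = `2^-ddCt`.
#'
#' @param ct Data.frame with columns `gene`, `sample`, `group`, `ct`.
#' @param target_gene Gene of interest.
#' @param condition_group,reference_group Group labels.
#' @param housekeeping Two reference genes, default `c("ACTB", "GAPDH")`.
#' @return Fold change (condition vs reference).
#' @export
#' @examples
#' ct <- expand.grid(gene = c("NPPA", "ACTB", "GAPDH"),
#'                   sample = 1:3, group = c("WT", "I79N"))
#' ct$ct <- 20
#' ct$ct[ct$gene == "NPPA" & ct$group == "I79N"] <- 20 - log2(18.6)
#' ddct_fold(ct, "NPPA", "I79N", "WT")  # 18.6
ddct_fold <- function(ct, target_gene, condition_group, reference_group,
                      housekeeping = c("ACTB", "GAPDH")) {
  need <- c("gene", "sample", "group", "ct")
  if (!all(need %in% names(ct))) stop_invalid("ct table needs gene, sample, group, ct")
  if (length(housekeeping) != 2) stop_invalid("exactly two housekeeping genes required")
  if (any(!is.finite(ct$ct))) stop_invalid("all Ct values must be finite")
  dct_group <- function(grp) {
    sub <- ct[ct$group == grp, ]
    samples <- unique(sub$sample)
    vals <- vapply(samples, function(s) {
      ss <- sub[sub$sample == s, ]
      tgt <- ss$ct[ss$gene == target_gene]
      hks <- vapply(housekeeping, function(h) {
        v <- ss$ct[ss$gene == h]
        if (!length(v)) NA_real_ else mean(v)
      }, numeric(1))
      if (!length(tgt) || any(is.na(hks)))
        stop_invalid(sprintf(
          "missing Ct measurement for sample %s in group %s (need %s)",
          s, grp, paste(c(target_gene, housekeeping), collapse = ", ")))
      mean(tgt) - mean(hks)
    }, numeric(1))
    mean(vals)
  }
  ddct <- dct_group(condition_group) - dct_group(reference_group)
  2^(-ddct)
}
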