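#' Housekeeping genes used for count normalisation
#'
#' The seven reference genes used by default when generating and
#' normalising transcript-count panels.
#' @export
HOUSEKEEPING_GENES <- c("PIK3CA", "ATP5F1", "IPO8", "PPIA", "SPCS1", "AKT", "RPS13")

#' Default injected fold changes for the synthetic count panel
#'
#' A fixed 68-gene complement of differential expression (45 up, 23
#' down) emulating the remodelling signature of the variant line:
#' hypertrophy markers NPPA (18.6-fold) and NPPB (5.9-fold), Notch
#' pathway components, collagens, down-regulated pluripotency and
#' developmental markers, and graded anonymous effects filling out the
#' volcano. Used as the `fold_changes` default of [gen_counts()].
#'
#' @return Named numeric vector of group-2/group-1 fold changes.
#' @export
default_panel_folds <- function() {
  up_named <- c(NPPA = 18.6, NPPB = 5.9, NOTCH1 = 2.5, NOTCH3 = 2.2,
                NOTCH4 = 2.8, JAG1 = 2.0, HEY1 = 2.4,
                COL1A1 = 6.0, COL3A1 = 4.5, COL9A2 = 3.5)
  up_anon <- setNames(round(seq(1.6, 4.0, length.out = 35), 2),
                      sprintf("UPR%02d", seq_len(35)))
  dn_named <- c(SOX2 = 0.40, BMP4 = 0.45)
  dn_anon <- setNames(round(seq(0.30, 0.65, length.out = 21), 2),
                      sprintf("DNR%02d", seq_len(21)))
  c(up_named, up_anon, dn_named, dn_anon)
}

#' Generate a synthetic gene-by-sample transcript count matrix
#'
#' Emulates a targeted transcript-count panel (two genotype groups,
#' unequal group sizes) with gamma-Poisson (negative-binomial-like)
#' counts: gene `g` in sample `s` is Poisson with a gamma-distributed
#' mean of expectation `mu[g] * fold[g, group(s)]` and dispersion `phi`,
#' so `Var = mu + phi * mu^2`. Housekeeping genes are constrained to fold
#' 1 by construction (they are the normalisation anchor downstream).
#' Genes named in `fold_changes` have their group-2 mean multiplied by
#' the fold; the default [default_panel_folds()] injects a 68-gene
#' remodelling signature (45 up, 23 down) led by the
#' natriuretic-peptide markers at 18.6- and 5.9-fold.
#'
#' @param n_genes Total number of genes (default 236, a typical detected
#'   panel size).
#' @param group_sizes Two integers >= 2; default `c(4, 3)` (control,
#'   variant).
#' @param housekeeping Character vector of stable reference genes;
#'   default [HOUSEKEEPING_GENES].
#' @param fold_changes Named numeric vector, gene -> fold applied to the
#'   group-2 mean. Folds must be > 0 and must not touch housekeeping
#'   genes.
#' @param dispersion Gamma-Poisson dispersion `phi` >= 0 (0 = Poisson).
#'   The default 0.01 corresponds to a replicate coefficient of
#'   variation of about 10%, the precision a targeted count panel must
#'   have for fold changes of a few fold to clear a Benjamini-Yekutieli
#'   correction at group sizes of 4 and 3, as observed panels do.
#' @param baseline_mean Median baseline expression (counts).
#' @param seed Integer seed.
#' @param group_labels Length-2 labels, default `c("WT", "I79N")`.
#'
#' @return An object of class `count_matrix`: list with `counts` (genes x
#'   samples integer matrix), `groups` (factor), `housekeeping`, `truth`.
#' @export
#' @examples
#' cm <- gen_counts(seed = 1)
#' dim(cm$counts)
gen_counts <- function(n_genes = 236, group_sizes = c(4, 3),
                       housekeeping = HOUSEKEEPING_GENES,
                       fold_changes = default_panel_folds(),
                       dispersion = 0.01, baseline_mean = 500, seed = 1,
                       group_labels = c("WT", "I79N")) {
  if (length(group_sizes) != 2L || any(group_sizes < 2))
    stop_invalid("`group_sizes` must be two counts >= 2")
  check_number(dispersion, "dispersion", 0)
  check_number(baseline_mean, "baseline_mean", 0, strict_lower = TRUE)
  if (length(fold_changes) && is.null(names(fold_changes)))
    stop_invalid("`fold_changes` must be a named vector")
  if (any(fold_changes <= 0)) stop_invalid("all fold changes must be > 0")
  if (any(names(fold_changes) %in% housekeeping))
    stop_invalid("housekeeping genes cannot carry a fold change")
  n_named <- length(housekeeping) + length(fold_changes)
  if (n_genes < n_named)
    stop_invalid("`n_genes` smaller than the number of named genes")

  filler <- sprintf("GENE%03d", seq_len(n_genes - n_named))
  genes <- c(housekeeping, names(fold_changes), filler)
  n_samples <- sum(group_sizes)
  groups <- factor(rep(group_labels, group_sizes), levels = group_labels)
  samples <- paste0(rep(group_labels, group_sizes), "_",
                    c(seq_len(group_sizes[1]), seq_len(group_sizes[2])))

  old <- local_seed(seed)
  on.exit(restore_seed(old))
  # per-gene baseline means: housekeeping pinned at the baseline, the rest
  # log-normal around it (a realistic panel spans ~2 orders of magnitude)
  mu <- setNames(rlnorm(n_genes, log(baseline_mean), 1), genes)
  mu[housekeeping] <- baseline_mean
  mu[names(fold_changes)] <- baseline_mean
  fold <- setNames(rep(1, n_genes), genes)
  fold[names(fold_changes)] <- fold_changes

  counts <- matrix(0L, n_genes, n_samples, dimnames = list(genes, samples))
  for (j in seq_len(n_samples)) {
    m <- if (groups[j] == group_labels[2]) mu * fold else mu
    lam <- if (dispersion < 1e-12) m
           else rgamma(n_genes, shape = 1 / dispersion, scale = m * dispersion)
    counts[, j] <- rpois(n_genes, lam)
  }
  structure(list(counts = counts, groups = groups, housekeeping = housekeeping,
                 truth = list(kind = "counts", mu = mu, fold = fold,
                              dispersion = dispersion, group_sizes = group_sizes,
                              seed = seed)),
            class = "count_matrix")
}
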