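#' Estimated cardiomyocyte volume
#'
#' Mean cell length multiplied by mean cross-section area.
#'
#' @param mean_length_um mean cell length, um (> 0)
#' @param mean_cross_section_um2 mean cell cross-section, um^2 (> 0)
#' @return volume in um^3
#' @examples
#' estimate_cm_volume(50, 61)   # 3050 um^3
#' @export
estimate_cm_volume <- function(mean_length_um, mean_cross_section_um2) {
  check_positive(mean_length_um, "mean_length_um")
  check_positive(mean_cross_section_um2, "mean_cross_section_um2")
  structure(mean_length_um * mean_cross_section_um2, units = "um^3")
}

#' Muscular mass of an engineered heart tissue
#'
#' Tissue length multiplied by the alpha-actinin-positive cross-section.
#'
#' @param tissue_length_mm tissue length, mm (> 0)
#' @param actinin_cross_section_mm2 actinin-positive cross-section, mm^2 (> 0)
#' @return volume in mm^3
#' @export
muscular_mass <- function(tissue_length_mm, actinin_cross_section_mm2) {
  check_positive(tissue_length_mm, "tissue_length_mm")
  check_positive(actinin_cross_section_mm2, "actinin_cross_section_mm2")
  structure(tissue_length_mm * actinin_cross_section_mm2, units = "mm^3")
}

#' Adult-gene-set maturation score
#'
#' Average abundance of a set of adult-cardiomyocyte-specific genes in one
#' group relative to another: the score is the ratio of the gene-set mean of
#' per-gene group means (group A over group B). Per-gene fold changes are
#' also returned; genes with a zero group-B mean get a pseudocount with a
#' warning.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns; normalized non-negative abundances
#' @param gene_set character vector of gene ids (must be rows of `expr`)
#' @param group_a,group_b column names or indices of the two groups
#' @param pseudocount added to zero denominators
#' @param gene_mean "arithmetic" (default, matching an average-abundance
#'   ratio) or "geometric" (mean of log folds)
#' @return list with `score` (fold, group A / group B), `per_gene` (data
#'   frame of per-gene means and folds)
#' @export
maturation_score <- function(expr, gene_set, group_a, group_b,
                             pseudocount = 0.5,
                             gene_mean = c("arithmetic", "geometric")) {
  gene_mean <- match.arg(gene_mean)
  if (!length(gene_set)) stop_eht("empty gene set")
  missing <- setdiff(gene_set, rownames(expr))
  if (length(missing))
    stop_eht("gene set members absent from matrix: %s",
             paste(utils::head(missing, 5), collapse = ", "))
  if (!length(group_a) || !length(group_b)) stop_eht("both groups must be non-empty")
  if (any(expr < 0)) stop_eht("expression matrix must be non-negative")
  a <- rowMeans(expr[gene_set, group_a, drop = FALSE])
  b <- rowMeans(expr[gene_set, group_b, drop = FALSE])
  zero <- b == 0
  if (any(zero)) {
    warning(sprintf("%d gene(s) with zero denominator mean; using pseudocount %g",
                    sum(zero), pseudocount), call. = FALSE)
    a[zero] <- a[zero] + pseudocount
    b[zero] <- b[zero] + pseudocount
  }
  score <- if (gene_mean == "arithmetic") mean(a) / mean(b)
           else exp(mean(log(a / b)))
  list(score = score,
       per_gene = data.frame(gene = gene_set, mean_a = a, mean_b = b,
                             fold = a / b, row.names = NULL))
}

#' Group-level mean / SEM aggregation
#'
#' Aggregates per-sample metrics by group label, reporting mean, SD, SEM
#' (SD divided by the square root of n) and n per metric and group, plus the
#' fold change of each group mean versus a reference group. Groups with a
#' single sample have `NA` SEM.
#'
#' @param data data frame of per-sample metric columns
#' @param group factor or character vector of group labels, one per row
#' @param reference reference group label for the fold column (default the
#'   first level)
#' @return data frame: `group`, `metric`, `n`, `mean`, `sd`, `sem`,
#'   `fold_vs_reference`
#' @export
group_aggregate <- function(data, group, reference = NULL) {
  if (nrow(data) != length(group)) stop_eht("`group` must match rows of `data`")
  group <- as.character(group)
  lv <- unique(group)
  reference <- reference %||% lv[1]
  if (!reference %in% lv) stop_eht("unknown reference group '%s'", reference)
  num <- names(data)[vapply(data, is.numeric, TRUE)]
  rows <- list()
  for (m in num) {
    ref_mean <- mean(data[[m]][group == reference], na.rm = TRUE)
    for (g in lv) {
      x <- data[[m]][group == g]
      x <- x[!is.na(x)]
      n <- length(x)
      if (n < 1) stop_eht("group '%s' has no samples for metric '%s'", g, m)
      s <- if (n > 1) stats::sd(x) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, n = n, mean = mean(x), sd = s,
        sem = if (n > 1) s / sqrt(n) else NA_real_,
        fold_vs_reference = if (is.finite(ref_mean) && ref_mean != 0)
          mean(x) / ref_mean else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Synthetic normalized expression matrix with a shifted gene set
#'
#' Log-normal abundances for `n_genes` genes over two groups; the members of
#' the embedded adult gene set are `set_fold` times more abundant (in
#' expectation) in group A than in group B.
#'
#' @param n_genes total genes
#' @param n_set size of the embedded gene set
#' @param set_fold true set-level fold (group A / group B)
#' @param n_per_group samples per group
#' @param sigma_log SD of the log-normal sample noise (natural log)
#' @param base_mean expected abundance of unshifted genes
#' @param rng_seed integer seed
#' @return list with `expr` (matrix), `gene_set`, `group_a`, `group_b`,
#'   `truth` (the generating fold)
#' @export
generate_expression_matrix <- function(n_genes = 200, n_set = 20,
                                       set_fold = 2.1, n_per_group = 6,
                                       sigma_log = 0.3, base_mean = 100,
                                       rng_seed = 1L) {
  with_rng(rng_seed, {
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
    set_ids <- gene_ids[seq_len(n_set)]
    cols <- c(sprintf("A%d", seq_len(n_per_group)),
              sprintf("B%d", seq_len(n_per_group)))
    gene_base <- base_mean * exp(stats::rnorm(n_genes, 0, 0.5))
    mu <- matrix(gene_base, n_genes, 2 * n_per_group)
    mu[seq_len(n_set), seq_len(n_per_group)] <-
      mu[seq_len(n_set), seq_len(n_per_group)] * set_fold
    noise <- matrix(exp(stats::rnorm(length(mu), -sigma_log^2 / 2, sigma_log)),
                    n_genes, 2 * n_per_group)
    expr <- mu * noise
    dimnames(expr) <- list(gene_ids, cols)
    list(expr = expr, gene_set = set_ids,
         group_a = cols[seq_len(n_per_group)],
         group_b = cols[n_per_group + seq_len(n_per_group)],
         truth = set_fold)
  })
}
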