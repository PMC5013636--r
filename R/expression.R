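## Bulk expression utilities: median-of-ratios size factors, a documented
## variance-stabilizing stand-in transform with per-gene batch-median
## alignment, a transformed-scale differential expression test with BH
## control, Pearson/complete-linkage clustering with PCA, and the CIN70
## chromosomal-instability score with covariate adjustment.

#' Construct an expression study container
#'
#' @param counts Nonnegative integer matrix, genes x samples (dimnames set).
#' @param meta Data frame with one row per sample (matched to columns of
#'   `counts` by the `sample` column) and columns among `sample`, `stage`,
#'   `subject`, `batch`, `species`.
#' @return A list of class `expression_study` with `counts`, `meta` and,
#'   after [normalize_study()], `size_factors` and `vst`.
#' @export
expression_study <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  if (!"sample" %in% names(meta)) stop("meta must have a sample column")
  if (!setequal(colnames(counts), meta$sample)) {
    stop("meta must cover exactly the samples in counts")
  }
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "expression_study")
}

#' @exportS3Method base::print
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if ("stage" %in% names(x$meta)) {
    cat("  stages:", paste(names(table(x$meta$stage)), table(x$meta$stage),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' The scaling-factor normalization of count matrices: for each sample, the
#' median across genes (expressed in every sample) of the ratio of its count
#' to the gene's geometric mean, rescaled so the factors have geometric
#' mean 1. Falls back to total-count scaling with a warning when no gene is
#' expressed in all samples.
#'
#' @param counts Genes x samples count matrix.
#' @return Positive numeric vector of per-sample factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    warning("no gene expressed in all samples; using total-count scaling")
    sf <- colSums(counts)
    if (any(sf == 0)) stop("sample with zero total count")
    return(sf / exp(mean(log(sf))))
  }
  sub <- counts[allpos, , drop = FALSE]
  log_gm <- rowMeans(log(sub))
  sf <- apply(sub, 2L, function(cj) exp(stats::median(log(cj) - log_gm)))
  sf / exp(mean(log(sf)))
}

#' Variance-flattening transform with per-gene batch-median alignment
#'
#' Applies the package's variance-stabilizing stand-in,
#' `log2(count / size_factor + 1)`, then aligns batches per gene by shifting
#' each batch's values so that every batch median equals the gene's global
#' median (computed before alignment). The alignment is an additive shift on
#' the log scale and is idempotent.
#'
#' @param counts Genes x samples count matrix.
#' @param size_factors Per-sample positive factors (default: recomputed).
#' @param batches Per-sample batch labels; `NULL` skips alignment.
#' @return Transformed (and aligned) numeric matrix.
#' @export
vst_batch_align <- function(counts, size_factors = NULL, batches = NULL) {
  counts <- as.matrix(counts)
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(counts)
  x <- log2(sweep(counts, 2L, size_factors, "/") + 1)
  if (is.null(batches) || length(unique(batches)) < 2L) return(x)
  stopifnot(length(batches) == ncol(x))
  tab <- table(batches)
  if (any(tab == 1L)) {
    message("single-sample batch(es): ", paste(names(tab)[tab == 1L], collapse = ", "))
  }
  align_batch_medians(x, batches)
}

## Per-gene additive shift so each batch's median equals the global median.
align_batch_medians <- function(x, batches) {
  gmed <- apply(x, 1L, stats::median)
  for (b in unique(batches)) {
    idx <- which(batches == b)
    bmed <- apply(x[, idx, drop = FALSE], 1L, stats::median)
    x[, idx] <- x[, idx, drop = FALSE] + (gmed - bmed)
  }
  x
}

#' Transformed-scale differential expression between two groups
#'
#' Per-gene Welch t-test on transformed expression values (the package's
#' documented stand-in for a count-model test), with the log2 fold change as
#' the difference of group means and Benjamini-Hochberg control across
#' genes. In paired mode the test is a one-sample t-test on within-subject
#' differences.
#'
#' @param x Transformed expression matrix (genes x samples).
#' @param groups Per-sample group labels.
#' @param group_a,group_b The two labels to compare (fold change is
#'   `group_b` over `group_a`).
#' @param subjects Optional per-sample subject ids; when given, samples are
#'   paired within subject (subjects lacking either group are dropped).
#' @return Data frame of class results: `gene`, `log2fc`, `p`, `q`,
#'   `comparison`.
#' @export
differential_expression <- function(x, groups, group_a, group_b,
                                    subjects = NULL) {
  x <- as.matrix(x)
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2L || length(ib) < 2L) stop("need >= 2 samples per group")
  paired <- !is.null(subjects)
  if (paired) {
    common <- intersect(subjects[ia], subjects[ib])
    if (length(common) < 2L) stop("need >= 2 complete subjects for pairing")
    ia <- ia[match(common, subjects[ia])]
    ib <- ib[match(common, subjects[ib])]
  }
  a <- x[, ia, drop = FALSE]
  b <- x[, ib, drop = FALSE]
  lfc <- rowMeans(b) - rowMeans(a)
  p <- vapply(seq_len(nrow(x)), function(g) {
    av <- a[g, ]; bv <- b[g, ]
    if (paired) {
      d <- bv - av
      if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
      return(stats::t.test(d)$p.value)
    }
    if (stats::sd(av) == 0 && stats::sd(bv) == 0) {
      return(if (mean(av) == mean(bv)) 1 else 0)
    }
    stats::t.test(bv, av)$p.value
  }, numeric(1))
  genes <- rownames(x)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(x)))
  data.frame(gene = genes, log2fc = lfc, p = p,
             q = stats::p.adjust(p, method = "BH"),
             comparison = paste0(group_b, "_vs_", group_a),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Threshold a differential-expression table
#'
#' @param de Result of [differential_expression()].
#' @param q_max BH q-value cutoff (default 0.25).
#' @param fc_min Minimum linear fold change (default 1.25); applied as
#'   `|log2fc| > log2(fc_min)`.
#' @param use Which significance column gates, `"q"` (default) or `"p"`.
#' @param p_max Cutoff when `use = "p"`.
#' @return The passing subset, split into `up` and `down` gene vectors plus
#'   the filtered table.
#' @export
de_threshold <- function(de, q_max = 0.25, fc_min = 1.25, use = c("q", "p"),
                         p_max = 0.05) {
  use <- match.arg(use)
  sig <- if (use == "q") de$q < q_max else de$p < p_max
  keep <- sig & abs(de$log2fc) > log2(fc_min)
  sub <- de[keep, , drop = FALSE]
  list(table = sub,
       up = sub$gene[sub$log2fc > 0],
       down = sub$gene[sub$log2fc < 0])
}

#' Pearson-correlation clustering and PCA of samples
#'
#' Distance is `1 - Pearson r` between sample profiles, clustered with
#' complete linkage; PCA is on centred transformed values. Constant sample
#' profiles have undefined correlation and are excluded with a warning. Each
#' principal component is oriented so its largest-magnitude loading is
#' positive, making the output deterministic.
#'
#' @param x Transformed expression matrix (genes x samples).
#' @param gene_subset Optional gene ids restricting the analysis.
#' @return List with `cor` (sample correlation matrix), `hclust`, `order`
#'   (dendrogram leaf order), `pca` (samples x components scores) and
#'   `var_explained`.
#' @export
correlation_cluster_pca <- function(x, gene_subset = NULL) {
  x <- as.matrix(x)
  if (!is.null(gene_subset)) {
    x <- x[intersect(rownames(x), gene_subset), , drop = FALSE]
  }
  if (ncol(x) < 3L) stop("need >= 3 samples")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant sample profile(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  cm <- stats::cor(x)
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "complete")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(cor = cm, hclust = hc, order = colnames(x)[hc$order],
       pca = pc$x, var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' CIN70 chromosomal-instability score with covariate adjustment
#'
#' The raw score is the per-sample sum of normalized counts over the CIN70
#' gene list; it is variance-flattened as `log2(raw + 1)` and adjusted by
#' taking residuals of a least-squares fit on indicator covariates
#' (typically subject and batch), so repeated sampling of a patient and
#' processing batches do not masquerade as instability differences.
#'
#' @param study An [expression_study()].
#' @param cin_genes Character vector of instability-signature gene ids
#'   (supplied as data, e.g. read from a GMT file).
#' @param covariates Character vector of metadata columns to adjust for
#'   (default `c("subject", "batch")`, intersected with available columns).
#' @param size_factors Optional precomputed size factors.
#' @return Data frame per sample: `sample`, `raw`, `transformed`,
#'   `adjusted`.
#' @export
cin70_score <- function(study, cin_genes,
                        covariates = c("subject", "batch"),
                        size_factors = NULL) {
  counts <- study$counts
  present <- intersect(rownames(counts), cin_genes)
  if (length(present) == 0L) stop("no CIN gene present in the study")
  if (length(present) < length(cin_genes)) {
    message(length(cin_genes) - length(present), " CIN gene(s) absent from the study")
  }
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(counts)
  norm <- sweep(counts[present, , drop = FALSE], 2L, size_factors, "/")
  raw <- colSums(norm)
  transformed <- log2(raw + 1)
  covariates <- intersect(covariates, names(study$meta))
  if (length(covariates) == 0L) {
    adjusted <- transformed - mean(transformed)
  } else {
    df <- study$meta[, covariates, drop = FALSE]
    df[] <- lapply(df, as.factor)
    mm <- stats::model.matrix(~ ., data = df)
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      warning("rank-deficient covariate design; redundant columns dropped")
    }
    adjusted <- stats::residuals(stats::lm.fit(mm[, qr_mm$pivot[seq_len(qr_mm$rank)],
                                                  drop = FALSE], transformed))
  }
  data.frame(sample = colnames(counts), raw = raw, transformed = transformed,
             adjusted = as.numeric(adjusted), row.names = NULL,
             stringsAsFactors = FALSE)
}
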