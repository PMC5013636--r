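## Per-gene linear mixed-effects progression modelling: transformed
## expression as a function of lesion stage (fixed effect) with a random
## intercept per subject; Wald tests on the three stage contrasts;
## early/late/stepwise designation; one-to-one homolog intersection across
## species; and motif-set overrepresentation with a conjugate Bayes factor.

## Containment denominator df for the within-subject stage effect: the
## convention of classic mixed-model software for level-1 fixed effects,
## N - n_subjects - p_within (= 10 for six subjects x three stages).
lme_containment_df <- function(n_obs, n_subjects, p_within) {
  max(1L, n_obs - n_subjects - p_within)
}

#' Fit a random-intercept stage model for one gene
#'
#' Fits `value ~ stage + (1 | subject)` by REML with the requested reference
#' stage and returns Wald t-tests for each non-reference stage coefficient,
#' using the containment denominator degrees of freedom
#' (`N - n_subjects - 2` for three stages), the convention of the classic
#' mixed-effects software this models after.
#'
#' @param values Numeric vector of transformed expression values.
#' @param stage Factor-like vector of lesion stages per sample.
#' @param subject Subject (patient/mouse) id per sample.
#' @param reference_stage Stage used as the model reference level.
#' @return List with `coef` (named stage contrasts), `se`, `p`, `df`,
#'   `converged`. A numerically unstable or degenerate gene returns
#'   `converged = FALSE` and `NA` statistics rather than an error.
#' @export
fit_gene_lme <- function(values, stage, subject, reference_stage) {
  stage <- stats::relevel(factor(stage), ref = reference_stage)
  dat <- data.frame(y = values, stage = stage, subject = factor(subject))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ stage + (1 | subject), data = dat, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    )),
    error = function(e) NULL)
  lev <- levels(stage)
  nm <- paste0(lev[-1L], "-", lev[1L])
  df <- lme_containment_df(length(values), nlevels(dat$subject),
                           nlevels(stage) - 1L)
  if (is.null(fit) || stats::sd(values) == 0) {
    na <- stats::setNames(rep(NA_real_, length(nm)), nm)
    return(list(coef = na, se = na, p = na, df = df, converged = FALSE))
  }
  b <- lme4::fixef(fit)[-1L]
  vc <- as.matrix(stats::vcov(fit))[-1L, -1L, drop = FALSE]
  se <- sqrt(diag(vc))
  tstat <- b / se
  list(coef = stats::setNames(as.numeric(b), nm),
       se = stats::setNames(as.numeric(se), nm),
       p = stats::setNames(2 * stats::pt(-abs(tstat), df), nm),
       df = df,
       converged = all(is.finite(b)) && all(is.finite(se)) && all(se > 0))
}

#' Fit the progression model across all genes of a study
#'
#' For each gene, fits the random-intercept stage model once by REML and
#' derives all three stage contrasts (middle vs first, last vs first, last
#' vs middle) with Wald t-tests (containment df, see [fit_gene_lme()]) from
#' the fitted coefficients and their covariance — identical to refitting
#' with the other reference level, an identity the test suite verifies.
#' Only subjects contributing all three stages are used. Per-gene fits
#' reuse a template model via `lme4::refit` for speed. Paired linear-scale
#' fold changes (the within-subject mean of ratios of anti-logged values)
#' are reported for each contrast.
#'
#' @param x Transformed expression matrix (genes x samples).
#' @param meta Data frame with `sample`, `stage`, `subject` (samples matched
#'   to columns of `x`).
#' @param stages Ordered stage labels, earliest first (default the three
#'   sorted unique stages in order of appearance).
#' @return Data frame of class `progression_calls`: per gene, `converged`,
#'   the three contrast coefficients/p-values, and paired fold changes.
#' @export
fit_progression <- function(x, meta, stages = NULL) {
  x <- as.matrix(x)
  meta <- meta[match(colnames(x), meta$sample), , drop = FALSE]
  if (is.null(stages)) stages <- unique(meta$stage)
  if (length(stages) != 3L) stop("exactly three stages are required")
  ## complete-set restriction: subjects with all three stages
  keep_subj <- names(which(tapply(meta$stage, meta$subject, function(s)
    all(stages %in% s))))
  if (length(keep_subj) < 3L) stop("need >= 3 subjects with complete stage sets")
  idx <- which(meta$subject %in% keep_subj)
  x <- x[, idx, drop = FALSE]
  meta <- meta[idx, , drop = FALSE]
  stage <- factor(meta$stage, levels = stages)
  subject <- factor(meta$subject)

  nm <- c(paste0(stages[2L], "-", stages[1L]),
          paste0(stages[3L], "-", stages[1L]),
          paste0(stages[3L], "-", stages[2L]))
  ## contrast rows in terms of (beta_mid, beta_last) with reference stages[1]
  L <- rbind(c(1, 0), c(0, 1), c(-1, 1))

  dat <- data.frame(y = x[1L, ], stage = stage, subject = subject)
  template <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ stage + (1 | subject), data = dat, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  t_df <- lme_containment_df(ncol(x), nlevels(subject), 2L)

  ngene <- nrow(x)
  coefm <- matrix(NA_real_, ngene, 3L, dimnames = list(rownames(x), nm))
  pm <- coefm
  conv <- logical(ngene)
  for (g in seq_len(ngene)) {
    y <- x[g, ]
    if (stats::sd(y) == 0) next
    fit <- tryCatch(
      suppressMessages(suppressWarnings(lme4::refit(template, newresp = y))),
      error = function(e) NULL)
    if (is.null(fit)) next
    b <- lme4::fixef(fit)[-1L]
    vc <- as.matrix(stats::vcov(fit))[-1L, -1L, drop = FALSE]
    est <- as.numeric(L %*% b)
    se <- sqrt(diag(L %*% vc %*% t(L)))
    if (!all(is.finite(est)) || !all(is.finite(se)) || any(se <= 0)) next
    coefm[g, ] <- est
    pm[g, ] <- 2 * stats::pt(-abs(est / se), t_df)
    conv[g] <- TRUE
  }

  fc <- paired_fold_changes(x, stage, subject, stages)
  out <- data.frame(gene = rownames(x), converged = conv,
                    coef_early = coefm[, 1L], p_early = pm[, 1L],
                    coef_full = coefm[, 2L], p_full = pm[, 2L],
                    coef_late = coefm[, 3L], p_late = pm[, 3L],
                    fc_early = fc[, 1L], fc_full = fc[, 2L], fc_late = fc[, 3L],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "stages") <- stages
  attr(out, "df") <- t_df
  class(out) <- c("progression_calls", class(out))
  out
}

## Signed linear-scale paired fold changes: per subject, anti-log the
## within-subject stage means, take the ratio, then average ratios across
## subjects; reported as the signed ratio (negative reciprocal when < 1).
paired_fold_changes <- function(x, stage, subject, stages) {
  subj_stage_mean <- function(st) {
    cols <- which(stage == st)
    m <- vapply(levels(subject), function(s) {
      cs <- cols[subject[cols] == s]
      rowMeans(x[, cs, drop = FALSE])
    }, numeric(nrow(x)))
    matrix(m, nrow = nrow(x))
  }
  m1 <- 2^subj_stage_mean(stages[1L])
  m2 <- 2^subj_stage_mean(stages[2L])
  m3 <- 2^subj_stage_mean(stages[3L])
  ratio_mean <- function(num, den) rowMeans(num / pmax(den, .Machine$double.eps))
  fc <- cbind(ratio_mean(m2, m1), ratio_mean(m3, m1), ratio_mean(m3, m2))
  ifelse(fc >= 1, fc, -1 / fc)
}

#' Designate genes as early, late, stepwise or none
#'
#' The gate is a nominal p below `alpha` for the full (last vs first stage)
#' contrast. Gated genes are designated *early* when the first-transition
#' contrast is also nominally significant with a sign matching the full
#' contrast, *late* when the second-transition contrast is, *stepwise* when
#' both are, and *none* otherwise. No multiplicity correction is applied at
#' this step. Non-converged genes are excluded (designation `none`).
#'
#' @param calls Result of [fit_progression()].
#' @param alpha Nominal significance level (default 0.05).
#' @return `calls` with a `designation` column added.
#' @export
classify_progression <- function(calls, alpha = 0.05) {
  gate <- calls$converged & !is.na(calls$p_full) & calls$p_full < alpha
  early <- gate & !is.na(calls$p_early) & calls$p_early < alpha &
    sign(calls$coef_early) == sign(calls$coef_full)
  late <- gate & !is.na(calls$p_late) & calls$p_late < alpha &
    sign(calls$coef_late) == sign(calls$coef_full)
  desig <- rep("none", nrow(calls))
  desig[early] <- "early"
  desig[late] <- "late"
  desig[early & late] <- "stepwise"
  calls$designation <- desig
  calls
}

#' Restrict a homology map to one-to-one pairs
#'
#' A feature surviving the filter participates in exactly one cross-species
#' pair; any feature in a many-to-many group is discarded together with its
#' partners, leaving a bijection.
#'
#' @param map Data frame with columns `gene_a`, `gene_b` (one row per
#'   candidate cross-species pair).
#' @return The filtered map (possibly empty).
#' @export
one_to_one_homologs <- function(map) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(map)))
  map <- unique(map[, c("gene_a", "gene_b")])
  ka <- table(map$gene_a)
  kb <- table(map$gene_b)
  keep <- ka[map$gene_a] == 1L & kb[map$gene_b] == 1L
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conserved progression gene sets across two species
#'
#' Merges per-species progression calls through a filtered one-to-one
#' homology map; a homolog pair is conserved for a designation when both
#' species carry that designation with the same sign of the full-contrast
#' coefficient.
#'
#' @param calls_a,calls_b Classified call tables ([classify_progression()])
#'   for species A and B.
#' @param map One-to-one homology map (`gene_a` in species A ids, `gene_b`
#'   in species B ids); filtered through [one_to_one_homologs()] internally.
#' @return List with `pairs` (merged table of conserved pairs), `sets`
#'   (named list of conserved gene-pair tables per designation) and
#'   `counts`.
#' @export
cross_species_sets <- function(calls_a, calls_b, map) {
  map <- one_to_one_homologs(map)
  ia <- match(map$gene_a, calls_a$gene)
  ib <- match(map$gene_b, calls_b$gene)
  ok <- !is.na(ia) & !is.na(ib)
  map <- map[ok, , drop = FALSE]; ia <- ia[ok]; ib <- ib[ok]
  da <- calls_a$designation[ia]
  db <- calls_b$designation[ib]
  sa <- sign(calls_a$coef_full[ia])
  sb <- sign(calls_b$coef_full[ib])
  conserved <- da == db & da != "none" & sa == sb
  pairs <- data.frame(gene_a = map$gene_a, gene_b = map$gene_b,
                      designation = da, sign = sa,
                      stringsAsFactors = FALSE)[conserved, , drop = FALSE]
  rownames(pairs) <- NULL
  sets <- split(pairs, factor(pairs$designation,
                              levels = c("early", "late", "stepwise")))
  list(pairs = pairs, sets = sets,
       counts = vapply(sets, nrow, integer(1)))
}

#' Motif-target overrepresentation with a conjugate Bayes factor
#'
#' For each motif target set, forms the 2x2 table of the universe split by
#' membership in the query gene set and in the target set, reports the
#' one-sided Fisher exact p for enrichment, and a Bayes factor comparing a
#' saturated association model (uniform Dirichlet prior over the four cells)
#' against an independence model (independent uniform Beta priors on the two
#' margins); both marginal likelihoods are available in closed form. A
#' Bayes factor above `bf_threshold` is flagged as significant.
#'
#' @param gene_set Character vector of query genes (e.g. an early set).
#' @param motif_target_sets Named list of target gene vectors per motif.
#' @param universe Character vector of all candidate genes (must contain
#'   `gene_set`).
#' @param bf_threshold Flagging threshold (default 3).
#' @return Data frame per motif: overlap counts, `p_fisher`, `bayes_factor`
#'   (`NA` for a target set empty within the universe), `significant`.
#' @export
gather_overrepresentation <- function(gene_set, motif_target_sets, universe,
                                      bf_threshold = 3) {
  if (!all(gene_set %in% universe)) stop("gene_set must be contained in universe")
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  res <- lapply(names(motif_target_sets), function(motif) {
    targets <- intersect(motif_target_sets[[motif]], universe)
    n11 <- length(intersect(gene_set, targets))
    n12 <- length(gene_set) - n11
    n21 <- length(targets) - n11
    n22 <- length(universe) - n11 - n12 - n21
    if (length(targets) == 0L) {
      return(data.frame(motif = motif, overlap = 0L, set_size = length(gene_set),
                        target_size = 0L, p_fisher = NA_real_,
                        bayes_factor = NA_real_, significant = FALSE,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    tab <- matrix(c(n11, n21, n12, n22), 2L)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    bf <- dirichlet_2x2_bf(n11, n12, n21, n22)
    degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
    data.frame(motif = motif, overlap = n11, set_size = length(gene_set),
               target_size = length(targets), p_fisher = p,
               bayes_factor = bf, significant = is.finite(bf) & bf > bf_threshold,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

## Closed-form Bayes factor for association in a 2x2 table:
## association: p ~ Dirichlet(1,1,1,1) over the four cells;
## independence: p_ij = r_i * c_j with r, c ~ Beta(1,1).
## The multinomial coefficient cancels in the ratio.
dirichlet_2x2_bf <- function(n11, n12, n21, n22) {
  n <- n11 + n12 + n21 + n22
  log_assoc <- lgamma(4) - lgamma(n + 4) +
    lgamma(n11 + 1) + lgamma(n12 + 1) + lgamma(n21 + 1) + lgamma(n22 + 1)
  log_indep <- lbeta(n11 + n12 + 1, n21 + n22 + 1) +
    lbeta(n11 + n21 + 1, n12 + n22 + 1)
  exp(log_assoc - log_indep)
}
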