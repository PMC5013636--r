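## Cohort signatures, enrichment-based cohort ranking, z-score-sum
## expression signatures, and quartile log-rank survival testing.

#' Derive a tumour-vs-normal cohort signature
#'
#' Runs the package's differential-expression test between normal and tumour
#' samples and keeps the genes exceeding a linear fold change of `fc_min` at
#' nominal `p < p_max`, split into upregulated and downregulated sets.
#'
#' @param x Transformed expression matrix (genes x samples).
#' @param groups Per-sample labels.
#' @param normal,tumour The two labels (fold change is tumour over normal).
#' @param fc_min Linear fold-change threshold (default 2).
#' @param p_max Nominal p threshold (default 0.05).
#' @param name Cohort name.
#' @return List of class `cohort_signature`: `name`, `up`, `down`,
#'   `thresholds`, `de` (the full DE table). Empty signatures are allowed
#'   (with a warning).
#' @export
derive_cohort_signature <- function(x, groups, normal, tumour,
                                    fc_min = 2, p_max = 0.05,
                                    name = "cohort") {
  de <- differential_expression(x, groups, normal, tumour)
  thr <- de_threshold(de, use = "p", p_max = p_max, fc_min = fc_min)
  if (length(thr$up) + length(thr$down) == 0L) {
    warning("empty cohort signature for ", name)
  }
  structure(list(name = name, up = thr$up, down = thr$down,
                 thresholds = c(fc_min = fc_min, p_max = p_max), de = de),
            class = "cohort_signature")
}

#' Rank cohorts by squared enrichment of their signatures
#'
#' Scores each cohort against a progression-ranked gene list as the sum over
#' its signature directions (up and down sets) of squared NES restricted to
#' significant enrichments (q below `q_max`), minus `penalty_lambda` for
#' each non-significant direction; cohorts are ranked by descending score.
#'
#' @param ranked_genes,scores Progression ranking (gene ids + scores).
#' @param signatures Named list of `cohort_signature` objects (or plain
#'   lists with `up`/`down`).
#' @param n_perm,seed Permutation controls for [gsea_significance()].
#' @param q_max Significance cutoff (default 0.25).
#' @param penalty_lambda Penalty per non-significant direction (default 0).
#' @return Data frame per cohort: `cohort`, `score`, `n_significant`,
#'   `rank`, ordered by rank; cohorts with no computable NES rank last and
#'   are flagged.
#' @export
rank_cohorts_by_enrichment <- function(ranked_genes, scores, signatures,
                                       n_perm = 1000L, seed = 1L,
                                       q_max = 0.25, penalty_lambda = 0) {
  sets <- list()
  for (nm in names(signatures)) {
    sig <- signatures[[nm]]
    if (length(sig$up) > 0L) sets[[paste0(nm, ".up")]] <- sig$up
    if (length(sig$down) > 0L) sets[[paste0(nm, ".down")]] <- sig$down
  }
  enr <- gsea_significance(ranked_genes, scores, sets,
                           n_perm = n_perm, seed = seed)
  out <- lapply(names(signatures), function(nm) {
    rows <- enr[enr$set %in% paste0(nm, c(".up", ".down")), , drop = FALSE]
    computable <- is.finite(rows$nes)
    if (!any(computable)) {
      return(data.frame(cohort = nm, score = NA_real_, n_significant = 0L,
                        computable = FALSE, stringsAsFactors = FALSE))
    }
    sig <- computable & !is.na(rows$q) & rows$q < q_max
    score <- sum(rows$nes[sig]^2) - penalty_lambda * sum(!sig)
    data.frame(cohort = nm, score = score, n_significant = sum(sig),
               computable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(!out$computable, -ifelse(is.na(out$score), -Inf, out$score),
                   out$cohort), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Z-score-sum signature score per sample
#'
#' Replaces each gene's expression with its z-score within the cohort, then
#' scores each sample as the sum of z-scores over the upregulated genes
#' minus the sum over the downregulated genes. Zero-variance genes
#' contribute 0.
#'
#' @param x Expression matrix (genes x samples).
#' @param up_genes,down_genes Signature gene sets.
#' @return Named numeric vector of per-sample scores.
#' @export
zscore_signature_score <- function(x, up_genes, down_genes = character()) {
  x <- as.matrix(x)
  present <- intersect(rownames(x), union(up_genes, down_genes))
  if (length(present) == 0L) stop("no signature gene present in the matrix")
  z <- function(genes) {
    g <- intersect(rownames(x), genes)
    if (length(g) == 0L) return(rep(0, ncol(x)))
    zs <- t(apply(x[g, , drop = FALSE], 1L, function(v) {
      s <- stats::sd(v)
      if (s == 0) {
        message("zero-variance signature gene contributes 0")
        return(rep(0, length(v)))
      }
      (v - mean(v)) / s
    }))
    colSums(zs)
  }
  stats::setNames(z(up_genes) - z(down_genes), colnames(x))
}

#' Quartile log-rank test of a signature score against survival
#'
#' Sorts samples by score (ties broken by sample id for determinism), takes
#' the top and bottom quartiles, and compares their survival with the
#' standard two-group log-rank test (1 df), returning Kaplan-Meier step
#' functions for both groups.
#'
#' @param scores Named numeric vector of signature scores.
#' @param surv Data frame with `sample`, `time`, `event` (1 = death/event,
#'   0 = censored).
#' @param quantile_frac Fraction in each extreme group (default 0.25).
#' @return List with `chisq`, `p`, `groups` (per-sample assignment), and
#'   `km` (data frame of step coordinates per group). Degenerate input with
#'   no events yields `NA` statistics with a message.
#' @export
quartile_logrank <- function(scores, surv, quantile_frac = 0.25) {
  stopifnot(all(c("sample", "time", "event") %in% names(surv)))
  surv <- surv[match(names(scores), surv$sample), , drop = FALSE]
  if (anyNA(surv$sample)) stop("scores and survival table do not match")
  ord <- order(-scores, names(scores))
  nq <- max(1L, floor(length(scores) * quantile_frac))
  top <- ord[seq_len(nq)]
  bottom <- rev(ord)[seq_len(nq)]
  idx <- c(top, bottom)
  grp <- factor(rep(c("top", "bottom"), each = nq), levels = c("bottom", "top"))
  time <- surv$time[idx]
  event <- surv$event[idx]
  if (sum(event) < 2L) {
    message("fewer than two events after quartile selection; log-rank undefined")
    return(list(chisq = NA_real_, p = NA_real_,
                groups = data.frame(sample = surv$sample[idx], group = grp),
                km = NULL))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- sd_$chisq
  p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  km <- data.frame(group = rep(sub("^grp=", "", names(fit$strata)),
                               fit$strata),
                   time = fit$time, surv = fit$surv,
                   n_risk = fit$n.risk, n_event = fit$n.event,
                   stringsAsFactors = FALSE)
  list(chisq = chisq, p = p,
       groups = data.frame(sample = surv$sample[idx], group = grp,
                           stringsAsFactors = FALSE),
       km = km)
}
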