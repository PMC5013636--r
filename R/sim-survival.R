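## Synthetic survival cohorts whose hazard depends on a z-score-sum
## expression signature, with independent censoring.

#' Simulate a survival cohort driven by a signature score
#'
#' Generates a standard-normal expression matrix, computes the z-score-sum
#' signature score over the supplied gene sets, and draws exponential event
#' times with rate proportional to `exp(hazard_coef * standardized score)`
#' (so `hazard_coef` is the log hazard ratio per score standard deviation).
#' Each record is independently censored with probability `censor_rate`, at
#' a uniform time before its event.
#'
#' @param cfg A [sim_config()] (uses `hazard_coef`, `censor_rate`, `seed`).
#' @param up_genes,down_genes Signature gene sets (nonempty union).
#' @param n_samples Cohort size (default 200).
#' @param n_noise_genes Additional unrelated genes in the matrix.
#' @return List with `expression` (genes x samples), `surv` (data frame:
#'   sample, time, event) and `truth` (per-sample score and true rate).
#' @export
simulate_survival_cohort <- function(cfg, up_genes, down_genes = character(),
                                     n_samples = 200L, n_noise_genes = 50L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(up_genes) + length(down_genes) == 0L) {
    stop("signature gene sets must be nonempty")
  }
  set.seed(cfg$seed + 3L)
  genes <- c(up_genes, down_genes,
             if (n_noise_genes > 0L) sprintf("NZ%03d", seq_len(n_noise_genes)))
  samples <- sprintf("T%03d", seq_len(n_samples))
  expr <- matrix(stats::rnorm(length(genes) * n_samples), length(genes),
                 n_samples, dimnames = list(genes, samples))
  score <- zscore_signature_score(expr, up_genes, down_genes)
  zs <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
        else score * 0
  rate <- exp(cfg$hazard_coef * zs)
  time <- stats::rexp(n_samples, rate = rate)
  event <- rep(1L, n_samples)
  cens <- stats::runif(n_samples) < cfg$censor_rate
  time[cens] <- stats::runif(sum(cens), 0, time[cens])
  event[cens] <- 0L
  list(expression = expr,
       surv = data.frame(sample = samples, time = time, event = event,
                         stringsAsFactors = FALSE),
       truth = list(score = score, rate = rate))
}
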