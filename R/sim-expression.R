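## Synthetic two-species expression studies with planted early/late/stepwise
## genes, subject random intercepts, batch shifts and a partially one-to-one
## homology map.

## Stage-effect multipliers on the log2 scale for the three progression
## patterns: early genes shift at the first transition and stay shifted,
## late genes shift only at the second, stepwise genes shift at both.
stage_pattern <- function(label) {
  switch(label,
         early = c(0, 1, 1),
         late = c(0, 0, 1),
         stepwise = c(0, 1, 2),
         c(0, 0, 0))
}

#' Simulate a matched pair of expression studies across two species
#'
#' Counts are negative binomial around
#' `mu = 2^(baseline + stage_effect + subject_intercept + batch_shift)`.
#' Planted genes follow the early/late/stepwise patterns with effect size
#' `effect_size_log2` per transition and a per-gene random sign, concordant
#' between species for one-to-one homolog pairs. A configurable fraction of
#' genes forms clean one-to-one homolog pairs; the remainder is split
#' between many-to-many groups and unmapped genes, exercising the homolog
#' filter. Every subject carries all three stages.
#'
#' @param cfg A [sim_config()].
#' @return List with `study_a`, `study_b` ([expression_study()] objects,
#'   human-like and mouse-like), `homology` (raw map with `gene_a`,
#'   `gene_b`, `group`, including many-to-many rows), and `truth` (data
#'   frame: homolog group, per-species gene ids, `label`, `sign`).
#' @export
simulate_expression_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  G <- cfg$genes_total
  stages <- cfg$lesion_classes
  n_sub <- cfg$n_subjects

  n_one <- floor(cfg$one_to_one_fraction * G)
  n_multi <- floor(0.5 * (G - n_one))       # genes in many-to-many groups
  genes_a <- sprintf("HG%04d", seq_len(G))
  genes_b <- sprintf("Mg%04d", seq_len(G))

  ## homology map: clean pairs, then 2-to-1 groups, then unmapped
  map <- data.frame(gene_a = genes_a[seq_len(n_one)],
                    gene_b = genes_b[seq_len(n_one)],
                    group = sprintf("HLG%04d", seq_len(n_one)),
                    stringsAsFactors = FALSE)
  if (n_multi >= 2L) {
    multi_a <- genes_a[(n_one + 1L):(n_one + n_multi)]
    multi_b <- genes_b[(n_one + 1L):(n_one + n_multi)]
    ## pair consecutive species-A genes to a single species-B gene
    for (i in seq(1L, n_multi - 1L, by = 2L)) {
      grp <- sprintf("HLGM%04d", i)
      map <- rbind(map,
                   data.frame(gene_a = multi_a[c(i, i + 1L)],
                              gene_b = multi_b[i], group = grp,
                              stringsAsFactors = FALSE))
    }
  }

  ## planted labels, concordant within one-to-one pairs
  n_early <- round(cfg$frac_early * G)
  n_late <- round(cfg$frac_late * G)
  n_step <- round(cfg$frac_stepwise * G)
  labels <- rep("none", G)
  planted_idx <- sample(seq_len(n_one),
                        min(n_one, n_early + n_late + n_step))
  labels[planted_idx] <- rep(c("early", "late", "stepwise"),
                             c(n_early, n_late, n_step))[seq_along(planted_idx)]
  signs <- ifelse(stats::runif(G) < 0.5, -1, 1)
  truth <- data.frame(gene_a = genes_a, gene_b = genes_b,
                      label = labels, sign = signs,
                      one_to_one = seq_len(G) <= n_one,
                      stringsAsFactors = FALSE)

  make_study <- function(genes, species) {
    subjects <- sprintf("%s_S%02d", species, seq_len(n_sub))
    meta <- data.frame(
      sample = paste0(rep(subjects, each = length(stages)), "_",
                      rep(stages, n_sub)),
      stage = rep(stages, n_sub),
      subject = rep(subjects, each = length(stages)),
      batch = paste0("b", 1L + (rep(seq_len(n_sub), each = length(stages)) - 1L) %%
                       2L),
      species = species, stringsAsFactors = FALSE)
    baseline <- stats::rnorm(G, mean = 7, sd = 1.5)
    batch_sign <- ifelse(stats::runif(G) < 0.5, -1, 1)
    u <- matrix(stats::rnorm(G * n_sub, 0, cfg$subject_sd), G, n_sub)
    stage_idx <- match(meta$stage, stages)
    mu_log2 <- matrix(0, G, nrow(meta))
    for (g in seq_len(G)) {
      eff <- signs[g] * cfg$effect_size_log2 * stage_pattern(labels[g])
      mu_log2[g, ] <- baseline[g] + eff[stage_idx] +
        u[g, match(meta$subject, subjects)] +
        ifelse(meta$batch == "b2", batch_sign[g] * cfg$batch_shift, 0)
    }
    counts <- matrix(stats::rnbinom(length(mu_log2), mu = 2^mu_log2,
                                    size = 1 / cfg$nb_dispersion),
                     G, nrow(meta),
                     dimnames = list(genes, meta$sample))
    expression_study(counts, meta)
  }

  list(study_a = make_study(genes_a, "human"),
       study_b = make_study(genes_b, "mouse"),
       homology = map, truth = truth)
}
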