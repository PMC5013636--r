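# Synthetic-data generators: determinism, ground-truth fidelity, and the
# structural features each downstream stage relies on.

test_that("mutation cohort generation is seed-deterministic", {
  cfg <- sim_config(seed = 42, n_patients = 2,
                    class_mean_counts = c(NS = 30, AK = 60, SCC = 100),
                    reference_length = 2e4)
  a <- simulate_mutation_cohort(cfg)
  b <- simulate_mutation_cohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$reference, b$reference)
  expect_identical(a$truth, b$truth)
})

test_that("variants sit on matching reference contexts and rebuild their signature", {
  # exposures concentrated on the UVB signature: the rebuilt catalogue must
  # match it closely at high mutation count (law of large numbers)
  W <- default_truth_signatures()
  cfg <- sim_config(seed = 7, n_patients = 1, lesion_classes = "SCC",
                    class_mean_counts = c(SCC = 10000),
                    truth_signatures = W,
                    truth_exposures = matrix(c(1, 0), 2, 1,
                                             dimnames = list(colnames(W), "SCC")),
                    reference_length = 3e5, shared_clone_fraction = 0)
  sim <- simulate_mutation_cohort(cfg)
  expect_gt(nrow(sim$variants), 9000)
  cat96 <- build_catalog96(sim$variants, sim$reference)  # errors on mismatch
  v <- as.numeric(cat96[, 1])
  cosine <- sum(v * W[, 1]) / sqrt(sum(v^2) * sum(W[, 1]^2))
  expect_gte(cosine, 0.99)
})

test_that("shared-clone copying drives within-patient overlap; zero sharing is chance-level", {
  base <- list(seed = 11, n_patients = 4,
               class_mean_counts = c(NS = 200, AK = 400, SCC = 600),
               reference_length = 5e5)
  cfg0 <- do.call(sim_config, c(base, shared_clone_fraction = 0))
  sim0 <- simulate_mutation_cohort(cfg0)
  ov0 <- site_overlap(sim0$variants)
  # footprint >> counts: random collisions essentially absent
  expect_lte(mean(ov0$per_pair$overlap), 1)
  expect_null(sim0$truth$shared_sites)

  cfg5 <- do.call(sim_config, c(base, shared_clone_fraction = 0.05))
  sim5 <- simulate_mutation_cohort(cfg5)
  ov5 <- site_overlap(sim5$variants)
  expect_gt(sum(ov5$per_pair$overlap), sum(ov0$per_pair$overlap))
  # every recorded shared site is indeed present in both samples
  ss <- sim5$truth$shared_sites
  keys <- paste(sim5$variants$sample, sim5$variants$pos, sim5$variants$alt)
  expect_true(all(paste(ss$sample, ss$pos, ss$alt) %in% keys))
  expect_true(all(paste(ss$from_sample, ss$pos, ss$alt) %in% keys))
})

test_that("expression pair plants stage patterns with concordant homolog truth", {
  cfg <- sim_config(seed = 3, genes_total = 300, n_subjects = 4,
                    subject_sd = 0, nb_dispersion = 0.05,
                    effect_size_log2 = 2)
  sim <- simulate_expression_pair(cfg)
  expect_identical(dim(sim$study_a$counts), c(300L, 12L))

  # planted early gene: stage-mean log2 difference at the first transition
  # tracks the configured effect size (sample-mean oracle, strong effect)
  x <- log2(sim$study_a$counts + 1)
  st <- sim$study_a$meta$stage
  early <- sim$truth[sim$truth$label == "early", ]
  expect_gt(nrow(early), 0)
  d <- rowMeans(x[early$gene_a, st == "AK", drop = FALSE]) -
       rowMeans(x[early$gene_a, st == "NS", drop = FALSE])
  # recovered effect (sign-corrected) averages to the configured size
  expect_lt(abs(mean(d * early$sign) - 2), 0.1 * 2)
  expect_true(all(sign(d) == early$sign))
  # and late genes are flat across the first transition
  late <- sim$truth[sim$truth$label == "late", ]
  d_late <- rowMeans(x[late$gene_a, st == "AK", drop = FALSE]) -
            rowMeans(x[late$gene_a, st == "NS", drop = FALSE])
  expect_lt(max(abs(d_late)), 0.5)

  # null model: zero effect size labels everything none
  cfg0 <- sim_config(seed = 3, genes_total = 100, effect_size_log2 = 0,
                     frac_early = 0, frac_late = 0, frac_stepwise = 0)
  expect_true(all(simulate_expression_pair(cfg0)$truth$label == "none"))

  # many-to-many homologs are absent from the one-to-one filtered map
  filt <- one_to_one_homologs(sim$homology)
  multi <- sim$homology$gene_b[duplicated(sim$homology$gene_b)]
  expect_false(any(filt$gene_b %in% multi))
  # and truth marks only clean pairs as one_to_one
  expect_true(all(sim$truth$gene_a[sim$truth$one_to_one] %in% filt$gene_a))
})

test_that("miRNA generator produces anti-correlated truth pairs at full penetrance", {
  cfg <- sim_config(seed = 5, penetrance = 1)
  sim <- simulate_mirna_and_pairs(cfg, n_perturbed = 5)
  tp <- sim$truth$pairs
  expect_gt(nrow(tp), 0)
  stages <- unique(sim$meta$stage)
  stage_means <- function(mat, id) {
    vapply(stages, function(s)
      mean(log2(mat[id, sim$meta$stage == s] + 1)), numeric(1))
  }
  for (i in seq_len(nrow(tp))) {
    r <- cor(stage_means(sim$mirna_counts, tp$mirna[i]),
             stage_means(sim$mrna_counts, tp$gene[i]))
    expect_lt(r, 0)
  }
  # determinism of the truth pair list
  sim2 <- simulate_mirna_and_pairs(cfg, n_perturbed = 5)
  expect_identical(sim2$truth$pairs, tp)
  # zero penetrance: no truth pairs at all
  sim0 <- simulate_mirna_and_pairs(sim_config(seed = 5, penetrance = 0))
  expect_null(sim0$truth$pairs)
  expect_error(sim_config(penetrance = 1.5), "proportions")
})

test_that("survival generator ties hazard to the signature score and censors independently", {
  up <- sprintf("UP%02d", 1:5); dn <- sprintf("DN%02d", 1:5)
  cfg <- sim_config(seed = 9, hazard_coef = 1.5, censor_rate = 0)
  sim <- simulate_survival_cohort(cfg, up, dn, n_samples = 150)
  expect_true(all(sim$surv$event == 1))
  # higher scores must shorten survival on average
  expect_lt(cor(sim$truth$score, sim$surv$time, method = "spearman"), -0.3)

  # censor_rate = 1: everything censored, downstream log-rank flags it
  cfg1 <- sim_config(seed = 9, hazard_coef = 0, censor_rate = 1)
  sim1 <- simulate_survival_cohort(cfg1, up, dn, n_samples = 40)
  expect_true(all(sim1$surv$event == 0))
  scores <- zscore_signature_score(sim1$expression, up, dn)
  expect_message(res <- quartile_logrank(scores, sim1$surv), "undefined")
  expect_true(is.na(res$p))
  expect_error(simulate_survival_cohort(cfg1, character(), character()),
               "nonempty")
})

test_that("simulated files round-trip through the package readers", {
  tmp <- withr::local_tempdir()
  cfg <- sim_config(seed = 2, n_patients = 2,
                    class_mean_counts = c(NS = 20, AK = 30, SCC = 40),
                    reference_length = 2e4)
  sim <- simulate_mutation_cohort(cfg)
  write_maf(sim$variants, file.path(tmp, "v.maf.tsv"))
  v2 <- read_maf(file.path(tmp, "v.maf.tsv"))
  expect_equal(v2$pos, sim$variants$pos)
  expect_equal(v2$alt, sim$variants$alt)
  write_reference_fasta(sim$reference, file.path(tmp, "ref.fa"))
  expect_identical(read_reference_fasta(file.path(tmp, "ref.fa")), sim$reference)

  pair <- simulate_expression_pair(sim_config(seed = 2, genes_total = 50))
  write_counts(pair$study_a$counts, pair$study_a$meta,
               file.path(tmp, "c.tsv"), file.path(tmp, "m.tsv"))
  rt <- read_counts(file.path(tmp, "c.tsv"), file.path(tmp, "m.tsv"))
  expect_equal(rt$counts, pair$study_a$counts)
  expect_equal(rt$meta, pair$study_a$meta)

  sets <- list(setA = c("g1", "g2"), setB = c("g3"))
  write_gmt(sets, file.path(tmp, "s.gmt"))
  expect_identical(read_gmt(file.path(tmp, "s.gmt")), sets)
})
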