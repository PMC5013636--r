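# Mixed-effects progression modelling: reparameterization identity,
# reduction to fixed effects, the designation rule table, homolog filtering,
# cross-species intersection, and motif overrepresentation.

# Small balanced design: n_sub subjects x three stages.
lme_design <- function(n_sub = 6, stages = c("NS", "AK", "SCC")) {
  data.frame(sample = paste0("s", seq_len(3 * n_sub)),
             stage = rep(stages, n_sub),
             subject = rep(paste0("p", seq_len(n_sub)), each = 3),
             stringsAsFactors = FALSE)
}

test_that("reference swap negates the shared contrast coefficient", {
  set.seed(1)
  d <- lme_design(6)
  y <- rnorm(18) + rep(c(0, 0.4, 1), 6) + rep(rnorm(6, 0, 0.5), each = 3)
  f_ns <- fit_gene_lme(y, d$stage, d$subject, reference_stage = "NS")
  f_ak <- fit_gene_lme(y, d$stage, d$subject, reference_stage = "AK")
  expect_lt(abs(f_ns$coef["AK-NS"] + f_ak$coef["NS-AK"]), 1e-6)
  expect_lt(abs(f_ns$p["AK-NS"] - f_ak$p["NS-AK"]), 1e-6)
  # the SCC-AK contrast from the AK-referenced fit equals the derived one
  # used by fit_progression (single-fit contrast identity)
  x <- matrix(y, 1, dimnames = list("g1", d$sample))
  calls <- fit_progression(x, d, stages = c("NS", "AK", "SCC"))
  expect_lt(abs(calls$coef_late - f_ak$coef["SCC-AK"]), 1e-6)
  expect_lt(abs(calls$p_late - f_ak$p["SCC-AK"]), 1e-6)
  expect_lt(abs(calls$coef_early - f_ns$coef["AK-NS"]), 1e-6)
})

test_that("with no subject variance the estimates reduce to stage-mean differences", {
  set.seed(2)
  d <- lme_design(8)
  y <- rnorm(24, sd = 0.3) + rep(c(1, 2.5, 3.2), 8)
  x <- matrix(y, 1, dimnames = list("g1", d$sample))
  calls <- fit_progression(x, d, stages = c("NS", "AK", "SCC"))
  mns <- tapply(y, d$stage, mean)
  expect_lt(abs(calls$coef_early - (mns["AK"] - mns["NS"])), 1e-5)
  expect_lt(abs(calls$coef_full - (mns["SCC"] - mns["NS"])), 1e-5)
  expect_lt(abs(calls$coef_late - (mns["SCC"] - mns["AK"])), 1e-5)
})

test_that("degenerate genes are flagged non-converged, not errors", {
  d <- lme_design(4)
  f <- fit_gene_lme(rep(3, 12), d$stage, d$subject, "NS")
  expect_false(f$converged)
  expect_true(all(is.na(f$p)))
  x <- rbind(g_const = rep(3, 12),
             g_ok = rnorm(12, 8))
  colnames(x) <- d$sample
  calls <- fit_progression(x, d, stages = c("NS", "AK", "SCC"))
  expect_false(calls$converged[1])
  expect_true(calls$converged[2])
  expect_equal(classify_progression(calls)$designation[1], "none")
})

test_that("designation follows the gate + sign-matched second-test rule", {
  mk_call <- function(p_full, c_full, p_early, c_early, p_late, c_late) {
    data.frame(gene = "g", converged = TRUE,
               coef_early = c_early, p_early = p_early,
               coef_full = c_full, p_full = p_full,
               coef_late = c_late, p_late = p_late,
               fc_early = NA, fc_full = NA, fc_late = NA,
               stringsAsFactors = FALSE)
  }
  de <- function(...) classify_progression(mk_call(...))$designation
  # gate fails: none regardless of the transitions
  expect_equal(de(0.2, 1, 0.01, 1, 0.01, 1), "none")
  # early only
  expect_equal(de(0.01, 1, 0.01, 1, 0.3, 1), "early")
  # sign mismatch on the early contrast: not early; late with matching sign
  expect_equal(de(0.01, 1, 0.01, -1, 0.3, 1), "none")
  expect_equal(de(0.01, 1, 0.01, -1, 0.02, 1), "late")
  # both fire: stepwise
  expect_equal(de(0.01, 1, 0.01, 1, 0.02, 1), "stepwise")
  # alpha is configurable
  expect_equal(classify_progression(mk_call(0.08, 1, 0.01, 1, 0.3, 1),
                                    alpha = 0.1)$designation, "early")
})

test_that("paired fold changes are the within-subject mean of anti-logged ratios", {
  d <- lme_design(3)
  # constant per-subject values per stage, easy hand computation
  y <- log2(rep(c(2, 6, 12), 3) * rep(c(1, 2, 4), each = 3))
  x <- matrix(y, 1, dimnames = list("g1", d$sample))
  calls <- fit_progression(x, d, stages = c("NS", "AK", "SCC"))
  # every subject has AK/NS = 3, SCC/NS = 6, SCC/AK = 2
  expect_equal(calls$fc_early, 3, tolerance = 1e-9)
  expect_equal(calls$fc_full, 6, tolerance = 1e-9)
  expect_equal(calls$fc_late, 2, tolerance = 1e-9)
  # downregulation is reported as a signed negative reciprocal
  x_dn <- matrix(-y, 1, dimnames = list("g1", d$sample))
  calls_dn <- fit_progression(x_dn, d, stages = c("NS", "AK", "SCC"))
  expect_equal(calls_dn$fc_early, -3, tolerance = 1e-9)
})

test_that("one-to-one homolog filter removes many-to-many groups entirely", {
  map <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("x", "x", "y"),
                    stringsAsFactors = FALSE)
  out <- one_to_one_homologs(map)
  expect_equal(out, data.frame(gene_a = "c", gene_b = "y",
                               stringsAsFactors = FALSE))
  clean <- data.frame(gene_a = c("a", "b"), gene_b = c("x", "y"),
                      stringsAsFactors = FALSE)
  expect_equal(one_to_one_homologs(clean), clean)
  # empty result allowed
  allmulti <- data.frame(gene_a = c("a", "a"), gene_b = c("x", "y"))
  expect_equal(nrow(one_to_one_homologs(allmulti)), 0L)
})

test_that("cross-species sets require identical designation and sign", {
  mk <- function(genes, desig, sgn) {
    data.frame(gene = genes, converged = TRUE,
               coef_early = sgn, p_early = 0.01,
               coef_full = sgn, p_full = 0.01,
               coef_late = sgn, p_late = 0.5,
               fc_early = NA, fc_full = NA, fc_late = NA,
               designation = desig, stringsAsFactors = FALSE)
  }
  calls_a <- mk(c("a1", "a2", "a3"), c("early", "early", "late"), c(1, 1, 1))
  calls_b <- mk(c("b1", "b2", "b3"), c("early", "late", "late"), c(1, -1, 1))
  map <- data.frame(gene_a = c("a1", "a2", "a3"),
                    gene_b = c("b1", "b2", "b3"), stringsAsFactors = FALSE)
  cs <- cross_species_sets(calls_a, calls_b, map)
  # a1/b1: conserved early; a2/b2: designation mismatch; a3/b3: conserved late
  expect_equal(cs$pairs$gene_a, c("a1", "a3"))
  expect_equal(unname(cs$counts[c("early", "late")]), c(1L, 1L))
  # no shared designations -> empty
  cs0 <- cross_species_sets(mk("a1", "early", 1), mk("b1", "late", 1),
                            data.frame(gene_a = "a1", gene_b = "b1"))
  expect_equal(nrow(cs0$pairs), 0L)
})

test_that("overrepresentation: Fisher p matches hypergeometric tail, BF matches integration", {
  # brute-force hypergeometric tail on a 20-gene universe
  universe <- paste0("u", 1:20)
  gene_set <- universe[1:8]
  targets <- universe[c(1:5, 9:12)]
  res <- gather_overrepresentation(gene_set, list(m1 = targets), universe)
  q <- length(intersect(gene_set, targets))
  p_brute <- sum(dhyper(q:min(length(gene_set), length(targets)),
                        length(targets), 20 - length(targets),
                        length(gene_set)))
  expect_equal(res$p_fisher, p_brute, tolerance = 1e-12)

  # Bayes factor against a 2D numerical integration of the independence
  # marginal likelihood and a Monte Carlo check of the association model
  n11 <- 5; n12 <- 3; n21 <- 4; n22 <- 8
  bf <- sccprogress:::dirichlet_2x2_bf(n11, n12, n21, n22)
  indep <- integrate(Vectorize(function(r) {
    r^(n11 + n12) * (1 - r)^(n21 + n22) *
      integrate(function(c) c^(n11 + n21) * (1 - c)^(n12 + n22),
                0, 1)$value
  }), 0, 1)$value
  n <- n11 + n12 + n21 + n22
  assoc <- gamma(4) / gamma(n + 4) *
    gamma(n11 + 1) * gamma(n12 + 1) * gamma(n21 + 1) * gamma(n22 + 1)
  expect_equal(bf, assoc / indep, tolerance = 1e-6)

  # small disjoint sets in a large universe (expected overlap well below 1):
  # the observation is consistent with independence, so BF < 1
  big_universe <- paste0("v", 1:100)
  res_dis <- gather_overrepresentation(big_universe[1:5],
                                       list(m = big_universe[6:10]),
                                       big_universe)
  expect_lt(res_dis$bayes_factor, 1)
  # degenerate table flagged
  res_deg <- gather_overrepresentation(universe, list(m = universe), universe)
  expect_true(res_deg$degenerate)
  # empty target set -> undefined sentinel
  res_empty <- gather_overrepresentation(gene_set, list(m = "absent"), universe)
  expect_true(is.na(res_empty$bayes_factor))
})
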