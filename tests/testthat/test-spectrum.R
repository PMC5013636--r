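# Mutation-spectrum statistics: DNP collapsing, 96-class catalogues,
# spectra, loads, SMG filtering and site overlap.

test_that("adjacent SNVs collapse into DNP and longer runs merge left-anchored", {
  v <- vtab(vrow(pos = 10, ref = "C", alt = "T"),
            vrow(pos = 11, ref = "C", alt = "T"))
  out <- collapse_dnps(v)
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos, 10)
  expect_equal(out$ref, "CC")
  expect_equal(out$alt, "TT")

  v3 <- vtab(vrow(pos = 5, ref = "C", alt = "T"),
             vrow(pos = 6, ref = "C", alt = "T"),
             vrow(pos = 7, ref = "C", alt = "T"))
  out3 <- collapse_dnps(v3)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$ref, "CCC")
  expect_equal(out3$alt, "TTT")
  expect_equal(out3$pos, 5)

  # non-adjacent, different samples, different chroms: untouched
  v_apart <- vtab(vrow(pos = 10, ref = "C", alt = "T"),
                  vrow(pos = 12, ref = "C", alt = "T"),
                  vrow(sample = "S2", pos = 13, ref = "C", alt = "T"))
  expect_equal(nrow(collapse_dnps(v_apart)), 3L)

  # duplicated position within a sample is malformed
  v_dup <- vtab(vrow(pos = 10, ref = "C", alt = "T"),
                vrow(pos = 10, ref = "C", alt = "A"))
  expect_error(collapse_dnps(v_dup), "malformed")
})

test_that("96-class catalogue bins by trinucleotide context with purine flip", {
  # reference: positions 1..5 = A C A G T; C at 2 has context ACA
  ref <- make_reference("ACAGT")
  v <- vrow(pos = 2, ref = "C", alt = "T")
  cat96 <- build_catalog96(v, ref)
  expect_equal(sum(cat96), 1L)
  expect_equal(cat96["A[C>T]A", "S1"], 1L)

  # G>A with forward context TGT == revcomp ACA, counts as C>T in ACA
  ref2 <- make_reference("ATGTA")
  v2 <- vrow(pos = 3, ref = "G", alt = "A")
  cat2 <- build_catalog96(v2, ref2)
  expect_equal(cat2["A[C>T]A", "S1"], 1L)

  # empty list -> zero vector; total conserved over SNVs
  expect_equal(sum(build_catalog96(vrow(pos = 2, ref = "C", alt = "T")[0, ],
                                   ref, samples = "S1")), 0L)

  # reference mismatch names the record
  expect_error(build_catalog96(vrow(pos = 2, ref = "G", alt = "A"), ref),
               "mismatch")
})

test_that("catalogue is strand-symmetric and conserves SNV totals", {
  set.seed(42)
  n <- 60
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  ref <- make_reference(seq)
  bases <- strsplit(seq, "")[[1]]
  pos <- sample(2:499, n)
  refb <- bases[pos]
  alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  v <- do.call(rbind, lapply(seq_len(n), function(i)
    vrow(pos = pos[i], ref = refb[i], alt = alt[i])))
  cat1 <- build_catalog96(v, ref)
  expect_equal(sum(cat1), n)

  # reverse-complement the entire reference and all variants: same catalogue
  L <- nchar(seq)
  seq_rc <- revcomp(seq)
  v_rc <- v
  v_rc$pos <- L - v$pos + 1
  v_rc$ref <- chartr("ACGT", "TGCA", v$ref)
  v_rc$alt <- chartr("ACGT", "TGCA", v$alt)
  cat_rc <- build_catalog96(v_rc, make_reference(seq_rc))
  expect_equal(cat1, cat_rc)
})

test_that("spectrum summary computes class fractions and DNP statistics", {
  # 9 CC>TT among 10 DNPs
  dnps <- do.call(rbind, lapply(1:10, function(i)
    vrow(pos = i * 10, ref = if (i <= 9) "CC" else "CA",
         alt = if (i <= 9) "TT" else "TG")))
  s <- spectrum_summary(dnps)
  expect_equal(s$cc_tt_fraction, 0.9)
  expect_equal(s$n_dnp, 10L)

  # all T>A SNVs -> six-class vector (0,0,0,1,0,0); fractions sum to 1
  snvs <- do.call(rbind, lapply(1:5, function(i)
    vrow(pos = i * 3, ref = "T", alt = "A")))
  s2 <- spectrum_summary(snvs)
  expect_equal(unname(s2$six_class), c(0, 0, 0, 1, 0, 0))
  expect_equal(sum(s2$six_class), 1)

  # purine-reference SNVs fold into pyrimidine classes (A>T counts as T>A)
  s3 <- spectrum_summary(vrow(pos = 3, ref = "A", alt = "T"))
  expect_equal(unname(s3$six_class["T>A"]), 1)

  # no DNPs -> undefined sentinel, not zero and not an error
  expect_true(is.na(spectrum_summary(snvs)$cc_tt_fraction))
})

test_that("mutation load is count over footprint with per-class summaries", {
  mk <- function(sample, cls, n) do.call(rbind, lapply(seq_len(n), function(i)
    vrow(sample = sample, lesion_class = cls, pos = i + 1, ref = "C", alt = "T")))
  v <- rbind(mk("A1", "AK", 128))
  expect_equal(mutation_load(v, 64)$per_sample$load, 2.0)
  # the AK cohort mean count over the footprint implied by the SCC pair
  footprint <- 2927 / 45.7
  expect_equal(round(mutation_load(mk("A1", "AK", 1186), footprint)$per_sample$load, 1),
               18.5)
  expect_error(mutation_load(v, 0), "positive")
  # zero variants for a sample listed in the table: load 0 via empty class
  expect_equal(nrow(mutation_load(v, 10)$per_class), 1L)
})

test_that("SMG filter applies the recurrence AND prior-evidence/COSMIC rule", {
  mk_gene <- function(gene, n_samples, cosmic) do.call(rbind,
    lapply(seq_len(n_samples), function(i)
      vrow(sample = paste0("S", i), pos = i * 5, ref = "C", alt = "T",
           gene = gene, cosmic_count = cosmic)))
  v <- rbind(mk_gene("hiCosmic", 7, 401),
             mk_gene("loCosmic", 7, 100),
             mk_gene("knownFew", 3, 0),
             mk_gene("knownMany", 8, 0))
  out <- smg_filter(v, known_genes = c("knownFew", "knownMany"))
  expect_setequal(out$gene, c("hiCosmic", "knownMany"))
  # boundary: cosmic exactly at threshold is excluded
  out2 <- smg_filter(mk_gene("edge", 7, 400))
  expect_equal(nrow(out2), 0L)
  # monotone: raising the threshold never adds genes
  for (thr in c(0, 100, 400, 1000)) {
    g_lo <- smg_filter(v, cosmic_threshold = thr)$gene
    g_hi <- smg_filter(v, cosmic_threshold = thr + 50)$gene
    expect_true(all(g_hi %in% g_lo))
  }
})

test_that("site overlap equals brute-force tuple intersection on random toys", {
  # toy: A = {x,y,z}, B = {y,z,w} -> 2
  a <- vtab(vrow(sample = "A", lesion_class = "NS", pos = 1, ref = "C", alt = "T"),
            vrow(sample = "A", lesion_class = "NS", pos = 2, ref = "C", alt = "T"),
            vrow(sample = "A", lesion_class = "NS", pos = 3, ref = "C", alt = "T"))
  b <- vtab(vrow(sample = "B", lesion_class = "AK", pos = 2, ref = "C", alt = "T"),
            vrow(sample = "B", lesion_class = "AK", pos = 3, ref = "C", alt = "T"),
            vrow(sample = "B", lesion_class = "AK", pos = 4, ref = "C", alt = "T"))
  ov <- site_overlap(rbind(a, b))
  expect_equal(ov$per_pair$overlap, 2L)

  set.seed(7)
  for (i in 1:100) {
    va <- random_variant_set("A", "P1", "NS", sample(1:20, 1))
    vb <- random_variant_set("B", "P1", "AK", sample(1:20, 1))
    ov <- site_overlap(rbind(va, vb))$per_pair$overlap
    expect_equal(ov, brute_overlap(va, vb))
    # symmetry in sample order
    ov_sym <- site_overlap(rbind(vb, va))$per_pair$overlap
    expect_equal(ov_sym, ov)
  }
})

test_that("duplicated lesion classes yield flagged extra pairs and higher-order counts", {
  v <- rbind(
    random_variant_set("NSs", "P4", "NS", 8, 1:30),
    random_variant_set("AKs", "P4", "AK", 8, 1:30),
    random_variant_set("SCC1", "P4", "SCC", 8, 1:30),
    random_variant_set("SCC2", "P4", "SCC", 8, 1:30))
  ov <- site_overlap(v)
  # 4 samples -> 6 pairwise combinations, SCC/SCC among them, flagged
  expect_equal(nrow(ov$per_pair), 6L)
  expect_true(any(ov$per_pair$class_pair == "SCC/SCC"))
  expect_true(all(ov$per_pair$duplicated_class[ov$per_pair$class_pair %in%
                                                 c("SCC/SCC", "NS/SCC", "AK/SCC")]))
  # 3-way and 4-way intersections are reported
  expect_true(all(c(3, 4) %in% ov$higher_order$k))
})

test_that("cohort means aggregate per-pair overlaps per class pair", {
  per_pair <- data.frame(
    class_pair = c(rep("AK/NS", 4), rep("AK/SCC", 2)),
    overlap = c(2, 0, 1, 0, 4, 6))
  m <- overlap_cohort_means(per_pair)
  expect_equal(m$mean_overlap[m$class_pair == "AK/NS"], 0.75)
  expect_equal(m$mean_overlap[m$class_pair == "AK/SCC"], 5)
  expect_equal(nrow(overlap_cohort_means(per_pair[0, ])), 0L)
})
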