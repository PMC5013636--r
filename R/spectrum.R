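## Mutation-spectrum statistics: DNP collapsing, 96-class catalogues,
## six-class spectra, per-Mb loads, recurrently-mutated-gene filtering and
## within-patient site-specific overlap.

#' Validate a variant table
#'
#' Variant tables are MAF-like data frames with one row per somatic variant
#' and columns `patient`, `sample`, `lesion_class`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, and optionally `vaf`, `gene`, `cosmic_count`.
#'
#' @param variants Data frame of variants.
#' @return The validated data frame (invisibly unchanged).
#' @keywords internal
check_variants <- function(variants) {
  needed <- c("patient", "sample", "lesion_class", "chrom", "pos", "ref", "alt")
  missing <- setdiff(needed, names(variants))
  if (length(missing) > 0L) {
    stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(variants$ref == variants$alt)) {
    stop("ref must differ from alt for every variant")
  }
  if (any(nchar(variants$ref) != nchar(variants$alt))) {
    stop("ref and alt must have equal length (substitutions only)")
  }
  variants
}

#' Collapse adjacent same-sample SNVs into multi-nucleotide records
#'
#' Adjacent single-base substitutions within a sample (positions differing by
#' one on the same chromosome) are merged into a single dinucleotide record
#' with concatenated ref/alt alleles; runs of three or more merge
#' left-to-right into one left-anchored multi-nucleotide record. CC>TT
#' dinucleotide variants produced this way are the classic UVB fingerprint.
#'
#' @param variants Variant data frame (see [check_variants()]).
#' @return Variant data frame with merged records; the `vaf` of a merged
#'   record is the mean of its constituents, `gene`/`cosmic_count` are taken
#'   from the first.
#' @export
collapse_dnps <- function(variants) {
  check_variants(variants)
  if (nrow(variants) == 0L) return(variants)
  ord <- order(variants$sample, variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  key <- paste(v$sample, v$chrom, v$pos, sep = "\r")
  if (anyDuplicated(key)) {
    stop("malformed input: multiple records at one position within a sample")
  }
  n <- nrow(v)
  same_run <- c(FALSE,
                v$sample[-1] == v$sample[-n] &
                v$chrom[-1] == v$chrom[-n] &
                v$pos[-1] == v$pos[-n] + 1L &
                nchar(v$ref[-1]) == 1L & nchar(v$ref[-n]) == 1L)
  run_id <- cumsum(!same_run)
  out <- lapply(split(seq_len(n), run_id), function(idx) {
    first <- v[idx[1L], , drop = FALSE]
    if (length(idx) > 1L) {
      first$ref <- paste(v$ref[idx], collapse = "")
      first$alt <- paste(v$alt[idx], collapse = "")
      if ("vaf" %in% names(v)) first$vaf <- mean(v$vaf[idx])
    }
    first
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build per-sample 96-class trinucleotide catalogues
#'
#' Each single-base substitution is placed in its reference trinucleotide
#' context and counted in the pyrimidine-centric 96-class layout
#' ([sbs96_classes()]); purine-reference calls are reverse-complemented.
#' Multi-nucleotide records (collapsed DNPs) are excluded.
#'
#' @param variants Variant data frame.
#' @param reference Named character vector of chromosome sequences (A/C/G/T),
#'   or a `Biostrings::DNAStringSet`.
#' @param samples Optional character vector fixing the sample set (columns);
#'   defaults to the samples present in `variants`.
#' @return Integer matrix, 96 rows (named by class) x samples.
#' @export
build_catalog96 <- function(variants, reference, samples = NULL) {
  check_variants(variants)
  if (methods::is(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  if (is.null(samples)) samples <- unique(variants$sample)
  classes <- sbs96_classes()
  cat96 <- matrix(0L, nrow = 96L, ncol = length(samples),
                  dimnames = list(classes, samples))
  snv <- variants[nchar(variants$ref) == 1L, , drop = FALSE]
  if (nrow(snv) == 0L) return(cat96)
  if (any(snv$pos < 2L)) stop("SNV at position < 2 has no 5' context")
  ctx <- character(nrow(snv))
  for (chr in unique(snv$chrom)) {
    if (!chr %in% names(reference)) stop("chromosome absent from reference: ", chr)
    idx <- which(snv$chrom == chr)
    seqc <- reference[[chr]]
    if (any(snv$pos[idx] + 1L > nchar(seqc))) {
      stop("SNV at position without 3' context on ", chr)
    }
    ctx[idx] <- substr(rep(seqc, length(idx)), snv$pos[idx] - 1L, snv$pos[idx] + 1L)
  }
  mid <- substr(ctx, 2L, 2L)
  bad <- which(mid != snv$ref)
  if (length(bad) > 0L) {
    b <- bad[1L]
    stop(sprintf("reference mismatch for %s:%d (sample %s): ref %s but reference has %s",
                 snv$chrom[b], snv$pos[b], snv$sample[b], snv$ref[b], mid[b]))
  }
  lab <- mapply(classify_sbs96, snv$ref, snv$alt, ctx, USE.NAMES = FALSE)
  tab <- table(factor(lab, levels = classes),
               factor(snv$sample, levels = samples))
  cat96[] <- as.integer(tab)
  cat96
}

#' Summarize the mutation spectrum of a variant table
#'
#' Computes the six-class substitution fractions over SNVs
#' (pyrimidine-centric), the fraction of C>T SNVs at CpG sites (3' G on the
#' pyrimidine strand; requires a reference for context), the CC>TT fraction
#' of dinucleotide variants, and a VAF histogram.
#'
#' @param variants Variant data frame, after [collapse_dnps()].
#' @param reference Optional reference (as in [build_catalog96()]) for the
#'   CpG fraction; if `NULL` the CpG fraction is `NA`.
#' @param vaf_binwidth Bin width for the VAF histogram over \[0, 1\].
#' @return List with `six_class` (named fractions summing to 1 over SNVs),
#'   `cpg_ct_fraction`, `cc_tt_fraction` (`NA` when there are no DNPs, an
#'   undefined value rather than zero), `n_snv`, `n_dnp`, and `vaf_hist`
#'   (data frame of bin mids and counts).
#' @export
spectrum_summary <- function(variants, reference = NULL, vaf_binwidth = 0.05) {
  check_variants(variants)
  snv <- variants[nchar(variants$ref) == 1L, , drop = FALSE]
  dnp <- variants[nchar(variants$ref) == 2L, , drop = FALSE]

  six <- stats::setNames(rep(NA_real_, 6L), SBS_SUBSTITUTIONS)
  if (nrow(snv) > 0L) {
    ref <- snv$ref
    alt <- snv$alt
    flip <- ref %in% c("G", "A")
    ref[flip] <- chartr("GA", "CT", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    cls <- paste0(ref, ">", alt)
    six[] <- as.numeric(table(factor(cls, levels = SBS_SUBSTITUTIONS))) / nrow(snv)
  }

  cpg <- NA_real_
  if (!is.null(reference) && nrow(snv) > 0L) {
    cat96 <- build_catalog96(snv, reference)
    tot <- rowSums(cat96)
    ct <- grepl("\\[C>T\\]", names(tot))
    ct_cpg <- grepl("\\[C>T\\]G$", names(tot))
    if (sum(tot[ct]) > 0) cpg <- sum(tot[ct_cpg]) / sum(tot[ct])
  }

  cc_tt <- NA_real_
  if (nrow(dnp) > 0L) {
    hit <- (dnp$ref == "CC" & dnp$alt == "TT") |
           (dnp$ref == "GG" & dnp$alt == "AA")
    cc_tt <- mean(hit)
  }

  breaks <- seq(0, 1, by = vaf_binwidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  vh <- NULL
  if ("vaf" %in% names(variants) && any(!is.na(variants$vaf))) {
    h <- graphics::hist(variants$vaf[!is.na(variants$vaf)], breaks = breaks,
                        plot = FALSE, include.lowest = TRUE)
    vh <- data.frame(mid = h$mids, count = h$counts)
  }

  list(six_class = six, cpg_ct_fraction = cpg, cc_tt_fraction = cc_tt,
       n_snv = nrow(snv), n_dnp = nrow(dnp), vaf_hist = vh)
}

#' Per-sample mutation loads (variants per megabase)
#'
#' @param variants Variant data frame.
#' @param footprint_mb Callable territory in megabases; always an explicit
#'   input, never an embedded constant.
#' @return List with `per_sample` (data frame: sample, lesion_class, n,
#'   load) and `per_class` (data frame: lesion_class, mean, min, max of
#'   both counts and loads).
#' @export
mutation_load <- function(variants, footprint_mb) {
  check_variants(variants)
  if (!is.numeric(footprint_mb) || length(footprint_mb) != 1L ||
      footprint_mb <= 0) {
    stop("footprint_mb must be a single positive number")
  }
  meta <- unique(variants[, c("sample", "lesion_class")])
  n <- as.numeric(table(factor(variants$sample, levels = meta$sample)))
  per_sample <- data.frame(sample = meta$sample,
                           lesion_class = meta$lesion_class,
                           n = n, load = n / footprint_mb,
                           stringsAsFactors = FALSE)
  agg <- function(x) c(mean = mean(x), min = min(x), max = max(x))
  cls <- unique(per_sample$lesion_class)
  per_class <- do.call(rbind, lapply(cls, function(cl) {
    s <- per_sample[per_sample$lesion_class == cl, ]
    data.frame(lesion_class = cl,
               mean_n = mean(s$n), min_n = min(s$n), max_n = max(s$n),
               mean_load = mean(s$load), min_load = min(s$load),
               max_load = max(s$load), stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, per_class = per_class)
}

#' Filter for significantly mutated genes
#'
#' A gene is retained when it is recurrently mutated in at least
#' `min_pairings` tumour/control pairings (distinct samples carrying at least
#' one mutation in the gene) and is either on a list of genes previously
#' implicated in the disease or has a COSMIC recorded mutation count above
#' `cosmic_threshold`.
#'
#' @param variants Variant data frame with `gene` and (optionally)
#'   `cosmic_count` columns; missing COSMIC counts are treated as 0.
#' @param known_genes Character vector of previously implicated genes.
#' @param min_pairings Minimum number of pairings (default 7).
#' @param cosmic_threshold COSMIC count that substitutes for prior evidence
#'   (default 400; retention requires strictly greater).
#' @return Data frame of retained genes with pairing counts and the maximum
#'   annotated COSMIC count.
#' @export
smg_filter <- function(variants, known_genes = character(),
                       min_pairings = 7L, cosmic_threshold = 400L) {
  check_variants(variants)
  if (!"gene" %in% names(variants)) stop("variants must carry a gene column")
  v <- variants[!is.na(variants$gene), , drop = FALSE]
  if (nrow(v) == 0L) {
    return(data.frame(gene = character(), pairings = integer(),
                      cosmic_count = numeric(), known = logical()))
  }
  cosmic <- if ("cosmic_count" %in% names(v)) v$cosmic_count else rep(NA_real_, nrow(v))
  if (anyNA(cosmic)) {
    message(sum(is.na(cosmic)), " variants lack a COSMIC count; treated as 0")
    cosmic[is.na(cosmic)] <- 0
  }
  pairings <- tapply(v$sample, v$gene, function(s) length(unique(s)))
  cmax <- tapply(cosmic, v$gene, max)
  genes <- names(pairings)
  known <- genes %in% known_genes
  keep <- pairings >= min_pairings & (known | cmax > cosmic_threshold)
  out <- data.frame(gene = genes, pairings = as.integer(pairings),
                    cosmic_count = as.numeric(cmax), known = known,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(-out$pairings, out$gene), , drop = FALSE]
}

## Overlap between two samples' variant sets, keyed by (chrom, pos, alt).
overlap_count <- function(va, vb) {
  ka <- unique(paste(va$chrom, va$pos, va$alt, sep = "\r"))
  kb <- unique(paste(vb$chrom, vb$pos, vb$alt, sep = "\r"))
  length(intersect(ka, kb))
}

#' Within-patient site-specific variant overlap
#'
#' For every patient, counts the site-identical variants (same chromosome,
#' position and alternate allele) shared between each pair of that patient's
#' samples from different lesion classes, plus same-class pairs where a class
#' is duplicated (flagged, as with a patient carrying two carcinomas), plus
#' the higher-order intersections across three or four samples when present.
#'
#' @param variants Variant data frame.
#' @return List with `per_pair` (data frame: patient, sample_a, sample_b,
#'   class_pair, overlap, duplicated_class flag), `higher_order` (data
#'   frame of 3-way/4-way intersection counts per patient) and
#'   `class_pair_means` (cohort mean overlap per class pair, averaging over
#'   the sample pairs observed, as in published per-patient overlap tables).
#' @export
site_overlap <- function(variants) {
  check_variants(variants)
  per_pair <- NULL
  higher <- NULL
  for (pt in unique(variants$patient)) {
    pv <- variants[variants$patient == pt, , drop = FALSE]
    smp <- unique(pv[, c("sample", "lesion_class")])
    if (nrow(smp) < 2L) next
    dup_classes <- unique(smp$lesion_class[duplicated(smp$lesion_class)])
    cmb <- utils::combn(seq_len(nrow(smp)), 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- smp[cmb[1L, j], ]
      b <- smp[cmb[2L, j], ]
      ov <- overlap_count(pv[pv$sample == a$sample, ],
                          pv[pv$sample == b$sample, ])
      cp <- paste(sort(c(a$lesion_class, b$lesion_class)), collapse = "/")
      per_pair <- rbind(per_pair, data.frame(
        patient = pt, sample_a = a$sample, sample_b = b$sample,
        class_pair = cp, overlap = ov,
        duplicated_class = a$lesion_class %in% dup_classes |
          b$lesion_class %in% dup_classes,
        stringsAsFactors = FALSE))
    }
    if (nrow(smp) >= 3L) {
      for (k in 3:min(4L, nrow(smp))) {
        cmbk <- utils::combn(seq_len(nrow(smp)), k)
        for (j in seq_len(ncol(cmbk))) {
          keys <- lapply(smp$sample[cmbk[, j]], function(s) {
            sv <- pv[pv$sample == s, ]
            unique(paste(sv$chrom, sv$pos, sv$alt, sep = "\r"))
          })
          higher <- rbind(higher, data.frame(
            patient = pt,
            samples = paste(smp$sample[cmbk[, j]], collapse = ","),
            k = k, overlap = length(Reduce(intersect, keys)),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(per_pair)) {
    per_pair <- data.frame(patient = character(), sample_a = character(),
                           sample_b = character(), class_pair = character(),
                           overlap = integer(), duplicated_class = logical())
  }
  list(per_pair = per_pair, higher_order = higher,
       class_pair_means = overlap_cohort_means(per_pair))
}

#' Cohort mean overlap per lesion-class pair
#'
#' Aggregates a per-pair overlap table (as from [site_overlap()], or typed in
#' from a published per-patient overlap table) into the arithmetic mean
#' overlap for each class pair, averaging over the sample pairs observed.
#'
#' @param per_pair Data frame with columns `class_pair` and `overlap`.
#' @return Data frame with `class_pair`, `n_pairs`, `mean_overlap`.
#' @export
overlap_cohort_means <- function(per_pair) {
  stopifnot(all(c("class_pair", "overlap") %in% names(per_pair)))
  if (nrow(per_pair) == 0L) {
    return(data.frame(class_pair = character(), n_pairs = integer(),
                      mean_overlap = numeric()))
  }
  sp <- split(per_pair$overlap, per_pair$class_pair)
  data.frame(class_pair = names(sp),
             n_pairs = vapply(sp, length, integer(1)),
             mean_overlap = vapply(sp, mean, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
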