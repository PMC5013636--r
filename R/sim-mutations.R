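## Synthetic somatic-mutation cohorts: a random reference sequence, variants
## drawn from a known signature mixture and placed at context-matching
## positions, patient/lesion structure with partially shared clones, and
## the ground truth needed to score every downstream mutation statistic.

## Draw per-sample total counts: Poisson around the class mean, or negative
## binomial with variance mu + a mu^2 when count_dispersion (a) > 0.
draw_total_count <- function(mu, a) {
  if (a > 0) stats::rnbinom(1L, mu = mu, size = 1 / a) else stats::rpois(1L, mu)
}

#' Simulate a somatic-mutation cohort with known signature mixture
#'
#' Generates a uniform-random reference chromosome, then per patient and
#' lesion class draws a total mutation count around the class mean, draws
#' 96-class contexts from the class's signature mixture, and places each
#' mutation at a reference position whose trinucleotide matches the drawn
#' context on either strand (positions drawn without replacement within a
#' sample). Within each patient, a fraction `shared_clone_fraction` of each
#' later lesion's variants is replaced by site-identical copies of variants
#' from earlier lesions, emulating partially shared clones. Variant allele
#' frequencies are drawn from class-specific Beta distributions (more
#' clonal, higher-VAF lesions later in progression).
#'
#' @param cfg A [sim_config()].
#' @return List with `reference` (named character vector), `variants`
#'   (variant data frame as in [check_variants()]), `truth` (list:
#'   `exposures` per sample, `shared_sites` data frame, `class_totals`).
#' @export
simulate_mutation_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  W <- cfg$truth_signatures
  E <- cfg$truth_exposures
  set.seed(cfg$seed)
  classes96 <- sbs96_classes()

  ## reference and context index (both strands, pyrimidine-centric)
  refseq <- paste(sample(DNA_BASES, cfg$reference_length, replace = TRUE),
                  collapse = "")
  reference <- c(chr1 = refseq)
  bases <- strsplit(refseq, "", fixed = TRUE)[[1L]]
  n <- length(bases)
  tri <- paste0(bases[1:(n - 2L)], bases[2:(n - 1L)], bases[3:n])
  pos_mid <- 2:(n - 1L)
  ## canonical (pyrimidine-centric) context of every position
  mid_is_pyr <- bases[pos_mid] %in% c("C", "T")
  canon <- ifelse(mid_is_pyr, tri, revcomp(tri))
  ctx_index <- split(pos_mid, canon)
  ## context string of each 96-class: 5' + pyrimidine ref + 3'
  class_ctx <- paste0(substr(classes96, 1L, 1L), substr(classes96, 3L, 3L),
                      substr(classes96, 7L, 7L))
  class_alt <- substr(classes96, 5L, 5L)

  variants <- NULL
  truth_expo <- NULL
  shared_sites <- NULL
  for (pt in seq_len(cfg$n_patients)) {
    patient <- sprintf("P%02d", pt)
    patient_earlier <- NULL  # accumulated earlier-lesion variants
    for (ci in seq_along(cfg$lesion_classes)) {
      cls <- cfg$lesion_classes[ci]
      sample_id <- paste0(patient, "_", cls)
      mu <- cfg$class_mean_counts[[cls]]
      total <- draw_total_count(mu, cfg$count_dispersion)
      expo <- E[, cls] / sum(E[, cls])
      p96 <- as.numeric(W %*% expo)
      counts96 <- as.numeric(stats::rmultinom(1L, total, p96))
      ## place mutations context by context, without position reuse
      rows <- vector("list", 96L)
      used <- new.env(hash = TRUE)
      for (j in which(counts96 > 0L)) {
        pool <- ctx_index[[class_ctx[j]]]
        if (is.null(pool) || length(pool) < counts96[j]) {
          stop("context ", class_ctx[j], " exhausted on the reference; ",
               "increase reference_length")
        }
        picked <- sample(pool, counts96[j])
        ## bounded retries against within-sample position collisions
        for (tries in seq_len(1000L)) {
          clash <- vapply(as.character(picked), function(k)
            !is.null(used[[k]]), logical(1))
          if (!any(clash)) break
          picked[clash] <- sample(pool, sum(clash))
          if (tries == 1000L) stop("could not place context ", class_ctx[j],
                                   " without collision after 1000 retries")
        }
        for (k in as.character(picked)) used[[k]] <- TRUE
        refb <- bases[picked]
        pyr <- refb %in% c("C", "T")
        alt <- ifelse(pyr, class_alt[j],
                      chartr("ACGT", "TGCA", class_alt[j]))
        rows[[j]] <- data.frame(pos = picked, ref = refb, alt = alt,
                                stringsAsFactors = FALSE)
      }
      sv <- do.call(rbind, rows)
      if (is.null(sv)) {
        sv <- data.frame(pos = integer(), ref = character(),
                         alt = character())
      }
      ## progressively more clonal lesions: higher-VAF Beta draws later on
      vaf_shape <- if (ci == 1L) c(1.5, 8) else if (ci == 2L) c(2, 5) else c(3, 4)
      sv <- data.frame(patient = patient, sample = sample_id,
                       lesion_class = cls, chrom = "chr1", pos = sv$pos,
                       ref = sv$ref, alt = sv$alt,
                       vaf = stats::rbeta(nrow(sv), vaf_shape[1L], vaf_shape[2L]),
                       gene = paste0("g", ceiling(sv$pos / 2000)),
                       cosmic_count = 0L, stringsAsFactors = FALSE)
      ## shared clones: copy earlier-lesion variants site-identically
      if (ci > 1L && cfg$shared_clone_fraction > 0 &&
          !is.null(patient_earlier) && nrow(sv) > 0L) {
        n_share <- min(floor(cfg$shared_clone_fraction * nrow(sv)),
                       nrow(patient_earlier))
        if (n_share > 0L) {
          src <- patient_earlier[sample(nrow(patient_earlier), n_share), ,
                                 drop = FALSE]
          ## replace rows whose positions are not already shared
          repl <- utils::head(which(!sv$pos %in% src$pos), n_share)
          n_share <- length(repl)
          src <- src[seq_len(n_share), , drop = FALSE]
          sv$pos[repl] <- src$pos
          sv$ref[repl] <- src$ref
          sv$alt[repl] <- src$alt
          sv$gene[repl] <- src$gene
          shared_sites <- rbind(shared_sites, data.frame(
            patient = patient, sample = sample_id, chrom = "chr1",
            pos = src$pos, alt = src$alt, from_sample = src$sample,
            stringsAsFactors = FALSE))
          sv <- sv[!duplicated(sv$pos), , drop = FALSE]
        }
      }
      variants <- rbind(variants, sv)
      patient_earlier <- rbind(patient_earlier,
                               sv[, c("sample", "pos", "ref", "alt", "gene")])
      truth_expo <- rbind(truth_expo, data.frame(
        sample = sample_id, t(expo), check.names = FALSE,
        stringsAsFactors = FALSE))
    }
  }
  rownames(variants) <- NULL
  list(reference = reference, variants = variants,
       truth = list(exposures = truth_expo, shared_sites = shared_sites,
                    class_totals = cfg$class_mean_counts))
}
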