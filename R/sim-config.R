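## Configuration of the synthetic-data generator.  Defaults mirror the
## study design the pipeline targets: three lesion classes with mean
## mutation counts 372 / 1,186 / 2,927 (chronically sun-exposed skin,
## actinic keratosis, carcinoma), a ~64 Mb callable exome footprint, six
## patients with complete lesion sets, and a UVB-dominated signature
## mixture.

#' Default synthetic signature basis
#'
#' Well-separated 96-class signatures mimicking distinct mutational
#' processes. `k = 2` gives a UVB-like signature concentrated on C>T at
#' dipyrimidine contexts (5' C or T) plus a flat background, the minimal
#' pair for UV-driven cohorts. `k = 4` gives four peaked processes —
#' UVB-like C>T, oxidative-damage-like C>A, APOBEC-like C>G at TpC, and a
#' T>C-dominated process — as real signature catalogues are peaked rather
#' than uniform. Columns sum to 1.
#'
#' @param k Number of signatures, 2 (default) or 4.
#' @return 96 x k matrix with named rows and columns.
#' @export
default_truth_signatures <- function(k = 2L) {
  classes <- sbs96_classes()
  peaked <- function(pattern) {
    w <- rep(0.001, 96L)
    names(w) <- classes
    w[grepl(pattern, classes)] <- 1
    w / sum(w)
  }
  uvb <- peaked("^[CT]\\[C>T\\]")
  if (k == 2L) {
    bg <- stats::setNames(rep(1 / 96, 96L), classes)
    return(cbind(UVB = uvb, background = bg))
  }
  if (k == 4L) {
    return(cbind(UVB = uvb,
                 oxidative = peaked("\\[C>A\\]"),
                 apobec = peaked("^T\\[C>G\\]"),
                 TtoC = peaked("\\[T>C\\]")))
  }
  stop("k must be 2 or 4")
}

#' Synthetic-generator configuration
#'
#' Collects every knob of the synthetic generators with study-shaped
#' defaults; the seed fully determines all outputs.
#'
#' @param seed Integer seed.
#' @param n_patients Patients (each with a complete lesion set).
#' @param lesion_classes Ordered lesion-class labels, earliest first.
#' @param class_mean_counts Mean somatic variant count per lesion class.
#' @param count_dispersion Negative-binomial dispersion of per-sample totals
#'   (variance `mu + a mu^2`); 0 (the default) draws Poisson totals.
#' @param shared_clone_fraction Fraction of a later lesion's variants copied
#'   site-identically from the patient's earlier lesions (default 0.003,
#'   matching the near-chance overlap scale of the targeted cohort).
#' @param footprint_mb Callable territory for load computation (default
#'   64.05 Mb); a scalar decoupled from the reference length.
#' @param reference_length Length of the uniform-random reference (1 Mb).
#' @param truth_signatures 96 x k matrix, columns summing to 1.
#' @param truth_exposures k x classes matrix of mixture weights per lesion
#'   class (columns normalized internally); defaults favour UVB more
#'   strongly in later classes.
#' @param genes_total Genes per species in the expression generator.
#' @param frac_early,frac_late,frac_stepwise Planted fractions (sum <= 1).
#' @param effect_size_log2 Planted per-transition shift (log2 units).
#' @param subject_sd Random-intercept standard deviation (log2 units).
#' @param batch_shift Magnitude of the per-gene batch shift (log2 units).
#' @param nb_dispersion Negative-binomial dispersion of expression counts.
#' @param n_subjects Subjects per species (complete stage sets).
#' @param one_to_one_fraction Fraction of genes in clean one-to-one homolog
#'   pairs; the remainder are many-to-many or unmapped.
#' @param mirna_target_map Named list mapping each miRNA to its target
#'   genes; `NULL` lets the miRNA generator build a synthetic seed-match
#'   map.
#' @param penetrance Fraction of a perturbed miRNA's targets that respond
#'   (in \[0, 1\]).
#' @param hazard_coef Log hazard ratio per standard deviation of the
#'   signature score in the survival generator.
#' @param censor_rate Independent censoring probability per record.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 6L,
                       lesion_classes = c("NS", "AK", "SCC"),
                       class_mean_counts = c(NS = 372, AK = 1186, SCC = 2927),
                       count_dispersion = 0,
                       shared_clone_fraction = 0.003,
                       footprint_mb = 64.05,
                       reference_length = 1e6,
                       truth_signatures = default_truth_signatures(),
                       truth_exposures = NULL,
                       genes_total = 2000L,
                       frac_early = 0.05, frac_late = 0.05,
                       frac_stepwise = 0.05,
                       effect_size_log2 = 1,
                       subject_sd = 0.5,
                       batch_shift = 0.5,
                       nb_dispersion = 0.1,
                       n_subjects = 6L,
                       one_to_one_fraction = 0.8,
                       mirna_target_map = NULL,
                       penetrance = 0.8,
                       hazard_coef = 0.5,
                       censor_rate = 0.2) {
  if (is.null(names(class_mean_counts))) {
    names(class_mean_counts) <- lesion_classes
  }
  if (!all(lesion_classes %in% names(class_mean_counts))) {
    stop("class_mean_counts must cover every lesion class")
  }
  truth_signatures <- as.matrix(truth_signatures)
  k <- ncol(truth_signatures)
  if (any(abs(colSums(truth_signatures) - 1) > 1e-9)) {
    stop("truth signature columns must sum to 1")
  }
  if (is.null(truth_exposures)) {
    truth_exposures <- if (k == 2L) {
      matrix(c(0.5, 0.5, 0.8, 0.2, 0.9, 0.1), nrow = 2L,
             dimnames = list(colnames(truth_signatures), lesion_classes))
    } else {
      matrix(1 / k, k, length(lesion_classes),
             dimnames = list(colnames(truth_signatures), lesion_classes))
    }
  }
  truth_exposures <- as.matrix(truth_exposures)
  if (nrow(truth_exposures) != k) {
    stop("truth_exposures rows must match the signature count")
  }
  props <- c(frac_early = frac_early, frac_late = frac_late,
             frac_stepwise = frac_stepwise,
             shared_clone_fraction = shared_clone_fraction,
             penetrance = penetrance, censor_rate = censor_rate,
             one_to_one_fraction = one_to_one_fraction)
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]: ",
         paste(names(props)[props < 0 | props > 1], collapse = ", "))
  }
  if (frac_early + frac_late + frac_stepwise > 1) {
    stop("planted fractions must sum to at most 1")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (count_dispersion < 0) stop("count_dispersion must be >= 0")
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  if (footprint_mb <= 0) stop("footprint_mb must be positive")
  if (!is.finite(hazard_coef)) stop("hazard_coef must be finite")
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              lesion_classes = lesion_classes,
              class_mean_counts = class_mean_counts,
              count_dispersion = count_dispersion,
              shared_clone_fraction = shared_clone_fraction,
              footprint_mb = footprint_mb,
              reference_length = reference_length,
              truth_signatures = truth_signatures,
              truth_exposures = truth_exposures,
              genes_total = as.integer(genes_total),
              frac_early = frac_early, frac_late = frac_late,
              frac_stepwise = frac_stepwise,
              effect_size_log2 = effect_size_log2,
              subject_sd = subject_sd, batch_shift = batch_shift,
              nb_dispersion = nb_dispersion,
              n_subjects = as.integer(n_subjects),
              one_to_one_fraction = one_to_one_fraction,
              mirna_target_map = mirna_target_map,
              penetrance = penetrance,
              hazard_coef = hazard_coef, censor_rate = censor_rate)
  class(cfg) <- "sim_config"
  cfg
}
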