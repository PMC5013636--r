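## Synthetic miRNA/mRNA pairs: perturbed miRNAs whose mapped targets move in
## the opposite direction with configurable penetrance, plus null genes and
## null miRNAs, with the truth pair list emitted alongside.

#' Build a synthetic miRNA-to-target seed-match map
#'
#' @param n_mirna Number of miRNAs.
#' @param n_genes Size of the gene pool.
#' @param targets_per_mirna Targets mapped to each miRNA.
#' @param seed Integer seed.
#' @return Named list of target gene vectors per miRNA.
#' @export
synthetic_target_map <- function(n_mirna = 30L, n_genes = 1000L,
                                 targets_per_mirna = 15L, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("TG%04d", seq_len(n_genes))
  out <- lapply(seq_len(n_mirna), function(i)
    sample(genes, targets_per_mirna))
  names(out) <- sprintf("miR-%03d", seq_len(n_mirna))
  out
}

#' Simulate stage-responsive miRNAs with anti-correlated targets
#'
#' A chosen subset of miRNAs moves up (or down) monotonically across the
#' three stages; each perturbed miRNA's mapped targets move in the opposite
#' direction with probability `penetrance` per target. All remaining genes
#' and miRNAs are null. Counts are negative binomial on both sides.
#'
#' @param cfg A [sim_config()]; if `cfg$mirna_target_map` is `NULL` a
#'   synthetic seed-match map is built.
#' @param n_perturbed Number of perturbed miRNAs (default 10, capped at the
#'   map size).
#' @param mirna_effect_log2 Per-transition miRNA shift (default 2).
#' @param gene_effect_log2 Per-transition target shift (default 1.5).
#' @param n_per_stage Samples per stage (default 6).
#' @return List with `mirna_counts`, `mrna_counts` (matrices; samples share
#'   metadata `meta`), `target_map`, and `truth` (list: `perturbed` data
#'   frame of miRNA directions; `pairs` data frame of responding
#'   miRNA-target pairs).
#' @export
simulate_mirna_and_pairs <- function(cfg, n_perturbed = 10L,
                                     mirna_effect_log2 = 2,
                                     gene_effect_log2 = 1.5,
                                     n_per_stage = 6L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  target_map <- cfg$mirna_target_map
  if (is.null(target_map)) {
    target_map <- synthetic_target_map(seed = cfg$seed + 2L)
  }
  if (length(target_map) == 0L) stop("mirna_target_map must be nonempty")
  stages <- cfg$lesion_classes
  mirnas <- names(target_map)
  genes <- sort(unique(unlist(target_map)))
  n_perturbed <- min(n_perturbed, length(mirnas))

  meta <- data.frame(
    sample = paste0("M", seq_len(3L * n_per_stage)),
    stage = rep(stages, each = n_per_stage), stringsAsFactors = FALSE)
  stage_idx <- match(meta$stage, stages) - 1L   # 0, 1, 2

  perturbed <- sample(mirnas, n_perturbed)
  mir_dir <- ifelse(stats::runif(n_perturbed) < 0.5, -1, 1)
  names(mir_dir) <- perturbed

  truth_pairs <- NULL
  gene_shift <- stats::setNames(rep(0, length(genes)), genes)
  for (m in perturbed) {
    responders <- target_map[[m]][stats::runif(length(target_map[[m]])) <
                                    cfg$penetrance]
    responders <- setdiff(responders, names(gene_shift)[gene_shift != 0])
    if (length(responders) > 0L) {
      gene_shift[responders] <- -mir_dir[m] * gene_effect_log2
      truth_pairs <- rbind(truth_pairs, data.frame(
        mirna = m, gene = responders,
        mirna_direction = if (mir_dir[m] > 0) "up" else "down",
        gene_direction = if (mir_dir[m] > 0) "down" else "up",
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(truth_pairs)) {
    truth_pairs <- truth_pairs[order(truth_pairs$mirna, truth_pairs$gene), ,
                               drop = FALSE]
    rownames(truth_pairs) <- NULL
  }

  nb <- function(mu_log2) {
    matrix(stats::rnbinom(length(mu_log2), mu = 2^mu_log2,
                          size = 1 / cfg$nb_dispersion),
           nrow(mu_log2), ncol(mu_log2))
  }
  mir_base <- stats::rnorm(length(mirnas), 10, 1)
  mir_mu <- matrix(mir_base, length(mirnas), nrow(meta))
  for (m in perturbed) {
    i <- match(m, mirnas)
    mir_mu[i, ] <- mir_mu[i, ] + mir_dir[m] * mirna_effect_log2 * stage_idx
  }
  mirna_counts <- nb(mir_mu)
  dimnames(mirna_counts) <- list(mirnas, meta$sample)

  gene_base <- stats::rnorm(length(genes), 7, 1)
  gene_mu <- matrix(gene_base, length(genes), nrow(meta))
  shifted <- which(gene_shift != 0)
  for (i in shifted) {
    gene_mu[i, ] <- gene_mu[i, ] + gene_shift[i] * stage_idx
  }
  mrna_counts <- nb(gene_mu)
  dimnames(mrna_counts) <- list(genes, meta$sample)

  list(mirna_counts = mirna_counts, mrna_counts = mrna_counts, meta = meta,
       target_map = target_map,
       truth = list(perturbed = data.frame(
         mirna = perturbed,
         direction = ifelse(mir_dir > 0, "up", "down"),
         stringsAsFactors = FALSE),
         pairs = truth_pairs))
}
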