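## Ranked-list gene-set enrichment: the weighted Kolmogorov-Smirnov running
## sum, gene-label permutation significance with NES and BH q per direction,
## the cross-species transcription-factor target concordance filter, and the
## TF co-target overlap network.

#' GSEA running sum and enrichment score
#'
#' Standard weighted Kolmogorov-Smirnov statistic: walking down the ranked
#' list, membership hits increment the running sum in proportion to
#' `|score|^weight_exponent` (normalized over the set), misses decrement it
#' by `1/(N - m)`; the enrichment score is the signed maximum deviation.
#'
#' @param ranked_genes Character vector of unique gene ids, ordered from the
#'   top of the ranking.
#' @param scores Numeric ranking scores aligned with `ranked_genes`.
#' @param gene_set Character vector of member genes.
#' @param weight_exponent Hit-weight exponent (default 1; 0 gives the
#'   classic unweighted statistic).
#' @return List with `es` and `profile` (running sum at every position).
#'   `es` is `NA` when the set does not intersect the list, and 0 in the
#'   degenerate case where the set covers the whole list.
#' @export
gsea_running_sum <- function(ranked_genes, scores, gene_set,
                             weight_exponent = 1) {
  if (anyDuplicated(ranked_genes)) stop("ranked gene ids must be unique")
  n <- length(ranked_genes)
  hit <- ranked_genes %in% gene_set
  m <- sum(hit)
  if (m == 0L) return(list(es = NA_real_, profile = rep(NA_real_, n)))
  if (m == n) return(list(es = 0, profile = rep(0, n)))
  w <- abs(scores)^weight_exponent
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - m)
  profile <- cumsum(inc)
  es <- profile[which.max(abs(profile))]
  list(es = es, profile = profile)
}

## Fast ES for permutation nulls: computes the running-sum extremum from the
## sorted hit positions only, in O(m) after the hit draw.
gsea_es_fast <- function(hit_pos, weights_abs, n) {
  m <- length(hit_pos)
  hit_pos <- sort.int(hit_pos)
  w <- weights_abs[hit_pos]
  cw <- cumsum(w) / sum(w)
  miss_before <- (hit_pos - seq_len(m)) / (n - m)  # misses preceding each hit
  ## candidate extrema: just after each hit, and just before each hit
  after <- cw - miss_before
  before <- c(0, cw[-m]) - miss_before
  cand <- c(after, before, if (hit_pos[m] < n) -((n - m) / (n - m)) + cw[m] else NULL)
  cand[which.max(abs(cand))]
}

#' Permutation significance for gene sets on a ranked list
#'
#' For each set, the enrichment score is referred to a null built by
#' repeatedly drawing random gene labels of the same size from the ranked
#' list (gene-label permutation). NES is the ES divided by the mean
#' magnitude of same-sign null scores; the empirical p uses same-sign null
#' scores with an add-one correction; BH q-values are computed within each
#' direction.
#'
#' @param ranked_genes,scores Ranked gene ids and aligned scores.
#' @param gene_sets Named list of gene-id vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param weight_exponent Passed to the running sum.
#' @return Data frame per set: `set`, `size` (in-list), `es`, `nes`, `p`,
#'   `q`, `direction`.
#' @export
gsea_significance <- function(ranked_genes, scores, gene_sets,
                              n_perm = 1000L, seed = 1L,
                              weight_exponent = 1) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  n <- length(ranked_genes)
  w <- abs(scores)^weight_exponent
  set.seed(seed)
  res <- lapply(names(gene_sets), function(nmset) {
    hit <- which(ranked_genes %in% gene_sets[[nmset]])
    m <- length(hit)
    if (m == 0L || m == n) {
      return(data.frame(set = nmset, size = m, es = if (m == 0L) NA_real_ else 0,
                        nes = NA_real_, p = NA_real_, q = NA_real_,
                        direction = NA_character_, stringsAsFactors = FALSE))
    }
    es <- gsea_es_fast(hit, w, n)
    null_es <- vapply(seq_len(n_perm), function(i)
      gsea_es_fast(sample.int(n, m), w, n), numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    if (length(same) == 0L) {
      nes <- NA_real_
      p <- 1 / (n_perm + 1)
    } else {
      nes <- es / mean(abs(same))
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    }
    data.frame(set = nmset, size = m, es = es, nes = nes, p = p, q = NA_real_,
               direction = if (es > 0) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  for (d in c("up", "down")) {
    idx <- which(out$direction %in% d)
    out$q[idx] <- stats::p.adjust(out$p[idx], method = "BH")
  }
  out
}

#' Cross-species transcription-factor concordance filter
#'
#' A factor is selected when (i) in at least one adjacent stage comparison
#' (first transition = early, second = late) its target set is significantly
#' enriched (q below `q_max`) in the same direction in both species, and
#' (ii) its targets are also significantly enriched, in a direction shared
#' by both species, in the full first-to-last comparison. The stage label
#' records which adjacent comparison(s) fired: `early`, `late`, or `global`
#' when both did.
#'
#' @param enrich_a,enrich_b Named lists of [gsea_significance()] tables per
#'   comparison for the two species; names must include `early`, `late`,
#'   `full`.
#' @param q_max Significance cutoff (default 0.25).
#' @return Data frame per selected factor: `factor`, `stage`, and the
#'   per-comparison directions in each species (early/late entries `NA`
#'   when that comparison did not fire).
#' @export
tf_concordance_filter <- function(enrich_a, enrich_b, q_max = 0.25) {
  stopifnot(all(c("early", "late", "full") %in% names(enrich_a)),
            all(c("early", "late", "full") %in% names(enrich_b)))
  sig_dir <- function(tab, f) {
    row <- tab[tab$set == f, , drop = FALSE]
    if (nrow(row) != 1L || is.na(row$q) || row$q >= q_max) return(NA_character_)
    row$direction
  }
  factors <- sort(unique(c(enrich_a$full$set, enrich_b$full$set)))
  out <- lapply(factors, function(f) {
    fa <- sig_dir(enrich_a$full, f); fb <- sig_dir(enrich_b$full, f)
    if (is.na(fa) || is.na(fb) || fa != fb) return(NULL)
    ea <- sig_dir(enrich_a$early, f); eb <- sig_dir(enrich_b$early, f)
    la <- sig_dir(enrich_a$late, f); lb <- sig_dir(enrich_b$late, f)
    early_hit <- !is.na(ea) && !is.na(eb) && ea == eb
    late_hit <- !is.na(la) && !is.na(lb) && la == lb
    if (!early_hit && !late_hit) return(NULL)
    stage <- if (early_hit && late_hit) "global" else if (early_hit) "early" else "late"
    data.frame(factor = f, stage = stage, full_direction = fa,
               early_direction = if (early_hit) ea else NA_character_,
               late_direction = if (late_hit) la else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(factor = character(), stage = character(),
                      full_direction = character(),
                      early_direction = character(),
                      late_direction = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Transcription-factor co-target overlap network
#'
#' Connects two selected factors when the overlap of their target sets
#' within the regulated gene universe is larger than expected by chance
#' (one-sided Fisher exact test below `p_threshold`); the edge weight is the
#' overlap size. Factors whose target set is empty within the universe are
#' isolated nodes.
#'
#' @param factors Character vector of selected factor names.
#' @param target_sets Named list of target gene vectors.
#' @param universe Regulated gene universe.
#' @param p_threshold Edge significance threshold (default 1e-4).
#' @return List with `edges` (data frame: `from`, `to`, `overlap`, `p`) and
#'   `nodes`.
#' @export
tf_cotarget_network <- function(factors, target_sets, universe,
                                p_threshold = 1e-4) {
  universe <- unique(universe)
  tsets <- lapply(factors, function(f) intersect(target_sets[[f]], universe))
  names(tsets) <- factors
  edges <- NULL
  if (length(factors) >= 2L) {
    cmb <- utils::combn(factors, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      ta <- tsets[[a]]; tb <- tsets[[b]]
      if (length(ta) == 0L || length(tb) == 0L) next
      n11 <- length(intersect(ta, tb))
      tab <- matrix(c(n11, length(tb) - n11,
                      length(ta) - n11,
                      length(universe) - length(ta) - length(tb) + n11), 2L)
      p <- stats::fisher.test(tab, alternative = "greater")$p.value
      if (p < p_threshold) {
        edges <- rbind(edges, data.frame(from = a, to = b, overlap = n11,
                                         p = p, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        overlap = integer(), p = numeric())
  }
  list(edges = edges, nodes = factors)
}
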