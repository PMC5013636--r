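## Small-RNA quantification and miRNA-mRNA functional pairs: read filtering,
## parts-per-million quantification against a miRNA reference, differential
## expression with the two-of-three recurrence rule, one-sided Fisher
## target-set enrichment, and cross-species pair conservation.

#' Filter small-RNA reads
#'
#' Keeps adapter-trimmed reads of length at least 10 nt whose terminal
#' single-base homopolymer run is at most 8 nt (reads ending in a
#' homopolymer of 9 nt or more are artefacts of the library chemistry and
#' are discarded).
#'
#' @param reads Character vector of read sequences.
#' @return List with `usable` (the retained reads), `n_usable`, and
#'   `discarded` (named counts by reason: `short`, `homopolymer`).
#' @export
filter_small_rna_reads <- function(reads) {
  if (length(reads) == 0L) {
    warning("no reads supplied")
    return(list(usable = character(), n_usable = 0L,
                discarded = c(short = 0L, homopolymer = 0L)))
  }
  len <- nchar(reads)
  short <- len < 10L
  tail_run <- function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1L]]
    rl <- rle(rev(ch))
    rl$lengths[1L]
  }
  homop <- !short & vapply(reads, tail_run, numeric(1), USE.NAMES = FALSE) >= 9L
  usable <- reads[!short & !homop]
  list(usable = usable, n_usable = length(usable),
       discarded = c(short = sum(short), homopolymer = sum(homop)))
}

## Mismatch count between equal-length strings (vectorized over x).
string_mismatches <- function(x, ref) {
  rc <- strsplit(ref, "", fixed = TRUE)[[1L]]
  vapply(strsplit(x, "", fixed = TRUE), function(ch) sum(ch != rc), numeric(1))
}

#' Quantify miRNA abundance in parts per million
#'
#' Assigns each usable read to the reference miRNAs it matches — a read
#' matches when it equals the reference sequence or a prefix of it with at
#' most `max_mismatch` mismatches — splitting multi-matching reads
#' fractionally across their matches. Abundance is expressed in parts per
#' million of the usable reads.
#'
#' @param usable_reads Character vector of filtered reads.
#' @param reference Named character vector of miRNA sequences (unique ids).
#' @param max_mismatch Allowed mismatches within the prefix (default 1).
#' @return List of class `mirna_profile`: `counts` (fractional, per miRNA),
#'   `ppm`, `n_usable`, `unmapped_fraction`.
#' @export
quantify_mirna <- function(usable_reads, reference, max_mismatch = 1L) {
  if (anyDuplicated(names(reference))) stop("duplicate reference ids")
  n_usable <- length(usable_reads)
  counts <- stats::setNames(numeric(length(reference)), names(reference))
  if (n_usable > 0L) {
    rlen <- nchar(usable_reads)
    match_mat <- matrix(FALSE, n_usable, length(reference))
    for (j in seq_along(reference)) {
      ref <- reference[[j]]
      ok <- rlen <= nchar(ref)
      if (!any(ok)) next
      for (L in unique(rlen[ok])) {
        idx <- which(rlen == L & ok)
        mm <- string_mismatches(usable_reads[idx], substr(ref, 1L, L))
        match_mat[idx[mm <= max_mismatch], j] <- TRUE
      }
    }
    nmatch <- rowSums(match_mat)
    hit <- which(nmatch > 0L)
    for (i in hit) {
      js <- which(match_mat[i, ])
      counts[js] <- counts[js] + 1 / length(js)
    }
  }
  ppm <- if (n_usable > 0L) counts / n_usable * 1e6 else counts * 0
  structure(list(counts = counts, ppm = ppm, n_usable = n_usable,
                 unmapped_fraction = if (n_usable > 0L)
                   1 - sum(ppm) / 1e6 else NA_real_),
            class = "mirna_profile")
}

#' miRNA differential expression with the two-of-three recurrence rule
#'
#' Per pairwise stage comparison, a two-sided t-test on `log2(ppm + 1)` with
#' a linear fold-change requirement; a miRNA is *recurrent* when it is
#' significant with a consistent direction in at least `min_recurrent` of
#' the pairwise comparisons. miRNAs with all-zero abundance in both groups
#' of a comparison are excluded from that comparison.
#'
#' @param ppm miRNA x samples matrix of ppm values.
#' @param stages Per-sample stage labels.
#' @param comparisons List of 2-vectors `c(reference, test)`; default all
#'   three pairwise comparisons of the three stage labels in order.
#' @param fc_min Linear fold-change threshold (default 1.5).
#' @param p_max Nominal p threshold (default 0.05).
#' @param min_recurrent Comparisons required for recurrence (default 2).
#' @return List with `per_comparison` (long data frame: mirna, comparison,
#'   log2fc, p, significant, direction) and `recurrent` (data frame: mirna,
#'   n_significant, direction, recurrent).
#' @export
de_mirna_recurrent <- function(ppm, stages, comparisons = NULL,
                               fc_min = 1.5, p_max = 0.05,
                               min_recurrent = 2L) {
  ppm <- as.matrix(ppm)
  if (is.null(comparisons)) {
    st <- unique(stages)
    if (length(st) != 3L) stop("default comparisons need exactly three stages")
    comparisons <- list(c(st[1L], st[2L]), c(st[2L], st[3L]), c(st[1L], st[3L]))
  }
  x <- log2(ppm + 1)
  long <- NULL
  for (cmp in comparisons) {
    ia <- which(stages == cmp[1L]); ib <- which(stages == cmp[2L])
    if (length(ia) < 2L || length(ib) < 2L) stop("need >= 2 samples per group")
    lab <- paste0(cmp[2L], "_vs_", cmp[1L])
    for (i in seq_len(nrow(ppm))) {
      if (all(ppm[i, c(ia, ib)] == 0)) next
      av <- x[i, ia]; bv <- x[i, ib]
      lfc <- mean(bv) - mean(av)
      p <- if (stats::sd(av) == 0 && stats::sd(bv) == 0) {
        if (mean(av) == mean(bv)) 1 else 0
      } else stats::t.test(bv, av)$p.value
      long <- rbind(long, data.frame(
        mirna = rownames(ppm)[i], comparison = lab, log2fc = lfc, p = p,
        significant = p < p_max & abs(lfc) > log2(fc_min),
        direction = if (lfc > 0) "up" else "down",
        stringsAsFactors = FALSE))
    }
  }
  rec <- do.call(rbind, lapply(split(long, long$mirna), function(d) {
    sig <- d[d$significant, , drop = FALSE]
    ns_up <- sum(sig$direction == "up")
    ns_down <- sum(sig$direction == "down")
    ns <- max(ns_up, ns_down)
    data.frame(mirna = d$mirna[1L], n_significant = ns,
               direction = if (ns == 0L) NA_character_
                           else if (ns_up >= ns_down) "up" else "down",
               recurrent = ns >= min_recurrent, stringsAsFactors = FALSE)
  }))
  rownames(rec) <- NULL
  list(per_comparison = long, recurrent = rec)
}

#' miRNA-mRNA functional pairs by target-set enrichment
#'
#' For each differentially expressed miRNA and each comparison, tests by
#' one-sided Fisher exact test whether its predicted targets are
#' overrepresented among the genes moving in the opposite direction
#' (q below `q_max`, linear fold change above `fc_min`), with BH correction
#' across miRNAs within a comparison. For miRNAs passing `q_max`, emits one
#' pair per anti-directional differentially expressed target; pairs are
#' ranked by the number of comparisons in which they are significant.
#'
#' @param mirna_de `per_comparison` table from [de_mirna_recurrent()] (only
#'   rows with `significant = TRUE` seed pairs).
#' @param gene_de Named list per comparison of gene DE tables
#'   ([differential_expression()]); comparison names must match
#'   `mirna_de$comparison`.
#' @param target_map Named list: predicted target gene vectors per miRNA.
#' @param q_max Enrichment and gene-DE q cutoff (default 0.25).
#' @param fc_min Gene fold-change cutoff (default 1.25).
#' @return List with `enrichment` (per miRNA x comparison Fisher results)
#'   and `pairs` (data frame: mirna, gene, mirna_direction, gene_direction,
#'   comparisons, n_comparisons), ranked by `n_comparisons`.
#' @export
functional_pairs <- function(mirna_de, gene_de, target_map,
                             q_max = 0.25, fc_min = 1.25) {
  enr <- NULL
  pair_rows <- NULL
  for (cmp in unique(mirna_de$comparison)) {
    if (!cmp %in% names(gene_de)) next
    gde <- gene_de[[cmp]]
    universe <- unique(gde$gene)
    if (length(universe) == 0L) stop("empty gene universe")
    thr <- de_threshold(gde, q_max = q_max, fc_min = fc_min)
    md <- mirna_de[mirna_de$comparison == cmp & mirna_de$significant, ,
                   drop = FALSE]
    if (nrow(md) == 0L) next
    rows <- lapply(seq_len(nrow(md)), function(i) {
      mir <- md$mirna[i]
      anti <- if (md$direction[i] == "up") thr$down else thr$up
      targets <- intersect(target_map[[mir]], universe)
      n11 <- length(intersect(targets, anti))
      if (length(targets) == 0L) {
        p <- 1
      } else {
        tab <- matrix(c(n11, length(anti) - n11,
                        length(targets) - n11,
                        length(universe) - length(anti) - length(targets) + n11),
                      2L)
        p <- stats::fisher.test(tab, alternative = "greater")$p.value
      }
      data.frame(mirna = mir, comparison = cmp,
                 mirna_direction = md$direction[i],
                 n_targets = length(targets), n_anti = length(anti),
                 overlap = n11, p = p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- stats::p.adjust(tab$p, method = "BH")
    enr <- rbind(enr, tab)
    for (i in which(tab$q < q_max)) {
      mir <- tab$mirna[i]
      anti <- if (tab$mirna_direction[i] == "up") thr$down else thr$up
      hits <- intersect(intersect(target_map[[mir]], universe), anti)
      if (length(hits) > 0L) {
        pair_rows <- rbind(pair_rows, data.frame(
          mirna = mir, gene = hits, comparison = cmp,
          mirna_direction = tab$mirna_direction[i],
          gene_direction = if (tab$mirna_direction[i] == "up") "down" else "up",
          stringsAsFactors = FALSE))
      }
    }
  }
  pairs <- data.frame(mirna = character(), gene = character(),
                      mirna_direction = character(),
                      gene_direction = character(),
                      comparisons = character(), n_comparisons = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(pair_rows)) {
    key <- paste(pair_rows$mirna, pair_rows$gene, pair_rows$mirna_direction,
                 sep = "\r")
    sp <- split(pair_rows, key)
    pairs <- do.call(rbind, lapply(sp, function(d) data.frame(
      mirna = d$mirna[1L], gene = d$gene[1L],
      mirna_direction = d$mirna_direction[1L],
      gene_direction = d$gene_direction[1L],
      comparisons = paste(sort(unique(d$comparison)), collapse = ","),
      n_comparisons = length(unique(d$comparison)),
      stringsAsFactors = FALSE)))
    pairs <- pairs[order(-pairs$n_comparisons, pairs$mirna, pairs$gene), ,
                   drop = FALSE]
    rownames(pairs) <- NULL
  }
  list(enrichment = enr, pairs = pairs)
}

#' Conserved functional pairs across species
#'
#' A pair is conserved when its miRNA (through a family-name map) and its
#' target (through a one-to-one homology map) both appear in the other
#' species' pair list with the same direction pattern. The result is
#' symmetric in species order and is exported as a bipartite miRNA-gene
#' edge list in species-A identifiers.
#'
#' @param pairs_a,pairs_b `pairs` tables from [functional_pairs()].
#' @param homology_map One-to-one gene map (`gene_a`, `gene_b`), filtered
#'   through [one_to_one_homologs()] internally.
#' @param mirna_map Data frame mapping miRNA names (`mirna_a`, `mirna_b`);
#'   defaults to the identity on shared names.
#' @return Data frame of conserved pairs (species-A ids) with directions.
#' @export
conserve_pairs <- function(pairs_a, pairs_b, homology_map, mirna_map = NULL) {
  homology_map <- one_to_one_homologs(homology_map)
  if (is.null(mirna_map)) {
    shared <- intersect(pairs_a$mirna, pairs_b$mirna)
    mirna_map <- data.frame(mirna_a = shared, mirna_b = shared,
                            stringsAsFactors = FALSE)
  }
  b_key <- paste(pairs_b$mirna, pairs_b$gene, pairs_b$mirna_direction,
                 pairs_b$gene_direction, sep = "\r")
  ma <- match(pairs_a$mirna, mirna_map$mirna_a)
  ga <- match(pairs_a$gene, homology_map$gene_a)
  ok <- !is.na(ma) & !is.na(ga)
  a_as_b <- paste(mirna_map$mirna_b[ma], homology_map$gene_b[ga],
                  pairs_a$mirna_direction, pairs_a$gene_direction, sep = "\r")
  conserved <- ok & a_as_b %in% b_key
  out <- pairs_a[conserved, c("mirna", "gene", "mirna_direction",
                              "gene_direction"), drop = FALSE]
  rownames(out) <- NULL
  out[order(out$mirna, out$gene), , drop = FALSE]
}
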