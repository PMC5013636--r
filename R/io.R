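## Plain-text readers and writers for the pipeline's interchange formats:
## MAF-like variant TSV, reference FASTA (via Biostrings), genes x samples
## count TSV with a sample-metadata TSV, GMT gene sets, and survival tables.
## Every writer round-trips losslessly through its reader.

#' Write / read a MAF-like variant table
#'
#' Tab-separated, one row per variant, columns `patient, sample,
#' lesion_class, chrom, pos, ref, alt, vaf, gene, cosmic_count`
#' (1-based positions, MAF convention).
#'
#' @param variants Variant data frame.
#' @param path File path.
#' @return `read_maf` returns the variant data frame.
#' @export
write_maf <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_maf
#' @export
read_maf <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_variants(v)
}

#' Write / read a reference FASTA
#'
#' @param reference Named character vector of sequences.
#' @param path File path.
#' @return `read_reference_fasta` returns a named character vector.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write / read a genes x samples count matrix with metadata
#'
#' The count TSV has gene ids in the first column; the metadata TSV has one
#' row per sample.
#'
#' @param counts Matrix with dimnames.
#' @param meta Sample metadata data frame.
#' @param counts_path,meta_path File paths.
#' @return `read_counts` returns `list(counts, meta)`.
#' @export
write_counts <- function(counts, meta, counts_path, meta_path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, meta_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df[[1L]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  list(counts = counts, meta = meta)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional per-set descriptions (default `"na"`).
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) p[-(1:2)])
  names(out) <- vapply(parts, `[[`, character(1), 1L)
  out
}

#' Write / read a survival table
#'
#' Tab-separated with columns `sample`, `time`, `event` and any additional
#' flags (e.g. a mutation-status column used for cohort selection).
#'
#' @param surv Data frame.
#' @param path File path.
#' @return `read_survival` returns the data frame.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival
#' @export
read_survival <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a network edge list (tab-separated, Cytoscape-importable)
#'
#' @param edges Data frame with `from` and `to` columns (plus attributes).
#' @param path File path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
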