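## Canonical 96-class single-base-substitution (SBS) context layout.
## Pyrimidine-centric: every SNV is expressed with the mutated base as C or T,
## reverse-complementing purine-reference calls, and classified by the six
## substitution types x 16 flanking-base combinations.

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

#' The canonical 96 substitution-in-context class labels
#'
#' Labels have the form `"A[C>T]G"`: the 5' flanking base, the pyrimidine
#' substitution, and the 3' flanking base. Order is substitution-major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base, then 3' base, the
#' conventional layout of mutational-signature catalogues.
#'
#' @return Character vector of length 96.
#' @export
sbs96_classes <- function() {
  out <- character(96)
  i <- 1L
  for (sub in SBS_SUBSTITUTIONS) {
    for (p5 in DNA_BASES) {
      for (p3 in DNA_BASES) {
        out[i] <- paste0(p5, "[", sub, "]", p3)
        i <- i + 1L
      }
    }
  }
  out
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## Classify one SNV given its reference trinucleotide context (forward
## strand).  Returns the canonical class label.
classify_sbs96 <- function(ref, alt, context) {
  stopifnot(nchar(context) == 3L)
  if (substr(context, 2L, 2L) != ref) {
    stop("reference base does not match the supplied context: ", context,
         " vs ref ", ref)
  }
  if (ref %in% c("G", "A")) {
    context <- revcomp(context)
    ref <- chartr("GA", "CT", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  paste0(substr(context, 1L, 1L), "[", ref, ">", alt, "]",
         substr(context, 3L, 3L))
}
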