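# Shared in-code fixtures for the suite.

# A variant row with sensible defaults.
vrow <- function(patient = "P1", sample = "S1", lesion_class = "NS",
                 chrom = "chr1", pos, ref, alt, vaf = 0.3, gene = NA,
                 cosmic_count = NA) {
  data.frame(patient = patient, sample = sample, lesion_class = lesion_class,
             chrom = chrom, pos = pos, ref = ref, alt = alt, vaf = vaf,
             gene = gene, cosmic_count = cosmic_count,
             stringsAsFactors = FALSE)
}

vtab <- function(...) do.call(rbind, list(...))

# A tiny deterministic reference: pos i's base cycles A,C,G,T unless given.
make_reference <- function(seq) c(chr1 = seq)

# Random variant sets for property tests on overlap counting.
random_variant_set <- function(sample, patient, lesion_class, n,
                               pos_pool = 1:50) {
  pos <- sample(pos_pool, n)
  vtab_rows <- lapply(pos, function(p)
    vrow(patient = patient, sample = sample, lesion_class = lesion_class,
         pos = p, ref = "C", alt = sample(c("T", "A", "G"), 1)))
  do.call(rbind, vtab_rows)
}

# Independent brute-force overlap: explicit tuple-set intersection.
brute_overlap <- function(va, vb) {
  ta <- unique(mapply(function(c, p, a) paste(c, p, a), va$chrom, va$pos, va$alt))
  tb <- unique(mapply(function(c, p, a) paste(c, p, a), vb$chrom, vb$pos, vb$alt))
  sum(ta %in% tb)
}
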