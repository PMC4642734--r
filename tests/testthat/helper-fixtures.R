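# small fixture builders shared across test files

toy_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

write_fa <- function(genome, path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  path
}

# a random reference window with a centered substitution variant, as
# extract_window would produce it
random_window <- function(len = 400L, chrom = "chr1", pos0 = NULL) {
  seq <- rand_dna(len)
  v <- len %/% 2L
  ref <- substr(seq, v, v)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  variant <- meltamp::parse_variant(paste(chrom, v, ref, alt, sep = ":"))
  genome <- toy_genome(chr1 = seq)
  meltamp::extract_window(genome, variant, flank = len) # clipped to the chrom
}

# a single-chromosome genome whose one variant context supports a unique
# amplicon; returns genome, variant, window
planted_locus <- function(len = 4000L, flank = 400L) {
  seq <- rand_dna(len)
  pos <- len %/% 2L
  ref <- substr(seq, pos, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  variant <- meltamp::parse_variant(paste("chr1", pos, ref, alt, sep = ":"))
  genome <- toy_genome(chr1 = seq)
  list(genome = genome, variant = variant,
       window = meltamp::extract_window(genome, variant, flank = flank))
}

# collect `n` status-ok assay designs from fixture genomes
fixture_ok_assays <- function(n, seed, clamp = meltamp::clamp_spec("automatic"),
                              urea_molar = 0) {
  fx <- meltamp::make_fixture_genome(seed, n_chrom = 4L, chrom_len = 50000L,
                                     n_variants = n, duplication_fraction = 0)
  out <- list()
  for (k in seq_len(nrow(fx$truth))) {
    v <- meltamp::parse_variant(fx$truth$label[k])
    w <- meltamp::extract_window(fx$genome, v, flank = 500L)
    a <- meltamp::build_assay(v, w, clamp = clamp, genome = fx$genome,
                              urea_molar = urea_molar)
    if (a$status == "ok") out[[length(out) + 1L]] <- a
    if (length(out) >= n) break
  }
  out
}
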