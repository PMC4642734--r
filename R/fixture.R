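#' Generate a synthetic genome fixture with planted variants
#'
#' Builds a random genome (seeded, byte-reproducible), plants variants in
#' unique local contexts, and verbatim-duplicates a stated fraction of the
#' variant loci onto another chromosome so that any primer pair designed
#' there amplifies two regions and the pipeline must reject the assay
#' ("No primers found"). A truth table records the expected pipeline status
#' per locus. This is the offline stand-in for a real genome build in tests
#' and worked examples; see the package vignette for what it does and does
#' not emulate.
#'
#' @param seed integer RNG seed.
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param n_variants number of planted variants (substitutions).
#' @param duplication_fraction fraction of loci whose +/- `dup_span` context
#'   is copied onto a different chromosome.
#' @param dup_span half-width of the duplicated context in bp; must exceed
#'   the largest possible amplicon extent so every candidate pair is
#'   non-specific at a duplicated locus.
#' @param out_dir if non-`NULL`, writes `genome.fa` and `truth.tsv` (and a
#'   `variants.txt` input list) there.
#' @return list with `genome` (`DNAStringSet`), `truth` (data.frame:
#'   `label`, `chrom`, `pos`, `ref`, `alt`, `duplicated`,
#'   `expected_status`), and the written `paths` when `out_dir` was given.
#' @export
make_fixture_genome <- function(seed, n_chrom = 4L, chrom_len = 50000L,
                                n_variants = 20L, duplication_fraction = 0,
                                dup_span = 250L, out_dir = NULL) {
  stopifnot(n_chrom >= 2L, chrom_len >= 4L * dup_span,
            duplication_fraction >= 0, duplication_fraction <= 1)
  n_dup <- round(duplication_fraction * n_variants)
  # slots: variant loci plus paste targets for duplicated contexts, all
  # non-overlapping with margins
  slot_w <- 2L * dup_span + 600L
  per_chrom <- (chrom_len - 1000L) %/% slot_w
  total_slots <- per_chrom * n_chrom
  if (total_slots < n_variants + n_dup)
    stop("genome too small for ", n_variants, " variants (+", n_dup,
         " duplication targets); increase chrom_len or n_chrom")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  chroms <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = ""), "")
  names(chroms) <- paste0("chr", seq_len(n_chrom))

  slot_chrom <- rep(seq_len(n_chrom), each = per_chrom)
  slot_center <- rep(500L + slot_w %/% 2L + slot_w * (seq_len(per_chrom) - 1L),
                     times = n_chrom)
  pick <- sample(total_slots, n_variants + n_dup)
  var_slots <- pick[seq_len(n_variants)]
  dup_slots <- if (n_dup > 0) pick[n_variants + seq_len(n_dup)] else integer(0)
  dup_loci <- if (n_dup > 0) sort(sample(n_variants, n_dup)) else integer(0)

  truth <- data.frame(label = character(n_variants), chrom = character(n_variants),
                      pos = integer(n_variants), ref = character(n_variants),
                      alt = character(n_variants),
                      duplicated = logical(n_variants),
                      expected_status = character(n_variants),
                      stringsAsFactors = FALSE)
  for (k in seq_len(n_variants)) {
    ci <- slot_chrom[var_slots[k]]
    pos <- slot_center[var_slots[k]]
    ref <- substr(chroms[ci], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    dup <- k %in% dup_loci
    truth[k, ] <- list(paste0("chr", ci, ":", pos, ":", ref, ":", alt),
                       paste0("chr", ci), pos, ref, alt, dup,
                       if (dup) "no_primers_found" else "ok")
  }
  # paste duplicated contexts onto other chromosomes
  for (j in seq_along(dup_loci)) {
    k <- dup_loci[j]
    src_ci <- slot_chrom[var_slots[k]]
    src_pos <- truth$pos[k]
    ctx <- substr(chroms[src_ci], src_pos - dup_span, src_pos + dup_span)
    # target slot may share the chromosome: slots are far apart, so the copy
    # still yields a second, distinct amplification
    tgt <- dup_slots[j]
    tgt_ci <- slot_chrom[tgt]
    tgt_pos <- slot_center[tgt]
    substr(chroms[tgt_ci], tgt_pos - dup_span, tgt_pos + dup_span) <- ctx
  }

  genome <- Biostrings::DNAStringSet(chroms)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fa")
    tt <- file.path(out_dir, "truth.tsv")
    vl <- file.path(out_dir, "variants.txt")
    Biostrings::writeXStringSet(genome, fa, width = 70L)
    utils::write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(truth$label, vl)
    paths <- list(genome = fa, truth = tt, variants = vl)
  }
  list(genome = genome, truth = truth, paths = paths)
}
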