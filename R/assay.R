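#' Default GC-clamp sequence
#'
#' The GC-rich high-melting-domain sequence shipped by default (43 nt;
#' commonly referred to as a 42-bp clamp -- the published sequence is kept
#' verbatim and is fully user-replaceable via [clamp_spec()]).
#' @export
DEFAULT_CLAMP_SEQ <- "GCGCCCGCCGCGCCCCGCGCCCGTCCCGCCGCCCCCGCCCGGG"

#' GC-clamp specification
#'
#' @param mode clamp placement: `"none"`, `"automatic"` (side of the
#'   amplicon with the highest average melting temperature; indels always
#'   5'), `"five_prime"` or `"three_prime"`.
#' @param seq clamp sequence 5'->3' on the clamped strand.
#' @param label_note free-text assay metadata (e.g. fluorophore label or the
#'   three-primer half-clamp tailing scheme used on the bench); carried
#'   through, never interpreted.
#' @return object of class `clamp_spec`.
#' @export
clamp_spec <- function(mode = c("none", "automatic", "five_prime", "three_prime"),
                       seq = DEFAULT_CLAMP_SEQ, label_note = "") {
  mode <- match.arg(mode)
  .check_dna(seq, "clamp sequence")
  structure(list(mode = mode, seq = seq, label_note = label_note),
            class = "clamp_spec")
}

#' Choose the clamp side from the unclamped melting profile
#'
#' In automatic mode the amplicon is split at `floor(len/2)`; the clamp goes
#' on the 5' side iff the mean per-base Tm of the 5' half exceeds that of
#' the 3' half (ties 5'), so that melting temperature decreases away from
#' the clamp. Amplicons carrying an insertion/deletion always take the clamp
#' at the 5' end. Explicit modes are honored as requested.
#'
#' @param profile_ref [melting_profile()] of the *unclamped* reference
#'   amplicon.
#' @param mode a [clamp_spec()] mode string.
#' @param var_class `"substitution"` or `"indel"`.
#' @return `"5-prime"`, `"3-prime"`, or `"none"`.
#' @export
choose_clamp_side <- function(profile_ref, mode, var_class = "substitution") {
  mode <- match.arg(mode, c("none", "automatic", "five_prime", "three_prime"))
  if (mode == "none") return("none")
  if (mode == "five_prime") return("5-prime")
  if (mode == "three_prime") return("3-prime")
  if (var_class == "indel") return("5-prime")
  stopifnot(inherits(profile_ref, "melting_profile"))
  tm <- profile_ref$tm_per_base
  n <- length(tm)
  half <- floor(n / 2)
  if (mean(tm[seq_len(half)]) >= mean(tm[seq(half + 1L, n)])) "5-prime"
  else "3-prime"
}

#' Attach the GC-clamp to both allele amplicons
#'
#' The clamp sequence is specified 5'->3' on the clamped strand and is
#' appended verbatim on either end (the melting model is strand-symmetric,
#' so sequence-level concatenation captures the thermodynamics regardless of
#' which physical primer carries the clamp).
#'
#' @param amplicon_ref,amplicon_alt unclamped allele amplicons.
#' @param side `"5-prime"`, `"3-prime"` or `"none"`.
#' @param clamp a [clamp_spec()] object.
#' @return list with `ref`, `alt` (clamped sequences) and `clamp_span`
#'   (1-based inclusive interval of the clamp within the *reference*
#'   amplicon, or `NULL` for side `"none"`). For the alternate allele of an
#'   indel the same span applies when the clamp is 5'; a 3' clamp span in
#'   alt coordinates is shifted by the allele length difference.
#' @export
attach_clamp <- function(amplicon_ref, amplicon_alt, side, clamp = clamp_spec()) {
  stopifnot(side %in% c("5-prime", "3-prime", "none"))
  if (side == "none")
    return(list(ref = amplicon_ref, alt = amplicon_alt, clamp_span = NULL,
                clamp_span_alt = NULL))
  cl <- nchar(clamp$seq)
  if (side == "5-prime") {
    list(ref = paste0(clamp$seq, amplicon_ref),
         alt = paste0(clamp$seq, amplicon_alt),
         clamp_span = c(1L, cl), clamp_span_alt = c(1L, cl))
  } else {
    nr <- nchar(amplicon_ref); na <- nchar(amplicon_alt)
    list(ref = paste0(amplicon_ref, clamp$seq),
         alt = paste0(amplicon_alt, clamp$seq),
         clamp_span = c(nr + 1L, nr + cl), clamp_span_alt = c(na + 1L, na + cl))
  }
}

#' Design one complete melting assay for a variant
#'
#' The full pipeline for one variant: primer selection with in-silico PCR
#' specificity ([select_pair()]); on success, both allele amplicons are cut
#' from the window, the clamp side is chosen on the unclamped reference
#' profile, the clamp attached, both clamped profiles computed, and the
#' average melting temperature of the inter-primer target (reference allele;
#' primers and clamp excluded) and the urea-corrected analysis temperature
#' derived.
#'
#' @param variant a [parse_variant()] object.
#' @param window the variant's [extract_window()].
#' @param constraints a [primer_constraints()] object.
#' @param clamp a [clamp_spec()] object.
#' @param model a [default_model()] object.
#' @param genome a [read_genome()] `DNAStringSet`.
#' @param urea_molar urea concentration of the separation matrix, mol/L.
#' @param retry_depth,max_product,max_mismatch passed to [select_pair()].
#' @return object of class `assay_design`; see [results_row()] for the flat
#'   field list. Failed designs carry `status = "no_primers_found"` and a
#'   `reason`.
#' @export
build_assay <- function(variant, window, constraints = primer_constraints(),
                        clamp = clamp_spec(), model = default_model(),
                        genome, urea_molar = 0,
                        retry_depth = 1L, max_product = 4000L,
                        max_mismatch = 0L) {
  stopifnot(inherits(variant, "variant"), inherits(window, "sequence_window"),
            inherits(clamp, "clamp_spec"))
  sel <- select_pair(window, constraints, model, genome,
                     retry_depth = retry_depth, max_product = max_product,
                     max_mismatch = max_mismatch)
  if (sel$status != "ok") {
    return(structure(list(
      variant = variant, pair = NULL, status = "no_primers_found",
      reason = sel$reason, clamp_pos = "none",
      amplicon_ref = NA_character_, amplicon_alt = NA_character_,
      profile_ref = NULL, profile_alt = NULL,
      avg_melt_temp = NA_real_, analysis_temp = NA_real_,
      annealing_tm = NA_real_, urea_molar = urea_molar
    ), class = "assay_design"))
  }
  pair <- sel$pair
  len_diff <- nchar(variant$alt) - nchar(variant$ref)
  amp_ref <- substr(window$ref_seq, pair$fwd_start, pair$rev_end)
  amp_alt <- substr(window$alt_seq, pair$fwd_start, pair$rev_end + len_diff)
  v_local_ref <- window$var_index_ref - pair$fwd_start + 1L
  v_local_alt <- window$var_index_alt - pair$fwd_start + 1L

  prof_unclamped <- melting_profile(amp_ref, model)
  side <- choose_clamp_side(prof_unclamped, clamp$mode, variant$var_class)
  att <- attach_clamp(amp_ref, amp_alt, side, clamp)
  shift_ref <- if (side == "5-prime") nchar(clamp$seq) else 0L
  vi_ref <- v_local_ref + shift_ref +
    seq(0L, max(nchar(variant$ref) - 1L, 0L))
  vi_alt <- v_local_alt + shift_ref + seq(0L, max(nchar(variant$alt) - 1L, 0L))
  profile_ref <- melting_profile(att$ref, model, clamp_span = att$clamp_span,
                                 variant_index = vi_ref)
  profile_alt <- melting_profile(att$alt, model, clamp_span = att$clamp_span_alt,
                                 variant_index = vi_alt)

  # inter-primer target on the clamped reference amplicon
  target <- c(pair$fwd_len + 1L, pair$product_len - pair$rev_len) + shift_ref
  avg_tm <- average_melt_temp(profile_ref, target[1], target[2])
  structure(list(
    variant = variant, pair = pair, status = "ok", reason = NULL,
    clamp_pos = side,
    amplicon_ref = att$ref, amplicon_alt = att$alt,
    profile_ref = profile_ref, profile_alt = profile_alt,
    target_region = target,
    avg_melt_temp = avg_tm,
    analysis_temp = analysis_temperature(avg_tm, urea_molar),
    annealing_tm = pair$annealing_tm, urea_molar = urea_molar
  ), class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Assay for", x$variant$label, "- status:", x$status, "\n")
  if (x$status == "ok") {
    cat(sprintf("  primers %s / %s (annealing %.1f C)\n",
                x$pair$fwd_seq, x$pair$rev_seq, x$annealing_tm))
    cat(sprintf("  clamp: %s; avg target melt %.1f C; analysis %.1f C (%g M urea)\n",
                x$clamp_pos, x$avg_melt_temp, x$analysis_temp, x$urea_molar))
  } else {
    cat("  reason:", x$reason, "\n")
  }
  invisible(x)
}

#' Flatten an assay design into one results-table row
#'
#' Column order is fixed: ID, chrom, pos, ref, alt, status, fwd_primer,
#' rev_primer, product_len_ref, product_len_alt, variant_pos_in_amplicon
#' (1-based, clamped coordinates), annealing_tm, avg_melt_temp,
#' analysis_temp, clamp_pos, amplicon_ref, amplicon_alt. Temperatures are
#' rounded to one decimal; failed designs render the primer fields as
#' "No primers found" and numeric fields as NA.
#'
#' @param assay an [build_assay()] `assay_design`.
#' @return one-row data.frame.
#' @export
results_row <- function(assay) {
  stopifnot(inherits(assay, "assay_design"))
  v <- assay$variant
  ok <- assay$status == "ok"
  data.frame(
    ID = v$label, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    status = assay$status,
    fwd_primer = if (ok) assay$pair$fwd_seq else "No primers found",
    rev_primer = if (ok) assay$pair$rev_seq else "No primers found",
    product_len_ref = if (ok) assay$pair$product_len else NA_integer_,
    product_len_alt = if (ok) assay$pair$product_len_alt else NA_integer_,
    variant_pos_in_amplicon = if (ok) assay$profile_ref$variant_index[1] else NA_integer_,
    annealing_tm = if (ok) round(assay$annealing_tm, 1) else NA_real_,
    avg_melt_temp = if (ok) round(assay$avg_melt_temp, 1) else NA_real_,
    analysis_temp = if (ok) round(assay$analysis_temp, 1) else NA_real_,
    clamp_pos = assay$clamp_pos,
    amplicon_ref = if (ok) assay$amplicon_ref else NA_character_,
    amplicon_alt = if (ok) assay$amplicon_alt else NA_character_,
    stringsAsFactors = FALSE
  )
}
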