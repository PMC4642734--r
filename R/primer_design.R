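#' Primer selection constraints
#'
#' Hard and soft constraints for the exhaustive primer-pair search, in the
#' Primer3 style: primer length and melting-temperature windows with optima,
#' GC-content bounds, product-size interval (defaults follow the 70-140 bp
#' target range of melting-based variant scanning), a cap on 3'-anchored
#' self/cross complementarity, and a minimum distance between each primer's
#' 3' end and the variant.
#'
#' @param size_min,size_opt,size_max primer length bounds and optimum (bp).
#' @param tm_min,tm_opt,tm_max primer Tm bounds and optimum (degrees C).
#' @param gc_min,gc_max GC-fraction bounds (0-1).
#' @param product_min,product_max amplicon length interval (bp), both alleles.
#' @param max_end_self longest allowed 3'-anchored complementary run
#'   (self or cross), bases.
#' @param min_variant_gap minimum distance from either primer's 3' end to
#'   the nearest variant base (bp).
#' @return object of class `primer_constraints`.
#' @export
primer_constraints <- function(size_min = 18L, size_opt = 20L, size_max = 27L,
                               tm_min = 57, tm_opt = 60, tm_max = 63,
                               gc_min = 0.2, gc_max = 0.8,
                               product_min = 70L, product_max = 140L,
                               max_end_self = 4L, min_variant_gap = 5L) {
  pc <- list(size_min = as.integer(size_min), size_opt = as.integer(size_opt),
             size_max = as.integer(size_max),
             tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
             gc_min = gc_min, gc_max = gc_max,
             product_min = as.integer(product_min),
             product_max = as.integer(product_max),
             max_end_self = as.integer(max_end_self),
             min_variant_gap = as.integer(min_variant_gap))
  if (!(pc$size_min <= pc$size_opt && pc$size_opt <= pc$size_max))
    stop("need size_min <= size_opt <= size_max")
  if (!(pc$tm_min <= pc$tm_opt && pc$tm_opt <= pc$tm_max))
    stop("need tm_min <= tm_opt <= tm_max")
  if (!(pc$gc_min >= 0 && pc$gc_max <= 1 && pc$gc_min <= pc$gc_max))
    stop("need 0 <= gc_min <= gc_max <= 1")
  if (pc$product_min < 2L * pc$size_min)
    stop("product_min must be >= 2 * size_min")
  if (pc$product_min > pc$product_max)
    stop("need product_min <= product_max")
  if (pc$min_variant_gap < 0L) stop("min_variant_gap must be >= 0")
  structure(pc, class = "primer_constraints")
}

#' Two-state nearest-neighbor primer melting temperature
#'
#' Tm of a primer/template duplex from the unified nearest-neighbor tables:
#' \deqn{T_m = \Delta H / (\Delta S + R \ln(C_T/4)) - 273.15}
#' with terminal-dependent duplex initiation terms, the monovalent-salt
#' entropy correction per stack, total strand concentration \eqn{C_T} from
#' the model, and the factor 4 for non-self-complementary duplexes.
#'
#' @param seq primer sequence, 10-36 bases over ACGT.
#' @param model a [default_model()] object.
#' @return Tm in degrees C.
#' @examples
#' primer_tm("TGCAAGATTGTACCTTCCTTGGT")
#' @export
primer_tm <- function(seq, model = default_model()) {
  .check_dna(seq, "primer")
  n <- nchar(seq)
  if (n < 10 || n > 36) stop("primer length must be in [10, 36]: got ", n)
  sp <- .step_params(seq, model)
  ini <- .init_params(seq, model)
  dH <- sum(sp$dH) + ini$dH
  dS <- sum(sp$dS) + ini$dS
  dH / (dS + .R_GAS * log(model$strand_molar / 4)) - 273.15
}

.gc_fraction <- function(seqs) {
  nchar(gsub("[^GC]", "", seqs)) / nchar(seqs)
}

# TRUE when the 3'-anchored complementary run of a against b exceeds
# max_end_self, i.e. the reverse complement of a's 3'-terminal
# (max_end_self + 1)-mer occurs anywhere in b.
.end_self_violation <- function(a, b, max_end_self) {
  k <- max_end_self + 1L
  la <- nchar(a)
  pat <- .rc(substr(a, la - k + 1L, la))
  grepl(pat, b, fixed = TRUE)
}

#' Primer-pair penalty
#'
#' The declared selection objective: the sum, over both primers, of the
#' absolute deviations of length from `size_opt` and Tm from `tm_opt`, plus
#' the absolute Tm difference between the two primers. Lower is better;
#' hard-constraint violations are filtered before scoring, not penalized.
#'
#' @param fwd_len,rev_len primer lengths (bp).
#' @param fwd_tm,rev_tm primer melting temperatures (degrees C).
#' @param constraints a [primer_constraints()] object.
#' @return non-negative penalty (vectorized).
#' @export
pair_penalty <- function(fwd_len, rev_len, fwd_tm, rev_tm, constraints) {
  stopifnot(inherits(constraints, "primer_constraints"))
  abs(fwd_len - constraints$size_opt) + abs(rev_len - constraints$size_opt) +
    abs(fwd_tm - constraints$tm_opt) + abs(rev_tm - constraints$tm_opt) +
    abs(fwd_tm - rev_tm)
}

# candidate primers on one side of the variant; returns a data.frame with
# window-local 1-based coordinates, sequence, tm, gc
.candidate_primers <- function(seq, start3_range, lens, side, constraints, model) {
  n <- nchar(seq)
  grid <- expand.grid(p3 = start3_range, len = lens)
  if (side == "fwd") {
    # p3 = 3'-end position on the window; primer occupies [p3-len+1, p3]
    grid$start <- grid$p3 - grid$len + 1L
    grid$end <- grid$p3
  } else {
    # p3 = template position of the primer's 3' end (leftmost base of the
    # reverse-primer binding site); primer occupies [p3, p3+len-1]
    grid$start <- grid$p3
    grid$end <- grid$p3 + grid$len - 1L
  }
  grid <- grid[grid$start >= 1L & grid$end <= n, , drop = FALSE]
  if (!nrow(grid)) return(grid)
  tmpl <- substring(seq, grid$start, grid$end)
  grid$seq <- if (side == "fwd") tmpl else
    vapply(tmpl, .rc, "", USE.NAMES = FALSE)
  grid$gc <- .gc_fraction(grid$seq)
  keep <- grid$gc >= constraints$gc_min & grid$gc <= constraints$gc_max
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(grid)
  grid$tm <- vapply(grid$seq, primer_tm, numeric(1), model = model,
                    USE.NAMES = FALSE)
  grid <- grid[grid$tm >= constraints$tm_min & grid$tm <= constraints$tm_max, ,
               drop = FALSE]
  if (!nrow(grid)) return(grid)
  selfbad <- mapply(.end_self_violation, grid$seq, grid$seq,
                    MoreArgs = list(max_end_self = constraints$max_end_self))
  grid[!selfbad, , drop = FALSE]
}

#' Enumerate all feasible primer pairs for a variant window
#'
#' Exhaustively enumerates forward/reverse primer combinations on the
#' reference window that satisfy every hard constraint -- primer length, Tm
#' and GC bounds, 3' self/cross complementarity, product-size bounds for
#' both alleles, primers clear of the variant by `min_variant_gap` -- scores
#' them with [pair_penalty()], and returns them sorted by ascending penalty
#' with deterministic tie-breaking (shorter product, smaller forward start,
#' lexicographic forward sequence).
#'
#' @param window an [extract_window()] object.
#' @param constraints a [primer_constraints()] object.
#' @param model a [default_model()] object.
#' @return data.frame, one row per feasible pair: `fwd_seq`, `rev_seq`,
#'   `fwd_start`, `fwd_len`, `rev_end`, `rev_len`, `product_len`,
#'   `product_len_alt`, `fwd_tm`, `rev_tm`, `annealing_tm`
#'   (= min of the two), `penalty`. Coordinates are window-local, 1-based
#'   inclusive; the product spans `[fwd_start, rev_end]`. Zero rows when no
#'   pair is feasible.
#' @export
enumerate_pairs <- function(window, constraints = primer_constraints(),
                            model = default_model()) {
  stopifnot(inherits(window, "sequence_window"),
            inherits(constraints, "primer_constraints"))
  seq <- window$ref_seq
  v <- window$var_index_ref
  v_end <- v + nchar(window$variant$ref) - 1L
  gap <- constraints$min_variant_gap
  lens <- seq(constraints$size_min, constraints$size_max)
  len_diff <- nchar(window$variant$alt) - nchar(window$variant$ref)

  # each primer's 3' end keeps >= min_variant_gap bases strictly between
  # itself and the nearest variant base
  f3_lo <- max(1L, v - constraints$product_max)
  f3_hi <- v - gap - 1L
  r3_lo <- v_end + gap + 1L
  r3_hi <- min(nchar(seq), v_end + constraints$product_max)
  if (f3_hi < f3_lo || r3_hi < r3_lo) return(.empty_pairs())
  fwd <- .candidate_primers(seq, seq(f3_lo, f3_hi), lens, "fwd", constraints, model)
  rev <- .candidate_primers(seq, seq(r3_lo, r3_hi), lens, "rev", constraints, model)
  if (!nrow(fwd) || !nrow(rev)) return(.empty_pairs())

  # pair up under the product-length bounds (both alleles)
  rev <- rev[order(rev$end), , drop = FALSE]
  rev_end <- rev$end
  pair_f <- integer(0); pair_r <- integer(0)
  for (i in seq_len(nrow(fwd))) {
    lo <- fwd$start[i] + max(constraints$product_min,
                             constraints$product_min - len_diff) - 1L
    hi <- fwd$start[i] + min(constraints$product_max,
                             constraints$product_max - len_diff) - 1L
    j <- which(rev_end >= lo & rev_end <= hi)
    if (length(j)) {
      pair_f <- c(pair_f, rep.int(i, length(j)))
      pair_r <- c(pair_r, j)
    }
  }
  if (!length(pair_f)) return(.empty_pairs())

  pairs <- data.frame(
    fwd_seq = fwd$seq[pair_f], rev_seq = rev$seq[pair_r],
    fwd_start = fwd$start[pair_f], fwd_len = fwd$len[pair_f],
    rev_end = rev$end[pair_r], rev_len = rev$len[pair_r],
    fwd_tm = fwd$tm[pair_f], rev_tm = rev$tm[pair_r],
    stringsAsFactors = FALSE
  )
  pairs$product_len <- pairs$rev_end - pairs$fwd_start + 1L
  pairs$product_len_alt <- pairs$product_len + len_diff

  # 3' cross-complementarity, grouped by unique pattern for speed
  bad <- logical(nrow(pairs))
  for (fs in unique(pairs$fwd_seq)) {
    idx <- which(pairs$fwd_seq == fs)
    bad[idx] <- bad[idx] | .end_self_violation(fs, pairs$rev_seq[idx],
                                               constraints$max_end_self)
  }
  for (rs in unique(pairs$rev_seq)) {
    idx <- which(pairs$rev_seq == rs)
    bad[idx] <- bad[idx] | .end_self_violation(rs, pairs$fwd_seq[idx],
                                               constraints$max_end_self)
  }
  pairs <- pairs[!bad, , drop = FALSE]
  if (!nrow(pairs)) return(.empty_pairs())

  pairs$annealing_tm <- pmin(pairs$fwd_tm, pairs$rev_tm)
  pairs$penalty <- pair_penalty(pairs$fwd_len, pairs$rev_len,
                                pairs$fwd_tm, pairs$rev_tm, constraints)
  ord <- order(pairs$penalty, pairs$product_len, pairs$fwd_start,
               pairs$fwd_seq, method = "radix")
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs[, c("fwd_seq", "rev_seq", "fwd_start", "fwd_len", "rev_end", "rev_len",
            "product_len", "product_len_alt", "fwd_tm", "rev_tm",
            "annealing_tm", "penalty")]
}

.empty_pairs <- function() {
  data.frame(fwd_seq = character(0), rev_seq = character(0),
             fwd_start = integer(0), fwd_len = integer(0),
             rev_end = integer(0), rev_len = integer(0),
             product_len = integer(0), product_len_alt = integer(0),
             fwd_tm = numeric(0), rev_tm = numeric(0),
             annealing_tm = numeric(0), penalty = numeric(0),
             stringsAsFactors = FALSE)
}

#' Select the primer pair for a variant, enforcing genome specificity
#'
#' Walks the penalty-ranked pair list from [enumerate_pairs()] and runs each
#' candidate through [insilico_pcr()] against the whole genome; the first
#' pair amplifying exactly one genomic region is accepted. By default only
#' the top candidate is tried (`retry_depth = 1`): a non-specific top pair
#' rejects the assay ("No primers found") rather than silently falling back.
#'
#' @param window an [extract_window()] object.
#' @param constraints a [primer_constraints()] object.
#' @param model a [default_model()] object.
#' @param genome a [read_genome()] `DNAStringSet`.
#' @param retry_depth how many ranked candidates to try before giving up.
#' @param max_product in-silico PCR product-size cap (bp).
#' @param max_mismatch allowed mismatches per primer site in the specificity
#'   scan (3'-terminal base must always match).
#' @return list with `status` (`"ok"` or `"no_primers_found"`), `pair`
#'   (one-row data.frame or `NULL`), `products` (the in-silico PCR products
#'   of the accepted pair), `reason` (`NULL`, `"no_feasible_primers"`, or
#'   `"not_specific"`), and `tried` (number of candidates tested).
#' @export
select_pair <- function(window, constraints = primer_constraints(),
                        model = default_model(), genome,
                        retry_depth = 1L, max_product = 4000L,
                        max_mismatch = 0L) {
  pairs <- enumerate_pairs(window, constraints, model)
  if (!nrow(pairs))
    return(list(status = "no_primers_found", pair = NULL, products = NULL,
                reason = "no_feasible_primers", tried = 0L))
  depth <- min(as.integer(retry_depth), nrow(pairs))
  for (i in seq_len(depth)) {
    prods <- insilico_pcr(genome, pairs$fwd_seq[i], pairs$rev_seq[i],
                          max_product = max_product, max_mismatch = max_mismatch)
    if (specificity(prods) == "unique")
      return(list(status = "ok", pair = pairs[i, , drop = FALSE],
                  products = prods, reason = NULL, tried = i))
  }
  list(status = "no_primers_found", pair = NULL, products = NULL,
       reason = "not_specific", tried = depth)
}
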