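#' Per-base closing probabilities of a DNA duplex
#'
#' Computes the equilibrium probability that each base pair of a duplex is
#' closed (helical) at a given temperature under a Poland-Scheraga model:
#' configurations are alternating helical and denatured (loop) runs, with
#' nearest-neighbor stacking weights for adjacent closed pairs, a
#' cooperativity-weighted power-law entropy penalty \eqn{\sigma (L+d)^{-c}}
#' for each internal loop of length L, free terminal open runs, and one
#' duplex-association weight per molecule (carrying the initiation terms and
#' the strand concentration). The partition sums are evaluated by
#' forward/backward recursions with the long-range loop term accelerated by
#' the model's Fixman-Freire sum-of-exponentials fit.
#'
#' @param seq DNA sequence (string over ACGT, length >= 2).
#' @param temp_c temperature(s) in degrees Celsius.
#' @param model a [default_model()] object.
#' @return for a single temperature, a numeric vector of `nchar(seq)`
#'   probabilities in \[0, 1\]; for a temperature vector, an
#'   `nchar(seq) x length(temp_c)` matrix (one column per temperature).
#' @examples
#' m <- default_model()
#' closing_probabilities("ACGTACGTACGT", 70, m)
#' @export
closing_probabilities <- function(seq, temp_c, model = default_model()) {
  stopifnot(is.numeric(temp_c), length(temp_c) >= 1)
  prep <- .ps_prepare(seq, model)
  P <- .ps_eval(prep, temp_c, model)
  if (length(temp_c) == 1L) as.vector(P) else P
}

# precompute the sequence-dependent thermodynamic inputs once
.ps_prepare <- function(seq, model) {
  .check_dna(seq, "seq")
  if (nchar(seq) < 2) stop("seq must have length >= 2")
  stopifnot(inherits(model, "thermo_model"))
  sp <- .step_params(seq, model)
  ini <- .init_params(seq, model)
  list(dH = sp$dH, dS = sp$dS, init_dH = ini$dH, init_dS = ini$dS,
       n = nchar(seq))
}

.ps_eval <- function(prep, temp_c, model) {
  ps_closed_cpp(prep$dH, prep$dS, temp_c + 273.15, model$sigma,
                model$ff_a, model$ff_b, prep$init_dH, prep$init_dS,
                log(model$strand_molar / 4))
}

#' Per-base melting profile of an amplicon
#'
#' For every base, finds the temperature at which its closing probability
#' crosses 0.5 (the per-base melting temperature Tm). A coarse 1 degree scan
#' over the bracket locates the lowest crossing for each base (multiple
#' crossings are resolved to the lowest and flagged), then bisection refines
#' each crossing to `tol`. The bracket auto-widens (down to -100, up to
#' 250 degrees C) when it does not contain the crossing; a base whose
#' crossing cannot be bracketed even then gets an `NA` sentinel with a
#' warning.
#'
#' @param seq DNA sequence (ACGT, length >= 2).
#' @param model a [default_model()] object.
#' @param t_lo,t_hi initial temperature bracket in degrees C.
#' @param tol bisection tolerance in degrees C.
#' @param clamp_span optional length-2 integer vector, 1-based inclusive
#'   interval of a GC-clamp within `seq` (annotation only).
#' @param variant_index optional 1-based position(s) of the variant base(s)
#'   within `seq` (annotation only).
#' @return object of class `melting_profile`: list with `seq`,
#'   `tm_per_base` (degrees C, `NA` where no crossing exists),
#'   `clamp_span`, `variant_index`, `grid` (the bracket actually used) and
#'   `multiple_crossings` (logical).
#' @examples
#' m <- default_model()
#' p <- melting_profile(strrep("ACGT", 20), m)
#' range(p$tm_per_base)
#' @export
melting_profile <- function(seq, model = default_model(), t_lo = 0, t_hi = 120,
                            tol = 0.01, clamp_span = NULL, variant_index = NULL) {
  .check_dna(seq, "seq")
  n <- nchar(seq)
  if (n < 2) stop("seq must have length >= 2")
  if (t_lo >= t_hi) stop("t_lo must be < t_hi")
  if (!is.null(clamp_span)) {
    stopifnot(length(clamp_span) == 2, clamp_span[1] >= 1, clamp_span[2] <= n,
              clamp_span[1] <= clamp_span[2])
  }

  prep <- .ps_prepare(seq, model)
  pc <- function(tc) .ps_eval(prep, tc, model)

  # widen the bracket until it straddles p = 0.5 for every base (or give up)
  lo_lim <- -100; hi_lim <- 250
  while (any(pc(t_lo) < 0.5) && t_lo > lo_lim) t_lo <- max(lo_lim, t_lo - 20)
  while (any(pc(t_hi) >= 0.5) && t_hi < hi_lim) t_hi <- min(hi_lim, t_hi + 20)

  grid <- seq(t_lo, t_hi, by = 1)
  if (grid[length(grid)] < t_hi) grid <- c(grid, t_hi)
  P <- pc(grid) # n x length(grid)
  closed <- P >= 0.5

  tm <- rep(NA_real_, n)
  multi <- FALSE
  lo_i <- rep(NA_integer_, n) # grid interval holding the lowest crossing
  for (i in seq_len(n)) {
    cr <- which(closed[i, -length(grid)] & !closed[i, -1])
    if (length(cr) == 0) next
    if (length(cr) > 1) multi <- TRUE
    lo_i[i] <- cr[1]
  }
  if (multi)
    message("melting_profile: multiple 0.5-crossings detected; using the lowest")
  if (anyNA(lo_i))
    warning("melting_profile: no 0.5-crossing for ", sum(is.na(lo_i)),
            " base(s) within [", t_lo, ", ", t_hi, "] C; NA returned")

  # bisection, batched over bases sharing a probe temperature
  lo <- grid[lo_i]
  hi <- grid[lo_i + 1L]
  active <- which(!is.na(lo_i))
  while (length(active)) {
    width <- hi[active] - lo[active]
    active <- active[width > tol]
    if (!length(active)) break
    mids <- (lo[active] + hi[active]) / 2
    umids <- unique(mids)
    Pm <- pc(umids) # n x length(umids)
    for (k in seq_along(umids)) {
      idx <- active[mids == umids[k]]
      up <- Pm[idx, k] >= 0.5
      lo[idx[up]] <- umids[k]
      hi[idx[!up]] <- umids[k]
    }
  }
  tm <- (lo + hi) / 2

  structure(list(seq = seq, tm_per_base = tm, clamp_span = clamp_span,
                 variant_index = variant_index, grid = c(t_lo, t_hi),
                 multiple_crossings = multi),
            class = "melting_profile")
}

#' @export
print.melting_profile <- function(x, ...) {
  cat(sprintf("Melting profile, %d bp; Tm range %.1f-%.1f C\n",
              nchar(x$seq), min(x$tm_per_base, na.rm = TRUE),
              max(x$tm_per_base, na.rm = TRUE)))
  if (!is.null(x$clamp_span))
    cat(sprintf("  clamp at bases %d-%d\n", x$clamp_span[1], x$clamp_span[2]))
  if (!is.null(x$variant_index))
    cat(sprintf("  variant at base %s\n", paste(x$variant_index, collapse = ",")))
  invisible(x)
}

#' Average melting temperature over a target region
#'
#' Arithmetic mean of the per-base melting temperatures over a 1-based
#' inclusive region, conventionally the inter-primer target (primers and any
#' clamp excluded; the caller supplies the interval).
#'
#' @param profile a [melting_profile()] object.
#' @param region_start,region_end 1-based inclusive bounds of the region.
#' @return mean Tm in degrees C.
#' @export
average_melt_temp <- function(profile, region_start, region_end) {
  stopifnot(inherits(profile, "melting_profile"))
  n <- length(profile$tm_per_base)
  if (region_start < 1 || region_end > n || region_start > region_end)
    stop("empty or out-of-bounds region [", region_start, ", ", region_end, "]")
  mean(profile$tm_per_base[region_start:region_end])
}

#' Urea-corrected analysis temperature
#'
#' Capillary-electrophoresis analysis temperature for a denaturing polymer
#' containing urea: the target's average melting temperature lowered by
#' 3 degrees C per molar urea.
#'
#' @param avg_tm average melting temperature of the target, degrees C.
#' @param urea_molar urea concentration in the matrix, mol/L (>= 0).
#' @return analysis temperature in degrees C.
#' @examples
#' analysis_temperature(75, 1) # 72
#' @export
analysis_temperature <- function(avg_tm, urea_molar) {
  stopifnot(is.numeric(avg_tm), is.numeric(urea_molar))
  if (any(urea_molar < 0)) stop("urea_molar must be >= 0")
  avg_tm - 3.0 * urea_molar
}

#' Helicity curve of an amplicon
#'
#' Fraction of closed base pairs (mean closing probability, theta) as a
#' function of temperature -- the predicted analogue of the dissociation
#' signal recorded in a high-resolution melting experiment.
#'
#' @param seq DNA sequence (ACGT, length >= 2).
#' @param model a [default_model()] object.
#' @param t_grid ascending temperatures in degrees C.
#' @return data.frame with columns `temp_c` and `theta`.
#' @export
helicity_curve <- function(seq, model = default_model(),
                           t_grid = seq(60, 100, by = 0.5)) {
  if (length(t_grid) == 0) stop("t_grid is empty")
  if (is.unsorted(t_grid, strictly = FALSE)) stop("t_grid must be ascending")
  prep <- .ps_prepare(seq, model)
  P <- .ps_eval(prep, t_grid, model)
  theta <- vapply(seq_along(t_grid), function(k) mean(P[, k]), numeric(1))
  data.frame(temp_c = t_grid, theta = theta)
}

#' Write paired ref/alt melting profiles as TSV
#'
#' Emits the data behind a melting-profile chart: one row per base of the
#' (clamped) amplicon with per-base Tm for both alleles, clamp and variant
#' flags. For indels the two alleles differ in length; rows beyond the
#' shorter allele carry `NA` for that allele.
#'
#' @param profile_ref,profile_alt [melting_profile()] objects for the
#'   reference and alternate allele amplicons.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_profile_tsv <- function(profile_ref, profile_alt, path) {
  stopifnot(inherits(profile_ref, "melting_profile"),
            inherits(profile_alt, "melting_profile"))
  n <- max(nchar(profile_ref$seq), nchar(profile_alt$seq))
  pad <- function(x, n) c(x, rep(NA, n - length(x)))
  span_flag <- function(span) {
    f <- rep(0L, n)
    if (!is.null(span)) f[seq(span[1], span[2])] <- 1L
    f
  }
  df <- data.frame(
    position = seq_len(n),
    base_ref = pad(strsplit(profile_ref$seq, "")[[1]], n),
    tm_ref = pad(round(profile_ref$tm_per_base, 3), n),
    base_alt = pad(strsplit(profile_alt$seq, "")[[1]], n),
    tm_alt = pad(round(profile_alt$tm_per_base, 3), n),
    is_clamp = span_flag(profile_ref$clamp_span),
    is_variant = span_flag(
      if (is.null(profile_ref$variant_index)) NULL
      else range(profile_ref$variant_index))
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# convention: 1-based position", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
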