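#' @useDynLib meltamp, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), 1 M NaCl reference state.
.nn_dH <- c(
  AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
  CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0
)
.nn_dS <- c(
  AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
  CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9
)
# duplex initiation, per terminal base pair
.init_dH <- c(GC = 0.1, AT = 2.3)
.init_dS <- c(GC = -2.8, AT = 4.1)

.R_GAS <- 1.987 # cal/(mol K)

# map all 16 dinucleotide steps onto the 10 unique ones (reverse-complement
# symmetry of a Watson-Crick duplex)
.step_key <- local({
  steps <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  rc2 <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  vapply(steps, function(s) if (s %in% names(.nn_dH)) s else rc2(s), "",
         USE.NAMES = TRUE)
})

#' Build the thermodynamic model for melting calculations
#'
#' Assembles the parameter set used by both the statistical-mechanical
#' melting model ([closing_probabilities()], [melting_profile()]) and the
#' two-state primer melting temperature ([primer_tm()]): SantaLucia unified
#' nearest-neighbor stacking enthalpies/entropies with a monovalent-salt
#' entropy correction, Poland-Scheraga loop-entropy parameters, and a
#' Fixman-Freire sum-of-exponentials approximation of the loop weight
#' \eqn{g(L) = (L+d)^{-c}} that is fitted at build time and asserted to stay
#' within 1\% relative error over \eqn{L \in [1, 10^4]}.
#'
#' @param overrides named list of parameter overrides. Recognized names:
#'   `sigma` (loop cooperativity, dimensionless, in (0,1)), `loop_c`
#'   (loop-closure exponent, > 1), `loop_d` (offset in the loop weight),
#'   `na_molar` (monovalent cation concentration, mol/L, > 0),
#'   `strand_molar` (total strand concentration, mol/L, > 0),
#'   `ff_exponentials` (number of exponentials in the Fixman-Freire fit,
#'   >= 1), `ff_max_len` (largest loop length covered by the fit).
#' @return an object of class `thermo_model`: a list with the fields above
#'   plus the nearest-neighbor tables (`nn_dH`, `nn_dS`, `init_dH`,
#'   `init_dS`), the fitted Fixman-Freire amplitudes `ff_a` and decay rates
#'   `ff_b`, and `ff_max_rel_err`, the measured relative fit error.
#' @examples
#' m <- default_model()
#' m$sigma
#' m2 <- default_model(list(na_molar = 0.1))
#' @export
default_model <- function(overrides = list()) {
  par <- list(
    sigma = 1.26e-4,
    loop_c = 2.15,
    loop_d = 1,
    na_molar = 0.05,
    strand_molar = 5e-8,
    ff_exponentials = 14L,
    ff_max_len = 1e4
  )
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named list")
    unknown <- setdiff(names(overrides), names(par))
    if (length(unknown))
      stop("unknown thermodynamic parameter(s): ", paste(unknown, collapse = ", "))
    par[names(overrides)] <- overrides
  }
  if (!(par$sigma > 0 && par$sigma < 1))
    stop("sigma must lie in (0, 1)")
  if (par$loop_c <= 1) stop("loop exponent c must be > 1")
  if (par$loop_d < 0) stop("loop offset d must be >= 0")
  if (par$na_molar <= 0) stop("na_molar must be > 0")
  if (par$strand_molar <= 0) stop("strand_molar must be > 0")
  par$ff_exponentials <- as.integer(par$ff_exponentials)
  if (par$ff_exponentials < 1L) stop("ff_exponentials must be >= 1")

  ff <- .fit_fixman_freire(par$loop_c, par$loop_d, par$ff_exponentials,
                           par$ff_max_len)
  if (par$ff_exponentials >= 10L && ff$max_rel_err > 0.01)
    stop(sprintf(
      "Fixman-Freire fit residual %.3g exceeds 1%% over L in [1, %g]",
      ff$max_rel_err, par$ff_max_len))

  model <- c(par, list(
    nn_dH = .nn_dH, nn_dS = .nn_dS,
    init_dH = .init_dH, init_dS = .init_dS,
    ff_a = ff$a, ff_b = ff$b, ff_max_rel_err = ff$max_rel_err
  ))
  class(model) <- "thermo_model"
  model
}

# Fit g(L) = (L+d)^(-c) by a sum of K exponentials; amplitudes by
# relative-error-weighted linear least squares, decay rates log-spaced over
# the loop-length scales.
.fit_fixman_freire <- function(c_exp, d, K, Lmax) {
  L <- seq_len(Lmax)
  g <- (L + d)^(-c_exp)
  Lk <- 10^seq(-0.5, log10(Lmax), length.out = K)
  b <- 1 / Lk
  A <- exp(-outer(L, b))
  w <- 1 / g
  fit <- stats::lm.fit(A * w, g * w)
  a <- unname(fit$coefficients)
  a[is.na(a)] <- 0
  gff <- as.vector(A %*% a)
  list(a = a, b = b, max_rel_err = max(abs(gff / g - 1)))
}

#' @export
print.thermo_model <- function(x, ...) {
  cat("Thermodynamic melting model\n")
  cat(sprintf("  sigma = %g, loop exponent c = %g, loop offset d = %g\n",
              x$sigma, x$loop_c, x$loop_d))
  cat(sprintf("  [Na+] = %g M, strand conc = %g M\n", x$na_molar, x$strand_molar))
  cat(sprintf("  Fixman-Freire: %d exponentials, max rel. error %.2e over L <= %g\n",
              x$ff_exponentials, x$ff_max_rel_err, x$ff_max_len))
  invisible(x)
}

# loop statistical weight sigma * g(L) as the model actually uses it
# (the Fixman-Freire sum of exponentials, not the raw power law)
.loop_weight <- function(model, L) {
  model$sigma * as.vector(exp(-outer(L, model$ff_b)) %*% model$ff_a)
}

# per-step dH (cal/mol) and salt-corrected dS (cal/mol/K) for a sequence
.step_params <- function(seq, model) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  steps <- paste0(b[-n], b[-1])
  key <- .step_key[steps]
  list(
    dH = unname(model$nn_dH[key]) * 1000,
    dS = unname(model$nn_dS[key]) + 0.368 * log(model$na_molar)
  )
}

# terminal-dependent duplex initiation terms for a sequence (cal units)
.init_params <- function(seq, model) {
  b <- strsplit(seq, "")[[1]]
  cls <- ifelse(b[c(1, length(b))] %in% c("G", "C"), "GC", "AT")
  list(
    dH = sum(model$init_dH[cls]) * 1000,
    dS = sum(model$init_dS[cls])
  )
}

# log of the duplex-association weight beta(T): one per associated molecule.
# Includes the initiation terms of the duplex's terminal base pairs and the
# translational entropy of bimolecular association, ln(C_T/4) for
# non-self-complementary strands.
.log_beta <- function(seq, tK, model) {
  ini <- .init_params(seq, model)
  -(ini$dH - tK * ini$dS) / (.R_GAS * tK) + log(model$strand_molar / 4)
}

.check_dna <- function(seq, what = "sequence", allow_n = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string")
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, seq))
    stop(what, " contains characters outside ",
         if (allow_n) "ACGTN" else "ACGT", ": ", seq)
  invisible(seq)
}
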