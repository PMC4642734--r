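# Independent oracles. These deliberately avoid the package's recursion /
# scanning code paths: the melting oracle enumerates all 2^n open/closed
# configurations, the in-silico PCR oracle does a naive full sliding-window
# scan, and the primer-Tm oracle carries its own copy of the unified
# nearest-neighbor tables.

MODEL <- meltamp::default_model()

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# ---- Poland-Scheraga enumeration oracle -----------------------------------

# per-n pattern tables, cached: bit matrix, stack mask, internal-loop lengths
.ps_tables_cache <- new.env(parent = emptyenv())

ps_pattern_tables <- function(n) {
  key <- as.character(n)
  if (!is.null(.ps_tables_cache[[key]])) return(.ps_tables_cache[[key]])
  npat <- 2L^n
  bits <- matrix(0L, npat, n)
  for (i in seq_len(n))
    bits[, i] <- as.integer(bitwAnd(seq_len(npat) - 1L, bitwShiftL(1L, i - 1L)) > 0L)
  stacks <- (bits[, -n, drop = FALSE] * bits[, -1, drop = FALSE])
  loops <- vector("list", npat)
  for (p in seq_len(npat)) {
    r <- rle(bits[p, ])
    internal <- r$values == 0L
    if (length(internal) >= 1) internal[1] <- FALSE
    if (length(internal) >= 1) internal[length(internal)] <- FALSE
    loops[[p]] <- r$lengths[internal & r$values == 0L]
  }
  tab <- list(bits = bits, stacks = stacks, loops = loops)
  .ps_tables_cache[[key]] <- tab
  tab
}

# closing probabilities by exhaustive configuration enumeration, using the
# same statistical weight rules as the model (including its sum-of-
# exponentials loop function and association weight)
ps_enum_p <- function(seq, temp_c, model = MODEL) {
  n <- nchar(seq)
  tK <- temp_c + 273.15
  b <- strsplit(seq, "")[[1]]
  steps <- paste0(b[-n], b[-1])
  key <- vapply(steps, function(s) {
    if (s %in% names(model$nn_dH)) s
    else chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "")
  dH <- unname(model$nn_dH[key]) * 1000
  dS <- unname(model$nn_dS[key]) + 0.368 * log(model$na_molar)
  logw <- -(dH - tK * dS) / (1.987 * tK)
  gff <- function(L) vapply(L, function(l) sum(model$ff_a * exp(-model$ff_b * l)),
                            numeric(1))
  ends <- b[c(1, n)]
  cls <- ifelse(ends %in% c("G", "C"), "GC", "AT")
  idH <- sum(model$init_dH[cls]) * 1000
  idS <- sum(model$init_dS[cls])
  log_beta <- -(idH - tK * idS) / (1.987 * tK) + log(model$strand_molar / 4)

  tab <- ps_pattern_tables(n)
  loop_lw <- vapply(tab$loops, function(L)
    if (length(L)) sum(log(model$sigma * gff(L))) else 0, numeric(1))
  logW <- as.vector(tab$stacks %*% logw) + loop_lw + log_beta
  logW[1] <- -Inf                      # all-open handled as dissociated state
  m <- max(logW, 0)                    # 0 is the log-weight of dissociation
  W <- exp(logW - m)
  Z <- exp(0 - m) + sum(W)
  S <- as.vector(t(tab$bits) %*% W)
  S / Z
}

# ---- naive in-silico PCR oracle -------------------------------------------

# genome as list of character vectors (one per chromosome), built once
naive_genome_chars <- function(genome) {
  lapply(seq_along(genome), function(i) strsplit(as.character(genome[[i]]), "")[[1]])
}

rc_chars <- function(chars) rev(chartr("ACGTN", "TGCAN", chars))

# all sites of a primer on one chromosome: full O(N*L) scan, both strands,
# 3'-terminal base must match
naive_sites_chrom <- function(gch, primer, max_mismatch) {
  pch <- strsplit(primer, "")[[1]]
  L <- length(pch)
  N <- length(gch)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pch else rc_chars(pch)
    if (N < L) next
    mm <- integer(N - L + 1L)
    for (l in seq_len(L))
      mm <- mm + (gch[l:(N - L + l)] != pat[l])
    i3 <- if (strand == "+") L else 1L
    ok3 <- gch[i3:(N - L + i3)] == pat[i3]
    hit <- which(mm <= max_mismatch & ok3)
    if (length(hit))
      out[[strand]] <- data.frame(start = hit, end = hit + L - 1L,
                                  strand = strand, mismatches = mm[hit],
                                  stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

naive_find_sites <- function(genome, primer, max_mismatch = 0L,
                             gchars = naive_genome_chars(genome)) {
  out <- list()
  for (i in seq_along(genome)) {
    s <- naive_sites_chrom(gchars[[i]], primer, max_mismatch)
    if (!is.null(s)) {
      s$chrom <- names(genome)[i]
      out[[length(out) + 1L]] <- s[, c("chrom", "start", "end", "strand", "mismatches")]
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand, method = "radix"), ]
  rownames(res) <- NULL
  res
}

# all-pairs product oracle: plus-strand site of one primer with a downstream
# minus-strand site of the other, same chromosome, within max_product and at
# least as long as the longest primer
naive_pcr <- function(genome, fwd, rev, max_product = 4000L, max_mismatch = 0L,
                      gchars = naive_genome_chars(genome)) {
  sf <- naive_find_sites(genome, fwd, max_mismatch, gchars)
  sr <- naive_find_sites(genome, rev, max_mismatch, gchars)
  min_len <- max(nchar(fwd), nchar(rev))
  prods <- list()
  combos <- list(list(sf, sr), list(sr, sf))
  for (cmb in combos) {
    a <- cmb[[1]]; b <- cmb[[2]]
    ap <- a[a$strand == "+", , drop = FALSE]
    bm <- b[b$strand == "-", , drop = FALSE]
    if (!nrow(ap) || !nrow(bm)) next
    for (i in seq_len(nrow(ap))) for (j in seq_len(nrow(bm))) {
      if (ap$chrom[i] != bm$chrom[j]) next
      len <- bm$end[j] - ap$start[i] + 1L
      if (ap$start[i] <= bm$start[j] && ap$end[i] <= bm$end[j] &&
          len >= min_len && len <= max_product)
        prods[[length(prods) + 1L]] <- c(ap$chrom[i], ap$start[i], bm$end[j])
    }
  }
  if (!length(prods))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  df <- unique(data.frame(chrom = vapply(prods, `[`, "", 1),
                          start = as.integer(vapply(prods, `[`, "", 2)),
                          end = as.integer(vapply(prods, `[`, "", 3)),
                          stringsAsFactors = FALSE))
  df <- df[order(df$chrom, df$start, df$end, method = "radix"), ]
  rownames(df) <- NULL
  df
}

# ---- nearest-neighbor primer Tm oracle ------------------------------------

# independent copy of the unified tables (kcal/mol; cal/mol/K)
nn_tm_oracle <- function(seq, na_molar, strand_molar) {
  H <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
         GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
         CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  S <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
         GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
         CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  steps <- paste0(b[-n], b[-1])
  dH <- sum(H[steps]) * 1000
  dS <- sum(S[steps]) + 0.368 * (n - 1) * log(na_molar)
  for (e in b[c(1, n)]) {
    if (e %in% c("G", "C")) { dH <- dH + 100;  dS <- dS - 2.8 }
    else                    { dH <- dH + 2300; dS <- dS + 4.1 }
  }
  dH / (dS + 1.987 * log(strand_molar / 4)) - 273.15
}

# ---- character-map reverse-complement oracle ------------------------------

rc_oracle <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}
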