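#' Find all binding sites of a primer in a genome
#'
#' Scans both strands of every chromosome for occurrences of the primer with
#' at most `max_mismatch` mismatches. The primer's 3'-terminal base must
#' always match (a 3' mismatch blocks polymerase extension), so mismatches
#' are only tolerated elsewhere. Matching is delegated to
#' [Biostrings::vmatchPattern()]; the contract is the naive full-scan result
#' set.
#'
#' @param genome a [read_genome()] `DNAStringSet`.
#' @param primer primer sequence 5'->3' (ACGT, >= 12 bases).
#' @param max_mismatch allowed mismatches per site (default 0).
#' @return data.frame sorted by (chrom, start): columns `chrom`, `start`,
#'   `end` (1-based inclusive site coordinates on the plus strand), `strand`
#'   (`"+"` when the primer matches the plus strand, `"-"` when it matches
#'   the minus strand) and `mismatches`.
#' @export
find_sites <- function(genome, primer, max_mismatch = 0L) {
  .check_dna(primer, "primer")
  if (nchar(primer) < 12) stop("primer too short (< 12 bases): ", primer)
  max_mismatch <- as.integer(max_mismatch)
  res <- rbind(
    .scan_strand(genome, primer, "+", max_mismatch),
    .scan_strand(genome, primer, "-", max_mismatch)
  )
  res <- res[order(res$chrom, res$start, res$strand, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

.scan_strand <- function(genome, primer, strand, max_mismatch) {
  pat <- if (strand == "+") primer else reverse_complement(primer)
  hits <- Biostrings::vmatchPattern(pat, genome, max.mismatch = max_mismatch)
  out <- list()
  pat_chars <- strsplit(pat, "")[[1]]
  plen <- length(pat_chars)
  # the primer's 3'-terminal base sits at the match end on "+", at the match
  # start on "-"; index of that base within the plus-strand pattern:
  idx3 <- if (strand == "+") plen else 1L
  for (ci in seq_along(hits)) {
    ir <- hits[[ci]]
    if (!length(ir)) next
    st <- IRanges::start(ir); en <- IRanges::end(ir)
    keep <- st >= 1L & en <= length(genome[[ci]])
    st <- st[keep]; en <- en[keep]
    if (!length(st)) next
    found <- as.character(Biostrings::extractAt(
      genome[[ci]], IRanges::IRanges(st, en)))
    mm <- vapply(found, function(s) {
      sum(strsplit(s, "")[[1]] != pat_chars)
    }, integer(1), USE.NAMES = FALSE)
    ok3 <- substr(found, idx3, idx3) == pat_chars[idx3]
    keep2 <- mm <= max_mismatch & ok3
    if (!any(keep2)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = names(genome)[ci], start = st[keep2], end = en[keep2],
      strand = strand, mismatches = mm[keep2], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' In-silico PCR
#'
#' Finds every genomic region a primer pair would amplify: a site of one
#' primer on the plus strand paired with a downstream site of the other
#' primer on the minus strand (both orientations considered), on the same
#' chromosome, with a product no longer than `max_product` and long enough
#' to contain both primers. The result is symmetric in the primer order.
#'
#' @param genome a [read_genome()] `DNAStringSet`.
#' @param fwd,rev primer sequences 5'->3'.
#' @param max_product product-size cap in bp (UCSC-like default 4000).
#' @param max_mismatch allowed mismatches per primer site.
#' @return data.frame sorted by (chrom, start, end): columns `chrom`,
#'   `start`, `end` (1-based inclusive product span), `strand` (strand hit
#'   by `fwd`), `product_len`, `fwd_mismatches`, `rev_mismatches`.
#' @export
insilico_pcr <- function(genome, fwd, rev, max_product = 4000L,
                         max_mismatch = 0L) {
  sites_f <- find_sites(genome, fwd, max_mismatch)
  sites_r <- find_sites(genome, rev, max_mismatch)
  min_len <- max(nchar(fwd), nchar(rev))
  prods <- rbind(
    .pair_sites(sites_f, sites_r, max_product, min_len, fwd_on_plus = TRUE),
    .pair_sites(sites_r, sites_f, max_product, min_len, fwd_on_plus = FALSE)
  )
  if (nrow(prods)) {
    prods <- prods[!duplicated(prods[, c("chrom", "start", "end")]), ,
                   drop = FALSE]
    prods <- prods[order(prods$chrom, prods$start, prods$end,
                         method = "radix"), , drop = FALSE]
    rownames(prods) <- NULL
  }
  prods
}

# pair plus-strand sites of primer A with downstream minus-strand sites of
# primer B on the same chromosome
.pair_sites <- function(sites_a, sites_b, max_product, min_len, fwd_on_plus) {
  a <- sites_a[sites_a$strand == "+", , drop = FALSE]
  b <- sites_b[sites_b$strand == "-", , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      product_len = integer(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0), stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    for (i in ai) for (j in bi) {
      len <- b$end[j] - a$start[i] + 1L
      if (a$start[i] <= b$start[j] && a$end[i] <= b$end[j] &&
          len >= min_len && len <= max_product) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = a$start[i], end = b$end[j],
          strand = if (fwd_on_plus) "+" else "-",
          product_len = len,
          fwd_mismatches = if (fwd_on_plus) a$mismatches[i] else b$mismatches[j],
          rev_mismatches = if (fwd_on_plus) b$mismatches[j] else a$mismatches[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Classify primer-pair specificity
#'
#' A pair is specific iff in-silico PCR yields exactly one product; more
#' than one amplified region rejects the pair (such assays are likely to
#' fail in the PCR), and zero products means no amplification.
#'
#' @param products data.frame from [insilico_pcr()].
#' @return `"unique"`, `"multiple"`, or `"none"`.
#' @export
specificity <- function(products) {
  n <- if (is.null(products)) 0L else nrow(products)
  if (n == 1L) "unique" else if (n > 1L) "multiple" else "none"
}

#' Write in-silico PCR products as BED
#'
#' BED is 0-based half-open; coordinates are converted from the package's
#' 1-based inclusive representation.
#'
#' @param products data.frame from [insilico_pcr()].
#' @param path output path.
#' @param name feature-name prefix.
#' @return the path, invisibly.
#' @export
write_products_bed <- function(products, path, name = "product") {
  bed <- data.frame(
    chrom = products$chrom,
    start = products$start - 1L,
    end = products$end,
    name = paste0(name, "_", seq_len(max(1L, nrow(products)))[seq_len(nrow(products))]),
    score = 0L,
    strand = products$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
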