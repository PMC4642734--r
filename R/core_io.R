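#' Parse a colon-delimited variant specification
#'
#' Accepts `chromosome:position:reference_allele:alternative_allele`
#' (e.g. `"chr9:66783838:C:T"`). The chromosome may carry or omit a `chr`
#' prefix; it is normalized to carry it. Positions are 1-based, pointing at
#' the first reference-allele base.
#'
#' @param spec a single variant specification string.
#' @return an object of class `variant`: list with `chrom`, `pos` (integer),
#'   `ref`, `alt` (uppercase), `label` (the normalized spec) and `var_class`
#'   (`"substitution"` iff both alleles have length 1, else `"indel"`).
#' @examples
#' parse_variant("chr9:66783838:C:T")
#' parse_variant("1:50:AT:A")$var_class
#' @export
parse_variant <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || is.na(spec))
    stop("variant spec must be a single string")
  parts <- strsplit(trimws(spec), ":", fixed = TRUE)[[1]]
  if (length(parts) != 4L)
    stop("malformed variant spec (need chrom:pos:ref:alt): ", spec)
  chrom <- .norm_chrom(parts[1])
  if (!nzchar(sub("^chr", "", chrom)))
    stop("empty chromosome field in: ", spec)
  if (!grepl("^[0-9]+$", parts[2]))
    stop("position is not a positive integer in: ", spec)
  pos <- as.integer(parts[2])
  if (is.na(pos) || pos < 1) stop("position must be >= 1 in: ", spec)
  ref <- toupper(parts[3]); alt <- toupper(parts[4])
  if (!grepl("^[ACGT]+$", ref)) stop("reference allele is not ACGT in: ", spec)
  if (!grepl("^[ACGT]+$", alt)) stop("alternative allele is not ACGT in: ", spec)
  if (ref == alt) stop("reference and alternative alleles are identical in: ", spec)
  .variant(chrom, pos, ref, alt,
           label = paste(chrom, pos, ref, alt, sep = ":"))
}

.variant <- function(chrom, pos, ref, alt, label) {
  structure(list(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, label = label,
    var_class = if (nchar(ref) == 1L && nchar(alt) == 1L) "substitution" else "indel"
  ), class = "variant")
}

.norm_chrom <- function(x) {
  x <- trimws(x)
  if (grepl("^chr", x, ignore.case = TRUE)) paste0("chr", sub("^chr", "", x, ignore.case = TRUE))
  else paste0("chr", x)
}

#' @export
print.variant <- function(x, ...) {
  cat(sprintf("Variant %s: %s:%d %s>%s (%s)\n",
              x$label, x$chrom, x$pos, x$ref, x$alt, x$var_class))
  invisible(x)
}

#' Load an rsID lookup table
#'
#' Offline stand-in for a dbSNP lookup: maps rsIDs to variants. Two formats
#' are accepted, selected by file extension:
#' \itemize{
#'   \item TSV with columns `rsid`, `chrom`, `pos`, `ref`, `alt` (no header,
#'     `#` comment lines ignored);
#'   \item VCF v4.x whose ID column carries rsIDs (multi-ALT records are
#'     split into one entry per alternate allele; later duplicates of an
#'     rsID are ignored with a warning).
#' }
#'
#' @param path path to the table.
#' @return object of class `rsid_table`: named list of [parse_variant()]-style
#'   variant objects keyed by rsID, with attribute `source_path`.
#' @export
read_rsid_table <- function(path) {
  if (!file.exists(path)) stop("rsID table not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(fix) # single-record VCF
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    rows <- list()
    for (i in seq_len(nrow(fix))) {
      id <- fix$ID[i]
      if (is.na(id) || !grepl("^rs[0-9]+$", id)) next
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      for (alt in alts) {
        if (!grepl("^[ACGTacgt]+$", alt)) next
        rows[[length(rows) + 1L]] <- list(
          rsid = id, chrom = fix$CHROM[i], pos = fix$POS[i],
          ref = fix$REF[i], alt = alt)
      }
    }
    df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                            col.names = c("rsid", "chrom", "pos", "ref", "alt"),
                            colClasses = "character")
  }
  if (is.null(df) || nrow(df) == 0) stop("rsID table is empty: ", path)
  tab <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$rsid[i]
    if (!grepl("^rs[0-9]+$", id))
      stop("malformed rsID in table: ", id)
    if (!is.null(tab[[id]])) {
      warning("duplicate rsID in table, keeping first: ", id)
      next
    }
    tab[[id]] <- .variant(.norm_chrom(df$chrom[i]), as.integer(df$pos[i]),
                          toupper(df$ref[i]), toupper(df$alt[i]), label = id)
    if (tab[[id]]$ref == tab[[id]]$alt)
      stop("rsID table row with identical ref and alt: ", id)
  }
  structure(tab, class = "rsid_table", source_path = path)
}

#' Resolve an rsID against a lookup table
#'
#' Unknown rsIDs are not an error here: they return a typed invalid marker
#' so that batch mode can collect them all and report, mirroring the rule
#' that invalid rs numbers must be removed before the run (or skipped with
#' `skip_invalid`).
#'
#' @param rsid an rsID string (`rs` followed by digits; anything else is a
#'   format error).
#' @param table an [read_rsid_table()] object.
#' @return a `variant` with `label = rsid`, or an object of class
#'   `invalid_rsid` carrying the rsid.
#' @export
resolve_rsid <- function(rsid, table) {
  if (!is.character(rsid) || length(rsid) != 1L || !grepl("^rs[0-9]+$", rsid))
    stop("malformed rsID: ", rsid)
  if (!inherits(table, "rsid_table")) stop("table must be an rsid_table")
  v <- table[[rsid]]
  if (is.null(v))
    return(structure(list(rsid = rsid), class = "invalid_rsid"))
  v$label <- rsid
  v
}

#' Read a variant list file
#'
#' One entry per line; `#` comments and blank lines are ignored. Lines are
#' either rsIDs (resolved through `rsid_table`) or 4-field colon specs; the
#' two forms may be mixed.
#'
#' @param path variant list file.
#' @param rsid_table optional [read_rsid_table()] object (required if any
#'   line is an rsID).
#' @return list of `variant` / `invalid_rsid` objects, in input order.
#' @export
read_variant_list <- function(path, rsid_table = NULL) {
  if (!file.exists(path)) stop("variant list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    if (grepl("^rs[0-9]+$", ln)) {
      if (is.null(rsid_table))
        stop("rsID '", ln, "' in variant list but no rsID table supplied")
      resolve_rsid(ln, rsid_table)
    } else {
      parse_variant(ln)
    }
  })
}

#' Load a reference genome from FASTA
#'
#' @param path FASTA file (plain text). Sequence names are taken up to the
#'   first whitespace; chromosomes are matched with or without a `chr`
#'   prefix downstream.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# find a chromosome in the genome, tolerating chr-prefix differences
.genome_chrom <- function(genome, chrom) {
  nm <- names(genome)
  hit <- which(nm == chrom)
  if (!length(hit)) hit <- which(.norm_chrom_vec(nm) == .norm_chrom(chrom))
  if (!length(hit)) stop("chromosome not found in genome: ", chrom)
  hit[1]
}

.norm_chrom_vec <- function(x) vapply(x, .norm_chrom, "", USE.NAMES = FALSE)

#' Extract the sequence window around a variant
#'
#' Cuts `flank` bases of reference context on each side of the variant
#' (clipped to the chromosome), verifies that the genome carries the
#' declared reference allele at the declared position (hard error
#' otherwise), and builds the alternate-allele sequence by substitution.
#'
#' @param genome a [read_genome()] `DNAStringSet`.
#' @param variant a [parse_variant()] object.
#' @param flank flank length in bp on each side.
#' @param allow_n if `FALSE` (default), any non-ACGT base in the window is a
#'   hard error (the thermodynamic model is undefined for ambiguity codes);
#'   if `TRUE` the window is returned flagged `ambiguous = TRUE`.
#' @return object of class `sequence_window`: list with `variant`, `start`
#'   (1-based position of the window's first base on the chromosome),
#'   `ref_seq`, `alt_seq`, `var_index_ref`, `var_index_alt` (1-based offsets
#'   of the first variant base within each sequence) and `ambiguous`.
#' @export
extract_window <- function(genome, variant, flank = 500, allow_n = FALSE) {
  stopifnot(inherits(variant, "variant"), flank >= 0)
  ci <- .genome_chrom(genome, variant$chrom)
  chrom_seq <- genome[[ci]]
  clen <- length(chrom_seq)
  ref_len <- nchar(variant$ref)
  if (variant$pos + ref_len - 1L > clen)
    stop("variant ", variant$label, " lies outside chromosome ", variant$chrom,
         " (length ", clen, ")")
  start <- max(1L, variant$pos - as.integer(flank))
  end <- min(clen, variant$pos + ref_len - 1L + as.integer(flank))
  ref_seq <- toupper(as.character(Biostrings::subseq(chrom_seq, start, end)))
  var_index <- variant$pos - start + 1L
  genome_ref <- substr(ref_seq, var_index, var_index + ref_len - 1L)
  if (genome_ref != variant$ref)
    stop("reference check failed for ", variant$label, ": genome has '",
         genome_ref, "' at ", variant$chrom, ":", variant$pos,
         ", variant declares '", variant$ref, "'")
  ambiguous <- grepl("[^ACGT]", ref_seq)
  if (ambiguous && !allow_n)
    stop("window around ", variant$label,
         " contains ambiguity codes (N); use allow_n = TRUE to keep it")
  alt_seq <- paste0(substr(ref_seq, 1L, var_index - 1L), variant$alt,
                    substr(ref_seq, var_index + ref_len, nchar(ref_seq)))
  structure(list(
    variant = variant, start = start, ref_seq = ref_seq, alt_seq = alt_seq,
    var_index_ref = var_index, var_index_alt = var_index,
    ambiguous = ambiguous
  ), class = "sequence_window")
}

#' Reverse complement of a DNA sequence
#'
#' @param seq string over ACGTN.
#' @return the reverse complement, uppercase.
#' @examples
#' reverse_complement("ACGT") # "ACGT"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  .check_dna(seq, "seq", allow_n = TRUE)
  .rc(seq)
}

# hot path: plain character arithmetic, no validation
.rc <- function(seq) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", seq))))
}
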