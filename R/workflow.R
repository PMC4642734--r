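#' Batch run configuration
#'
#' @param genome_path reference FASTA.
#' @param variants_path variant list (one rsID or colon spec per line).
#' @param rsid_table_path optional rsID lookup table (TSV or VCF).
#' @param flank window flank in bp; must be at least
#'   `product_max/2 + size_max` so every candidate product fits.
#' @param clamp a [clamp_spec()].
#' @param urea_molar urea concentration of the separation matrix, mol/L.
#' @param constraints a [primer_constraints()].
#' @param model a [default_model()].
#' @param retry_depth,max_product,max_mismatch in-silico PCR settings (see
#'   [select_pair()]).
#' @param output_dir where results, profiles and the run log are written;
#'   `NULL` disables file output.
#' @param skip_invalid if `FALSE` (default) any unresolved rsID aborts the
#'   whole batch, listing the offenders; if `TRUE` they become rows with
#'   status `invalid_input`.
#' @param allow_n tolerate ambiguity codes in windows (flagged, not fatal).
#' @return object of class `run_config`.
#' @export
run_config <- function(genome_path, variants_path, rsid_table_path = NULL,
                       flank = 500L, clamp = clamp_spec(), urea_molar = 0,
                       constraints = primer_constraints(),
                       model = default_model(),
                       retry_depth = 1L, max_product = 4000L,
                       max_mismatch = 0L,
                       output_dir = NULL, skip_invalid = FALSE,
                       allow_n = FALSE) {
  if (!file.exists(genome_path)) stop("genome not found: ", genome_path)
  if (!file.exists(variants_path)) stop("variant list not found: ", variants_path)
  if (!is.null(rsid_table_path) && !file.exists(rsid_table_path))
    stop("rsID table not found: ", rsid_table_path)
  flank <- as.integer(flank)
  need <- ceiling(constraints$product_max / 2) + constraints$size_max
  if (flank < need)
    stop("flank (", flank, ") must be >= product_max/2 + size_max (", need, ")")
  structure(list(
    genome_path = genome_path, variants_path = variants_path,
    rsid_table_path = rsid_table_path, flank = flank, clamp = clamp,
    urea_molar = urea_molar, constraints = constraints, model = model,
    retry_depth = as.integer(retry_depth),
    max_product = as.integer(max_product),
    max_mismatch = as.integer(max_mismatch),
    output_dir = output_dir, skip_invalid = isTRUE(skip_invalid),
    allow_n = isTRUE(allow_n)
  ), class = "run_config")
}

#' Run the amplicon-design pipeline over a variant list
#'
#' One results row per input line, in input order. Unresolved rsIDs abort
#' the run with a message listing them unless `skip_invalid` was set, in
#' which case they become `invalid_input` rows. Deterministic end to end:
#' the same inputs give byte-identical outputs.
#'
#' @param config a [run_config()] object.
#' @return (invisibly) list with `results` (data.frame of [results_row()]s),
#'   `assays` (the full `assay_design` objects, `NULL` for invalid rows) and
#'   `log` (character vector, one structured line per variant per stage).
#'   When `config$output_dir` is set, writes `results.tsv`,
#'   `<label>.profile.tsv` for each ok assay, and `run.log`.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  genome <- read_genome(config$genome_path)
  rsid_table <- if (!is.null(config$rsid_table_path))
    read_rsid_table(config$rsid_table_path) else NULL
  entries <- read_variant_list(config$variants_path, rsid_table)

  invalid <- vapply(entries, inherits, logical(1), what = "invalid_rsid")
  if (any(invalid) && !config$skip_invalid) {
    bad <- vapply(entries[invalid], function(e) e$rsid, "")
    stop("invalid rsID(s) in input, remove them or set skip_invalid: ",
         paste(bad, collapse = ", "))
  }

  log_lines <- character(0)
  push_log <- function(...) log_lines[[length(log_lines) + 1L]] <<- paste(...)
  seen <- character(0)
  rows <- vector("list", length(entries))
  assays <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (inherits(e, "invalid_rsid")) {
      push_log("variant", e$rsid, "stage=resolve status=invalid_input")
      rows[[i]] <- data.frame(
        ID = e$rsid, chrom = NA_character_, pos = NA_integer_,
        ref = NA_character_, alt = NA_character_, status = "invalid_input",
        fwd_primer = "No primers found", rev_primer = "No primers found",
        product_len_ref = NA_integer_, product_len_alt = NA_integer_,
        variant_pos_in_amplicon = NA_integer_, annealing_tm = NA_real_,
        avg_melt_temp = NA_real_, analysis_temp = NA_real_,
        clamp_pos = "none", amplicon_ref = NA_character_,
        amplicon_alt = NA_character_, stringsAsFactors = FALSE)
      next
    }
    key <- paste(e$chrom, e$pos, e$ref, e$alt, sep = ":")
    if (key %in% seen)
      push_log("variant", e$label, "stage=parse note=duplicate-of-earlier-entry")
    seen <- c(seen, key)
    window <- extract_window(genome, e, flank = config$flank,
                             allow_n = config$allow_n)
    assay <- build_assay(e, window, config$constraints, config$clamp,
                         config$model, genome, config$urea_molar,
                         retry_depth = config$retry_depth,
                         max_product = config$max_product,
                         max_mismatch = config$max_mismatch)
    if (assay$status == "ok") {
      push_log("variant", e$label,
               sprintf("stage=design status=ok fwd=%s rev=%s clamp=%s annealing=%.1f avg_melt=%.1f analysis=%.1f",
                       assay$pair$fwd_seq, assay$pair$rev_seq, assay$clamp_pos,
                       assay$annealing_tm, assay$avg_melt_temp,
                       assay$analysis_temp))
    } else {
      push_log("variant", e$label,
               paste0("stage=design status=no_primers_found reason=", assay$reason))
    }
    assays[[i]] <- assay
    rows[[i]] <- results_row(assay)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_tsv(results, file.path(config$output_dir, "results.tsv"))
    for (a in assays) {
      if (!is.null(a) && a$status == "ok") {
        fn <- file.path(config$output_dir,
                        paste0(gsub("[^A-Za-z0-9_.-]", "_", a$variant$label),
                               ".profile.tsv"))
        write_profile_tsv(a$profile_ref, a$profile_alt, fn)
      }
    }
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
  }
  invisible(list(results = results, assays = assays, log = log_lines))
}

#' Write the results table as TSV
#'
#' Locale-independent formatting; temperatures with one decimal; a header
#' comment states the coordinate convention.
#'
#' @param results data.frame of [results_row()]s.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  out <- results
  for (col in c("annealing_tm", "avg_melt_temp", "analysis_temp"))
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.1f", out[[col]]))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# convention: 1-based positions, inclusive intervals", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` comments and section headers like
#' `[thermo]` are ignored (keys are globally unique). Returns a named
#' character vector for the caller (typically the CLI) to interpret.
#'
#' @param path config file.
#' @return named character vector.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  stats::setNames(vapply(kv, `[`, "", 3), vapply(kv, `[`, "", 2))
}
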