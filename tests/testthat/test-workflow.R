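test_that("fixture genomes are byte-reproducible and carry a coherent truth table", {
  fx1 <- make_fixture_genome(42, n_chrom = 2L, chrom_len = 20000L,
                             n_variants = 5L, duplication_fraction = 0)
  fx2 <- make_fixture_genome(42, n_chrom = 2L, chrom_len = 20000L,
                             n_variants = 5L, duplication_fraction = 0)
  d1 <- tempfile(); d2 <- tempfile()
  fx1p <- make_fixture_genome(42, n_chrom = 2L, chrom_len = 20000L,
                              n_variants = 5L, duplication_fraction = 0,
                              out_dir = d1)
  fx2p <- make_fixture_genome(42, n_chrom = 2L, chrom_len = 20000L,
                              n_variants = 5L, duplication_fraction = 0,
                              out_dir = d2)
  expect_identical(readLines(fx1p$paths$genome), readLines(fx2p$paths$genome))
  expect_identical(fx1$truth, fx2$truth)
  expect_true(all(fx1$truth$expected_status == "ok"))
  # planted alleles agree with the genome
  for (k in seq_len(nrow(fx1$truth)))
    expect_equal(substr(as.character(fx1$genome[[fx1$truth$chrom[k]]]),
                        fx1$truth$pos[k], fx1$truth$pos[k]),
                 fx1$truth$ref[k])
  fx3 <- make_fixture_genome(42, n_chrom = 2L, chrom_len = 20000L,
                             n_variants = 6L, duplication_fraction = 0.5)
  expect_equal(sum(fx3$truth$duplicated), 3L)
  expect_equal(fx3$truth$expected_status[fx3$truth$duplicated],
               rep("no_primers_found", 3))
})

test_that("run_batch processes a variant list in order and writes outputs", {
  dir <- tempfile()
  fx <- make_fixture_genome(77, n_chrom = 3L, chrom_len = 30000L,
                            n_variants = 6L, duplication_fraction = 0,
                            out_dir = dir)
  out <- tempfile()
  cfg <- run_config(fx$paths$genome, fx$paths$variants,
                    clamp = clamp_spec("automatic"), urea_molar = 3,
                    output_dir = out)
  res <- run_batch(cfg)
  expect_equal(nrow(res$results), 6L)
  expect_identical(res$results$ID, fx$truth$label) # input order preserved
  expect_true(file.exists(file.path(out, "results.tsv")))
  expect_true(file.exists(file.path(out, "run.log")))
  ok <- res$results$status == "ok"
  expect_true(any(ok))
  # a profile file exists exactly for the ok assays
  profs <- list.files(out, pattern = "profile\\.tsv$")
  expect_equal(length(profs), sum(ok))
  # urea correction carried into the table
  expect_equal(res$results$analysis_temp[ok], res$results$avg_melt_temp[ok] - 9,
               tolerance = 0.051) # fields are rounded to 1 decimal
})

test_that("an unknown rsID aborts the batch unless skip_invalid is set", {
  dir <- tempfile()
  fx <- make_fixture_genome(78, n_chrom = 2L, chrom_len = 20000L,
                            n_variants = 2L, duplication_fraction = 0,
                            out_dir = dir)
  rsid_tab <- file.path(dir, "rsids.tsv")
  writeLines(paste("rs1001", fx$truth$chrom[1], fx$truth$pos[1],
                   fx$truth$ref[1], fx$truth$alt[1], sep = "\t"), rsid_tab)
  vl <- file.path(dir, "vl.txt")
  writeLines(c("rs1001", "rs424242", fx$truth$label[2]), vl)

  cfg <- run_config(fx$paths$genome, vl, rsid_table_path = rsid_tab)
  expect_error(run_batch(cfg), "rs424242")

  cfg2 <- run_config(fx$paths$genome, vl, rsid_table_path = rsid_tab,
                     skip_invalid = TRUE)
  res <- run_batch(cfg2)
  expect_equal(nrow(res$results), 3L)
  expect_equal(res$results$status[2], "invalid_input")
  expect_equal(res$results$ID[1], "rs1001")
  expect_equal(res$results$status[1], "ok")
})

test_that("repeated runs are byte-identical", {
  dir <- tempfile()
  fx <- make_fixture_genome(79, n_chrom = 2L, chrom_len = 25000L,
                            n_variants = 3L, duplication_fraction = 0,
                            out_dir = dir)
  o1 <- tempfile(); o2 <- tempfile()
  r1 <- run_batch(run_config(fx$paths$genome, fx$paths$variants,
                             clamp = clamp_spec("automatic"), output_dir = o1))
  r2 <- run_batch(run_config(fx$paths$genome, fx$paths$variants,
                             clamp = clamp_spec("automatic"), output_dir = o2))
  expect_identical(r1$results, r2$results)
  expect_identical(readLines(file.path(o1, "results.tsv")),
                   readLines(file.path(o2, "results.tsv")))
  expect_identical(r1$log, r2$log)
})

test_that("run_config validates the flank against the product size", {
  dir <- tempfile()
  fx <- make_fixture_genome(80, n_chrom = 2L, chrom_len = 20000L,
                            n_variants = 2L, duplication_fraction = 0,
                            out_dir = dir)
  expect_error(run_config(fx$paths$genome, fx$paths$variants, flank = 50),
               "flank")
})

test_that("flat key=value config files parse, ignoring sections and comments", {
  f <- tempfile()
  writeLines(c("# comment", "[thermo]", "na_molar = 0.05", "sigma=1.26e-4",
               "[primer3]", "size_opt = 20"), f)
  kv <- read_config_file(f)
  expect_equal(kv[["na_molar"]], "0.05")
  expect_equal(kv[["sigma"]], "1.26e-4")
  expect_equal(kv[["size_opt"]], "20")
  writeLines("this is not a key value line", f)
  expect_error(read_config_file(f), "malformed")
})

test_that("the command-line interface parses arguments and runs", {
  cli <- system.file("cli", "meltamp", package = "meltamp")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  # no arguments: usage on stdout, exit status 2
  usage <- suppressWarnings(
    system2(rscript, cli, stdout = TRUE, stderr = TRUE, env = env))
  expect_equal(attr(usage, "status"), 2L)
  expect_match(paste(usage, collapse = "\n"), "usage: meltamp")
  # a standalone in-silico PCR call on a planted genome
  set.seed(113)
  fwd <- rand_dna(20); rev <- rand_dna(20)
  g <- toy_genome(chr1 = paste0(rand_dna(300), fwd, rand_dna(50),
                                reverse_complement(rev), rand_dna(300)))
  fa <- write_fa(g)
  out <- suppressWarnings(
    system2(rscript, c(cli, "ispcr", "--genome", fa, "--fwd", fwd,
                       "--rev", rev),
            stdout = TRUE, stderr = TRUE, env = env))
  expect_match(paste(out, collapse = "\n"), "specificity: unique")
})
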