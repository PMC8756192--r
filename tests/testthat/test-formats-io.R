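test_that("SAM positions are converted between 1-based text and 0-based internal", {
  g <- toy_genome()
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               "@SQ\tSN:chr1\tLN:3000", "@SQ\tSN:chr2\tLN:2000",
               "r1\t0\tchr1\t101\t60\t5M\t*\t0\t0\tACGTA\tIIIII",
               "r2\t16\tchr2\t1\t60\t5M\t*\t0\t0\tACGTA\tIIIII\tRG:Z:x"),
             path)
  reads <- read_sam(path, g)
  expect_equal(nrow(reads), 2L)
  expect_equal(reads$pos, c(100L, 0L))
  expect_equal(reads$tags, c("", "RG:Z:x"))
  out <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, g, out)
  body <- grep("^@", readLines(out), value = TRUE, invert = TRUE)
  expect_equal(as.integer(sub("^r.\t\\d+\tchr.\t(\\d+).*", "\\1", body)), c(101L, 1L))
})

test_that("SAM round-trip reproduces simulator reads field-for-field", {
  sim <- small_sim()
  reads <- sim$tumor[1:500]
  path <- withr::local_tempfile(fileext = ".sam.gz")
  n <- write_sam(reads, sim$genome, path)
  expect_equal(n, 500L)
  back <- read_sam(path, sim$genome)
  expect_equal(back, reads)
})

test_that("SAM reader rejects malformed and inconsistent records", {
  g <- toy_genome()
  tf <- function(lines) {
    p <- withr::local_tempfile(fileext = ".sam", .local_envir = parent.frame(2))
    writeLines(c("@SQ\tSN:chr1\tLN:3000", lines), p)
    p
  }
  expect_error(read_sam(tf("r1\t0\tchr1\t1\t60\t4M\t*\t0\t0\tACGT\tIII"), g),
               "QUAL length")
  expect_error(read_sam(tf("r1\t0\tchr1\t1\t60\t5M\t*\t0\t0\tACGT\tIIII"), g),
               "cigar query length")
  expect_error(read_sam(tf("r1\t0\tchrX\t1\t60\t4M\t*\t0\t0\tACGT\tIIII"), g),
               "unknown contig")
  expect_error(read_sam(tf("r1\t0\tchr1\t2999\t60\t4M\t*\t0\t0\tACGT\tIIII"), g),
               "beyond contig bounds")
  # empty body is fine
  p <- withr::local_tempfile(fileext = ".sam")
  writeLines("@SQ\tSN:chr1\tLN:3000", p)
  expect_equal(nrow(read_sam(p, g)), 0L)
  # header order must match genome order
  p2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:chr2\tLN:2000", "@SQ\tSN:chr1\tLN:3000"), p2)
  expect_error(read_sam(p2, g), "contig order")
})

test_that("VCF round-trip is stable and converts coordinates", {
  g <- toy_genome()
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               paste0("chr1\t101\t.\t", substr(g$seq[1], 101, 101),
                      "\tN\t10\tPASS\tAF=0.5")), path)
  v <- read_vcf(path, g)
  expect_equal(v$pos, 100L)
  out <- withr::local_tempfile(fileext = ".vcf")
  sim <- small_sim()
  truth <- shardcall:::truth_to_variants(sim$somatic, with_af = TRUE)
  write_vcf(truth, sim$genome, out)
  back <- read_vcf(out, sim$genome)
  expect_equal(shardcall:::vcf_format_body(back), shardcall:::vcf_format_body(truth))
  # headerless file rejected, empty-with-header yields empty stream
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines("chr1\t1\t.\tA\tC\t.\t.\t.", bad)
  expect_error(read_vcf(bad, g), "#CHROM")
  hdr <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), hdr)
  expect_equal(nrow(read_vcf(hdr, g)), 0L)
})

test_that("recalibration reports round-trip losslessly and are validated", {
  t_empty <- recal_table(metadata = list(genome_id = "g", known_id = "k"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_recal_report(t_empty, p)
  back <- read_recal_report(p)
  expect_equal(nrow(back), 0L)
  expect_equal(attr(back, "metadata")$genome_id, "g")

  rows <- data.table::data.table(
    read_group = rep(c("tumor", "normal"), each = 500),
    reported_q = rep(2:51, 20), cycle = rep(c(1:50, -(1:50)), 10),
    dinuc_context = rep(c("AC", "GT", "NN", "CG"), 250),
    observations = 1000L + seq_len(1000), errors = seq_len(1000))
  tab <- recal_table(rows, metadata = list(genome_id = "g", known_id = "k"))
  write_recal_report(tab, p)
  expect_equal(read_recal_report(p), tab)

  writeLines(c("#genome_id=g", "#known_id=k",
               paste(shardcall:::RECAL_COLS, collapse = "\t"),
               "tumor\t30\t1\tAC\t5\t9"), p)
  expect_error(read_recal_report(p), "errors > observations")
  writeLines(c(paste(shardcall:::RECAL_COLS, collapse = "\t"),
               "tumor\t30\t1\tAC\t-5\t-9"), p)
  expect_error(read_recal_report(p), "negative")
})

test_that("FASTA writer emits a correct sidecar index", {
  g <- toy_genome(c(alpha = 123L, beta = 457L))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta_genome(g, fa)
  back <- read_fasta_genome(fa)
  expect_equal(back$seq, g$seq)
  expect_equal(back$names, g$names)
  fai <- read.delim(paste0(fa, ".fai"), header = FALSE)
  expect_equal(fai$V1, c("alpha", "beta"))
  expect_equal(fai$V2, c(123L, 457L))
  # offsets point at the first sequence byte of each record
  raw <- readChar(fa, file.size(fa), useBytes = TRUE)
  for (i in 1:2)
    expect_equal(substr(raw, fai$V3[i] + 1, fai$V3[i] + 10), substr(g$seq[i], 1, 10))
})
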