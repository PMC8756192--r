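test_that("reservoir sampling is deterministic, bounded and complete", {
  sim <- small_sim()
  g <- sim$genome
  s1 <- sample_positions(sim$tumor, 500L, g, seed = 9L)
  s2 <- sample_positions(sim$tumor, 500L, g, seed = 9L)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$positions), 500L)
  expect_false(is.unsorted(s1$positions$ord))
  # requesting more than the population returns every mapped read position
  few <- sim$tumor[1:10]
  sall <- sample_positions(few, 100L, g, seed = 1L)
  expect_equal(nrow(sall$positions), 10L)
  expect_setequal(sall$positions$pos, few$pos)
  expect_error(sample_positions(few[0], 10L, g, 1L), "no mapped reads")
})

test_that("uniform samples on one contig give uniform quantile regions", {
  g <- reference_genome(c(c1 = paste0(rep("ACGT", 2500), collapse = "")))
  samples <- structure(list(positions = data.table::data.table(
    ord = 0L, pos = 0:9999), seed = 1L, requested = 10000L),
    class = "sample_positions")
  spec <- compute_regions(samples, g, 4L)
  expect_equal(spec$regions$start, c(0L, 2500L, 5000L, 7500L))
  expect_equal(spec$regions$end, c(2500L, 5000L, 7500L, 10000L))
})

test_that("regions are disjoint, cover the genome, and respect contigs", {
  sim <- small_sim()
  g <- sim$genome
  for (n in c(1L, 7L, 32L)) {
    s <- sample_positions(sim$tumor, 60L * n, g, seed = 3L)
    spec <- compute_regions(s, g, n)
    r <- spec$regions
    expect_false(any(r$start >= r$end))
    # exhaustive coverage: every base of every contig in exactly one region
    for (i in seq_along(g$names)) {
      cov <- integer(g$lengths[[i]])
      rr <- r[r$contig == g$names[i]]
      for (j in seq_len(nrow(rr)))
        cov[(rr$start[j] + 1L):rr$end[j]] <- cov[(rr$start[j] + 1L):rr$end[j]] + 1L
      expect_true(all(cov == 1L))
    }
  }
  expect_error(compute_regions(sample_positions(sim$tumor, 60L, g, 3L), g,
                               sum(g$lengths) + 1L), "exceeds genome length")
})

test_that("region boundaries refine consistently as N doubles", {
  sim <- small_sim()
  g <- sim$genome
  s <- sample_positions(sim$tumor, 960L, g, seed = 4L)   # divisible by 4 and 8
  b4 <- compute_regions(s, g, 4L)$regions
  b8 <- compute_regions(s, g, 8L)$regions
  key <- function(r) paste(r$contig, r$start)
  expect_true(all(key(b4) %in% key(b8)))
})

test_that("reads are assigned to all overlapped regions with one primary", {
  g <- toy_genome()
  spec <- shardcall:::new_region_spec(data.table::data.table(
    contig = c("chr1", "chr1", "chr1", "chr2"),
    start = c(0L, 1000L, 2000L, 0L),
    end = c(1000L, 2000L, 3000L, 2000L)), g)

  inside <- mk_read("a", 99L, "chr1", 1200L)
  a <- assign_to_regions(inside, list(contig = "chr1", start = 1400L, end = 1500L),
                         spec, g)
  expect_equal(a$regions, 1L)
  expect_equal(a$primary, 1L)

  # mates starting in adjacent regions: both mates carry both regions
  m1 <- mk_read("b", 99L, "chr1", 1850L)
  m2_interval <- list(contig = "chr1", start = 2050L, end = 2150L)
  b <- assign_to_regions(m1, m2_interval, spec, g)
  expect_equal(b$regions, c(1L, 2L))
  expect_equal(b$primary, 1L)

  # single read straddling a boundary: both flanking regions, primary left
  c_ <- assign_to_regions(mk_read("c", 0L, "chr1", 1990L), NULL, spec, g)
  expect_equal(c_$regions, c(1L, 2L))
  expect_equal(c_$primary, 1L)

  expect_error(assign_to_regions(mk_read("d", 0L, "chr1", 5000L), NULL, spec, g),
               "outside genome|beyond")
})

test_that("shuffling conserves reads: primary copies partition the input", {
  sim <- small_sim()
  g <- sim$genome
  s <- sample_positions(sim$tumor, 480L, g, seed = 2L)
  spec <- compute_regions(s, g, 8L)
  dir <- withr::local_tempdir()
  man <- shuffle_by_region(sim$tumor, sim$normal, spec, g, dir)
  expect_equal(nrow(man), nrow(spec$regions))
  total_mapped <- sum(shardcall:::read_is_mapped(sim$tumor)) +
    sum(shardcall:::read_is_mapped(sim$normal))
  expect_equal(sum(man$n_primary), total_mapped)
  expect_true(all(man$n_reads >= man$n_primary))

  # boundary pair duplicated into adjacent region files with identical fields
  shards <- lapply(man$path, read_sam, genome = g)
  all_sh <- data.table::rbindlist(shards)
  dup_q <- all_sh[, .N, by = c("qname", "flag")][N > 1L]
  expect_gt(nrow(dup_q), 0L)
  one <- all_sh[all_sh$qname == dup_q$qname[1] & all_sh$flag == dup_q$flag[1]]
  core <- c("qname", "flag", "rname", "pos", "cigar", "seq", "qual")
  expect_equal(unique(one[, core, with = FALSE]), one[1, core, with = FALSE])
  xp <- shardcall:::sam_tag_get(one$tags, "XP")
  expect_equal(sum(xp == "1"), 1L)

  # N = 1: every mapped read of both samples in the single spec's files
  spec1 <- compute_regions(s, g, 1L)
  man1 <- shuffle_by_region(sim$tumor, sim$normal, spec1, g,
                            withr::local_tempdir())
  expect_equal(sum(man1$n_reads), total_mapped)
  expect_equal(man1$n_reads, man1$n_primary)
})

test_that("region specs survive the BED round trip", {
  sim <- small_sim()
  g <- sim$genome
  spec <- compute_regions(sample_positions(sim$tumor, 240L, g, 1L), g, 4L)
  p <- withr::local_tempfile(fileext = ".bed")
  write_region_bed(spec, p)
  back <- read_region_bed(p, g)
  expect_equal(back$regions, spec$regions)
})
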