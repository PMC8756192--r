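test_that("pileup emits in-region columns from passing bases only", {
  g <- toy_genome()
  r <- mk_read("a", 0L, "chr1", 0L, seq = substr(g$seq[1], 1, 100))
  col <- pileup_region(r, g, list(contig = "chr1", start = 0L, end = 100L))
  expect_equal(nrow(col), 100L)
  expect_true(all(col$depth == 1L))
  expect_equal(col$ref, strsplit(substr(g$seq[1], 1, 100), "")[[1]])
  # a duplicate-flagged read contributes nothing
  dup <- mk_read("d", 1024L, "chr1", 0L, seq = substr(g$seq[1], 1, 100))
  expect_equal(nrow(pileup_region(dup, g, list(contig = "chr1", start = 0L, end = 100L))), 0L)
  # only in-region positions are emitted even though the read spans further
  col2 <- pileup_region(r, g, list(contig = "chr1", start = 40L, end = 60L))
  expect_equal(col2$pos, 40:59)
  # low mapq and low baseq are excluded
  lowq <- mk_read("l", 0L, "chr1", 0L, seq = substr(g$seq[1], 1, 100),
                  qual = strrep("+", 100))   # phred 10 < 13
  expect_equal(nrow(pileup_region(lowq, g, list(contig = "chr1", start = 0L, end = 100L))), 0L)
  expect_error(pileup_region(rbind(r, mk_read("z", 0L, "chr1", 0L,
                                              seq = substr(g$seq[1], 1, 100)),
                                   mk_read("y", 0L, "chr1", 5L,
                                           seq = substr(g$seq[1], 6, 105)))[c(1, 3, 2)],
                             g, list(contig = "chr1", start = 0L, end = 100L)),
               "coordinate-sorted")
})

test_that("site scoring matches the stated likelihood-ratio formula", {
  # single alt read at Q20, depth 1, f = 1: tlod = log10(0.99 / (0.01/3))
  t1 <- data.table::data.table(contig = "chr1", pos = 10L, ref = "A", depth = 1L,
                               nA = 0L, nC = 1L, nG = 0L, nT = 0L,
                               qA = NA_real_, qC = 20, qG = NA_real_, qT = NA_real_)
  relaxed <- caller_params(tlod_min = 0, nlod_min = -100, min_depth = 1L)
  call <- call_site(t1, NULL, relaxed)
  expect_equal(as.numeric(sub(".*TLOD=([0-9.]+);.*", "\\1", call$info)),
               log10(0.99 / (0.01 / 3)), tolerance = 1e-3)
  expect_equal(call$alt, "C")
  # zero alt reads: no call
  t0 <- data.table::copy(t1); t0$nC <- 0L; t0$nA <- 1L; t0$qA <- 20
  expect_null(call_site(t0, NULL, relaxed))
  # zero tumor depth: no call
  tz <- data.table::copy(t1); tz$depth <- 0L
  expect_null(call_site(tz, NULL, relaxed))
})

test_that("simulated 0.5-AF locus is called with accurate allele fraction", {
  g <- toy_genome(c(chr1 = 2000L))
  shardcall:::with_seed(31L, {
    locus <- 1000L
    ref <- substr(g$seq[1], locus + 1L, locus + 1L)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    mkreads <- function(n, prefix, p_alt) {
      rows <- lapply(seq_len(n), function(i) {
        s <- as.integer(locus - sample(0:99, 1))
        sq <- substr(g$seq[1], s + 1L, s + 100L)
        if (stats::runif(1) < p_alt) {
          off <- locus - s + 1L
          substr(sq, off, off) <- alt
        }
        mk_read(sprintf("%s%04d", prefix, i), 0L, "chr1", s, seq = sq,
                qual = strrep("?", 100))   # Q30
      })
      sort_region(data.table::rbindlist(rows), g)
    }
    tum <- mkreads(60L, "t", 0.5)
    nor <- mkreads(30L, "n", 0)
    calls <- call_region(tum, nor, g, list(contig = "chr1", start = 0L, end = 2000L))
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$pos, locus)
    taf <- as.numeric(sub(".*TAF=([0-9.]+);.*", "\\1", calls$info))
    expect_lt(abs(taf - 0.5), 0.15)
  })
})

test_that("vectorized region calling equals per-site scoring", {
  sim <- small_sim()
  g <- sim$genome
  sorted <- mark_duplicates(sort_region(rbind(sim$tumor, sim$normal), g), g)
  smp <- shardcall:::sam_tag_get(sorted$tags, "RG")
  reg <- list(contig = "chr2", start = 1000L, end = 2500L)
  tum <- sorted[smp == "tumor"]
  nor <- sorted[smp == "normal"]
  fast <- call_region(tum, nor, g, reg)
  tcol <- pileup_region(tum, g, reg)
  ncol_ <- pileup_region(nor, g, reg)
  slow <- list()
  nidx <- match(tcol$pos, ncol_$pos)
  for (i in seq_len(nrow(tcol)))
    slow[[length(slow) + 1L]] <- call_site(
      tcol[i], if (is.na(nidx[i])) NULL else ncol_[nidx[i]], caller_params())
  slow <- data.table::rbindlist(slow)
  if (nrow(slow)) expect_equal(fast, slow) else expect_equal(nrow(fast), 0L)
})

test_that("planted somatic SNVs are called and germline hets are not", {
  sim <- small_sim()
  g <- sim$genome
  sorted <- mark_duplicates(sort_region(rbind(sim$tumor, sim$normal), g), g)
  tab <- build_recal_table(sorted, g,
                           known_sites_mask(shardcall:::truth_to_variants(sim$germline), g))
  recal <- apply_bqsr(sorted, tab)
  smp <- shardcall:::sam_tag_get(recal$tags, "RG")
  calls <- list()
  for (i in seq_along(g$names))
    calls[[i]] <- call_region(recal[smp == "tumor" & recal$rname == g$names[i]],
                              recal[smp == "normal" & recal$rname == g$names[i]],
                              g, list(contig = g$names[i], start = 0L,
                                      end = g$lengths[[i]]))
  calls <- data.table::rbindlist(calls)
  key <- function(v) paste(v$contig, v$pos, v$alt)
  som <- sim$somatic[sim$somatic$af >= 0.35]   # strong loci at 30x depth
  expect_gt(mean(key(som) %in% key(calls)), 0.8)
  expect_false(any(key(sim$germline) %in% key(calls)))
})

test_that("shard merging preserves genome order and rejects stray records", {
  sim <- small_sim()
  g <- sim$genome
  spec <- compute_regions(sample_positions(sim$tumor, 240L, g, 6L), g, 4L)
  R <- nrow(spec$regions)
  shards <- rep(list(shardcall:::empty_variants()), R)
  expect_equal(nrow(merge_shard_vcfs(shards, spec)), 0L)
  v <- function(contig, pos) data.table::data.table(
    contig = contig, pos = pos, id = ".", ref = "A", alt = "C",
    qual = "10", filter = "PASS", info = ".")
  shards[[1]] <- v(spec$regions$contig[1], spec$regions$start[1])
  shards[[R]] <- v(spec$regions$contig[R], spec$regions$start[R])
  merged <- merge_shard_vcfs(shards, spec)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$contig, c(spec$regions$contig[1], spec$regions$contig[R]))
  bad <- shards
  bad[[1]] <- v(spec$regions$contig[R], spec$regions$start[R])
  expect_error(merge_shard_vcfs(bad, spec), "outside its region")
  expect_error(merge_shard_vcfs(shards[-1], spec), "shard count")
})
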