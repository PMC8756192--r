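test_that("empirical quality follows the smoothed phred formula", {
  expect_equal(empirical_quality(0L, 0L), -10 * log10(1 / 2))
  expect_equal(empirical_quality(998L, 0L), 30)
  expect_equal(empirical_quality(100L, 100L), -10 * log10(101 / 102))
  expect_equal(empirical_quality(10^9L, 0L), 60)   # capped
  expect_error(empirical_quality(-1L, 0L), "negative")
  expect_error(empirical_quality(5L, 6L), "exceed")
  # nonincreasing in errors at fixed observations
  q <- empirical_quality(rep(1000L, 1001L), 0:1000)
  expect_true(all(diff(q) <= 0))
})

test_that("table merge is an exact commutative monoid", {
  meta <- list(genome_id = "g", known_id = "k")
  t1 <- recal_table(data.table::data.table(
    read_group = "t", reported_q = 40L, cycle = 1L, dinuc_context = "AC",
    observations = 10L, errors = 1L), meta)
  t2 <- recal_table(data.table::data.table(
    read_group = "t", reported_q = 40L, cycle = 1L, dinuc_context = "AC",
    observations = 5L, errors = 2L), meta)
  empty <- recal_table(metadata = meta)
  expect_equal(merge_recal_tables(t1, empty), t1)
  m <- merge_recal_tables(t1, t2)
  expect_equal(m$observations, 15L)
  expect_equal(m$errors, 3L)
  expect_equal(merge_recal_tables(t1, t2), merge_recal_tables(t2, t1))
  t3 <- recal_table(metadata = list(genome_id = "other", known_id = "k"))
  expect_error(merge_recal_tables(t1, t3), "metadata")
})

test_that("clean matching reads count observations without errors", {
  g <- toy_genome()
  r <- mk_read("a", 0L, "chr1", 200L, seq = substr(g$seq[1], 201, 300))
  tab <- build_recal_table(r, g)
  expect_equal(sum(tab$observations), 100L)
  expect_equal(sum(tab$errors), 0L)
  # one planted mismatch at a known site is fully masked
  sq <- substr(g$seq[1], 201, 300)
  mism <- setdiff(c("A", "C", "G", "T"), substr(sq, 50, 50))[1]
  substr(sq, 50, 50) <- mism
  r2 <- mk_read("a", 0L, "chr1", 200L, seq = sq)
  known <- data.table::data.table(contig = "chr1", pos = 249L, id = ".",
                                  ref = substr(g$seq[1], 250, 250), alt = mism,
                                  qual = ".", filter = ".", info = ".")
  mask <- known_sites_mask(known, g)
  tab2 <- build_recal_table(r2, g, mask)
  expect_equal(sum(tab2$observations), 99L)
  expect_equal(sum(tab2$errors), 0L)
  # without the mask the mismatch is an error
  tab3 <- build_recal_table(r2, g)
  expect_equal(sum(tab3$errors), 1L)
})

test_that("duplicate, secondary, mapq-0 and boundary-copy reads are skipped", {
  g <- toy_genome()
  ok <- mk_read("keep", 0L, "chr1", 0L, seq = substr(g$seq[1], 1, 100))
  skip <- rbind(
    mk_read("dup", 1024L, "chr1", 0L, seq = substr(g$seq[1], 1, 100)),
    mk_read("sec", 256L, "chr1", 0L, seq = substr(g$seq[1], 1, 100)),
    mk_read("mq0", 0L, "chr1", 0L, mapq = 0L, seq = substr(g$seq[1], 1, 100)),
    mk_read("bcopy", 0L, "chr1", 0L, seq = substr(g$seq[1], 1, 100),
            tags = "RG:Z:tumor\tXP:i:0"))
  tab <- build_recal_table(rbind(ok, skip), g)
  expect_equal(sum(tab$observations), 100L)
})

test_that("partial tables from any split merge to the single-pass table", {
  sim <- small_sim()
  g <- sim$genome
  sorted <- mark_duplicates(sort_region(rbind(sim$tumor, sim$normal), g), g)
  mask <- known_sites_mask(shardcall:::truth_to_variants(sim$germline), g)
  whole <- build_recal_table(sorted, g, mask)
  offsets <- g$goffset
  gpos <- offsets[match(sorted$rname, g$names)] + sorted$pos
  shardcall:::with_seed(13L, {
    for (rep in 1:5) {
      cuts <- sort(sample(sum(g$lengths) - 1L, 7L))
      bounds <- c(0, cuts, sum(g$lengths))
      parts <- lapply(seq_len(8L), function(i) {
        sel <- gpos >= bounds[i] & gpos < bounds[i + 1L]
        build_recal_table(sorted[sel], g, mask)
      })
      merged <- tree_merge_tables(parts[sample(8L)])
      expect_equal(data.table::as.data.table(merged), data.table::as.data.table(whole))
      expect_equal(sum(vapply(parts, function(t) sum(t$observations), numeric(1))),
                   sum(whole$observations))
    }
  })
})

test_that("planted error rates are recovered in the covariate counts", {
  sim <- small_sim()
  g <- sim$genome
  sorted <- mark_duplicates(sort_region(sim$normal, g), g)
  mask <- known_sites_mask(shardcall:::truth_to_variants(sim$germline), g)
  tab <- build_recal_table(sorted, g, mask)
  band <- tab[abs(tab$cycle) >= 80 & tab$dinuc_context != "CG"]
  p_hat <- sum(band$errors) / sum(band$observations)
  se <- sqrt(0.01 * 0.99 / sum(band$observations))
  expect_lt(abs(p_hat - 0.01), 3 * se + 1e-4)
  low <- tab[abs(tab$cycle) <= 30 & tab$dinuc_context != "CG"]
  p_low <- sum(low$errors) / sum(low$observations)
  expect_lt(abs(p_low - 0.001), 3 * sqrt(0.001 * 0.999 / sum(low$observations)) + 1e-4)
})

test_that("recalibration applies empirical qualities with the fallback chain", {
  meta <- list(genome_id = "g", known_id = "k")
  tab <- recal_table(data.table::data.table(
    read_group = c("tumor", "tumor"),
    reported_q = c(40L, 40L),
    cycle = c(1L, 2L),
    dinuc_context = c("NN", "AA"),
    observations = c(998L, 10L),
    errors = c(0L, 1L)), meta)
  r <- mk_read("a", 0L, "chr1", 0L, seq = "AAAA", qual = "IIII", cigar = "4M")
  out <- apply_bqsr(r, tab, min_obs = 100L)
  q <- shardcall:::phred_ints(out$qual)
  # cycle 1 ("NN" context): full key (998, 0) -> Q30
  expect_equal(q[1], 30L)
  # cycle 2: full key too thin (10 obs) -> (rg, q) aggregate (1008, 1) -> Q27
  expect_equal(q[2], as.integer(round(empirical_quality(1008L, 1L))))
  # cycles 3-4: keys absent, aggregates cover them the same way
  expect_equal(q[3], as.integer(round(empirical_quality(1008L, 1L))))
  # unknown read group: untouched at the final fallback
  r2 <- mk_read("b", 0L, "chr1", 0L, seq = "AAAA", qual = "IIII", cigar = "4M",
                tags = "RG:Z:other")
  expect_equal(apply_bqsr(r2, tab)$qual, "IIII")
  # sequences never change
  expect_equal(out$seq, r$seq)
})

test_that("recalibration shrinks the gap between implied and true error", {
  sim <- small_sim()
  g <- sim$genome
  sorted <- mark_duplicates(sort_region(rbind(sim$tumor, sim$normal), g), g)
  mask <- known_sites_mask(shardcall:::truth_to_variants(sim$germline), g)
  tab <- build_recal_table(sorted, g, mask)
  recal <- apply_bqsr(sorted, tab)
  L <- 100L
  cyc_of <- function(reads) {
    isrev <- shardcall:::read_is_reverse(reads)
    m <- matrix(0L, nrow(reads), L)
    m[!isrev, ] <- matrix(1:L, sum(!isrev), L, byrow = TRUE)
    m[isrev, ] <- matrix(L:1, sum(isrev), L, byrow = TRUE)
    as.integer(t(m))
  }
  qs0 <- unlist(shardcall:::phred_ints(sorted$qual))
  qs1 <- unlist(shardcall:::phred_ints(recal$qual))
  cyc <- cyc_of(sorted)
  true_rate <- ifelse(cyc >= 71L, 0.01, 0.001)
  gap <- function(q) mean(abs(10^(-q / 10) - true_rate))
  expect_lt(gap(qs1), gap(qs0))
  # mean assigned quality in the miscalibrated band sits near phred(1%) = 20
  expect_lt(abs(mean(qs1[cyc >= 71L]) - 20), 2)
})
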