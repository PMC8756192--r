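# Deterministic desk-scale simulator: reference, germline/somatic truth,
# paired tumor/normal reads with a systematic quality-miscalibration model,
# PCR duplicate pairs, and optional boundary-straddling pairs. Reads are
# emitted pre-aligned (exact simulated coordinates, ungapped 100M cigars);
# the same reads can be exported as gzipped FASTQ for the chunker.

#' Simulation parameters
#'
#' Defaults describe the study conditions used throughout the test suite: a
#' 60 kb three-contig genome, 60x tumor / 30x normal paired 100 bp reads
#' with 300 +/- 30 bp fragments, 1e-3 germline het rate, 30 somatic SNVs
#' with allele fractions from \{0.1, 0.2, 0.35, 0.5, 0.8\}, 5% PCR duplicate
#' pairs, and a miscalibration model that reports Q40 everywhere while the
#' true error rate is 1e-3 for machine cycles < `band_start` and 1e-2 from
#' `band_start` on, doubled in the `context_dinuc` machine-orientation
#' context.
#'
#' @param contig_lengths named integer vector of contig lengths.
#' @param germline_rate per-bp probability of a germline het.
#' @param n_somatic number of somatic SNVs to plant.
#' @param somatic_afs allele-fraction choices for somatic SNVs.
#' @param tumor_depth,normal_depth mean coverage per sample.
#' @param read_length,fragment_mean,fragment_sd read/fragment geometry (bp).
#' @param dup_fraction fraction of pairs cloned as PCR duplicates.
#' @param reported_q constant reported base quality (phred).
#' @param error_base,error_band true per-base error rates below/within the
#'   miscalibrated cycle band.
#' @param band_start first machine cycle (1-based) of the miscalibrated band.
#' @param context_dinuc,context_mult machine-orientation dinucleotide whose
#'   error rate is multiplied by `context_mult`.
#' @param skew coverage weight of the first half of each contig (1 = uniform).
#' @param boundary_pairs extra pairs forced to straddle contig midpoints
#'   (positions that quantile partitioning tends to cut).
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @return named list of parameters.
#' @export
sim_params <- function(contig_lengths = c(chr1 = 30000L, chr2 = 20000L, chr3 = 10000L),
                       germline_rate = 1e-3, n_somatic = 30L,
                       somatic_afs = c(0.1, 0.2, 0.35, 0.5, 0.8),
                       tumor_depth = 60, normal_depth = 30,
                       read_length = 100L, fragment_mean = 300, fragment_sd = 30,
                       dup_fraction = 0.05, reported_q = 40L,
                       error_base = 1e-3, error_band = 1e-2, band_start = 71L,
                       context_dinuc = "CG", context_mult = 2,
                       skew = 1, boundary_pairs = 0L, seed = 1L) {
  stopifnot(tumor_depth > 0, normal_depth > 0,
            all(somatic_afs > 0), all(somatic_afs <= 1),
            read_length <= fragment_mean,
            all(contig_lengths >= read_length))
  as.list(environment())
}

#' Simulate a reference genome
#'
#' Uniform A/C/G/T composition (GC 0.5). Deterministic given `params$seed`.
#'
#' @param params [sim_params()].
#' @return a [reference_genome()].
#' @export
simulate_reference <- function(params) {
  seqs <- with_seed(params$seed, {
    vapply(params$contig_lengths, function(len)
      paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
  })
  names(seqs) <- names(params$contig_lengths)
  reference_genome(seqs)
}

# sample one sample's fragments; returns data.table(contig, start, flen)
sample_fragments <- function(params, genome, n_pairs) {
  L <- params$read_length
  segs <- data.table::data.table(
    contig = rep(genome$names, each = 2L),
    from = as.vector(vapply(genome$lengths, function(l) c(0L, l %/% 2L), integer(2))),
    to = as.vector(vapply(genome$lengths, function(l) c(l %/% 2L, l), integer(2))),
    w = rep(c(params$skew, 1), length(genome$names)))
  segs[, "wlen" := (segs$to - segs$from) * segs$w]
  seg <- sample.int(nrow(segs), n_pairs, replace = TRUE, prob = segs$wlen)
  flen <- pmax(as.integer(round(stats::rnorm(n_pairs, params$fragment_mean,
                                             params$fragment_sd))), L)
  ctg <- segs$contig[seg]
  clen <- genome$lengths[ctg]
  flen <- pmin(flen, as.integer(clen))
  start <- segs$from[seg] +
    as.integer(floor(stats::runif(n_pairs) * (segs$to[seg] - segs$from[seg])))
  start <- pmin(start, as.integer(clen) - flen)
  start <- pmax(start, 0L)
  data.table::data.table(contig = ctg, start = start, flen = flen)
}

make_pair_reads <- function(frags, qnames, genome, params, rgid, lib) {
  L <- params$read_length
  ord <- match(frags$contig, genome$names)
  s1 <- frags$start
  s2 <- frags$start + frags$flen - L
  seq1 <- substring(genome$seq[ord], s1 + 1L, s1 + L)
  seq2 <- substring(genome$seq[ord], s2 + 1L, s2 + L)
  qual <- strrep(substr(rawToChar(as.raw(params$reported_q + 33L)), 1, 1), L)
  tags <- paste0("RG:Z:", rgid, "\tLB:Z:", lib)
  n <- nrow(frags)
  fwd <- data.table::data.table(
    qname = qnames, flag = 99L, rname = frags$contig, pos = s1, mapq = 60L,
    cigar = paste0(L, "M"), rnext = "=", pnext = s2, tlen = frags$flen,
    seq = seq1, qual = qual, tags = tags)
  rev <- data.table::data.table(
    qname = qnames, flag = 147L, rname = frags$contig, pos = s2, mapq = 60L,
    cigar = paste0(L, "M"), rnext = "=", pnext = s1, tlen = -frags$flen,
    seq = seq2, qual = qual, tags = tags)
  rbind(fwd, rev)
}

# plant variant alleles onto reads; one bernoulli draw per fragment molecule
plant_alleles <- function(reads, variants, prob_col) {
  L <- nchar(reads$seq[1])
  for (i in seq_len(nrow(variants))) {
    v <- variants[i]
    cover <- which(reads$rname == v$contig & reads$pos <= v$pos &
                     reads$pos + L > v$pos)
    if (!length(cover)) next
    qn <- sort(unique(reads$qname[cover]))
    carry <- qn[stats::runif(length(qn)) < v[[prob_col]]]
    hit <- cover[reads$qname[cover] %in% carry]
    if (!length(hit)) next
    off <- v$pos - reads$pos[hit] + 1L
    x <- reads$seq[hit]
    substring(x, off, off) <- v$alt
    data.table::set(reads, hit, "seq", x)
  }
  reads
}

# inject sequencing errors per the miscalibration model; returns registry
inject_errors <- function(reads, params) {
  n <- nrow(reads)
  L <- nchar(reads$seq)
  row <- rep(seq_len(n), L)
  qidx <- sequence(L)
  seq_raw <- charToRaw(paste0(reads$seq, collapse = ""))
  seq_off <- cumsum(c(0L, L[-n]))
  cov <- base_covariates(reads, row, qidx, CODE_OF[as.integer(seq_raw) + 1L], seq_off)
  mc <- abs(cov$cycle)
  rate <- rep(params$error_base, length(mc))
  rate[mc >= params$band_start] <- params$error_band
  ctx <- dinuc_code(params$context_dinuc)
  rate[cov$dinuc == ctx] <- rate[cov$dinuc == ctx] * params$context_mult
  hit <- which(stats::runif(length(row)) < rate)
  registry <- data.table::data.table(qname = character(), flag = integer(),
                                     cycle = integer(), refpos = integer(),
                                     true_base = character(), obs_base = character())
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    old <- strsplit(rawToChar(seq_raw[seq_off[row[hit]] + qidx[hit]]), "")[[1]]
    pick <- as.integer(floor(stats::runif(length(hit)) * 3)) + 1L
    newb <- vapply(seq_along(hit), function(j)
      setdiff(bases, old[j])[pick[j]], character(1))
    seq_raw[seq_off[row[hit]] + qidx[hit]] <- charToRaw(paste0(newb, collapse = ""))
    big <- rawToChar(seq_raw)
    data.table::set(reads, NULL, "seq", substring(big, seq_off + 1L, seq_off + L))
    registry <- data.table::data.table(
      qname = reads$qname[row[hit]], flag = reads$flag[row[hit]],
      cycle = mc[hit], refpos = reads$pos[row[hit]] + qidx[hit] - 1L,
      true_base = old, obs_base = newb)
  }
  list(reads = reads, registry = registry)
}

simulate_sample <- function(params, genome, variants, prob_col, sample_name) {
  L <- params$read_length
  G <- sum(genome$lengths)
  depth <- if (sample_name == "tumor") params$tumor_depth else params$normal_depth
  n_pairs <- as.integer(round(depth * G / (2 * L)))
  frags <- sample_fragments(params, genome, n_pairs)
  if (params$boundary_pairs > 0L) {
    k <- min(params$boundary_pairs, n_pairs)
    mid_ctg <- rep(genome$names, length.out = k)
    mid <- genome$lengths[mid_ctg] %/% 2L
    frags[seq_len(k), c("contig", "start", "flen") := list(
      mid_ctg, as.integer(mid - L %/% 2L), as.integer(max(2L * L, 250L)))]
  }
  qnames <- sprintf("%s_%06d", sample_name, seq_len(n_pairs))
  reads <- make_pair_reads(frags, qnames, genome, params,
                           rgid = sample_name, lib = paste0("lib_", sample_name))
  reads <- plant_alleles(reads, variants, prob_col)
  # PCR duplicates: clone whole pairs after allele planting, before errors
  dup_sel <- which(stats::runif(n_pairs) < params$dup_fraction)
  registry_dup <- data.table::data.table(original = character(), duplicate = character())
  if (length(dup_sel)) {
    clones <- reads[reads$qname %in% qnames[dup_sel]]
    newnames <- paste0(clones$qname, ".d1")
    registry_dup <- data.table::data.table(original = qnames[dup_sel],
                                           duplicate = paste0(qnames[dup_sel], ".d1"))
    clones[, "qname" := newnames]
    reads <- rbind(reads, clones)
  }
  err <- inject_errors(reads, params)
  list(reads = err$reads, duplicates = registry_dup, errors = err$registry)
}

#' Simulate tumor/normal aligned reads with truth sets
#'
#' Draws germline het loci (rate `germline_rate`, present in both samples
#' with per-fragment probability 0.5) and `n_somatic` somatic SNV loci
#' (tumor-only, per-fragment probability = the locus allele fraction),
#' generates proper paired 100M-cigar reads at the configured depths, clones
#' PCR duplicate pairs, and injects sequencing errors per the miscalibration
#' model. Deterministic given `params$seed`.
#'
#' @param params [sim_params()].
#' @param genome genome from [simulate_reference()].
#' @return list with `tumor`/`normal` read tables, `germline` and `somatic`
#'   truth tables (contig, pos, ref, alt, af), `duplicates` registry, and
#'   `errors` registry.
#' @export
simulate_reads <- function(params, genome) {
  with_seed(params$seed + 1000003L, {
    # germline het loci
    germ <- list()
    for (i in seq_along(genome$names)) {
      len <- genome$lengths[[i]]
      at <- which(stats::runif(len) < params$germline_rate) - 1L
      if (length(at))
        germ[[length(germ) + 1L]] <- data.table::data.table(
          contig = genome$names[i], pos = at)
    }
    germ <- if (length(germ)) data.table::rbindlist(germ) else
      data.table::data.table(contig = character(), pos = integer())
    add_alleles <- function(v) {
      ord <- match(v$contig, genome$names)
      v[, "ref" := substring(genome$seq[ord], v$pos + 1L, v$pos + 1L)]
      v[, "alt" := vapply(seq_len(nrow(v)), function(i)
        setdiff(c("A", "C", "G", "T"), v$ref[i])[
          as.integer(floor(stats::runif(1) * 3)) + 1L], character(1))]
      v
    }
    germ <- add_alleles(germ)
    germ[, "af" := 0.5]
    # somatic loci, distinct from germline
    offsets <- cumsum(c(0, genome$lengths[-length(genome$lengths)]))
    G <- sum(genome$lengths)
    gkey <- offsets[match(germ$contig, genome$names)] + germ$pos
    som_g <- integer(0)
    while (length(som_g) < params$n_somatic) {
      cand <- as.integer(floor(stats::runif(params$n_somatic) * G))
      som_g <- unique(c(som_g, setdiff(cand, gkey)))
    }
    som_g <- sort(som_g[seq_len(params$n_somatic)])
    ordn <- findInterval(som_g, offsets)
    som <- data.table::data.table(contig = genome$names[ordn],
                                  pos = as.integer(som_g - offsets[ordn]))
    som <- add_alleles(som)
    som[, "af" := sample(params$somatic_afs, params$n_somatic, replace = TRUE)]

    tumor_vars <- rbind(cbind(germ[, c("contig", "pos", "ref", "alt")], p = 0.5),
                        cbind(som[, c("contig", "pos", "ref", "alt")], p = som$af))
    normal_vars <- cbind(germ[, c("contig", "pos", "ref", "alt")], p = 0.5)
    tum <- simulate_sample(params, genome, tumor_vars, "p", "tumor")
    nor <- simulate_sample(params, genome, normal_vars, "p", "normal")
    list(tumor = tum$reads, normal = nor$reads,
         germline = germ, somatic = som,
         duplicates = rbind(cbind(tum$duplicates, sample = "tumor"),
                            cbind(nor$duplicates, sample = "normal")),
         errors = rbind(cbind(tum$errors, sample = "tumor"),
                        cbind(nor$errors, sample = "normal")))
  })
}

truth_to_variants <- function(truth, with_af = FALSE) {
  data.table::data.table(
    contig = truth$contig, pos = truth$pos, id = ".", ref = truth$ref,
    alt = truth$alt, qual = ".", filter = ".",
    info = if (with_af) sprintf("AF=%.4f", truth$af) else ".")
}

#' Simulate a complete dataset onto disk
#'
#' Writes `ref.fa` (+ `.fai`), `tumor.sam`, `normal.sam`, `known.vcf` (the
#' germline truth, doubling as the known-sites input), `truth_somatic.vcf`,
#' `truth_germline.vcf` and `duplicates.tsv` under `out_dir`.
#'
#' @param params [sim_params()].
#' @param out_dir output directory (created).
#' @return invisibly, the list from [simulate_reads()] plus `genome` and
#'   the file `paths`.
#' @export
simulate_dataset <- function(params, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_reference(params)
  sim <- simulate_reads(params, genome)
  paths <- list(
    ref = file.path(out_dir, "ref.fa"),
    tumor = file.path(out_dir, "tumor.sam"),
    normal = file.path(out_dir, "normal.sam"),
    known = file.path(out_dir, "known.vcf"),
    truth_somatic = file.path(out_dir, "truth_somatic.vcf"),
    truth_germline = file.path(out_dir, "truth_germline.vcf"),
    duplicates = file.path(out_dir, "duplicates.tsv"))
  write_fasta_genome(genome, paths$ref)
  rg <- function(s) data.table::data.table(id = s, sm = s, lb = paste0("lib_", s))
  write_sam(sim$tumor, genome, paths$tumor, read_groups = rg("tumor"))
  write_sam(sim$normal, genome, paths$normal, read_groups = rg("normal"))
  write_vcf(truth_to_variants(sim$germline), genome, paths$known)
  write_vcf(truth_to_variants(sim$somatic, with_af = TRUE), genome, paths$truth_somatic,
            info_defs = '##INFO=<ID=AF,Number=1,Type=Float,Description="True allele fraction">')
  write_vcf(truth_to_variants(sim$germline), genome, paths$truth_germline)
  data.table::fwrite(sim$duplicates, paths$duplicates, sep = "\t")
  invisible(c(sim, list(genome = genome, paths = paths)))
}

#' Export simulated reads as paired gzipped FASTQ
#'
#' Reads are written in machine orientation (reverse-strand records are
#' reverse-complemented, qualities reversed), first-in-pair records to `r1`,
#' second-in-pair to `r2`, pair order preserved.
#'
#' @param reads simulated read table of one sample.
#' @param r1,r2 output paths (`.gz` suffix gzips).
#' @return number of pairs written, invisibly.
#' @export
write_fastq_pairs <- function(reads, r1, r2) {
  fwd <- reads[bitwAnd(reads$flag, FLAG_FIRST) != 0L]
  rev <- reads[bitwAnd(reads$flag, FLAG_SECOND) != 0L]
  data.table::setorderv(fwd, "qname")
  data.table::setorderv(rev, "qname")
  if (!identical(fwd$qname, rev$qname)) stop("unpaired reads in FASTQ export")
  machine <- function(r) {
    isrev <- read_is_reverse(r)
    sq <- r$seq; qv <- r$qual
    if (any(isrev)) {
      sq[isrev] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(sq[isrev])))
      qv[isrev] <- vapply(qv[isrev], function(x)
        rawToChar(rev(charToRaw(x))), character(1), USE.NAMES = FALSE)
    }
    list(seq = sq, qual = qv)
  }
  wr <- function(r, path, mate) {
    m <- machine(r)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(paste0("@", r$qname, "/", mate, "\n", m$seq, "\n+\n", m$qual), con)
  }
  wr(fwd, r1, 1L)
  wr(rev, r2, 2L)
  invisible(nrow(fwd))
}
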