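# Built-in position-local tumor/normal somatic SNV caller. Each site is
# scored only from its own pileup column, so calls are exactly invariant to
# how the genome was partitioned; external callers can be plugged in behind
# the same per-region contract (region interval + two region SAM paths in,
# VCF shard out) but are not bundled.

#' Default parameters of the built-in somatic caller
#'
#' @param tlod_min minimum tumor log10 odds for emitting a call.
#' @param nlod_min minimum normal ref-ness log10 odds (ref vs. het).
#' @param min_depth minimum tumor pileup depth.
#' @param max_normal_af maximum alternate allele fraction in the normal.
#' @param min_mapq,min_baseq pileup inclusion thresholds.
#' @return named list of parameters.
#' @export
caller_params <- function(tlod_min = 6.3, nlod_min = 2.2, min_depth = 8L,
                          max_normal_af = 0.03, min_mapq = 20L, min_baseq = 13L) {
  list(tlod_min = tlod_min, nlod_min = nlod_min, min_depth = min_depth,
       max_normal_af = max_normal_af, min_mapq = min_mapq, min_baseq = min_baseq)
}

#' Pileup of one sample over one region
#'
#' Emits one column per reference position inside the region interval with
#' at least one passing base. Duplicate-flagged, secondary/supplementary and
#' low-mapq reads are excluded; bases below `min_baseq` are excluded.
#' Boundary copies present in the shard contribute, so every read
#' overlapping an in-region position is visible.
#'
#' @param reads coordinate-sorted, duplicate-flagged read table of one
#'   sample (error if unsorted).
#' @param genome a [reference_genome()].
#' @param region list/row with `contig`, `start`, `end` (0-based half-open).
#' @param min_mapq,min_baseq inclusion thresholds.
#' @return data.table with contig, pos (0-based), ref, depth, per-allele
#'   counts nA/nC/nG/nT and mean phred qA/qC/qG/qT (NA when absent).
#' @export
pileup_region <- function(reads, genome, region, min_mapq = 20L, min_baseq = 13L) {
  ordc <- match(reads$rname, genome$names)
  mp <- read_is_mapped(reads)
  if (sum(mp) > 1L) {
    om <- ordc[mp]; pm <- reads$pos[mp]; nm <- length(om)
    ok <- om[-1] > om[-nm] | (om[-1] == om[-nm] & pm[-1] >= pm[-nm])
    if (!all(ok)) stop("pileup_region requires coordinate-sorted input")
  }
  use <- mp & !read_is_dup(reads) & !read_is_secondary(reads) &
    reads$mapq >= min_mapq
  ord_reg <- contig_ordinal(genome, region$contig)
  r <- reads[use & ordc - 1L == ord_reg &
               reads$pos < region$end &
               reads$pos + ref_widths(reads$cigar) > region$start]
  empty <- data.table::data.table(
    contig = character(), pos = integer(), ref = character(), depth = integer(),
    nA = integer(), nC = integer(), nG = integer(), nT = integer(),
    qA = numeric(), qC = numeric(), qG = numeric(), qT = numeric())
  if (!nrow(r)) return(empty)
  bases <- expand_aligned_bases(r, genome, covariates = FALSE)
  bases <- bases[bases$qual >= min_baseq &
                   bases$refpos >= region$start & bases$refpos < region$end]
  if (!nrow(bases)) return(empty)
  # per-(position, allele) counts and quality sums via dense integer keys;
  # per-group quality sums accumulate in base order (sorted reads), so the
  # resulting means are identical for any partitioning
  W <- region$end - region$start
  key <- (bases$refpos - region$start) * 5L + bases$qcode + 1L
  cntm <- matrix(tabulate(key, 5L * W), nrow = 5L)
  sq <- matrix(0, nrow = 5L, ncol = W)
  rs <- rowsum(as.numeric(bases$qual), key)
  sq[as.integer(rownames(rs))] <- rs[, 1]
  depth <- colSums(cntm)
  posns <- which(depth > 0L)
  col <- data.table::data.table(
    contig = region$contig,
    pos = region$start + posns - 1L,
    ref = CODE_CHAR[genome$codes[[ord_reg + 1L]][region$start + posns] + 1L],
    depth = as.integer(depth[posns]))
  for (b in 0:3) {
    nb <- cntm[b + 1L, posns]
    col[, (paste0("n", CODE_CHAR[b + 1L])) := as.integer(nb)]
    col[, (paste0("q", CODE_CHAR[b + 1L])) :=
          ifelse(nb > 0L, sq[b + 1L, posns] / nb, NA_real_)]
  }
  col[]
}

# P(read base | allele fraction f): alt reads f(1-e) + (1-f)e/3,
# ref reads (1-f)(1-e) + f e/3
p_alt <- function(f, eps) f * (1 - eps) + (1 - f) * eps / 3
p_ref <- function(f, eps) (1 - f) * (1 - eps) + f * eps / 3

# vectorized scoring core shared by call_site and call_region
score_sites <- function(ref, tdepth, talt, tref, eps_ta, eps_tr,
                        ndepth, nalt, nref, eps_na, eps_nr) {
  f <- talt / tdepth
  tlod <- talt * log10(p_alt(f, eps_ta) / p_alt(0, eps_ta))
  tlod <- tlod + ifelse(tref > 0,
                        tref * log10(p_ref(f, eps_tr) / p_ref(0, eps_tr)), 0)
  nlod <- ifelse(nref > 0,
                 nref * log10(p_ref(0, eps_nr) / p_ref(0.5, eps_nr)), 0)
  nlod <- nlod + ifelse(nalt > 0,
                        nalt * log10(p_alt(0, eps_na) / p_alt(0.5, eps_na)), 0)
  naf <- ifelse(ndepth > 0, nalt / ndepth, 0)
  list(f = f, tlod = tlod, nlod = nlod, naf = naf)
}

allele_count <- function(col, b) col[[paste0("n", b)]]
allele_meanq <- function(col, b) col[[paste0("q", b)]]

pick_alt <- function(col) {
  alleles <- setdiff(c("A", "C", "G", "T"), col$ref)
  counts <- vapply(alleles, function(b) allele_count(col, b), integer(1))
  alleles[which.max(counts)]   # ties: first in A<C<G<T order
}

#' Score one tumor/normal locus
#'
#' Evaluates the alt-read model `P(alt read | AF = f) = f(1-e) + (1-f)e/3`
#' at `f = tumor alt count / depth` against `f = 0` (TLOD), and the normal
#' column's ref-ness against a germline het (`AF = 0.5`) (NLOD), with
#' per-allele error rates `e` from the allele's mean phred. A call is
#' emitted iff TLOD, NLOD, tumor depth and normal alt fraction all pass.
#'
#' @param t,n single pileup columns (see [pileup_region()]) at the same
#'   locus; `n` may be `NULL` (no normal coverage).
#' @param params [caller_params()].
#' @return one-row data.table (variant + TLOD/NLOD/TAF/TDP/NDP info), or
#'   `NULL` for no call.
#' @export
call_site <- function(t, n = NULL, params = caller_params()) {
  if (is.null(t) || !nrow(t) || t$depth == 0L) return(NULL)
  alt <- pick_alt(t)
  talt <- allele_count(t, alt)
  if (talt == 0L) return(NULL)
  tref <- allele_count(t, t$ref)
  eps_ta <- 10^(-allele_meanq(t, alt) / 10)
  eps_tr <- if (tref > 0) 10^(-allele_meanq(t, t$ref) / 10) else 1e-3
  if (is.null(n) || !nrow(n)) {
    ndepth <- 0L; nalt <- 0L; nref <- 0L; eps_na <- 1e-3; eps_nr <- 1e-3
  } else {
    ndepth <- n$depth
    nalt <- allele_count(n, alt)
    nref <- allele_count(n, t$ref)
    eps_na <- if (nalt > 0) 10^(-allele_meanq(n, alt) / 10) else 1e-3
    eps_nr <- if (nref > 0) 10^(-allele_meanq(n, t$ref) / 10) else 1e-3
  }
  s <- score_sites(t$ref, t$depth, talt, tref, eps_ta, eps_tr,
                   ndepth, nalt, nref, eps_na, eps_nr)
  if (!(s$tlod >= params$tlod_min && s$nlod >= params$nlod_min &&
        t$depth >= params$min_depth && s$naf <= params$max_normal_af))
    return(NULL)
  somatic_record(t$contig, t$pos, t$ref, alt, s$tlod, s$nlod, s$f,
                 t$depth, ndepth)
}

somatic_record <- function(contig, pos, ref, alt, tlod, nlod, taf, tdp, ndp) {
  data.table::data.table(
    contig = contig, pos = pos, id = ".", ref = ref, alt = alt,
    qual = sprintf("%.3f", tlod), filter = "PASS",
    info = sprintf("TLOD=%.3f;NLOD=%.3f;TAF=%.4f;TDP=%d;NDP=%d",
                   tlod, nlod, taf, as.integer(tdp), as.integer(ndp)))
}

VCF_INFO_DEFS <- c(
  '##INFO=<ID=TLOD,Number=1,Type=Float,Description="Tumor log10 odds of variant vs reference">',
  '##INFO=<ID=NLOD,Number=1,Type=Float,Description="Normal log10 odds of reference vs germline het">',
  '##INFO=<ID=TAF,Number=1,Type=Float,Description="Tumor alternate allele fraction">',
  '##INFO=<ID=TDP,Number=1,Type=Integer,Description="Tumor pileup depth">',
  '##INFO=<ID=NDP,Number=1,Type=Integer,Description="Normal pileup depth">')

#' Call somatic SNVs in one region
#'
#' Pileups of the (recalibrated) tumor and normal shard are matched by
#' position and scored site by site; only in-region positions can be
#' emitted. Equivalent to applying [call_site()] at every tumor column.
#'
#' @param tumor,normal sorted, flagged, recalibrated read tables of the
#'   region shard, one per sample.
#' @param genome a [reference_genome()].
#' @param region list/row with `contig`, `start`, `end`.
#' @param params [caller_params()].
#' @return variant data.table (possibly empty) ordered by position.
#' @export
call_region <- function(tumor, normal, genome, region, params = caller_params()) {
  tcol <- pileup_region(tumor, genome, region, params$min_mapq, params$min_baseq)
  ncol_ <- pileup_region(normal, genome, region, params$min_mapq, params$min_baseq)
  if (!nrow(tcol)) return(empty_variants())
  bases <- c("A", "C", "G", "T")
  nT <- nrow(tcol)
  cntm <- as.matrix(tcol[, paste0("n", bases), with = FALSE])
  qm <- as.matrix(tcol[, paste0("q", bases), with = FALSE])
  refix <- match(tcol$ref, bases)
  sel <- cntm
  hasref <- !is.na(refix)
  sel[cbind(which(hasref), refix[hasref])] <- -1L
  altix <- max.col(sel, ties.method = "first")
  talt <- cntm[cbind(seq_len(nT), altix)]

  keep <- which(talt > 0L)
  if (!length(keep)) return(empty_variants())
  tcol <- tcol[keep]
  altix <- altix[keep]; refix <- refix[keep]; talt <- talt[keep]
  cntm <- cntm[keep, , drop = FALSE]; qm <- qm[keep, , drop = FALSE]
  k <- length(keep)
  tref <- ifelse(is.na(refix), 0L,
                 cntm[cbind(seq_len(k), ifelse(is.na(refix), 1L, refix))])
  eps_ta <- 10^(-qm[cbind(seq_len(k), altix)] / 10)
  eps_tr <- ifelse(tref > 0, 10^(-qm[cbind(seq_len(k), ifelse(is.na(refix), 1L, refix))] / 10), 1e-3)

  nidx <- match(tcol$pos, ncol_$pos)
  hasn <- !is.na(nidx)
  ndepth <- integer(k); nalt <- integer(k); nref <- integer(k)
  eps_na <- rep(1e-3, k); eps_nr <- rep(1e-3, k)
  if (any(hasn)) {
    ncntm <- as.matrix(ncol_[, paste0("n", bases), with = FALSE])
    nqm <- as.matrix(ncol_[, paste0("q", bases), with = FALSE])
    j <- nidx[hasn]
    ndepth[hasn] <- ncol_$depth[j]
    nalt[hasn] <- ncntm[cbind(j, altix[hasn])]
    nref[hasn] <- ifelse(is.na(refix[hasn]), 0L,
                         ncntm[cbind(j, ifelse(is.na(refix[hasn]), 1L, refix[hasn]))])
    ena <- 10^(-nqm[cbind(j, altix[hasn])] / 10)
    enr <- 10^(-nqm[cbind(j, ifelse(is.na(refix[hasn]), 1L, refix[hasn]))] / 10)
    eps_na[hasn] <- ifelse(nalt[hasn] > 0, ena, 1e-3)
    eps_nr[hasn] <- ifelse(nref[hasn] > 0, enr, 1e-3)
  }
  s <- score_sites(tcol$ref, tcol$depth, talt, tref, eps_ta, eps_tr,
                   ndepth, nalt, nref, eps_na, eps_nr)
  emit <- s$tlod >= params$tlod_min & s$nlod >= params$nlod_min &
    tcol$depth >= params$min_depth & s$naf <= params$max_normal_af
  if (!any(emit)) return(empty_variants())
  somatic_record(tcol$contig[emit], tcol$pos[emit], tcol$ref[emit],
                 bases[altix[emit]], s$tlod[emit], s$nlod[emit], s$f[emit],
                 tcol$depth[emit], ndepth[emit])
}

#' Merge per-region VCF shards in genome order
#'
#' @param shards list of variant tables, one per region, in region-ordinal
#'   order.
#' @param spec the `region_spec` the shards were called under; each shard's
#'   records must lie inside its region (error otherwise), which also
#'   guarantees no locus appears twice.
#' @return single variant table in genome order.
#' @export
merge_shard_vcfs <- function(shards, spec) {
  if (length(shards) != n_regions_of(spec))
    stop("shard count differs from region count")
  for (i in seq_along(shards)) {
    s <- shards[[i]]
    if (!nrow(s)) next
    reg <- spec$regions[i]
    if (any(s$contig != reg$contig | s$pos < reg$start | s$pos >= reg$end))
      stop("shard ", i - 1L, " contains a record outside its region")
  }
  merged <- data.table::rbindlist(shards)
  if (!nrow(merged)) return(empty_variants())
  if (anyDuplicated(merged[, c("contig", "pos")]))
    stop("duplicate locus across shards")
  merged[]
}
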