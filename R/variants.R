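# Alignment of read pairs to the RAD contig reference, pileup construction,
# the two-tier variant sets (comprehensive CcRAD1, fully-informative CcRAD2),
# zygosity imputation and testcross/intercross marker classification.

#' Align a single read (or pair) against one contig
#'
#' Seeded banded alignment; both orientations are tried. A read is accepted
#' iff it aligns with at most `max_mm` mismatches and at most `max_gap` nt of
#' gaps; ties are broken by fewest mismatches, then leftmost offset.
#'
#' @param se_seq,pe_seq Mate sequences (`pe_seq = NULL` for a single read).
#' @param contig Contig sequence (single string).
#' @param max_mm,max_gap Acceptance thresholds (defaults 3 and 2).
#' @return List with `accepted` plus per-mate `offset` (0-based),
#'   `mismatches`, `gaps`, `revcomp`. The pair is accepted iff the anchored
#'   single end is accepted.
#' @export
align_read_pair <- function(se_seq, pe_seq = NULL, contig, max_mm = 3, max_gap = 2) {
  if (nchar(contig) < nchar(se_seq))
    return(list(accepted = FALSE, reason = "contig shorter than read"))
  se <- cpp_align_one(se_seq, contig, seed_len = 13L,
                      max_mm = as.integer(max_mm), max_gap = as.integer(max_gap))
  if (!isTRUE(se$accepted)) return(list(accepted = FALSE, se = se))
  pe <- if (!is.null(pe_seq))
    cpp_align_one(pe_seq, contig, seed_len = 13L,
                  max_mm = as.integer(max_mm), max_gap = as.integer(max_gap))
  list(accepted = TRUE, se = se, pe = pe)
}

#' Build a multi-sample pileup over the contig reference
#'
#' Aligns every pair (single end anchors the pair; the mate is restricted to
#' the single end's contig) and accumulates per-sample allele counts: bases,
#' and left-anchored 1-2 nt insertion/deletion alleles (`I:<anchor+ins>`,
#' `D:<len>` keyed at the first deleted base). Depth at a column equals the
#' sum of its allele counts.
#'
#' @param pairs Quality-filtered `rad_read_pairs` of all samples.
#' @param contigs Contig data.frame from [assemble_rad_contigs()] (columns
#'   `contig_id`, `sequence`).
#' @param max_mm,max_gap Per-read alignment acceptance thresholds.
#' @return `rad_pileup`: data.table (`contig_id`, `pos` 0-based, `sample_id`,
#'   `allele`, `count`) with attributes `samples`, `contigs`, `align_stats`.
#' @export
build_pileup <- function(pairs, contigs, max_mm = 3, max_gap = 2) {
  samples <- sort(unique(pairs$sample_id))
  smp <- match(pairs$sample_id, samples)
  res <- cpp_align_pairs(contigs$sequence, pairs$se_seq, pairs$pe_seq,
                         as.integer(smp), length(samples),
                         seed_len = 13L, max_mm = as.integer(max_mm),
                         max_gap = as.integer(max_gap))
  pu <- data.table::as.data.table(res$counts)
  pu[, `:=`(contig_id = contigs$contig_id[contig],
            sample_id = samples[sample])]
  pu[, c("contig", "sample") := NULL]
  # an inserted-allele read also produced a base event at its anchor:
  # re-assign it from the anchor base to the insertion allele
  ins <- pu[startsWith(allele, "I:")]
  if (nrow(ins) > 0) {
    ins_adj <- ins[, .(contig_id, pos, sample_id,
                       allele = substring(allele, 3, 3), adj = count)]
    pu <- merge(pu, ins_adj, by = c("contig_id", "pos", "sample_id", "allele"),
                all.x = TRUE)
    pu[!is.na(pu$adj), count := pmax(0L, count - adj)]
    pu[, adj := NULL]
    pu <- pu[count > 0]
  }
  data.table::setorder(pu, contig_id, pos, sample_id, allele)
  data.table::setcolorder(pu, c("contig_id", "pos", "sample_id", "allele", "count"))
  attr(pu, "samples") <- samples
  attr(pu, "contigs") <- contigs
  attr(pu, "align_stats") <- list(n_pairs = res$n_pairs,
                                  n_se_unaligned = res$n_se_unaligned,
                                  n_pe_unaligned = res$n_pe_unaligned)
  pu
}

indel_span <- function(allele) {
  # length difference vs the reference implied by an allele key
  out <- integer(length(allele))
  d <- startsWith(allele, "D:")
  out[d] <- as.integer(substring(allele[d], 3))
  i <- startsWith(allele, "I:")
  out[i] <- nchar(allele[i]) - 3L
  out
}

#' Call the comprehensive variant set (CcRAD1)
#'
#' A column enters CcRAD1 iff at least two distinct alleles are observed
#' (the strongest alternative supported by `min_alt_reads` reads) and the
#' coverage threshold is met. Indel alleles longer than 2 nt are never
#' emitted. Coverage is pooled across samples by default; `scope =
#' "per_sample"` requires `min_cov` within every sample instead.
#'
#' @param pileup A `rad_pileup`.
#' @param min_cov Minimum coverage (default 6).
#' @param min_alt_reads Minimum reads supporting an alternative allele
#'   (default 1).
#' @param scope `"pooled"` (default) or `"per_sample"`.
#' @return data.table of variant sites: `contig_id`, `pos`, `ref`, `alts`
#'   (comma-joined), `class` (`"SNP"`/`"indel"`), `biallelic`,
#'   `pooled_depth`.
#' @export
call_ccrad1 <- function(pileup, min_cov = 6, min_alt_reads = 1,
                        scope = c("pooled", "per_sample")) {
  scope <- match.arg(scope)
  contigs <- attr(pileup, "contigs")
  samples <- attr(pileup, "samples")
  pu <- pileup[indel_span(allele) <= 2L]
  ag <- pu[, .(count = sum(count)), by = .(contig_id, pos, allele)]
  ref_base <- substring(contigs$sequence[match(ag$contig_id, contigs$contig_id)],
                        ag$pos + 1L, ag$pos + 1L)
  ag[, ref := ref_base]
  sites <- ag[, {
    dep <- as.numeric(sum(count))
    nonref <- .SD[allele != ref[1]]
    best_alt <- if (nrow(nonref)) as.numeric(max(nonref$count)) else 0
    list(ref = ref[1], pooled_depth = dep,
         n_obs_alleles = .N, best_alt = best_alt,
         alts = paste(nonref$allele[order(-nonref$count, nonref$allele)],
                      collapse = ","),
         class = if (nrow(nonref) && any(indel_span(nonref$allele) > 0))
           "indel" else "SNP")
  }, by = .(contig_id, pos)]
  sites <- sites[n_obs_alleles >= 2 & best_alt >= min_alt_reads]
  if (scope == "pooled") {
    sites <- sites[pooled_depth >= min_cov]
  } else {
    per <- pu[, .(d = sum(count)), by = .(contig_id, pos, sample_id)]
    ok <- per[, .(ok = .N == length(samples) && all(d >= min_cov)),
              by = .(contig_id, pos)]
    sites <- merge(sites, ok[ok == TRUE, .(contig_id, pos)],
                   by = c("contig_id", "pos"))
  }
  sites[, biallelic := n_obs_alleles == 2]
  sites[, c("n_obs_alleles", "best_alt") := NULL]
  data.table::setorder(sites, contig_id, pos)
  sites[]
}

#' Impute the zygosity of one sample at one pileup column
#'
#' Decision rules, applied in order: no reads -> `no_call`; three or more
#' alleles each supported by `het_min_reads` reads -> `ambiguous`;
#' heterozygous iff the top-two alleles each have >= `het_min_reads` reads,
#' the minor of the two has within-sample frequency inside `het_window`, the
#' major is below the window top, and depth >= `het_min_depth`; homozygous
#' for the major allele iff the minor-allele frequency (all non-major reads)
#' is below `hom_maf` and depth >= `min_hom_depth`; otherwise `ambiguous`.
#'
#' @param counts Named vector of allele read counts for one sample.
#' @param het_window Within-sample allele frequency window for a het call
#'   (default `c(0.25, 0.75)`, endpoints inclusive).
#' @param het_min_depth,het_min_reads Depth and per-allele read minima for a
#'   het call (defaults 4 and 2).
#' @param hom_maf Strict upper bound on minor allele frequency for a hom
#'   call (default 0.10).
#' @param min_hom_depth Minimum depth for a definite hom call (default 2; a
#'   single read never yields a definite genotype).
#' @return List: `zygosity` (`"het"`, `"hom"`, `"ambiguous"`, `"no_call"`),
#'   `alleles`, `depth`, `minor_freq`.
#' @export
impute_genotype <- function(counts, het_window = c(0.25, 0.75),
                            het_min_depth = 4, het_min_reads = 2,
                            hom_maf = 0.10, min_hom_depth = 2) {
  counts <- counts[counts > 0]
  depth <- sum(counts)
  if (length(counts) == 0 || depth == 0)
    return(list(zygosity = "no_call", alleles = character(), depth = 0,
                minor_freq = NA_real_))
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  a <- names(counts)
  c1 <- counts[1]
  c2 <- if (length(counts) >= 2) counts[2] else 0
  minor_freq <- (depth - c1) / depth  # exact at decimal boundaries
  if (length(counts) >= 3 && counts[3] >= het_min_reads)
    return(list(zygosity = "ambiguous", alleles = a[1:2], depth = depth,
                minor_freq = minor_freq))
  if (c2 >= het_min_reads && depth >= het_min_depth &&
      c2 / depth >= het_window[1] && c1 / depth <= het_window[2])
    return(list(zygosity = "het", alleles = a[1:2], depth = depth,
                minor_freq = minor_freq))
  if (minor_freq < hom_maf && depth >= min_hom_depth)
    return(list(zygosity = "hom", alleles = a[1], depth = depth,
                minor_freq = minor_freq))
  list(zygosity = "ambiguous", alleles = a[seq_len(min(2, length(a)))],
       depth = depth, minor_freq = minor_freq)
}

#' Impute genotypes of every sample at a set of sites
#'
#' Vectorised application of [impute_genotype()] over the (site, sample)
#' grid. Samples with no reads at a site are `no_call`.
#'
#' @param pileup A `rad_pileup`.
#' @param sites Variant sites (from [call_ccrad1()] or [select_ccrad2()]).
#' @param ... Passed to the per-column rules (see [impute_genotype()]).
#' @return data.table: `contig_id`, `pos`, `sample_id`, `zygosity`, `a1`,
#'   `a2` (NA unless het/ambiguous), `depth`, `minor_freq`.
#' @export
impute_genotypes <- function(pileup, sites, het_window = c(0.25, 0.75),
                             het_min_depth = 4, het_min_reads = 2,
                             hom_maf = 0.10, min_hom_depth = 2) {
  samples <- attr(pileup, "samples")
  key <- c("contig_id", "pos")
  pu <- merge(pileup, sites[, key, with = FALSE], by = key)
  st <- pu[order(-count, allele),
           .(depth = sum(count), c1 = count[1], c2 = if (.N >= 2) count[2] else 0L,
             c3 = if (.N >= 3) count[3] else 0L,
             a1 = allele[1], a2 = if (.N >= 2) allele[2] else NA_character_),
           by = .(contig_id, pos, sample_id)]
  grid <- data.table::CJ(site = seq_len(nrow(sites)), sample_id = samples)
  grid <- cbind(sites[grid$site, key, with = FALSE], grid[, .(sample_id)])
  st <- merge(grid, st, by = c(key, "sample_id"), all.x = TRUE)
  st[is.na(depth), `:=`(depth = 0L, c1 = 0L, c2 = 0L, c3 = 0L)]
  st[, minor_freq := ifelse(depth > 0, (depth - c1) / depth, NA_real_)]
  st[, zygosity := "ambiguous"]
  st[depth > 0 & minor_freq < hom_maf & depth >= min_hom_depth, zygosity := "hom"]
  st[depth >= het_min_depth & c2 >= het_min_reads &
       c2 / depth >= het_window[1] & c1 / depth <= het_window[2],
     zygosity := "het"]
  st[c3 >= het_min_reads, zygosity := "ambiguous"]
  st[depth == 0, zygosity := "no_call"]
  st[zygosity == "hom", a2 := NA_character_]
  st[, c("c1", "c2", "c3") := NULL]
  data.table::setorder(st, contig_id, pos, sample_id)
  st[]
}

#' Select the fully-informative variant set (CcRAD2)
#'
#' A CcRAD1 site is retained iff every sample has at least one aligned read
#' at the column (1-read allele calling achieved for each sample).
#'
#' @param sites CcRAD1 sites.
#' @param pileup The `rad_pileup` the sites were called from.
#' @return The retained subset of `sites`.
#' @export
select_ccrad2 <- function(sites, pileup) {
  samples <- attr(pileup, "samples")
  per <- pileup[, .(d = sum(count)), by = .(contig_id, pos, sample_id)]
  ok <- per[, .(n_with_reads = .N), by = .(contig_id, pos)]
  ok <- ok[n_with_reads == length(samples)]
  merge(sites, ok[, .(contig_id, pos)], by = c("contig_id", "pos"))
}

#' Classify markers as testcross / intercross
#'
#' For every ordered pair of samples, a site is a testcross marker of the
#' pair when the first (informative) sample is heterozygous and the second
#' is homozygous; a site heterozygous in all samples is a common intercross
#' marker. Ambiguous or missing genotypes make the involved comparisons
#' uninformative.
#'
#' @param genotypes Output of [impute_genotypes()] at CcRAD2 sites.
#' @return List: `markers` (one row per site with `class` =
#'   `"testcross"`/`"common_intercross"`/`"uninformative"` and, for
#'   testcross events, one row per ordered pair: `informative`, `paired`),
#'   `summary` (per-class site and contig counts).
#' @export
classify_markers <- function(genotypes) {
  samples <- sort(unique(genotypes$sample_id))
  wide <- data.table::dcast(data.table::as.data.table(genotypes),
                            contig_id + pos ~ sample_id, value.var = "zygosity")
  events <- list()
  for (i in samples) for (j in samples) {
    if (i == j) next
    hit <- wide[wide[[i]] == "het" & wide[[j]] == "hom"]
    if (nrow(hit) > 0)
      events[[length(events) + 1]] <- hit[, .(contig_id, pos,
                                              class = "testcross",
                                              informative = i, paired = j)]
  }
  all_het <- wide[Reduce(`&`, lapply(samples, function(s) wide[[s]] == "het"))]
  if (nrow(all_het) > 0)
    events[[length(events) + 1]] <- all_het[, .(contig_id, pos,
                                                class = "common_intercross",
                                                informative = NA_character_,
                                                paired = NA_character_)]
  ev <- if (length(events)) data.table::rbindlist(events) else
    data.table::data.table(contig_id = character(), pos = integer(),
                           class = character(), informative = character(),
                           paired = character())
  key <- paste(wide$contig_id, wide$pos)
  uninf <- !(key %in% paste(ev$contig_id, ev$pos))
  if (any(uninf))
    ev <- rbind(ev, data.table::data.table(
      contig_id = wide$contig_id[uninf], pos = wide$pos[uninf],
      class = "uninformative", informative = NA_character_,
      paired = NA_character_))
  data.table::setorder(ev, contig_id, pos, class, informative)

  lab <- ifelse(ev$class == "testcross",
                paste(ev$informative, "testcross over", ev$paired), ev$class)
  summ <- data.table::as.data.table(ev)[, .(
    n_sites = .N, n_contigs = length(unique(contig_id))), by = .(label = lab)]
  data.table::setorder(summ, label)
  list(markers = ev[], summary = summ[])
}

#' Write called sites and genotypes as VCF 4.2
#'
#' Three (or more) sample columns with GT, AD and DP; contig headers; 1-based
#' positions. Indel alleles are re-anchored to the standard left-anchored
#' VCF representation.
#'
#' @param path Output file.
#' @param sites Variant sites (CcRAD1/CcRAD2).
#' @param genotypes Matching [impute_genotypes()] table.
#' @param pileup The source `rad_pileup` (for AD counts and contig headers).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(path, sites, genotypes, pileup) {
  contigs <- attr(pileup, "contigs")
  samples <- attr(pileup, "samples")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=radsnp",
           sprintf("##contig=<ID=%s,length=%d>", contigs$contig_id,
                   nchar(contigs$sequence)),
           "##INFO=<ID=SET,Number=1,Type=String,Description=\"Variant set\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- character(nrow(sites))
  gt_dt <- data.table::as.data.table(genotypes)
  pu <- data.table::as.data.table(pileup)
  for (k in seq_len(nrow(sites))) {
    s <- sites[k, ]
    cseq <- contigs$sequence[contigs$contig_id == s$contig_id]
    alleles <- strsplit(s$alts, ",", fixed = TRUE)[[1]]
    spec <- vcf_alleles(cseq, s$pos, s$ref, alleles)
    gts <- gt_dt[contig_id == s$contig_id & pos == s$pos]
    pus <- pu[contig_id == s$contig_id & pos == s$pos]
    cols <- vapply(samples, function(sm) {
      g <- gts[sample_id == sm]
      ad <- vapply(c(s$ref, alleles), function(a) {
        x <- pus[sample_id == sm & allele == a]$count
        if (length(x)) sum(x) else 0L
      }, integer(1))
      gt <- "./."
      if (nrow(g) == 1) {
        if (g$zygosity == "hom") {
          i <- spec$index[[g$a1]]
          if (!is.null(i)) gt <- paste0(i, "/", i)
        } else if (g$zygosity == "het") {
          i1 <- spec$index[[g$a1]]; i2 <- spec$index[[g$a2]]
          if (!is.null(i1) && !is.null(i2))
            gt <- paste(sort(c(i1, i2)), collapse = "/")
        }
      }
      paste0(gt, ":", paste(ad, collapse = ","), ":", sum(ad))
    }, character(1))
    rows[k] <- paste(c(s$contig_id, spec$pos1, ".", spec$ref,
                       paste(spec$alt, collapse = ","), ".", "PASS",
                       "SET=CcRAD", "GT:AD:DP", cols), collapse = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# re-anchor allele keys to VCF REF/ALT strings at a site
vcf_alleles <- function(contig_seq, pos0, ref_base, alleles) {
  dels <- alleles[startsWith(alleles, "D:")]
  maxdel <- if (length(dels)) max(as.integer(substring(dels, 3))) else 0L
  if (maxdel > 0) {
    if (pos0 < 1) stop("deletion at contig start cannot be left-anchored")
    a0 <- pos0 - 1L
    anchor <- substring(contig_seq, a0 + 1, a0 + 1)
    ref <- substring(contig_seq, a0 + 1, pos0 + maxdel)
    tail_from <- function(i) substring(contig_seq, i + 1, pos0 + maxdel)
    alt <- vapply(alleles, function(a) {
      if (startsWith(a, "D:")) {
        len <- as.integer(substring(a, 3))
        paste0(anchor, tail_from(pos0 + len))
      } else if (startsWith(a, "I:")) {
        paste0(anchor, substring(a, 3), tail_from(pos0 + 1))
      } else paste0(anchor, a, tail_from(pos0 + 1))
    }, character(1))
    pos1 <- a0 + 1L
  } else {
    ref <- ref_base
    alt <- vapply(alleles, function(a) {
      if (startsWith(a, "I:")) substring(a, 3) else a
    }, character(1))
    pos1 <- pos0 + 1L
  }
  index <- as.list(setNames(seq_along(alleles), alleles))
  index[[ref_base]] <- 0L
  list(pos1 = pos1, ref = ref, alt = alt, index = index)
}

#' Run the variant-calling stage end to end
#'
#' Quality filter, alignment and pileup, CcRAD1 calling, genotype
#' imputation, CcRAD2 selection and marker classification with the default
#' thresholds (coverage >= 6 pooled; het window 0.25-0.75, depth >= 4, two
#' reads per allele; hom MAF < 0.10).
#'
#' @param pairs `rad_read_pairs` of all samples (unfiltered).
#' @param contigs Contig reference from [assemble_rad_contigs()].
#' @param min_cov,min_alt_reads CcRAD1 thresholds (see [call_ccrad1()]).
#' @param het_window,het_min_depth,het_min_reads,hom_maf,min_hom_depth
#'   Zygosity rules (see [impute_genotype()]).
#' @param max_mm,max_gap Alignment acceptance thresholds.
#' @param primary_only Align against NODE1 contigs only (default TRUE), so
#'   alternative haplotype contigs do not absorb one haplotype's reads.
#' @return List: `pileup`, `ccrad1`, `ccrad2`, `genotypes` (at CcRAD2
#'   sites), `markers`, `summary`.
#' @export
call_variants <- function(pairs, contigs, min_cov = 6, min_alt_reads = 1,
                          het_window = c(0.25, 0.75), het_min_depth = 4,
                          het_min_reads = 2, hom_maf = 0.10,
                          min_hom_depth = 2, max_mm = 3, max_gap = 2,
                          primary_only = TRUE) {
  qf <- quality_filter(pairs)
  if (primary_only && !is.null(contigs$node)) {
    # one reference per locus: alternative haplotype contigs would siphon a
    # haplotype's reads and mask heterozygous columns
    contigs <- contigs[contigs$node == "NODE1", , drop = FALSE]
  }
  pileup <- build_pileup(qf, contigs, max_mm = max_mm, max_gap = max_gap)
  ccrad1 <- call_ccrad1(pileup, min_cov = min_cov, min_alt_reads = min_alt_reads)
  ccrad2 <- select_ccrad2(ccrad1, pileup)
  genotypes <- impute_genotypes(pileup, ccrad2, het_window = het_window,
                                het_min_depth = het_min_depth,
                                het_min_reads = het_min_reads,
                                hom_maf = hom_maf, min_hom_depth = min_hom_depth)
  cls <- classify_markers(genotypes)
  list(pileup = pileup, ccrad1 = ccrad1, ccrad2 = ccrad2,
       genotypes = genotypes, markers = cls$markers, summary = cls$summary)
}
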