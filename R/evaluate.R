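# Validation against simulator ground truth: anchoring assembled contigs
# back onto the reference genome and scoring genotype concordance at called
# sites.

#' Anchor contigs onto the simulated reference genome
#'
#' Each contig's leading bases are matched against the two restriction
#' flanks of every planted cut site (Hamming distance, template variants
#' tolerated), then the whole contig is aligned to the corresponding
#' reference region to build an indel-aware position map.
#'
#' @param contigs Contig data.frame ([assemble_rad_contigs()]).
#' @param reference The `rad_reference` the libraries were simulated from.
#' @param max_mm Maximum Hamming distance for flank anchoring (default 8).
#' @return List with `anchors` (data.frame `contig_id`, `chrom`, `cut`,
#'   `side`, `flank_mm`) and `maps` (named list: per contig an integer
#'   vector, genome position of each contig position, NA where inserted).
#' @export
map_contigs_to_reference <- function(contigs, reference, max_mm = 8) {
  rl <- 54L
  ch <- reference$chroms
  fl <- reference$sites
  flanks <- rbind(
    data.frame(chrom = fl$chrom, cut = fl$cut, side = "+",
               seq = substring(ch[fl$chrom], fl$cut + 1, fl$cut + rl)),
    data.frame(chrom = fl$chrom, cut = fl$cut, side = "-",
               seq = revcomp_chr(substring(ch[fl$chrom], fl$cut - rl + 1, fl$cut))))
  ses <- substring(contigs$sequence, 1, rl)
  nf <- nrow(flanks)
  pool <- c(flanks$seq, ses)
  pr <- cpp_hamming_pairs(pool, as.integer(max_mm))
  pr <- pr[pr$i <= nf & pr$j > nf, , drop = FALSE]
  pr$contig <- pr$j - nf

  anchors <- data.frame(contig_id = contigs$contig_id, chrom = NA_character_,
                        cut = NA_integer_, side = NA_character_,
                        flank_mm = NA_integer_, stringsAsFactors = FALSE)
  maps <- vector("list", nrow(contigs))
  names(maps) <- contigs$contig_id
  for (k in seq_len(nrow(contigs))) {
    hits <- pr[pr$contig == k, , drop = FALSE]
    if (nrow(hits) == 0) next
    best <- hits[which.min(hits$dist), ]
    f <- flanks[best$i, ]
    anchors$chrom[k] <- f$chrom
    anchors$cut[k] <- f$cut
    anchors$side[k] <- f$side
    anchors$flank_mm[k] <- best$dist
    L <- nchar(contigs$sequence[k])
    pad <- 30L
    if (f$side == "+") {
      region <- substring(ch[[f$chrom]], f$cut + 1,
                          min(f$cut + L + pad, nchar(ch[[f$chrom]])))
    } else {
      region <- revcomp_chr(substring(ch[[f$chrom]], max(1, f$cut - L - pad + 1),
                                      f$cut))
    }
    to_genome <- function(region_pos0)
      if (f$side == "+") f$cut + region_pos0 else f$cut - 1L - region_pos0
    pm <- rep(NA_integer_, L)
    # the anchor block sits at the cut by construction
    pm[seq_len(rl)] <- to_genome(0:(rl - 1L))
    if (L > rl) {
      # the sheared-end island may start a few bases after the anchor when no
      # minimal-insert read was drawn: align it separately, indel-aware
      island <- substring(contigs$sequence[k], rl + 1, L)
      aln <- Biostrings::pairwiseAlignment(island, region, type = "global-local")
      gp <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      gs <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      si <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
      pi <- 0L
      for (t in seq_along(gp)) {
        has_p <- gp[t] != "-"
        has_s <- gs[t] != "-"
        if (has_p) pi <- pi + 1L
        if (has_p && has_s) pm[rl + pi] <- to_genome(si)
        if (has_s) si <- si + 1L
      }
    }
    maps[[k]] <- pm
  }
  list(anchors = anchors, maps = maps)
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Genotype concordance against simulator truth
#'
#' Translates called site positions to genome coordinates via
#' [map_contigs_to_reference()], looks up the truth genotype of each sample
#' (reference homozygote where no truth variant exists), and scores every
#' definite (het/hom) imputation at SNV sites. Abstentions (`ambiguous`,
#' `no_call`) are reported via `definite_rate`, not counted as errors;
#' truth-indel positions are excluded (coordinate semantics differ across
#' strands).
#'
#' @param genotypes [impute_genotypes()] output at the evaluated sites.
#' @param sites The evaluated site table (e.g. CcRAD2).
#' @param contigs Contig reference.
#' @param reference `rad_reference`.
#' @param truth `derive_accessions()$truth`.
#' @return List: `n_sites`, `n_claims`, `n_match`, `concordance`,
#'   `definite_rate`, `per_sample` (data.frame).
#' @export
genotype_concordance <- function(genotypes, sites, contigs, reference, truth) {
  mp <- map_contigs_to_reference(contigs, reference)
  snv <- sites[sites$class == "SNP", ]
  g <- data.table::as.data.table(genotypes)
  g <- merge(g, snv[, c("contig_id", "pos")], by = c("contig_id", "pos"))
  data.table::setkeyv(g, c("contig_id", "pos", "sample_id"))

  tv <- truth$variants
  tv_key <- paste(tv$CHROM, tv$POS)
  samples <- sort(unique(g$sample_id))
  gt_cols <- c("GT_A", "GT_B", "GT_C")[seq_along(samples)]

  n_claims <- 0L; n_match <- 0L; n_eval <- 0L
  per <- setNames(data.frame(sample = samples, claims = 0L, matches = 0L),
                  c("sample", "claims", "matches"))
  anch <- mp$anchors
  site_keys <- unique(g[, .(contig_id, pos)])
  n_sites_mapped <- 0L
  for (r in seq_len(nrow(site_keys))) {
    cid <- site_keys$contig_id[r]; p <- site_keys$pos[r]
    ai <- match(cid, anch$contig_id)
    if (is.na(anch$chrom[ai])) next
    pm <- mp$maps[[cid]]
    if (p + 1 > length(pm) || is.na(pm[p + 1])) next
    gpos <- pm[p + 1]
    minus <- anch$side[ai] == "-"
    ti <- match(paste(anch$chrom[ai], gpos), tv_key)
    if (!is.na(ti) && tv$CLASS[ti] == "indel") next
    n_sites_mapped <- n_sites_mapped + 1L
    ref_b <- substring(reference$chroms[[anch$chrom[ai]]], gpos + 1, gpos + 1)
    for (si in seq_along(samples)) {
      n_eval <- n_eval + 1L
      row <- g[contig_id == cid & pos == p & sample_id == samples[si]]
      if (nrow(row) != 1 || !(row$zygosity %in% c("het", "hom"))) next
      truth_gt <- if (is.na(ti)) c(ref_b, ref_b) else
        strsplit(tv[[gt_cols[si]]][ti], "/", fixed = TRUE)[[1]]
      called <- if (row$zygosity == "het") c(row$a1, row$a2) else c(row$a1, row$a1)
      if (minus) called <- comp_base(called)
      ok <- setequal(unique(called), unique(truth_gt)) &&
        (length(unique(called)) == length(unique(truth_gt)))
      n_claims <- n_claims + 1L
      per$claims[si] <- per$claims[si] + 1L
      if (ok) { n_match <- n_match + 1L; per$matches[si] <- per$matches[si] + 1L }
    }
  }
  list(n_sites = n_sites_mapped, n_claims = n_claims, n_match = n_match,
       concordance = if (n_claims > 0) n_match / n_claims else NA_real_,
       definite_rate = if (n_eval > 0) n_claims / n_eval else NA_real_,
       per_sample = per)
}
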