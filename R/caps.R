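# Conversion of SNPs to CAPS assays: allele-differential restriction sites,
# amplicon fragment prediction, the gel-detectability design filter, and
# scoring of observed digestion patterns into genotypes.

apply_allele <- function(sequence, pos0, ref, alt) {
  if (substring(sequence, pos0 + 1, pos0 + nchar(ref)) != ref)
    stop("variant inconsistent with the contig sequence at position ", pos0)
  paste0(substring(sequence, 1, pos0), alt,
         substring(sequence, pos0 + nchar(ref) + 1, nchar(sequence)))
}

#' Find allele-differential restriction sites for a variant
#'
#' Builds the reference- and alternative-allele sequences and reports every
#' (enzyme, cut) present under exactly one allele. Cut coordinates of the
#' alternative allele downstream of an indel are mapped back to the
#' reference frame, so a shared downstream site is never reported as
#' differential.
#'
#' @param contig Contig sequence (single string).
#' @param pos0 0-based variant position on the contig.
#' @param ref,alt Reference and alternative alleles (VCF-style left-anchored
#'   for indels).
#' @param enzymes Character vector of enzyme names (default: the full CAPS
#'   panel, PstI excluded).
#' @return data.frame `enzyme`, `cut` (0-based, reference frame), `strand`,
#'   `cutting_allele` (`"ref"`/`"alt"`).
#' @export
differential_digestion <- function(contig, pos0, ref, alt,
                                   enzymes = setdiff(enzyme_registry()$name, "PstI")) {
  seq_ref <- contig
  seq_alt <- apply_allele(contig, pos0, ref, alt)
  shift <- nchar(alt) - nchar(ref)
  out <- list()
  for (e in enzymes) {
    sr <- find_recognition_sites(seq_ref, e)
    sa <- find_recognition_sites(seq_alt, e)
    # map alt-frame cuts back to the reference frame
    sa$cut_ref <- ifelse(sa$cut > pos0 + nchar(alt) - 1, sa$cut - shift, sa$cut)
    ref_only <- sr[!(sr$cut %in% sa$cut_ref), , drop = FALSE]
    alt_only <- sa[!(sa$cut_ref %in% sr$cut), , drop = FALSE]
    if (nrow(ref_only))
      out[[length(out) + 1]] <- data.frame(enzyme = e, cut = ref_only$cut,
                                           strand = ref_only$strand,
                                           cutting_allele = "ref")
    if (nrow(alt_only))
      out[[length(out) + 1]] <- data.frame(enzyme = e, cut = alt_only$cut_ref,
                                           strand = alt_only$strand,
                                           cutting_allele = "alt")
  }
  if (length(out) == 0)
    return(data.frame(enzyme = character(), cut = integer(), strand = character(),
                      cutting_allele = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$enzyme, res$cut), , drop = FALSE]
}

# minimum pairwise difference among the distinct fragment lengths of the two
# homozygote patterns (gel detectability margin)
min_fragment_difference <- function(frags_a, frags_b) {
  u <- sort(unique(c(frags_a, frags_b)))
  if (length(u) < 2) return(Inf)
  min(diff(u))
}

#' Design CAPS assays for a variant on a contig
#'
#' The amplicon is placed geometrically: primer landing sites are confined
#' to `primer_window` nt at either contig end, and the product is trimmed
#' symmetrically towards `product_range` when the contig is longer than the
#' maximum product. For every differential site inside the amplicon, both
#' homozygote fragment patterns are predicted (all cuts of the enzyme under
#' that allele, shared sites included); the assay is accepted iff the
#' minimum pairwise difference among the distinct fragment lengths of the
#' two patterns is at least `min_frag_diff` (agarose-gel detectability).
#'
#' @param contig Contig sequence.
#' @param pos0,ref,alt The variant (as in [differential_digestion()]).
#' @param enzymes Enzyme panel.
#' @param product_range Allowed product sizes, nt (default `c(100, 400)`).
#' @param primer_window Primer placement window at each contig end (default
#'   50 nt).
#' @param min_frag_diff Minimum fragment-size difference (default 20 nt).
#' @return data.frame of accepted assays: `enzyme`, `amp_start`, `amp_end`,
#'   `product_size`, `cut_positions_ref`, `cut_positions_alt` (comma
#'   strings, amplicon frame), `fragments_hom_uncut`, `fragments_hom_cut`,
#'   `fragments_het`, `cutting_allele`, `fragment_size_difference`.
#'   Attribute `rejected` lists candidate sites that failed the margin.
#' @export
design_caps_assays <- function(contig, pos0, ref, alt,
                               enzymes = setdiff(enzyme_registry()$name, "PstI"),
                               product_range = c(100, 400),
                               primer_window = 50, min_frag_diff = 20) {
  L <- nchar(contig)
  if (L < product_range[1])
    stop("contig shorter than the minimum product size")
  amp_start <- 0L
  amp_end <- L
  if (L > product_range[2]) {
    trim <- L - product_range[2]
    amp_start <- min(primer_window, ceiling(trim / 2))
    amp_end <- L - min(primer_window, floor(trim / 2))
    if (amp_end - amp_start > product_range[2])
      stop("contig too long: product cannot reach the size bound from the ",
           primer_window, " nt primer windows")
  }
  if (pos0 < amp_start || pos0 >= amp_end)
    stop("variant outside the feasible amplicon")
  amp <- substring(contig, amp_start + 1, amp_end)
  psize <- amp_end - amp_start

  diffs <- differential_digestion(amp, pos0 - amp_start, ref, alt, enzymes)
  seq_alt <- apply_allele(amp, pos0 - amp_start, ref, alt)
  accepted <- list(); rejected <- list()
  for (e in unique(diffs$enzyme)) {
    cuts_ref <- find_recognition_sites(amp, e)
    cuts_alt <- find_recognition_sites(seq_alt, e)
    cr <- sort(unique(cuts_ref$cut[cuts_ref$cut > 0 & cuts_ref$cut < psize]))
    ca <- sort(unique(cuts_alt$cut[cuts_alt$cut > 0 & cuts_alt$cut < nchar(seq_alt)]))
    fr <- predict_fragments(psize, cr)
    fa <- predict_fragments(nchar(seq_alt), ca)
    margin <- min_fragment_difference(fr, fa)
    row <- data.frame(
      enzyme = e, amp_start = amp_start, amp_end = amp_end,
      product_size = psize,
      cut_positions_ref = paste(cr, collapse = ","),
      cut_positions_alt = paste(ca, collapse = ","),
      fragments_hom_uncut = paste(if (length(cr) <= length(ca)) fr else fa, collapse = ","),
      fragments_hom_cut = paste(if (length(cr) <= length(ca)) fa else fr, collapse = ","),
      fragments_het = paste(sort(unique(c(fr, fa)), decreasing = TRUE), collapse = ","),
      cutting_allele = if (length(ca) > length(cr)) "alt" else "ref",
      fragment_size_difference = margin,
      stringsAsFactors = FALSE)
    if (is.finite(margin) && margin >= min_frag_diff)
      accepted[[length(accepted) + 1]] <- row
    else rejected[[length(rejected) + 1]] <- row
  }
  out <- if (length(accepted)) do.call(rbind, accepted) else
    utils::head(data.frame(enzyme = character(), amp_start = integer(),
                           amp_end = integer(), product_size = integer(),
                           cut_positions_ref = character(),
                           cut_positions_alt = character(),
                           fragments_hom_uncut = character(),
                           fragments_hom_cut = character(),
                           fragments_het = character(),
                           cutting_allele = character(),
                           fragment_size_difference = numeric()), 0)
  attr(out, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else NULL
  out
}

parse_frags <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1]])

#' Score an observed digestion pattern into a genotype
#'
#' Matches the observed fragment sizes against the three predicted patterns
#' (homozygous uncut, homozygous cut, heterozygous = union of the two)
#' within a relative gel tolerance. No or ambiguous match returns
#' `"unscored"`.
#'
#' @param observed Numeric vector of observed fragment sizes (bands).
#' @param assay One row of [design_caps_assays()] output.
#' @param tol Relative size tolerance per band (default 0.05).
#' @return `"hom_uncut"`, `"hom_cut"`, `"het"` or `"unscored"`.
#' @export
score_caps_pattern <- function(observed, assay, tol = 0.05) {
  if (length(observed) == 0) stop("empty observation")
  pats <- list(hom_uncut = parse_frags(assay$fragments_hom_uncut),
               hom_cut = parse_frags(assay$fragments_hom_cut),
               het = parse_frags(assay$fragments_het))
  match_pat <- function(obs, pat) {
    obs <- sort(unique(obs)); pat <- sort(unique(pat))
    if (length(obs) != length(pat)) return(FALSE)
    all(abs(obs - pat) <= tol * pat)
  }
  hits <- names(pats)[vapply(pats, match_pat, logical(1), obs = observed)]
  if (length(hits) == 1) hits else "unscored"
}

#' Digest a diploid amplicon pair into the observed band set
#'
#' Convenience for in-silico genotyping: digests both haplotype amplicons
#' with one enzyme and returns the union of fragment lengths (the bands a
#' gel would show, co-migrating duplicates merged).
#'
#' @param amplicons Character vector of the two haplotype sequences.
#' @param enzyme Enzyme name.
#' @return Sorted integer vector of band sizes.
#' @export
digest_amplicons <- function(amplicons, enzyme) {
  sort(unique(unlist(lapply(amplicons, function(s) digest(s, enzyme)$length))))
}

#' Packaged CAPS validation panel
#'
#' The 24 CAPS assays used to validate RAD-derived SNP calls in the
#' *Cynara cardunculus* mapping parents: per assay the enzyme, predicted
#' product size and cut coordinate, the published restriction products of
#' the homozygous and heterozygous parent, the observed segregation outcome
#' and the linkage-group placement. Transcribed verbatim, including the
#' panel's internal arithmetic inconsistencies (see the methods vignette).
#'
#' @return data.frame with one row per assay.
#' @export
caps_validation_table <- function() {
  path <- system.file("extdata", "caps_validation_assays.tsv", package = "radsnp")
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
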