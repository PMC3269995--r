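# RAD locus clustering and per-locus contig assembly: quality screen,
# exact-identity single-end clustering with coverage bounds, mini de Bruijn
# assembly per locus over a k sweep, and the contig-level filters.

#' Quality-filter read pairs
#'
#' A read fails when it has more than `max_low` bases at or below
#' `phred_threshold`; a pair is discarded when either mate fails.
#'
#' @param pairs `rad_read_pairs` table.
#' @param max_low Maximum tolerated low-quality bases per read (default 5).
#' @param phred_threshold Phred score at or below which a base counts as
#'   low quality (default 10).
#' @return The retained pairs; attribute `discard_log` holds a data.table of
#'   dropped read ids with the failing mate(s).
#' @export
quality_filter <- function(pairs, max_low = 5, phred_threshold = 10) {
  if (any(nchar(pairs$se_qual) != nchar(pairs$se_seq)) ||
      any(nchar(pairs$pe_qual) != nchar(pairs$pe_seq)))
    stop("quality strings must match sequence lengths")
  code <- 33L + as.integer(phred_threshold)
  low1 <- cpp_count_lowq(pairs$se_qual, code)
  low2 <- cpp_count_lowq(pairs$pe_qual, code)
  bad <- low1 > max_low | low2 > max_low
  log <- data.table::data.table(
    read_id = pairs$read_id[bad],
    se_failed = low1[bad] > max_low,
    pe_failed = low2[bad] > max_low)
  out <- pairs[!bad, ]
  attr(out, "discard_log") <- log
  out
}

#' Cluster reads by exact single-end identity
#'
#' Reads sharing a byte-identical single-end sequence form one cluster
#' (candidate RAD locus). Clusters outside the coverage bounds are removed:
#' too shallow is noise, too deep is repetitive DNA. Reads of all samples are
#' pooled; sample identity is retained on the members.
#'
#' @param pairs Quality-filtered `rad_read_pairs`.
#' @param min_cov,max_cov Inclusive coverage bounds (defaults 25 and 400).
#' @return data.table of retained pairs with added `cluster_id` and cluster
#'   `coverage`; attribute `clusters` summarises each retained cluster
#'   (`cluster_id`, `se_representative`, `coverage`).
#' @export
cluster_single_ends <- function(pairs, min_cov = 25, max_cov = 400) {
  dt <- data.table::as.data.table(pairs)
  if (nrow(dt) == 0) {
    attr(dt, "clusters") <- data.table::data.table(
      cluster_id = integer(), se_representative = character(), coverage = integer())
    return(dt)
  }
  dt[, coverage := .N, by = se_seq]
  dt <- dt[coverage >= min_cov & coverage <= max_cov]
  reps <- unique(dt$se_seq)
  dt[, cluster_id := match(se_seq, reps)]
  summary <- unique(dt[, .(cluster_id, se_representative = se_seq, coverage)])
  data.table::setorder(summary, cluster_id)
  attr(dt, "clusters") <- summary
  dt
}

#' Assemble one RAD locus
#'
#' Builds a per-locus de Bruijn graph from the single-end representative and
#' the paired-end mates (both orientations) for each k in `k_values`, walks
#' from the anchor, and keeps the distinct resulting contigs. Contigs are
#' prefix-anchored on the SE representative; a clean two-way branch (the two
#' haplotypes) forks the walk once, any other ambiguity stops it. Surviving
#' distinct sequences are ordered by (length, mean k-mer coverage) and
#' labelled NODE1, NODE2, ...
#'
#' @param se_representative Anchor sequence (cluster representative).
#' @param pe_seqs Character vector of mate sequences of the cluster members.
#' @param k_values k sweep (default `c(21, 25, 29, 33)`).
#' @param min_count Minimum k-mer support to extend (default 2).
#' @param branch_frac Minority support fraction that makes a two-way branch a
#'   haplotype fork rather than noise (default 0.25).
#' @param max_nodes Maximum alternative contigs kept per locus (default 3).
#' @return data.frame `node`, `sequence`, `length`, `kmer_cov`; zero rows if
#'   no contig extends beyond the anchor.
#' @export
assemble_locus <- function(se_representative, pe_seqs,
                           k_values = c(21, 25, 29, 33),
                           min_count = 2, branch_frac = 0.25, max_nodes = 3) {
  if (length(k_values) == 0) stop("k_values must be non-empty")
  if (any(k_values < 2)) stop("k values must be >= 2")
  # locus-forward orientation: mates are sequenced toward the cut site
  reads <- c(se_representative, revcomp_chr(pe_seqs))
  res <- cpp_assemble_locus(reads, se_representative, as.integer(sort(k_values)),
                            as.integer(min_count), branch_frac,
                            max_forks = 1L, max_len = 5000L)
  cand <- data.frame(sequence = res$sequence, kmer_cov = res$kmer_cov,
                     stringsAsFactors = FALSE)
  if (nrow(cand) == 0) return(empty_contigs())
  # collapse across the k sweep: exact duplicates, then proper substrings
  cand <- cand[order(-nchar(cand$sequence), -cand$kmer_cov), , drop = FALSE]
  cand <- cand[!duplicated(cand$sequence), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(cand))) {
      if (i != j && keep[j] && nchar(cand$sequence[j]) <= nchar(cand$sequence[i]) &&
          grepl(cand$sequence[j], cand$sequence[i], fixed = TRUE))
        keep[j] <- (nchar(cand$sequence[j]) == nchar(cand$sequence[i]))
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- utils::head(cand, max_nodes)
  data.frame(node = paste0("NODE", seq_len(nrow(cand))),
             sequence = cand$sequence,
             length = nchar(cand$sequence),
             kmer_cov = cand$kmer_cov,
             stringsAsFactors = FALSE)
}

empty_contigs <- function() {
  data.frame(node = character(), sequence = character(), length = integer(),
             kmer_cov = numeric(), stringsAsFactors = FALSE)
}

#' Contig-level filters
#'
#' Removes contigs shorter than `min_len`, with paired-end coverage below
#' `min_pecov`, or containing a run of two or more N. Order is preserved and
#' the operation is idempotent.
#'
#' @param contigs data.frame with at least `sequence`, `length`,
#'   `pe_coverage`.
#' @param min_len Minimum length (default 100).
#' @param min_pecov Minimum paired-end coverage (default 4.0).
#' @return Filtered data.frame.
#' @export
filter_contigs <- function(contigs, min_len = 100, min_pecov = 4.0) {
  if (nrow(contigs) == 0) return(contigs)
  keep <- contigs$length >= min_len &
    contigs$pe_coverage >= min_pecov &
    !grepl("NN", contigs$sequence, fixed = TRUE)
  contigs[keep, , drop = FALSE]
}

#' Assembly summary statistics
#'
#' N50 is the largest length L such that contigs of length >= L cover at
#' least half of the assembly; `alternative_fraction` is the share of loci
#' with more than one contig (alternative assemblies).
#'
#' @param contigs Non-empty contig data.frame (columns `sequence`, `length`,
#'   optionally `locus_id`).
#' @return List: `contig_count`, `total_bp`, `mean_length`, `n50`,
#'   `gc_fraction`, `alternative_fraction`.
#' @export
assembly_stats <- function(contigs) {
  if (nrow(contigs) == 0) stop("no contigs")
  len <- sort(contigs$length, decreasing = TRUE)
  total <- sum(len)
  n50 <- len[which(cumsum(len) >= total / 2)[1]]
  alt <- if (!is.null(contigs$locus_id)) {
    tab <- table(contigs$locus_id)
    mean(tab > 1)
  } else 0
  list(contig_count = nrow(contigs),
       total_bp = total,
       mean_length = mean(contigs$length),
       n50 = n50,
       gc_fraction = gc_fraction(contigs$sequence),
       alternative_fraction = alt)
}

#' Full RAD contig assembly
#'
#' The pipeline stage: quality filter, exact-identity SE clustering with
#' coverage bounds on the template sample, merging of allelic clusters whose
#' representatives differ by at most `merge_mismatch` nt (heterozygous or
#' diverged cut flanks -> one locus, one reference), per-locus assembly over
#' the k sweep, paired-end coverage estimation by k-mer read placement, and
#' the contig filters.
#'
#' @param pairs `rad_read_pairs` (all samples).
#' @param template `"auto"` (sample with most retained reads, the default),
#'   `"pooled"`, or a sample id: which reads seed clusters and contigs.
#' @param k_values,min_cov,max_cov,min_len,min_pecov,merge_mismatch Tuning
#'   knobs; defaults follow the package's standard settings (k sweep
#'   21/25/29/33, SE coverage 25-400, length >= 100, PE coverage >= 4).
#' @param coverage_scope `"pooled"` (default) applies the SE coverage bounds
#'   to reads pooled over samples; `"per_sample"` requires the bounds within
#'   the template sample.
#' @return data.frame of contigs: `contig_id` (`locus<i>_NODE<j>`),
#'   `locus_id`, `node`, `sequence`, `length`, `kmer_cov`, `pe_coverage`,
#'   `se_representative`. Attribute `log` records drop counts.
#' @export
assemble_rad_contigs <- function(pairs,
                                 template = "auto",
                                 k_values = c(21, 25, 29, 33),
                                 min_cov = 25, max_cov = 400,
                                 min_len = 100, min_pecov = 4.0,
                                 merge_mismatch = 3,
                                 coverage_scope = c("pooled", "per_sample")) {
  coverage_scope <- match.arg(coverage_scope)
  qf <- quality_filter(pairs)
  if (identical(template, "auto")) {
    tab <- sort(table(qf$sample_id), decreasing = TRUE)
    template <- names(tab)[1]
  }
  tmpl <- if (identical(template, "pooled")) qf else qf[qf$sample_id == template, ]
  if (identical(template, "pooled") || coverage_scope == "per_sample") {
    cl <- cluster_single_ends(tmpl, min_cov = min_cov, max_cov = max_cov)
  } else {
    # cluster on the template, but evaluate the coverage bounds on reads
    # pooled across all samples sharing the exact SE sequence
    cl <- cluster_single_ends(tmpl, min_cov = 1, max_cov = Inf)
    pooled <- table(qf$se_seq)
    reps0 <- attr(cl, "clusters")
    pooled_cov <- as.integer(pooled[reps0$se_representative])
    ok <- pooled_cov >= min_cov & pooled_cov <= max_cov
    keep_ids <- reps0$cluster_id[ok]
    cl <- cl[cl$cluster_id %in% keep_ids, ]
    attr(cl, "clusters") <- reps0[ok, ]
  }
  clusters <- attr(cl, "clusters")
  if (nrow(clusters) == 0) {
    out <- cbind(empty_contigs(), contig_id = character(), locus_id = integer(),
                 pe_coverage = numeric(), se_representative = character())
    return(out)
  }

  # merge allelic clusters (SE representatives within merge_mismatch)
  grp <- seq_len(nrow(clusters))
  if (merge_mismatch > 0 && nrow(clusters) > 1) {
    pr <- cpp_hamming_pairs(clusters$se_representative, as.integer(merge_mismatch))
    if (nrow(pr) > 0) {
      find <- function(i) { while (grp[i] != i) { grp[i] <<- grp[grp[i]]; i <- grp[i] }; i }
      for (k in seq_len(nrow(pr))) {
        a <- find(pr$i[k]); b <- find(pr$j[k])
        if (a != b) grp[max(a, b)] <- min(a, b)
      }
      grp <- vapply(seq_along(grp), find, 1L)
    }
  }
  clusters$locus <- match(grp, sort(unique(grp)))

  cl_dt <- data.table::as.data.table(cl)
  cl_dt[, locus := clusters$locus[match(cluster_id, clusters$cluster_id)]]

  out <- vector("list", max(clusters$locus))
  dropped_anchorless <- 0L
  for (lid in sort(unique(clusters$locus))) {
    members <- cl_dt[locus == lid]
    sub <- clusters[clusters$locus == lid, ]
    anchor <- sub$se_representative[which.max(sub$coverage)]
    ctg <- assemble_locus(anchor, members$pe_seq, k_values = k_values)
    if (nrow(ctg) == 0) { dropped_anchorless <- dropped_anchorless + 1L; next }
    mapped <- cpp_map_reads_kmer(ctg$sequence, revcomp_chr(members$pe_seq), 21L)
    rl <- nchar(members$pe_seq[1])
    ctg$pe_coverage <- mapped * rl / ctg$length
    ctg$locus_id <- lid
    ctg$se_representative <- anchor
    out[[lid]] <- ctg
  }
  contigs <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(contigs)) contigs <- cbind(empty_contigs(), pe_coverage = numeric(),
                                         locus_id = integer(), se_representative = character())
  n_pre <- nrow(contigs)
  contigs <- filter_contigs(contigs, min_len = min_len, min_pecov = min_pecov)
  if (nrow(contigs) > 0) {
    # re-letter nodes within locus after filtering
    contigs$node <- stats::ave(seq_len(nrow(contigs)), contigs$locus_id,
                               FUN = seq_along)
    contigs$node <- paste0("NODE", contigs$node)
    contigs$contig_id <- paste0("locus", contigs$locus_id, "_", contigs$node)
    rownames(contigs) <- NULL
    contigs <- contigs[, c("contig_id", "locus_id", "node", "sequence", "length",
                           "kmer_cov", "pe_coverage", "se_representative")]
  }
  attr(contigs, "log") <- list(
    template = template,
    n_pairs_in = nrow(pairs), n_pairs_qf = nrow(qf),
    n_clusters = nrow(clusters), n_loci = length(unique(clusters$locus)),
    dropped_anchorless = dropped_anchorless,
    dropped_by_filters = n_pre - nrow(contigs))
  contigs
}
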