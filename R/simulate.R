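# Synthetic three-parent RAD experiment generator. Every downstream stage
# (assembly, variant calling, CAPS, linkage) can be exercised against the
# ground truth this module records.

#' Simulation parameters for a three-parent RAD experiment
#'
#' Defaults mirror the experiment the package emulates: paired-end 2x54 nt
#' reads anchored at PstI (CTGCAG) sites, shear-derived inserts size-selected
#' to 300-800 nt (mean 500), three accessions differing at 5.6 variants per
#' 1,000 nt with unequal sequencing depth (weights 1.2 : 2.6 : 5.9), and 94
#' F1 progeny.
#'
#' @param genome_length Total genome length in nt.
#' @param n_chromosomes Number of chromosomes (equal lengths).
#' @param pstI_site_spacing Mean nt between planted CTGCAG sites.
#' @param divergence_rate Pairwise variant rate between accessions, per nt.
#' @param het_rate Per-nt heterozygosity of the three accessions.
#' @param indel_fraction Fraction of variants that are 1-2 nt indels.
#' @param site_loss_fraction Per-accession fraction of RAD cut sites destroyed
#'   on both haplotypes (taxon-specific locus dropout). No published estimate
#'   exists; exposed as a free parameter.
#' @param read_length Read length in nt (both mates).
#' @param insert_range Min/max insert (cut site to shear point), nt.
#' @param insert_mean,insert_sd Truncated-normal shear model parameters.
#' @param insert_dist `"truncnorm"` (default) or `"uniform"` within
#'   `insert_range`.
#' @param depth_weights Relative per-sample read counts.
#' @param error_rate Per-base substitution error probability.
#' @param lowq_fraction Fraction of reads given six Phred-10 bases, to
#'   exercise the quality filter.
#' @param gc Background GC fraction of the simulated genome.
#' @param n_progeny F1 population size.
#' @param seed Integer seed; all generator stages derive their streams from it.
#' @return An object of class `sim_params` (validated list).
#' @export
sim_params <- function(genome_length = 2e6,
                       n_chromosomes = 1,
                       pstI_site_spacing = 5000,
                       divergence_rate = 0.0056,
                       het_rate = c(0.001, 0.002, 0.004),
                       indel_fraction = 0.045,
                       site_loss_fraction = 0.05,
                       read_length = 54,
                       insert_range = c(300, 800),
                       insert_mean = 500,
                       insert_sd = 100,
                       insert_dist = c("truncnorm", "uniform"),
                       depth_weights = c(1.2, 2.6, 5.9),
                       error_rate = 0.001,
                       lowq_fraction = 0,
                       gc = 0.374,
                       n_progeny = 94,
                       seed = 1) {
  insert_dist <- match.arg(insert_dist)
  p <- list(genome_length = as.numeric(genome_length),
            n_chromosomes = as.integer(n_chromosomes),
            pstI_site_spacing = as.numeric(pstI_site_spacing),
            divergence_rate = divergence_rate,
            het_rate = het_rate,
            indel_fraction = indel_fraction,
            site_loss_fraction = site_loss_fraction,
            read_length = as.integer(read_length),
            insert_range = as.numeric(insert_range),
            insert_mean = insert_mean, insert_sd = insert_sd,
            insert_dist = insert_dist,
            depth_weights = depth_weights,
            error_rate = error_rate,
            lowq_fraction = lowq_fraction,
            gc = gc,
            n_progeny = as.integer(n_progeny),
            seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  if (p$genome_length <= 0) stop("genome_length must be > 0")
  if (p$n_chromosomes < 1) stop("n_chromosomes must be >= 1")
  rates <- c(p$divergence_rate, p$het_rate, p$indel_fraction,
             p$site_loss_fraction, p$error_rate, p$lowq_fraction, p$gc)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (length(p$het_rate) != 3) stop("het_rate must have length 3")
  if (length(p$insert_range) != 2 || diff(p$insert_range) < 0)
    stop("insert_range must be c(min, max) with min <= max")
  if (p$insert_range[1] < 2 * p$read_length)
    stop("insert_range min must be >= 2 * read_length")
  if (length(p$depth_weights) != 3 || any(p$depth_weights <= 0))
    stop("depth_weights must be three positive values")
  if (p$pstI_site_spacing < 2 * p$insert_range[2])
    stop("pstI_site_spacing < 2 * max insert: RAD loci would overlap ambiguously")
  if (p$n_progeny < 1) stop("n_progeny must be >= 1")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("RAD simulation parameters\n")
  cat(sprintf("  genome: %s nt over %d chromosome(s), PstI spacing ~%s nt, GC %.1f%%\n",
              format(x$genome_length, big.mark = ","), x$n_chromosomes,
              format(x$pstI_site_spacing, big.mark = ","), 100 * x$gc))
  cat(sprintf("  divergence %.4f/nt, het %s, indel fraction %.3f\n",
              x$divergence_rate, paste(x$het_rate, collapse = "/"), x$indel_fraction))
  cat(sprintf("  reads 2x%d nt, inserts [%d, %d] (%s), depth weights %s\n",
              x$read_length, x$insert_range[1], x$insert_range[2], x$insert_dist,
              paste(x$depth_weights, collapse = ":")))
  invisible(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

revcomp_chr <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

#' Simulate a haploid reference genome with planted PstI sites
#'
#' Background sequence is i.i.d. at the configured GC; CTGCAG sites are
#' planted at roughly even spacing (10\% jitter) and every spurious
#' occurrence of the recognition sequence is removed by resampling, so the
#' RAD locus inventory is known exactly.
#'
#' @param params A [sim_params()] object.
#' @return Object of class `rad_reference`: list with `chroms` (named
#'   character vector), `sites` (data.frame `chrom`, `start` 0-based pattern
#'   start, `cut` 0-based top-strand cut coordinate) and `params`.
#' @export
simulate_reference <- function(params) {
  validate_sim_params(params)
  with_seed(params$seed, {
    chrom_len <- floor(params$genome_length / params$n_chromosomes)
    if (chrom_len < 2 * params$pstI_site_spacing)
      stop("chromosomes too short for the requested site spacing")
    chroms <- character(params$n_chromosomes)
    names(chroms) <- paste0("chr", seq_len(params$n_chromosomes))
    sites <- vector("list", params$n_chromosomes)
    margin <- params$insert_range[2] + 10
    for (ci in seq_len(params$n_chromosomes)) {
      s <- random_dna(chrom_len, params$gc)
      sp <- params$pstI_site_spacing
      n_sites <- max(1L, floor((chrom_len - 2 * margin) / sp))
      centers <- margin + sp * (seq_len(n_sites) - 0.5)
      starts <- round(centers + runif(n_sites, -0.1 * sp, 0.1 * sp))
      for (st in starts)
        substr(s, st + 1, st + 6) <- "CTGCAG"
      # purge spurious recognition sites (background or junction artefacts)
      for (iter in 1:100) {
        occ <- gregexpr("CTGCAG", s, fixed = TRUE)[[1]]
        occ <- occ[occ > 0] - 1L
        spurious <- setdiff(occ, starts)
        if (length(spurious) == 0) break
        for (sp0 in spurious) {
          repl <- random_dna(6, params$gc)
          substr(s, sp0 + 1, sp0 + 6) <- repl
        }
      }
      chroms[ci] <- s
      sites[[ci]] <- data.frame(chrom = names(chroms)[ci], start = as.integer(starts),
                                stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, sites)
    sites$cut <- sites$start + 5L  # PstI CTGCA^G
    structure(list(chroms = chroms, sites = sites, params = params),
              class = "rad_reference")
  })
}

#' @export
print.rad_reference <- function(x, ...) {
  cat(sprintf("rad_reference: %d chromosome(s), %s nt, %d planted PstI sites\n",
              length(x$chroms), format(sum(nchar(x$chroms)), big.mark = ","),
              nrow(x$sites)))
  invisible(x)
}

# draw variant positions on one chromosome, outside site windows, min 4 nt apart
draw_positions <- function(chrom_len, rate, forbidden) {
  n <- rbinom(1, chrom_len, rate)
  if (n == 0) return(integer())
  pos <- sort(sample.int(chrom_len - 10L, n))
  pos <- pos[!(pos %in% forbidden)]
  if (length(pos) > 1) pos <- pos[c(TRUE, diff(pos) >= 4)]
  pos
}

draw_alt <- function(ref_base, n) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) sample(setdiff(bases, ref_base[i]), 1), "")
}

#' Derive three diploid accessions and the ground-truth variant table
#'
#' Each accession's consensus is mutated away from the reference at half the
#' pairwise divergence rate (so any two accessions differ at approximately
#' `divergence_rate` per nt); within-accession heterozygosity is added to the
#' second haplotype at the accession's `het_rate`. A configurable fraction of
#' planted PstI sites is destroyed homozygously per accession, producing
#' taxon-specific RAD locus dropout. All introduced variants (SNPs and 1-2 nt
#' left-anchored indels) are enumerated in the truth table.
#'
#' @param reference A `rad_reference` from [simulate_reference()].
#' @param params The same [sim_params()] object.
#' @return List of class `rad_accessions`: `accessions` (list of three, each
#'   with `accession_id`, `role`, `haplotypes` = list of two named character
#'   vectors), `truth` (list with `variants` and `loci` data.frames).
#' @export
derive_accessions <- function(reference, params) {
  stopifnot(inherits(reference, "rad_reference"))
  if (length(params$het_rate) != 3) stop("het_rate must have length 3")
  with_seed(params$seed + 1L, {
    ids <- c("accA", "accB", "accC")
    roles <- c("parentA", "parentB", "reference_donor")
    chroms <- reference$chroms
    site_win <- unlist(lapply(seq_len(nrow(reference$sites)), function(i)
      reference$sites$start[i] + 0:5), use.names = FALSE)
    site_chrom <- rep(reference$sites$chrom, each = 6)

    all_edits <- list()
    for (ai in 1:3) {
      for (cn in names(chroms)) {
        L <- nchar(chroms[[cn]])
        forb <- site_win[site_chrom == cn]
        cons_pos <- draw_positions(L, params$divergence_rate / 2, forb)
        het_pos <- draw_positions(L, params$het_rate[ai], c(forb, cons_pos,
                                                            cons_pos + 1, cons_pos + 2,
                                                            cons_pos - 1, cons_pos - 2))
        ed <- make_edits(chroms[[cn]], cn, c(cons_pos, het_pos),
                         c(rep("both", length(cons_pos)), rep("hap2", length(het_pos))),
                         params$indel_fraction)
        # destroyed cut sites: homozygous substitution inside the hexamer
        ssel <- reference$sites[reference$sites$chrom == cn, , drop = FALSE]
        n_loss <- rbinom(1, nrow(ssel), params$site_loss_fraction)
        if (n_loss > 0) {
          li <- sample.int(nrow(ssel), n_loss)
          lpos <- ssel$start[li] + sample(0:5, n_loss, replace = TRUE)
          ref_b <- substring(chroms[[cn]], lpos + 1, lpos + 1)
          loss <- data.frame(chrom = cn, pos = as.integer(lpos), ref = ref_b,
                             alt = draw_alt(ref_b, n_loss), phase = "both",
                             class = "SNP", stringsAsFactors = FALSE)
          ed <- rbind(ed, loss)
        }
        if (nrow(ed) > 0) {
          ed$accession <- ids[ai]
          all_edits[[length(all_edits) + 1]] <- ed
        }
      }
    }
    edits <- if (length(all_edits)) do.call(rbind, all_edits) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), phase = character(), class = character(),
                 accession = character())

    # reject substitutions that would create a novel CTGCAG (inventory safety)
    if (nrow(edits) > 0) {
      keep <- vapply(seq_len(nrow(edits)), function(i) {
        e <- edits[i, ]
        win_start <- max(0, e$pos - 6)
        win <- substring(chroms[[e$chrom]], win_start + 1, e$pos + 7)
        mut <- paste0(substring(win, 1, e$pos - win_start),
                      e$alt,
                      substring(win, e$pos - win_start + 1 + nchar(e$ref), nchar(win)))
        !grepl("CTGCAG", mut, fixed = TRUE)
      }, logical(1))
      edits <- edits[keep, , drop = FALSE]
    }

    accs <- vector("list", 3)
    for (ai in 1:3) {
      ed <- edits[edits$accession == ids[ai], , drop = FALSE]
      hap1 <- hap2 <- chroms
      for (cn in names(chroms)) {
        ec <- ed[ed$chrom == cn, , drop = FALSE]
        hap1[[cn]] <- apply_edits(chroms[[cn]], ec[ec$phase == "both", , drop = FALSE])
        hap2[[cn]] <- apply_edits(chroms[[cn]], ec)
      }
      accs[[ai]] <- list(accession_id = ids[ai], role = roles[ai],
                         haplotypes = list(hap1 = hap1, hap2 = hap2))
    }

    truth <- build_truth(reference, edits, ids)
    structure(list(accessions = accs, truth = truth, params = params),
              class = "rad_accessions")
  })
}

# build edit records (SNP / 1-2 nt indel) at given positions
make_edits <- function(chrom_seq, chrom_name, pos, phase, indel_fraction) {
  n <- length(pos)
  if (n == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), phase = character(), class = character(),
                      stringsAsFactors = FALSE))
  is_indel <- runif(n) < indel_fraction
  ref_b <- substring(chrom_seq, pos + 1, pos + 1)
  alt <- character(n)
  ref <- ref_b
  cls <- ifelse(is_indel, "indel", "SNP")
  snp_i <- which(!is_indel)
  if (length(snp_i)) alt[snp_i] <- draw_alt(ref_b[snp_i], length(snp_i))
  for (i in which(is_indel)) {
    m <- sample(1:2, 1)
    if (runif(1) < 0.5) { # insertion after the anchor base
      alt[i] <- paste0(ref_b[i], random_dna(m, 0.5))
    } else {             # deletion of the m bases after the anchor
      ref[i] <- substring(chrom_seq, pos[i] + 1, pos[i] + 1 + m)
      alt[i] <- ref_b[i]
    }
  }
  data.frame(chrom = chrom_name, pos = as.integer(pos), ref = ref, alt = alt,
             phase = phase, class = cls, stringsAsFactors = FALSE)
}

# apply a set of non-overlapping edits to one chromosome string
apply_edits <- function(chrom_seq, edits) {
  if (nrow(edits) == 0) return(chrom_seq)
  x <- strsplit(chrom_seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i] + 1L
    nref <- nchar(edits$ref[i])
    if (nref > 1) x[(p + 1):(p + nref - 1)] <- ""  # deletion
    x[p] <- edits$alt[i]                            # SNP or insertion
  }
  paste(x, collapse = "")
}

build_truth <- function(reference, edits, ids) {
  gt_of <- function(acc, key_all, ref_all, alt_all) {
    # genotype per accession at every truth position
    gt <- paste0(ref_all, "/", ref_all)
    sub <- edits[edits$accession == acc, , drop = FALSE]
    if (nrow(sub) > 0) {
      key <- paste(sub$chrom, sub$pos)
      m <- match(key_all, key)
      hit <- !is.na(m)
      a <- sub$alt[m[hit]]
      ph <- sub$phase[m[hit]]
      gt[hit] <- ifelse(ph == "both",
                        paste0(a, "/", a),
                        paste0(ref_all[hit], "/", a))
    }
    gt
  }
  if (nrow(edits) > 0) {
    key_all <- unique(paste(edits$chrom, edits$pos))
    ord <- order(match(sub("\\s.*", "", key_all), names(reference$chroms)),
                 as.integer(sub(".*\\s", "", key_all)))
    key_all <- key_all[ord]
    first <- edits[match(key_all, paste(edits$chrom, edits$pos)), , drop = FALSE]
    variants <- data.frame(
      CHROM = first$chrom, POS = first$pos, REF = first$ref,
      stringsAsFactors = FALSE)
    alt_list <- tapply(edits$alt, paste(edits$chrom, edits$pos), function(z)
      paste(unique(z), collapse = ","))
    variants$ALT <- as.character(alt_list[key_all])
    variants$GT_A <- gt_of(ids[1], key_all, first$ref, first$alt)
    variants$GT_B <- gt_of(ids[2], key_all, first$ref, first$alt)
    variants$GT_C <- gt_of(ids[3], key_all, first$ref, first$alt)
    cls <- tapply(edits$class, paste(edits$chrom, edits$pos), function(z)
      if (any(z == "indel")) "indel" else "SNP")
    variants$CLASS <- as.character(cls[key_all])
  } else {
    variants <- data.frame(CHROM = character(), POS = integer(), REF = character(),
                           ALT = character(), GT_A = character(), GT_B = character(),
                           GT_C = character(), CLASS = character(),
                           stringsAsFactors = FALSE)
  }

  # locus presence: a site is absent for an accession iff destroyed on both
  # haplotypes (phase == "both" edit inside the hexamer)
  loci <- reference$sites[rep(seq_len(nrow(reference$sites)), each = 2), , drop = FALSE]
  loci$SIDE <- rep(c("+", "-"), nrow(reference$sites))
  names(loci)[names(loci) == "cut"] <- "CUT_POS"
  names(loci)[names(loci) == "chrom"] <- "CHROM"
  for (k in 1:3) {
    sub <- edits[edits$accession == ids[k] & edits$phase == "both", , drop = FALSE]
    lost <- rep(FALSE, nrow(loci))
    if (nrow(sub) > 0) {
      for (i in seq_len(nrow(loci))) {
        s0 <- loci$start[i]
        lost[i] <- any(sub$chrom == loci$CHROM[i] & sub$pos >= s0 & sub$pos <= s0 + 5)
      }
    }
    loci[[paste0("PRESENT_", LETTERS[k])]] <- !lost
  }
  loci$start <- NULL
  rownames(loci) <- NULL
  list(variants = variants, loci = loci)
}

#' Enumerate RAD loci of one haplotype sequence
#'
#' One locus per side of each internal PstI cut: side `"+"` reads rightward
#' from the cut, `"-"` leftward. `extent` is the distance to the neighbouring
#' cut (or chromosome end), the maximum usable insert for that locus.
#'
#' @param sequence A chromosome string.
#' @param enzyme Enzyme (default PstI).
#' @return data.frame `cut` (0-based), `side`, `extent`.
#' @export
enumerate_rad_loci <- function(sequence, enzyme = "PstI") {
  n <- nchar(sequence)
  cuts <- attr(digest(sequence, enzyme), "cuts")
  if (length(cuts) == 0)
    return(data.frame(cut = integer(), side = character(), extent = integer()))
  right <- data.frame(cut = cuts, side = "+",
                      extent = c(diff(cuts), n - cuts[length(cuts)]))
  left <- data.frame(cut = cuts, side = "-",
                     extent = c(cuts[1], diff(cuts)))
  out <- rbind(right, left)
  out[order(out$cut, out$side), ]
}

#' Simulate one accession's RAD paired-end library
#'
#' Every single-end read starts exactly at a cut site (restriction side); the
#' mate is read inward from a shear point whose distance from the cut is
#' drawn from the configured insert distribution, truncated to the locus
#' extent. Substitution errors are injected at `error_rate`; qualities are
#' constant Q40 except for the optional planted low-quality reads.
#'
#' @param accession One element of `derive_accessions()$accessions`.
#' @param params [sim_params()].
#' @param n_pairs Number of read pairs to emit.
#' @param seed Stream seed (defaults to a stream derived from `params$seed`).
#' @return `rad_read_pairs` data.table: `read_id`, `sample_id`, `se_seq`,
#'   `pe_seq`, `se_qual`, `pe_qual` plus `truth_*` provenance columns.
#' @export
simulate_rad_library <- function(accession, params, n_pairs,
                                 seed = params$seed + 10L) {
  stopifnot(is.list(accession), !is.null(accession$haplotypes))
  rl <- params$read_length
  with_seed(seed, {
    loci <- list()
    for (h in 1:2) {
      haps <- accession$haplotypes[[h]]
      for (cn in names(haps)) {
        lo <- enumerate_rad_loci(haps[[cn]])
        if (nrow(lo) > 0) {
          lo$chrom <- cn; lo$hap <- h
          loci[[length(loci) + 1]] <- lo
        }
      }
    }
    loci <- data.table::rbindlist(loci)
    loci <- loci[loci$extent >= params$insert_range[1], ]
    if (nrow(loci) == 0) stop("accession has no RAD locus supporting the insert range")

    idx <- sample.int(nrow(loci), n_pairs, replace = TRUE)
    lsel <- loci[idx, ]
    imax <- pmin(params$insert_range[2], lsel$extent)
    ins <- draw_inserts(n_pairs, params, imax)

    hapseq <- character(n_pairs)
    for (h in 1:2) {
      haps <- accession$haplotypes[[h]]
      for (cn in unique(lsel$chrom[lsel$hap == h])) {
        m <- lsel$hap == h & lsel$chrom == cn
        hapseq[m] <- haps[[cn]]
      }
    }
    plus <- lsel$side == "+"
    se <- pe <- character(n_pairs)
    se[plus] <- substring(hapseq[plus], lsel$cut[plus] + 1, lsel$cut[plus] + rl)
    pe[plus] <- revcomp_chr(substring(hapseq[plus],
                                      lsel$cut[plus] + ins[plus] - rl + 1,
                                      lsel$cut[plus] + ins[plus]))
    se[!plus] <- revcomp_chr(substring(hapseq[!plus],
                                       lsel$cut[!plus] - rl + 1, lsel$cut[!plus]))
    pe[!plus] <- substring(hapseq[!plus],
                           lsel$cut[!plus] - ins[!plus] + 1,
                           lsel$cut[!plus] - ins[!plus] + rl)

    se <- inject_errors(se, params$error_rate)
    pe <- inject_errors(pe, params$error_rate)
    q <- strrep("I", rl)  # Q40
    seq_qual <- rep(q, n_pairs)
    pe_qual <- rep(q, n_pairs)
    if (params$lowq_fraction > 0) {
      nl <- floor(params$lowq_fraction * n_pairs)
      if (nl > 0) {
        li <- sample.int(n_pairs, nl)
        for (i in li) {
          qq <- seq_qual[i]
          for (p in sample.int(rl, 6)) substr(qq, p, p) <- "+"  # Q10
          seq_qual[i] <- qq
        }
      }
    }
    data.table::data.table(
      read_id = sprintf("%s_p%07d", accession$accession_id, seq_len(n_pairs)),
      sample_id = accession$accession_id,
      se_seq = se, pe_seq = pe, se_qual = seq_qual, pe_qual = pe_qual,
      truth_chrom = lsel$chrom, truth_hap = lsel$hap,
      truth_cut = lsel$cut, truth_side = lsel$side, truth_insert = ins)
  })
}

draw_inserts <- function(n, params, imax) {
  lo <- params$insert_range[1]
  if (params$insert_dist == "uniform") {
    return(floor(runif(n, lo, imax + 1)))
  }
  out <- round(rnorm(n, params$insert_mean, params$insert_sd))
  bad <- which(out < lo | out > imax)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    out[bad] <- round(rnorm(length(bad), params$insert_mean, params$insert_sd))
    bad <- bad[out[bad] < lo | out[bad] > imax[bad]]
    guard <- guard + 1
  }
  if (length(bad) > 0) out[bad] <- floor(runif(length(bad), lo, imax[bad] + 1))
  as.integer(out)
}

inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  rl <- nchar(reads[1])
  total <- length(reads) * rl
  n_err <- rbinom(1, total, error_rate)
  if (n_err == 0) return(reads)
  at <- sample.int(total, n_err)
  ri <- (at - 1) %/% rl + 1
  pp <- (at - 1) %% rl + 1
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_err)) {
    cur <- substr(reads[ri[k]], pp[k], pp[k])
    substr(reads[ri[k]], pp[k], pp[k]) <- sample(setdiff(bases, cur), 1)
  }
  reads
}

#' Simulate the three-sample library set with unequal depth
#'
#' Total pairs are split across the accessions proportionally to
#' `depth_weights` (largest-remainder rounding), reproducing the unequal
#' per-sample yields of a multiplexed run.
#'
#' @param accessions A `rad_accessions` object.
#' @param params [sim_params()].
#' @param total_pairs Total read pairs over the three samples.
#' @return A single `rad_read_pairs` data.table (all samples).
#' @export
simulate_library_set <- function(accessions, params, total_pairs) {
  w <- params$depth_weights / sum(params$depth_weights)
  n <- floor(total_pairs * w)
  rem <- total_pairs - sum(n)
  if (rem > 0) {
    extra <- order(total_pairs * w - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1
  }
  out <- lapply(1:3, function(i)
    simulate_rad_library(accessions$accessions[[i]], params, n[i],
                         seed = params$seed + 10L + i))
  data.table::rbindlist(out)
}

#' Simulate F1 progeny genotypes by Mendelian transmission
#'
#' Each progeny draws one haplotype per parent per marker. With map positions
#' (`chrom`, `cm` columns in `markers`) adjacent-marker recombination follows
#' the Kosambi inverse of the cM gap; without them markers segregate
#' independently.
#'
#' @param parentA,parentB Marker allele pairs: data.frames with columns
#'   `a1`, `a2` (one row per marker), or `NULL` to read columns
#'   `a1`,`a2`,`b1`,`b2` from `markers`.
#' @param markers data.frame with `marker_id` and optionally `chrom`, `cm`,
#'   and the four allele columns.
#' @param params [sim_params()] (supplies `n_progeny` and `seed`).
#' @return List: `genotypes` (markers x progeny character matrix "x/y"),
#'   `transA`, `transB` (transmitted haplotype index matrices, 1 or 2).
#' @export
simulate_progeny <- function(parentA = NULL, parentB = NULL, markers, params) {
  if (params$n_progeny < 1) stop("n_progeny must be >= 1")
  if (is.null(parentA)) parentA <- markers[, c("a1", "a2")]
  if (is.null(parentB)) parentB <- data.frame(a1 = markers$b1, a2 = markers$b2)
  nm <- nrow(markers)
  np <- params$n_progeny
  with_seed(params$seed + 20L, {
    trans <- function() {
      if (!is.null(markers$cm) && !is.null(markers$chrom)) {
        m <- matrix(0L, nm, np)
        for (cn in unique(markers$chrom)) {
          ii <- which(markers$chrom == cn)
          ii <- ii[order(markers$cm[ii])]
          m[ii[1], ] <- sample(1:2, np, replace = TRUE)
          if (length(ii) > 1) {
            gaps <- diff(markers$cm[ii])
            r <- kosambi_r(gaps)
            for (k in seq_along(gaps)) {
              sw <- runif(np) < r[k]
              m[ii[k + 1], ] <- ifelse(sw, 3L - m[ii[k], ], m[ii[k], ])
            }
          }
        }
        m
      } else {
        matrix(sample(1:2, nm * np, replace = TRUE), nm, np)
      }
    }
    tA <- trans(); tB <- trans()
    alA <- matrix(ifelse(tA == 1L, parentA[[1]][row(tA)], parentA[[2]][row(tA)]), nm, np)
    alB <- matrix(ifelse(tB == 1L, parentB[[1]][row(tB)], parentB[[2]][row(tB)]), nm, np)
    g <- matrix(paste0(alA, "/", alB), nm, np,
                dimnames = list(markers$marker_id,
                                sprintf("F1_%03d", seq_len(np))))
    list(genotypes = g, transA = tA, transB = tB)
  })
}
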