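# Clustering and per-locus assembly: quality screen boundaries, exact-identity
# clustering with coverage bounds, contig recovery against simulator truth,
# contig filters and summary statistics.

test_that("quality filter drops reads with more than five Phred<=10 bases", {
  q_ok5 <- paste0(strrep("+", 5), strrep("I", 49))   # 5 bases at Q10
  q_bad6 <- paste0(strrep("+", 6), strrep("I", 48))  # 6 bases at Q10
  se <- rep(strrep("A", 54), 3)
  pairs <- make_pairs(se, se_qual = c(strrep("I", 54), q_ok5, q_bad6))
  out <- quality_filter(pairs)
  expect_equal(out$read_id, c("r001", "r002"))
  expect_equal(attr(out, "discard_log")$read_id, "r003")
  # pair dropped if either mate fails
  pairs2 <- make_pairs(se[1], pe_qual = q_bad6)
  expect_equal(nrow(quality_filter(pairs2)), 0)
  # mismatched lengths error
  pairs3 <- make_pairs(se[1], se_qual = "II")
  expect_error(quality_filter(pairs3), "length")
})

test_that("clustering is an exact-identity partition with coverage bounds", {
  a <- strrep("A", 54); b <- paste0(strrep("A", 53), "C")
  pairs <- make_pairs(c(rep(a, 30), rep(b, 24)))
  cl <- cluster_single_ends(pairs, min_cov = 25, max_cov = 400)
  cls <- attr(cl, "clusters")
  # one-base difference -> distinct clusters; 24x fails the floor
  expect_equal(nrow(cls), 1)
  expect_equal(cls$se_representative, a)
  expect_equal(cls$coverage, 30)
  # partition: every retained read in exactly one cluster
  expect_equal(sort(as.integer(table(cl$cluster_id))),
               sort(as.integer(table(cl$se_seq))))
  # boundary cases: 25 retained, 401 removed
  p25 <- make_pairs(rep(a, 25))
  expect_equal(nrow(attr(cluster_single_ends(p25), "clusters")), 1)
  p401 <- make_pairs(rep(a, 401))
  expect_equal(nrow(attr(cluster_single_ends(p401), "clusters")), 0)
  # empty input -> empty output
  expect_equal(nrow(cluster_single_ends(make_pairs(character()))), 0)
})

test_that("error-free locus assembles to the exact truth sequence", {
  # 400 nt locus; mates drawn at every insert so the island tiles fully
  set.seed(7)
  locus <- random_seq(400)
  se_rep <- substring(locus, 1, 54)
  inserts <- rep(c(seq(108, 396, by = 3), 400), 2)
  pe <- radsnp:::revcomp_chr(substring(locus, inserts - 53, inserts))
  ctg <- assemble_locus(se_rep, pe)
  expect_equal(nrow(ctg), 1)
  expect_identical(ctg$sequence[1], locus)
  expect_error(assemble_locus(se_rep, pe, k_values = integer()), "non-empty")
})

test_that("diverged haplotypes in the mate region yield NODE1/NODE2", {
  set.seed(8)
  h1 <- random_seq(400)
  h2 <- h1
  substr(h2, 250, 250) <- if (substring(h1, 250, 250) == "A") "C" else "A"
  inserts <- rep(c(seq(108, 396, by = 3), 400), 2)
  pe <- c(radsnp:::revcomp_chr(substring(h1, inserts - 53, inserts)),
          radsnp:::revcomp_chr(substring(h2, inserts - 53, inserts)))
  ctg <- assemble_locus(substring(h1, 1, 54), pe)
  expect_equal(ctg$node[1:2], c("NODE1", "NODE2"))
  expect_setequal(ctg$sequence[1:2], c(h1, h2))
})

test_that("contig filters apply the published thresholds and are idempotent", {
  ctg <- data.frame(
    node = "NODE1",
    sequence = c(strrep("A", 99), strrep("A", 100), strrep("A", 150),
                 paste0(strrep("A", 99), "NN", strrep("A", 99))),
    length = c(99L, 100L, 150L, 200L),
    pe_coverage = c(10, 10, 3.9, 10),
    stringsAsFactors = FALSE)
  out <- filter_contigs(ctg)
  expect_equal(out$length, 100L)         # 99 nt short, 3.9x shallow, NN ambiguous
  expect_identical(filter_contigs(out), out)
})

test_that("assembly statistics follow the stated definitions", {
  ctg <- data.frame(sequence = c(strrep("A", 100), strrep("A", 200),
                                 strrep("A", 300), strrep("G", 400)),
                    length = c(100L, 200L, 300L, 400L),
                    locus_id = c(1, 2, 3, 3))
  st <- assembly_stats(ctg)
  expect_equal(st$n50, 300)
  expect_equal(st$mean_length, 250)
  expect_equal(st$contig_count * st$mean_length, st$total_bp)
  expect_equal(st$alternative_fraction, 1 / 3)
  expect_equal(assembly_stats(data.frame(sequence = "GGCC", length = 4L))$gc_fraction, 1)
  expect_error(assembly_stats(ctg[0, ]), "no contigs")
})

test_that("divergence-0 loci with full insert support are recovered exactly", {
  # oracle: the simulator truth itself. All accessions identical to the
  # reference; >= 30x uniform depth; full insert support = some mate drawn
  # near the minimal insert so the island abuts the anchor.
  p <- sim_params(genome_length = 1e5, pstI_site_spacing = 4000,
                  divergence_rate = 0, het_rate = c(0, 0, 0),
                  indel_fraction = 0, site_loss_fraction = 0,
                  insert_range = c(108, 150), insert_dist = "uniform",
                  error_rate = 0, seed = 17)
  ref <- simulate_reference(p)
  acc <- derive_accessions(ref, p)
  pairs <- simulate_library_set(acc, p, 12000)   # ~60 pairs/locus pooled
  contigs <- assemble_rad_contigs(pairs)
  flank_of <- function(chrom, cut, side, len) {
    if (side == "+") substring(ref$chroms[[chrom]], cut + 1, cut + len)
    else radsnp:::revcomp_chr(substring(ref$chroms[[chrom]], cut - len + 1, cut))
  }
  # full insert support: the island abuts the anchor exactly, i.e. the
  # template sample drew mates at the minimal insert (2 x read length) with
  # at least the assembler's k-mer support floor
  pt <- pairs[pairs$sample_id == attr(contigs, "log")$template, ]
  key <- paste(pt$truth_chrom, pt$truth_cut, pt$truth_side)
  full <- tapply(pt$truth_insert, key, function(x) sum(x == 108) >= 2)
  anch <- map_contigs_to_reference(contigs, ref)$anchors
  akey <- paste(anch$chrom, anch$cut, anch$side)
  recovered <- vapply(names(full)[full], function(k) {
    ci <- which(akey == k)
    if (length(ci) == 0) return(FALSE)
    parts <- strsplit(k, " ")[[1]]
    any(vapply(ci, function(i) {
      identical(contigs$sequence[i],
                flank_of(parts[1], as.integer(parts[2]), parts[3],
                         contigs$length[i]))
    }, logical(1)))
  }, logical(1))
  expect_gt(length(recovered), 20)
  expect_gte(mean(recovered), 0.95)
})

test_that("assembly is deterministic", {
  sim <- small_sim()
  again <- assemble_rad_contigs(sim$pairs)
  expect_identical(again$sequence, sim$contigs$sequence)
})
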