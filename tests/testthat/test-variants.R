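# Variant calling: alignment acceptance contract, pileup conservation,
# CcRAD1/CcRAD2 thresholds, zygosity rules (with an exhaustive enumeration
# oracle), marker classification (enumeration oracle), VCF round trip.

test_that("alignment accepts <=3 mismatches and <=2 nt gaps, rejects beyond", {
  set.seed(5)
  ctg <- random_seq(300)
  read <- substring(ctg, 101, 154)
  r0 <- align_read_pair(read, contig = ctg)
  expect_true(r0$accepted)
  expect_equal(r0$se$offset, 100)
  expect_equal(r0$se$mismatches, 0)
  expect_equal(r0$se$gaps, 0)
  mutate_at <- function(s, at) {
    for (p in at) substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                             substring(s, p, p))[1]
    s
  }
  # 3 mismatches accepted, 4 rejected
  r3 <- align_read_pair(mutate_at(read, c(20, 30, 40)), contig = ctg)
  expect_true(r3$accepted)
  expect_equal(r3$se$mismatches, 3)
  r4 <- align_read_pair(mutate_at(read, c(20, 25, 30, 40)), contig = ctg)
  expect_false(r4$accepted)
  # 2 nt deletion accepted, 3 nt rejected
  del <- function(s, at, n) paste0(substring(s, 1, at - 1), substring(s, at + n))
  rd2 <- align_read_pair(paste0(del(read, 25, 2), substring(ctg, 155, 156)),
                         contig = ctg)
  expect_true(rd2$accepted)
  expect_equal(rd2$se$gaps, 2)
  rd3 <- align_read_pair(paste0(del(read, 25, 3), substring(ctg, 155, 157)),
                         contig = ctg)
  expect_false(rd3$accepted)
  # contig shorter than read
  expect_false(align_read_pair(read, contig = "ACGT")$accepted)
})

test_that("pileup conserves depth and separates indel alleles", {
  set.seed(6)
  ctg <- paste0(substring(random_seq(300), 1, 300))
  contigs <- data.frame(contig_id = "c1", sequence = ctg,
                        stringsAsFactors = FALSE)
  se <- substring(ctg, 1, 54)
  # 6 exact pairs + 4 pairs whose mate carries a 1 nt deletion at 120
  pe_exact <- substring(ctg, 101, 154)
  pe_del <- paste0(substring(ctg, 101, 119), substring(ctg, 121, 155))
  pairs <- make_pairs(rep(se, 10), c(rep(pe_exact, 6), rep(pe_del, 4)))
  pu <- build_pileup(pairs, contigs)
  # depth = sum of counts at every column
  d100 <- pu[pu$pos == 110, ]
  expect_equal(sum(d100$count), 10)
  # deletion allele registered at its first deleted base with count 4
  delrow <- pu[startsWith(pu$allele, "D:"), ]
  expect_equal(nrow(delrow), 1)
  expect_equal(delrow$count, 4)
  expect_equal(delrow$allele, "D:1")
  expect_equal(delrow$pos, 119)
  # reference allele carries the other 6 reads there
  refrow <- pu[pu$pos == 119 & !startsWith(pu$allele, "D:"), ]
  expect_equal(sum(refrow$count), 6)
})

test_that("CcRAD1 calling honours coverage and indel-length limits", {
  contigs <- data.frame(contig_id = "c1", sequence = strrep("A", 100),
                        stringsAsFactors = FALSE)
  col <- function(pos, alleles, counts, sample = "s1")
    data.frame(contig_id = "c1", pos = pos, sample_id = sample,
               allele = alleles, count = counts)
  pu <- make_pileup(rbind(
    col(10, c("A", "C"), c(3, 2)),            # depth 5: below threshold
    col(20, c("A", "C"), c(3, 3)),            # depth 6: in
    col(30, "C", 100),                        # monomorphic: out
    col(40, c("A", "I:AGGG"), c(6, 3)),       # 3 nt insertion: never emitted
    col(50, c("A", "D:2"), c(6, 3))),         # 2 nt deletion: in
    contigs)
  sites <- call_ccrad1(pu)
  expect_setequal(sites$pos, c(20, 50))
  expect_equal(sites$class[sites$pos == 50], "indel")
  expect_true(all(sites$biallelic))
  # raising the threshold never increases the site count (monotonicity)
  n <- vapply(4:10, function(mc) nrow(call_ccrad1(pu, min_cov = mc)), integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("zygosity rules match an exhaustive enumeration oracle", {
  # spec-stated examples first
  expect_equal(impute_genotype(c(A = 10, C = 10))$zygosity, "het")
  expect_equal(impute_genotype(c(A = 2, C = 2))$zygosity, "het")
  expect_equal(impute_genotype(c(A = 19, C = 1))$zygosity, "hom")
  expect_equal(impute_genotype(c(A = 19, C = 1))$alleles, "A")
  expect_equal(impute_genotype(c(A = 8, C = 2))$zygosity, "ambiguous")
  expect_equal(impute_genotype(integer())$zygosity, "no_call")
  # oracle: direct transcription of the stated rules over all count pairs
  oracle <- function(c1, c2) {
    depth <- c1 + c2
    if (depth == 0) return("no_call")
    hi <- max(c1, c2); lo <- min(c1, c2)
    if (lo >= 2 && depth >= 4 && lo / depth >= 0.25 && hi / depth <= 0.75)
      return("het")
    if (lo / depth < 0.10 && depth >= 2) return("hom")
    "ambiguous"
  }
  for (c1 in 0:20) for (c2 in 0:c1) {
    counts <- c(A = c1, C = c2)
    expect_identical(impute_genotype(counts)$zygosity, oracle(c1, c2),
                     label = sprintf("counts %d/%d", c1, c2))
  }
  # three alleles each with >= 2 reads is ambiguous
  expect_equal(impute_genotype(c(A = 10, C = 8, G = 2))$zygosity, "ambiguous")
})

test_that("CcRAD2 requires one read in every sample and is a subset", {
  contigs <- data.frame(contig_id = "c1", sequence = strrep("A", 100),
                        stringsAsFactors = FALSE)
  rows <- rbind(
    data.frame(contig_id = "c1", pos = 10, sample_id = c("s1", "s2", "s3"),
               allele = c("A", "C", "C"), count = c(12, 6, 1)),
    data.frame(contig_id = "c1", pos = 20, sample_id = c("s1", "s2"),
               allele = c("A", "C"), count = c(12, 6)))
  pu <- make_pileup(rows, contigs, samples = c("s1", "s2", "s3"))
  cc1 <- call_ccrad1(pu)
  cc2 <- select_ccrad2(cc1, pu)
  expect_setequal(cc1$pos, c(10, 20))
  expect_equal(cc2$pos, 10)   # depths (12, 6, 0) excluded
  expect_lte(nrow(cc2), nrow(cc1))
})

test_that("marker classification matches an enumeration oracle", {
  # oracle over all genotype 3-tuples from {het, hom, ambiguous, no_call}
  states <- c("het", "hom", "ambiguous", "no_call")
  grid <- expand.grid(s1 = states, s2 = states, s3 = states,
                      stringsAsFactors = FALSE)
  gt <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    data.frame(contig_id = "c", pos = i, sample_id = c("s1", "s2", "s3"),
               zygosity = unlist(grid[i, ]), a1 = "A", a2 = "C",
               stringsAsFactors = FALSE)))
  cls <- classify_markers(gt)
  for (i in seq_len(nrow(grid))) {
    g <- unlist(grid[i, ])
    ev <- cls$markers[cls$markers$pos == i, ]
    want_tc <- sum(outer(seq_len(3), seq_len(3), Vectorize(function(a, b)
      a != b && g[a] == "het" && g[b] == "hom")))
    expect_equal(sum(ev$class == "testcross"), want_tc, label = paste(g, collapse = "/"))
    expect_equal(sum(ev$class == "common_intercross"), as.integer(all(g == "het")))
    if (want_tc == 0 && !all(g == "het"))
      expect_equal(ev$class, "uninformative")
  }
  # spec example: (hom, het, hom) -> middle sample testcross over both others
  ev <- cls$markers[cls$markers$pos ==
                      which(grid$s1 == "hom" & grid$s2 == "het" & grid$s3 == "hom"), ]
  expect_setequal(paste(ev$informative, ev$paired),
                  c("s2 s1", "s2 s3"))
})

test_that("classification totals account for every CcRAD2 site", {
  sim <- small_sim()
  v <- call_variants(sim$pairs, sim$contigs)
  expect_lte(nrow(v$ccrad2), nrow(v$ccrad1))
  m <- v$markers
  site_key <- unique(paste(m$contig_id, m$pos))
  expect_equal(length(site_key), nrow(v$ccrad2))
  # no site double-counted within one ordered pair
  tc <- m[m$class == "testcross", ]
  expect_false(any(duplicated(paste(tc$contig_id, tc$pos, tc$informative, tc$paired))))
})

test_that("VCF output is valid and round-trips through a standard reader", {
  skip_if_not_installed("VariantAnnotation")
  sim <- small_sim()
  v <- call_variants(sim$pairs, sim$contigs)
  path <- withr::local_tempfile(fileext = ".vcf")
  snv <- v$ccrad2[v$ccrad2$class == "SNP", ][1:10, ]
  write_vcf(path, snv, v$genotypes, v$pileup)
  vcf <- VariantAnnotation::readVcf(path)
  expect_equal(nrow(vcf), 10)
  rr <- SummarizedExperiment::rowRanges(vcf)
  expect_equal(as.character(GenomicRanges::seqnames(rr)), snv$contig_id)
  expect_equal(BiocGenerics::start(rr), snv$pos + 1L)  # 1-based
  # AD counts round-trip
  ad <- VariantAnnotation::geno(vcf)$AD
  pu <- v$pileup
  for (i in c(1, 5, 10)) {
    for (s in attr(pu, "samples")) {
      cnt <- pu[pu$contig_id == snv$contig_id[i] & pu$pos == snv$pos[i] &
                  pu$sample_id == s, ]
      expect_equal(sum(ad[i, s][[1]]), sum(cnt$count))
    }
  }
  # het genotype encoded 0/1
  gt <- VariantAnnotation::geno(vcf)$GT
  hets <- v$genotypes[v$genotypes$zygosity == "het", ]
  hit <- merge(data.frame(contig_id = snv$contig_id, pos = snv$pos,
                          row = seq_len(10)), hets)
  if (nrow(hit) > 0) {
    i <- hit$row[1]
    expect_true(any(gt[i, ] %in% c("0/1", "1/2")))
  }
  # header-only VCF for zero sites
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(path2, snv[0, ], v$genotypes, v$pileup)
  vcf0 <- VariantAnnotation::readVcf(path2)
  expect_equal(nrow(vcf0), 0)
})

test_that("shallower depth weight lowers that sample's het yield", {
  sim <- small_sim()
  v <- call_variants(sim$pairs, sim$contigs)
  hets <- table(v$genotypes$sample_id[v$genotypes$zygosity == "het"])
  # accA carries the 1.2 depth weight, accC the 5.9
  expect_lt(hets[["accA"]], hets[["accC"]])
})
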