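# Generator: parameter validation, determinism, divergence calibration,
# truth-table completeness, library geometry, progeny transmission.

test_that("sim_params validates its invariants", {
  expect_error(sim_params(genome_length = 0), "genome_length")
  expect_error(sim_params(het_rate = c(0.1, 0.1)), "length 3")
  expect_error(sim_params(insert_range = c(80, 400)), "2 \\* read_length")
  expect_error(sim_params(pstI_site_spacing = 1000), "overlap")
  expect_error(sim_params(depth_weights = c(1, -1, 2)), "positive")
})

test_that("reference genome plants the expected sites and is deterministic", {
  p <- small_sim_params(seed = 3)
  ref <- simulate_reference(p)
  # ~ genome_length / spacing sites, every one an exact CTGCAG
  expect_equal(nrow(ref$sites), 49, tolerance = 0.15)
  for (i in seq_len(nrow(ref$sites)))
    expect_identical(substring(ref$chroms[[ref$sites$chrom[i]]],
                               ref$sites$start[i] + 1, ref$sites$start[i] + 6),
                     "CTGCAG")
  # no occurrence other than the planted ones
  occ <- gregexpr("CTGCAG", ref$chroms[[1]], fixed = TRUE)[[1]] - 1L
  expect_setequal(occ, ref$sites$start)
  # determinism
  ref2 <- simulate_reference(p)
  expect_identical(ref$chroms, ref2$chroms)
})

test_that("pairwise accession divergence matches the configured rate", {
  # binomial counting oracle: brute-force consensus diff vs divergence_rate
  p <- sim_params(genome_length = 1e6, pstI_site_spacing = 5000,
                  divergence_rate = 0.0056, het_rate = c(0, 0, 0),
                  indel_fraction = 0, site_loss_fraction = 0, seed = 5)
  ref <- simulate_reference(p)
  acc <- derive_accessions(ref, p)
  diff_count <- function(a, b) {
    x <- strsplit(a$haplotypes$hap1[[1]], "")[[1]]
    y <- strsplit(b$haplotypes$hap1[[1]], "")[[1]]
    sum(x != y)
  }
  tol <- 3 * sqrt(0.0056 * 1e6)
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    d <- diff_count(acc$accessions[[pr[1]]], acc$accessions[[pr[2]]])
    expect_lt(abs(d - 5600), tol + 80)  # + small allowance for edit thinning
  }
})

test_that("het_rate zero gives identical haplotypes; truth enumerates all diffs", {
  p <- sim_params(genome_length = 1e5, pstI_site_spacing = 4000,
                  het_rate = c(0, 0, 0), indel_fraction = 0,
                  site_loss_fraction = 0.1, seed = 9)
  ref <- simulate_reference(p)
  acc <- derive_accessions(ref, p)
  for (a in acc$accessions)
    expect_identical(a$haplotypes$hap1, a$haplotypes$hap2)
  # brute-force diff of each accession consensus vs reference: every
  # difference must appear in the truth table with the right genotype
  tv <- acc$truth$variants
  for (k in 1:3) {
    x <- strsplit(ref$chroms[[1]], "")[[1]]
    y <- strsplit(acc$accessions[[k]]$haplotypes$hap1[[1]], "")[[1]]
    dpos <- which(x != y) - 1L
    sub <- tv[tv[[paste0("GT_", LETTERS[k])]] != paste0(tv$REF, "/", tv$REF), ]
    expect_setequal(dpos, sub$POS)
    gt <- sub[match(dpos, sub$POS), paste0("GT_", LETTERS[k])]
    expect_identical(gt, paste0(y[dpos + 1], "/", y[dpos + 1]))
  }
})

test_that("heterozygosity lands on the second haplotype at the stated rate", {
  p <- sim_params(genome_length = 2e5, pstI_site_spacing = 5000,
                  het_rate = c(0.004, 0, 0), indel_fraction = 0,
                  divergence_rate = 0, site_loss_fraction = 0, seed = 13)
  ref <- simulate_reference(p)
  acc <- derive_accessions(ref, p)
  x <- strsplit(acc$accessions[[1]]$haplotypes$hap1[[1]], "")[[1]]
  y <- strsplit(acc$accessions[[1]]$haplotypes$hap2[[1]], "")[[1]]
  nhet <- sum(x != y)
  expect_lt(abs(nhet - 0.004 * 2e5), 3 * sqrt(0.004 * 2e5) + 40)
})

test_that("destroyed cut sites are flagged absent in the locus truth table", {
  p <- sim_params(genome_length = 1e5, pstI_site_spacing = 4000,
                  het_rate = c(0, 0, 0), indel_fraction = 0,
                  site_loss_fraction = 0.3, seed = 21)
  ref <- simulate_reference(p)
  acc <- derive_accessions(ref, p)
  lo <- acc$truth$loci
  for (k in 1:3) {
    hap <- acc$accessions[[k]]$haplotypes$hap1[[1]]
    for (i in seq_len(nrow(lo))) {
      s0 <- ref$sites$start[match(lo$CUT_POS[i], ref$sites$cut)]
      intact <- substring(hap, s0 + 1, s0 + 6) == "CTGCAG"
      expect_identical(lo[[paste0("PRESENT_", LETTERS[k])]][i], intact)
    }
  }
  expect_gt(sum(!lo$PRESENT_A), 0)  # losses actually happened at 0.3
})

test_that("library geometry: reads anchor at cut sites, inserts in range", {
  sim <- small_sim()
  pairs <- sim$pairs
  expect_true(all(pairs$truth_insert >= 108 & pairs$truth_insert <= 400))
  expect_equal(unique(nchar(pairs$se_seq)), 54)
  expect_equal(unique(nchar(pairs$pe_seq)), 54)
  # error-free: every SE read is an exact substring of one haplotype
  idx <- sample(nrow(pairs), 40)
  for (i in idx) {
    a <- sim$accessions$accessions[[match(pairs$sample_id[i], c("accA", "accB", "accC"))]]
    hap <- a$haplotypes[[pairs$truth_hap[i]]][[pairs$truth_chrom[i]]]
    s <- pairs$se_seq[i]
    hit <- if (pairs$truth_side[i] == "+")
      substring(hap, pairs$truth_cut[i] + 1, pairs$truth_cut[i] + 54) == s
    else
      substring(hap, pairs$truth_cut[i] - 53, pairs$truth_cut[i] + 0) ==
        radsnp:::revcomp_chr(s)
    expect_true(hit)
  }
})

test_that("depth weights split the library deterministically within 2%", {
  sim <- small_sim()
  frac <- table(sim$pairs$sample_id) / nrow(sim$pairs)
  want <- c(1.2, 2.6, 5.9) / 9.7
  expect_true(all(abs(frac - want) < 0.02))
})

test_that("library simulation is reproducible for a fixed seed", {
  sim <- small_sim()
  again <- simulate_rad_library(sim$accessions$accessions[[1]], sim$params,
                                100, seed = 99)
  again2 <- simulate_rad_library(sim$accessions$accessions[[1]], sim$params,
                                 100, seed = 99)
  expect_identical(again, again2)
})

test_that("RAD locus inventory: two loci per internal cut site", {
  bg <- function(n) gsub("CTGCAG", "CTACAG", random_seq(n), fixed = TRUE)
  set.seed(2)
  s <- paste0(bg(3000), "CTGCAG", bg(3000), "CTGCAG", bg(3000))
  lo <- enumerate_rad_loci(s)
  expect_equal(nrow(lo), 4)
  expect_equal(sum(lo$side == "+"), 2)
})

test_that("progeny transmission is Mendelian and respects the map", {
  p <- sim_params(seed = 31, n_progeny = 94)
  mk <- data.frame(marker_id = c("m1", "m2"), a1 = c("A", "A"), a2 = c("G", "G"),
                   b1 = c("A", "A"), b2 = c("A", "A"),
                   chrom = c("c1", "c1"), cm = c(0, 0))
  # two markers at 0 cM cosegregate perfectly
  pr <- simulate_progeny(markers = mk, params = p)
  expect_identical(pr$genotypes[1, ], pr$genotypes[2, ])
  # het x hom: mean split over seeds approaches 47:47
  splits <- vapply(1:30, function(s) {
    pp <- sim_params(seed = s, n_progeny = 94)
    g <- simulate_progeny(markers = mk[1, ], params = pp)$genotypes
    mean(g == "A/A")
  }, numeric(1))
  expect_lt(abs(mean(splits) - 0.5), 0.02)
  # het x het gives 1:2:1
  mk2 <- data.frame(marker_id = "m", a1 = "A", a2 = "G", b1 = "A", b2 = "G")
  cls <- vapply(1:30, function(s) {
    pp <- sim_params(seed = 100 + s, n_progeny = 94)
    g <- simulate_progeny(markers = mk2, params = pp)$genotypes
    mean(g %in% c("A/G", "G/A"))
  }, numeric(1))
  expect_lt(abs(mean(cls) - 0.5), 0.03)
  expect_error(simulate_progeny(markers = mk, params = sim_params(n_progeny = 1)), NA)
})

test_that("fastq round trip preserves reads and qualities", {
  sim <- small_sim()
  sub <- sim$pairs[sim$pairs$sample_id == "accA", ][1:20, ]
  d <- withr::local_tempdir()
  write_fastq_pairs(sub, d)
  back <- read_fastq_pairs(file.path(d, "accA_1.fastq"),
                           file.path(d, "accA_2.fastq"), "accA")
  expect_identical(back$se_seq, sub$se_seq)
  expect_identical(back$pe_seq, sub$pe_seq)
  expect_identical(back$se_qual, sub$se_qual)
  expect_identical(back$read_id, sub$read_id)
})
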