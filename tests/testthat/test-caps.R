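# CAPS conversion: differential sites, locality, the design margin, pattern
# scoring, and the packaged validation panel.

# naive IUPAC matcher used as the brute-force oracle for differential sites
naive_sites <- function(seq, pattern) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", N = "ACGT",
                R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")
  L <- nchar(pattern)
  hits <- integer()
  for (i in seq_len(nchar(seq) - L + 1)) {
    w <- substring(seq, i, i + L - 1)
    ok <- all(vapply(seq_len(L), function(p)
      grepl(substring(w, p, p), iupac[[substring(pattern, p, p)]], fixed = TRUE),
      logical(1)))
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

test_that("a SNP creating a site is reported as differential for that allele", {
  ctg <- paste0(strrep("T", 100), "GATAGC", strrep("A", 100))
  d <- differential_digestion(ctg, 104, "G", "T")  # GATAGC -> GATATC (EcoRV)
  ev <- d[d$enzyme == "EcoRV", ]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$cutting_allele, "alt")
  expect_equal(ev$cut, 100 + 3)  # GAT^ATC
  # swapping ref/alt swaps the cutting-allele label, nothing else
  ctg2 <- paste0(strrep("T", 100), "GATATC", strrep("A", 100))
  d2 <- differential_digestion(ctg2, 104, "T", "G")
  ev2 <- d2[d2$enzyme == "EcoRV", ]
  expect_equal(ev2$cutting_allele, "ref")
  expect_equal(ev2$cut, ev$cut)
  # SNP outside every recognition window: empty
  ctg3 <- paste0(strrep("T", 50), "A", strrep("T", 50))
  expect_equal(nrow(differential_digestion(ctg3, 50, "A", "G")), 0)
  expect_error(differential_digestion(ctg, 104, "C", "T"), "inconsistent")
})

test_that("SNP at an N position of a degenerate pattern is not differential", {
  # XmnI GAANNNNTTC: variant inside the N spacer matches under both alleles;
  # oracle: naive matcher scan of both allele sequences
  ctg <- paste0(strrep("T", 60), "GAACAGTTTC", strrep("A", 60))
  pos0 <- 63  # the C inside the spacer
  expect_identical(substring(ctg, pos0 + 1, pos0 + 1), "C")
  d <- differential_digestion(ctg, pos0, "C", "G", enzymes = "XmnI")
  expect_equal(nrow(d), 0)
  alt_seq <- paste0(substring(ctg, 1, pos0), "G", substring(ctg, pos0 + 2))
  expect_identical(naive_sites(ctg, "GAANNNNTTC"),
                   naive_sites(alt_seq, "GAANNNNTTC"))
})

test_that("locality: differential sites stay near the variant", {
  set.seed(23)
  for (i in 1:10) {
    ctg <- random_seq(400)
    pos0 <- sample(50:350, 1)
    ref <- substring(ctg, pos0 + 1, pos0 + 1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    d <- differential_digestion(ctg, pos0, ref, alt)
    if (nrow(d) > 0) {
      reach <- nchar(enzyme_registry()$recognition) +
        pmax(0, enzyme_registry()$cut_offset - nchar(enzyme_registry()$recognition))
      maxreach <- max(reach)
      expect_true(all(abs(d$cut - pos0) <= maxreach + 10))
    }
  }
})

test_that("design enforces the 20 nt gel-detectability margin", {
  # engineered rejection: cut at 180 of a 341 nt product -> fragments 180/161,
  # pairwise differences {19, 161, 180}: smallest below the margin
  base <- random_seq(341, seed = 24)
  ctg <- paste0(substring(base, 1, 174), "GATAGC", substring(base, 181, 341))
  expect_equal(nchar(ctg), 341)
  a <- design_caps_assays(ctg, 178, "G", "T", enzymes = "EcoRV",
                          product_range = c(100, 400))
  rej <- attr(a, "rejected")
  if (nrow(a) > 0) a <- a[a$enzyme == "EcoRV", ]
  expect_equal(nrow(a), 0)
  expect_false(is.null(rej))
  expect_lt(rej$fragment_size_difference[rej$enzyme == "EcoRV"], 20)
  # and the published-geometry case is accepted: cut at 162 of 372
  base2 <- random_seq(372, seed = 25)
  ctg2 <- paste0(substring(base2, 1, 159), "GATAGC", substring(base2, 166, 372))
  a2 <- design_caps_assays(ctg2, 163, "G", "T", enzymes = "EcoRV",
                           product_range = c(100, 400))
  expect_equal(nrow(a2), 1)
  expect_setequal(radsnp:::parse_frags(a2$fragments_hom_cut), c(162, 210))
  expect_gte(a2$fragment_size_difference, 20)
  expect_error(design_caps_assays(strrep("A", 90), 45, "A", "G",
                                  product_range = c(100, 400)), "shorter")
})

test_that("fragment sets conserve product size in accepted assays", {
  set.seed(26)
  n_checked <- 0
  for (i in 1:60) {
    ctg <- random_seq(350)
    pos0 <- sample(60:290, 1)
    ref <- substring(ctg, pos0 + 1, pos0 + 1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    a <- tryCatch(design_caps_assays(ctg, pos0, ref, alt),
                  error = function(e) NULL)
    if (is.null(a)) next
    rej <- attr(a, "rejected")
    if (!is.null(rej)) a <- rbind(a, rej)  # conservation holds for both
    if (nrow(a) == 0) next
    for (j in seq_len(nrow(a))) {
      expect_equal(sum(radsnp:::parse_frags(a$fragments_hom_uncut[j])),
                   a$product_size[j])
      # het pattern = union of the two homozygote patterns
      expect_setequal(radsnp:::parse_frags(a$fragments_het[j]),
                      union(radsnp:::parse_frags(a$fragments_hom_uncut[j]),
                            radsnp:::parse_frags(a$fragments_hom_cut[j])))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 3)
})

test_that("pattern scoring assigns the published band sets", {
  assay <- data.frame(fragments_hom_uncut = "372",
                      fragments_hom_cut = "210,162",
                      fragments_het = "372,210,162")
  expect_equal(score_caps_pattern(372, assay), "hom_uncut")
  expect_equal(score_caps_pattern(c(372, 210, 162), assay), "het")
  expect_equal(score_caps_pattern(c(162, 210), assay), "hom_cut")
  expect_equal(score_caps_pattern(c(500, 100), assay), "unscored")
  expect_error(score_caps_pattern(numeric(), assay), "empty")
  # 5% gel tolerance
  expect_equal(score_caps_pattern(c(365, 215, 160), assay), "het")
})

test_that("end-to-end: design, digest and score recovers progeny genotypes", {
  # truth testcross SNP creating an EcoRV site; 94 progeny scored noise-free
  base <- random_seq(372, seed = 27)
  ctg <- paste0(substring(base, 1, 159), "GATAGC", substring(base, 166, 372))
  pos0 <- 163; ref <- "G"; alt <- "T"
  assay <- design_caps_assays(ctg, pos0, ref, alt, enzymes = "EcoRV")
  expect_equal(nrow(assay), 1)
  alt_seq <- radsnp:::apply_allele(ctg, pos0, ref, alt)
  p <- sim_params(seed = 28, n_progeny = 94)
  mk <- data.frame(marker_id = "snp1", a1 = "G", a2 = "T", b1 = "G", b2 = "G")
  pr <- simulate_progeny(markers = mk, params = p)
  calls <- vapply(seq_len(94), function(j) {
    alleles <- strsplit(pr$genotypes[1, j], "/", fixed = TRUE)[[1]]
    amps <- ifelse(alleles == "G", ctg, alt_seq)
    score_caps_pattern(digest_amplicons(amps, "EcoRV"), assay)
  }, character(1))
  want <- ifelse(pr$genotypes[1, ] %in% c("G/G"), "hom_uncut",
                 ifelse(pr$genotypes[1, ] %in% c("T/T"), "hom_cut", "het"))
  expect_identical(unname(calls), unname(want))
})

test_that("the packaged validation panel parses with its published tallies", {
  tab <- caps_validation_table()
  expect_equal(nrow(tab), 24)
  expect_equal(sum(tab$segregation == "Test cross"), 19)
  placed <- tab$segregation == "Test cross" & grepl("^LG ", tab$linkage_group)
  expect_equal(sum(placed), 17)
  expect_equal(length(unique(tab$linkage_group[placed])), 10)
  # cut coordinate consistent with the published fragment pair where the
  # panel's arithmetic is internally consistent
  row <- tab[tab$snp_id == "211-167", ]
  expect_setequal(predict_fragments(row$product_size, row$restriction_site),
                  c(162, 210))
})
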