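# Shared fixtures: one small three-accession simulation reused across test
# files (built once per run), plus tiny constructors.

.fixture_cache <- new.env(parent = emptyenv())

# assembly-ready geometry: contiguous shear window starting at 2x read length
small_sim_params <- function(seed = 11, ...) {
  sim_params(genome_length = 2e5, pstI_site_spacing = 4000,
             insert_range = c(108, 400), insert_dist = "uniform",
             error_rate = 0, seed = seed, ...)
}

small_sim <- function() {
  if (!is.null(.fixture_cache$small_sim)) return(.fixture_cache$small_sim)
  p <- small_sim_params()
  ref <- simulate_reference(p)
  acc <- derive_accessions(ref, p)
  pairs <- simulate_library_set(acc, p, 12000)
  contigs <- assemble_rad_contigs(pairs)
  .fixture_cache$small_sim <- list(params = p, reference = ref,
                                   accessions = acc, pairs = pairs,
                                   contigs = contigs)
  .fixture_cache$small_sim
}

# hand-built read-pair table
make_pairs <- function(se, pe = NULL, sample_id = "s1",
                       se_qual = NULL, pe_qual = NULL) {
  n <- length(se)
  if (is.null(pe)) pe <- se
  if (is.null(se_qual)) se_qual <- strrep("I", nchar(se))
  if (is.null(pe_qual)) pe_qual <- strrep("I", nchar(pe))
  data.table::data.table(
    read_id = sprintf("r%03d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    se_seq = se, pe_seq = pe, se_qual = se_qual, pe_qual = pe_qual)
}

# a pileup-like table built by hand for calling-rule tests
make_pileup <- function(df, contigs, samples = sort(unique(df$sample_id))) {
  pu <- data.table::as.data.table(df)
  data.table::setcolorder(pu, c("contig_id", "pos", "sample_id", "allele", "count"))
  attr(pu, "samples") <- samples
  attr(pu, "contigs") <- contigs
  pu
}

random_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}
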