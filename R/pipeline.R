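#' Run the full synthetic RAD pipeline
#'
#' Simulate (reference, accessions, three-sample library), assemble the RAD
#' contig reference, call and classify variants, and summarise. This is the
#' end-to-end demonstration path; each stage is also available separately.
#'
#' Note on geometry: a single-end-anchored contig requires the shear window
#' to tile contiguously from the cut site (insert minimum near
#' `2 * read_length`); with a gel-selection window like 300-800 nt the mate
#' coverage is disjoint from the single-end block and loci cannot be
#' assembled into anchored contigs (see the methods vignette).
#'
#' @param params [sim_params()]. For assembly-ready geometry pass e.g.
#'   `insert_range = c(108, 400), insert_dist = "uniform"`.
#' @param total_pairs Total read pairs across the three samples.
#' @param ... Stage overrides forwarded to [assemble_rad_contigs()].
#' @return List: `reference`, `accessions`, `pairs`, `contigs`, `stats`
#'   (assembly), `variants` (see [call_variants()]).
#' @export
run_rad_pipeline <- function(params, total_pairs, ...) {
  reference <- simulate_reference(params)
  accessions <- derive_accessions(reference, params)
  pairs <- simulate_library_set(accessions, params, total_pairs)
  contigs <- assemble_rad_contigs(pairs, ...)
  if (nrow(contigs) == 0) stop("assembly produced no contigs under this geometry")
  stats <- assembly_stats(contigs)
  variants <- call_variants(pairs, contigs)
  list(reference = reference, accessions = accessions, pairs = pairs,
       contigs = contigs, stats = stats, variants = variants)
}
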