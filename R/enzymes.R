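#' Built-in restriction enzyme registry
#'
#' The panel used for CAPS conversion of RAD SNPs: BamHI, EcoRI, EcoRV, NdeI,
#' XbaI, XmnI, DraI (6 bp recognition), BccI and FokI (5 bp, type IIS with
#' downstream cut), TaqI and MseI (4 bp), plus PstI (the RAD library enzyme).
#' `cut_offset` is the top-strand cut coordinate measured in nt from the
#' 5' start of the recognition pattern; for type IIS enzymes it exceeds the
#' pattern length (FokI GGATG(9): 5+9, BccI CCATC(4): 5+4).
#'
#' @return A data.frame with columns `name`, `recognition` (IUPAC),
#'   `cut_offset` and `palindromic`.
#' @export
#' @examples
#' enzyme_registry()
enzyme_registry <- function() {
  data.frame(
    name = c("PstI", "BamHI", "EcoRI", "EcoRV", "NdeI", "XbaI",
             "BccI", "FokI", "XmnI", "DraI", "TaqI", "MseI"),
    recognition = c("CTGCAG", "GGATCC", "GAATTC", "GATATC", "CATATG", "TCTAGA",
                    "CCATC", "GGATG", "GAANNNNTTC", "TTTAAA", "TCGA", "TTAA"),
    cut_offset = c(5L, 1L, 1L, 3L, 2L, 1L, 9L, 14L, 5L, 3L, 1L, 1L),
    palindromic = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                    FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Look up one enzyme from the registry
#'
#' @param name Enzyme name (case sensitive, e.g. `"EcoRV"`), or a one-row
#'   data.frame in registry format for user-defined enzymes.
#' @return A one-row data.frame in [enzyme_registry()] format.
#' @export
get_enzyme <- function(name) {
  if (is.data.frame(name)) {
    stopifnot(all(c("name", "recognition", "cut_offset", "palindromic") %in% names(name)))
    return(name[1, , drop = FALSE])
  }
  reg <- enzyme_registry()
  hit <- reg[reg$name == name, , drop = FALSE]
  if (nrow(hit) == 0) stop("unknown enzyme: ", name)
  hit
}

#' Find restriction recognition sites on both strands
#'
#' IUPAC-degenerate matching of the recognition pattern on the plus strand
#' and, for non-palindromic enzymes, of its reverse complement. Each site is
#' reported with the realized top-strand cut coordinate (0-based index of the
#' first base after the cut); minus-strand sites use the mirrored offset.
#' Cut coordinates may fall outside `[0, nchar(sequence)]` for type IIS
#' enzymes cutting beyond a terminal site.
#'
#' @param sequence A single DNA string over A/C/G/T.
#' @param enzyme Enzyme name or registry row (see [get_enzyme()]).
#' @return data.frame with columns `start` (0-based pattern start), `strand`
#'   (`"+"`/`"-"`), and `cut` (0-based top-strand cut coordinate), sorted by
#'   `cut`.
#' @export
#' @examples
#' find_recognition_sites("TTGAATTCTT", "EcoRI")
find_recognition_sites <- function(sequence, enzyme) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  enz <- get_enzyme(enzyme)
  subj <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(enz$recognition)
  L <- length(pat)
  hits_plus <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
  out <- data.frame(start = BiocGenerics::start(hits_plus) - 1L,
                    strand = rep("+", length(hits_plus)),
                    stringsAsFactors = FALSE)
  out$cut <- out$start + enz$cut_offset
  if (!enz$palindromic) {
    hits_minus <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                           subj, fixed = FALSE)
    if (length(hits_minus) > 0) {
      mins <- data.frame(start = BiocGenerics::start(hits_minus) - 1L,
                         strand = "-", stringsAsFactors = FALSE)
      # mirror the top-strand offset around the recognition pattern
      mins$cut <- mins$start + L - enz$cut_offset
      out <- rbind(out, mins)
    }
  }
  out <- out[order(out$cut, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digest a sequence with a restriction enzyme
#'
#' Cuts at every in-range top-strand cut coordinate. Fragment lengths always
#' sum to the input length; a sequence with s internal cut sites yields s + 1
#' fragments.
#'
#' @param sequence A single non-empty DNA string.
#' @param enzyme Enzyme name or registry row. Default `"PstI"`.
#' @return data.frame with columns `fragment` (sequence), `start`, `end`
#'   (0-based half-open) and `length`; attribute `cuts` holds the ordered cut
#'   coordinates used.
#' @export
#' @examples
#' digest("AAACTGCAGAAA", "PstI")  # fragments AAACTGCA | GAAA, cut at 8
digest <- function(sequence, enzyme = "PstI") {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop("cannot digest an empty sequence")
  n <- nchar(sequence)
  sites <- find_recognition_sites(sequence, enzyme)
  cuts <- sort(unique(sites$cut[sites$cut > 0 & sites$cut < n]))
  bounds <- c(0L, cuts, n)
  out <- data.frame(
    start = bounds[-length(bounds)],
    end = bounds[-1]
  )
  out$fragment <- substring(sequence, out$start + 1L, out$end)
  out$length <- out$end - out$start
  out <- out[, c("fragment", "start", "end", "length")]
  attr(out, "cuts") <- cuts
  out
}

#' Predict restriction fragment lengths of a PCR product
#'
#' Given the amplicon size and the cut coordinates realized under one allele,
#' returns the gel fragment lengths: first cut, successive differences, and
#' the tail. Lengths sum to `product_size`.
#'
#' @param product_size Amplicon length in nt.
#' @param cut_positions Strictly increasing cut coordinates, each in
#'   `(0, product_size)`. May be empty (uncut allele).
#' @return Integer vector of fragment lengths.
#' @export
#' @examples
#' predict_fragments(372, 162)  # 162 and 210
predict_fragments <- function(product_size, cut_positions = integer()) {
  stopifnot(length(product_size) == 1, product_size > 0)
  cut_positions <- as.integer(sort(cut_positions))
  if (length(cut_positions) > 0) {
    if (any(cut_positions <= 0 | cut_positions >= product_size))
      stop("cut positions must lie strictly inside (0, product_size)")
    if (anyDuplicated(cut_positions)) stop("duplicated cut positions")
  }
  as.integer(diff(c(0L, cut_positions, as.integer(product_size))))
}
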