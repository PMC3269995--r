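# CpG-stratified k-mer spectra and the Karlin-Mrazek dinucleotide rate.
# Spectra are dense vectors over the 4^k words in lexicographic A<C<G<T
# order; windows containing non-ACGT letters are skipped.

#' Count k-mers over a sequence set
#'
#' Forward-strand counting without canonicalization (set `canonical = TRUE`
#' to merge reverse complements). The total count equals
#' `sum(pmax(nchar(sequences) - k + 1, 0))` for N-free input; windows
#' containing N are skipped.
#'
#' @param sequences Character vector (or `DNAStringSet`) of sequences.
#' @param k Word length (default 10; dense counting limited to k <= 12).
#' @param canonical Merge each k-mer with its reverse complement.
#' @return `kmer_spectrum`: list with `k`, `counts` (integer vector of
#'   length 4^k, lexicographic order), `total`, `canonical`.
#' @export
count_kmers <- function(sequences, k = 10, canonical = FALSE) {
  stopifnot(k >= 1)
  if (k > 12) stop("dense spectra limited to k <= 12")
  x <- if (inherits(sequences, "DNAStringSet")) sequences else
    Biostrings::DNAStringSet(sequences)
  if (k > max(Biostrings::width(x))) {
    warning("k exceeds the longest sequence; empty spectrum")
    counts <- integer(4^k)
  } else {
    counts <- Biostrings::oligonucleotideFrequency(
      x, width = k, step = 1, simplify.as = "collapsed", with.labels = FALSE)
    counts <- as.integer(counts)
  }
  if (canonical) {
    rc <- revcomp_index(k)
    counts <- counts + counts[rc]
    lower <- seq_along(counts) <= rc
    counts[!lower] <- 0L
    # self-complementary words were doubled
    self <- which(rc == seq_along(counts))
    counts[self] <- counts[self] %/% 2L
  }
  structure(list(k = as.integer(k), counts = counts,
                 total = sum(as.numeric(counts)), canonical = canonical),
            class = "kmer_spectrum")
}

# index of the reverse complement of each k-mer in lexicographic order
revcomp_index <- function(k) {
  idx <- seq_len(4^k) - 1
  out <- numeric(length(idx))
  rem <- idx
  for (p in seq_len(k)) {       # read digits from the low (3') end
    digit <- rem %% 4
    rem <- rem %/% 4
    out <- out * 4 + (3 - digit) # complement: A<->T (0<->3), C<->G (1<->2)
  }
  as.integer(out + 1)
}

#' Decode spectrum indices to k-mer strings
#' @param idx 1-based indices into a dense spectrum.
#' @param k Word length.
#' @return Character vector of k-mers.
#' @export
kmer_strings <- function(idx, k) {
  bases <- c("A", "C", "G", "T")
  rem <- idx - 1
  out <- matrix("", length(idx), k)
  for (p in k:1) {
    out[, p] <- bases[rem %% 4 + 1]
    rem <- rem %/% 4
  }
  apply(out, 1, paste, collapse = "")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k=%d, %s words observed, total count %s%s\n",
              x$k, format(sum(x$counts > 0), big.mark = ","),
              format(x$total, big.mark = ","),
              if (x$canonical) " (canonical)" else ""))
  invisible(x)
}

#' Occurrence histogram of a spectrum
#'
#' How many distinct k-mers occur exactly c times, for each observed c.
#'
#' @param spectrum A `kmer_spectrum`, or an integer vector of counts.
#' @return data.frame `occurrence`, `n_kmers`.
#' @export
kmer_histogram <- function(spectrum) {
  counts <- if (inherits(spectrum, "kmer_spectrum")) spectrum$counts else spectrum
  counts <- counts[counts > 0]
  if (length(counts) == 0)
    return(data.frame(occurrence = integer(), n_kmers = integer()))
  tab <- tabulate(counts)
  occ <- which(tab > 0)
  data.frame(occurrence = occ, n_kmers = tab[occ])
}

# per-word occurrence count of a dinucleotide (overlap-counted), computed
# arithmetically from the lexicographic index
dinuc_in_kmers <- function(idx, k, dinucleotide) {
  d <- match(strsplit(dinucleotide, "")[[1]], c("A", "C", "G", "T")) - 1
  if (length(d) != 2 || anyNA(d)) stop("dinucleotide must be 2 letters over ACGT")
  i0 <- idx - 1
  cnt <- integer(length(idx))
  for (p in 0:(k - 2)) {
    b1 <- (i0 %/% 4^(k - 1 - p)) %% 4
    b2 <- (i0 %/% 4^(k - 2 - p)) %% 4
    cnt <- cnt + as.integer(b1 == d[1] & b2 == d[2])
  }
  cnt
}

#' Split a spectrum by dinucleotide content
#'
#' Each observed k-mer is assigned to a class by its overlap-counted number
#' of occurrences of the focal dinucleotide (0, 1, or >= 2), and an
#' occurrence histogram is built per class. The class histograms sum
#' cell-wise to the full-spectrum histogram.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param dinucleotide Focal 2-mer (default `"CG"`, i.e. CpG).
#' @return `spectrum_split`: list with `dinucleotide` and `histograms`, a
#'   named list of data.frames for classes `"0"`, `"1"`, `"ge2"`.
#' @export
split_by_dinucleotide <- function(spectrum, dinucleotide = "CG") {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (nchar(dinucleotide) != 2 ||
      !all(strsplit(dinucleotide, "")[[1]] %in% c("A", "C", "G", "T")))
    stop("dinucleotide must be 2 letters over ACGT")
  nz <- which(spectrum$counts > 0)
  cls <- dinuc_in_kmers(nz, spectrum$k, dinucleotide)
  cls <- pmin(cls, 2L)
  hs <- lapply(0:2, function(g) kmer_histogram(spectrum$counts[nz[cls == g]]))
  names(hs) <- c("0", "1", "ge2")
  structure(list(dinucleotide = dinucleotide, histograms = hs),
            class = "spectrum_split")
}

#' @export
print.spectrum_split <- function(x, ...) {
  n <- vapply(x$histograms, function(h) sum(h$n_kmers), numeric(1))
  cat(sprintf("spectrum_split on %s: %s / %s / %s distinct k-mers with 0 / 1 / >=2 occurrences\n",
              x$dinucleotide, format(n[1], big.mark = ","),
              format(n[2], big.mark = ","), format(n[3], big.mark = ",")))
  invisible(x)
}

#' Random-dinucleotide negative controls for a spectrum split
#'
#' Repeats the class split using dinucleotides sampled uniformly from the 15
#' alternatives to the focal one. On sequence without dinucleotide bias no
#' control should show a preferential (skewed) class distribution.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param n_controls Number of controls (>= 1).
#' @param seed Integer seed.
#' @param exclude Focal dinucleotide to exclude (default `"CG"`).
#' @return Named list of `spectrum_split`, one per sampled dinucleotide.
#' @export
random_dinucleotide_control <- function(spectrum, n_controls, seed,
                                        exclude = "CG") {
  if (n_controls < 1) stop("n_controls must be >= 1")
  bases <- c("A", "C", "G", "T")
  all_d <- as.vector(outer(bases, bases, paste0))
  pool <- setdiff(all_d, exclude)
  with_seed(seed, {
    picks <- sample(pool, n_controls, replace = n_controls > length(pool))
    out <- lapply(picks, function(d) split_by_dinucleotide(spectrum, d))
    names(out) <- picks
    out
  })
}

#' GC fraction of a sequence set
#' @param sequences Character vector of DNA sequences.
#' @return Fraction of G+C over all A/C/G/T bases.
#' @export
gc_fraction <- function(sequences) {
  x <- Biostrings::DNAStringSet(sequences)
  f <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  tot <- colSums(f)
  sum(tot[c("C", "G")]) / sum(tot)
}

#' Karlin-Mrazek CpG rate of a sequence set
#'
#' rho = f(CpG) / (p(C) * p(G)), with f(CpG) the overlap-counted CG
#' dinucleotide frequency per dinucleotide window (sum of L - 1 over
#' sequences) and p(C), p(G) the mononucleotide frequencies. Values below 1
#' indicate CpG suppression. Invariant under concatenation order.
#'
#' @param sequences Character vector of DNA sequences.
#' @param dinucleotide Focal dinucleotide (default `"CG"`).
#' @return List of class `cpg_stats`: `f_dinuc`, `p1`, `p2`, `rho`,
#'   `dinucleotide`.
#' @export
cpg_rate <- function(sequences, dinucleotide = "CG") {
  if (length(sequences) == 0) stop("empty sequence set")
  x <- Biostrings::DNAStringSet(sequences)
  b <- strsplit(dinucleotide, "")[[1]]
  stopifnot(length(b) == 2)
  mono <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  tot <- sum(mono)
  p1 <- sum(mono[, b[1]]) / tot
  p2 <- sum(mono[, b[2]]) / tot
  if (p1 * p2 == 0)
    stop("dinucleotide rate undefined: p(", b[1], ")*p(", b[2], ") = 0")
  nwin <- sum(pmax(Biostrings::width(x) - 1, 0))
  ndi <- sum(Biostrings::vcountPattern(dinucleotide, x))
  f <- ndi / nwin
  structure(list(dinucleotide = dinucleotide, f_dinuc = f, p1 = p1, p2 = p2,
                 rho = f / (p1 * p2)), class = "cpg_stats")
}

#' @export
print.cpg_stats <- function(x, ...) {
  cat(sprintf("%s rate: f=%.4f, p(%s)=%.4f, p(%s)=%.4f, rho=%.3f\n",
              x$dinucleotide, x$f_dinuc, substr(x$dinucleotide, 1, 1), x$p1,
              substr(x$dinucleotide, 2, 2), x$p2, x$rho))
  invisible(x)
}
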