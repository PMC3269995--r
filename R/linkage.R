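# Segregation and two-point linkage: chi-square goodness of fit with the
# mapping inclusion / distortion criteria, recombination estimation with
# LOD, Kosambi map distances, and single-linkage grouping at a LOD
# threshold.

#' Chi-square goodness of fit against a segregation ratio
#'
#' A marker is `included` for mapping when its statistic does not exceed the
#' alpha = 0.01 critical value (fitting, or deviating only marginally, from
#' expectation); it is flagged `distorted` when the statistic exceeds the
#' alpha = 0.1 critical value.
#'
#' @param observed Non-negative class counts (sum > 0).
#' @param ratio Expected ratio, e.g. `c(1, 1)` or `c(1, 2, 1)`.
#' @param alpha_include Significance level bounding inclusion (default 0.01).
#' @param alpha_distort Significance level flagging distortion (default 0.1).
#' @return List of class `segregation_result`: `observed`, `expected`,
#'   `chi2`, `df`, `p_value`, `included`, `distorted`.
#' @export
#' @examples
#' chi_square_gof(c(60, 34), c(1, 1))  # chi2 = 7.19 > 6.635: excluded
chi_square_gof <- function(observed, ratio, alpha_include = 0.01,
                           alpha_distort = 0.1) {
  stopifnot(length(observed) == length(ratio), all(observed >= 0), sum(observed) > 0)
  if (any(ratio <= 0)) stop("expected class proportions must be positive")
  expected <- sum(observed) * ratio / sum(ratio)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(observed = observed, expected = expected, chi2 = chi2,
                 df = df, p_value = pchisq(chi2, df, lower.tail = FALSE),
                 included = chi2 <= qchisq(1 - alpha_include, df),
                 distorted = chi2 > qchisq(1 - alpha_distort, df)),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("chi2 = %.3f (df %d, p = %.3g): %s%s\n", x$chi2, x$df, x$p_value,
              if (x$included) "included for mapping" else "excluded",
              if (x$distorted) ", distorted" else ""))
  invisible(x)
}

#' Segregation report for a genotype matrix
#'
#' Applies [chi_square_gof()] per marker. With `ratio = "auto"` the expected
#' ratio is 1:1 for two observed classes and 1:2:1 for three (het class
#' expected double).
#'
#' @param genotypes Markers x progeny character matrix; `NA` or `"-"` =
#'   missing.
#' @param ratio `"auto"`, or a numeric ratio applied to all markers (class
#'   order = sorted class labels; for 1:2:1 the middle entry must be the het
#'   class, which `"auto"` resolves as the label containing two distinct
#'   alleles, e.g. `"a/b"` or `"h"`).
#' @return data.frame: `marker_id`, class counts, `chi2`, `df`, `p_value`,
#'   `included`, `distorted`.
#' @export
segregation_report <- function(genotypes, ratio = "auto") {
  res <- lapply(seq_len(nrow(genotypes)), function(i) {
    g <- genotypes[i, ]
    g <- g[!is.na(g) & g != "-"]
    tab <- table(g)
    classes <- names(tab)
    r <- if (identical(ratio, "auto")) {
      if (length(tab) == 3) {
        het <- heterozygous_class(classes)
        ord <- c(setdiff(classes, het)[1], het, setdiff(classes, het)[2])
        tab <- tab[ord]
        c(1, 2, 1)
      } else rep(1, length(tab))
    } else ratio
    sr <- chi_square_gof(as.integer(tab), r)
    data.frame(marker_id = rownames(genotypes)[i],
               classes = paste(names(tab), collapse = "|"),
               counts = paste(as.integer(tab), collapse = "|"),
               chi2 = sr$chi2, df = sr$df, p_value = sr$p_value,
               included = sr$included, distorted = sr$distorted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

heterozygous_class <- function(classes) {
  two <- vapply(classes, function(cl) {
    al <- strsplit(cl, "/", fixed = TRUE)[[1]]
    length(unique(al)) == 2 || identical(cl, "h")
  }, logical(1))
  if (sum(two) == 1) classes[two] else classes[2]
}

#' Kosambi map distance
#'
#' d = 25 ln((1 + 2r) / (1 - 2r)) centiMorgans; approximately 100 r for
#' small r, diverging as r approaches 0.5.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Distance(s) in cM.
#' @export
#' @examples
#' kosambi_cm(0.25)  # 25 * ln(3) = 27.465
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("Kosambi distance undefined for r >= 0.5 (or r < 0)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi function
#' @param d Map distance(s) in cM.
#' @return Recombination fraction(s).
#' @export
kosambi_r <- function(d) {
  if (any(d < 0)) stop("negative map distance")
  e <- exp(4 * d / 100)
  (e - 1) / (2 * (e + 1))
}

#' Two-point analysis of a testcross marker pair
#'
#' Both markers carry two genotype classes; recombinants are counted under
#' the phase that minimises r. The LOD is the base-10 likelihood ratio of
#' linkage at the estimate against independence,
#' `n_nr log10(2(1 - r)) + n_r log10(2 r)`, with r clamped to
#' `[1/(2n), 0.5]` for evaluation. Missing genotypes are excluded pairwise.
#'
#' @param g1,g2 Genotype vectors over the same progeny (two classes each;
#'   `NA`/`"-"` missing).
#' @return List of class `two_point_result`: `n`, `n_recombinant`, `r_hat`,
#'   `lod`, `cm`.
#' @export
two_point_testcross <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2) & g1 != "-" & g2 != "-"
  if (!any(ok)) stop("no shared scored progeny")
  a <- as.integer(factor(g1[ok])) - 1L
  b <- as.integer(factor(g2[ok])) - 1L
  if (max(a) > 1 || max(b) > 1) stop("markers must be testcross-coded (two classes)")
  n <- length(a)
  if (n < 2) stop("need at least two shared progeny")
  mism <- sum(a != b)
  rec <- min(mism, n - mism)  # phase minimising r
  r_hat <- rec / n
  r_ev <- min(max(r_hat, 1 / (2 * n)), 0.5)
  lod <- (n - rec) * log10(2 * (1 - r_ev)) + rec * log10(2 * r_ev)
  lod <- max(lod, 0)
  structure(list(n = n, n_recombinant = rec, r_hat = r_hat, lod = lod,
                 cm = kosambi_cm(min(r_hat, 0.5 - 1e-9))),
            class = "two_point_result")
}

#' @export
print.two_point_result <- function(x, ...) {
  cat(sprintf("two-point: r = %.4f (%d/%d), LOD = %.2f, %.2f cM\n",
              x$r_hat, x$n_recombinant, x$n, x$lod, x$cm))
  invisible(x)
}

#' All pairwise two-point results for a genotype matrix
#'
#' @param genotypes Markers x progeny matrix (testcross-coded).
#' @return data.frame `marker1`, `marker2`, `n`, `r_hat`, `lod`, `cm`.
#' @export
two_point_all <- function(genotypes) {
  ids <- rownames(genotypes)
  nm <- nrow(genotypes)
  out <- vector("list", nm * (nm - 1) / 2)
  k <- 0
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      tp <- two_point_testcross(genotypes[i, ], genotypes[j, ])
      k <- k + 1
      out[[k]] <- data.frame(marker1 = ids[i], marker2 = ids[j], n = tp$n,
                             r_hat = tp$r_hat, lod = tp$lod, cm = tp$cm,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Group markers into linkage groups
#'
#' Single-linkage transitive closure over marker pairs with
#' `lod >= threshold` and `r_hat <= max_rec`. Group labels are deterministic
#' (ordered by smallest member id); markers joining no pair are singletons.
#'
#' @param pairs data.frame as from [two_point_all()].
#' @param threshold LOD threshold (default 6.0).
#' @param max_rec Maximum recombination fraction for an edge (default 0.40).
#' @param markers Optional full marker id vector (to include unlinked
#'   markers never appearing in `pairs`).
#' @return List of class `linkage_grouping`: `groups` (named list of member
#'   vectors, `LG1`, `LG2`, ... by smallest member), `singletons`,
#'   `threshold`.
#' @export
group_markers <- function(pairs, threshold = 6.0, max_rec = 0.40,
                          markers = NULL) {
  ids <- sort(unique(c(pairs$marker1, pairs$marker2, markers)))
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  sel <- pairs$lod >= threshold & pairs$r_hat <= max_rec
  for (k in which(sel)) {
    a <- find(match(pairs$marker1[k], ids))
    b <- find(match(pairs$marker2[k], ids))
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(ids), find, 1L)
  groups <- split(ids, root)
  groups <- groups[order(vapply(groups, min, ""))]
  sizes <- vapply(groups, length, 1L)
  singletons <- as.character(unlist(groups[sizes == 1], use.names = FALSE))
  groups <- groups[sizes > 1]
  names(groups) <- if (length(groups)) paste0("LG", seq_along(groups)) else character()
  structure(list(groups = groups, singletons = singletons,
                 threshold = threshold, max_rec = max_rec),
            class = "linkage_grouping")
}

#' @export
print.linkage_grouping <- function(x, ...) {
  cat(sprintf("linkage grouping at LOD >= %.1f, r <= %.2f: %d group(s), %d singleton(s)\n",
              x$threshold, x$max_rec, length(x$groups), length(x$singletons)))
  for (g in names(x$groups))
    cat(sprintf("  %s (%d): %s\n", g, length(x$groups[[g]]),
                paste(utils::head(x$groups[[g]], 8), collapse = ", ")))
  invisible(x)
}
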