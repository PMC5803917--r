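#' Exact over-representation p-value for a 2x2 gene contingency table
#'
#' Given the cross-classification of a gene universe by (differentially
#' expressed vs not) x (in pathway vs not),
#' \describe{
#'   \item{a}{unique DEGs in the pathway}
#'   \item{b}{unique DEGs outside the pathway}
#'   \item{c}{unique non-DEGs in the pathway}
#'   \item{d}{unique non-DEGs outside the pathway}
#' }
#' with `n = a + b + c + d`, the probability of observing exactly `a`
#' pathway DEGs with all margins fixed is the hypergeometric point
#' probability `(a+b)! (c+d)! (a+c)! (b+d)! / (a! b! c! d! n!)`. The
#' over-representation (enrichment) p-value sums this point probability over
#' all tables at least as extreme, i.e. over k >= a
#' (`alternative = "greater"`, the default). `"two.sided"` sums every table
#' whose point probability does not exceed the observed one (the usual
#' Fisher two-sided rule).
#'
#' Computation is done in log space via `lchoose`, summing each tail with
#' the running maximum factored out, so results are accurate to near machine
#' precision even for very small p.
#'
#' All four count arguments are recycled to a common length, so the
#' function is vectorised over tables.
#'
#' @param a,b,c,d Non-negative integer counts (vectors recycled to a common
#'   length).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
#' @examples
#' fisher_p(1, 0, 0, 9)            # single DEG landing in a 1-gene pathway: 0.1
#' fisher_p(0, 0, 10, 90)          # no DEGs at all: 1
fisher_p <- function(a, b, c, d, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  m <- recycle_counts(a, b, c, d)
  with(m, {
    n <- a + b + c + d
    D <- a + b           # DEG margin
    K <- a + c           # pathway margin
    if (alternative == "greater") {
      hyper_upper_tail(a, D, K, n)
    } else {
      hyper_two_sided(a, D, K, n)
    }
  })
}

#' Hypergeometric point probability of the observed table
#'
#' The probability of exactly `a` pathway DEGs with all margins fixed; the
#' closed-form factorial expression evaluated in log space.
#'
#' @inheritParams fisher_p
#' @return Numeric vector of point probabilities.
#' @export
fisher_point_p <- function(a, b, c, d) {
  m <- recycle_counts(a, b, c, d)
  with(m, {
    n <- a + b + c + d
    exp(hyper_lpoint(a, a + b, a + c, n))
  })
}

recycle_counts <- function(a, b, c, d) {
  len <- max(length(a), length(b), length(c), length(d))
  m <- list(a = rep_len(a, len), b = rep_len(b, len),
            c = rep_len(c, len), d = rep_len(d, len))
  for (nm in names(m)) {
    x <- m[[nm]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != round(x))) {
      abort_data(sprintf("count `%s` must be non-negative integer(s)", nm))
    }
  }
  lapply(m, as.numeric)
}

# log point probability P(X = k) for X ~ Hypergeometric(n, K, D)
hyper_lpoint <- function(k, D, K, n) {
  lchoose(D, k) + lchoose(n - D, K - k) - lchoose(n, K)
}

# P(X >= a); unimodality of the pmf puts the largest term at the (clamped)
# mode, which is factored out before summing.
hyper_upper_tail <- function(a, D, K, n) {
  kmax <- pmin(D, K)
  len <- kmax - a + 1L
  idx <- rep.int(seq_along(a), len)
  kk <- sequence(len, from = a)
  lp <- hyper_lpoint(kk, D[idx], K[idx], n[idx])
  kmode <- pmin(pmax(floor((D + 1) * (K + 1) / (n + 2)), a), kmax)
  lmax <- hyper_lpoint(kmode, D, K, n)
  s <- rowsum(exp(lp - lmax[idx]), idx, reorder = TRUE)[, 1L]
  pmin(1, exp(lmax + log(s)))
}

# Fisher's two-sided rule: sum all tables whose point probability does not
# exceed the observed one (with the customary 1 + 1e-7 relative slack).
hyper_two_sided <- function(a, D, K, n) {
  kmin <- pmax(0, D + K - n)
  kmax <- pmin(D, K)
  len <- kmax - kmin + 1L
  idx <- rep.int(seq_along(a), len)
  kk <- sequence(len, from = kmin)
  lp <- hyper_lpoint(kk, D[idx], K[idx], n[idx])
  lobs <- hyper_lpoint(a, D, K, n)
  keep <- lp <= lobs[idx] + log1p(1e-7)
  kmode <- pmin(pmax(floor((D + 1) * (K + 1) / (n + 2)), kmin), kmax)
  lmax <- hyper_lpoint(kmode, D, K, n)
  contrib <- ifelse(keep, exp(lp - lmax[idx]), 0)
  s <- rowsum(contrib, idx, reorder = TRUE)[, 1L]
  pmin(1, exp(lmax + log(s)))
}

#' Build the enrichment contingency table for one DEG set and one pathway
#'
#' Both the DEG pool and the pathway are first intersected with the gene
#' universe; up- and down-regulated genes are pooled into a single DEG set
#' (direction plays no role in the count).
#'
#' @param degs Character vector of DEG symbols (up and down pooled).
#' @param pathway_genes Character vector of the pathway's gene symbols.
#' @param universe Character vector: the knowledge-base gene universe.
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`, `n`.
#' @export
#' @examples
#' build_contingency(c("A", "D"), c("A", "B", "C"), LETTERS[1:10])
build_contingency <- function(degs, pathway_genes, universe) {
  universe <- unique(universe)
  if (!length(universe)) {
    abort_data("gene universe is empty; load a non-empty knowledge base")
  }
  degs <- intersect(unique(degs), universe)
  pw <- intersect(unique(pathway_genes), universe)
  a <- length(intersect(degs, pw))
  b <- length(degs) - a
  c <- length(pw) - a
  d <- length(universe) - a - b - c
  tibble(a = a, b = b, c = c, d = d, n = a + b + c + d)
}
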