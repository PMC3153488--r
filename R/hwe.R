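# Hardy-Weinberg structure diagnostics: per-marker chi-square and exact
# tests, genome-wide scans, and Sidak multiple-testing thresholds. Pooling
# subpopulations with divergent allele frequencies produces a heterozygote
# deficit (Wahlund effect), so an excess of HWE violators in a merged
# sample is direct evidence of structure.

#' Hardy-Weinberg equilibrium tests from genotype counts
#'
#' Pearson chi-square (1 df) against the HWE expectations implied by the
#' sample allele frequency, and the conditional exact test that enumerates
#' all heterozygote counts compatible with the observed allele counts and
#' sums the probabilities of configurations no more probable than the one
#' observed.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (total > 0).
#' @return A list with `chi2`, `p_chi2`, `p_fisher` and `monomorphic`
#'   (TRUE when one allele is absent, in which case `chi2 = 0` and both
#'   p-values are 1 by convention).
#' @examples
#' hwe_tests(30, 40, 30)   # chi2 = 4
#' @export
hwe_tests <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) {
    return(list(chi2 = 0, p_chi2 = 1, p_fisher = 1, monomorphic = TRUE))
  }
  p <- nA / (2 * n)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  p_chi2 <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p_chi2 = p_chi2,
       p_fisher = hwe_exact_p(n_AA, n_Aa, n_aa), monomorphic = FALSE)
}

# exact HWE p-value: enumerate heterozygote counts h with the parity of the
# minor allele count, conditional on the allele counts
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  nr <- min(nA, na)                      # rarer allele count
  h <- seq(nr %% 2, nr, by = 2)          # feasible heterozygote counts
  hom_r <- (nr - h) / 2                  # homozygotes of the rarer allele
  hom_c <- n - h - hom_r
  logp <- lfactorial(n) - lfactorial(hom_r) - lfactorial(h) -
    lfactorial(hom_c) + h * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, h)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

#' Sidak-corrected per-test significance threshold
#'
#' `1 - (1 - alpha_family)^(1/n_tests)`: the per-test level at which
#' `n_tests` independent tests give family-wise error `alpha_family`.
#'
#' @param alpha_family Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return Per-test alpha.
#' @examples
#' sidak_threshold(0.05, 2)   # 0.02532057
#' @export
sidak_threshold <- function(alpha_family, n_tests) {
  stopifnot(n_tests >= 1, alpha_family > 0, alpha_family < 1)
  1 - (1 - alpha_family)^(1 / n_tests)
}

#' @rdname sidak_threshold
#' @param alpha_per_test Per-test level in (0, 1).
#' @return `sidak_family_alpha()`: the family-wise error implied by testing
#'   each of `n_tests` at `alpha_per_test`.
#' @export
sidak_family_alpha <- function(alpha_per_test, n_tests) {
  stopifnot(n_tests >= 1, alpha_per_test > 0, alpha_per_test < 1)
  1 - (1 - alpha_per_test)^n_tests
}

#' Genome-wide Hardy-Weinberg scan
#'
#' Applies [hwe_tests()] to every marker of a genotype matrix and flags
#' violators at the Sidak-corrected threshold for the number of markers
#' actually tested.
#'
#' @param geno Genotype matrix, markers in rows, individuals in columns
#'   (allele counts 0/1/2, NA allowed), or a [genotype_dataset()].
#' @param alpha Family-wise error rate (default 0.05).
#' @param correction `"sidak"` (default) or `"none"` (per-test alpha).
#' @return A list with `results` (tibble: `marker`, `chi2`, `p_chi2`,
#'   `p_fisher`, `monomorphic`, `sig_chi2`, `sig_fisher`), `threshold`,
#'   `n_tests`, `n_sig_chi2`, `n_sig_fisher`.
#' @export
genomewide_hwe_scan <- function(geno, alpha = 0.05,
                                correction = c("sidak", "none")) {
  correction <- match.arg(correction)
  if (inherits(geno, "genotype_dataset")) geno <- geno$geno
  if (is.null(dim(geno)) || nrow(geno) == 0) stop("empty genotype matrix")
  if (is.null(rownames(geno))) rownames(geno) <- paste0("m", seq_len(nrow(geno)))
  res <- apply(geno, 1, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(c(NA, NA, NA, NA))
    tst <- hwe_tests(sum(g == 2), sum(g == 1), sum(g == 0))
    c(tst$chi2, tst$p_chi2, tst$p_fisher, tst$monomorphic)
  })
  tested <- !is.na(res[2, ])
  n_tests <- sum(tested)
  if (n_tests == 0) stop("no marker with genotype data to test")
  threshold <- if (correction == "sidak") sidak_threshold(alpha, n_tests)
               else alpha
  out <- tibble::tibble(
    marker = rownames(geno),
    chi2 = res[1, ], p_chi2 = res[2, ], p_fisher = res[3, ],
    monomorphic = as.logical(res[4, ]),
    sig_chi2 = !is.na(res[2, ]) & res[2, ] < threshold,
    sig_fisher = !is.na(res[3, ]) & res[3, ] < threshold)
  list(results = out, threshold = threshold, n_tests = n_tests,
       n_sig_chi2 = sum(out$sig_chi2), n_sig_fisher = sum(out$sig_fisher))
}
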