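#' Two-locus marker-QTL parameterization
#'
#' Describes a biallelic test marker (allele T at frequency `p`) and a
#' biallelic QTL (allele A at frequency `q`) segregating in one randomly
#' mating population, linked through the linkage-disequilibrium coefficient
#' `D`. The conditional allele probabilities `Q = P(T|A) = (pq + D)/q` and
#' `R = P(T|a) = (p(1-q) - D)/(1-q)` are derived and stored.
#'
#' @param q QTL allele-A frequency, in (0, 1).
#' @param p Test-marker allele-T frequency, in (0, 1).
#' @param D LD coefficient between marker and QTL. Must lie within the
#'   Lewontin bounds `-min(pq, (1-p)(1-q)) <= D <= min(p(1-q), (1-p)q)`.
#' @return An object of class `locus_pair` with fields `q`, `p`, `D`, `Q`, `R`.
#' @examples
#' locus_pair(q = 0.3, p = 0.6, D = 0.05)
#' @export
locus_pair <- function(q, p, D = 0) {
  stopifnot(is.numeric(q), is.numeric(p), is.numeric(D),
            length(q) == 1, length(p) == 1, length(D) == 1)
  if (q <= 0 || q >= 1) stop("QTL allele frequency q must be in (0,1)")
  if (p <= 0 || p >= 1) stop("marker allele frequency p must be in (0,1)")
  bounds <- lewontin_bounds(p, q)
  if (D < bounds[1] - 1e-12)
    stop(sprintf("D = %g below lower Lewontin bound -min(pq, (1-p)(1-q)) = %g",
                 D, bounds[1]))
  if (D > bounds[2] + 1e-12)
    stop(sprintf("D = %g above upper Lewontin bound min(p(1-q), (1-p)q) = %g",
                 D, bounds[2]))
  structure(list(q = q, p = p, D = D,
                 Q = (p * q + D) / q,
                 R = (p * (1 - q) - D) / (1 - q)),
            class = "locus_pair")
}

#' Lewontin bounds for a two-locus LD coefficient
#'
#' @param p,q Allele frequencies at the two loci.
#' @return Numeric vector `c(lower, upper)`.
#' @export
lewontin_bounds <- function(p, q) {
  c(-min(p * q, (1 - p) * (1 - q)), min(p * (1 - q), (1 - p) * q))
}

#' QTL genotypic effects on a quantitative trait
#'
#' Genotypes AA, Aa and aa shift the trait by `d`, `h` and `-d` about the
#' population mean `mu`; residual variation is Normal with variance `sigma2`.
#'
#' @param mu Population trait mean (trait units).
#' @param d Additive genotypic value of AA relative to the homozygote
#'   midpoint (trait units).
#' @param h Dominance value of Aa (trait units). Defaults to 0.
#' @param sigma2 Residual trait variance (trait units squared), > 0.
#' @return An object of class `qtl_effects`.
#' @export
qtl_effects <- function(mu = 0, d = 1, h = 0, sigma2 = 1) {
  stopifnot(is.numeric(mu), is.numeric(d), is.numeric(h), is.numeric(sigma2))
  if (sigma2 <= 0) stop("residual variance sigma2 must be > 0")
  structure(list(mu = mu, d = d, h = h, sigma2 = sigma2),
            class = "qtl_effects")
}

#' One source subpopulation of an admixed sample
#'
#' Allele frequencies for the QTL (`q`), test marker (`p`) and control
#' marker (`c`) in one randomly mating subpopulation, plus the
#' within-subpopulation LD `D` between test marker and QTL. The control
#' marker is assumed to be in linkage equilibrium with both the QTL and the
#' test marker inside each subpopulation.
#'
#' @param q,p,c Allele frequencies in (0, 1).
#' @param D Test-marker/QTL LD coefficient; checked against Lewontin bounds.
#' @return An object of class `subpop_model`.
#' @export
subpop_model <- function(q, p, c, D = 0) {
  lp <- locus_pair(q = q, p = p, D = D)   # validates q, p, D
  if (c <= 0 || c >= 1) stop("control marker frequency c must be in (0,1)")
  structure(list(q = q, p = p, c = c, D = D, pair = lp),
            class = "subpop_model")
}

#' Full parametric description of an admixed study population
#'
#' Two randomly mating subpopulations instantly admixed, subpopulation 1
#' contributing a proportion `m` of the mixture, with a single biallelic QTL
#' acting on a normally distributed trait.
#'
#' @param m Proportion of subpopulation 1, in (0, 1].
#' @param subpop1,subpop2 [subpop_model()] objects.
#' @param effects A [qtl_effects()] object.
#' @return An object of class `admixture_spec`.
#' @examples
#' admixture_spec(0.5,
#'                subpop_model(q = 0.8, p = 0.8, c = 0.8, D = 0),
#'                subpop_model(q = 0.2, p = 0.2, c = 0.2, D = 0),
#'                qtl_effects(d = 1, h = 0, sigma2 = 1))
#' @export
admixture_spec <- function(m, subpop1, subpop2, effects = qtl_effects()) {
  stopifnot(inherits(subpop1, "subpop_model"), inherits(subpop2, "subpop_model"),
            inherits(effects, "qtl_effects"))
  if (!is.numeric(m) || length(m) != 1 || m <= 0 || m > 1)
    stop("admixture proportion m must be in (0, 1]")
  structure(list(m = m, subpop1 = subpop1, subpop2 = subpop2,
                 effects = effects),
            class = "admixture_spec")
}

#' @export
print.admixture_spec <- function(x, ...) {
  cat(sprintf("admixture_spec: m = %g\n", x$m))
  for (i in 1:2) {
    s <- x[[paste0("subpop", i)]]
    cat(sprintf("  subpop %d: q = %g, p = %g, c = %g, D = %g\n",
                i, s$q, s$p, s$c, s$D))
  }
  e <- x$effects
  cat(sprintf("  effects: mu = %g, d = %g, h = %g, sigma2 = %g\n",
              e$mu, e$d, e$h, e$sigma2))
  invisible(x)
}

#' @export
print.locus_pair <- function(x, ...) {
  cat(sprintf("locus_pair: q = %g, p = %g, D = %g (Q = %g, R = %g)\n",
              x$q, x$p, x$D, x$Q, x$R))
  invisible(x)
}
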