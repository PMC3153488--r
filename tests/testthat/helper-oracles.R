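# Brute-force enumeration oracles, independent of the closed-form
# implementations they check.

# Joint genotype distribution at two loci from random union of gametes:
# enumerate all 4 x 4 ordered haplotype pairs and accumulate by allele
# counts. Rows = QTL genotypes AA/Aa/aa, cols = marker TT/Tt/tt.
oracle_joint_distribution <- function(q, p, D) {
  hap <- c(TA = p * q + D,
           Ta = p * (1 - q) - D,
           tA = (1 - p) * q - D,
           ta = (1 - p) * (1 - q) + D)
  carries_T <- c(1, 1, 0, 0)
  carries_A <- c(1, 0, 1, 0)
  tab <- matrix(0, 3, 3, dimnames = list(c("AA", "Aa", "aa"),
                                         c("TT", "Tt", "tt")))
  for (i in 1:4) for (j in 1:4) {
    nA <- carries_A[i] + carries_A[j]
    nT <- carries_T[i] + carries_T[j]
    tab[3 - nA, 3 - nT] <- tab[3 - nA, 3 - nT] + hap[i] * hap[j]
  }
  tab
}

# Exact moments of (X, Y, Z) in the admixed population by cell enumeration
# over subpopulation x QTL genotype x marker genotype x control genotype.
oracle_mixture_moments <- function(spec) {
  eff <- spec$effects
  w <- c(spec$m, 1 - spec$m)
  acc <- c(ex = 0, ex2 = 0, ez = 0, ez2 = 0, exz = 0,
           eg = 0, eg2 = 0, exg = 0, ezg = 0)
  within_cov <- numeric(2)
  for (i in 1:2) {
    sp <- spec[[paste0("subpop", i)]]
    jt <- oracle_joint_distribution(sp$q, sp$p, sp$D)
    pz <- dbinom(0:2, 2, sp$c)
    exi <- 0; egi <- 0; exgi <- 0
    for (gi in 1:3) for (xi in 1:3) {
      pr <- jt[gi, xi]
      g <- 3 - gi; x <- 3 - xi
      gv <- c(-eff$d, eff$h, eff$d)[g + 1]
      exi <- exi + pr * x; egi <- egi + pr * gv; exgi <- exgi + pr * x * gv
      for (z in 0:2) {
        pw <- w[i] * pr * pz[z + 1]
        acc <- acc + pw * c(x, x^2, z, z^2, x * z, gv, gv^2, x * gv, z * gv)
      }
    }
    within_cov[i] <- exgi - exi * egi
  }
  pz_hat <- acc["ez"] / 2
  list(mean_x = unname(acc["ex"]),
       var_x = unname(acc["ex2"] - acc["ex"]^2),
       mean_y = unname(eff$mu + acc["eg"]),
       var_y = unname(acc["eg2"] - acc["eg"]^2 + eff$sigma2),
       var_z = unname(acc["ez2"] - acc["ez"]^2),
       delta = unname(acc["ez2"] - acc["ez"]^2 - 2 * pz_hat * (1 - pz_hat)),
       cov_xy = unname(acc["exg"] - acc["ex"] * acc["eg"]),
       cov_xz = unname(acc["exz"] - acc["ex"] * acc["ez"]),
       cov_zy = unname(acc["ezg"] - acc["ez"] * acc["eg"]),
       within_cov_xy = within_cov)
}

# Mixture haplotype-level LD by pooling haplotype frequencies.
oracle_mixture_ld <- function(spec) {
  f <- function(sp) c(TA = sp$p * sp$q + sp$D)
  w <- c(spec$m, 1 - spec$m)
  f_mix <- w[1] * (spec$subpop1$p * spec$subpop1$q + spec$subpop1$D) +
    w[2] * (spec$subpop2$p * spec$subpop2$q + spec$subpop2$D)
  p_mix <- w[1] * spec$subpop1$p + w[2] * spec$subpop2$p
  q_mix <- w[1] * spec$subpop1$q + w[2] * spec$subpop2$q
  f_mix - p_mix * q_mix
}

# Random valid admixture scenario (frequencies bounded away from 0/1,
# within-subpopulation LD inside the Lewontin bounds, divergent control).
random_spec <- function(zero_ld = FALSE, min_dc = 0.1) {
  m <- runif(1, 0.2, 0.8)
  draw_sub <- function(cfreq) {
    q <- runif(1, 0.15, 0.85); p <- runif(1, 0.15, 0.85)
    D <- if (zero_ld) 0 else {
      bd <- lewontin_bounds(p, q)
      runif(1, 0.8 * bd[1], 0.8 * bd[2])
    }
    subpop_model(q = q, p = p, c = cfreq, D = D)
  }
  c1 <- runif(1, 0.5 + min_dc / 2, 0.9)
  c2 <- runif(1, 0.1, 0.5 - min_dc / 2)
  admixture_spec(m, draw_sub(c1), draw_sub(c2),
                 qtl_effects(mu = runif(1, -1, 1), d = runif(1, 0.5, 2),
                             h = runif(1, -0.5, 0.5),
                             sigma2 = runif(1, 0.5, 2)))
}
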