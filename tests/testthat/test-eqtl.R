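# eQTL scan layer: per-marker scanning, 5 Mb peak merging, strand-aware
# cis/trans windows, and scan summaries.

mk_dataset <- function(gm, chrom, pos) {
  genotype_dataset(gm, data.frame(marker = rownames(gm), chrom = chrom,
                                  pos = pos))
}

test_that("scanning a trait is the marker-wise composition of the single fits", {
  set.seed(41)
  n <- 60
  gm <- rbind(m1 = rbinom(n, 2, 0.5), m2 = rbinom(n, 2, 0.3),
              m3 = rbinom(n, 2, 0.7))
  ds <- mk_dataset(gm, chrom = c("1", "2", "3"), pos = c(1e6, 2e6, 3e6))
  y <- setNames(rnorm(n) + 0.5 * gm["m2", ], colnames(ds$geno))
  sc <- scan_trait(y, ds, method = "simple")
  expect_equal(nrow(sc), 3)
  expect_true(all(sc$status == "ok"))
  for (mk in rownames(gm)) {
    f <- fit_simple(gm[mk, ], y)
    expect_equal(sc$p[sc$marker == mk], f$p, tolerance = 1e-12)
    expect_equal(sc$b[sc$marker == mk], f$b, tolerance = 1e-12)
  }
})

test_that("markers that cannot be analyzed are flagged, not dropped", {
  n <- 40
  set.seed(42)
  gm <- rbind(ok = rbinom(n, 2, 0.5),
              gone = rep(NA_real_, n),
              mono = rep(1, n))
  ds <- mk_dataset(gm, chrom = c("1", "2", "3"), pos = c(1, 1, 1))
  y <- setNames(rnorm(n), colnames(ds$geno))
  sc <- scan_trait(y, ds, method = "simple")
  expect_equal(nrow(sc), 3)
  expect_equal(sc$status[sc$marker == "gone"], "all_missing")
  expect_equal(sc$status[sc$marker == "mono"], "monomorphic")
  expect_true(is.na(sc$p[sc$marker == "gone"]))
  # flagged markers never enter peaks
  pk <- call_peaks(sc, threshold = 1)
  expect_false("gone" %in% unlist(pk$members))
})

test_that("sample alignment is by id, so permuting columns changes nothing", {
  set.seed(43)
  n <- 50
  gm <- rbind(m1 = rbinom(n, 2, 0.4), m2 = rbinom(n, 2, 0.6))
  ds <- mk_dataset(gm, chrom = c("1", "2"), pos = c(1, 1))
  y <- setNames(rnorm(n) + 0.3 * gm["m1", ], colnames(ds$geno))
  sc1 <- scan_trait(y, ds, method = "simple")
  perm <- sample(n)
  sc2 <- scan_trait(y[perm], ds, method = "simple")
  expect_equal(sc1$p, sc2$p, tolerance = 1e-12)
  expect_error(scan_trait(setNames(y, paste0("zz", seq_len(n))), ds),
               "no overlapping samples")
})

test_that("peak calling applies the 5 Mb single-linkage merge rule", {
  res <- function(pos, p, chrom = "1")
    tibble::tibble(marker = paste0("s", seq_along(pos)), chrom = chrom,
                   pos = pos, p = p)

  expect_equal(nrow(call_peaks(res(c(1e6, 4e6), c(0.5, 0.9)), 1e-3)), 0)

  # 3 Mb apart: one peak located at the smaller p
  pk <- call_peaks(res(c(1e6, 4e6), c(1e-5, 1e-8)), 1e-3)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$pos, 4e6)
  expect_equal(pk$min_p, 1e-8)
  expect_equal(pk$n_markers, 2)

  # 6 Mb apart: two peaks
  pk2 <- call_peaks(res(c(1e6, 7e6), c(1e-5, 1e-8)), 1e-3)
  expect_equal(nrow(pk2), 2)

  # chaining: consecutive 4 Mb gaps merge into a single 9 Mb-wide peak
  pk3 <- call_peaks(res(c(1e6, 5e6, 9e6), c(1e-5, 1e-4, 1e-6)), 1e-3)
  expect_equal(nrow(pk3), 1)
  expect_equal(pk3$n_markers, 3)

  # ties break to the lowest position
  pk4 <- call_peaks(res(c(2e6, 3e6), c(1e-7, 1e-7)), 1e-3)
  expect_equal(pk4$pos, 2e6)

  # chromosomes are independent
  two <- rbind(res(c(1e6), 1e-7, "1"), res(c(1.5e6), 1e-7, "2"))
  expect_equal(nrow(call_peaks(two, 1e-3)), 2)
})

test_that("peak calling is idempotent and order-invariant", {
  set.seed(44)
  pos <- sort(sample(1:8e7, 40))
  res <- tibble::tibble(marker = paste0("s", 1:40), chrom = "3", pos = pos,
                        p = 10^runif(40, -9, -1))
  pk <- call_peaks(res, 1e-4)
  # re-calling on the called peaks (one marker per peak) changes nothing
  again <- call_peaks(tibble::tibble(marker = paste0("p", seq_len(nrow(pk))),
                                     chrom = pk$chrom, pos = pk$pos,
                                     p = pk$min_p), 1e-4)
  expect_equal(nrow(again), nrow(pk))
  expect_equal(again$pos, pk$pos)
  # shuffled input gives the same peaks
  pk_shuf <- call_peaks(res[sample(nrow(res)), ], 1e-4)
  expect_equal(pk_shuf$pos, pk$pos)
  expect_equal(pk_shuf$min_p, pk$min_p)
  # every significant marker belongs to exactly one peak
  expect_equal(sum(pk$n_markers), sum(res$p <= 1e-4))
  expect_equal(sort(unlist(pk$members)),
               sort(res$marker[res$p <= 1e-4]))
})

test_that("cis windows run 500 kb upstream of the start to 500 kb past the 3' end, strand-aware", {
  ann <- tibble::tibble(gene = "g1", chrom = "1", start = 1e7,
                        end = 1.005e7, strand = "+")
  mkpeak <- function(pos, chrom = "1", gene = "g1")
    tibble::tibble(gene = gene, chrom = chrom, pos = pos, min_p = 1e-9,
                   n_markers = 1L, members = list("s1"),
                   member_pos = list(pos))

  expect_equal(classify_cis_trans(mkpeak(1e7 - 4e5), ann)$class, "cis")
  expect_equal(classify_cis_trans(mkpeak(1e7 - 5e5), ann)$class, "cis")
  expect_equal(classify_cis_trans(mkpeak(1.005e7 + 5.01e5), ann)$class,
               "trans")
  expect_equal(classify_cis_trans(mkpeak(1e7, chrom = "2"), ann)$class,
               "trans")
  expect_equal(classify_cis_trans(mkpeak(1e7, gene = "unannotated"),
                                  ann)$class, "unknown")

  # asymmetric windows expose the strand logic: on the minus strand the
  # upstream window sits at higher coordinates
  ann_minus <- tibble::tibble(gene = "g1", chrom = "1", start = 1e7,
                              end = 1.005e7, strand = "-")
  up_only <- function(pk, a) classify_cis_trans(pk, a, window_upstream = 5e5,
                                                window_downstream = 0)$class
  expect_equal(up_only(mkpeak(1.005e7 + 4e5), ann_minus), "cis")
  expect_equal(up_only(mkpeak(1e7 - 4e5), ann_minus), "trans")
  expect_equal(up_only(mkpeak(1e7 - 4e5), ann), "cis")

  # membership of any member marker suffices
  wide <- mkpeak(2e7)
  wide$member_pos <- list(c(2e7, 1e7))
  wide$members <- list(c("s1", "s2"))
  expect_equal(classify_cis_trans(wide, ann)$class, "cis")
})

test_that("scan summaries conserve peak counts and partition cis/trans", {
  empty <- call_peaks(tibble::tibble(marker = character(0),
                                     chrom = character(0),
                                     pos = numeric(0), p = numeric(0)), 0.05)
  s0 <- summarize_scan(classify_cis_trans(empty, tibble::tibble(
    gene = character(0), chrom = character(0), start = numeric(0),
    end = numeric(0), strand = character(0))))
  expect_true(all(s0$n == 0))

  pk <- tibble::tibble(
    gene = c("gA", "gA", "gB"), chrom = c("1", "2", "1"),
    pos = c(1e7, 2e7, 5e6), min_p = rep(1e-9, 3), n_markers = rep(1L, 3),
    members = list("a", "b", "c"),
    member_pos = list(1e7, 2e7, 5e6),
    class = c("cis", "trans", "trans"))
  sm <- summarize_scan(pk)
  get <- function(cat) sm$n[sm$category == cat]
  expect_equal(get("2"), 1)   # gA has two peaks
  expect_equal(get("1"), 1)   # gB has one
  expect_equal(get("total"), 3)
  expect_equal(get("cis"), 1)
  expect_equal(get("trans"), 2)
  expect_equal(get("total"), sum(pk$n_markers >= 1))
  expect_equal(get("cis") + get("trans") + get("unknown"), get("total"))
})

test_that("a planted cis-QTL is located by the scan and structure inflates off-chromosome peaks", {
  # genome: chromosome 1 carries the QTL-linked marker, chromosomes 2-6
  # carry unlinked but divergent markers; structure makes the unlinked
  # markers spuriously significant under the simple fit
  set.seed(45)
  n <- 1200
  spec <- default_scenarios()$ld_strong_struct$spec
  s <- simulate_admixed_sample(spec, n, seed = 46)
  L <- 10
  p1 <- runif(L, 0.6, 0.9); p2 <- p1 - 0.4
  lab1 <- s$true_label == 1L
  panel <- matrix(NA_real_, L, n)
  panel[, lab1] <- simulate_marker_panel(p1, rep(0, L - 1), sum(lab1))
  panel[, !lab1] <- simulate_marker_panel(p2, rep(0, L - 1), sum(!lab1))
  rownames(panel) <- paste0("u", 1:L)
  gm <- rbind(qtl_marker = s$x, ctrl = s$z, panel)
  ds <- genotype_dataset(gm, data.frame(
    marker = rownames(gm),
    chrom = c("1", "7", as.character(rep(2:6, each = 2))),
    pos = c(1e6, 1e6, rep(c(1e6, 2e7), 5))))
  y <- setNames(s$y, colnames(ds$geno))

  sc_simple <- scan_trait(y, ds, method = "simple")
  sc_corr <- scan_trait(y, ds, method = "corrected", control = "ctrl")
  thr <- sidak_threshold(0.05, nrow(gm))
  off_simple <- sum(sc_simple$p < thr & sc_simple$chrom != "1", na.rm = TRUE)
  off_corr <- sum(sc_corr$p < thr & sc_corr$chrom != "1" &
                    sc_corr$marker != "ctrl", na.rm = TRUE)
  expect_gt(off_simple, off_corr)
  expect_lte(off_corr, 2)
  # the causal marker stays significant after correction
  expect_lt(sc_corr$p[sc_corr$marker == "qtl_marker"], thr)
})
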