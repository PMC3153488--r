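# Genome-wide per-trait association scanning, p-value-profile peak
# calling with a 5 Mb merge rule, and cis/trans classification of peaks
# against transcript annotation.

#' Scan one trait against every marker of a dataset
#'
#' Runs the chosen association analysis marker by marker. Samples are
#' aligned by id between the trait vector and the genotype columns, never
#' by position. Markers that cannot be fitted (all genotypes missing,
#' monomorphic, or a fit error) are reported with a `status` reason rather
#' than silently dropped.
#'
#' @param y Named numeric vector of trait values (names = sample ids), or
#'   unnamed with length equal to the number of samples in `geno`.
#' @param geno A [genotype_dataset()].
#' @param method `"simple"`, `"corrected"` or `"structured"`.
#' @param control For `method = "corrected"`: either the id of a control
#'   marker in `geno`, or `"auto"` to screen and select per test marker
#'   (the highest-delta eligible candidate on a different chromosome).
#' @param membership_prob For `method = "structured"`: named vector of
#'   membership probabilities.
#' @param max_missing_fraction Screening threshold for `control = "auto"`.
#' @return A tibble with one row per marker: `marker`, `chrom`, `pos`,
#'   `b`, `se`, `t`, `df`, `p`, `n_used`, `method`, `control_marker`,
#'   `status` (`"ok"` or the failure reason).
#' @export
scan_trait <- function(y, geno, method = c("simple", "corrected",
                                           "structured"),
                       control = "auto", membership_prob = NULL,
                       max_missing_fraction = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(geno, "genotype_dataset"))
  if (is.null(names(y))) {
    if (length(y) != length(geno$samples))
      stop("unnamed trait vector must match the number of samples")
    names(y) <- geno$samples
  }
  shared <- intersect(geno$samples, names(y)[!is.na(y)])
  if (length(shared) == 0) stop("no overlapping samples between trait and genotypes")
  yv <- y[shared]
  gm <- geno$geno[, shared, drop = FALSE]
  if (method == "structured") {
    if (is.null(membership_prob)) stop("structured scan needs membership_prob")
    if (is.null(names(membership_prob))) {
      if (length(membership_prob) != length(geno$samples))
        stop("unnamed membership vector must match the number of samples")
      names(membership_prob) <- geno$samples
    }
    pmv <- membership_prob[shared]
  }

  # rank control candidates once; per test marker use the best candidate
  # on a different chromosome
  ranked <- NULL
  if (method == "corrected") {
    if (identical(control, "auto")) {
      ok_missing <- rowMeans(is.na(gm)) < max_missing_fraction
      cand <- geno$map$marker[geno$map$autosome & ok_missing[geno$map$marker]]
      if (length(cand) == 0) stop("no eligible control markers")
      ranked <- attr(select_control_marker(gm[cand, , drop = FALSE],
                                           map = geno$map), "candidates")
    } else {
      if (!control %in% rownames(gm))
        stop("control marker not found in dataset: ", control)
    }
  }

  map <- geno$map
  n_mark <- nrow(map)
  out <- tibble::tibble(
    marker = map$marker, chrom = map$chrom, pos = map$pos,
    b = NA_real_, se = NA_real_, t = NA_real_, df = NA_integer_,
    p = NA_real_, n_used = NA_integer_, method = method,
    control_marker = NA_character_, status = "ok")

  for (i in seq_len(n_mark)) {
    xv <- gm[map$marker[i], ]
    if (all(is.na(xv))) { out$status[i] <- "all_missing"; next }
    if (stats::var(xv, na.rm = TRUE) == 0) { out$status[i] <- "monomorphic"; next }
    fit <- tryCatch({
      switch(method,
        simple = fit_simple(xv, yv),
        corrected = {
          ctl <- if (!is.null(ranked)) {
            cands <- ranked$marker[ranked$chrom != map$chrom[i] &
                                     ranked$marker != map$marker[i]]
            if (length(cands) == 0) stop("no control marker on another chromosome")
            cands[1]
          } else control
          out$control_marker[i] <- ctl
          fit_corrected(xv, gm[ctl, ], yv)
        },
        structured = fit_structured(xv, pmv, yv))
    }, error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      out$status[i] <- fit
    } else {
      out$b[i] <- fit$b; out$se[i] <- fit$se; out$t[i] <- fit$t
      out$df[i] <- fit$df; out$p[i] <- fit$p; out$n_used[i] <- fit$n_used
    }
  }
  out
}

#' Call eQTL peaks from a per-marker p-value profile
#'
#' An eQTL is an independent peak in the p-value profile of one
#' chromosome: markers significant at `threshold` are grouped by
#' single-linkage chaining (a significant marker joins a peak whenever it
#' lies within `merge_distance` of any member), each group forming one
#' peak whose location is its smallest p-value (ties break to the lowest
#' position).
#'
#' @param results Tibble with columns `marker`, `chrom`, `pos`, `p`
#'   (e.g. from [scan_trait()]); rows with NA p are ignored.
#' @param threshold Significance threshold on p.
#' @param merge_distance Peaks closer than this are merged (bp; default
#'   5e6).
#' @param gene Optional trait/gene id attached to the peaks.
#' @return A tibble with one row per peak: `gene`, `chrom`, `pos`,
#'   `min_p`, `n_markers`, `members` (list of marker ids), `member_pos`
#'   (list of their positions).
#' @export
call_peaks <- function(results, threshold, merge_distance = 5e6,
                       gene = NA_character_) {
  sig <- results[!is.na(results$p) & results$p <= threshold, , drop = FALSE]
  empty <- tibble::tibble(gene = character(0), chrom = character(0),
                          pos = numeric(0), min_p = numeric(0),
                          n_markers = integer(0), members = list(),
                          member_pos = list())
  if (nrow(sig) == 0) return(empty)
  peaks <- list()
  for (ch in unique(sig$chrom)) {
    sc <- sig[sig$chrom == ch, , drop = FALSE]
    sc <- sc[order(sc$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(sc$pos) > merge_distance))
    for (g in unique(grp)) {
      sg <- sc[grp == g, , drop = FALSE]
      best <- which(sg$p == min(sg$p))
      best <- best[which.min(sg$pos[best])]
      peaks[[length(peaks) + 1]] <- tibble::tibble(
        gene = gene, chrom = as.character(ch), pos = sg$pos[best],
        min_p = sg$p[best], n_markers = nrow(sg),
        members = list(sg$marker), member_pos = list(sg$pos))
    }
  }
  do.call(rbind, peaks)
}

#' Read transcript annotation (BED or 1-based TSV)
#'
#' BED input is 0-based half-open and converted to 1-based inclusive
#' coordinates; the TSV dialect (`gene`, `chrom`, `start`, `end`,
#' `strand`) is already 1-based inclusive.
#'
#' @param path File path.
#' @param format `"tsv"` or `"bed"`.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`, `strand`
#'   (`start <= end`, genomic orientation).
#' @export
read_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("BED annotation needs 6 columns (chrom, start, end, name, score, strand)")
    out <- tibble::tibble(gene = df[[4]], chrom = as.character(df[[1]]),
                          start = df[[2]] + 1, end = df[[3]],
                          strand = df[[6]])
  } else {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "start", "end", "strand")
    if (!all(need %in% names(df)))
      stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
    out <- tibble::as_tibble(df[need])
    out$chrom <- as.character(out$chrom)
  }
  if (any(out$start > out$end)) stop("annotation has start > end")
  if (!all(out$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out
}

#' Classify peaks as cis or trans relative to their regulated transcript
#'
#' A peak is cis when any of its member markers lies on the transcript's
#' chromosome within the window from `window_upstream` bp upstream of the
#' transcript start to `window_downstream` bp downstream of the 3' end;
#' otherwise trans. Upstream/downstream are resolved by strand: for a
#' minus-strand transcript the biological start is the higher genomic
#' coordinate. Peaks whose gene has no annotation get `"unknown"`.
#'
#' @param peaks Peak tibble from [call_peaks()] (with a `gene` column).
#' @param annotation Annotation tibble (see [read_annotation()]).
#' @param window_upstream,window_downstream Window sizes in bp (default
#'   5e5 each).
#' @return `peaks` with a `class` column (`"cis"`, `"trans"`, `"unknown"`).
#' @export
classify_cis_trans <- function(peaks, annotation,
                               window_upstream = 5e5,
                               window_downstream = 5e5) {
  if (nrow(peaks) == 0) {
    peaks$class <- character(0)
    return(peaks)
  }
  cls <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ann <- annotation[annotation$gene == peaks$gene[i], , drop = FALSE]
    if (nrow(ann) == 0) { cls[i] <- "unknown"; next }
    ann <- ann[1, ]
    if (ann$strand == "+") {
      lo <- ann$start - window_upstream
      hi <- ann$end + window_downstream
    } else {
      lo <- ann$start - window_downstream
      hi <- ann$end + window_upstream
    }
    mp <- peaks$member_pos[[i]]
    cls[i] <- if (peaks$chrom[i] == ann$chrom && any(mp >= lo & mp <= hi))
      "cis" else "trans"
  }
  peaks$class <- cls
  peaks
}

#' Summarize peaks over all scanned traits
#'
#' Tabulates how many traits have 1, 2, ..., >= 10 peaks, the total peak
#' count, and the cis/trans totals.
#'
#' @param peaks Peak tibble (rows from [call_peaks()], possibly several
#'   traits, ideally after [classify_cis_trans()]).
#' @return A tibble with columns `category` (`"1"` ... `"9"`, `">=10"`,
#'   `"total"`, `"cis"`, `"trans"`, `"unknown"`) and `n`.
#' @export
summarize_scan <- function(peaks) {
  cats <- c(as.character(1:9), ">=10", "total", "cis", "trans", "unknown")
  n <- stats::setNames(rep(0L, length(cats)), cats)
  if (nrow(peaks) > 0) {
    per_trait <- table(peaks$gene)
    for (k in per_trait) {
      key <- if (k >= 10) ">=10" else as.character(k)
      n[key] <- n[key] + 1L
    }
    n["total"] <- nrow(peaks)
    if ("class" %in% names(peaks)) {
      n["cis"] <- sum(peaks$class == "cis")
      n["trans"] <- sum(peaks$class == "trans")
      n["unknown"] <- sum(peaks$class == "unknown")
    }
  }
  tibble::tibble(category = cats, n = as.integer(n))
}
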