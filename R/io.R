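# File I/O: the 0/1/2 genotype TSV dialect, biallelic-SNP VCF import,
# phenotype tables, and the genotype_dataset container shared by the
# association and scan layers.

#' Genotype dataset container
#'
#' Allele-count matrix (markers in rows, samples in columns; entries 0, 1,
#' 2 or NA) together with the marker map and a provenance record. The map
#' is sorted by chromosome and position on construction.
#'
#' @param geno Numeric matrix of allele counts with marker rownames.
#' @param map Data frame with columns `marker`, `chrom`, `pos` and
#'   optionally `autosome` (inferred from the chromosome label when absent:
#'   labels that parse as numbers are autosomes).
#' @param samples Character vector of sample ids (defaults to the matrix
#'   column names).
#' @param provenance Optional list describing the source (file, format,
#'   counted allele per marker).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(geno, map, samples = colnames(geno),
                             provenance = list()) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno))) rownames(geno) <- map$marker
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(geno)))
  colnames(geno) <- samples
  map <- tibble::as_tibble(map)
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)),
            nrow(map) == nrow(geno))
  if (nrow(map) == 0) stop("zero markers in dataset")
  if (anyDuplicated(map$marker)) stop("duplicate marker ids")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  bad <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad)) stop("genotype entries must be allele counts 0/1/2 or NA")
  if (!"autosome" %in% names(map)) {
    lab <- sub("^[Cc]hr", "", as.character(map$chrom))
    map$autosome <- !is.na(suppressWarnings(as.numeric(lab)))
  }
  ord <- order(chrom_rank(map$chrom), map$pos)
  map <- map[ord, ]
  geno <- geno[map$marker, , drop = FALSE]
  structure(list(geno = geno, map = map, samples = samples,
                 provenance = provenance),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d markers x %d samples (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  cat("  chromosomes:", paste(unique(x$map$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Read genotypes from a TSV dialect or a VCF
#'
#' The TSV dialect has header columns `marker`, `chrom`, `pos` followed by
#' one column per sample; entries are allele counts `0`, `1`, `2` or `NA`.
#' VCF import keeps biallelic SNP records only (multiallelic or indel sites
#' are skipped, with the count reported via `message()`), converting
#' genotype calls to counts of the ALT allele; `./.` becomes NA. The
#' counted allele for each marker is stored in the provenance record, since
#' the sign of a fitted regression coefficient depends on allele
#' orientation.
#'
#' @param path File path.
#' @param format `"tsv012"` or `"vcf"`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("tsv012", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  switch(format,
         tsv012 = read_genotypes_tsv(path),
         vcf = read_genotypes_vcf(path))
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(df)[1:3]))
    stop("genotype TSV must start with columns marker, chrom, pos: ", path)
  if (nrow(df) == 0) stop("zero markers in genotype file: ", path)
  samples <- names(df)[-(1:3)]
  if (length(samples) == 0) stop("no sample columns in genotype file: ", path)
  gm <- as.matrix(df[, -(1:3), drop = FALSE])
  suppressWarnings(storage.mode(gm) <- "numeric")
  raw <- as.matrix(df[, -(1:3), drop = FALSE])
  bad <- which(is.na(gm) & !(raw %in% c("NA", "", NA)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("malformed genotype '%s' at line %d (marker %s, sample %s)",
                 raw[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L,
                 df$marker[bad[1, 1]], samples[bad[1, 2]]))
  ok <- matrix(gm %in% c(0, 1, 2) | is.na(gm), nrow(gm))
  if (!all(ok)) {
    i <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("genotype value %s not in {0,1,2,NA} at line %d",
                 gm[i[1], i[2]], i[1] + 1L))
  }
  rownames(gm) <- df$marker
  genotype_dataset(gm,
                   map = df[, need],
                   samples = samples,
                   provenance = list(source = path, format = "tsv012",
                                     counted_allele = stats::setNames(
                                       rep("as-coded", nrow(gm)), df$marker)))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message(n_skip, " non-biallelic-SNP record(s) skipped in ", path)
  if (sum(snp) == 0) stop("zero biallelic SNP markers in VCF: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  counts <- matrix(NA_real_, nrow(gt), ncol(gt),
                   dimnames = list(ids, colnames(gt)))
  known <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
             "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2)
  counts[] <- known[gt]
  genotype_dataset(counts,
                   map = data.frame(marker = ids,
                                    chrom = fix[, "CHROM"],
                                    pos = as.numeric(fix[, "POS"])),
                   samples = colnames(gt),
                   provenance = list(source = path, format = "vcf",
                                     counted_allele = stats::setNames(alt[snp], ids),
                                     n_skipped = n_skip))
}

#' Write a genotype dataset in the 0/1/2 TSV dialect
#'
#' @param geno A [genotype_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_dataset"))
  df <- data.frame(marker = geno$map$marker, chrom = geno$map$chrom,
                   pos = geno$map$pos, check.names = FALSE)
  df <- cbind(df, as.data.frame(geno$geno, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a phenotype/expression table
#'
#' TSV with a sample-id column (the first column) and one numeric column
#' per trait; NA allowed. Sample alignment with genotypes is done
#' downstream by id, never by position.
#'
#' @param path File path.
#' @return A tibble whose first column is `sample_id`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype TSV needs a sample id column and at least one trait")
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in phenotype file: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (j in 2:ncol(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !(col %in% c("NA", "", NA)))
      if (length(bad) > 0)
        stop(sprintf("non-numeric phenotype value '%s' in row %d, column '%s'",
                     col[bad[1]], bad[1], names(df)[j]))
      df[[j]] <- num
    }
  }
  tibble::as_tibble(df)
}

#' Write a phenotype table
#'
#' Values are written with full (17 significant digit) precision so a
#' write/read round trip reproduces fits bit for bit.
#'
#' @param pheno Data frame whose first column is the sample id.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- as.data.frame(pheno)
  for (j in 2:ncol(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Export a simulated admixed sample as analysis-ready files
#'
#' Writes the test marker (chromosome 1), control marker (chromosome 2)
#' and any panel markers (spread over chromosomes 3 onward) as a genotype
#' TSV, the trait as a phenotype TSV, and the membership assignments as a
#' third TSV, so simulated data round-trips through the public readers.
#'
#' @param sample An `admix_sample` from [simulate_admixed_sample()].
#' @param prefix Output path prefix; files `<prefix>_genotypes.tsv`,
#'   `<prefix>_phenotypes.tsv`, `<prefix>_membership.tsv` are written.
#' @param panel Optional marker panel matrix (markers x individuals).
#' @return Named character vector of the paths written.
#' @export
write_admix_sample <- function(sample, prefix, panel = NULL) {
  stopifnot(inherits(sample, "admix_sample"))
  n <- length(sample$x)
  ids <- sprintf("ind%04d", seq_len(n))
  gm <- rbind(test_marker = sample$x, control_marker = sample$z)
  map <- data.frame(marker = c("test_marker", "control_marker"),
                    chrom = c("1", "2"), pos = c(1e6, 1e6))
  if (!is.null(panel)) {
    stopifnot(ncol(panel) == n)
    if (is.null(rownames(panel)))
      rownames(panel) <- paste0("panel", seq_len(nrow(panel)))
    chroms <- as.character(3 + (seq_len(nrow(panel)) - 1) %% 20)
    map <- rbind(map, data.frame(marker = rownames(panel), chrom = chroms,
                                 pos = 1e6 + 1e5 * seq_len(nrow(panel))))
    gm <- rbind(gm, panel)
  }
  colnames(gm) <- ids
  ds <- genotype_dataset(gm, map, samples = ids,
                         provenance = list(source = "simulated",
                                           format = "tsv012"))
  paths <- c(genotypes = paste0(prefix, "_genotypes.tsv"),
             phenotypes = paste0(prefix, "_phenotypes.tsv"),
             membership = paste0(prefix, "_membership.tsv"))
  write_genotypes(ds, paths["genotypes"])
  write_phenotypes(data.frame(sample_id = ids, trait = sample$y),
                   paths["phenotypes"])
  utils::write.table(
    data.frame(sample_id = ids, true_label = sample$true_label,
               membership_prob = sample$membership_prob),
    paths["membership"], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
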