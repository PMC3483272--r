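# File I/O in the PLINK dialect: whitespace .eigenvec / phenotype files
# (header optional, detected by a leading "FID"), combined TSV (header
# required), phenotype codes 1 = healthy control, 2 = diseased case,
# 0 / -9 = missing.

.has_fid_header <- function(path) {
  first <- readLines(path, n = 1L)
  length(first) == 1L && grepl("^\\s*#?FID\\b", first)
}

.read_ws_table <- function(path, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = header, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

.check_numeric_cols <- function(df, cols, path) {
  for (cn in cols) {
    x <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(x) & !is.na(df[[cn]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column %s at data line %d",
                   path, cn, bad[1]))
    if (anyNA(x))
      stop(sprintf("%s: missing value in column %s", path, cn))
    df[[cn]] <- x
  }
  df
}

.map_phenotype <- function(code, path) {
  code <- suppressWarnings(as.numeric(code))
  if (anyNA(code) || !all(code %in% c(-9, 0, 1, 2)))
    stop(path, ": phenotype codes must be 1 (healthy), 2 (diseased), or 0/-9 (missing)")
  out <- rep(NA_character_, length(code))
  out[code == 1] <- "healthy"
  out[code == 2] <- "diseased"
  out
}

#' Read a cohort from delimited text
#'
#' Two layouts are accepted. A single combined TSV (header required) with
#' columns `FID`, `IID`, `PHENOTYPE` (or `PHENO`), `PC1..PCk` and optional
#' `WEIGHT`; or a PLINK-style pair: a whitespace `.eigenvec` file
#' (`FID IID PC1..PCk`, header optional) plus a phenotype file
#' (`FID IID PHENO`, header optional) sharing the same `(FID, IID)` keys.
#' Phenotype codes follow the PLINK convention (1 = healthy, 2 = diseased);
#' subjects with missing codes (0 or -9) are excluded with a message.
#'
#' @param path Combined TSV, or `.eigenvec` file when `pheno_path` is given.
#' @param pheno_path Optional phenotype file path.
#' @return A [cohort()] in file order.
#' @export
read_cohort <- function(path, pheno_path = NULL) {
  if (is.null(pheno_path)) {
    df <- .read_ws_table(path, header = TRUE)
    names(df)[names(df) == "PHENO"] <- "PHENOTYPE"
    need <- c("FID", "IID", "PHENOTYPE")
    if (!all(need %in% names(df)))
      stop(path, ": combined cohort table needs columns FID, IID, PHENOTYPE")
    pc_cols <- grep("^PC[0-9]+$", names(df), value = TRUE)
    if (!length(pc_cols)) stop(path, ": no PC columns (PC1..PCk) found")
    pc_cols <- pc_cols[order(as.integer(sub("PC", "", pc_cols)))]
    df <- .check_numeric_cols(df, pc_cols, path)
    weights <- if ("WEIGHT" %in% names(df))
      .check_numeric_cols(df, "WEIGHT", path)$WEIGHT else rep(1, nrow(df))
    pheno <- .map_phenotype(df$PHENOTYPE, path)
    fid <- as.character(df$FID); iid <- as.character(df$IID)
    coords <- as.matrix(df[, pc_cols, drop = FALSE])
  } else {
    ev <- .read_ws_table(path, header = .has_fid_header(path))
    if (!.has_fid_header(path))
      names(ev) <- c("FID", "IID", paste0("PC", seq_len(ncol(ev) - 2L)))
    pc_cols <- grep("^PC[0-9]+$", names(ev), value = TRUE)
    if (!length(pc_cols)) stop(path, ": no PC columns found")
    ev <- .check_numeric_cols(ev, pc_cols, path)
    ph <- .read_ws_table(pheno_path, header = .has_fid_header(pheno_path))
    if (ncol(ph) < 3L) stop(pheno_path, ": expected FID IID PHENO columns")
    names(ph)[1:3] <- c("FID", "IID", "PHENOTYPE")
    key_ev <- paste(ev$FID, ev$IID); key_ph <- paste(ph$FID, ph$IID)
    if (anyDuplicated(key_ev)) stop(path, ": duplicate (FID, IID) keys")
    if (anyDuplicated(key_ph)) stop(pheno_path, ": duplicate (FID, IID) keys")
    if (!setequal(key_ev, key_ph))
      stop("eigenvec and phenotype files do not share the same (FID, IID) keys")
    ph <- ph[match(key_ev, key_ph), ]
    pheno <- .map_phenotype(ph$PHENOTYPE, pheno_path)
    fid <- as.character(ev$FID); iid <- as.character(ev$IID)
    coords <- as.matrix(ev[, pc_cols, drop = FALSE])
    weights <- rep(1, nrow(ev))
  }
  if (anyDuplicated(paste(fid, iid))) stop(path, ": duplicate (FID, IID) keys")
  drop <- is.na(pheno)
  if (any(drop))
    message(sprintf("excluding %d subject(s) with missing phenotype code",
                    sum(drop)))
  if (all(drop)) stop("no subjects with a non-missing phenotype")
  cohort(iid[!drop], pheno[!drop], coords[!drop, , drop = FALSE],
         weights[!drop], fid = fid[!drop])
}

#' Write homogenized weights as a TSV
#'
#' Columns `FID IID WEIGHT` at full precision, in cohort order; the file
#' round-trips through [read_cohort()]'s `WEIGHT` column exactly.
#'
#' @param x A [homogenize()] result or a [cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(x, path) {
  if (inherits(x, "homog_result")) {
    df <- data.frame(FID = x$fid, IID = x$ids,
                     WEIGHT = sprintf("%.17g", unname(x$final_weights)))
  } else if (inherits(x, "cohort")) {
    df <- data.frame(FID = x$fid, IID = x$ids,
                     WEIGHT = sprintf("%.17g", x$weights))
  } else stop("x must be a homogenization result or a cohort")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weights TSV (`FID IID WEIGHT`)
#'
#' @param path Path written by [write_weights()].
#' @return Named numeric vector of weights (names = IID).
#' @export
read_weights <- function(path) {
  df <- .read_ws_table(path, header = TRUE)
  if (!all(c("IID", "WEIGHT") %in% names(df)))
    stop(path, ": expected columns FID IID WEIGHT")
  df <- .check_numeric_cols(df, "WEIGHT", path)
  stats::setNames(df$WEIGHT, as.character(df$IID))
}

#' Write a PC projection as a PLINK-style .eigenvec file
#'
#' Whitespace table `FID IID PC1..PCk`, no header.
#'
#' @param proj A [compute_pcs()] result.
#' @param path Output path.
#' @param fid Family IDs; default the subject IDs.
#' @return `path`, invisibly.
#' @export
write_eigenvec <- function(proj, path, fid = proj$subjects) {
  df <- data.frame(FID = fid, IID = proj$subjects,
                   format(proj$coords, digits = 10, trim = TRUE))
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PLINK .raw additive genotype file
#'
#' Whitespace table with header `FID IID PAT MAT SEX PHENOTYPE` followed by
#' one column per SNP holding dosages 0/1/2 (`NA` for missing).
#'
#' @param path Path to the .raw file.
#' @return A [genotype_matrix()]; the file's `PHENOTYPE` and `FID` columns
#'   are attached as attributes `"phenotype_code"` and `"fid"`.
#' @export
read_plink_raw <- function(path) {
  df <- .read_ws_table(path, header = TRUE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(df)[1:6]))
    stop(path, ": expected PLINK .raw header FID IID PAT MAT SEX PHENOTYPE ...")
  calls <- as.matrix(df[, -(1:6), drop = FALSE])
  storage.mode(calls) <- "double"
  g <- genotype_matrix(calls, subjects = as.character(df$IID),
                       snps = colnames(calls))
  attr(g, "phenotype_code") <- df$PHENOTYPE
  attr(g, "fid") <- as.character(df$FID)
  g
}

#' Read genotype dosages from a VCF
#'
#' Dosage is the count of ALT alleles in the GT field; missing calls become
#' `NA`.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return A [genotype_matrix()] (subjects x SNPs).
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- !is.na(gt) & !grepl("\\.", gt)
  parts <- strsplit(gt[ok], "[/|]")
  dos[ok] <- vapply(parts, function(a) sum(a != "0"), numeric(1))
  snp_ids <- rownames(gt)
  if (is.null(snp_ids) || anyDuplicated(snp_ids))
    snp_ids <- sprintf("snp%d", seq_len(nrow(gt)))
  genotype_matrix(t(dos), subjects = colnames(gt), snps = snp_ids)
}
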