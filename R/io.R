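#' Read a phenotype/covariate table
#'
#' Whitespace-delimited table with a header row; one id column, one trait
#' column and optional covariate columns.  Individuals with missing (`NA`)
#' phenotype are dropped.
#'
#' @param path file path.
#' @param trait trait column name.
#' @param covariates covariate column names (may be empty).
#' @param id id column name (default: first column).
#' @return list with `ids`, `y`, `X` (intercept plus covariates).
#' @export
read_phenotype <- function(path, trait, covariates = NULL, id = NULL) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (is.null(id)) id <- names(tab)[1]
  for (col in c(id, trait, covariates))
    if (!col %in% names(tab)) stop("column not found in phenotype file: ", col)
  keep <- !is.na(tab[[trait]])
  tab <- tab[keep, , drop = FALSE]
  X <- matrix(1, nrow(tab), 1L, dimnames = list(NULL, "(Intercept)"))
  if (length(covariates))
    X <- cbind(X, as.matrix(tab[, covariates, drop = FALSE]))
  list(ids = as.character(tab[[id]]), y = as.numeric(tab[[trait]]), X = X)
}

#' Read a BED-like region definition file
#'
#' Whitespace-delimited columns: chrom, start, end, name; positions are
#' 1-based inclusive, as in VCF coordinates.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_regions <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("region file needs 4 columns: chrom start end name")
  names(tab)[1:4] <- c("chrom", "start", "end", "name")
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  tab[, 1:4]
}

# normalise a dosage matrix (individuals x variants) to minor-allele
# orientation; NA-safe
.minor_orient <- function(D) {
  af <- colMeans(D, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) D[, flip] <- 2 - D[, flip]
  D
}

#' Read genotypes from a plain dosage-matrix file
#'
#' Whitespace-delimited; header `id pos <sample ids...>`, one row per
#' variant with its identifier, physical position and per-individual
#' dosages (0/1/2, `NA` allowed).
#'
#' @param path file path.
#' @return list of class `geno_set`: `ids` (individuals), `chrom`, `pos`,
#'   `vid`, and `D`, the individuals x variants dosage matrix in
#'   minor-allele orientation.
#' @export
read_genotype_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 3L) stop("dosage matrix needs id, pos and sample columns")
  ids <- names(tab)[-(1:2)]
  D <- t(as.matrix(tab[, -(1:2), drop = FALSE]))
  colnames(D) <- tab[[1]]
  rownames(D) <- ids
  structure(list(ids = ids, chrom = rep(".", nrow(tab)),
                 pos = as.integer(tab[[2]]), vid = as.character(tab[[1]]),
                 D = .minor_orient(D)),
            class = "geno_set")
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field into minor-allele dosages.  Multi-allelic records
#' are skipped with a warning; missing genotypes become `NA` (imputed to
#' the variant mean when a region is built).
#'
#' @param path VCF path (plain text or bgzipped).
#' @return a `geno_set` as in [read_genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(a, function(x) {
      if (any(x == "." | x == "")) return(NA_real_)
      sum(x == "1")
    }, numeric(1))
  }
  D <- t(apply(gt, 1L, count_alt))          # variants x individuals
  D <- t(D)                                 # individuals x variants
  vid <- fix[, "ID"]
  vid[is.na(vid) | vid == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(vid) | vid == "."]
  colnames(D) <- vid
  structure(list(ids = colnames(gt), chrom = fix[, "CHROM"],
                 pos = as.integer(fix[, "POS"]), vid = vid,
                 D = .minor_orient(D)),
            class = "geno_set")
}

#' Assemble regions from a genotype set and region definitions
#'
#' Subsets the genotype set to each region's 1-based inclusive interval,
#' drops monomorphic variants (with a log message), aligns individuals to
#' `sample_order`, and returns [flm_region()] objects.  Regions left with
#' no polymorphic variant are skipped with a warning.
#'
#' @param geno a `geno_set`.
#' @param regiondefs data.frame from [read_regions()].
#' @param sample_order individual ids defining the row order (must all be
#'   present in the genotype set).
#' @param verbose log dropped-variant counts.
#' @return named list of [flm_region()] objects.
#' @export
make_regions <- function(geno, regiondefs, sample_order = geno$ids,
                         verbose = FALSE) {
  missing_ids <- setdiff(sample_order, geno$ids)
  if (length(missing_ids))
    stop("individuals absent from genotype data: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "),
         if (length(missing_ids) > 5L) ", ...")
  D <- geno$D[match(sample_order, geno$ids), , drop = FALSE]
  out <- list()
  n_mono <- 0L
  for (i in seq_len(nrow(regiondefs))) {
    sel <- which(geno$chrom %in% c(regiondefs$chrom[i], ".") &
                   geno$pos >= regiondefs$start[i] &
                   geno$pos <= regiondefs$end[i])
    if (!length(sel)) {
      warning("region ", regiondefs$name[i], " contains no variants")
      next
    }
    reg <- tryCatch(
      flm_region(D[, sel, drop = FALSE], geno$pos[sel],
                 name = regiondefs$name[i], ids = geno$vid[sel],
                 drop_monomorphic = TRUE),
      error = function(e) NULL)
    if (is.null(reg)) {
      warning("region ", regiondefs$name[i], " is monomorphic; skipped")
      next
    }
    n_mono <- n_mono + length(sel) - reg$m
    out[[regiondefs$name[i]]] <- reg
  }
  if (verbose && n_mono > 0L)
    message(n_mono, " monomorphic variant(s) dropped")
  out
}

#' Write a regional scan result table
#'
#' @param res data.frame from [region_scan()].
#' @param path output TSV path.
#' @export
write_region_results <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a simulated dataset as VCF + FAM + phenotype files
#'
#' Writes plain-text files suitable for an end-to-end round trip through
#' the readers: a VCF v4.2 with GT genotypes reconstructed from the
#' dosages, a FAM pedigree file and a whitespace phenotype table.
#'
#' @param ped a [pedigree()].
#' @param region a [flm_region()] whose rows follow the pedigree order.
#' @param y phenotype vector in the same order.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the named vector of written paths.
#' @export
export_dataset <- function(ped, region, y, dir, prefix = "simdata") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- ped$id
  stopifnot(length(y) == length(ids), region$n == length(ids))
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  fam_path <- file.path(dir, paste0(prefix, ".fam"))
  phe_path <- file.path(dir, paste0(prefix, ".phe"))
  bed_path <- file.path(dir, paste0(prefix, ".regions"))

  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=regflm simulator",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
  for (j in seq_len(region$m)) {
    g <- round(region$G[, j])
    rec <- paste(c("1", region$positions$raw[j], region$ids[j], "A", "T",
                   ".", "PASS", ".", "GT", gt_code[g + 1L]),
                 collapse = "\t")
    lines <- c(lines, rec)
  }
  writeLines(lines, vcf_path)
  utils::write.table(
    data.frame(ped$family, ped$id,
               ifelse(is.na(ped$father), "0", ped$father),
               ifelse(is.na(ped$mother), "0", ped$mother), ped$sex),
    fam_path, sep = " ", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(data.frame(id = ids, trait = y), phe_path,
                     sep = " ", quote = FALSE, row.names = FALSE)
  writeLines(paste("1", min(region$positions$raw),
                   max(region$positions$raw), region$name, sep = "\t"),
             bed_path)
  invisible(c(vcf = vcf_path, fam = fam_path, pheno = phe_path,
              regions = bed_path))
}
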