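#' Construct a reference panel from a dosage matrix
#'
#' A reference panel holds genotype dosages (individuals x variants, values in
#' \[0, 2\]) together with a variant index used for linkage-disequilibrium
#' lookups.
#'
#' @param dosage Numeric matrix, individuals in rows, variants in columns.
#'   Column names must equal the variant ids. Missing genotypes as `NA`.
#' @param variants Tibble with columns `chrom`, `pos`, `vid` (and optionally
#'   `ref`, `alt`), one row per dosage column in the same order.
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  if (!all(c("chrom", "pos", "vid") %in% names(variants))) {
    abort("variant index needs columns chrom, pos, vid")
  }
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) abort("dosages must lie within [0, 2]")
  n_obs <- colSums(!is.na(dosage))
  if (any(n_obs == 0)) abort("every variant needs > 0 non-missing dosages")
  if (anyDuplicated(variants$vid)) {
    warn("duplicated variant ids in panel; keeping first occurrence")
    keep <- !duplicated(variants$vid)
    dosage <- dosage[, keep, drop = FALSE]
    variants <- variants[keep, ]
  }
  colnames(dosage) <- variants$vid
  structure(
    list(dosage = dosage, variants = as_tibble(variants)),
    class = "reference_panel"
  )
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d individuals x %d variants on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), dplyr::n_distinct(x$variants$chrom)))
  invisible(x)
}

#' Read a reference panel from VCF
#'
#' Parses genotypes from a VCF (optionally bgzipped) and converts them to
#' allele dosages by counting non-reference alleles; phasing is ignored.
#'
#' @param path Path to a VCF file.
#' @return A [reference_panel()].
#' @export
read_reference_panel <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  vid <- as.character(fix[, "ID"])
  vid[is.na(vid) | vid == "."] <- paste0(fix[is.na(vid) | vid == ".", "CHROM"], ":",
                                         fix[is.na(vid) | vid == ".", "POS"])
  dose <- apply(gt, 2, function(col) {
    alleles <- strsplit(col, "[/|]")
    vapply(alleles, function(a) {
      if (length(a) == 0 || any(a == ".") || anyNA(a)) return(NA_real_)
      sum(a != "0")
    }, numeric(1))
  })
  dose <- matrix(dose, nrow = nrow(gt),
                 dimnames = list(vid, colnames(gt)))
  variants <- tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    vid = vid,
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"])
  )
  reference_panel(t(dose), variants)
}

#' Write a reference panel to VCF
#'
#' Emits a minimal VCF 4.2 with GT genotypes. Dosages are rounded to
#' \{0, 1, 2\} for genotype encoding; `NA` becomes `./.`.
#'
#' @param panel A [reference_panel()].
#' @param path Output path (plain text `.vcf`).
#' @return Invisibly, `path`.
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  ref <- v$ref %||% rep("A", nrow(v))
  alt <- v$alt %||% rep("G", nrow(v))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  n_ind <- nrow(panel$dosage)
  samples <- rownames(panel$dosage) %||% sprintf("I%04d", seq_len(n_ind))
  body <- vapply(seq_len(nrow(v)), function(j) {
    d <- round(panel$dosage[, j])
    g <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(v$chrom[j], v$pos[j], v$vid[j], ref[j], alt[j], ".", "PASS", ".",
            "GT", g), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=vdmomics",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of genotype dosages across the individuals
#' non-missing at both sites. Variants on different chromosomes are defined
#' to have r-squared 0 (with a warning); a zero-variance site yields `NA`,
#' which downstream steps treat as "not in LD".
#'
#' @param panel A [reference_panel()].
#' @param a,b Variant ids present in the panel.
#' @return A number in \[0, 1\], or `NA` if undefined.
#' @export
ld_r2 <- function(panel, a, b) {
  ia <- match(a, panel$variants$vid)
  ib <- match(b, panel$variants$vid)
  if (is.na(ia) || is.na(ib)) abort("both variants must be present in the panel")
  if (panel$variants$chrom[ia] != panel$variants$chrom[ib]) {
    warn("variants on different chromosomes; r^2 defined as 0")
    return(0)
  }
  da <- panel$dosage[, ia]
  db <- panel$dosage[, ib]
  keep <- !is.na(da) & !is.na(db)
  if (sum(keep) < 2) return(NA_real_)
  da <- da[keep]; db <- db[keep]
  if (stats::sd(da) == 0 || stats::sd(db) == 0) return(NA_real_)
  cor(da, db)^2
}

# Pairwise r^2 matrix for a set of variant ids known to the panel.
# Missing variants yield NA rows/columns. Used by clumping and LD-status
# annotation; diagonal is 1 for variants with variance, NA otherwise.
ld_r2_matrix <- function(panel, vids) {
  idx <- match(vids, panel$variants$vid)
  out <- matrix(NA_real_, length(vids), length(vids),
                dimnames = list(vids, vids))
  present <- !is.na(idx)
  if (sum(present) >= 1) {
    d <- panel$dosage[, idx[present], drop = FALSE]
    cc <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))^2
    out[present, present] <- cc
  }
  out
}
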