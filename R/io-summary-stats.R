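#' Column mapping for GWAS summary-statistics files
#'
#' Defaults follow the common consortium convention: `CHR`, `POS`, `SNP`,
#' `A1`, `A2`, `P`, `DIR`, `N`. Override individual entries when a file uses
#' different headers. The direction column is optional; when absent, every
#' variant gets direction 0 (unknown) and is excluded from signed
#' meta-analysis but retained elsewhere.
#'
#' @param chrom,pos,vid,effect_allele,other_allele,pvalue,direction,n Header
#'   names in the file.
#' @return Named character vector mapping internal field names to headers.
#' @export
summary_stats_cols <- function(chrom = "CHR", pos = "POS", vid = "SNP",
                               effect_allele = "A1", other_allele = "A2",
                               pvalue = "P", direction = "DIR", n = "N") {
  c(chrom = chrom, pos = pos, vid = vid, effect_allele = effect_allele,
    other_allele = other_allele, pvalue = pvalue, direction = direction, n = n)
}

#' Read one cohort's GWAS summary statistics
#'
#' Reads a tab-delimited per-variant association file for a single cohort and
#' phenotype, validates it, and returns a tidy per-variant table. Rows whose
#' p-value falls outside (0, 1] are rejected with a warning giving the count;
#' duplicated variant ids keep the first occurrence.
#'
#' @param path Tab-delimited file with a header.
#' @param cohort_id Cohort label stored on every row.
#' @param phenotype One of `"PAR-dr"` (paragraph delayed recall) or `"WL-dr"`
#'   (word-list delayed recall).
#' @param role `"discovery"` or `"replication"`.
#' @param col_map Header mapping from [summary_stats_cols()].
#' @return A tibble with columns `cohort_id`, `phenotype`, `role`, `chrom`,
#'   `pos`, `vid`, `effect_allele`, `other_allele`, `pvalue`, `direction`,
#'   `n`.
#' @export
read_summary_stats <- function(path, cohort_id,
                               phenotype = c("PAR-dr", "WL-dr"),
                               role = c("discovery", "replication"),
                               col_map = summary_stats_cols()) {
  phenotype <- match.arg(phenotype)
  role <- match.arg(role)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) abort(sprintf("summary-statistics file '%s' is empty", path))
  mandatory <- setdiff(names(col_map), "direction")
  missing <- col_map[mandatory][!col_map[mandatory] %in% names(raw)]
  if (length(missing)) {
    abort(sprintf("summary-statistics file '%s' lacks mandatory column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  has_dir <- col_map[["direction"]] %in% names(raw)
  gwas <- tibble(
    cohort_id = cohort_id,
    phenotype = phenotype,
    role = role,
    chrom = as.character(raw[[col_map[["chrom"]]]]),
    pos = as.integer(raw[[col_map[["pos"]]]]),
    vid = as.character(raw[[col_map[["vid"]]]]),
    effect_allele = as.character(raw[[col_map[["effect_allele"]]]]),
    other_allele = as.character(raw[[col_map[["other_allele"]]]]),
    pvalue = as.numeric(raw[[col_map[["pvalue"]]]]),
    direction = if (has_dir) as.integer(raw[[col_map[["direction"]]]]) else 0L,
    n = as.numeric(raw[[col_map[["n"]]]])
  )
  if (!has_dir) {
    inform("no direction column found; directions set to 0 (unknown)")
  }
  bad_p <- is.na(gwas$pvalue) | gwas$pvalue <= 0 | gwas$pvalue > 1
  if (any(bad_p)) {
    warn(sprintf("rejected %d row(s) with p-value outside (0, 1]", sum(bad_p)))
    gwas <- gwas[!bad_p, ]
  }
  if (nrow(gwas) == 0) abort("no valid rows after p-value filtering")
  if (any(gwas$pos < 1, na.rm = TRUE)) abort("positions must be >= 1 (1-based)")
  dup <- duplicated(gwas$vid)
  if (any(dup)) {
    warn(sprintf("%d duplicated variant id(s); keeping first occurrence", sum(dup)))
    gwas <- gwas[!dup, ]
  }
  if (!all(gwas$direction %in% c(-1L, 0L, 1L))) {
    abort("direction values must be -1, 0 or +1")
  }
  gwas
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_summary_stats()]: writes the per-variant columns using the
#' supplied header mapping so a written file round-trips through the reader.
#'
#' @param gwas Tibble as returned by [read_summary_stats()].
#' @param path Output path (TSV).
#' @param col_map Header mapping from [summary_stats_cols()].
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(gwas, path, col_map = summary_stats_cols()) {
  out <- tibble(
    !!col_map[["chrom"]] := gwas$chrom,
    !!col_map[["pos"]] := gwas$pos,
    !!col_map[["vid"]] := gwas$vid,
    !!col_map[["effect_allele"]] := gwas$effect_allele,
    !!col_map[["other_allele"]] := gwas$other_allele,
    !!col_map[["pvalue"]] := gwas$pvalue,
    !!col_map[["direction"]] := gwas$direction,
    !!col_map[["n"]] := gwas$n
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
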