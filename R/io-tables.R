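#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT: set name, description, then member symbols.
#' Returns the collection in long form, one row per (set, gene), which is the
#' shape every enrichment function in the package consumes.
#'
#' @param path GMT file.
#' @return Tibble with columns `set_name`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("GMT file '%s' is empty", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    abort(sprintf("malformed GMT line %d: fewer than 3 fields", short[1]))
  }
  nms <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nms)) abort("duplicated gene-set names in GMT")
  sets <- fgsea::gmtPathways(path)
  out <- enframe(sets, name = "set_name", value = "gene") |> unnest("gene")
  if (any(!nzchar(out$gene))) out <- out[nzchar(out$gene), ]
  out
}

#' Write a gene-set collection to GMT
#'
#' @param gene_sets Long tibble with columns `set_name`, `gene`.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  sets <- split(gene_sets$gene, gene_sets$set_name)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from BED or GTF
#'
#' Gene bounds are stored 1-based inclusive (GRCh37 convention) regardless of
#' the input encoding: BED's 0-based half-open start is shifted by +1; GTF is
#' already 1-based inclusive. The flank (default 2 kb each side) is recorded
#' on the model and applied when mapping SNPs to genes.
#'
#' @param path BED (3+ columns, no header) or GTF file.
#' @param flank Flanking distance in base pairs added up/downstream of the
#'   transcription bounds during SNP mapping.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return Tibble with columns `gene_id`, `symbol`, `chrom`, `tx_start`,
#'   `tx_end`, `flank`.
#' @export
read_gene_models <- function(path, flank = 2000, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  if (flank < 0) abort("flank must be >= 0")
  if (format == "bed") {
    bed <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           comment = "#")
    if (ncol(bed) < 3) abort("BED file needs at least 3 columns")
    name <- if (ncol(bed) >= 4) bed[[4]] else sprintf("gene%05d", seq_len(nrow(bed)))
    out <- tibble(
      gene_id = as.character(name),
      symbol = as.character(name),
      chrom = as.character(bed[[1]]),
      tx_start = as.integer(bed[[2]]) + 1L,
      tx_end = as.integer(bed[[3]]),
      flank = as.integer(flank)
    )
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GTF gene models requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    keep <- if (!is.null(gr$type)) gr[gr$type %in% c("gene", "transcript")] else gr
    if (length(keep) == 0) abort("no gene or transcript records in GTF")
    ids <- keep$gene_id %||% sprintf("gene%05d", seq_along(keep))
    sym <- keep$gene_name %||% ids
    out <- tibble(
      gene_id = as.character(ids),
      symbol = as.character(sym),
      chrom = as.character(GenomicRanges::seqnames(keep)),
      tx_start = GenomicRanges::start(keep),
      tx_end = GenomicRanges::end(keep),
      flank = as.integer(flank)
    ) |> distinct(.data$gene_id, .keep_all = TRUE)
  }
  if (any(out$tx_start > out$tx_end)) abort("gene model with tx_start > tx_end")
  if (anyDuplicated(out$gene_id)) {
    warn("duplicated gene ids; keeping first occurrence")
    out <- distinct(out, .data$gene_id, .keep_all = TRUE)
  }
  out
}

#' Write gene models to BED
#'
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param path Output BED path (start written 0-based half-open).
#' @return Invisibly, `path`.
#' @export
write_gene_models_bed <- function(genes, path) {
  out <- tibble(genes$chrom, genes$tx_start - 1L, genes$tx_end, genes$gene_id)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read an eQTL or meQTL annotation table
#'
#' Tab-delimited with header columns `chrom`, `pos`, `vid`, `target`
#' (positions 1-based). `target` is the regulated gene (eQTL) or CpG site
#' (meQTL) identifier.
#'
#' @param path TSV file.
#' @param kind `"eQTL"` or `"meQTL"`.
#' @param tissue Tissue label stored on every record.
#' @return Tibble with columns `kind`, `tissue`, `chrom`, `pos`, `vid`,
#'   `target`.
#' @export
read_annotation_table <- function(path, kind = c("eQTL", "meQTL"), tissue) {
  kind <- match.arg(kind)
  raw <- readr::read_tsv(path, progress = FALSE, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    vid = readr::col_character(), target = readr::col_character()
  ))
  need <- c("chrom", "pos", "vid", "target")
  if (!all(need %in% names(raw))) {
    abort(sprintf("annotation table '%s' needs columns: %s", path,
                  paste(need, collapse = ", ")))
  }
  if (any(raw$pos < 1, na.rm = TRUE)) abort("annotation positions must be >= 1")
  out <- tibble(kind = kind, tissue = tissue,
                chrom = raw$chrom, pos = raw$pos, vid = raw$vid,
                target = raw$target)
  dup <- duplicated(out[c("tissue", "vid", "target")])
  if (any(dup)) {
    warn(sprintf("%d duplicated (tissue, vid, target) record(s) dropped", sum(dup)))
    out <- out[!dup, ]
  }
  out
}

#' Read regulator-to-target lists
#'
#' Tab-delimited with header columns `regulator`, `target`; one row per
#' regulated gene. No minimum-target filter is applied here - see
#' [filter_regulons()].
#'
#' @param path TSV file.
#' @return Tibble with columns `regulator`, `target`.
#' @export
read_regulons <- function(path) {
  raw <- readr::read_tsv(path, progress = FALSE, col_types = readr::cols(
    regulator = readr::col_character(), target = readr::col_character()
  ))
  if (!all(c("regulator", "target") %in% names(raw))) {
    abort("regulon file needs columns regulator, target")
  }
  distinct(tibble(regulator = raw$regulator, target = raw$target))
}

#' Read a plain-text gene list (one symbol per line)
#'
#' Used for the immune-gene annotation.
#'
#' @param path Text file, one gene symbol per line.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Construct an expression dataset
#'
#' Couples a gene x sample value matrix with a sample sheet carrying ordered
#' group labels (e.g. cognitive statuses from unimpaired to impaired).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param samples Tibble with columns `sample`, `group`; every matrix column
#'   must appear.
#' @param group_levels Character vector declaring the group order; defaults to
#'   order of first appearance in `samples`.
#' @param study_id Study label.
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, samples, group_levels = NULL,
                               study_id = "study") {
  stopifnot(is.matrix(values))
  if (!all(is.finite(values))) abort("expression matrix must be finite")
  if (!all(c("sample", "group") %in% names(samples))) {
    abort("sample sheet needs columns sample, group")
  }
  if (!all(colnames(values) %in% samples$sample)) {
    abort("every matrix column needs a row in the sample sheet")
  }
  samples <- samples[match(colnames(values), samples$sample), ]
  group_levels <- group_levels %||% unique(samples$group)
  if (!all(samples$group %in% group_levels)) {
    abort("sample sheet contains groups not in group_levels")
  }
  structure(
    list(values = values, samples = as_tibble(samples),
         group_levels = group_levels, study_id = study_id),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> '%s': %d genes x %d samples; groups: %s\n",
              x$study_id, nrow(x$values), ncol(x$values),
              paste(x$group_levels, collapse = " < ")))
  invisible(x)
}

#' Read an expression dataset from TSV files
#'
#' @param path_matrix TSV: first column `gene`, remaining columns one per
#'   sample.
#' @param path_samples TSV sample sheet with columns `sample`, `group` and
#'   optionally `group_order` (integer rank declaring the group order).
#' @param study_id Study label.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path_matrix, path_samples, study_id = "study") {
  m <- readr::read_tsv(path_matrix, progress = FALSE, show_col_types = FALSE)
  if (names(m)[1] != "gene") abort("expression matrix must start with a 'gene' column")
  values <- as.matrix(m[, -1])
  rownames(values) <- m$gene
  storage.mode(values) <- "double"
  s <- readr::read_tsv(path_samples, progress = FALSE, show_col_types = FALSE)
  lv <- if ("group_order" %in% names(s)) {
    unique(s$group[order(s$group_order)])
  } else NULL
  expression_dataset(values, s, group_levels = lv, study_id = study_id)
}

#' Write an expression dataset to TSV files
#'
#' @param ds An [expression_dataset()].
#' @param path_matrix,path_samples Output paths.
#' @return Invisibly, `path_matrix`.
#' @export
write_expression <- function(ds, path_matrix, path_samples) {
  m <- as_tibble(ds$values, rownames = "gene")
  readr::write_tsv(m, path_matrix, progress = FALSE)
  s <- mutate(ds$samples,
              group_order = match(.data$group, ds$group_levels))
  readr::write_tsv(s, path_samples, progress = FALSE)
  invisible(path_matrix)
}
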