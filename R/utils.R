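# Internal helpers shared across modules.

# Validate a probability-like scalar/vector lies in (0, 1].
check_pvalues <- function(p, what = "p-value") {
  if (length(p) == 0) abort(sprintf("%s vector is empty", what))
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    abort(sprintf("%s values must lie in (0, 1]", what))
  }
  invisible(p)
}

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. Seeds are kept below 2^31 - 1.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed %% .Machine$integer.max)
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream label.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  (as.double(seed) * 7919 + h) %% 2147483629
}

#' Write a JSON run-metadata sidecar next to an output file
#'
#' Records the seed, the analysis parameters and MD5 digests of the input
#' files that produced a tabular output, so a result file carries its own
#' provenance.
#'
#' @param out_path Path of the output file the sidecar describes; the sidecar
#'   is written to `<out_path>.meta.json`.
#' @param seed Integer seed used for any randomness (or `NULL`).
#' @param parameters Named list of analysis parameters.
#' @param inputs Character vector of input file paths to digest.
#' @return Invisibly, the sidecar path.
#' @export
write_run_metadata <- function(out_path, seed = NULL, parameters = list(),
                               inputs = character()) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    structure(list(), names = character())
  }
  meta <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = parameters,
    input_digests = digests
  )
  side <- paste0(out_path, ".meta.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(side)
}
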