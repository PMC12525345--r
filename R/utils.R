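# Shared small helpers: TSV IO in the dialects the pipeline reads and
# writes, and seed derivation for per-stage reproducibility.

read_tsv_checked <- function(path, required = NULL, what = "file") {
  if (!file.exists(path)) {
    stop(sprintf("%s not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    stop(sprintf("empty input: %s", path), call. = FALSE)
  }
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L) {
      stop(sprintf("format error in %s: missing column(s) %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Derive a stage-specific seed from a global seed
#'
#' Each pipeline stage draws its randomness from a seed derived
#' deterministically from the single global seed and the stage name, so a
#' stage can be rerun in isolation without perturbing the others.
#'
#' @param global_seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 69069 + h * 2654435) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
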