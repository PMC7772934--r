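#' @importFrom stats cor sd var runif rnorm hclust cutree as.dist kmeans
#' @importFrom utils read.table write.table head tail
NULL

# Population (1/N) standard deviation; one convention used package-wide.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

pop_var <- function(x) {
  mean((x - mean(x))^2)
}

#' Derive a per-stage sub-seed from a run-level seed
#'
#' One global seed is expanded into independent per-stage seeds with a
#' documented counter scheme, so any pipeline stage can be reproduced in
#' isolation.  Stage seeds are `(seed * 1000003 + 7919 * counter)` reduced
#' modulo `2^31 - 1`, which keeps them inside R's integer range.
#'
#' @param seed Integer run-level seed.
#' @param counter Integer stage counter (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(counter))
  as.integer((as.numeric(seed) * 1000003 + 7919 * as.numeric(counter)) %%
               (2^31 - 1))
}

# Uniform integer in 1..n from the current RNG stream.
rand_int <- function(n) {
  if (n < 1L) stop("rand_int: n must be >= 1")
  as.integer(floor(runif(1L) * n)) + 1L
}

# Short config hash for output metadata headers (FNV-1a over the
# deparsed config; no external digest dependency needed).
config_hash <- function(obj) {
  txt <- paste(deparse(obj), collapse = " ")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

meta_header <- function(seed = NA, cfg = NULL) {
  sprintf("# mvmarker %s\tseed=%s\tconfig=%s",
          as.character(utils::packageVersion("mvmarker")),
          as.character(seed),
          if (is.null(cfg)) "-" else config_hash(cfg))
}

# Write a data.frame/matrix as TSV with the standard metadata header line.
write_tsv_meta <- function(x, path, seed = NA, cfg = NULL,
                           row_names = FALSE, col_names = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed, cfg), con)
  write.table(x, con, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = col_names)
  invisible(path)
}
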