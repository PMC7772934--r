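#' Load a run configuration from a key-value text file
#'
#' Plain `key = value` lines (comments with `#`); unknown keys are an
#' error listing the valid keys.  Missing keys take the standard
#' defaults (see [anneal_config()]); an empty file therefore yields the
#' default configuration.  Keys: `t_max`, `t_min`, `alpha`,
#' `total_iter`, `sl`, `hl`, `p`, `t_runs`, `seed`, `objectives`
#' (comma-separated subset of snr,corrdist,ai).
#'
#' @param path Path to the config file, or NULL for pure defaults.
#' @param overrides Named list of values taking precedence over the file
#'   (CLI flags).
#' @return List with `anneal` (an [anneal_config()]), `t_runs`, `seed`
#'   and `objectives`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  valid <- c("t_max", "t_min", "alpha", "total_iter", "sl", "hl", "p",
             "t_runs", "seed", "objectives")
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("malformed config line: ", ln)
      key <- trimws(kv[1L])
      if (!(key %in% valid))
        stop("unknown config key '", key, "'; valid keys: ",
             paste(valid, collapse = ", "))
      vals[[key]] <- trimws(kv[2L])
    }
  }
  for (key in names(overrides)) {
    if (!(key %in% valid))
      stop("unknown config key '", key, "'; valid keys: ",
           paste(valid, collapse = ", "))
    if (!is.null(overrides[[key]])) vals[[key]] <- overrides[[key]]
  }
  num <- function(key, default) {
    if (is.null(vals[[key]])) default else as.numeric(vals[[key]])
  }
  objectives <- if (is.null(vals$objectives)) c("snr", "corrdist", "ai")
    else strsplit(as.character(vals$objectives), ",", fixed = TRUE)[[1L]]
  objectives <- match.arg(trimws(objectives),
                          c("snr", "corrdist", "ai"), several.ok = TRUE)
  list(anneal = anneal_config(t_max = num("t_max", 100),
                              t_min = num("t_min", 1e-4),
                              alpha = num("alpha", 0.9),
                              total_iter = num("total_iter", 100L),
                              sl = num("sl", 100L), hl = num("hl", 50L),
                              p = num("p", 50L)),
       t_runs = as.integer(num("t_runs", 3L)),
       seed = as.integer(num("seed", 1L)),
       objectives = objectives)
}
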