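# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for a named simulation stage
#'
#' Each simulation stage (design, DNA counts, RNA counts per replicate, ...)
#' consumes its own RNG stream derived deterministically from the master seed,
#' so generating e.g. RNA molecules replicate-by-replicate gives the same
#' draws as generating all replicates at once.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @param index optional integer sub-index (e.g. replicate number).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
stage_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double range
  v <- (abs(seed) %% m) * 48271 + h * 8191 + index * 131071
  as.integer(v %% (m - 1) + 1)
}

# Configuration error that names the offending field (spec'd error contract).
stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

# Two-sided normal p-value from a z statistic.
z_pvalue <- function(z) 2 * pnorm(-abs(z))

# Clamp a numeric vector into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shared grouping keys recognised on count/result tables.
ID_COLS <- c("snp_id", "region_id", "orientation", "replicate", "fraction",
             "concentration")

id_cols_of <- function(x) intersect(ID_COLS, names(x))

# Defensive copy + coercion so by-reference data.table ops never touch user
# input.
as_dt <- function(x) {
  if (!is.data.frame(x)) stop("expected a data.frame/data.table", call. = FALSE)
  as.data.table(x)
}

require_cols <- function(x, cols, what = "table") {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
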