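#' @importFrom stats cor quantile t.test p.adjust phyper predict rnorm runif
#'   rbinom sd var setNames
#' @importFrom utils write.table read.table packageVersion head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' Stages of the pipeline draw their random numbers from seeds derived
#' deterministically from one global seed and the stage name, so each stage is
#' independently reproducible. The result is kept within 32-bit integer range.
#'
#' @param global_seed Integer global seed.
#' @param stage Character stage name.
#' @return A single integer seed.
#' @export
derive_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(global_seed) * 31 + h * 10007) %% (2^31 - 1) + 1)
}

# canonical unordered-pair representation: lexicographically smaller id first
canonical_pairs <- function(a, b) {
  swap <- a > b
  u <- ifelse(swap, b, a)
  v <- ifelse(swap, a, b)
  list(u = u, v = v, key = paste(u, v, sep = "\r"))
}

assert_protein_ids <- function(ids, what = "protein identifier") {
  bad <- !nzchar(ids) | grepl("[[:space:]]", ids) | is.na(ids)
  if (any(bad)) {
    stop(sprintf("invalid %s: %s", what,
                 paste(utils::head(ids[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}
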