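# Classed conditions so callers can distinguish malformed files (format)
# from inputs violating a domain invariant (validation).

ann_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "archannot_error", "error")))
}

format_error <- function(...) ann_stop(paste0(...), "archannot_format_error")

validation_error <- function(...) ann_stop(paste0(...), "archannot_validation_error")

config_error <- function(...) ann_stop(paste0(...), "archannot_config_error")

#' Normalize an environment label
#'
#' Sampling-environment labels are compared by exact string equality after
#' lowercasing, trimming, and collapsing internal whitespace; no fuzzy
#' matching is attempted.
#'
#' @param x character vector of environment labels.
#' @return normalized character vector.
#' @examples
#' normalize_environment(" Human  Gut ")
#' @export
normalize_environment <- function(x) {
  trimws(tolower(gsub("[[:space:]]+", " ", as.character(x))))
}

# stable per-component RNG streams derived from one global seed, so adding a
# generated file type never perturbs existing fixtures
stream_seed <- function(seed, stream) {
  streams <- c(
    mags = 1L, clusters = 2L, ko = 3L, superclusters = 4L,
    evidence = 5L, synteny = 6L, coverage = 7L
  )
  if (!stream %in% names(streams)) stop("unknown RNG stream: ", stream)
  as.integer((abs(as.numeric(seed)) * 7919 + streams[[stream]] * 104729) %%
    2147483629)
}

with_stream <- function(seed, stream, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}
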