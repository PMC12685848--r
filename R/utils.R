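# internal helpers: seed splitting and stderr logging

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stream-specific seed from a global seed
#'
#' All randomness in the package flows from one integer seed. Each stochastic
#' operation derives its own seed as a deterministic function of the global
#' seed and a stream label, so that adding or reordering operations never
#' perturbs the draws of another stream.
#'
#' The scheme is `(seed * 7919 + weighted-codepoint-sum(label)) mod (2^31 - 1)`
#' where the codepoint sum weights each character by its position (making the
#' label order-sensitive). All arithmetic stays in double precision well below
#' 2^53, so the result is exact.
#'
#' @param seed integer global seed.
#' @param stream character stream label, e.g. `"diplotypes:CYP2D6"`.
#' @return a single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' split_seed(1L, "diplotypes:CYP2D6")
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L)
  cp <- utf8ToInt(stream)
  h <- sum(cp * seq_along(cp))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

# machine-parsable stderr logging; prefixes: STAGE, WARN, DRIFT, NOTE
pgx_log <- function(prefix, fmt, ...) {
  message(sprintf("[%s] %s", prefix, sprintf(fmt, ...)))
}

# comma-joined flag sets <-> character vectors
join_flags <- function(flags) {
  flags <- unique(flags[nzchar(flags)])
  if (length(flags) == 0L) "" else paste(sort(flags), collapse = ",")
}

#' Test whether a comma-joined flag set contains a flag
#'
#' Diplotype tables carry their QC flags (`ambiguous`, `inconsistent`,
#' `cnv_rejected`) as a comma-joined string; this helper tests membership.
#'
#' @param flag_string character vector of comma-joined flag sets.
#' @param flag single flag name.
#' @return logical vector.
#' @export
#' @examples
#' has_flag(c("", "ambiguous,inconsistent"), "ambiguous")
has_flag <- function(flag_string, flag) {
  vapply(strsplit(ifelse(is.na(flag_string), "", flag_string), ",", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}
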