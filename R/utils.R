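# internal helpers shared across modules

# Run code under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream untouched".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Length of a 1-based inclusive coordinate interval
#'
#' The coordinate convention used throughout the package (ORF bounds, protein
#' domain slices) is 1-based and end-inclusive, so positions 265 through 463
#' of a protein span `463 - 265 + 1 = 199` residues.
#'
#' @param start,end Integer positions, 1-based, `end >= start`.
#' @return Integer interval length.
#' @examples
#' interval_length(265, 463)  # 199
#' @export
interval_length <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == length(end), all(start >= 1L), all(end >= start))
  end - start + 1L
}

vcapply <- function(x, f, ...) vapply(x, f, character(1L), ...)
viapply <- function(x, f, ...) vapply(x, f, integer(1L), ...)
vdapply <- function(x, f, ...) vapply(x, f, numeric(1L), ...)
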