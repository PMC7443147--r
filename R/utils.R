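#' @keywords internal
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Check that a character vector is over the A/C/G/T alphabet
#' @noRd
is_acgt <- function(x) {
  !is.na(x) & grepl("^[ACGT]+$", x)
}

#' Abort with a classed condition
#'
#' All user-facing validation failures carry class `screenforge_error` so
#' callers (and tests) can distinguish them from programming errors.
#' @noRd
sf_stop <- function(msg, class = "screenforge_error") {
  stop(errorCondition(msg, class = c(class, "screenforge_error")))
}

#' Random unique DNA k-mers
#' @noRd
random_kmers <- function(n, k) {
  out <- character(0)
  # rejection sampling to uniqueness; collision probability is negligible
  # for k = 20 but we guard anyway
  while (length(out) < n) {
    need <- n - length(out)
    m <- matrix(sample(DNA_ALPHABET, need * k, replace = TRUE), nrow = need)
    out <- unique(c(out, apply(m, 1, paste0, collapse = "")))
  }
  out[seq_len(n)]
}
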