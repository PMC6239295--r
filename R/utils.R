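#' @useDynLib tpsminer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The 20 standard residues, in the canonical column order used by all
# profile/pattern machinery in the package.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Map residue characters to 1..20; anything else (gap, '*', 'X', ...) -> 21,
# which scoring code treats as an automatic mismatch.
aa_code <- function(chars) {
  idx <- match(chars, AA20)
  idx[is.na(idx)] <- 21L
  idx
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. With seed = NULL the ambient RNG stream is used.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
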