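# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so no generator call leaks global state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a numeric matrix as CSV with enough digits that read-back is
# bit-exact (doubles round-trip through 17 significant digits).
write_matrix_csv <- function(mat, path, row_names = rownames(mat)) {
  chr <- matrix(formatC(mat, digits = 17, format = "g"), nrow = nrow(mat))
  df <- as.data.frame(chr, stringsAsFactors = FALSE)
  colnames(df) <- colnames(mat)
  if (!is.null(row_names)) df <- cbind(roi = row_names, df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- NULL
  if (identical(colnames(df)[1], "roi")) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}
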