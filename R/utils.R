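# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# enum of biosynthetic routes; "unknown" is the absence of an annotation
BIOSYNTHETIC_TYPES <- c("NRPS", "NIS", "NRPS+NIS", "PKS-hybrid", "unknown")

SOURCE_TAGS <- c("knownset", "background", "query")

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# split a pipe-separated field into a character vector (empty -> character(0))
split_pipes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "|", fixed = TRUE)[[1]]
}

join_pipes <- function(x) paste(x, collapse = "|")

# deterministic RNG scope that does not disturb the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
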