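# Internal helpers shared across modules.

# Deterministic 31-bit string hash (polynomial rolling hash mod a Mersenne
# prime).  Used to derive independent per-query RNG streams from a single
# user-facing seed; must be stable across platforms and sessions.
.str_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (k in utf8ToInt(x)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's stream.
.with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Shuffle that is safe for length-1 input (sample(x) would misbehave).
.shuffle <- function(x) x[sample.int(length(x))]

# Read a UTF-8 text file into data rows, dropping '#' comments and blank
# lines.  Returns a list with `lines` (character) and `lineno` (original file
# line numbers, for error messages).
.read_data_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(lines = raw[keep], lineno = which(keep))
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}
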