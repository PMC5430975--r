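# internal helpers

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Color-style module names by size rank, "grey" reserved for unassigned.
moduleColorPalette <- function(n) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
           "lightyellow", "royalblue", "darkred", "darkgreen",
           "darkturquoise", "darkgrey", "orange", "darkorange", "white",
           "skyblue", "saddlebrown", "steelblue")
  if (n <= length(pal)) pal[seq_len(n)]
  else c(pal, paste0("module", seq.int(length(pal) + 1L, n)))
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
}

# Two-sided p for a Pearson correlation via the Student-t transform.
corPValue <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}
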