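# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, and restores the state so
#' that seeded simulation helpers do not disturb the ambient random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-spectrum seed from the experiment seed and condition/replicate
# indices; kept below 2^31 - 1.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i) + 7919 * as.numeric(j)) %%
               2147483629)
}

# Round a window width up to the next odd integer (centred windows).
odd_width <- function(w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w + 1L else w
}

# Centred moving average with shrinking windows at the edges.
moving_average <- function(x, w) {
  n <- length(x)
  w <- odd_width(w)
  if (w > n) stop("window width (", w, ") exceeds signal length (", n, ")")
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(0L, i - h - 1L)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Centred rolling minimum with shrinking windows at the edges.
rolling_min <- function(x, w) {
  n <- length(x)
  w <- odd_width(w)
  if (w > n) stop("window width (", w, ") exceeds signal length (", n, ")")
  h <- (w - 1L) %/% 2L
  pad <- c(rep(Inf, h), x, rep(Inf, h))
  out <- rep(Inf, n)
  for (s in 0:(w - 1L)) out <- pmin(out, pad[(1L + s):(n + s)])
  out
}

# Letter labels in mass order: A..Z, AA, AB, ...
make_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}

# Canonical condition identifier used in designs and summaries.
condition_id <- function(toxin, concentration, is_control) {
  ifelse(is_control, paste0(toxin, ":control"),
         paste0(toxin, ":", format(concentration, trim = TRUE, scientific = FALSE)))
}

# Mass-dependent match tolerance (Da): the larger of a fixed and a ppm term.
mass_tolerance <- function(mass, tol_da, tol_ppm) {
  pmax(tol_da, tol_ppm * 1e-6 * mass)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
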