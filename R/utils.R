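# Internal helpers shared across modules.

CLASS_LEVELS <- c("A", "B", "C", "D", "E", "F", "G")
HIGH_CLASSES <- c("A", "B", "C")
NOISE_CLASS <- "D"
REVIEW_CLASSES <- c("E", "F", "G")

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index; stays < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1103L + 12347L * as.double(index)) %% 2147483647)
}

# 32-bit FNV-1a hash of a character vector, returned as 8 hex digits.
# Arithmetic kept exact in doubles by splitting the 32-bit state in halves.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# complementary error function (base R via the normal CDF)
erfc <- function(x) 2 * pnorm(-x * sqrt(2))

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# strict interior local maxima indices of a numeric vector
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] > 0]
}

# 3-point moving average with edge replication
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  xp <- c(x[1L], x, x[n])
  (xp[1:n] + xp[2:(n + 1L)] + xp[3:(n + 2L)]) / 3
}

# union-find on n nodes given an edge list (2-column integer matrix);
# returns integer component labels 1..k in order of first appearance
connected_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
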