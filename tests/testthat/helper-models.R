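## Shared fixtures: all models are built in code at test time.

toy_config <- function(cut_excess = 1L, include_cut_x = FALSE, E = 1L) {
  build_config(L = 2, E = E, R = 2, cut_excess = cut_excess,
               include_cut_x = include_cut_x)
}

default_config <- function(...) build_config(L = 10, E = 5, ...)

## scission time of a trajectory by the half-label ground truth
sct <- function(tr) {
  s <- tr$samples
  i <- which(s$bridging == 0L)[1]
  if (is.na(i)) NA_real_ else s$time[i]
}

## brute-force cross-interface bond count: enumerate the diagonal rule
## directly and count pairs straddling floor(N/2)
brute_cross_count <- function(L, R = 2L) {
  N <- R * L
  n2 <- N %/% 2L
  cnt <- 0L
  for (i in seq_len(N)) for (j in seq_len(N + L - 1L)) {
    if (j - i >= 0L && j - i <= L - 1L && i <= n2 && j > n2) cnt <- cnt + 1L
  }
  cnt
}
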