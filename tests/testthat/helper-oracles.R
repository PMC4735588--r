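# Independent oracles, kept free of the package's own machinery.

# exhaustive enumeration of every within-column shuffle of the rank matrix,
# returning the pooled null rank-product distribution
enumerate_null_rps <- function(ratios, direction) {
  n <- nrow(ratios)
  ranks <- apply(ratios, 2, rank, ties.method = "average")
  if (direction == "up") ranks <- n + 1 - ranks
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  cols <- lapply(seq_len(ncol(ratios)), function(j) perms(ranks[, j]))
  grid <- expand.grid(lapply(cols, seq_along))
  unlist(lapply(seq_len(nrow(grid)), function(g) {
    rm <- sapply(seq_along(cols), function(j) cols[[j]][[grid[g, j]]])
    exp(rowMeans(log(rm)))
  }))
}

# brute-force BH oracle: scan every observed p-value as a cutoff and take,
# for each p_i, the smallest m*t/#(p<=t) over cutoffs t >= p_i
bh_bruteforce <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}
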