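# beta-binomial draws for overdispersion simulations (icc = intra-class corr.)
rbb <- function(n, size, prob, icc) {
  if (icc <= 0) return(rbinom(n, size, prob))
  ab <- (1 - icc) / icc
  p <- rbeta(n, prob * ab, (1 - prob) * ab)
  rbinom(n, size, p)
}

grouped_from_broods <- function(broods) {
  data.frame(trials = broods$eggs_laid,
             failures = broods$eggs_undeveloped,
             group = broods$symbiotype,
             feminized = grepl("W", broods$symbiotype))
}

# brute-force letter sharing oracle: maximal cliques of the
# not-significantly-different graph, enumerated over all subsets (<= 6 groups)
clique_cover_sharing <- function(sig_matrix) {
  g <- rownames(sig_matrix)
  k <- length(g)
  subsets <- lapply(seq_len(2^k - 1), function(m) g[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2) return(TRUE)
    all(!sig_matrix[s, s])
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(o)
      length(o) > length(cliques[[i]]) && all(cliques[[i]] %in% o), logical(1)))
  }, logical(1))]
  share <- matrix(FALSE, k, k, dimnames = dimnames(sig_matrix))
  for (cl in maximal) share[cl, cl] <- TRUE
  diag(share) <- TRUE
  share
}

letters_sharing <- function(letters) {
  g <- names(letters)
  share <- outer(letters, letters, function(a, b)
    mapply(function(x, y) any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]]), a, b))
  dimnames(share) <- list(g, g)
  share
}

# individual-based forward simulation of the infected-female karyotype
# recursion: aggregate egg counts are multinomial, mothers resampled each
# generation in proportion to daughter production
simulate_karyotype_generations <- function(phi, n_mothers = 1e5,
                                           eggs_per_mother = 10,
                                           generations = 50, x0 = 0.5) {
  x <- x0
  for (g in seq_len(generations)) {
    n_xx <- rbinom(1, n_mothers, x)
    n_x0 <- n_mothers - n_xx
    # XX mothers: 1/2 XX daughters, 1/2 X0 (female w.p. phi)
    off_xx <- rmultinom(1, n_xx * eggs_per_mother, c(0.5, 0.5 * phi, 0.5 * (1 - phi)))
    # X0 mothers: 1/4 XX, 1/2 X0 (female w.p. phi), 1/4 OO
    off_x0 <- rmultinom(1, n_x0 * eggs_per_mother,
                        c(0.25, 0.5 * phi, 0.5 * (1 - phi) + 0.25))
    d_xx <- off_xx[1] + off_x0[1]
    d_x0 <- off_xx[2] + off_x0[2]
    x <- d_xx / (d_xx + d_x0)
  }
  x
}
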