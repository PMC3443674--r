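# Small programmatic fixtures shared across test files.

# Gaussian two-group study: G genes, n per group, optional per-gene shift
# applied to group 2.
make_study <- function(G = 6, n = 5, shift = 0, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(G * 2 * n, sd = sd), G, 2 * n,
              dimnames = list(paste0("g", seq_len(G)),
                              paste0("s", seq_len(2 * n))))
  m[, (n + 1):(2 * n)] <- m[, (n + 1):(2 * n)] + shift
  expression_study(m, group = rep(1:2, each = n))
}

# Hierarchy of consecutive disjoint blocks over g1..gG.
make_hierarchy <- function(sizes_by_set) {
  g <- 0L
  sets <- lapply(sizes_by_set, function(sizes) {
    subs <- lapply(sizes, function(p) {
      ids <- paste0("g", g + seq_len(p)); g <<- g + p; ids
    })
    names(subs) <- paste0("sub", seq_along(subs))
    subs
  })
  names(sets) <- paste0("set", seq_along(sets))
  gene_set_hierarchy(sets)
}

# Intraclass-correlated Gaussian matrix (independent of the package's
# generators; used as an oracle input).
make_intraclass <- function(G, n, sigma, rho, mean = 0) {
  z0 <- rnorm(n)
  z <- matrix(rnorm(G * n), G, n)
  x <- mean + sigma * (sqrt(rho) * rep(z0, each = G) + sqrt(1 - rho) * z)
  dim(x) <- c(G, n)
  rownames(x) <- paste0("g", seq_len(G))
  x
}
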