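# shared fixtures and small independent oracles, built in code

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# random labelled count table
random_table <- function(n_taxa, n_samples, lambda = 30, seed = 1) {
  set.seed(seed)
  count_table(matrix(stats::rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
                     dimnames = list(paste0("t", seq_len(n_taxa)),
                                     paste0("s", seq_len(n_samples)))))
}

# all permutations of 1:n (exhaustive-null oracle; n <= 6)
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix((seq_len(n))[-i][sub], nrow(sub)))))
}

# GOE matrix with unit diagonal
goe_matrix <- function(n, seed) {
  set.seed(seed)
  a <- matrix(stats::rnorm(n * n), n)
  m <- (a + t(a)) / sqrt(2 * n)
  diag(m) <- 1
  m
}

# block-diagonal matrix of independent GOE blocks (Poisson-spaced spectrum)
block_matrix <- function(n_blocks, block_size, seed) {
  n <- n_blocks * block_size
  m <- matrix(0, n, n)
  for (b in seq_len(n_blocks)) {
    set.seed(seed * 100 + b)
    a <- matrix(stats::rnorm(block_size^2), block_size)
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    m[idx, idx] <- (a + t(a)) / sqrt(2 * block_size)
  }
  diag(m) <- 1
  m
}
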