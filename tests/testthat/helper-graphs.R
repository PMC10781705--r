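# Small named graphs used throughout the suite, built in code.

p3_graph <- function() network(rbind(c(0, 1), c(1, 2)))              # path 0-1-2
star4_graph <- function() network(rbind(c(0, 1), c(0, 2), c(0, 3)))  # hub 0
c4_graph <- function() network(rbind(c(0, 1), c(1, 2), c(2, 3), c(0, 3)))
k3_graph <- function() network(rbind(c(0, 1), c(0, 2), c(1, 2)))
single_edge_graph <- function() network(rbind(c(0, 1)))

er30_graph <- function(seed = 5) generate_er(30, k_av = 4, seed = seed)

# Random simple graph on n nodes with edge probability p (plain G(n, p)).
random_graph <- function(n, p = 0.2, seed = 1) generate_er(n, k_av = p * (n - 1), seed = seed)

# Pearson chi-square goodness of fit of sampled pair frequencies against an
# exact distribution, pooling cells with small expected counts.
gof_pvalue <- function(draws, dist_matrix, min_expected = 5) {
  n <- nrow(dist_matrix)
  key <- factor(draws$i * n + draws$j, levels = 0:(n * n - 1))
  obs <- as.numeric(table(key))
  expd <- as.vector(t(dist_matrix)) * nrow(draws)  # row-major to match key
  keep <- expd > 0
  obs <- obs[keep]
  expd <- expd[keep]
  small <- expd < min_expected
  if (any(small)) {
    obs <- c(obs[!small], sum(obs[small]))
    expd <- c(expd[!small], sum(expd[small]))
  }
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
}
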