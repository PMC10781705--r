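Package: walklink
Title: Sampling-Based Path Link Prediction with Classical and Quantum-Walk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Samplers for path-based link prediction on simple undirected
    networks. Classical algorithms draw candidate links from the A^2 and A^3
    path-count score distributions through a query-counted graph oracle
    (degree, l-th neighbour and vertex-pair queries), and a continuous-time
    quantum-walk sampler is simulated classically by computing the even and
    odd measurement distributions proportional to cos(At)^2 and sin(At)^2
    via eigendecomposition of the adjacency matrix. Includes usefulness and
    cross-validated precision metrics, query-complexity accounting and
    resource estimators, and configuration-model scale-free network
    generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
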