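# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

kBT <- function(temperature = 300) 1.380649e-23 * temperature

# Full-scale default model (5 clusters x 10 domains, rabbit psoas isoform),
# force curves on a 1 nm grid wide enough for every canonical protocol.
full_model <- function() memo("full_model", function() {
  titin_model(length_grid = seq(1e-6, 2.15e-6, by = 1e-9))
})

# Same mechanics with refolding enabled on the default clusters.
full_model_refolding <- function() memo("full_model_refolding", function() {
  fm <- full_model()
  titin_model(clusters = cluster_model(refolding = list(omega1 = 1, x_f = 2.2e-9)),
              curves = fm$curves)
})

# Single-cluster (50-domain) model with refolding, shared force curves.
one_cluster_refolding_model <- function() memo("one_cluster_refold", function() {
  fm <- full_model()
  titin_model(clusters = cluster_model(n = 50, omega0 = 1e-4,
                                       refolding = list(omega1 = 1, x_f = 2.2e-9)),
              curves = fm$curves)
})

# Small toy model: 5 proximal Ig domains in 2 clusters, mild rates, coarse
# grid reaching below slack so constant-length holds at zero force work.
toy_model <- function(omega0 = c(0.3, 0.8), n = c(2, 3), refolding = NULL,
                      slack = 0.9e-6) {
  params <- mechanical_params(slack_length = slack)
  titin_model(params = params,
              iso = isoform(n_prox_ig = sum(n)),
              clusters = cluster_model(n = n, omega0 = omega0,
                                       refolding = refolding),
              length_grid = seq(0.4e-6, 2e-6, by = 1e-8))
}

hold_protocol <- function(l, duration = 1) {
  length_protocol(c(0, duration), c(l, l))
}

# Total-variation distance between two distributions on the same support
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
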