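# The full-size microcircuit build is expensive; share one realization
# across acceptance tests.
.epsv_cache <- new.env(parent = emptyenv())

get_epsv_net <- function() {
  if (is.null(.epsv_cache$net)) {
    .epsv_cache$net <- build_network(network_config(), seed = 1)
  }
  .epsv_cache$net
}
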