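## Shared fixtures, built in code.

# random non-negative state vectors for RHS oracle checks
randomStates <- function(n, seed = 42, scale = 50) {
  set.seed(seed)
  lapply(seq_len(n), function(i) runif(12, 0, scale))
}

baselineClamped <- function(params, act = 0.25) {
  c(T = params$T, PDK1 = params$PDK1, mTORC2 = params$mTORC2,
    ACT = act, HSP70 = params$HSP70)
}

# parameterization with every source and sink switched off
conservativeParams <- function(params = defaultParams()) {
  params$k3 <- 0
  for (l in paste0("lambda", 1:5)) params[[l]] <- 0
  params
}

# a mixed state spread over the moiety-carrying species
mixedState <- function(total = 60) {
  y <- setNames(numeric(12), pkcSpecies("dynamical")$name)
  y[c("PKC", "PKC_PA", "CPKC_PA", "CPKC_PAPHPT", "PKC_A")] <- total / 7
  y[c("C3", "C5")] <- total / 7 / 2  # moiety weight 2
  y
}
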