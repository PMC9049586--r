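#' pkcycle: deterministic kinetics of the protein kinase C life cycle
#'
#' Mass-action model of PKC synthesis, ordered constitutive phosphorylation,
#' second-messenger activation, dephosphorylation-driven down-regulation and
#' HSP70-mediated rescue, integrated with a stiff ODE solver under square-pulse
#' stimulation protocols.
#'
#' @keywords internal
#' @importFrom stats coef lm setNames
#' @importFrom utils head modifyList tail write.csv
"_PACKAGE"

## Dynamical species, in state-vector order. Concentrations of all
## protein-moiety species are in ng/ml; the activator is in nM; internal
## integration time is seconds.
.pkc_species <- data.frame(
  name = c("mRNA", "C1", "PKC", "C2", "PKC_PA", "CPKC_PA", "C3", "C4",
           "CPKC_PAPHPT", "PKC_PAPHPT_act", "PKC_A", "C5"),
  kind = "dynamical",
  unit = "ng/ml",
  moiety = c(0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 1L, 1L, 1L, 2L),
  stringsAsFactors = FALSE
)

.pkc_clamped <- data.frame(
  name = c("T", "PDK1", "mTORC2", "ACT", "PHLPP", "HSP70"),
  kind = "clamped",
  unit = c("au", "au", "au", "nM", "au", "au"),
  moiety = 0L,
  stringsAsFactors = FALSE
)

#' Species registry of the PKC life-cycle network
#'
#' Twelve dynamical species (the integrated state vector, in order) and six
#' chemostatted species that enter rate laws at protocol-defined levels but
#' are never integrated. The `moiety` column counts PKC protein moieties per
#' molecule (complexes `C3`, `C4`, `C5` carry two; `mRNA` and the loaded
#' transcript `C1` carry none). The PHLPP level is folded into the
#' pseudo-first-order dephosphorylation constant `k17` and therefore appears
#' in the registry but in no rate law.
#'
#' @param kind one of `"all"`, `"dynamical"`, `"clamped"`
#' @return a data.frame with columns `name`, `kind`, `unit`, `moiety`
#' @export
pkcSpecies <- function(kind = c("all", "dynamical", "clamped")) {
  kind <- match.arg(kind)
  out <- switch(kind,
    all = rbind(.pkc_species, .pkc_clamped),
    dynamical = .pkc_species,
    clamped = .pkc_clamped)
  rownames(out) <- NULL
  out
}

## One elementary mass-action step. `reactants`/`products` are named integer
## stoichiometries over dynamical species; `modifiers` over clamped species.
.step <- function(reaction, rate, reactants = c(), products = c(),
                  modifiers = c()) {
  list(reaction = reaction, rate = rate,
       reactants = reactants, products = products, modifiers = modifiers)
}

#' Build the PKC life-cycle reaction network
#'
#' Constructs the 13-reaction network (`R1`--`R12` plus `RM`, the slow
#' first-order turnover of the mature pool). Reversible reactions and
#' catalytic release steps are stored as elementary mass-action steps grouped
#' under their reaction id, each step carrying a single rate-constant
#' identifier. With `dual_degradation = TRUE` the variant reaction `RV`
#' (direct degradation of the membrane-bound active phospho form at rate
#' `lambda5`) is appended, giving the two-competing-pathway model.
#'
#' @param dual_degradation include the `RV` membrane-degradation pathway
#' @return an object of class `pkc_network`: species registry, elementary
#'   steps, stoichiometry matrix and moiety weights
#' @export
buildDefaultNetwork <- function(dual_degradation = FALSE) {
  steps <- list(
    ## synthesis: transcript loading onto polyribosomes, gated translation
    .step("R1", "k1", reactants = c(mRNA = 1L), products = c(C1 = 1L),
          modifiers = c(T = 1L)),
    .step("R1", "k2", reactants = c(C1 = 1L), products = c(mRNA = 1L)),
    .step("R2", "k3", reactants = c(C1 = 1L),
          products = c(PKC = 1L, mRNA = 1L)),
    .step("R3", "lambda1", reactants = c(PKC = 1L)),
    ## PDK1-mediated activation-loop phosphorylation (catalyst released)
    .step("R4", "k4", reactants = c(PKC = 1L), products = c(C2 = 1L),
          modifiers = c(PDK1 = 1L)),
    .step("R4", "k5", reactants = c(C2 = 1L), products = c(PKC = 1L)),
    .step("R4", "k6", reactants = c(C2 = 1L), products = c(PKC_PA = 1L)),
    ## mTORC2 complex formation
    .step("R5", "k7", reactants = c(PKC_PA = 1L), products = c(CPKC_PA = 1L),
          modifiers = c(mTORC2 = 1L)),
    .step("R5", "k8", reactants = c(CPKC_PA = 1L), products = c(PKC_PA = 1L)),
    .step("R6", "lambda2", reactants = c(PKC_PA = 1L)),
    ## autophosphorylation of the C-terminal tail (trans, then mature-assisted)
    .step("R7", "k9", reactants = c(CPKC_PA = 2L), products = c(C3 = 1L)),
    .step("R7", "k10", reactants = c(C3 = 1L), products = c(CPKC_PA = 2L)),
    .step("R7", "k11", reactants = c(C3 = 1L),
          products = c(CPKC_PAPHPT = 1L, CPKC_PA = 1L)),
    .step("R8", "k12", reactants = c(CPKC_PAPHPT = 1L, CPKC_PA = 1L),
          products = c(C4 = 1L)),
    .step("R8", "k13", reactants = c(C4 = 1L),
          products = c(CPKC_PAPHPT = 1L, CPKC_PA = 1L)),
    .step("R8", "k14", reactants = c(C4 = 1L),
          products = c(CPKC_PAPHPT = 2L)),
    ## second-messenger activation (reversible membrane binding)
    .step("R9", "k15", reactants = c(CPKC_PAPHPT = 1L),
          products = c(PKC_PAPHPT_act = 1L), modifiers = c(ACT = 1L)),
    .step("R9", "k16", reactants = c(PKC_PAPHPT_act = 1L),
          products = c(CPKC_PAPHPT = 1L)),
    ## PHLPP-mediated dephosphorylation (PHLPP level folded into k17)
    .step("R10", "k17", reactants = c(PKC_PAPHPT_act = 1L),
          products = c(PKC_A = 1L)),
    .step("R11", "lambda3", reactants = c(PKC_A = 1L)),
    ## HSP70-mediated rescue of the dephosphorylated active species
    .step("R12", "k18", reactants = c(CPKC_PAPHPT = 1L, PKC_A = 1L),
          products = c(C5 = 1L), modifiers = c(HSP70 = 1L)),
    .step("R12", "k19", reactants = c(C5 = 1L),
          products = c(CPKC_PAPHPT = 1L, PKC_A = 1L)),
    .step("R12", "k20", reactants = c(C5 = 1L),
          products = c(CPKC_PAPHPT = 2L)),
    ## slow turnover of the mature, fully phosphorylated pool
    .step("RM", "lambda4", reactants = c(CPKC_PAPHPT = 1L))
  )
  if (dual_degradation) {
    steps <- c(steps, list(
      .step("RV", "lambda5", reactants = c(PKC_PAPHPT_act = 1L))))
  }
  net <- structure(list(
    species = pkcSpecies("dynamical"),
    clamped = pkcSpecies("clamped"),
    steps = steps,
    dual_degradation = dual_degradation
  ), class = "pkc_network")
  net$stoichiometry <- stoichiometryMatrix(net)
  net
}

#' Reaction ids of a network (grouped, R1...R12 + RM [+ RV])
#' @param network a `pkc_network`
#' @return character vector of unique reaction ids
#' @export
reactionIds <- function(network) {
  unique(vapply(network$steps, `[[`, "", "reaction"))
}

#' Stoichiometry matrix over dynamical species
#'
#' One column per elementary step, rows in state-vector order; entry =
#' product stoichiometry minus reactant stoichiometry. Clamped modifiers do
#' not appear (they are chemostatted).
#'
#' @param network a `pkc_network`
#' @return integer matrix, 12 x n_steps
#' @export
stoichiometryMatrix <- function(network) {
  spp <- network$species$name
  S <- matrix(0L, nrow = length(spp), ncol = length(network$steps),
              dimnames = list(spp, vapply(network$steps, `[[`, "", "rate")))
  for (j in seq_along(network$steps)) {
    st <- network$steps[[j]]
    for (s in names(st$reactants)) S[s, j] <- S[s, j] - st$reactants[[s]]
    for (s in names(st$products))  S[s, j] <- S[s, j] + st$products[[s]]
  }
  S
}

#' Net PKC-moiety change of each reaction
#'
#' Moiety bookkeeping over grouped reactions: zero for every interconversion,
#' +1 for synthesis (R2) and -1 for each degradation reaction
#' (R3, R6, R11, RM, and RV in the variant).
#'
#' @param network a `pkc_network`
#' @return named numeric vector, one entry per reaction id
#' @export
moietyChange <- function(network) {
  w <- network$species$moiety
  S <- network$stoichiometry
  per_step <- as.numeric(w %*% S)
  rxn <- vapply(network$steps, `[[`, "", "reaction")
  ## reversible pairs cancel within a group only for net flux; report the
  ## per-step change of the group's defining direction instead: each step in
  ## a group has the same moiety change, so take the first
  vapply(split(per_step, factor(rxn, levels = unique(rxn))),
         function(x) x[[1]], numeric(1))
}

#' Mass-action flux of one elementary step
#'
#' flux = rate constant x product of reactant concentrations (raised to their
#' stoichiometric coefficients) x product of clamped-modifier levels.
#'
#' @param step an elementary step from `pkc_network$steps`
#' @param state named (or ordered) numeric state vector of the 12 dynamical
#'   species
#' @param params parameterization (named list/vector of rate constants)
#' @param clamped named levels of the clamped species entering rate laws
#' @return flux in concentration per second
#' @export
massActionFlux <- function(step, state, params, clamped = c()) {
  k <- params[[step$rate]]
  if (is.null(k)) stop("unknown rate constant id: ", step$rate)
  names(state) <- .pkc_species$name[seq_along(state)]
  f <- k
  for (s in names(step$reactants)) f <- f * state[[s]]^step$reactants[[s]]
  for (s in names(step$modifiers)) {
    lv <- clamped[[s]]
    if (is.null(lv)) stop("missing clamped level for modifier: ", s)
    f <- f * lv^step$modifiers[[s]]
  }
  unname(f)
}

#' Flux vector over all elementary steps
#' @inheritParams massActionFlux
#' @param network a `pkc_network`
#' @return numeric vector of per-step fluxes (concentration/second)
#' @export
fluxVector <- function(network, state, params, clamped) {
  vapply(network$steps, massActionFlux, numeric(1),
         state = state, params = params, clamped = clamped)
}

#' Stoichiometry-matrix right-hand side (S v)
#'
#' Generic ODE right-hand side assembled as the stoichiometry matrix times
#' the flux vector. This is the reference construction against which the
#' hand-coded [pkcDerivatives()] is verified; the simulator uses the latter.
#'
#' @inheritParams fluxVector
#' @return derivative of the state vector (per second)
#' @export
stoichRHS <- function(network, state, params, clamped) {
  as.numeric(network$stoichiometry %*% fluxVector(network, state, params, clamped))
}

#' Hand-coded right-hand side of the PKC life-cycle ODEs
#'
#' Explicit mass-balance equations for the 12 dynamical species. `params`
#' must already hold the *effective* time-resolved constants for the current
#' protocol segment (`k3` gated by the synthesis pulse, `k17` after PHLPP
#' blocking) and `clamped` the current activator level and HSP70 level.
#'
#' @inheritParams fluxVector
#' @return derivative of the state vector (per second)
#' @export
pkcDerivatives <- function(state, params, clamped) {
  p <- params
  mRNA <- state[[1]]; C1 <- state[[2]]; PKC <- state[[3]]; C2 <- state[[4]]
  PA <- state[[5]]; CPA <- state[[6]]; C3 <- state[[7]]; C4 <- state[[8]]
  M <- state[[9]]; A <- state[[10]]; D <- state[[11]]; C5 <- state[[12]]

  v1f <- p$k1 * mRNA * clamped[["T"]]
  v1r <- p$k2 * C1
  v2  <- p$k3 * C1
  v3  <- p$lambda1 * PKC
  v4f <- p$k4 * PKC * clamped[["PDK1"]]
  v4r <- p$k5 * C2
  v4c <- p$k6 * C2
  v5f <- p$k7 * PA * clamped[["mTORC2"]]
  v5r <- p$k8 * CPA
  v6  <- p$lambda2 * PA
  v7f <- p$k9 * CPA^2
  v7r <- p$k10 * C3
  v7c <- p$k11 * C3
  v8f <- p$k12 * M * CPA
  v8r <- p$k13 * C4
  v8c <- p$k14 * C4
  v9f <- p$k15 * M * clamped[["ACT"]]
  v9r <- p$k16 * A
  v10 <- p$k17 * A
  v11 <- p$lambda3 * D
  v12f <- p$k18 * M * clamped[["HSP70"]] * D
  v12r <- p$k19 * C5
  v12c <- p$k20 * C5
  vM  <- p$lambda4 * M
  vV  <- if (is.null(p$lambda5)) 0 else p$lambda5 * A

  c(
    -v1f + v1r + v2,                                   # mRNA
    v1f - v1r - v2,                                    # C1
    v2 - v3 - v4f + v4r,                               # PKC
    v4f - v4r - v4c,                                   # C2
    v4c - v5f + v5r - v6,                              # PKC_PA
    v5f - v5r - 2 * v7f + 2 * v7r + v7c - v8f + v8r,   # CPKC_PA
    v7f - v7r - v7c,                                   # C3
    v8f - v8r - v8c,                                   # C4
    v7c + 2 * v8c - v8f + v8r - v9f + v9r -
      v12f + v12r + 2 * v12c - vM,                     # CPKC_PAPHPT
    v9f - v9r - v10 - vV,                              # PKC_PAPHPT_act
    v10 - v11 - v12f + v12r,                           # PKC_A
    v12f - v12r - v12c                                 # C5
  )
}

#' Moiety-weighted total PKC
#'
#' Total PKC enzyme, the reported readout: the sum of all
#' dynamical species weighted by their PKC-moiety count,
#' `[PKC]+[C2]+[PKC_PA]+[CPKC_PA]+2[C3]+2[C4]+[CPKC_PAPHPT]+
#' [PKC_PAPHPT_act]+[PKC_A]+2[C5]` (mRNA and C1 carry no protein moiety).
#'
#' @param state state vector (length 12) or a matrix with 12 state columns
#' @return total PKC in ng/ml (vector if a matrix was given)
#' @export
conservedMoietyTotal <- function(state) {
  w <- .pkc_species$moiety
  if (is.matrix(state)) as.numeric(state %*% w) else sum(w * state)
}

#' @export
print.pkc_network <- function(x, ...) {
  cat("PKC life-cycle reaction network\n")
  cat(sprintf("  %d reactions (%s) as %d elementary mass-action steps\n",
              length(reactionIds(x)), paste(reactionIds(x), collapse = " "),
              length(x$steps)))
  cat(sprintf("  %d dynamical species, %d clamped species\n",
              nrow(x$species), nrow(x$clamped)))
  if (x$dual_degradation)
    cat("  variant: dual degradation (lambda5 on the membrane-active form)\n")
  invisible(x)
}

#' Serialize a network to a structured text document
#'
#' Writes species, elementary steps with stoichiometries and rate-constant
#' ids to YAML, for interoperability and provenance.
#'
#' @param network a `pkc_network`
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeNetworkYaml <- function(network, path) {
  doc <- list(
    species = lapply(seq_len(nrow(network$species)), function(i)
      as.list(network$species[i, ])),
    clamped = lapply(seq_len(nrow(network$clamped)), function(i)
      as.list(network$clamped[i, ])),
    steps = lapply(network$steps, function(st) list(
      reaction = st$reaction, rate = st$rate,
      reactants = as.list(st$reactants), products = as.list(st$products),
      modifiers = as.list(st$modifiers))))
  yaml::write_yaml(doc, path)
  invisible(path)
}
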