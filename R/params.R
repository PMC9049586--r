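## Parameter bookkeeping. All rate constants are stored in per-second units
## (bimolecular constants per concentration unit of the partner per second);
## clamped levels are dimensionless model units except the activator (nM).

.rate_names <- c(paste0("k", 1:20), paste0("lambda", 1:5))
.level_names <- c("T", "PDK1", "mTORC2", "HSP70", "mRNA0")
.param_names <- c(.rate_names, .level_names)

#' Shipped default parameterization
#'
#' Reads the frozen default parameterization calibrated to the reported
#' printed anchors (post-synthesis plateau 73 ng/ml, maturation half-time
#' 10--30 min, autophosphorylation half-time 5--10 min, dose--response and
#' sequential-pulse behaviour) from the configuration file shipped with the
#' package. Degradation anchors: `lambda1 = lambda3 = 0.001` per second
#' (naive and dephosphorylated-active species), `lambda4 = 0.00008` per
#' minute (mature pool; half-life about six days). `lambda5 = 0` in the base
#' model.
#'
#' @return named list of rate constants, clamped baseline levels and the
#'   initial PKC-mRNA concentration
#' @export
defaultParams <- function() {
  path <- system.file("extdata", "pkc_default_parameters.yaml",
                      package = "pkcycle", mustWork = TRUE)
  validateParams(yaml::read_yaml(path)$parameters)
}

#' Validate a parameterization
#'
#' Checks that every required rate constant and level is present, numeric,
#' finite and non-negative; unknown names are rejected.
#'
#' @param params named list or vector
#' @return the parameterization as a named list, invisibly validated
#' @export
validateParams <- function(params) {
  params <- as.list(params)
  missing <- setdiff(setdiff(.param_names, "lambda5"), names(params))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(params), .param_names)
  if (length(unknown))
    stop("unknown parameters: ", paste(unknown, collapse = ", "))
  if (is.null(params$lambda5)) params$lambda5 <- 0
  for (nm in names(params)) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter ", nm, " must be a single non-negative finite number")
  }
  params[.param_names]
}

#' Initial state of the model
#'
#' Basal state: all protein species at zero, PKC-mRNA at its initial level.
#' @param params a parameterization
#' @return named numeric state vector (length 12)
#' @export
initialState <- function(params) {
  y0 <- setNames(numeric(nrow(.pkc_species)), .pkc_species$name)
  y0[["mRNA"]] <- params$mRNA0
  y0
}
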