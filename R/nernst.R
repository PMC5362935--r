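# Physical constants (SI)
.GAS_CONSTANT <- 8.314    # J mol^-1 K^-1
.FARADAY <- 96485         # C mol^-1

#' Ionic context for Nernst calculations
#'
#' Bundles the extracellular chloride concentration, absolute temperature and
#' a fixed additive voltage offset (e.g. a liquid-junction potential that has
#' already been determined elsewhere and is simply applied as a constant).
#'
#' @param cl_o_mM Extracellular chloride concentration (mM). The default,
#'   146.4 mM, is the stoichiometric chloride content of a standard
#'   NaCl/KCl/CaCl2/MgCl2 recording solution (see [solution_chloride()]).
#' @param temp_K Absolute temperature (K); default 295 K (room temperature).
#' @param offset_mV Fixed voltage offset added to computed potentials (mV).
#' @return An object of class `nernst_context`.
#' @export
nernst_context <- function(cl_o_mM = 146.4, temp_K = 295, offset_mV = 0) {
  stopifnot(cl_o_mM > 0, temp_K >= 273, temp_K <= 320)
  structure(list(cl_o_mM = cl_o_mM, temp_K = temp_K, offset_mV = offset_mV),
            class = "nernst_context")
}

#' Chloride Nernst potential and its inverse
#'
#' `nernst()` converts an intracellular chloride concentration into the
#' chloride equilibrium potential, E_Cl = (RT/F) ln([Cl]i/[Cl]o) (anion
#' convention), plus the context's fixed offset. `cl_from_potential()` is the
#' exact inverse, recovering \[Cl\]i from a measured reversal potential. In
#' bicarbonate-free solutions the reversal potential of GABA-A/glycine
#' receptor currents equals E_Cl, so these two functions translate between
#' measured reversal potentials and intracellular chloride.
#'
#' @param cl_i_mM Intracellular chloride concentration (mM), > 0.
#' @param e_cl_mV Chloride equilibrium potential (mV).
#' @param ctx A [nernst_context()].
#' @return `nernst()`: E_Cl in mV. `cl_from_potential()`: \[Cl\]i in mM.
#' @examples
#' nernst(60, nernst_context(146.4, 295))   # about -22.7 mV
#' cl_from_potential(nernst(9), )           # 9
#' @export
nernst <- function(cl_i_mM, ctx = nernst_context()) {
  if (any(cl_i_mM <= 0)) stop("cl_i_mM must be > 0")
  slope <- 1000 * .GAS_CONSTANT * ctx$temp_K / .FARADAY  # mV
  slope * log(cl_i_mM / ctx$cl_o_mM) + ctx$offset_mV
}

#' @rdname nernst
#' @export
cl_from_potential <- function(e_cl_mV, ctx = nernst_context()) {
  slope <- 1000 * .GAS_CONSTANT * ctx$temp_K / .FARADAY
  ctx$cl_o_mM * exp((e_cl_mV - ctx$offset_mV) / slope)
}

# Cl- ions contributed per formula unit
.CL_STOICHIOMETRY <- c(
  NaCl = 1, KCl = 1, CsCl = 1, LiCl = 1, HCl = 1, NH4Cl = 1,
  CaCl2 = 2, MgCl2 = 2, BaCl2 = 2, CoCl2 = 2, CdCl2 = 2,
  TEACl = 1, cholineCl = 1, TrisCl = 1
)

#' Total chloride of a salt mixture
#'
#' Stoichiometric sum of chloride contributed by each salt in a solution
#' recipe, used to derive \[Cl\]o for Nernst calculations from a published
#' solution composition.
#'
#' @param composition Named numeric vector or list, `c(NaCl = 137, KCl = 5)`,
#'   concentrations in mM. Names must be recognized chloride salts
#'   (divalent-cation chlorides count twice).
#' @return Total chloride concentration (mM).
#' @examples
#' solution_chloride(c(NaCl = 137, KCl = 5, CaCl2 = 1, MgCl2 = 1.2)) # 146.4
#' @export
solution_chloride <- function(composition) {
  composition <- unlist(composition)
  if (length(composition) == 0) return(0)
  salts <- names(composition)
  if (is.null(salts) || any(!nzchar(salts)))
    stop("composition must be a named vector of salt concentrations")
  unknown <- setdiff(salts, names(.CL_STOICHIOMETRY))
  if (length(unknown) > 0)
    stop("unknown salt(s): ", paste(unknown, collapse = ", "))
  sum(composition * .CL_STOICHIOMETRY[salts])
}
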