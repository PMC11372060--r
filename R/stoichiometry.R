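#' Monomer masses of the KaiA3B3C3 clock proteins
#'
#' Nominal tag-inclusive monomer masses (kDa) of the recombinant constructs
#' used for native-PAGE band assignment: KaiC3 58, KaiA3 35, KaiB3 12.
#'
#' @return named numeric vector of masses in kDa.
#' @export
kai_monomer_masses <- function() {
  c(KaiC3 = 58, KaiA3 = 35, KaiB3 = 12)
}

#' Mass of a protein complex from monomer copy numbers
#'
#' @param spec named vector/list of nonnegative integer monomer copy numbers,
#'   e.g. `c(KaiC3 = 6, KaiA3 = 12, KaiB3 = 6)` for one KaiC3 hexamer, six
#'   KaiA3 dimers and six KaiB3 monomers.
#' @param masses named vector of monomer masses in kDa
#'   (default [kai_monomer_masses()]).
#' @return total mass in kDa.
#' @examples
#' complex_mass(c(KaiC3 = 6, KaiA3 = 12, KaiB3 = 6)) # 840
#' complex_mass(c(KaiC3 = 6)) # 348, the bare hexamer
#' @export
complex_mass <- function(spec, masses = kai_monomer_masses()) {
  spec <- unlist(spec)
  if (length(spec) == 0L) return(0)
  if (is.null(names(spec)) || any(names(spec) == "")) {
    cr_abort("complex spec must be named by protein", "key_error")
  }
  if (any(spec < 0) || any(spec != round(spec))) {
    cr_abort("copy numbers must be nonnegative integers", "domain_error")
  }
  missing <- setdiff(names(spec), names(masses))
  if (length(missing) > 0L) {
    cr_abort(paste0("no monomer mass for: ", paste(missing, collapse = ", ")),
             "key_error")
  }
  sum(spec * masses[names(spec)])
}

#' Molar ratio of two concentrations
#'
#' `conc_b / conc_a`, rounded half-even to the requested number of decimals
#' (the convention used for titration stoichiometries like "1:0.8").
#'
#' @param conc_a reference concentration, uM (> 0).
#' @param conc_b second concentration, uM.
#' @param decimals decimal places (default 1).
#' @return rounded dimensionless ratio.
#' @examples
#' molar_ratio(4.2, 3.4) # 0.8
#' @export
molar_ratio <- function(conc_a, conc_b, decimals = 1L) {
  if (!is_number(conc_a) || conc_a <= 0) {
    cr_abort("reference concentration must be > 0", "domain_error")
  }
  round(conc_b / conc_a, decimals)
}
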