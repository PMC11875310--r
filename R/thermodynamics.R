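#' Systematic thermal instability Ti = S/N
#'
#' The grid-based systematic thermal instability of a state is the ratio
#' of its total grid sizes S (free residues summed over the mesh grids) to
#' its total intra-pathway noncovalent interactions N. Larger values mean
#' a looser, less thermally stable network.
#'
#' @param N total noncovalent interactions (> 0).
#' @param S total grid sizes (free-residue count, >= 0).
#' @return Ti as a numeric; display at 2 decimals by convention.
#' @examples
#' thermal_instability(67, 99)  # 1.48
#' thermal_instability(30, 83)  # 2.77
#' @export
thermal_instability <- function(N, S) {
  if (!is.numeric(N) || !is.numeric(S) || any(N <= 0))
    stop("Ti is undefined for N <= 0")
  if (any(S < 0)) stop("S must be >= 0")
  S / N
}

#' Melting temperature threshold of a grid's controlled bridge
#'
#' Empirical affine model for the temperature at which the least-stable
#' noncovalent bridge controlled by a grid unfolds:
#' \deqn{T_m(\degree C) = 34 + (n - 2) \times 10 + (20 - s) \times 2}
#' where \code{n} is the number of basic H-bonds (about 1 kcal/mol each)
#' energetically equivalent to the controlled bridge(s) and \code{s} is
#' the grid size. Tm rises 10 degrees C per extra basic H-bond and falls
#' 2 degrees C per extra free residue in the grid.
#'
#' @param n basic-H-bond equivalents of the controlled bridge(s) (> 0).
#' @param s grid size, in free residues (>= 0).
#' @return Tm in degrees Celsius.
#' @examples
#' melting_threshold(2, 12)    # 50
#' melting_threshold(2.6, 12)  # 56
#' melting_threshold(2, 20)    # 34
#' @export
melting_threshold <- function(n, s) {
  if (!is.numeric(n) || any(n <= 0)) stop("n must be > 0")
  if (!is.numeric(s) || any(s < 0)) stop("s must be >= 0")
  34 + (n - 2) * 10 + (20 - s) * 2
}

#' Grid-based structural thermosensitivity Omega10
#'
#' Structural analogue of the functional Q10 for a gating transition from
#' an initial (closed or partially open) state to a final (open) state:
#' \deqn{\Omega_{10} = [(S_c - S_o) E / 2]^{N_c / N_o}}
#' with \code{S_c, S_o} the total grid sizes, \code{N_c, N_o} the total
#' noncovalent interactions of the two states, and \code{E} the mean
#' energy intensity of one interaction (kcal/mol, default 1). The exponent
#' is the enthalpy ratio \code{H_c/H_o = E N_c / (E N_o) = N_c/N_o}.
#'
#' @param S_c,S_o total grid sizes of the initial and final state
#'   (\code{S_c > S_o} for an activation-direction change).
#' @param N_c,N_o total interactions of the initial and final state
#'   (\code{N_o > 0}).
#' @param E energy per noncovalent interaction, kcal/mol (default 1).
#' @return Omega10 (dimensionless).
#' @examples
#' structural_thermosensitivity(99, 71, 67, 35)  # ~156, printed ~154.6
#' structural_thermosensitivity(83, 71, 30, 35)  # ~4.64
#' @export
structural_thermosensitivity <- function(S_c, S_o, N_c, N_o, E = 1) {
  if (!all(is.numeric(c(S_c, S_o, N_c, N_o, E)))) stop("numeric inputs required")
  if (N_o <= 0) stop("N_o must be > 0")
  if (S_c <= S_o)
    stop("S_c must exceed S_o: no activation-direction grid-size change")
  base <- (S_c - S_o) * E / 2
  if (base <= 0) stop("(S_c - S_o) * E / 2 must be > 0")
  base^(N_c / N_o)
}

#' Functional thermosensitivity Q10
#'
#' Standard Q10: the fold-change in activity normalized to a 10-degree
#' span, \eqn{Q_{10} = (X_2/X_1)^{10/(T_2-T_1)}} with temperatures in
#' Kelvin.
#'
#' @param X1,X2 relative channel activities at \code{T1} and \code{T2}
#'   (both > 0).
#' @param T1,T2 temperatures in Kelvin (\code{T1 != T2}).
#' @return Q10 (dimensionless).
#' @examples
#' functional_q10(1, 154.7, 300, 310)  # 154.7
#' functional_q10(2, 8, 300, 320)      # 2
#' @export
functional_q10 <- function(X1, X2, T1, T2) {
  if (!all(is.numeric(c(X1, X2, T1, T2)))) stop("numeric inputs required")
  if (X1 <= 0 || X2 <= 0) stop("activities must be > 0")
  if (T1 == T2) stop("T1 and T2 must differ")
  (X2 / X1)^(10 / (T2 - T1))
}

#' Activation enthalpy from per-subunit interaction bookkeeping
#'
#' Total enthalpy of a gating transition of a homo-oligomeric channel,
#' counted from the net loss of noncovalent bridges per subunit:
#' \deqn{\Delta H = (broken_{intra} + broken_{inter} - formed) \times
#'   subunits \times E}
#'
#' @param broken_intra intra-pathway interactions disrupted per subunit.
#' @param broken_inter intersubunit interactions disrupted per subunit.
#' @param formed new interactions formed per subunit.
#' @param subunits number of subunits in the assembly (default 4,
#'   homotetramer).
#' @param E energy per interaction, kcal/mol (default 1).
#' @return Activation enthalpy in kcal/mol.
#' @examples
#' activation_enthalpy(32, 4, 1, 4, 1)  # 140
#' @export
activation_enthalpy <- function(broken_intra, broken_inter, formed,
                                subunits = 4, E = 1) {
  v <- c(broken_intra, broken_inter, formed)
  if (!all(is.numeric(v)) || any(v < 0)) stop("counts must be >= 0")
  if (subunits < 1) stop("subunits must be >= 1")
  (broken_intra + broken_inter - formed) * subunits * E
}
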