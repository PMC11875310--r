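#' Default geometric criteria for noncovalent interaction detection
#'
#' Returns the package's default distance/angle windows for the six
#' interaction classes considered along a gating pathway: hydrogen bonds,
#' salt bridges, pi-pi stacking, cation-pi, CH-pi and lone-pair-pi
#' contacts. The values follow widely used literature geometry for
#' side-chain contact analysis and every one of them is overridable, either
#' programmatically or through a YAML criteria file
#' (\code{\link{read_criteria}}), so that an alternative published cutoff
#' table can be reproduced exactly.
#'
#' Distances are heavy-atom distances in Angstrom. Angles are in degrees:
#' \describe{
#'   \item{hydrogen_bond}{donor--acceptor distance \code{max_distance};
#'     surrogate donor angle (antecedent--donor--acceptor, measured on
#'     hydrogen-free models) at least \code{min_donor_angle}.}
#'   \item{salt_bridge}{any charged-group nitrogen within
#'     \code{max_distance} of a charged-group oxygen.}
#'   \item{pi_pi}{ring-centroid distance at most \code{max_distance_parallel}
#'     with inter-normal angle at most \code{max_parallel_angle} (stacked),
#'     or at most \code{max_distance_tshaped} with inter-normal angle at
#'     least \code{min_tshaped_angle} (T-shaped).}
#'   \item{cation_pi}{charged-group center to ring centroid at most
#'     \code{max_distance}, off-axis angle (ring normal vs centroid-to-cation
#'     vector) at most \code{max_offaxis_angle}.}
#'   \item{ch_pi}{aliphatic side-chain carbon to ring centroid at most
#'     \code{max_distance}, off-axis angle at most \code{max_offaxis_angle}.}
#'   \item{lone_pair_pi}{side-chain O/N lone-pair carrier to ring centroid
#'     at most \code{max_distance}, off-axis angle at most
#'     \code{max_offaxis_angle}.}
#' }
#'
#' @return A named list of class \code{geometric_criteria}.
#' @examples
#' crit <- default_criteria()
#' crit$hydrogen_bond$max_distance
#' @export
default_criteria <- function() {
  structure(list(
    hydrogen_bond = list(max_distance = 3.5, min_donor_angle = 90),
    salt_bridge   = list(max_distance = 4.0),
    pi_pi         = list(max_distance_parallel = 5.5,
                         max_parallel_angle = 30,
                         max_distance_tshaped = 6.0,
                         min_tshaped_angle = 60),
    cation_pi     = list(max_distance = 6.0, max_offaxis_angle = 45),
    ch_pi         = list(max_distance = 4.5, max_offaxis_angle = 60),
    lone_pair_pi  = list(max_distance = 4.0, max_offaxis_angle = 60),
    # per-type basic-H-bond energy equivalents (kcal/mol at E = 1)
    energy        = list(hydrogen_bond = 1, salt_bridge = 1, pi_pi = 1,
                         cation_pi = 1, ch_pi = 1, lone_pair_pi = 1)
  ), class = "geometric_criteria")
}

#' Read / write a criteria configuration file
#'
#' The criteria live in one editable YAML file with a section per
#' interaction type plus an \code{energy} section; values missing from the
#' file fall back to \code{\link{default_criteria}}.
#'
#' @param path YAML file path.
#' @param criteria a \code{geometric_criteria} list (for writing).
#' @return \code{read_criteria}: a \code{geometric_criteria} list;
#'   \code{write_criteria}: \code{path}, invisibly.
#' @export
read_criteria <- function(path) {
  user <- yaml::read_yaml(path)
  crit <- default_criteria()
  for (sec in intersect(names(user), names(crit))) {
    for (k in names(user[[sec]])) crit[[sec]][[k]] <- user[[sec]][[k]]
  }
  crit
}

#' @rdname read_criteria
#' @export
write_criteria <- function(criteria, path) {
  stopifnot(inherits(criteria, "geometric_criteria"))
  yaml::write_yaml(unclass(criteria), path)
  invisible(path)
}

# ---- side-chain chemistry tables ------------------------------------------
# atom-name tables per residue type; antecedent = covalently bonded heavy
# atom used for the surrogate donor angle

.hb_donors <- list(
  SER = list(c("OG",  "CB")),
  THR = list(c("OG1", "CB")),
  TYR = list(c("OH",  "CZ")),
  ASN = list(c("ND2", "CG")),
  GLN = list(c("NE2", "CD")),
  HIS = list(c("ND1", "CG"), c("NE2", "CD2")),
  LYS = list(c("NZ",  "CE")),
  ARG = list(c("NE",  "CD"), c("NH1", "CZ"), c("NH2", "CZ")),
  TRP = list(c("NE1", "CD1"))
)

.hb_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = c("OD1"), GLN = c("OE1"),
  SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  HIS = c("ND1", "NE2")
)

# charged groups: member atoms used for the distance screen
.pos_groups <- list(
  ARG = c("NH1", "NH2", "NE"),
  LYS = c("NZ"),
  HIS = c("ND1", "NE2")  # His treated as a possible cation
)
.neg_groups <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)

# aromatic ring atom sets; Trp carries both rings, the closer centroid wins
.ring_atoms <- list(
  PHE = list(six = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(six = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(five = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(five = c("CG", "CD1", "NE1", "CE2", "CD2"),
             six  = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)

# lone-pair-pi carriers: side-chain O/N atoms bearing lone pairs
.lp_carriers <- list(
  SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
  HIS = c("ND1", "NE2"), LYS = c("NZ"), MET = c("SD")
)

# side-chain atoms never offered as CH-pi carriers: aromatic ring carbons
.aromatic_carbons <- lapply(.ring_atoms, function(r) unique(unlist(r)))

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")
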