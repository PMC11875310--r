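# Synthetic fixtures: coordinate files with residue pairs posed at ideal
# interaction geometry, and abstract pathway networks with planted cycles
# whose ground truth is computed by the brute-force oracle at generation
# time. Everything is reproducible from a seed; no downloads involved.

# idealized rigid side-chain templates, CA at the origin, side chain
# extending along +y; bond lengths/angles approximate standard geometry
.templates <- list(
  ALA = list(CB = c(0, 1.53, 0)),
  SER = list(CB = c(0, 1.53, 0), OG = c(0, 2.94, 0)),
  ASP = list(CB = c(0, 1.53, 0), CG = c(0, 3.04, 0),
             OD1 = c(1.08, 3.67, 0), OD2 = c(-1.08, 3.67, 0)),
  GLU = list(CB = c(0, 1.53, 0), CG = c(0, 3.04, 0), CD = c(0, 4.55, 0),
             OE1 = c(1.08, 5.18, 0), OE2 = c(-1.08, 5.18, 0)),
  LYS = list(CB = c(0, 1.53, 0), CG = c(0, 3.04, 0), CD = c(0, 4.55, 0),
             CE = c(0, 6.06, 0), NZ = c(0, 7.5, 0)),
  ARG = list(CB = c(0, 1.53, 0), CG = c(0, 3.04, 0), CD = c(0, 4.55, 0),
             NE = c(0, 6.0, 0), CZ = c(0, 7.33, 0),
             NH1 = c(1.15, 8.0, 0), NH2 = c(-1.15, 8.0, 0)),
  PHE = list(CB = c(0, 1.53, 0), CG = c(0, 3.04, 0),
             CD1 = c(1.204, 3.735, 0), CE1 = c(1.204, 5.125, 0),
             CZ = c(0, 5.82, 0), CE2 = c(-1.204, 5.125, 0),
             CD2 = c(-1.204, 3.735, 0)),
  TYR = list(CB = c(0, 1.53, 0), CG = c(0, 3.04, 0),
             CD1 = c(1.204, 3.735, 0), CE1 = c(1.204, 5.125, 0),
             CZ = c(0, 5.82, 0), CE2 = c(-1.204, 5.125, 0),
             CD2 = c(-1.204, 3.735, 0), OH = c(0, 7.19, 0)),
  HIS = list(CB = c(0, 1.53, 0), CG = c(0, 3.04, 0),
             ND1 = c(1.113, 3.846, 0), CE1 = c(0.688, 5.157, 0),
             NE2 = c(-0.688, 5.157, 0), CD2 = c(-1.113, 3.846, 0)),
  TRP = list(CB = c(0, 1.53, 0), CG = c(0, 3.04, 0),
             CD1 = c(1.113, 3.846, 0), NE1 = c(0.688, 5.157, 0),
             CE2 = c(-0.688, 5.157, 0), CD2 = c(-1.113, 3.846, 0),
             CZ2 = c(-1.608, 6.178, 0), CH2 = c(-2.953, 5.892, 0),
             CZ3 = c(-3.377, 4.585, 0), CE3 = c(-2.458, 3.564, 0))
)
.backbone_template <- list(N = c(-1.20, -0.80, 0), CA = c(0, 0, 0),
                           C = c(1.20, -0.80, 0), O = c(1.80, -1.85, 0))

.rotz180 <- diag(c(-1, -1, 1))
# rotation standing the +y side chain down along -z (y -> -z, z -> y)
.rotx_m90 <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3, byrow = TRUE)

.residue_atoms <- function(resname, resno, chain, R = diag(3), t = c(0, 0, 0)) {
  tpl <- c(.backbone_template, .templates[[resname]])
  xyz <- t(vapply(tpl, function(p) as.numeric(R %*% p + t), numeric(3)))
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resid = resname, elety = names(tpl),
             elesy = substr(names(tpl), 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             o = 1, alt = "", stringsAsFactors = FALSE)
}

# geometry of one planted pose: residue A upright at the local origin,
# residue B placed so that the named anchor geometry holds
# res = c(first-in-sequence residue, posed partner)
.pose_recipes <- list(
  hydrogen_bond = list(res = c("SER", "SER"), distance = 2.9),
  salt_bridge   = list(res = c("ASP", "ARG"), distance = 2.85),
  pi_pi         = list(res = c("PHE", "PHE"), distance = 3.8),
  cation_pi     = list(res = c("PHE", "LYS"), distance = 4.5),
  ch_pi         = list(res = c("PHE", "ALA"), distance = 3.7),
  lone_pair_pi  = list(res = c("PHE", "SER"), distance = 3.3)
)

.phe_centroid <- c(0, 4.43, 0)

.build_pose <- function(type, res_a, res_b, d, chain_a, chain_b) {
  place <- function(resname, resno, chain, R, t)
    .residue_atoms(resname, resno, chain, R, t)
  at <- function(resname, atom) .templates[[resname]][[atom]]
  A <- place(.pose_recipes[[type]]$res[1], res_a, chain_a, diag(3),
             c(0, 0, 0))
  B <- switch(type,
    hydrogen_bond = {
      target <- at("SER", "OG") + c(0, d, 0)
      t <- target - as.numeric(.rotz180 %*% at("SER", "OG"))
      place("SER", res_b, chain_b, .rotz180, t)
    },
    salt_bridge = {
      target <- at("ASP", "OD1") + c(0, d, 0)
      t <- target - as.numeric(.rotz180 %*% at("ARG", "NH2"))
      place("ARG", res_b, chain_b, .rotz180, t)
    },
    pi_pi = {
      target <- .phe_centroid + c(0, 0, d)
      t <- target - as.numeric(.rotz180 %*% .phe_centroid)
      place("PHE", res_b, chain_b, .rotz180, t)
    },
    cation_pi = {
      target <- .phe_centroid + c(0, 0, d)
      t <- target - as.numeric(.rotx_m90 %*% at("LYS", "NZ"))
      place("LYS", res_b, chain_b, .rotx_m90, t)
    },
    ch_pi = {
      target <- .phe_centroid + c(0, 0, d)
      t <- target - as.numeric(.rotx_m90 %*% at("ALA", "CB"))
      place("ALA", res_b, chain_b, .rotx_m90, t)
    },
    lone_pair_pi = {
      target <- .phe_centroid + c(0, 0, d)
      t <- target - as.numeric(.rotx_m90 %*% at("SER", "OG"))
      place("SER", res_b, chain_b, .rotx_m90, t)
    },
    stop("unknown pose type: ", type)
  )
  rbind(A, B)
}

#' Blueprint for a coordinate fixture with planted interaction poses
#'
#' Describes a synthetic single- (or two-) chain structure in which each
#' interaction type is planted once as an ideally posed residue pair (the
#' pose satisfies the default criteria with a clear margin) plus decoy
#' pairs placed beyond every cutoff. The seed drives a random rigid motion
#' applied to each pose, so fixtures differ between seeds while detection
#' (rigid-motion invariant) must recover exactly the planted poses.
#'
#' @param seed integer RNG seed.
#' @param types interaction types to plant (default: all six).
#' @param n_decoys number of non-interacting decoy pairs (default 2).
#' @return An object of class \code{geometry_blueprint}: list with
#'   \code{seed}, \code{poses} (data frame: type, residue numbers/names,
#'   target distance) and \code{decoys}.
#' @examples
#' bp <- geometry_blueprint(seed = 7)
#' bp$poses
#' @export
geometry_blueprint <- function(seed = 1,
                               types = names(.pose_recipes),
                               n_decoys = 2) {
  stopifnot(all(types %in% names(.pose_recipes)))
  k <- length(types)
  poses <- data.frame(
    type = types,
    res_a = seq(1, by = 2, length.out = k),
    res_b = seq(2, by = 2, length.out = k),
    resname_a = vapply(types, function(t) .pose_recipes[[t]]$res[1],
                       character(1)),
    resname_b = vapply(types, function(t) .pose_recipes[[t]]$res[2],
                       character(1)),
    distance = vapply(types, function(t) .pose_recipes[[t]]$distance,
                      numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(poses) <- NULL
  decoys <- if (n_decoys > 0) data.frame(
    res_a = seq(2 * k + 1, by = 2, length.out = n_decoys),
    res_b = seq(2 * k + 2, by = 2, length.out = n_decoys),
    resname_a = rep(c("SER", "ARG"), length.out = n_decoys),
    resname_b = rep(c("SER", "ASP"), length.out = n_decoys),
    distance = 9.5
  ) else data.frame()
  structure(list(seed = as.integer(seed), poses = poses, decoys = decoys),
            class = "geometry_blueprint")
}

#' Generate a coordinate fixture from a geometry blueprint
#'
#' Builds an in-memory \code{structure_model} realizing the blueprint:
#' each pose is constructed at ideal geometry, given a seed-determined
#' random rigid motion, and parked in its own region of space (poses 40 A
#' apart) so no cross-pose contacts arise. Decoy pairs are posed like
#' hydrogen-bond pairs but separated beyond every cutoff. With
#' \code{split_chains = TRUE} the second residue of every pose goes to
#' chain B, yielding an intersubunit test assembly.
#'
#' @param blueprint a \code{geometry_blueprint}.
#' @param split_chains place pose partners on chains A and B
#'   (default \code{FALSE}: single chain A).
#' @return A \code{structure_model}; write it out with
#'   \code{\link{write_structure}}.
#' @examples
#' m <- generate_structure_fixture(geometry_blueprint(seed = 3))
#' m
#' @export
generate_structure_fixture <- function(blueprint, split_chains = FALSE) {
  stopifnot(inherits(blueprint, "geometry_blueprint"))
  set.seed(blueprint$seed)
  chain_b <- if (split_chains) "B" else "A"
  rows <- list()
  all_poses <- rbind(
    blueprint$poses,
    if (nrow(blueprint$decoys))
      cbind(type = "hydrogen_bond", blueprint$decoys)
  )
  for (i in seq_len(nrow(all_poses))) {
    p <- all_poses[i, ]
    d <- p$distance
    if (d > 8) {
      # decoy: head-on pair whose side-chain tips sit d apart
      ext <- function(rn) max(vapply(.templates[[rn]],
                                     function(p) p[2], numeric(1)))
      A <- .residue_atoms(p$resname_a, p$res_a, "A")
      B <- .residue_atoms(p$resname_b, p$res_b, chain_b, .rotz180,
                          c(0, ext(p$resname_a) + ext(p$resname_b) + d, 0))
      pose <- rbind(A, B)
    } else {
      pose <- .build_pose(p$type, p$res_a, p$res_b, d, "A", chain_b)
    }
    # seed-determined rigid motion: random rotation + offset inside the
    # pose's own 40 A parking cell
    R <- .random_rotation()
    off <- c(40 * (i - 1), 0, 0) + stats::runif(3, -2, 2)
    xyz <- t(R %*% t(as.matrix(pose[, c("x", "y", "z")])))
    pose$x <- xyz[, 1] + off[1]
    pose$y <- xyz[, 2] + off[2]
    pose$z <- xyz[, 3] + off[3]
    rows[[i]] <- pose
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(structure_id = paste0("synthetic_geom_seed",
                                       blueprint$seed),
                 atoms = atoms, chains = unique(atoms$chain),
                 assembly_size = length(unique(atoms$chain))),
            class = "structure_model")
}

.random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a random planted pathway network with oracle ground truth
#'
#' Draws \code{n_interactions} distinct residue pairs among
#' \code{n_residues} sequence positions, builds the thermoring network,
#' and attaches the exact per-edge grid sizes and total S computed by the
#' brute-force cycle oracle at generation time (never hand-entered).
#'
#' @param seed integer RNG seed (identical seeds give identical fixtures).
#' @param n_residues pathway length (residues numbered 1..n_residues).
#' @param n_interactions number of planted interaction pairs
#'   (at most 15, the oracle guard; at most \code{choose(n_residues, 2)}).
#' @return List with \code{network} (a \code{thermoring_network}) and
#'   \code{blueprint} (seed, sizes, planted pairs,
#'   \code{expected_per_edge_sizes}, \code{expected_S}).
#' @examples
#' fx <- generate_network_fixture(seed = 1, n_residues = 60, n_interactions = 8)
#' fx$blueprint$expected_S
#' @export
generate_network_fixture <- function(seed, n_residues, n_interactions) {
  if (n_interactions > 15)
    stop("n_interactions > 15 exceeds the brute-force oracle guard")
  if (n_interactions > choose(n_residues, 2))
    stop("more interactions requested than residue pairs available")
  set.seed(seed)
  pairs <- matrix(NA_integer_, 0, 2)
  while (nrow(pairs) < n_interactions) {
    p <- sort(sample.int(n_residues, 2))
    if (!any(pairs[, 1] == p[1] & pairs[, 2] == p[2]))
      pairs <- rbind(pairs, p)
  }
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  types <- sample(.interaction_types, n_interactions, replace = TRUE)
  planted <- data.frame(res_a = pairs[, 1], res_b = pairs[, 2],
                        type = types, stringsAsFactors = FALSE)
  iset <- .planted_iset(planted)
  net <- build_network(iset)
  oracle <- brute_force_grid_oracle(net)
  list(network = net,
       blueprint = list(seed = as.integer(seed),
                        n_residues = as.integer(n_residues),
                        planted_interactions = planted,
                        expected_per_edge_sizes = oracle$per_edge_sizes,
                        expected_S = oracle$S))
}

# wrap planted pairs as a minimal interaction_set
.planted_iset <- function(planted, energy = NULL) {
  if (!nrow(planted))
    return(.as_interaction_set(NULL, default_criteria(), NULL))
  recs <- data.frame(
    chain_a = "A", res_a = planted$res_a, name_a = "ALA",
    chain_b = "A", res_b = planted$res_b, name_b = "ALA",
    type = planted$type, distance = 3.0, key_angle = NA_real_,
    energy_equiv = if (is.null(energy)) 1 else energy,
    intersubunit = FALSE, stringsAsFactors = FALSE)
  .as_interaction_set(recs, default_criteria(), NULL)
}

#' The published biggest-grid replica fixture
#'
#' Rebuilds, as an abstract network, the biggest grid of the lipid-bound
#' pre-open closed state: engaged residues 362, 369, 462 and 469 with a
#' 362-462 pi interaction and a 369-469 H-bond, every intervening residue
#' free. The shortest round path through the 369-469 bond runs
#' 362-369...469-462-362 and encloses 12 free residues, so the H-bond is
#' controlled by a 12-residue grid (Tm of 50 degrees C at n = 2).
#'
#' @return List with \code{network}, \code{selection_range} and
#'   \code{expected_size} (12).
#' @examples
#' fx <- grid12_fixture()
#' grid_size_of_edge(fx$network, c(369, 469))
#' @export
grid12_fixture <- function() {
  planted <- data.frame(res_a = c(362, 369), res_b = c(462, 469),
                        type = c("pi_pi", "hydrogen_bond"),
                        stringsAsFactors = FALSE)
  net <- build_network(.planted_iset(planted))
  list(network = net, selection_range = c(330, 480), expected_size = 12L)
}

#' Write a network blueprint as JSON
#'
#' @param blueprint the \code{blueprint} element of
#'   \code{\link{generate_network_fixture}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_blueprint <- function(blueprint, path) {
  jsonlite::write_json(blueprint, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
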