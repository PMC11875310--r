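#' Detect noncovalent side-chain interactions along a pathway selection
#'
#' Screens every residue pair of a \code{\link{select_pathway}} selection
#' against the six geometric interaction classes (hydrogen bond, salt
#' bridge, pi-pi, cation-pi, CH-pi, lone-pair-pi) and returns one record
#' per qualifying pair and type. Detection is purely geometric and
#' deterministic: records are sorted by residue numbers, then type, and the
#' result is invariant under rigid motion of the coordinates and under
#' atom/residue iteration order.
#'
#' Only side-chain--side-chain contacts are considered unless
#' \code{include_backbone = TRUE}, which additionally admits backbone
#' N/O atoms as hydrogen-bond donors/acceptors. A pair that qualifies both
#' as a salt bridge and as a hydrogen bond is recorded once, as a salt
#' bridge; a pair already recorded as pi-pi is not additionally recorded as
#' CH-pi or lone-pair-pi, and a cation-pi pair is not additionally CH-pi
#' (distinct remaining types may coexist on one pair and later close a
#' zero-size grid). Candidate residues with incomplete side chains are
#' skipped for the affected feature with a collected warning, never an
#' error.
#'
#' @param selection a \code{pathway_selection}.
#' @param criteria a \code{geometric_criteria} list
#'   (default \code{\link{default_criteria}()}).
#' @param include_backbone admit backbone N/O in hydrogen bonds
#'   (default \code{FALSE} for intra-pathway detection).
#' @return An \code{interaction_set}: a data frame with columns
#'   \code{chain_a, res_a, name_a, chain_b, res_b, name_b, type, distance,
#'   key_angle, energy_equiv, intersubunit}, carrying the criteria and the
#'   selection as attributes.
#' @examples
#' m <- generate_structure_fixture(geometry_blueprint(seed = 1))
#' sel <- select_pathway(m, "A", 1, max(m$atoms$resno))
#' detect_interactions(sel)
#' @export
detect_interactions <- function(selection, criteria = default_criteria(),
                                include_backbone = FALSE) {
  stopifnot(inherits(selection, "pathway_selection"))
  if (nrow(selection$residues) == 0) stop("empty pathway selection")
  .check_criteria(criteria)
  feats <- .residue_features(selection$atoms, include_backbone)
  recs <- .detect_among(feats, feats, criteria, same_set = TRUE,
                        intersubunit = FALSE)
  .as_interaction_set(recs, criteria, selection)
}

#' Detect intersubunit (swapping) interactions in a multi-chain assembly
#'
#' Screens residue pairs on \emph{different} chains of an assembly for the
#' same six interaction classes — e.g. the swapping cation-pi contact
#' between an S4-S5 linker histidine of one subunit and an S5' arginine of
#' its neighbour in a homotetrameric channel. Symmetric copies across the
#' assembly are deduplicated to one record per unique residue-pair class
#' (unordered residue numbers + type), keeping the copy with the smallest
#' chain pair.
#'
#' @param model a \code{structure_model} with at least 2 chains.
#' @param criteria a \code{geometric_criteria} list.
#' @param include_backbone admit backbone N/O in hydrogen bonds; default
#'   \code{TRUE} for intersubunit contacts (a swapping tyrosine H-bond to a
#'   backbone NH is admissible across subunits).
#' @param start,end optional residue-number window applied to both partners.
#' @return An \code{interaction_set} with \code{intersubunit = TRUE} rows;
#'   empty (with a warning) for a single-chain model.
#' @export
detect_intersubunit <- function(model, criteria = default_criteria(),
                                include_backbone = TRUE,
                                start = NULL, end = NULL) {
  stopifnot(inherits(model, "structure_model"))
  .check_criteria(criteria)
  a <- model$atoms
  if (!is.null(start)) a <- a[a$resno >= start, , drop = FALSE]
  if (!is.null(end)) a <- a[a$resno <= end, , drop = FALSE]
  if (length(unique(a$chain)) < 2) {
    warning("single-chain model: no intersubunit interactions possible")
    return(.as_interaction_set(NULL, criteria, NULL))
  }
  chains <- sort(unique(a$chain))
  recs <- list()
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (i >= j) next
    fa <- .residue_features(a[a$chain == chains[i], , drop = FALSE],
                            include_backbone)
    fb <- .residue_features(a[a$chain == chains[j], , drop = FALSE],
                            include_backbone)
    recs[[length(recs) + 1L]] <-
      .detect_among(fa, fb, criteria, same_set = FALSE, intersubunit = TRUE)
  }
  recs <- do.call(rbind, recs)
  if (!is.null(recs) && nrow(recs)) {
    # deduplicate symmetric copies: one record per {res_a,res_b,type} class
    lo <- pmin(recs$res_a, recs$res_b); hi <- pmax(recs$res_a, recs$res_b)
    cls <- paste(lo, hi, recs$type, sep = "|")
    recs <- recs[order(cls, recs$chain_a, recs$chain_b), , drop = FALSE]
    recs <- recs[!duplicated(paste(pmin(recs$res_a, recs$res_b),
                                   pmax(recs$res_a, recs$res_b),
                                   recs$type, sep = "|")), , drop = FALSE]
  }
  .as_interaction_set(recs, criteria, NULL)
}

#' Assign basic-H-bond energy equivalents to interactions
#'
#' Every interaction carries an \code{energy_equiv}: its energy expressed
#' in basic hydrogen-bond units (about 1 kcal/mol each). Defaults come from
#' the per-type \code{energy} table of the criteria; overrides win. An
#' override entry may name one pair or a group of pairs sharing a total
#' \code{n} (e.g. two least-stable bridges of one grid jointly equivalent
#' to 2.6 basic H-bonds: each member receives an equal share so the group
#' sums to \code{n}).
#'
#' @param iset an \code{interaction_set}.
#' @param overrides a list of entries \code{list(pairs = list(c(resA, resB),
#'   ...), n = <total basic H-bonds>)}.
#' @param energy_table optional named per-type replacement for the criteria
#'   energy table.
#' @return The \code{interaction_set} with updated \code{energy_equiv}.
#' @examples
#' m <- generate_structure_fixture(geometry_blueprint(seed = 1))
#' sel <- select_pathway(m, "A", 1, max(m$atoms$resno))
#' is <- detect_interactions(sel)
#' is2 <- assign_energy_equivalents(is,
#'   overrides = list(list(pairs = list(c(is$res_a[1], is$res_b[1])), n = 2)))
#' @export
assign_energy_equivalents <- function(iset, overrides = NULL,
                                      energy_table = NULL) {
  stopifnot(inherits(iset, "interaction_set"))
  crit <- attr(iset, "criteria")
  etab <- if (is.null(energy_table)) crit$energy else energy_table
  if (nrow(iset)) {
    iset$energy_equiv <- vapply(iset$type, function(t) {
      v <- etab[[t]]; if (is.null(v)) 1 else as.numeric(v)
    }, numeric(1))
  }
  for (ov in overrides) {
    if (is.null(ov$pairs) || is.null(ov$n))
      stop("each override needs $pairs and $n")
    idx <- unlist(lapply(ov$pairs, function(p) {
      hit <- which((iset$res_a == p[1] & iset$res_b == p[2]) |
                   (iset$res_a == p[2] & iset$res_b == p[1]))
      if (!length(hit))
        stop("energy override references unknown pair ", p[1], "-", p[2])
      hit
    }))
    iset$energy_equiv[idx] <- ov$n / length(idx)
  }
  iset
}

#' Number of intra-pathway interactions (N)
#'
#' @param iset an \code{interaction_set}.
#' @return Integer count of intra-subunit records — the total N of a
#'   state's network.
#' @export
n_interactions <- function(iset) {
  stopifnot(inherits(iset, "interaction_set"))
  sum(!iset$intersubunit)
}

#' Write / read an interaction table as TSV
#'
#' Column dialect: \code{chain_a, res_a, name_a, chain_b, res_b, name_b,
#' type, distance_A, key_angle_deg, energy_equiv, intersubunit}, so
#' transcribed published supplementary tables can be diffed against and
#' re-imported.
#'
#' @param iset an \code{interaction_set}.
#' @param path TSV file path.
#' @return \code{write_interactions}: \code{path} invisibly;
#'   \code{read_interactions}: an \code{interaction_set}.
#' @export
write_interactions <- function(iset, path) {
  stopifnot(inherits(iset, "interaction_set"))
  out <- as.data.frame(iset)
  names(out)[names(out) == "distance"] <- "distance_A"
  names(out)[names(out) == "key_angle"] <- "key_angle_deg"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  names(d)[names(d) == "distance_A"] <- "distance"
  names(d)[names(d) == "key_angle_deg"] <- "key_angle"
  .as_interaction_set(d, default_criteria(), NULL)
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("Interaction set: %d interaction(s)", nrow(x)))
  if (nrow(x)) {
    tab <- table(x$type)
    cat(" [", paste(names(tab), tab, sep = ":", collapse = ", "), "]")
  }
  cat("\n")
  if (nrow(x)) print.data.frame(x, digits = 3)
  invisible(x)
}

# ---- internals ------------------------------------------------------------

.interaction_types <- c("hydrogen_bond", "salt_bridge", "pi_pi",
                        "cation_pi", "ch_pi", "lone_pair_pi")

.check_criteria <- function(criteria) {
  need <- c(.interaction_types, "energy")
  miss <- setdiff(need, names(criteria))
  if (length(miss))
    stop("criteria incomplete; missing: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

.empty_interactions <- function() {
  data.frame(chain_a = character(), res_a = integer(), name_a = character(),
             chain_b = character(), res_b = integer(), name_b = character(),
             type = character(), distance = numeric(), key_angle = numeric(),
             energy_equiv = numeric(), intersubunit = logical(),
             stringsAsFactors = FALSE)
}

.as_interaction_set <- function(recs, criteria, selection) {
  if (is.null(recs) || !nrow(recs)) recs <- .empty_interactions()
  ord <- order(recs$res_a, recs$res_b, recs$type)
  recs <- recs[ord, , drop = FALSE]
  rownames(recs) <- NULL
  structure(recs, criteria = criteria, pathway = selection,
            class = c("interaction_set", "data.frame"))
}

# geometric feature extraction: one entry per residue with donors,
# acceptors, charge groups, rings, CH carriers, lone-pair carriers
.residue_features <- function(atoms, include_backbone = FALSE) {
  keys <- unique(atoms[, c("chain", "resno", "insert", "resid")])
  keys <- keys[order(keys$chain, keys$resno, keys$insert), , drop = FALSE]
  idx <- split(seq_len(nrow(atoms)),
               paste(atoms$chain, atoms$resno, atoms$insert, sep = "|"))
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    ai <- atoms[idx[[paste(k$chain, k$resno, k$insert, sep = "|")]], ,
                drop = FALSE]
    xyz <- as.matrix(ai[, c("x", "y", "z")])
    rownames(xyz) <- ai$elety
    rn <- k$resid
    sc <- !(ai$elety %in% .backbone_atoms)
    get <- function(nms) xyz[intersect(nms, rownames(xyz)), , drop = FALSE]

    donors <- list()
    for (d in .hb_donors[[rn]] %||% list()) {
      if (all(d %in% rownames(xyz)))
        donors[[length(donors) + 1L]] <-
          list(atom = d[1], pos = xyz[d[1], ], ante = xyz[d[2], ])
    }
    if (include_backbone && all(c("N", "CA") %in% rownames(xyz)))
      donors[[length(donors) + 1L]] <-
        list(atom = "N", pos = xyz["N", ], ante = xyz["CA", ])
    acc <- get(.hb_acceptors[[rn]] %||% character())
    if (include_backbone) acc <- rbind(acc, get("O"))

    rings <- list()
    for (rnm in names(.ring_atoms[[rn]] %||% list())) {
      ra <- .ring_atoms[[rn]][[rnm]]
      if (all(ra %in% rownames(xyz))) {
        m <- xyz[ra, , drop = FALSE]
        rings[[length(rings) + 1L]] <-
          list(centroid = colMeans(m), normal = .plane_normal(m))
      }
    }
    cation <- NULL
    pg <- .pos_groups[[rn]]
    if (!is.null(pg) && all(pg %in% rownames(xyz))) {
      cation <- colMeans(xyz[pg, , drop = FALSE])
    }
    chc <- xyz[sc & ai$elesy == "C" &
                 !(ai$elety %in% (.aromatic_carbons[[rn]] %||% character())), ,
               drop = FALSE]
    out[[i]] <- list(
      chain = k$chain, resno = k$resno, resid = rn,
      donors = donors, acceptors = acc,
      pos_atoms = get(.pos_groups[[rn]] %||% character()),
      neg_atoms = get(.neg_groups[[rn]] %||% character()),
      rings = rings, cation = cation,
      ch_carbons = chc,
      lp_atoms = get(.lp_carriers[[rn]] %||% character()),
      center = colMeans(xyz),
      radius = max(sqrt(rowSums((xyz - rep(colMeans(xyz),
                                           each = nrow(xyz)))^2)))
    )
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.plane_normal <- function(m) {
  c0 <- sweep(m, 2, colMeans(m))
  v <- svd(c0, nu = 0)$v
  v[, 3]
}

.deg <- function(x) x * 180 / pi

# angle at p2 formed by p1-p2-p3
.angle3 <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  .deg(acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))))
}

# angle between a plane normal and a direction, folded to [0, 90]
.offaxis <- function(normal, vec) {
  ca <- abs(sum(normal * vec)) / sqrt(sum(normal^2) * sum(vec^2))
  .deg(acos(pmin(1, ca)))
}

.dist <- function(p, q) sqrt(sum((p - q)^2))

# minimum cross-distance between two coordinate matrices, with atom names
.min_pair_dist <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(NULL)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  w <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  list(d = sqrt(max(0, min(d2))), a = rownames(A)[w[1]], b = rownames(B)[w[2]])
}

# all candidate records between two feature lists
.detect_among <- function(fa, fb, criteria, same_set, intersubunit) {
  maxcut <- max(criteria$hydrogen_bond$max_distance,
                criteria$salt_bridge$max_distance,
                criteria$pi_pi$max_distance_parallel,
                criteria$pi_pi$max_distance_tshaped,
                criteria$cation_pi$max_distance,
                criteria$ch_pi$max_distance,
                criteria$lone_pair_pi$max_distance)
  recs <- list()
  for (i in seq_along(fa)) {
    jseq <- if (same_set) seq_len(i - 1L) else seq_along(fb)
    for (j in jseq) {
      A <- fa[[i]]; B <- fb[[j]]
      if (.dist(A$center, B$center) > A$radius + B$radius + maxcut) next
      # canonical partner order: smaller (chain, resno) first
      if (B$chain < A$chain || (B$chain == A$chain && B$resno < A$resno)) {
        tmp <- A; A <- B; B <- tmp
      }
      r <- .detect_pair(A, B, criteria)
      if (!is.null(r)) {
        r$intersubunit <- intersubunit
        recs[[length(recs) + 1L]] <- r
      }
    }
  }
  if (!length(recs)) return(NULL)
  do.call(rbind, recs)
}

# evaluate the six criteria on one ordered residue pair; returns best
# record per admissible type after precedence suppression
.detect_pair <- function(A, B, criteria) {
  hits <- list()
  add <- function(type, d, ang) {
    prev <- hits[[type]]
    if (is.null(prev) || d < prev$d) hits[[type]] <<- list(d = d, ang = ang)
    invisible(NULL)
  }

  # hydrogen bond: donor of one partner to acceptor of the other
  hb <- criteria$hydrogen_bond
  for (dir in list(list(A, B), list(B, A))) {
    D <- dir[[1]]; Ac <- dir[[2]]
    for (don in D$donors) {
      if (!nrow(Ac$acceptors)) next
      for (k in seq_len(nrow(Ac$acceptors))) {
        apos <- Ac$acceptors[k, ]
        d <- .dist(don$pos, apos)
        if (d > hb$max_distance) next
        ang <- .angle3(don$ante, don$pos, apos)
        if (ang >= hb$min_donor_angle) add("hydrogen_bond", d, ang)
      }
    }
  }

  # salt bridge: charged-group N to charged-group O
  sb <- criteria$salt_bridge
  for (dir in list(list(A$pos_atoms, B$neg_atoms),
                   list(B$pos_atoms, A$neg_atoms))) {
    mp <- .min_pair_dist(dir[[1]], dir[[2]])
    if (!is.null(mp) && mp$d <= sb$max_distance) add("salt_bridge", mp$d, NA)
  }

  # pi-pi: ring centroids, stacked or T-shaped
  pp <- criteria$pi_pi
  for (ra in A$rings) for (rb in B$rings) {
    d <- .dist(ra$centroid, rb$centroid)
    ang <- .offaxis(ra$normal, rb$normal)  # inter-normal angle in [0,90]
    if ((d <= pp$max_distance_parallel && ang <= pp$max_parallel_angle) ||
        (d <= pp$max_distance_tshaped && ang >= pp$min_tshaped_angle))
      add("pi_pi", d, ang)
  }

  # cation-pi: charged-group center over a ring face
  cp <- criteria$cation_pi
  for (dir in list(list(A$cation, B$rings), list(B$cation, A$rings))) {
    cat_pos <- dir[[1]]
    if (is.null(cat_pos)) next
    for (rg in dir[[2]]) {
      d <- .dist(cat_pos, rg$centroid)
      if (d > cp$max_distance) next
      ang <- .offaxis(rg$normal, cat_pos - rg$centroid)
      if (ang <= cp$max_offaxis_angle) add("cation_pi", d, ang)
    }
  }

  # CH-pi: aliphatic side-chain carbon over a ring face
  ch <- criteria$ch_pi
  for (dir in list(list(A$ch_carbons, B$rings), list(B$ch_carbons, A$rings))) {
    cc <- dir[[1]]
    if (!nrow(cc)) next
    for (rg in dir[[2]]) for (k in seq_len(nrow(cc))) {
      d <- .dist(cc[k, ], rg$centroid)
      if (d > ch$max_distance) next
      ang <- .offaxis(rg$normal, cc[k, ] - rg$centroid)
      if (ang <= ch$max_offaxis_angle) add("ch_pi", d, ang)
    }
  }

  # lone-pair-pi: side-chain O/N lone-pair carrier over a ring face
  lp <- criteria$lone_pair_pi
  for (dir in list(list(A$lp_atoms, B$rings), list(B$lp_atoms, A$rings))) {
    la <- dir[[1]]
    if (!nrow(la)) next
    for (rg in dir[[2]]) for (k in seq_len(nrow(la))) {
      d <- .dist(la[k, ], rg$centroid)
      if (d > lp$max_distance) next
      ang <- .offaxis(rg$normal, la[k, ] - rg$centroid)
      if (ang <= lp$max_offaxis_angle) add("lone_pair_pi", d, ang)
    }
  }

  # precedence: one bridge per pair where classes overlap chemically
  if (!is.null(hits$salt_bridge)) hits$hydrogen_bond <- NULL
  if (!is.null(hits$pi_pi)) { hits$ch_pi <- NULL; hits$lone_pair_pi <- NULL }
  if (!is.null(hits$cation_pi)) hits$ch_pi <- NULL
  if (!length(hits)) return(NULL)

  etab <- criteria$energy
  do.call(rbind, lapply(names(hits), function(t) {
    data.frame(chain_a = A$chain, res_a = A$resno, name_a = A$resid,
               chain_b = B$chain, res_b = B$resno, name_b = B$resid,
               type = t, distance = hits[[t]]$d,
               key_angle = as.numeric(hits[[t]]$ang),
               energy_equiv = as.numeric(etab[[t]] %||% 1),
               stringsAsFactors = FALSE)
  }))
}
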