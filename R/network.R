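#' Build the thermoring mesh network from an interaction set
#'
#' The network has one node per \emph{engaged} residue (a residue taking
#' part in at least one intra-pathway interaction). Consecutive engaged
#' residues are joined by \emph{sequence edges} whose integer weight is the
#' number of intervening \emph{free} (silent) residues — residues engaged
#' in no interaction — counted from author numbering, so unmodeled gaps
#' count as free by default. Every interaction contributes a zero-weight
#' \emph{interaction edge}. Grid sizes are then round-path weights in this
#' graph.
#'
#' @param iset an \code{interaction_set} (intersubunit records are
#'   ignored; interactions naming residues outside the selection are
#'   excluded with a warning).
#' @param selection the \code{pathway_selection} the set was detected on;
#'   defaults to the selection attached to \code{iset}.
#' @param count_gaps_as_free if \code{FALSE}, unmodeled residue numbers
#'   (selection gaps) do not contribute to sequence-edge weights.
#' @return An object of class \code{thermoring_network}: list with
#'   \code{nodes} (sorted engaged residue numbers) and \code{edges}
#'   (data frame: \code{id, from, to, weight, type, itype, energy_equiv}).
#' @examples
#' net <- grid12_fixture()$network
#' net
#' @export
build_network <- function(iset, selection = NULL, count_gaps_as_free = TRUE) {
  stopifnot(inherits(iset, "interaction_set"))
  if (is.null(selection)) selection <- attr(iset, "pathway")
  ii <- iset[!iset$intersubunit, , drop = FALSE]
  if (!nrow(ii)) stop("empty interaction set: no network to build")
  if (!is.null(selection)) {
    inside <- ii$res_a >= selection$start & ii$res_a <= selection$end &
              ii$res_b >= selection$start & ii$res_b <= selection$end
    if (any(!inside)) {
      warning(sum(!inside), " interaction(s) outside the pathway selection",
              " excluded")
      ii <- ii[inside, , drop = FALSE]
      if (!nrow(ii)) stop("no interactions left inside the selection")
    }
  }
  nodes <- sort(unique(c(ii$res_a, ii$res_b)))
  gaps <- if (!count_gaps_as_free && !is.null(selection))
    selection$gaps else integer()
  seq_e <- NULL
  if (length(nodes) > 1) {
    a <- nodes[-length(nodes)]; b <- nodes[-1]
    w <- b - a - 1L
    if (length(gaps)) {
      w <- w - vapply(seq_along(a), function(k)
        sum(gaps > a[k] & gaps < b[k]), integer(1))
    }
    seq_e <- data.frame(from = a, to = b, weight = as.integer(w),
                        type = "sequence", itype = NA_character_,
                        energy_equiv = NA_real_, stringsAsFactors = FALSE)
  }
  int_e <- data.frame(from = pmin(ii$res_a, ii$res_b),
                      to = pmax(ii$res_a, ii$res_b),
                      weight = 0L, type = "interaction",
                      itype = ii$type, energy_equiv = ii$energy_equiv,
                      stringsAsFactors = FALSE)
  edges <- rbind(seq_e, int_e)
  edges <- edges[order(edges$from, edges$to, edges$type, edges$itype), ,
                 drop = FALSE]
  edges$id <- seq_len(nrow(edges))
  rownames(edges) <- NULL
  thermoring_network(nodes, edges)
}

#' Construct a thermoring network from explicit nodes and edges
#'
#' Low-level constructor, used by \code{\link{build_network}} and by the
#' fixture generators; also handy for abstract test graphs. Edge weights
#' must be non-negative integers; interaction edges must have weight 0.
#'
#' @param nodes integer vector of residue numbers.
#' @param edges data frame with columns \code{from, to, weight, type}
#'   (\code{"sequence"} or \code{"interaction"}) and optionally
#'   \code{itype, energy_equiv}.
#' @return A \code{thermoring_network}.
#' @export
thermoring_network <- function(nodes, edges) {
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "weight", "type") %in% names(edges)))
  nodes <- sort(unique(as.integer(nodes)))
  if (!all(edges$from %in% nodes & edges$to %in% nodes))
    stop("edge endpoints must be network nodes")
  if (any(edges$weight < 0) || any(edges$weight != floor(edges$weight)))
    stop("edge weights must be non-negative integers")
  if (any(edges$type == "interaction" & edges$weight != 0))
    stop("interaction edges must have weight 0")
  if (is.null(edges$itype)) edges$itype <- NA_character_
  if (is.null(edges$energy_equiv))
    edges$energy_equiv <- ifelse(edges$type == "interaction", 1, NA_real_)
  edges$id <- seq_len(nrow(edges))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "thermoring_network")
}

#' @export
print.thermoring_network <- function(x, ...) {
  ni <- sum(x$edges$type == "interaction")
  cat(sprintf(paste0("Thermoring network: %d engaged residues, ",
                     "%d interaction edge(s), %d sequence edge(s)\n"),
              length(x$nodes), ni, nrow(x$edges) - ni))
  invisible(x)
}

.net_igraph <- function(net, drop_id = NULL) {
  e <- net$edges
  if (!is.null(drop_id)) e <- e[e$id != drop_id, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from), to = as.character(e$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes)))
  igraph::E(g)$weight <- e$weight
  igraph::E(g)$eid <- e$id
  g
}

#' Grid size controlled through one interaction edge
#'
#' The grid size of an interaction edge is the weight (free-residue count)
#' of the shortest round path (simple cycle) through that edge: the
#' shortest-path weight between its endpoints once the edge itself is
#' removed. If removing the edge disconnects its endpoints there is no
#' round path and \code{NA} is returned (acyclic marker).
#'
#' @param net a \code{thermoring_network}.
#' @param edge an edge id (row of \code{net$edges}) or a length-2 (or 3,
#'   with the interaction type) vector \code{c(from, to)} identifying an
#'   interaction edge.
#' @return Integer grid size, or \code{NA} if the edge lies on no cycle.
#' @examples
#' fx <- grid12_fixture()
#' grid_size_of_edge(fx$network, c(369, 469))
#' @export
grid_size_of_edge <- function(net, edge) {
  stopifnot(inherits(net, "thermoring_network"))
  id <- .resolve_edge(net, edge)
  .grid_size_cached(net, .net_igraph(net), id)
}

# shortest round path through edge `id`, reusing a prebuilt graph
.grid_size_cached <- function(net, g, id) {
  e <- net$edges[net$edges$id == id, ]
  gk <- igraph::delete_edges(g, which(igraph::E(g)$eid == id))
  d <- igraph::distances(gk, v = as.character(e$from),
                         to = as.character(e$to),
                         weights = igraph::E(gk)$weight)[1, 1]
  if (!is.finite(d)) return(NA_integer_)
  as.integer(d + e$weight)
}

.resolve_edge <- function(net, edge) {
  e <- net$edges
  if (length(edge) == 1 && edge %in% e$id) return(as.integer(edge))
  if (length(edge) >= 2) {
    lo <- min(edge[1:2]); hi <- max(edge[1:2])
    hit <- which(e$from == lo & e$to == hi & e$type == "interaction")
    if (length(edge) >= 3) hit <- hit[e$itype[hit] == edge[3]]
    if (length(hit) == 1) return(e$id[hit])
    if (length(hit) > 1)
      stop("ambiguous edge ", lo, "-", hi, ": give the interaction type")
  }
  stop("edge not found in network")
}

#' Enumerate the grids (minimum-weight cycle basis) of a network
#'
#' The mesh network's grids are taken as a minimum-weight cycle basis:
#' the set of independent round paths of smallest total free-residue
#' weight, with cycle count equal to
#' \code{edges - nodes + connected components}. Each basis cycle is one
#' grid; its size is the sum of sequence-edge weights along the cycle, and
#' the interactions it controls are its least-stable member interaction
#' edges (lowest energy equivalent; ties reported together). Candidate
#' cycles come from shortest round paths (Horton set plus per-edge shortest
#' cycles plus spanning-tree fundamental cycles) and are selected greedily
#' under GF(2) independence, ties broken by lexicographically smallest node
#' sequence.
#'
#' @param net a \code{thermoring_network}.
#' @return A list of grids, each a list with \code{label}, \code{size_s},
#'   \code{cycle} (ordered node sequence), \code{edge_ids} and
#'   \code{controlled} (data frame of least-stable interaction edges).
#'   Empty list for an acyclic network.
#' @export
enumerate_grids <- function(net) {
  stopifnot(inherits(net, "thermoring_network"))
  cys <- .mcb(net)
  .grids_from_cycles(net, cys)
}

.grids_from_cycles <- function(net, cys) {
  if (!length(cys)) return(list())
  e <- net$edges
  grids <- lapply(cys, function(eids) {
    sz <- sum(e$weight[match(eids, e$id)])
    list(size_s = as.integer(sz),
         cycle = .cycle_node_seq(net, eids),
         edge_ids = sort(eids))
  })
  ord <- order(-vapply(grids, `[[`, integer(1), "size_s"),
               vapply(grids, function(g) paste(g$cycle, collapse = ","),
                      character(1)))
  grids <- grids[ord]
  lab <- character(length(grids))
  seen <- integer()
  for (i in seq_along(grids)) {
    s <- grids[[i]]$size_s
    k <- sum(vapply(grids[seq_len(i - 1)], `[[`, integer(1), "size_s") == s)
    lab[i] <- paste0("Grid_", s, strrep("'", k))
  }
  for (i in seq_along(grids)) {
    grids[[i]]$label <- lab[i]
    ie <- e[e$id %in% grids[[i]]$edge_ids & e$type == "interaction", ,
            drop = FALSE]
    if (nrow(ie)) {
      ie <- ie[ie$energy_equiv == min(ie$energy_equiv), , drop = FALSE]
    }
    grids[[i]]$controlled <- ie
  }
  grids
}

# ordered node sequence of a simple cycle, starting at the smallest node,
# heading toward its smaller incident neighbour (reversal-canonical)
.cycle_node_seq <- function(net, eids) {
  e <- net$edges[match(eids, net$edges$id), , drop = FALSE]
  if (nrow(e) == 2 && e$from[1] == e$from[2] && e$to[1] == e$to[2])
    return(c(e$from[1], e$to[1]))
  adj <- list()
  for (k in seq_len(nrow(e))) {
    f <- as.character(e$from[k]); t <- as.character(e$to[k])
    adj[[f]] <- c(adj[[f]], e$to[k]); adj[[t]] <- c(adj[[t]], e$from[k])
  }
  start <- min(c(e$from, e$to))
  path <- c(start, min(adj[[as.character(start)]]))
  repeat {
    cur <- path[length(path)]; prev <- path[length(path) - 1]
    nbrs <- adj[[as.character(cur)]]
    nxt <- nbrs[nbrs != prev][1]
    if (nxt == start) break
    path <- c(path, nxt)
  }
  path
}

# ---- minimum-weight cycle basis -------------------------------------------

# candidate cycles as edge-id sets; Horton set + fundamental cycles +
# per-edge shortest cycles
.mcb_candidates <- function(net) {
  e <- net$edges
  g <- .net_igraph(net)
  vnames <- igraph::V(g)$name
  gw <- igraph::E(g)$weight
  gid <- igraph::E(g)$eid
  # endpoint lookup tables indexed by edge id, for the fast simplicity check
  efrom <- e$from[order(e$id)]
  eto <- e$to[order(e$id)]
  nmax <- max(net$nodes)
  cands <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  push <- function(eids) {
    if (is.null(eids) || length(eids) < 2) return(invisible(NULL))
    eids <- sort.int(unique(eids))
    key <- paste(eids, collapse = ",")
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    vs <- c(efrom[eids], eto[eids])
    cnt <- tabulate(vs, nbins = nmax)
    if (all(cnt[vs] == 2L) && sum(cnt == 2L) == length(eids))
      cands[[length(cands) + 1L]] <<- eids
    invisible(NULL)
  }
  # per-edge shortest cycle (shortest round path through each edge)
  for (k in seq_len(nrow(e))) {
    keep <- gid != e$id[k]
    gk <- igraph::subgraph_from_edges(g, which(keep),
                                      delete.vertices = FALSE)
    kid <- gid[keep]
    sp <- suppressWarnings(igraph::shortest_paths(
      gk, from = as.character(e$from[k]), to = as.character(e$to[k]),
      weights = gw[keep], output = "epath"))$epath[[1]]
    if (length(sp))
      push(c(kid[as.integer(sp)], e$id[k]))
  }
  # Horton set: SP(v,x) + (x,y) + SP(y,v)
  for (v in vnames) {
    sp <- suppressWarnings(igraph::shortest_paths(
      g, from = v, to = vnames, weights = gw, output = "epath"))$epath
    pathids <- lapply(sp, function(p) gid[as.integer(p)])
    names(pathids) <- vnames
    for (k in seq_len(nrow(e))) {
      push(c(pathids[[as.character(e$from[k])]],
             pathids[[as.character(e$to[k])]], e$id[k]))
    }
  }
  # fundamental cycles of a minimum spanning tree (rank guarantee)
  mst <- igraph::mst(g, weights = gw)
  tree_ids <- igraph::E(mst)$eid
  mw <- igraph::E(mst)$weight
  for (k in setdiff(e$id, tree_ids)) {
    ek <- e[e$id == k, ]
    tp <- suppressWarnings(igraph::shortest_paths(
      mst, from = as.character(ek$from), to = as.character(ek$to),
      weights = mw, output = "epath"))$epath[[1]]
    push(c(tree_ids[as.integer(tp)], k))
  }
  cands
}

# greedy GF(2) selection of an independent minimum-weight set
.mcb <- function(net) {
  e <- net$edges
  g <- .net_igraph(net)
  dim <- nrow(e) - length(net$nodes) + igraph::components(g)$no
  if (dim <= 0) return(list())
  cands <- .mcb_candidates(net)
  w <- vapply(cands, function(ids) sum(e$weight[match(ids, e$id)]), numeric(1))
  lex <- vapply(cands, function(ids)
    paste(sprintf("%06d", .cycle_node_seq(net, ids)), collapse = ","),
    character(1))
  ord <- order(w, lengths(cands), lex)
  cands <- cands[ord]
  pivots <- list()  # reduced rows, each a sorted integer edge-id set
  basis <- list()
  for (cy in cands) {
    r <- cy
    for (p in pivots) {
      if (min(p) %in% r) r <- sort(.sym_diff(r, p))
      if (!length(r)) break
    }
    if (length(r)) {
      pivots[[length(pivots) + 1L]] <- r
      pivots <- pivots[order(vapply(pivots, min, numeric(1)))]
      basis[[length(basis) + 1L]] <- cy
      if (length(basis) == dim) break
    }
  }
  if (length(basis) < dim)
    stop("internal error: cycle-basis candidates do not span the cycle space")
  basis
}

.sym_diff <- function(a, b) c(setdiff(a, b), setdiff(b, a))

.edge_keys <- function(ie) {
  if (!nrow(ie)) return(character())
  paste0(ie$from, "-", ie$to, ":", ie$itype)
}

#' Summarize a thermoring network
#'
#' Computes the state-level totals of a network: N (number of interaction
#' edges), S (total grid sizes over the minimum-weight cycle basis),
#' systematic thermal instability Ti = S/N, the biggest grid together with
#' the least-stable interaction(s) it controls, and the smallest
#' (zero-size) grids.
#'
#' @param net a \code{thermoring_network}.
#' @return A list of class \code{network_summary} with elements \code{N},
#'   \code{S}, \code{T_i}, \code{grids}, \code{biggest},
#'   \code{smallest_grids} and \code{per_edge_sizes} (named by
#'   \code{from-to:type} for every interaction edge).
#' @examples
#' summarize_network(grid12_fixture()$network)
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "thermoring_network"))
  grids <- enumerate_grids(net)
  ie <- net$edges[net$edges$type == "interaction", , drop = FALSE]
  N <- nrow(ie)
  S <- if (length(grids))
    sum(vapply(grids, `[[`, integer(1), "size_s")) else 0L
  g <- .net_igraph(net)
  pes <- vapply(seq_len(nrow(ie)), function(k)
    .grid_size_cached(net, g, ie$id[k]), integer(1))
  names(pes) <- .edge_keys(ie)
  # each interaction edge is controlled by the smallest basis grid holding it
  ctrl <- vapply(seq_len(nrow(ie)), function(k) {
    holds <- Filter(function(g) ie$id[k] %in% g$edge_ids, grids)
    if (!length(holds)) return(NA_character_)
    holds[[which.min(vapply(holds, `[[`, integer(1), "size_s"))]]$label
  }, character(1))
  names(ctrl) <- names(pes)
  biggest <- if (length(grids)) grids[[1]] else NULL
  structure(list(
    N = N, S = as.integer(S),
    T_i = if (N > 0) S / N else NA_real_,
    grids = grids,
    biggest = biggest,
    smallest_grids = Filter(function(g) g$size_s == 0L, grids),
    per_edge_sizes = pes,
    controlling_grid = ctrl
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Network summary: N = %d, S = %d, Ti = %.2f\n",
              x$N, x$S, x$T_i))
  if (!is.null(x$biggest)) {
    cat(sprintf("  biggest grid: %s (s = %d), cycle %s\n",
                x$biggest$label, x$biggest$size_s,
                paste(x$biggest$cycle, collapse = "-")))
    if (nrow(x$biggest$controlled))
      cat("  controls:",
          paste(sprintf("%d-%d (%s)", x$biggest$controlled$from,
                        x$biggest$controlled$to, x$biggest$controlled$itype),
                collapse = ", "), "\n")
  }
  cat(sprintf("  %d grid(s), %d of size 0\n",
              length(x$grids), length(x$smallest_grids)))
  invisible(x)
}

#' Exhaustive brute-force oracle for grid sizes
#'
#' Enumerates every simple cycle of the network by depth-first search and
#' derives (a) the exact per-interaction-edge minimum round-path weight and
#' (b) the exact minimum cycle-basis weight by greedy GF(2) selection over
#' the complete cycle list. Exponential in the worst case, so refused above
#' \code{max_interaction_edges}; intended as an independent verification
#' path for the fast shortest-path/Horton machinery on small networks.
#'
#' @param net a \code{thermoring_network}.
#' @param max_interaction_edges size guard (default 15).
#' @return List with \code{per_edge_sizes} (named integer vector, NA where
#'   an edge lies on no cycle), \code{S} (minimal basis weight) and
#'   \code{n_cycles} (number of simple cycles found).
#' @export
brute_force_grid_oracle <- function(net, max_interaction_edges = 15) {
  stopifnot(inherits(net, "thermoring_network"))
  ni <- sum(net$edges$type == "interaction")
  if (ni > max_interaction_edges)
    stop("refusing brute force: ", ni, " interaction edges > guard of ",
         max_interaction_edges)
  cys <- .all_simple_cycles(net)
  e <- net$edges
  ie <- e[e$type == "interaction", , drop = FALSE]
  wts <- vapply(cys, function(ids) sum(e$weight[match(ids, e$id)]), numeric(1))
  pes <- vapply(ie$id, function(id) {
    hit <- vapply(cys, function(ids) id %in% ids, logical(1))
    if (!any(hit)) NA_integer_ else as.integer(min(wts[hit]))
  }, integer(1))
  names(pes) <- .edge_keys(ie)
  # exact minimum basis: greedy over the full cycle list
  g <- .net_igraph(net)
  dim <- nrow(e) - length(net$nodes) + igraph::components(g)$no
  S <- 0L
  if (dim > 0) {
    ord <- order(wts, lengths(cys))
    pivots <- list(); picked <- 0L
    for (k in ord) {
      r <- cys[[k]]
      for (p in pivots) {
        if (min(p) %in% r) r <- sort(.sym_diff(r, p))
        if (!length(r)) break
      }
      if (length(r)) {
        pivots[[length(pivots) + 1L]] <- r
        pivots <- pivots[order(vapply(pivots, min, numeric(1)))]
        S <- S + as.integer(wts[k]); picked <- picked + 1L
        if (picked == dim) break
      }
    }
  }
  list(per_edge_sizes = pes, S = S, n_cycles = length(cys))
}

# all simple cycles of the undirected multigraph, as edge-id sets
.all_simple_cycles <- function(net) {
  e <- net$edges
  nodes <- net$nodes
  nmap <- seq_along(nodes); names(nmap) <- as.character(nodes)
  adj <- vector("list", length(nodes))
  for (k in seq_len(nrow(e))) {
    fi <- nmap[[as.character(e$from[k])]]
    ti <- nmap[[as.character(e$to[k])]]
    adj[[fi]] <- rbind(adj[[fi]], c(e$id[k], ti))
    adj[[ti]] <- rbind(adj[[ti]], c(e$id[k], fi))
  }
  out <- list()
  # paths restricted to vertices >= start; dedupe direction by first-vs-last
  # edge id at the anchor
  dfs <- function(start, cur, used_v, used_e, first_eid) {
    for (r in seq_len(nrow(adj[[cur]] %||% matrix(0, 0, 2)))) {
      eid <- adj[[cur]][r, 1]; nb <- adj[[cur]][r, 2]
      if (eid %in% used_e) next
      if (nb == start) {
        if (length(used_e) >= 1 && eid > first_eid)
          out[[length(out) + 1L]] <<- sort(c(used_e, eid))
        next
      }
      if (nb < start || nb %in% used_v) next
      dfs(start, nb, c(used_v, nb), c(used_e, eid), first_eid)
    }
  }
  for (s in seq_along(nodes)) {
    rows <- adj[[s]]
    if (is.null(rows)) next
    for (r in seq_len(nrow(rows))) {
      eid <- rows[r, 1]; nb <- rows[r, 2]
      if (nb <= s) next
      dfs(s, nb, c(s, nb), eid, eid)
    }
  }
  unique(out)
}

#' Export a network as an edge-list text file
#'
#' Writes nodes (residue numbers) and typed, weighted edges in a simple
#' tab-separated graph-exchange layout re-importable with
#' \code{\link{import_network}}.
#'
#' @param net a \code{thermoring_network}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path) {
  stopifnot(inherits(net, "thermoring_network"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# thermoring network v1", con)
  writeLines(paste0("nodes\t", paste(net$nodes, collapse = ",")), con)
  writeLines("from\tto\tweight\ttype\titype\tenergy_equiv", con)
  e <- net$edges
  writeLines(sprintf("%d\t%d\t%d\t%s\t%s\t%s", e$from, e$to, e$weight,
                     e$type, ifelse(is.na(e$itype), ".", e$itype),
                     ifelse(is.na(e$energy_equiv), ".",
                            format(e$energy_equiv))), con)
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln)]
  nodes <- as.integer(strsplit(sub("^nodes\t", "", ln[1]), ",")[[1]])
  tab <- utils::read.table(text = ln[-1], sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = ".")
  thermoring_network(nodes, tab)
}
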