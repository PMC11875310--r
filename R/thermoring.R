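#' Fit the thermoring model of a gating state
#'
#' The central estimator of the package. Given detected noncovalent
#' interactions along a gating pathway (or a structure to detect them in),
#' it builds the grid-like mesh network, enumerates its grids
#' (minimum-weight cycle basis), and evaluates the state-level
#' thermodynamic quantities: total interactions N, total grid sizes S,
#' systematic thermal instability Ti = S/N, and the melting temperature
#' threshold Tm of the biggest grid's least-stable bridge(s).
#'
#' \code{thermoring} is generic: pass an \code{interaction_set}, a
#' \code{pathway_selection}, a \code{structure_model}, or a file path (the
#' structure is then loaded, the pathway selected and interactions
#' detected with the given criteria).
#'
#' @param x input object (see Details).
#' @param ... passed on between methods.
#' @param selection the \code{pathway_selection} (for the
#'   \code{interaction_set} method; defaults to the one attached to the
#'   set).
#' @param energy_overrides per-pair/per-grid basic-H-bond overrides, as in
#'   \code{\link{assign_energy_equivalents}}.
#' @param n_override optional direct override for the biggest grid's n
#'   (Table-style inputs print n directly).
#' @param E energy per noncovalent interaction, kcal/mol (default 1).
#' @param count_gaps_as_free count unmodeled residues as free (default
#'   \code{TRUE}).
#' @param chain_id,start,end pathway bounds (structure/path methods).
#' @param criteria geometric criteria (structure/path methods).
#' @param include_backbone admit backbone H-bond atoms (default
#'   \code{FALSE}).
#' @return An object of class \code{thermoring}: list with
#'   \code{interactions}, \code{network}, \code{summary}
#'   (a \code{network_summary}), \code{N}, \code{S}, \code{T_i},
#'   \code{biggest} (label, size s, n, Tm, controlled bridges),
#'   \code{E} and \code{call}. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{plot}.
#' @examples
#' fx <- grid12_fixture()
#' fit <- thermoring(fx$network)
#' coef(fit)
#' @export
thermoring <- function(x, ...) UseMethod("thermoring")

#' @rdname thermoring
#' @export
thermoring.interaction_set <- function(x, selection = NULL,
                                       energy_overrides = NULL,
                                       n_override = NULL, E = 1,
                                       count_gaps_as_free = TRUE, ...) {
  if (!is.null(energy_overrides))
    x <- assign_energy_equivalents(x, energy_overrides)
  net <- build_network(x, selection = selection,
                       count_gaps_as_free = count_gaps_as_free)
  .fit_thermoring(x, net, n_override = n_override, E = E,
                  call = sys.call(-1))
}

#' @rdname thermoring
#' @export
thermoring.thermoring_network <- function(x, n_override = NULL, E = 1, ...) {
  .fit_thermoring(NULL, x, n_override = n_override, E = E,
                  call = sys.call(-1))
}

#' @rdname thermoring
#' @export
thermoring.pathway_selection <- function(x, criteria = default_criteria(),
                                         include_backbone = FALSE, ...) {
  iset <- detect_interactions(x, criteria, include_backbone)
  thermoring.interaction_set(iset, selection = x, ...)
}

#' @rdname thermoring
#' @export
thermoring.structure_model <- function(x, chain_id = NULL, start, end,
                                       criteria = default_criteria(),
                                       include_backbone = FALSE, ...) {
  sel <- select_pathway(x, chain_id, start, end)
  thermoring.pathway_selection(sel, criteria = criteria,
                               include_backbone = include_backbone, ...)
}

#' @rdname thermoring
#' @export
thermoring.character <- function(x, chain_id = NULL, start, end,
                                 criteria = default_criteria(), ...) {
  thermoring.structure_model(load_structure(x), chain_id = chain_id,
                             start = start, end = end,
                             criteria = criteria, ...)
}

.fit_thermoring <- function(iset, net, n_override = NULL, E = 1, call = NULL) {
  smry <- summarize_network(net)
  biggest <- NULL
  if (!is.null(smry$biggest)) {
    b <- smry$biggest
    n <- if (!is.null(n_override)) n_override
         else if (nrow(b$controlled)) sum(b$controlled$energy_equiv)
         else NA_real_
    biggest <- list(label = b$label, s = b$size_s, n = n,
                    T_m = if (is.na(n)) NA_real_
                          else melting_threshold(n, b$size_s),
                    cycle = b$cycle, controlled = b$controlled)
  }
  structure(list(interactions = iset, network = net, summary = smry,
                 N = smry$N, S = smry$S, T_i = smry$T_i,
                 biggest = biggest, E = E, call = call),
            class = "thermoring")
}

#' @export
print.thermoring <- function(x, ...) {
  cat("Thermoring model\n")
  cat(sprintf("  N (interactions)        : %d\n", x$N))
  cat(sprintf("  S (total grid sizes)    : %d\n", x$S))
  cat(sprintf("  Ti (instability, S/N)   : %.2f\n", x$T_i))
  if (!is.null(x$biggest)) {
    cat(sprintf("  biggest grid            : %s (s = %d, n = %s)\n",
                x$biggest$label, x$biggest$s,
                format(x$biggest$n)))
    cat(sprintf("  Tm of controlled bridge : %s degC\n",
                format(x$biggest$T_m)))
  }
  invisible(x)
}

#' @export
summary.thermoring <- function(object, ...) {
  print(object)
  g <- object$summary$grids
  if (length(g)) {
    cat("\nGrids (minimum-weight cycle basis):\n")
    for (gr in g) {
      ctl <- if (nrow(gr$controlled))
        paste(sprintf("%d-%d(%s)", gr$controlled$from, gr$controlled$to,
                      gr$controlled$itype), collapse = ",")
        else "-"
      cat(sprintf("  %-10s s=%-3d cycle=%s controls %s\n", gr$label,
                  gr$size_s, paste(gr$cycle, collapse = "-"), ctl))
    }
  }
  invisible(object)
}

#' @export
coef.thermoring <- function(object, ...) {
  c(N = object$N, S = object$S, T_i = object$T_i,
    s = if (is.null(object$biggest)) NA_real_ else object$biggest$s,
    n = if (is.null(object$biggest)) NA_real_ else object$biggest$n,
    T_m = if (is.null(object$biggest)) NA_real_ else object$biggest$T_m)
}

#' @export
plot.thermoring <- function(x, ...) {
  net <- x$network
  g <- .net_igraph(net)
  ie <- net$edges$type == "interaction"
  igraph::plot.igraph(
    g, layout = igraph::layout_in_circle(g),
    edge.color = ifelse(ie, "firebrick", "grey60"),
    edge.width = ifelse(ie, 2, 1),
    edge.label = ifelse(net$edges$weight > 0, net$edges$weight, NA),
    vertex.size = 8, vertex.color = "lightsteelblue",
    vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Compare two gating states: the thermoring transition model
#'
#' Evaluates the transition thermodynamics between an initial state
#' (closed or partially open) and a final state (open): grid-size and
#' interaction-count changes, structural thermosensitivity Omega10, and
#' (optionally) the activation enthalpy from per-subunit bookkeeping and a
#' functional Q10 from supplied activities.
#'
#' States may be \code{thermoring} fits or bare named vectors/lists with
#' elements \code{N} and \code{S} (printed state tables are valid input).
#'
#' @param from,to the initial and final states.
#' @param E energy per interaction, kcal/mol (default 1).
#' @param broken_inter intersubunit interactions disrupted per subunit
#'   (optional enthalpy bookkeeping).
#' @param formed new interactions formed per subunit.
#' @param subunits assembly size (default 4).
#' @param X1,X2,T1,T2 optional activities and Kelvin temperatures for a
#'   matched functional Q10.
#' @return An object of class \code{thermoring_transition}: list with
#'   \code{N_c, N_o, S_c, S_o, delta_N, delta_S, omega_10, delta_H, q_10}.
#' @examples
#' tr <- thermoring_transition(c(N = 67, S = 99), c(N = 35, S = 71))
#' tr$omega_10
#' @export
thermoring_transition <- function(from, to, E = 1, broken_inter = 0,
                                  formed = 0, subunits = 4,
                                  X1 = NULL, X2 = NULL, T1 = NULL, T2 = NULL) {
  st <- function(s) {
    if (inherits(s, "thermoring")) list(N = s$N, S = s$S)
    else if (all(c("N", "S") %in% names(s))) list(N = as.numeric(s[["N"]]),
                                                  S = as.numeric(s[["S"]]))
    else stop("state must be a thermoring fit or carry N and S")
  }
  a <- st(from); b <- st(to)
  omega <- structural_thermosensitivity(a$S, b$S, a$N, b$N, E)
  dH <- activation_enthalpy(broken_intra = max(0, a$N - b$N),
                            broken_inter = broken_inter, formed = formed,
                            subunits = subunits, E = E)
  q10 <- if (!is.null(X1) && !is.null(X2) && !is.null(T1) && !is.null(T2))
    functional_q10(X1, X2, T1, T2) else NA_real_
  structure(list(N_c = a$N, S_c = a$S, N_o = b$N, S_o = b$S,
                 delta_N = a$N - b$N, delta_S = a$S - b$S,
                 omega_10 = omega, delta_H = dH, q_10 = q10, E = E,
                 subunits = subunits),
            class = "thermoring_transition")
}

#' @export
print.thermoring_transition <- function(x, ...) {
  cat("Thermoring gating transition\n")
  cat(sprintf("  N: %g -> %g (delta %g)   S: %g -> %g (delta %g)\n",
              x$N_c, x$N_o, x$delta_N, x$S_c, x$S_o, x$delta_S))
  cat(sprintf("  Omega10 (structural)   : %.4g\n", x$omega_10))
  cat(sprintf("  deltaH (x%d subunits)  : %g kcal/mol\n", x$subunits,
              x$delta_H))
  if (!is.na(x$q_10)) cat(sprintf("  Q10 (functional)       : %.4g\n", x$q_10))
  invisible(x)
}
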