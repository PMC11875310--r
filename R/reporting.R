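#' Analyze one gating state of a structure into a state report
#'
#' End-to-end driver: load (or accept) a structure, select the gating
#' pathway on one chain, detect intra-pathway and (for multi-chain
#' assemblies) intersubunit interactions, fit the thermoring model, and
#' assemble a versioned report suitable for JSON/TSV export.
#'
#' @param x a structure file path, \code{structure_model} or
#'   \code{thermoring} fit.
#' @param chain_id chain to analyze (default: first chain).
#' @param start,end pathway bounds (author residue numbers).
#' @param criteria a \code{geometric_criteria} list.
#' @param energy_overrides,n_override,E passed to \code{\link{thermoring}}.
#' @param include_backbone admit backbone H-bond atoms intra-pathway.
#' @param intersubunit also scan intersubunit contacts when the assembly
#'   has >= 2 chains (default \code{TRUE}).
#' @param structure_id identifier recorded in the report.
#' @return An object of class \code{state_report}: a list with
#'   \code{schema_version}, \code{structure_id}, \code{pathway},
#'   \code{N}, \code{S}, \code{T_i}, \code{grids}, \code{biggest},
#'   \code{smallest}, \code{intersubunit} and \code{provenance}.
#' @examples
#' m <- generate_structure_fixture(geometry_blueprint(seed = 1))
#' rep <- analyze_state(m, start = 1, end = max(m$atoms$resno))
#' rep$N
#' @export
analyze_state <- function(x, chain_id = NULL, start = NULL, end = NULL,
                          criteria = default_criteria(),
                          energy_overrides = NULL, n_override = NULL, E = 1,
                          include_backbone = FALSE, intersubunit = TRUE,
                          structure_id = NULL) {
  if (is.character(x)) x <- load_structure(x)
  inter <- .empty_interactions()
  if (inherits(x, "thermoring")) {
    fit <- x
    if (is.null(structure_id)) structure_id <- "unnamed"
    pathway <- c(NA_integer_, NA_integer_)
    chain_id <- NA_character_
  } else {
    stopifnot(inherits(x, "structure_model"))
    if (is.null(start) || is.null(end))
      stop("pathway start and end are required")
    if (is.null(chain_id)) chain_id <- x$chains[1]
    if (is.null(structure_id)) structure_id <- x$structure_id
    sel <- select_pathway(x, chain_id, start, end)
    fit <- thermoring(sel, criteria = criteria,
                      include_backbone = include_backbone,
                      energy_overrides = energy_overrides,
                      n_override = n_override, E = E)
    if (intersubunit && x$assembly_size >= 2) {
      inter <- detect_intersubunit(x, criteria, start = start, end = end)
    }
    pathway <- c(start, end)
  }
  grids <- lapply(fit$summary$grids, function(g)
    list(label = g$label, size = g$size_s,
         cycle = g$cycle,
         controls = if (nrow(g$controlled))
           sprintf("%d-%d:%s", g$controlled$from, g$controlled$to,
                   g$controlled$itype) else character()))
  structure(list(
    schema_version = "1",
    structure_id = structure_id,
    chain = chain_id,
    pathway = list(start = pathway[1], end = pathway[2]),
    N = fit$N, S = fit$S, T_i = fit$T_i,
    grids = grids,
    biggest = if (is.null(fit$biggest)) NULL else
      list(label = fit$biggest$label, s = fit$biggest$s,
           n = fit$biggest$n, T_m = fit$biggest$T_m,
           controls = if (nrow(fit$biggest$controlled))
             sprintf("%d-%d:%s", fit$biggest$controlled$from,
                     fit$biggest$controlled$to,
                     fit$biggest$controlled$itype) else character()),
    smallest = vapply(fit$summary$smallest_grids, `[[`, character(1),
                      "label"),
    intersubunit = as.data.frame(inter),
    provenance = list(package = "thermoring",
                      criteria = unclass(attr(fit$interactions, "criteria")
                                         %||% default_criteria()),
                      E = E)
  ), class = "state_report")
}

#' @export
print.state_report <- function(x, ...) {
  cat(sprintf("State report %s (chain %s, pathway %s-%s)\n",
              x$structure_id, x$chain, x$pathway$start, x$pathway$end))
  cat(sprintf("  N = %d, S = %d, Ti = %.2f\n", x$N, x$S, x$T_i))
  if (!is.null(x$biggest))
    cat(sprintf("  biggest %s: s = %d, n = %s, Tm = %s degC\n",
                x$biggest$label, x$biggest$s, format(x$biggest$n),
                format(x$biggest$T_m)))
  if (nrow(x$intersubunit))
    cat(sprintf("  %d intersubunit interaction(s)\n", nrow(x$intersubunit)))
  invisible(x)
}

#' Write / read a state report
#'
#' JSON output carries the full report (schema-versioned, round-trips
#' through \code{read_state_report}); TSV output is a flat per-grid table.
#'
#' @param report a \code{state_report}.
#' @param path output path (\code{.json} or \code{.tsv}).
#' @return \code{path} invisibly; \code{read_state_report} returns the
#'   reconstructed \code{state_report}.
#' @export
write_state_report <- function(report, path) {
  stopifnot(inherits(report, "state_report"))
  if (grepl("\\.tsv$", path)) {
    g <- report$grids
    d <- data.frame(label = vapply(g, `[[`, character(1), "label"),
                    size = vapply(g, `[[`, integer(1), "size"),
                    cycle = vapply(g, function(x)
                      paste(x$cycle, collapse = "-"), character(1)),
                    controls = vapply(g, function(x)
                      paste(x$controls, collapse = ","), character(1)))
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' @rdname write_state_report
#' @export
read_state_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  x$grids <- lapply(seq_len(nrow(x$grids)), function(i) as.list(x$grids[i, ]))
  x$smallest <- as.character(x$smallest %||% character())
  if (is.null(x$intersubunit) || !length(x$intersubunit))
    x$intersubunit <- .empty_interactions()
  structure(x, class = "state_report")
}

#' Compare two state reports into a transition report
#'
#' Renders the side-by-side state comparison and the transition
#' thermodynamics (Omega10, activation enthalpy, optional annotated
#' experimental Q10/threshold values). Both reports must share pathway
#' bounds.
#'
#' @param from,to \code{state_report}s for the initial and final state.
#' @param E energy per interaction (kcal/mol).
#' @param broken_inter,formed,subunits enthalpy bookkeeping (per subunit).
#' @param q10_measured,threshold_measured optional experimental
#'   annotations carried into the report.
#' @return An object of class \code{transition_report}.
#' @export
compare_states <- function(from, to, E = 1, broken_inter = 0, formed = 0,
                           subunits = 4, q10_measured = NULL,
                           threshold_measured = NULL) {
  stopifnot(inherits(from, "state_report"), inherits(to, "state_report"))
  same_bounds <- identical(as.integer(from$pathway$start),
                           as.integer(to$pathway$start)) &&
                 identical(as.integer(from$pathway$end),
                           as.integer(to$pathway$end))
  if (!same_bounds)
    stop("state reports have mismatched pathway bounds: ",
         from$pathway$start, "-", from$pathway$end, " vs ",
         to$pathway$start, "-", to$pathway$end)
  tr <- thermoring_transition(c(N = from$N, S = from$S),
                              c(N = to$N, S = to$S), E = E,
                              broken_inter = broken_inter, formed = formed,
                              subunits = subunits)
  structure(list(
    schema_version = "1",
    from_state = from$structure_id, to_state = to$structure_id,
    pathway = from$pathway,
    delta_N = tr$delta_N, delta_S = tr$delta_S,
    omega_10 = tr$omega_10, delta_H = tr$delta_H,
    q10_measured = q10_measured, threshold_measured = threshold_measured
  ), class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("Transition %s -> %s\n", x$from_state, x$to_state))
  cat(sprintf("  deltaN = %g, deltaS = %g\n", x$delta_N, x$delta_S))
  cat(sprintf("  Omega10 = %.4g, deltaH = %g kcal/mol\n",
              x$omega_10, x$delta_H))
  if (!is.null(x$q10_measured))
    cat(sprintf("  measured Q10 (annotation): %g\n", x$q10_measured))
  invisible(x)
}

#' State-table regression: recompute Ti, Tm and transitions from totals
#'
#' Takes a per-state table of printed totals — N (interactions), S (total
#' grid sizes), n (basic-H-bond equivalents of the biggest grid's
#' controlled bridges) and s (biggest grid size) — and recomputes Ti and
#' Tm per state, plus Omega10 for requested transitions. This runs the
#' thermodynamic model with no structure input, so published state tables
#' can be regression-checked directly.
#'
#' @param states data frame with columns \code{state, N, S, n, s}
#'   (\code{n} may be a slash-separated string like \code{"2/3"}: one Tm
#'   per alternative is reported).
#' @param transitions optional data frame with columns \code{from, to}
#'   naming state ids.
#' @param E energy per interaction (kcal/mol).
#' @return A list of class \code{table_report} with \code{states} (input
#'   plus \code{T_i} and \code{T_m} columns) and \code{transitions} (with
#'   \code{omega_10}). Row order of the input does not matter: outputs are
#'   keyed by state id.
#' @examples
#' tab <- data.frame(state = c("closed3", "open"), N = c(67, 35),
#'                   S = c(99, 71), n = c(2, 2.6), s = c(12, 12))
#' table1_report(tab, data.frame(from = "closed3", to = "open"))
#' @export
table1_report <- function(states, transitions = NULL, E = 1) {
  need <- c("state", "N", "S", "n", "s")
  miss <- setdiff(need, names(states))
  if (length(miss))
    stop("states table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(states$N) | !is.finite(states$S) |
                 !is.finite(states$s))
  if (length(bad))
    stop("malformed state row(s): ", paste(bad, collapse = ", "))
  states <- states[order(states$state), , drop = FALSE]
  states$T_i <- thermal_instability(states$N, states$S)
  states$T_m <- vapply(seq_len(nrow(states)), function(i) {
    ns <- suppressWarnings(as.numeric(strsplit(as.character(states$n[i]),
                                               "/")[[1]]))
    if (any(is.na(ns))) stop("malformed n in state row ", i)
    paste(melting_threshold(ns, states$s[i]), collapse = "/")
  }, character(1))
  out <- list(states = states, transitions = NULL, E = E)
  if (!is.null(transitions)) {
    idx <- function(id) {
      k <- which(states$state == id)
      if (length(k) != 1) stop("unknown state id in transitions: ", id)
      k
    }
    transitions$omega_10 <- vapply(seq_len(nrow(transitions)), function(i) {
      a <- idx(transitions$from[i]); b <- idx(transitions$to[i])
      structural_thermosensitivity(states$S[a], states$S[b],
                                   states$N[a], states$N[b], E)
    }, numeric(1))
    out$transitions <- transitions
  }
  structure(out, class = "table_report")
}

#' @export
print.table_report <- function(x, ...) {
  cat("State table (recomputed Ti, Tm):\n")
  print.data.frame(x$states, digits = 4, row.names = FALSE)
  if (!is.null(x$transitions)) {
    cat("\nTransitions (Omega10 at E =", x$E, "kcal/mol):\n")
    print.data.frame(x$transitions, digits = 4, row.names = FALSE)
  }
  invisible(x)
}
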