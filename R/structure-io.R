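#' Read an atomic structure from a PDB or mmCIF file
#'
#' Parses a coordinate file into a uniform \code{structure_model}: a flat
#' atom table carrying chain, author residue numbering, insertion codes,
#' residue and atom names, element symbols, coordinates and occupancies.
#' Author numbering (\code{auth_seq_id} in mmCIF) is used throughout, so
#' residues can be addressed exactly as cited in the structural literature
#' (e.g. F330, L719 of rTRPV2). Only the first model of multi-model files
#' is kept; for alternate locations the highest-occupancy copy is retained
#' (ties broken by first occurrence).
#'
#' @param path path to a coordinate file.
#' @param format \code{"auto"} (default, by file extension), \code{"pdb"}
#'   or \code{"mmcif"}.
#' @return An object of class \code{structure_model}: a list with
#'   \code{structure_id}, \code{atoms} (data frame), \code{chains}
#'   (character vector) and \code{assembly_size} (number of chains).
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_structure(generate_structure_fixture(geometry_blueprint(seed = 1)), pdb)
#' m <- load_structure(pdb)
#' m
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "mmcif") {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    } else {
      bio3d::read.pdb(path, verbose = FALSE, multi = FALSE, rm.alt = FALSE)
    },
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e))
  )
  at <- raw$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  # amino-acid residues only; ligands/waters are outside the pathway model
  at <- at[at$resid %in% names(.aa_three_to_one), , drop = FALSE]
  if (nrow(at) == 0) stop("no protein atoms found in '", path, "'")
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert) | at$insert == "", "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    elesy = toupper(trimws(as.character(at$elesy))),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    o = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", as.character(at$alt)),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in '", path, "'")
  atoms <- .collapse_altloc(atoms)
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(
    list(structure_id = sub("\\.(pdb|cif|ent)$", "", basename(path),
                            ignore.case = TRUE),
         atoms = atoms,
         chains = unique(atoms$chain),
         assembly_size = length(unique(atoms$chain))),
    class = "structure_model"
  )
}

# keep, per atom name within a residue, the highest-occupancy altloc
# (first encountered on ties)
.collapse_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$o, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                          atoms$elety, sep = "|")), , drop = FALSE]
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure model:", x$structure_id, "\n")
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "insert")]))
  cat(sprintf("  %d chain(s) [%s], %d residues, %d atoms\n",
              length(x$chains), paste(x$chains, collapse = ","),
              nres, nrow(x$atoms)))
  invisible(x)
}

#' Write a structure model to disk
#'
#' Writes the atom table back to a standard coordinate format. PDB output
#' goes through \code{bio3d::write.pdb}; mmCIF output is a minimal
#' \code{atom_site} loop (author numbering in \code{auth_seq_id}) readable
#' by standard mmCIF parsers.
#'
#' @param model a \code{structure_model}.
#' @param path output file path.
#' @param format \code{"pdb"} or \code{"mmcif"}.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (format == "pdb") {
    bio3d::write.pdb(pdb = NULL, file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     elety = a$elety, insert = a$insert,
                     o = a$o, b = rep(0, nrow(a)), elesy = a$elesy)
  } else {
    hdr <- c(
      paste0("data_", gsub("[^A-Za-z0-9_]", "_", model$structure_id)),
      "loop_",
      paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
        "label_atom_id", "label_alt_id", "label_comp_id", "label_asym_id",
        "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
        "Cartn_x", "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
        "auth_seq_id", "auth_comp_id", "auth_asym_id", "auth_atom_id",
        "pdbx_PDB_model_num")))
    ins <- ifelse(a$insert == "", "?", a$insert)
    rows <- sprintf("ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
                    seq_len(nrow(a)), a$elesy, a$elety, a$resid, a$chain,
                    a$resno, ins, a$x, a$y, a$z, a$o,
                    a$resno, a$resid, a$chain, a$elety)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Select the gating-pathway residue segment of one chain
#'
#' Restricts a structure model to the ordered residue range
#' \code{[start, end]} of one chain — e.g. the lipid-dependent gating
#' pathway F330–L719 of rTRPV2. Residue numbers inside the range that are
#' absent from the model (unmodeled/disordered segments such as a pore
#' turret) are recorded explicitly as gaps, never silently dropped; by
#' default they count as free residues when sequence-edge weights are
#' computed downstream.
#'
#' @param model a \code{structure_model}.
#' @param chain_id chain identifier; default: first chain of the model.
#' @param start,end first and last author residue numbers of the segment
#'   (\code{start < end}).
#' @return An object of class \code{pathway_selection}: list with
#'   \code{chain_id}, \code{start}, \code{end}, \code{residues} (data frame,
#'   ordered by residue number), \code{gaps} (integer vector of unmodeled
#'   residue numbers inside the range) and \code{atoms}.
#' @examples
#' m <- generate_structure_fixture(geometry_blueprint(seed = 1))
#' sel <- select_pathway(m, "A", 1, 10)
#' sel
#' @export
select_pathway <- function(model, chain_id = NULL, start, end) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(chain_id)) chain_id <- model$chains[1]
  if (!chain_id %in% model$chains)
    stop("chain '", chain_id, "' not present in model (chains: ",
         paste(model$chains, collapse = ","), ")")
  if (!(is.numeric(start) && is.numeric(end) && start < end))
    stop("need numeric start < end")
  a <- model$atoms
  a <- a[a$chain == chain_id & a$resno >= start & a$resno <= end, , drop = FALSE]
  if (nrow(a) == 0)
    stop("empty selection: chain ", chain_id, ", residues ", start, "-", end)
  res <- unique(a[, c("chain", "resno", "insert", "resid")])
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  rownames(res) <- NULL
  gaps <- setdiff(seq(from = start, to = end), res$resno)
  structure(
    list(chain_id = chain_id, start = as.integer(start), end = as.integer(end),
         residues = res, gaps = as.integer(gaps), atoms = a,
         structure_id = model$structure_id),
    class = "pathway_selection"
  )
}

#' @export
print.pathway_selection <- function(x, ...) {
  cat(sprintf("Pathway selection: chain %s, residues %d-%d\n",
              x$chain_id, x$start, x$end))
  cat(sprintf("  %d modeled residues, %d gap positions\n",
              nrow(x$residues), length(x$gaps)))
  if (length(x$gaps))
    cat("  gaps:", .compress_ranges(x$gaps), "\n")
  invisible(x)
}

.compress_ranges <- function(v) {
  if (!length(v)) return("")
  v <- sort(unique(v))
  brk <- c(0, which(diff(v) != 1), length(v))
  paste(vapply(seq_len(length(brk) - 1), function(i) {
    seg <- v[(brk[i] + 1):brk[i + 1]]
    if (length(seg) == 1) as.character(seg) else paste0(seg[1], "-", seg[length(seg)])
  }, character(1)), collapse = ",")
}

.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
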