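# shared fixture builders (everything generated in code; no stored data)

`%||%` <- function(a, b) if (is.null(a)) b else a

# network of disjoint chords: chord k spans sizes[k] free residues, so the
# minimum cycle basis is one cycle per chord and S = sum(sizes)
make_chord_network <- function(sizes) {
  a <- integer(length(sizes)); b <- integer(length(sizes))
  pos <- 1L
  for (k in seq_along(sizes)) {
    a[k] <- pos
    b[k] <- pos + sizes[k] + 1L
    pos <- b[k] + 2L
  }
  planted <- data.frame(res_a = a, res_b = b, type = "hydrogen_bond",
                        stringsAsFactors = FALSE)
  build_network(thermoring:::.planted_iset(planted))
}

# apply a seeded random proper rotation + translation to all coordinates
rigid_transform <- function(model, seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- runif(3, -20, 20)
  xyz <- t(R %*% t(as.matrix(model$atoms[, c("x", "y", "z")])))
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}

# a tiny hand-laid three-residue PDB, written to a temp file
write_three_residue_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1      12.919   6.898  -5.040  1.00  0.00           C",
    "ATOM      4  N   SER A   2      10.845   6.435  -2.861  1.00  0.00           N",
    "ATOM      5  CA  SER A   2       9.921   6.911  -1.825  1.00  0.00           C",
    "ATOM      6  OG  SER A   2       9.211   8.054  -2.294  1.00  0.00           O",
    "ATOM      7  N   GLY A   3       9.000   5.000  -1.000  1.00  0.00           N",
    "ATOM      8  CA  GLY A   3       8.000   4.500  -0.500  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

full_range_selection <- function(model, chain = "A") {
  select_pathway(model, chain, min(model$atoms$resno), max(model$atoms$resno))
}
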