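planted_set <- function(res_a, res_b, type = "hydrogen_bond") {
  thermoring:::.planted_iset(
    data.frame(res_a = res_a, res_b = res_b, type = type,
               stringsAsFactors = FALSE))
}

test_that("build_network derives nodes, sequence weights and edges", {
  net <- build_network(planted_set(c(1, 5, 1), c(5, 9, 9)))
  expect_equal(net$nodes, c(1L, 5L, 9L))
  se <- net$edges[net$edges$type == "sequence", ]
  expect_equal(se$weight, c(3L, 3L))
  expect_equal(sum(net$edges$type == "interaction"), 3)
  expect_error(build_network(thermoring:::.planted_iset(
    data.frame(res_a = integer(), res_b = integer(),
               type = character()))), "empty")
})

test_that("interactions outside the selection are excluded with a warning", {
  iset <- planted_set(c(2, 3), c(8, 40))
  sel <- list(chain_id = "A", start = 1L, end = 20L, gaps = integer())
  class(sel) <- "pathway_selection"
  expect_warning(net <- build_network(iset, selection = sel), "outside")
  expect_equal(sum(net$edges$type == "interaction"), 1)
})

test_that("unmodeled gaps count as free residues unless switched off", {
  iset <- planted_set(c(2), c(10))
  sel <- list(chain_id = "A", start = 1L, end = 12L, gaps = c(5L, 6L))
  class(sel) <- "pathway_selection"
  net_free <- build_network(iset, selection = sel)
  net_skip <- build_network(iset, selection = sel, count_gaps_as_free = FALSE)
  expect_equal(net_free$edges$weight[net_free$edges$type == "sequence"], 7L)
  expect_equal(net_skip$edges$weight[net_skip$edges$type == "sequence"], 5L)
})

test_that("the published 12-residue grid replica yields size 12", {
  fx <- grid12_fixture()
  expect_equal(grid_size_of_edge(fx$network, c(369, 469)), fx$expected_size)
  expect_equal(grid_size_of_edge(fx$network, c(362, 462)), 12L)
})

test_that("three consecutively adjacent all-interacting residues give size 0", {
  net <- build_network(planted_set(c(1, 2, 1), c(2, 3, 3)))
  ie <- net$edges[net$edges$type == "interaction", ]
  for (id in ie$id) expect_equal(grid_size_of_edge(net, id), 0L)
})

test_that("an edge on no cycle returns the acyclic marker", {
  net <- thermoring_network(
    c(1, 10), data.frame(from = 1, to = 10, weight = 0,
                         type = "interaction", itype = "pi_pi"))
  expect_true(is.na(grid_size_of_edge(net, 1)))
  s <- summarize_network(net)
  expect_equal(s$S, 0L)
  expect_equal(s$N, 1L)
  expect_length(s$grids, 0)
})

test_that("theta graph: minimal basis picks the two smallest round paths", {
  net <- thermoring_network(
    c(1, 2), data.frame(from = 1, to = 2, weight = c(2, 3, 9),
                        type = "sequence"))
  g <- enumerate_grids(net)
  expect_equal(sort(vapply(g, `[[`, integer(1), "size_s")), c(5L, 11L))
  o <- brute_force_grid_oracle(net)
  expect_equal(o$S, 16L)
})

test_that("two edge-disjoint planted cycles of sizes 4 and 7 sum to S = 11", {
  net <- make_chord_network(c(4, 7))
  g <- enumerate_grids(net)
  expect_equal(sort(vapply(g, `[[`, integer(1), "size_s")), c(4L, 7L))
  s <- summarize_network(net)
  expect_equal(s$S, 11L)
  expect_equal(s$S, brute_force_grid_oracle(net)$S)
})

test_that("a 12-interaction mesh with basis sizes summing 22 gives Ti 1.83", {
  net <- make_chord_network(c(0, 0, 0, 1, 1, 1, 2, 2, 3, 3, 4, 5))
  s <- summarize_network(net)
  expect_equal(s$N, 12L)
  expect_equal(s$S, 22L)
  expect_equal(round(s$T_i, 2), 1.83)
})

test_that("parallel interaction edges close a zero-size two-cycle grid", {
  iset <- thermoring:::.planted_iset(
    data.frame(res_a = c(4, 4), res_b = c(9, 9),
               type = c("pi_pi", "hydrogen_bond"), stringsAsFactors = FALSE))
  net <- build_network(iset)
  s <- summarize_network(net)
  expect_equal(s$N, 2L)
  # basis: the 0-size two-cycle of the parallel pair, plus the 4-residue
  # round path closing over the sequence edge
  expect_equal(s$S, 4L)
  expect_length(s$smallest_grids, 1)
  expect_equal(s$smallest_grids[[1]]$size_s, 0L)
  expect_equal(unname(s$per_edge_sizes), c(0L, 0L))
  expect_equal(s$S, brute_force_grid_oracle(net)$S)
})

test_that("fast per-edge sizes and S match the brute-force oracle", {
  set.seed(42)
  for (seed in 1:30) {
    k <- sample(3:12, 1)
    fx <- generate_network_fixture(seed = seed, n_residues = 60,
                                   n_interactions = k)
    s <- summarize_network(fx$network)
    o <- brute_force_grid_oracle(fx$network)
    expect_identical(s$per_edge_sizes, o$per_edge_sizes,
                     info = paste("seed", seed))
    expect_equal(s$S, o$S, info = paste("seed", seed))
    expect_identical(s$per_edge_sizes, fx$blueprint$expected_per_edge_sizes)
  }
})

test_that("S is invariant under uniform residue renumbering", {
  fx <- generate_network_fixture(seed = 77, n_residues = 40,
                                 n_interactions = 9)
  shifted <- fx$blueprint$planted_interactions
  shifted$res_a <- shifted$res_a + 1000L
  shifted$res_b <- shifted$res_b + 1000L
  net2 <- build_network(thermoring:::.planted_iset(shifted))
  expect_equal(summarize_network(net2)$S, summarize_network(fx$network)$S)
})

test_that("removing an interaction edge never shrinks remaining grid sizes", {
  fx <- generate_network_fixture(seed = 5, n_residues = 50,
                                 n_interactions = 8)
  pl <- fx$blueprint$planted_interactions
  base <- summarize_network(fx$network)$per_edge_sizes
  for (drop in seq_len(nrow(pl))) {
    sub <- build_network(thermoring:::.planted_iset(pl[-drop, ]))
    sz <- summarize_network(sub)$per_edge_sizes
    common <- intersect(names(sz), names(base))
    keep <- !is.na(sz[common]) & !is.na(base[common])
    expect_true(all(sz[common][keep] >= base[common][keep]))
  }
})

test_that("N and S are local: a sub-segment computes like its restriction", {
  # two chord clusters far apart in sequence; restricting to the first
  # cluster's residue window reproduces its share of N and S
  pl <- data.frame(res_a = c(2, 5, 60, 64), res_b = c(10, 12, 70, 75),
                   type = "hydrogen_bond", stringsAsFactors = FALSE)
  full <- summarize_network(build_network(thermoring:::.planted_iset(pl)))
  sub <- pl[pl$res_b <= 20, ]
  local <- summarize_network(build_network(thermoring:::.planted_iset(sub)))
  expect_equal(local$N, 2L)
  in_window <- grepl("^(2|5)-", names(full$per_edge_sizes))
  expect_identical(full$per_edge_sizes[in_window], local$per_edge_sizes)
})

test_that("a grid reports its least-stable member interactions", {
  # the 12-residue replica ring holds both bridges; with the pi bridge
  # worth 2 basic H-bonds, the H-bond (energy 1) is the least stable
  iset <- thermoring:::.planted_iset(
    data.frame(res_a = c(362, 369), res_b = c(462, 469),
               type = c("pi_pi", "hydrogen_bond"), stringsAsFactors = FALSE),
    energy = c(2, 1))
  net <- build_network(iset)
  g <- enumerate_grids(net)
  ring <- g[[which(vapply(g, `[[`, integer(1), "size_s") == 12L)]]
  expect_equal(nrow(ring$controlled), 1)
  expect_equal(ring$controlled$itype, "hydrogen_bond")

  # with equal energies, ties are all reported
  net2 <- grid12_fixture()$network
  g2 <- enumerate_grids(net2)
  ring2 <- g2[[which(vapply(g2, `[[`, integer(1), "size_s") == 12L)]]
  expect_equal(nrow(ring2$controlled), 2)
})

test_that("every interaction edge is assigned a controlling basis grid", {
  fx <- generate_network_fixture(seed = 19, n_residues = 45,
                                 n_interactions = 7)
  s <- summarize_network(fx$network)
  cyclic <- !is.na(s$per_edge_sizes)
  expect_true(all(!is.na(s$controlling_grid[cyclic])))
})

test_that("network export/import round-trips", {
  fx <- generate_network_fixture(seed = 3, n_residues = 30,
                                 n_interactions = 6)
  p <- tempfile(fileext = ".txt")
  export_network(fx$network, p)
  back <- import_network(p)
  expect_equal(back$nodes, fx$network$nodes)
  expect_equal(back$edges[, c("from", "to", "weight", "type")],
               fx$network$edges[, c("from", "to", "weight", "type")])
})

test_that("the oracle refuses oversized networks", {
  fx <- generate_network_fixture(seed = 1, n_residues = 80,
                                 n_interactions = 15)
  expect_error(brute_force_grid_oracle(fx$network,
                                       max_interaction_edges = 10),
               "refusing")
})
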