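test_that("every posed interaction type is recovered and no decoy fires", {
  for (seed in c(1, 7, 23)) {
    bp <- geometry_blueprint(seed = seed)
    m <- generate_structure_fixture(bp)
    is <- detect_interactions(full_range_selection(m))
    # exactly the planted pairs, with the planted types
    got <- as.data.frame(is)[, c("res_a", "res_b", "type")]
    want <- data.frame(res_a = bp$poses$res_a, res_b = bp$poses$res_b,
                       type = bp$poses$type, stringsAsFactors = FALSE)
    want <- want[order(want$res_a), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("seed", seed))
    # decoys silent
    expect_false(any(is$res_a %in% bp$decoys$res_a))
    # every record satisfies its distance window
    crit <- default_criteria()
    caps <- c(hydrogen_bond = crit$hydrogen_bond$max_distance,
              salt_bridge = crit$salt_bridge$max_distance,
              pi_pi = crit$pi_pi$max_distance_tshaped,
              cation_pi = crit$cation_pi$max_distance,
              ch_pi = crit$ch_pi$max_distance,
              lone_pair_pi = crit$lone_pair_pi$max_distance)
    expect_true(all(is$distance <= caps[is$type]))
  }
})

test_that("pairs far beyond every cutoff yield an empty set", {
  bp <- geometry_blueprint(seed = 3, types = character(0), n_decoys = 3)
  m <- generate_structure_fixture(bp)
  is <- detect_interactions(full_range_selection(m))
  expect_equal(nrow(is), 0)
})

test_that("detection is invariant under rigid motion of all coordinates", {
  bp <- geometry_blueprint(seed = 5)
  m <- generate_structure_fixture(bp)
  is0 <- detect_interactions(full_range_selection(m))
  for (seed in 1:5) {
    is1 <- detect_interactions(full_range_selection(rigid_transform(m, seed)))
    expect_identical(is1$res_a, is0$res_a)
    expect_identical(is1$type, is0$type)
    expect_lt(max(abs(is1$distance - is0$distance)), 1e-9)
    ka <- abs(is1$key_angle - is0$key_angle)
    expect_lt(max(ka[is.finite(ka)]), 1e-6)
  }
})

test_that("detection is independent of residue iteration order", {
  m <- generate_structure_fixture(geometry_blueprint(seed = 9))
  is0 <- detect_interactions(full_range_selection(m))
  m2 <- m
  set.seed(1)
  m2$atoms <- m2$atoms[sample(nrow(m2$atoms)), ]
  is1 <- detect_interactions(full_range_selection(m2))
  strip <- function(x) {
    x <- as.data.frame(x)
    attributes(x)[c("criteria", "pathway")] <- NULL
    rownames(x) <- NULL
    x
  }
  expect_equal(strip(is0), strip(is1))
})

test_that("enlarging distance cutoffs never removes a detected interaction", {
  m <- generate_structure_fixture(geometry_blueprint(seed = 13))
  sel <- full_range_selection(m)
  base <- detect_interactions(sel)
  crit <- default_criteria()
  crit$hydrogen_bond$max_distance <- crit$hydrogen_bond$max_distance + 1
  crit$salt_bridge$max_distance <- crit$salt_bridge$max_distance + 1
  crit$cation_pi$max_distance <- crit$cation_pi$max_distance + 1
  crit$ch_pi$max_distance <- crit$ch_pi$max_distance + 1
  crit$lone_pair_pi$max_distance <- crit$lone_pair_pi$max_distance + 1
  crit$pi_pi$max_distance_parallel <- crit$pi_pi$max_distance_parallel + 1
  wide <- detect_interactions(sel, crit)
  key <- function(x) paste(x$res_a, x$res_b, x$type)
  expect_true(all(key(base) %in% key(wide)))
})

test_that("a salt-bridge pair is recorded once, not doubly as an H-bond", {
  m <- generate_structure_fixture(geometry_blueprint(seed = 2,
                                                     types = "salt_bridge"))
  is <- detect_interactions(full_range_selection(m))
  expect_equal(nrow(is), 1)
  expect_equal(is$type, "salt_bridge")
})

test_that("missing side-chain atoms skip the pair instead of crashing", {
  m <- generate_structure_fixture(geometry_blueprint(seed = 2,
                                                     types = "pi_pi"))
  # truncate one ring: drop three ring atoms of residue 1
  m$atoms <- m$atoms[!(m$atoms$resno == 1 &
                         m$atoms$elety %in% c("CZ", "CE1", "CE2")), ]
  is <- detect_interactions(full_range_selection(m))
  expect_equal(nrow(is), 0)
})

test_that("intersubunit detection labels and deduplicates swapping contacts", {
  m <- generate_structure_fixture(geometry_blueprint(seed = 6,
                                                     types = "cation_pi"),
                                  split_chains = TRUE)
  is <- detect_intersubunit(m)
  expect_equal(nrow(is), 1)
  expect_true(all(is$intersubunit))
  expect_false(is$chain_a == is$chain_b)

  # chains far apart: nothing detected
  far <- generate_structure_fixture(geometry_blueprint(seed = 6,
                                                       types = character(0),
                                                       n_decoys = 2),
                                    split_chains = TRUE)
  expect_equal(nrow(detect_intersubunit(far)), 0)

  # single-chain model: empty set with warning
  single <- generate_structure_fixture(geometry_blueprint(seed = 6))
  expect_warning(res <- detect_intersubunit(single), "single-chain")
  expect_equal(nrow(res), 0)
})

test_that("energy equivalents default per type and honor grid overrides", {
  m <- generate_structure_fixture(geometry_blueprint(seed = 1))
  is <- detect_interactions(full_range_selection(m))
  expect_true(all(is$energy_equiv == 1))

  # grid-level override: two pairs jointly worth 3 basic H-bonds
  p1 <- c(is$res_a[1], is$res_b[1]); p2 <- c(is$res_a[2], is$res_b[2])
  is2 <- assign_energy_equivalents(
    is, overrides = list(list(pairs = list(p1, p2), n = 3)))
  expect_equal(sum(is2$energy_equiv[1:2]), 3)

  # single-pair override
  is3 <- assign_energy_equivalents(
    is, overrides = list(list(pairs = list(p1), n = 2.6)))
  expect_equal(is3$energy_equiv[1], 2.6)

  expect_error(assign_energy_equivalents(
    is, overrides = list(list(pairs = list(c(900, 901)), n = 2))),
    "unknown pair")
})

test_that("interaction tables round-trip through the TSV dialect", {
  m <- generate_structure_fixture(geometry_blueprint(seed = 8))
  is <- detect_interactions(full_range_selection(m))
  p <- tempfile(fileext = ".tsv")
  write_interactions(is, p)
  hdr <- strsplit(readLines(p, n = 1), "\t")[[1]]
  expect_true(all(c("chain_a", "res_a", "name_a", "type", "distance_A",
                    "key_angle_deg", "energy_equiv", "intersubunit") %in% hdr))
  back <- read_interactions(p)
  expect_equal(as.data.frame(back)[, c("res_a", "res_b", "type")],
               as.data.frame(is)[, c("res_a", "res_b", "type")])
  expect_equal(back$distance, is$distance, tolerance = 1e-6)
})

test_that("incomplete criteria are rejected", {
  m <- generate_structure_fixture(geometry_blueprint(seed = 1))
  crit <- default_criteria()
  crit$pi_pi <- NULL
  expect_error(detect_interactions(full_range_selection(m), crit),
               "incomplete")
})

test_that("criteria round-trip through the YAML config file", {
  crit <- default_criteria()
  crit$hydrogen_bond$max_distance <- 3.2
  p <- tempfile(fileext = ".yaml")
  write_criteria(crit, p)
  back <- read_criteria(p)
  expect_equal(back$hydrogen_bond$max_distance, 3.2)
  expect_equal(back$pi_pi, crit$pi_pi)
})
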