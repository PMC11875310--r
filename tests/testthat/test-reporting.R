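make_report <- function(seed = 1) {
  m <- generate_structure_fixture(geometry_blueprint(seed = seed))
  analyze_state(m, chain_id = "A", start = 1, end = max(m$atoms$resno))
}

test_that("analyze_state assembles a consistent per-state report", {
  rep <- make_report()
  expect_s3_class(rep, "state_report")
  expect_equal(rep$N, 6L)
  expect_equal(rep$T_i, rep$S / rep$N)
  expect_equal(length(rep$grids), 6)
  expect_equal(rep$biggest$T_m,
               melting_threshold(rep$biggest$n, rep$biggest$s))
  expect_output(print(rep), "State report")
})

test_that("state reports round-trip through JSON and export TSV", {
  rep <- make_report(seed = 3)
  pj <- tempfile(fileext = ".json")
  write_state_report(rep, pj)
  back <- read_state_report(pj)
  expect_equal(back$N, rep$N)
  expect_equal(back$S, rep$S)
  expect_equal(back$structure_id, rep$structure_id)
  expect_equal(vapply(back$grids, function(g) as.integer(g$size), integer(1)),
               vapply(rep$grids, `[[`, integer(1), "size"))
  # identical inputs give byte-identical JSON (reproducibility)
  pj2 <- tempfile(fileext = ".json")
  write_state_report(make_report(seed = 3), pj2)
  expect_identical(readLines(pj), readLines(pj2))

  pt <- tempfile(fileext = ".tsv")
  write_state_report(rep, pt)
  # grid labels may carry prime marks, so disable quote interpretation
  tab <- utils::read.table(pt, sep = "\t", header = TRUE, quote = "")
  expect_equal(nrow(tab), length(rep$grids))
})

test_that("compare_states computes the transition and guards bounds", {
  a <- make_report(seed = 1)
  b <- make_report(seed = 2)
  # force a grid-size difference by overriding the totals through a
  # synthetic pair of abstract fits with shared bounds
  fit_c <- thermoring(make_chord_network(c(10, 6)))
  fit_o <- thermoring(make_chord_network(c(4, 2)))
  rc <- analyze_state(fit_c, structure_id = "closed")
  ro <- analyze_state(fit_o, structure_id = "open")
  tr <- compare_states(rc, ro, q10_measured = 3.88)
  expect_s3_class(tr, "transition_report")
  expect_equal(tr$omega_10, structural_thermosensitivity(16, 6, 2, 2))
  expect_equal(tr$q10_measured, 3.88)
  expect_output(print(tr), "Omega10")

  b$pathway$end <- b$pathway$end + 5L
  expect_error(compare_states(a, b), "mismatched pathway")
})

test_that("table regression reproduces Ti and Tm rows from printed totals", {
  states <- data.frame(
    state = c("partial", "open", "closed4", "closed3"),
    N = c(30, 35, 44, 67), S = c(83, 71, 88, 99),
    n = c("2/3", "2.6", "2", "2"), s = c(14, 12, 19, 12),
    stringsAsFactors = FALSE)
  trans <- data.frame(from = c("closed3", "closed4", "partial", "closed4"),
                      to = c("open", "partial", "open", "open"),
                      stringsAsFactors = FALSE)
  out <- table1_report(states, trans)
  st <- out$states
  expect_equal(round(st$T_i[match(c("partial", "open", "closed4", "closed3"),
                                  st$state)], 2),
               c(2.77, 2.03, 2.00, 1.48))
  expect_equal(st$T_m[st$state == "closed3"], "50")
  expect_equal(st$T_m[st$state == "closed4"], "36")
  expect_equal(st$T_m[st$state == "open"], "56")
  expect_equal(st$T_m[st$state == "partial"], "46/56")
  om <- out$transitions$omega_10
  expect_equal(om[1], 14^(67 / 35))
  expect_equal(om[2], 2.5^(44 / 30))
  expect_equal(om[3], 6^(30 / 35))
  expect_equal(om[4], 8.5^(44 / 35))
  expect_output(print(out), "Omega10")
})

test_that("table regression is row-order invariant and validates input", {
  states <- data.frame(state = c("a", "b"), N = c(10, 20), S = c(30, 25),
                       n = c("2", "2"), s = c(5, 7))
  out1 <- table1_report(states)
  out2 <- table1_report(states[2:1, ])
  expect_equal(out1$states, out2$states)

  single <- table1_report(states[1, ])
  expect_null(single$transitions)
  expect_equal(single$states$T_i, 3)

  bad <- states; bad$N[2] <- NA
  expect_error(table1_report(bad), "malformed state row")
  expect_error(table1_report(states[, -2]), "missing column")
  expect_error(table1_report(states,
                             data.frame(from = "a", to = "zzz")),
               "unknown state")
})

test_that("the command-line driver analyzes a structure end to end", {
  skip_if(Sys.which("Rscript") == "", "Rscript not on PATH")
  cli <- system.file("scripts", "thermoring-cli.R", package = "thermoring")
  skip_if(cli == "", "CLI script not installed")
  pdb <- tempfile(fileext = ".pdb")
  m <- generate_structure_fixture(geometry_blueprint(seed = 2))
  write_structure(m, pdb)
  out <- tempfile(fileext = ".json")
  res <- system2("Rscript",
                 c(cli, "analyze", "--structure", shQuote(pdb),
                   "--chain", "A", "--segment",
                   paste0("1-", max(m$atoms$resno)),
                   "--out", shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(res, "status") %||% 0L, 0L)
  expect_true(file.exists(out))
  rep <- read_state_report(out)
  expect_equal(rep$N, 6L)

  # missing file: non-zero exit, no partial output
  out2 <- tempfile(fileext = ".json")
  res2 <- suppressWarnings(system2(
    "Rscript", c(cli, "analyze", "--structure", shQuote(tempfile()),
                 "--segment", "1-10", "--out", shQuote(out2)),
    stdout = TRUE, stderr = TRUE))
  expect_true((attr(res2, "status") %||% 0L) != 0L)
  expect_false(file.exists(out2))
})
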