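test_that("terminal status distinguishes purchasable, known-synthesizable, open", {
  bb <- building_block_db("CCO", price = 2)
  fx <- fixed_reaction_db(r1 = "CCO", product = "CC=O", yield = 0.9)
  expect_identical(terminal_status("CCO", bb, fx), "purchasable")
  expect_identical(terminal_status("CC=O", bb, fx), "known_synthesizable")
  expect_identical(terminal_status("CCN", bb, fx), "open")
  # purchasable takes precedence over known-synthesizable
  fx2 <- fixed_reaction_db(r1 = "CC=O", product = "CCO", yield = 0.9)
  expect_identical(terminal_status("CCO", bb, fx2), "purchasable")
})

test_that("priorities follow heavy_atoms * depth^alpha", {
  expect_equal(compound_priority("c1ccccc1", 1), 6 * 1^1.1)
  expect_equal(compound_priority("c1ccccc1", 2), 6 * 2^1.1)
  expect_equal(compound_priority(10, 3, alpha = 1.1), 10 * 3^1.1)
  expect_error(compound_priority(6, 0), "depth")

  expect_equal(reaction_priority(list(heavy = c(5, 9), depth = 1)), 9)
  expect_equal(reaction_priority(list(heavy = c(5, 9), depth = 2)), 9 * 2^1.1)
  expect_equal(reaction_priority(list(reactants = "c1ccccc1", depth = 2)),
               6 * 2^1.1)
})

test_that("a purchasable target is never expanded", {
  bb <- building_block_db("CC(=O)Nc1ccccc1", price = 1)
  net <- expand("CC(=O)Nc1ccccc1", tpl_lib(), NULL, bb, NULL,
                expansion_config(max_generated = 50L))
  expect_identical(net$counters$generated, 0L)
})

test_that("a one-disconnection fixture yields the expected reaction and a route", {
  bb <- building_block_db(c("CC(=O)O", "Nc1ccccc1"), price = c(2, 3))
  lib <- tpl_lib()[tpl_lib()$template_id == "T01", ]
  class(lib) <- class(tpl_lib())
  net <- expand("CC(=O)Nc1ccccc1", lib, NULL, bb, NULL,
                expansion_config(algorithm = "breadth_first",
                                 max_generated = 10L))
  expect_identical(net$counters$generated, 1L)
  expect_setequal(stats::na.omit(c(net$reactions$r1, net$reactions$r2)),
                  c("CC(=O)O", "Nc1ccccc1"))
  sn <- build_subnetwork(net$target, net, NULL, bb)
  routes <- k_best_routes(sn, search_params(k = 1))
  expect_length(routes, 1L)
  expect_equal(routes[[1]]$cost, (2 + 3) / 0.5)  # default score 0.5 caps yield
})

test_that("the generated-reaction budget binds for every algorithm", {
  fx <- two_four_fixture()
  for (alg in c("breadth_first", "depth_first", "best_first_compound",
                "best_first_reaction")) {
    for (budget in c(0L, 3L, 12L)) {
      net <- expand(fx$target, tpl_lib(), NULL, fx$bb, NULL,
                    expansion_config(algorithm = alg, max_generated = budget))
      expect_lte(nrow(net$reactions), budget)
      if (budget == 0L) expect_identical(net$counters$generated, 0L)
    }
  }
})

test_that("every kept reaction scores at or above the threshold; raising it rejects all", {
  fx <- two_four_fixture()
  net <- expand(fx$target, tpl_lib(), NULL, fx$bb, NULL,
                expansion_config(max_generated = 30L, score_threshold = 0.2))
  expect_true(all(net$reactions$score >= 0.2))
  # default score is 0.5: a threshold above it rejects everything
  net2 <- expand(fx$target, tpl_lib(), NULL, fx$bb, NULL,
                 expansion_config(max_generated = 30L,
                                  score_threshold = 0.6))
  expect_identical(nrow(net2$reactions), 0L)
  expect_gt(net2$counters$rejected, 0L)
})

test_that("expansion is deterministic", {
  fx <- two_four_fixture()
  for (alg in c("breadth_first", "best_first_reaction")) {
    a <- expand(fx$target, tpl_lib(), NULL, fx$bb, NULL,
                expansion_config(algorithm = alg, max_generated = 25L))
    b <- expand(fx$target, tpl_lib(), NULL, fx$bb, NULL,
                expansion_config(algorithm = alg, max_generated = 25L))
    expect_identical(a$reactions, b$reactions)
    expect_identical(a$compounds, b$compounds)
  }
})

test_that("breadth-first discovers the shortest route before any longer one", {
  fx <- two_four_fixture()
  # the full network admits both a 2-step and a 4-step route
  net <- expand(fx$target, tpl_lib(), NULL, fx$bb, NULL,
                expansion_config(algorithm = "breadth_first",
                                 max_generated = 100L))
  sn <- build_subnetwork(net$target, net, NULL, fx$bb)
  lens <- vapply(k_best_routes(sn, search_params(k = 10)), `[[`, integer(1),
                 "n_reactions")
  expect_true(2L %in% lens)
  expect_true(any(lens >= 4L))
  # at the smallest budget where any route exists, it is a 2-step route
  for (budget in seq_len(100L)) {
    net <- expand(fx$target, tpl_lib(), NULL, fx$bb, NULL,
                  expansion_config(algorithm = "breadth_first",
                                   max_generated = budget))
    sn <- build_subnetwork(net$target, net, NULL, fx$bb)
    routes <- k_best_routes(sn, search_params(k = 5))
    if (length(routes)) {
      expect_identical(min(vapply(routes, `[[`, integer(1), "n_reactions")),
                       2L)
      break
    }
  }
})

test_that("best-first reaction solves the two/four-step fixture within 100 reactions", {
  fx <- two_four_fixture()
  net <- expand(fx$target, tpl_lib(), NULL, fx$bb, NULL,
                expansion_config(algorithm = "best_first_reaction",
                                 max_generated = 100L))
  expect_lte(net$counters$generated, 100L)
  sn <- build_subnetwork(net$target, net, NULL, fx$bb)
  expect_gt(length(k_best_routes(sn, search_params(k = 1))), 0L)
})

test_that("no reaction lists its product among its reactants; paths are repetition-free", {
  fx <- two_four_fixture()
  net <- expand(fx$target, tpl_lib(), NULL, fx$bb, NULL,
                expansion_config(max_generated = 60L))
  bad <- net$reactions$product == net$reactions$r1 |
    (!is.na(net$reactions$r2) & net$reactions$product == net$reactions$r2)
  expect_false(any(bad))
  sn <- build_subnetwork(net$target, net, NULL, fx$bb)
  for (r in k_best_routes(sn, search_params(k = 8))) {
    check_paths <- function(node, seen) {
      expect_false(node$compound %in% seen)
      for (ch in node$children) check_paths(ch, c(seen, node$compound))
    }
    check_paths(r$tree, character(0))
  }
})

test_that("invalid targets and empty libraries are handled", {
  expect_error(expand("junk(", tpl_lib()), "junk")
  expect_error(expand("CCO.Cl", tpl_lib()), "single-fragment")
  f <- tempfile(); writeLines("template_id\treaction_name\tsmirks\tn_reactants", f)
  net <- expand("CC(=O)Nc1ccccc1", load_templates(f), NULL, NULL, NULL,
                expansion_config(max_generated = 5L))
  expect_identical(nrow(net$reactions), 0L)
  expect_identical(net$compounds$key, "CC(=O)Nc1ccccc1")
})
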