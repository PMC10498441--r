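test_that("effective yields follow the fixed/generated rules", {
  cm <- cost_model()
  expect_equal(effective_yield(list(origin = "fixed", yield = 0.82), cm), 0.82)
  expect_equal(effective_yield(list(origin = "fixed", yield = NA), cm),
               cm$default_fixed_yield)
  expect_equal(effective_yield(list(origin = "generated", score = 0.9), cm),
               cm$generated_yield_cap)
  expect_equal(effective_yield(list(origin = "generated", score = 0.35), cm),
               0.35)
  expect_error(effective_yield(list(origin = "fixed", yield = 1.2), cm),
               "yield")
})

test_that("reaction cost is the reactant sum divided by yield plus overhead", {
  cm <- cost_model()
  expect_equal(reaction_cost(c(2, 3), 0.5, cm), 10)
  expect_equal(reaction_cost(1, 1, cm), 1)
  expect_equal(reaction_cost(4, 0.5, cm), 8)
  cm2 <- cost_model(per_reaction_overhead = 1.5)
  expect_equal(reaction_cost(c(2, 3), 0.5, cm2), 11.5)
  expect_error(reaction_cost(c(2, 3), 0, cm), "yield")
})

test_that("worked examples: chain, diamond and cycle", {
  wx <- worked_example_suite()
  chain <- k_best_routes(wx$chain$subnet, search_params(k = 3))
  expect_equal(route_costs(chain), wx$chain$expected$costs)

  diamond <- k_best_routes(wx$diamond$subnet, search_params(k = 2))
  expect_equal(route_costs(diamond), wx$diamond$expected$costs)

  cyc <- k_best_routes(wx$cycle$subnet, search_params(k = 5))
  expect_equal(route_costs(cyc), wx$cycle$expected$costs)
  for (r in cyc) {
    check <- function(node, seen) {
      expect_false(node$compound %in% seen)
      for (ch in node$children) check(ch, c(seen, node$compound))
    }
    check(r$tree, character(0))
  }
  # brute force agrees on the cyclic fixture and terminates
  expect_equal(route_costs(brute_force_k_best(wx$cycle$subnet, 5)),
               wx$cycle$expected$costs)
})

test_that("no more routes than exist are returned", {
  wx <- worked_example_suite()
  # the diamond has exactly two distinct routes
  expect_length(k_best_routes(wx$diamond$subnet, search_params(k = 5)), 2L)
})

test_that("k_best_routes matches the exhaustive oracle on random networks", {
  for (s in 1:60) {
    net <- make_synthetic_network(network_spec(seed = s))
    for (k in c(1L, 3L, 5L)) {
      a <- route_costs(k_best_routes(net$subnet, search_params(k = k)))
      b <- route_costs(brute_force_k_best(net$subnet, k))
      expect_equal(a, b, tolerance = 1e-9, info = paste("seed", s, "k", k))
    }
  }
})

test_that("route lists are sorted, bounded and super-additive in leaf prices", {
  for (s in c(101, 202, 303)) {
    net <- make_synthetic_network(network_spec(seed = s))
    routes <- k_best_routes(net$subnet, search_params(k = 5))
    costs <- route_costs(routes)
    expect_lte(length(routes), 5L)
    expect_true(all(diff(costs) >= -1e-12))
    for (r in routes) {
      leaf_sum <- sum(net$prices[r$leaves])
      expect_gte(r$cost, leaf_sum - 1e-9)
    }
  }
})

test_that("subnetwork extraction is reachability- and depth-bounded", {
  compounds <- data.frame(
    key = c("T", "A", "B", "Z1", "Z2"),
    purchasable = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    price = c(NA, NA, 1, NA, 2), stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = c("r1", "r2", "r3"), product = c("T", "A", "Z1"),
    r1 = c("A", "B", "Z2"), r2 = NA_character_, origin = "fixed",
    yield = 0.5, score = NA_real_, label = "x", stringsAsFactors = FALSE)
  sn <- make_subnetwork(compounds, reactions, "T")
  # r3 produces Z1 which is unreachable from T
  fake_net <- list(target = "T", compounds = data.frame(key = compounds$key),
                   reactions = data.frame(
                     id = reactions$id, product = reactions$product,
                     r1 = reactions$r1, r2 = reactions$r2,
                     score = 0.5, label = "t", stringsAsFactors = FALSE))
  bb <- building_block_db(c("B", "Z2"), price = c(1, 2), canonical = TRUE)
  out <- build_subnetwork("T", fake_net, NULL, bb)
  expect_setequal(out$reactions$id, c("r1", "r2"))
  expect_false("Z1" %in% out$compounds$key)

  out1 <- build_subnetwork("T", fake_net, NULL, bb, max_depth = 1)
  expect_identical(out1$reactions$id, "r1")
})

test_that("fixed reactions beneath a known-synthesizable leaf are stitched in", {
  # generated step: target <- A (template); fixed: A <- B <- C(purchasable)
  fx <- fixed_reaction_db(r1 = c("B", "C"), product = c("A", "B"),
                          yield = c(0.8, NA), name = c("f1", "f2"))
  fake_net <- list(target = "T", compounds = data.frame(key = c("T", "A")),
                   reactions = data.frame(
                     id = "g1", product = "T", r1 = "A", r2 = NA_character_,
                     score = 0.6, label = "gen", stringsAsFactors = FALSE))
  bb <- building_block_db("C", price = 4, canonical = TRUE)
  sn <- build_subnetwork("T", fake_net, fx, bb)
  expect_identical(nrow(sn$reactions), 3L)
  expect_setequal(sn$reactions$origin, c("generated", "fixed"))
  routes <- k_best_routes(sn, search_params(k = 1))
  expect_length(routes, 1L)
  # cost: C=4 -> B: 4/0.5 (default yield) -> A: 8/0.8 -> T: 10/0.6
  expect_equal(routes[[1]]$cost, ((4 / 0.5) / 0.8) / 0.6)
})

test_that("partial routes appear only when enabled and rank after cheaper complete routes", {
  compounds <- data.frame(key = c("T", "A", "B"),
                          purchasable = c(FALSE, TRUE, FALSE),
                          price = c(NA, 5, NA), stringsAsFactors = FALSE)
  reactions <- data.frame(id = c("ra", "rb"), product = "T",
                          r1 = c("A", "B"), r2 = NA_character_,
                          origin = "fixed", yield = 1.0, score = NA_real_,
                          label = "x", stringsAsFactors = FALSE)
  sn <- make_subnetwork(compounds, reactions, "T")
  complete_only <- k_best_routes(sn, search_params(k = 5))
  expect_length(complete_only, 1L)
  expect_false(complete_only[[1]]$is_partial)

  both <- k_best_routes(sn, search_params(k = 5, allow_partial = TRUE))
  expect_length(both, 2L)
  expect_false(both[[1]]$is_partial)
  expect_true(both[[2]]$is_partial)
  expect_gt(both[[2]]$cost, both[[1]]$cost)
  expect_equal(both[[2]]$cost, cost_model()$partial_leaf_penalty)
})

test_that("keep and avoid constraints are honored", {
  wx <- worked_example_suite()
  avoided <- constrained_search(wx$diamond$subnet,
                                search_params(k = 5, avoid = "r_b"))
  expect_length(avoided, 1L)
  expect_identical(avoided[[1]]$reaction_ids,
                   wx$diamond$expected$avoid_r_b_route_ids)

  kept <- constrained_search(wx$diamond$subnet,
                             search_params(k = 5, keep = "B"))
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$reaction_ids,
                   wx$diamond$expected$keep_B_route_ids)

  expect_error(search_params(keep = "c", avoid = "c"), "disjoint")
  # route-level contract on a larger random network
  net <- make_synthetic_network(network_spec(seed = 77))
  some_rxn <- net$subnet$reactions$id[1]
  res <- constrained_search(net$subnet,
                            search_params(k = 5, avoid = some_rxn))
  for (r in res) expect_false(some_rxn %in% r$reaction_ids)
})

test_that("strategies group by the target-producing reaction, ordered by best cost", {
  wx <- worked_example_suite()
  routes <- k_best_routes(wx$diamond$subnet, search_params(k = 5))
  st <- group_strategies(routes)
  expect_length(st, 2L)
  expect_identical(st[[1]]$final_reaction, "r_b")  # cost 8 beats 10

  expect_length(group_strategies(list()), 0L)
  one <- group_strategies(routes[1])
  expect_length(one, 1L)
  expect_length(one[[1]]$routes, 1L)

  # 4 routes, 3 sharing the final reaction -> strategies sized 3 and 1
  compounds <- data.frame(key = c("T", "M", "A", "B", "C", "D"),
                          purchasable = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
                          price = c(NA, NA, 1, 2, 3, 10),
                          stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = c("final1", "final2", "m1", "m2", "m3"),
    product = c("T", "T", "M", "M", "M"),
    r1 = c("M", "D", "A", "B", "C"), r2 = NA_character_,
    origin = "fixed", yield = 1.0, score = NA_real_, label = "x",
    stringsAsFactors = FALSE)
  sn <- make_subnetwork(compounds, reactions, "T")
  st4 <- group_strategies(k_best_routes(sn, search_params(k = 4)))
  expect_length(st4, 2L)
  expect_identical(unname(vapply(st4, function(s) length(s$routes),
                                 integer(1))),
                   c(3L, 1L))
  expect_identical(st4[[1]]$final_reaction, "final1")
})

test_that("the oracle refuses oversized networks", {
  net <- make_synthetic_network(network_spec(n_compounds = 20,
                                             n_reactions = 30, seed = 1))
  expect_error(brute_force_k_best(net$subnet, 3), "too large")
})
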