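bb_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(c("smiles,id,price,vendor,tier", lines), f)
  f
}

test_that("building blocks: tier filter, min-price dedup, canonical keys", {
  f <- bb_csv(c("OCC,e1,5,acme,1",
                "CCO,e2,3,bulk,2",
                "CCN,e3,7,acme,3",
                "C1=CC=CC=C1,e4,9,acme,1"))
  db <- read_building_blocks(f)
  expect_s3_class(db, "building_block_db")
  expect_false("CCN" %in% db$smiles)          # tier 3 dropped
  expect_equal(db$price[db$smiles == "CCO"], 3)  # duplicate keeps min
  expect_true("c1ccccc1" %in% db$smiles)      # canonicalized key
  expect_identical(nrow(db), 2L)

  db13 <- read_building_blocks(f, tiers = c(1L, 3L))
  expect_true("CCN" %in% db13$smiles)

  # idempotent: loading the same file twice gives equal databases
  expect_identical(db, read_building_blocks(f))

  empty <- read_building_blocks(bb_csv(character(0)))
  expect_identical(nrow(empty), 0L)

  f2 <- tempfile(); writeLines(c("smiles,price", "CCO,3"), f2)
  expect_error(read_building_blocks(f2), "columns")
})

test_that("unparsable building-block rows are skipped with a message", {
  f <- bb_csv(c("CCO,e1,3,acme,1", "xx((,e2,4,acme,1"))
  expect_message(db <- read_building_blocks(f), "skipped 1")
  expect_identical(nrow(db), 1L)
})

rxn_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_smiles\tyield\tname\tsource", lines), f)
  f
}

test_that("reaction db enforces the <=2 reactant / 1 product shape", {
  f <- rxn_tsv(c("CC(=O)O.Nc1ccccc1>>CC(=O)Nc1ccccc1\t0.9\tamide\tpat1",
                 "C.CC.CCC>>CCCC\t\tjunk\tpat2",
                 "CCO>>CCO\t0.5\tident\tpat3",
                 "CCO>O=S(=O)(O)O>CC=O\t0.7\toxid\tpat4"))
  expect_message(db <- read_reaction_db(f), "dropped 2")
  expect_identical(nrow(db), 2L)
  expect_identical(db$yield[1], 0.9)
  expect_identical(db$agents[2], "O=S(=O)(O)O")
  expect_identical(db$r2[2], NA_character_)
})

test_that("out-of-range yields become unreported with a warning", {
  f <- rxn_tsv("CC(=O)O.Nc1ccccc1>>CC(=O)Nc1ccccc1\t1.7\tamide\tpat")
  expect_warning(db <- read_reaction_db(f), "outside")
  expect_true(is.na(db$yield[1]))
})

test_that("route documents round-trip and carry generated-reaction metadata", {
  compounds <- data.frame(key = c("T", "A", "B"),
                          purchasable = c(FALSE, TRUE, TRUE),
                          price = c(NA, 2, 3), stringsAsFactors = FALSE)
  reactions <- data.frame(id = c("g1", "f1"), product = "T",
                          r1 = c("A", "B"), r2 = NA_character_,
                          origin = c("generated", "fixed"),
                          yield = c(NA, 0.8), score = c(0.6, NA),
                          label = c("amide coupling", "patent-123"),
                          stringsAsFactors = FALSE)
  sn <- make_subnetwork(compounds, reactions, "T")
  routes <- k_best_routes(sn, search_params(k = 2))
  f <- tempfile(fileext = ".json")
  write_routes(routes, sn, f, params = list(k = 2))
  doc <- read_routes(f)
  expect_identical(doc$target, "T")
  expect_identical(doc$n_routes, 2L)
  recs <- unlist(lapply(doc$strategies, function(s) s$routes),
                 recursive = FALSE)
  gen_steps <- Filter(function(x) x$origin == "generated",
                      unlist(lapply(recs, `[[`, "reactions"),
                             recursive = FALSE))
  expect_length(gen_steps, 1L)
  expect_identical(gen_steps[[1]]$label, "amide coupling")
  expect_equal(gen_steps[[1]]$feasibility_score, 0.6)
  expect_equal(gen_steps[[1]]$effective_yield, 0.6)

  # writing an empty result still yields a valid document
  f2 <- tempfile(fileext = ".json")
  write_routes(list(), sn, f2)
  expect_identical(read_routes(f2)$n_routes, 0L)

  tab <- route_table(group_strategies(routes))
  expect_identical(nrow(tab), 2L)
  expect_true(all(diff(tab$cost) >= 0))
})
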