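# Seeded generators for every input the system needs: random layered AND-OR
# networks with a guaranteed complete route, labeled training corpora built
# from a small fragment pool, and the hand-computed worked examples used
# across the documentation and tests.

#' Synthetic network specification
#'
#' @param n_compounds Total compounds including the target (default 12).
#' @param n_reactions Total reactions (default 18).
#' @param fraction_two_reactant Fraction of two-reactant reactions
#'   (default 0.5).
#' @param yield_range Range yields are drawn from (default `c(0.3, 1)`).
#' @param price_range Range building-block prices are drawn from
#'   (default `c(1, 100)`).
#' @param fraction_generated Fraction of reactions marked as
#'   template-generated (scored) rather than fixed (default 0.3).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @export
network_spec <- function(n_compounds = 12L, n_reactions = 18L,
                         fraction_two_reactant = 0.5,
                         yield_range = c(0.3, 1.0),
                         price_range = c(1, 100),
                         fraction_generated = 0.3, seed = 1L) {
  stopifnot(n_compounds >= 2L, n_reactions >= 1L,
            yield_range[1] > 0, yield_range[2] <= 1,
            price_range[1] > 0)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_reactions = as.integer(n_reactions),
                 fraction_two_reactant = fraction_two_reactant,
                 yield_range = yield_range, price_range = price_range,
                 fraction_generated = fraction_generated,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Generate a random layered synthesis network
#'
#' Builds a random AND-OR network with abstract compound keys, layered from
#' purchasable leaves up to a designated target so that at least one
#' complete route exists: every non-purchasable compound receives at least
#' one producing reaction whose reactants sit strictly below it. Yields,
#' scores and prices are drawn from the spec ranges; fully reproducible per
#' seed.
#'
#' @param spec A [network_spec()].
#' @return A list with `subnet` (a `synth_subnetwork`), `target`, and
#'   `prices` (named vector over the purchasable leaves).
#' @export
make_synthetic_network <- function(spec = network_spec()) {
  n <- spec$n_compounds
  n_bb <- max(2L, floor(n / 3))
  if (spec$n_reactions < n - n_bb) {
    stop("infeasible spec: need at least ", n - n_bb,
         " reactions to make every interior compound producible",
         call. = FALSE)
  }
  set.seed(spec$seed)
  keys <- sprintf("C%02d", seq_len(n))
  bb <- keys[seq_len(n_bb)]                      # layer 0
  interior <- keys[(n_bb + 1L):n]
  target <- keys[n]
  layer <- c(stats::setNames(rep(0L, n_bb), bb),
             stats::setNames(seq_along(interior), interior))
  prices <- stats::setNames(
    stats::runif(n_bb, spec$price_range[1], spec$price_range[2]), bb)

  draw_reaction <- function(product, id) {
    below <- keys[layer < layer[[product]]]
    two <- length(below) >= 2L &&
      stats::runif(1) < spec$fraction_two_reactant
    rs <- sample(below, if (two) 2L else 1L)
    generated <- stats::runif(1) < spec$fraction_generated
    y <- stats::runif(1, spec$yield_range[1], spec$yield_range[2])
    data.frame(id = id, product = product, r1 = rs[1],
               r2 = if (two) rs[2] else NA_character_,
               origin = if (generated) "generated" else "fixed",
               yield = if (generated) NA_real_ else y,
               score = if (generated) y else NA_real_,
               label = if (generated) "synthetic template" else "synthetic db",
               stringsAsFactors = FALSE)
  }

  rows <- list()
  for (i in seq_along(interior)) {           # guarantee producibility
    rows[[i]] <- draw_reaction(interior[i], sprintf("r%02d", i))
  }
  extra <- spec$n_reactions - length(rows)
  for (j in seq_len(extra)) {
    product <- sample(interior, 1L)
    rows[[length(rows) + 1L]] <-
      draw_reaction(product, sprintf("r%02d", length(rows) + 1L))
  }
  reactions <- do.call(rbind, rows)
  compounds <- data.frame(key = keys,
                          purchasable = keys %in% bb,
                          price = c(prices[bb], rep(NA_real_, n - n_bb)),
                          stringsAsFactors = FALSE)
  list(subnet = make_subnetwork(compounds, reactions, target),
       target = target, prices = prices)
}

#' Shipped fragment pool
#'
#' Reads the small library of simple mono-functional molecules (acids,
#' amines, alcohols, halides, boronic acids, ...) shipped with the package,
#' used to build chemically valid synthetic training corpora and database
#' fixtures.
#'
#' @return Data frame with columns `smiles` (canonical) and `class`.
#' @export
fragment_pool <- function() {
  path <- system.file("extdata", "fragments.tsv", package = "retroplan",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$smiles <- chem_canon(df$smiles)
  df
}

# enumerate reactant combinations of the pool that the template transforms,
# with their forward products; at most `limit` combos
template_pool_reactions <- function(template, pool = fragment_pool(),
                                    limit = 400L) {
  template <- as.list(template)
  fwd <- reverse_smirks(template$smirks)
  smis <- pool$smiles
  if (template$n_reactants == 1L) {
    combos <- lapply(smis, function(s) s)
  } else {
    combos <- list()
    # screen each slot by its reactant pattern to keep the cross product small
    parts <- strsplit(strsplit(template$smirks, ">>", fixed = TRUE)[[1]][2],
                      ".", fixed = TRUE)[[1]]
    m1 <- smis[chem_match(parts[1], smis)]
    m2 <- smis[chem_match(parts[2], smis)]
    for (a in m1) for (b in m2) {
      combos[[length(combos) + 1L]] <- c(a, b)
      if (length(combos) >= 4L * limit) break
    }
  }
  if (!length(combos)) return(list())
  outs <- chem_forward(fwd, combos)
  keep <- which(vapply(outs, length, integer(1)) > 0L)
  keep <- keep[seq_len(min(length(keep), limit))]
  lapply(keep, function(i) list(reactants = combos[[i]],
                                products = outs[[i]]))
}

#' Generate a labeled training corpus for one template
#'
#' Positives are built by forward-applying the template to fragment-pool
#' combinations and drawing a yield of at least the labeling threshold (or
#' none); negatives are (a) full matches drawn with a low yield, from
#' combinations reserved exclusively for that role so that the two classes
#' stay separable, and (b) reactant-matching records whose recorded product
#' is an unrelated pool molecule (product mismatch), with any yield. The
#' intended labels are exactly what [label_examples()] reproduces.
#'
#' @param template A template (list or one row of a library).
#' @param n_pos,n_neg Number of positive / negative records (defaults 500).
#' @param seed Integer seed.
#' @param low_yield_fraction Fraction of negatives that are low-yield full
#'   matches (default 0.05; the remainder are product mismatches).
#' @return A data frame with columns `r1`, `r2`, `product`, `yield`, `name`,
#'   `source` and the intended `label`.
#' @export
make_training_set <- function(template, n_pos = 500L, n_neg = 500L,
                              seed = 1L, low_yield_fraction = 0.05) {
  template <- as.list(template)
  rxns <- template_pool_reactions(template)
  if (length(rxns) < 10L) {
    stop("template ", template$template_id,
         " matches too few fragment-pool combinations to build a corpus",
         call. = FALSE)
  }
  set.seed(seed)
  n_low <- round(low_yield_fraction * n_neg)
  n_mis <- n_neg - n_low
  idx <- sample(seq_along(rxns))
  low_pool <- idx[seq_len(max(1L, min(n_low, floor(length(idx) / 4))))]
  pos_pool <- setdiff(idx, low_pool)

  rec <- function(rx, product, yield) {
    rs <- rx$reactants
    data.frame(r1 = rs[1], r2 = if (length(rs) == 2L) rs[2] else NA_character_,
               product = product, yield = yield,
               name = template$reaction_name, source = "synthetic",
               stringsAsFactors = FALSE)
  }

  rows <- list(); labels <- character(0)
  for (i in seq_len(n_pos)) {
    rx <- rxns[[sample(pos_pool, 1L)]]
    y <- if (stats::runif(1) < 0.3) NA_real_ else stats::runif(1, 0.10, 0.99)
    rows[[length(rows) + 1L]] <- rec(rx, sample(rx$products, 1L), y)
    labels <- c(labels, "positive")
  }
  for (i in seq_len(n_low)) {
    rx <- rxns[[sample(low_pool, 1L)]]
    rows[[length(rows) + 1L]] <- rec(rx, sample(rx$products, 1L),
                                     stats::runif(1, 0.005, 0.099))
    labels <- c(labels, "negative")
  }
  frag <- fragment_pool()$smiles
  made <- 0L; guard <- 0L
  while (made < n_mis && guard < 50L * n_mis) {
    guard <- guard + 1L
    rx <- rxns[[sample(idx, 1L)]]
    wrong <- sample(frag, 1L)
    if (wrong %in% rx$products || wrong %in% rx$reactants) next
    y <- if (stats::runif(1) < 0.3) NA_real_ else stats::runif(1, 0.05, 0.99)
    rows[[length(rows) + 1L]] <- rec(rx, wrong, y)
    labels <- c(labels, "negative")
    made <- made + 1L
  }
  out <- do.call(rbind, rows)
  out$label <- labels
  rownames(out) <- NULL
  out
}

#' Write a corpus as a reaction TSV
#'
#' Emits records in the `reactants>agents>product` dialect readable by
#' [read_reaction_db()].
#'
#' @param corpus Data frame with `r1`, `r2`, `product`, `yield`, `name`,
#'   `source`.
#' @param path Output TSV path.
#' @export
write_reaction_tsv <- function(corpus, path) {
  rsmiles <- vapply(seq_len(nrow(corpus)), function(i) {
    rs <- c(corpus$r1[i], corpus$r2[i])
    paste0(paste(rs[!is.na(rs)], collapse = "."), ">>", corpus$product[i])
  }, character(1))
  df <- data.frame(reaction_smiles = rsmiles,
                   yield = ifelse(is.na(corpus$yield), "", corpus$yield),
                   name = corpus$name, source = corpus$source,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hand-computed worked examples
#'
#' Small fixed subnetworks whose optimal routes were computed by hand,
#' embedded together with their expected outputs:
#' * `chain`: BB(price 2) -> X (yield 0.5) -> target (yield 0.5); the single
#'   route costs (2/0.5)/0.5 = 8.
#' * `diamond`: the target is producible from A (price 10, yield 1.0) or
#'   from B (price 4, yield 0.5); ordered costs 8 then 10.
#' * `cycle`: contains a two-reaction cycle between A and B plus a real
#'   route BB -> B -> A -> target of cost 8; the search must terminate and
#'   return repetition-free routes.
#' @return Named list of fixtures, each with `subnet`, `target` and an
#'   `expected` list.
#' @export
worked_example_suite <- function() {
  chain <- make_subnetwork(
    data.frame(key = c("BB", "X", "TGT"),
               purchasable = c(TRUE, FALSE, FALSE),
               price = c(2, NA, NA), stringsAsFactors = FALSE),
    data.frame(id = c("r1", "r2"), product = c("X", "TGT"),
               r1 = c("BB", "X"), r2 = NA_character_,
               origin = "fixed", yield = c(0.5, 0.5), score = NA_real_,
               label = "chain", stringsAsFactors = FALSE),
    "TGT")
  diamond <- make_subnetwork(
    data.frame(key = c("A", "B", "TGT"),
               purchasable = c(TRUE, TRUE, FALSE),
               price = c(10, 4, NA), stringsAsFactors = FALSE),
    data.frame(id = c("r_a", "r_b"), product = "TGT",
               r1 = c("A", "B"), r2 = NA_character_,
               origin = "fixed", yield = c(1.0, 0.5), score = NA_real_,
               label = "diamond", stringsAsFactors = FALSE),
    "TGT")
  cycle <- make_subnetwork(
    data.frame(key = c("BB", "A", "B", "TGT"),
               purchasable = c(TRUE, FALSE, FALSE, FALSE),
               price = c(2, NA, NA, NA), stringsAsFactors = FALSE),
    data.frame(id = c("r_ab", "r_ba", "r_bb", "r_t"),
               product = c("A", "B", "B", "TGT"),
               r1 = c("B", "A", "BB", "A"), r2 = NA_character_,
               origin = "fixed", yield = c(0.5, 0.5, 0.5, 1.0),
               score = NA_real_, label = "cycle", stringsAsFactors = FALSE),
    "TGT")
  list(
    chain = list(subnet = chain, target = "TGT",
                 expected = list(costs = 8.0)),
    diamond = list(subnet = diamond, target = "TGT",
                   expected = list(costs = c(8.0, 10.0),
                                   keep_B_route_ids = "r_b",
                                   avoid_r_b_route_ids = "r_a")),
    cycle = list(subnet = cycle, target = "TGT",
                 expected = list(costs = 8.0)))
}
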