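# Phases 2 and 3: subnetwork extraction and the vectorized Dijkstra search
# that returns the k lowest-cost diversified routes from the AND-OR graph.
#
# A subnetwork is the search-facing view of the problem: compounds are OR
# nodes (any producing reaction suffices), reactions are AND edges (all
# reactants are required). Compounds are plain string keys, so the search is
# agnostic to whether keys are canonical SMILES or abstract labels from the
# synthetic-network generator.

#' Cost model
#'
#' Route costs follow the recursion `cost(product) = sum(cost(reactants)) /
#' effective_yield + per_reaction_overhead`, with building-block prices at
#' the leaves. Open leaves admitted into partial routes are priced at
#' `partial_leaf_penalty`, which should dwarf any real price so complete
#' routes always rank first.
#'
#' @param default_fixed_yield Yield assumed for fixed reactions without a
#'   reported yield (default 0.50).
#' @param generated_yield_cap Upper bound on the yield assigned to generated
#'   reactions from their feasibility score (default 0.70).
#' @param partial_leaf_penalty Cost of an unpurchasable leaf in a partial
#'   route (default 10000).
#' @param per_reaction_overhead Additive cost per reaction step (default 0).
#' @export
cost_model <- function(default_fixed_yield = 0.50,
                       generated_yield_cap = 0.70,
                       partial_leaf_penalty = 10000,
                       per_reaction_overhead = 0) {
  stopifnot(default_fixed_yield > 0, default_fixed_yield <= 1,
            generated_yield_cap > 0, generated_yield_cap <= 1,
            partial_leaf_penalty > 0, per_reaction_overhead >= 0)
  structure(list(default_fixed_yield = default_fixed_yield,
                 generated_yield_cap = generated_yield_cap,
                 partial_leaf_penalty = partial_leaf_penalty,
                 per_reaction_overhead = per_reaction_overhead),
            class = "cost_model")
}

#' Search parameters
#'
#' @param k Number of routes requested (default 5).
#' @param max_depth Depth bound used when building the subnetwork
#'   (default `Inf`).
#' @param keep Identifiers (compound keys or reaction ids) every returned
#'   route must contain.
#' @param avoid Identifiers pruned from the subnetwork before searching.
#'   `keep` and `avoid` must be disjoint.
#' @param allow_partial Admit partial routes (open leaves at the penalty
#'   price) when `TRUE` (default `FALSE`).
#' @export
search_params <- function(k = 5L, max_depth = Inf, keep = character(0),
                          avoid = character(0), allow_partial = FALSE) {
  stopifnot(k >= 1L)
  if (length(intersect(keep, avoid))) {
    stop("keep and avoid sets must be disjoint; shared: ",
         paste(intersect(keep, avoid), collapse = ", "), call. = FALSE)
  }
  structure(list(k = as.integer(k), max_depth = max_depth,
                 keep = as.character(keep), avoid = as.character(avoid),
                 allow_partial = isTRUE(allow_partial)),
            class = "search_params")
}

#' Construct a subnetwork
#'
#' @param compounds Data frame with columns `key`, `purchasable` (logical),
#'   `price` (NA when not purchasable).
#' @param reactions Data frame with columns `id`, `product`, `r1`, `r2` (NA
#'   for single-reactant reactions), `origin` (`"generated"` or `"fixed"`),
#'   `yield` (fixed reactions; NA = unreported), `score` (generated
#'   reactions), `label` (template name or source citation).
#' @param target Target compound key (must be present in `compounds`).
#' @export
make_subnetwork <- function(compounds, reactions, target) {
  stopifnot(all(c("key", "purchasable", "price") %in% names(compounds)),
            all(c("id", "product", "r1", "r2", "origin") %in% names(reactions)))
  if (!"yield" %in% names(reactions)) reactions$yield <- NA_real_
  if (!"score" %in% names(reactions)) reactions$score <- NA_real_
  if (!"label" %in% names(reactions)) reactions$label <- ""
  if (!target %in% compounds$key) {
    stop("target ", sQuote(target), " is not in the subnetwork", call. = FALSE)
  }
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids", call. = FALSE)
  ok <- reactions$product %in% compounds$key & reactions$r1 %in% compounds$key &
    (is.na(reactions$r2) | reactions$r2 %in% compounds$key)
  if (!all(ok)) stop("reactions reference unregistered compounds", call. = FALSE)
  structure(list(target = target,
                 compounds = as.data.frame(compounds),
                 reactions = as.data.frame(reactions)),
            class = "synth_subnetwork")
}

#' @export
print.synth_subnetwork <- function(x, ...) {
  cat("<subnetwork> target ", x$target, ": ", nrow(x$compounds),
      " compounds (", sum(x$compounds$purchasable), " purchasable), ",
      nrow(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Extract the subnetwork reachable from the target
#'
#' Walks retrosynthetically from the target over the expanded network's
#' generated reactions merged with fixed-database reactions producing any
#' encountered compound, up to `max_depth` reaction steps, and annotates
#' purchasability and prices from the building-block database.
#'
#' @param target Target key (canonical SMILES).
#' @param network A `reaction_network` from [expand()], or `NULL` to search
#'   fixed reactions only.
#' @param fixed_db A `fixed_reaction_db` or `NULL`.
#' @param building_blocks A `building_block_db` or `NULL`.
#' @param max_depth Maximum number of reaction steps from the target
#'   (default `Inf`); `max_depth = 1` keeps only reactions directly
#'   producing the target.
#' @return A `synth_subnetwork`.
#' @export
build_subnetwork <- function(target, network = NULL, fixed_db = NULL,
                             building_blocks = NULL, max_depth = Inf) {
  gen <- if (!is.null(network)) network$reactions else NULL
  if (!is.null(network) && target != network$target &&
      !target %in% network$compounds$key) {
    stop("target ", sQuote(target), " absent from the expanded network",
         call. = FALSE)
  }
  seen <- c(stats::setNames(0L, target))
  queue <- target
  rxn_rows <- list()
  rxn_ids <- character(0)
  while (length(queue)) {
    key <- queue[1]; queue <- queue[-1]
    d <- seen[[key]]
    if (d >= max_depth) next
    prod_rxns <- list()
    if (!is.null(gen) && nrow(gen)) {
      g <- gen[gen$product == key, , drop = FALSE]
      for (i in seq_len(nrow(g))) {
        prod_rxns[[length(prod_rxns) + 1L]] <- data.frame(
          id = g$id[i], product = g$product[i], r1 = g$r1[i], r2 = g$r2[i],
          origin = "generated", yield = NA_real_, score = g$score[i],
          label = g$label[i], stringsAsFactors = FALSE)
      }
    }
    if (!is.null(fixed_db) && nrow(fixed_db)) {
      fx <- fixed_producers(fixed_db, key)
      for (i in seq_len(nrow(fx))) {
        prod_rxns[[length(prod_rxns) + 1L]] <- data.frame(
          id = paste0("f", match(rownames(fx)[i], rownames(fixed_db))),
          product = fx$product[i], r1 = fx$r1[i], r2 = fx$r2[i],
          origin = "fixed", yield = fx$yield[i], score = NA_real_,
          label = if (nzchar(fx$name[i])) fx$name[i] else fx$source[i],
          stringsAsFactors = FALSE)
      }
    }
    for (rx in prod_rxns) {
      if (rx$id %in% rxn_ids) next
      rxn_ids <- c(rxn_ids, rx$id)
      rxn_rows[[length(rxn_rows) + 1L]] <- rx
      for (r in stats::na.omit(c(rx$r1, rx$r2))) {
        if (!(r %in% names(seen))) {
          seen[[r]] <- d + 1L
          queue <- c(queue, r)
        }
      }
    }
  }
  keys <- names(seen)
  price <- bb_price(building_blocks, keys)
  compounds <- data.frame(key = keys, purchasable = !is.na(price),
                          price = price, stringsAsFactors = FALSE)
  reactions <- if (length(rxn_rows)) do.call(rbind, rxn_rows) else
    data.frame(id = character(0), product = character(0), r1 = character(0),
               r2 = character(0), origin = character(0), yield = numeric(0),
               score = numeric(0), label = character(0),
               stringsAsFactors = FALSE)
  make_subnetwork(compounds, reactions, target)
}

#' Effective yield of a reaction
#'
#' Fixed reactions use their reported yield when present, else the default;
#' generated reactions use their feasibility score capped at
#' `generated_yield_cap`.
#'
#' @param reaction One reaction (a list or one-row data frame with `origin`
#'   and `yield` or `score`).
#' @param cm A [cost_model()].
#' @return Yield in `(0, 1]`.
#' @export
effective_yield <- function(reaction, cm = cost_model()) {
  reaction <- as.list(reaction)
  if (identical(reaction$origin, "fixed")) {
    y <- reaction$yield
    if (is.null(y) || is.na(y)) return(cm$default_fixed_yield)
    if (y <= 0 || y > 1) stop("reported yield outside (0,1]: ", y, call. = FALSE)
    return(y)
  }
  s <- reaction$score
  if (is.null(s) || is.na(s)) stop("generated reaction without a score",
                                   call. = FALSE)
  min(s, cm$generated_yield_cap)
}

#' Cost of one reaction step
#'
#' @param reactant_costs Positive costs of the reactant sub-routes.
#' @param yield Effective yield in `(0, 1]`.
#' @param cm A [cost_model()].
#' @return `sum(reactant_costs) / yield + per_reaction_overhead`.
#' @export
reaction_cost <- function(reactant_costs, yield, cm = cost_model()) {
  stopifnot(all(reactant_costs > 0), yield > 0, yield <= 1)
  sum(reactant_costs) / yield + cm$per_reaction_overhead
}

# ---- internal: binary min-heap keyed by (cost, seq) ----------------------

heap_new <- function() {
  env <- new.env(parent = emptyenv())
  env$cost <- numeric(0)
  env$seq <- numeric(0)
  env$item <- list()
  env
}

heap_push <- function(h, cost, seq, item) {
  n <- length(h$cost) + 1L
  h$cost[n] <- cost; h$seq[n] <- seq; h$item[[n]] <- item
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (h$cost[p] < h$cost[i] ||
        (h$cost[p] == h$cost[i] && h$seq[p] <= h$seq[i])) break
    tmp <- h$cost[p]; h$cost[p] <- h$cost[i]; h$cost[i] <- tmp
    tmp <- h$seq[p]; h$seq[p] <- h$seq[i]; h$seq[i] <- tmp
    tmp <- h$item[[p]]; h$item[[p]] <- h$item[[i]]; h$item[[i]] <- tmp
    i <- p
  }
  invisible(h)
}

heap_pop <- function(h) {
  n <- length(h$cost)
  if (n == 0L) return(NULL)
  top <- h$item[[1L]]
  h$cost[1L] <- h$cost[n]; h$seq[1L] <- h$seq[n]; h$item[[1L]] <- h$item[[n]]
  h$cost <- h$cost[-n]; h$seq <- h$seq[-n]
  h$item[[n]] <- NULL
  n <- n - 1L
  i <- 1L
  while (TRUE) {
    l <- 2L * i; r <- l + 1L; m <- i
    if (l <= n && (h$cost[l] < h$cost[m] ||
                   (h$cost[l] == h$cost[m] && h$seq[l] < h$seq[m]))) m <- l
    if (r <= n && (h$cost[r] < h$cost[m] ||
                   (h$cost[r] == h$cost[m] && h$seq[r] < h$seq[m]))) m <- r
    if (m == i) break
    tmp <- h$cost[m]; h$cost[m] <- h$cost[i]; h$cost[i] <- tmp
    tmp <- h$seq[m]; h$seq[m] <- h$seq[i]; h$seq[i] <- tmp
    tmp <- h$item[[m]]; h$item[[m]] <- h$item[[i]]; h$item[[i]] <- tmp
    i <- m
  }
  top
}

# route entry: list(cost, rset (sorted reaction ids), compounds (unique keys
# in the tree), n_reactions (tree nodes with a reaction), tree)
leaf_entry <- function(key, price) {
  list(cost = price, rset = character(0), compounds = key, n_reactions = 0L,
       tree = list(compound = key, reaction = NULL, children = list()))
}

#' k lowest-cost diversified routes (vectorized Dijkstra)
#'
#' Each compound node accumulates up to `k` (cost, route) entries, admitted
#' in nondecreasing cost order. The candidate heap is initialized with the
#' reactions whose reactants are all purchasable; at each step the minimum
#' cost candidate is popped and, if valid, admitted as its product's next
#' value, after which new candidates are formed by combining it with the
#' stored entries of every co-reactant of reactions consuming the product.
#' Two routes are considered distinct only if their reaction sets differ
#' (the diversity rule); candidates repeating a compound on a root-to-leaf
#' path are discarded, which keeps the search correct on cyclic graphs.
#'
#' @param subnet A `synth_subnetwork`.
#' @param params A [search_params()] (only `k` and `allow_partial` are used
#'   here; see [constrained_search()] for keep/avoid).
#' @param cm A [cost_model()].
#' @param target Target key; defaults to the subnetwork's target.
#' @return List of `synth_route` objects sorted by cost ascending (at most
#'   `k`). A route is a list with `root`, `tree`, `cost`, `n_reactions`,
#'   `leaves`, `is_partial`, `reaction_ids`.
#' @export
k_best_routes <- function(subnet, params = search_params(), cm = cost_model(),
                          target = subnet$target) {
  stopifnot(inherits(subnet, "synth_subnetwork"))
  k <- params$k
  comp <- subnet$compounds
  rxn <- subnet$reactions
  n_rxn <- nrow(rxn)
  yields <- if (n_rxn) vapply(seq_len(n_rxn), function(i)
    effective_yield(rxn[i, ], cm), numeric(1)) else numeric(0)
  rxn_reactants <- lapply(seq_len(n_rxn), function(i)
    as.character(stats::na.omit(c(rxn$r1[i], rxn$r2[i]))))
  # purchasable compounds are leaves of the search; they are never treated
  # as reaction products
  purch <- stats::setNames(comp$price, comp$key)[comp$purchasable]
  consumers <- lapply(stats::setNames(seq_len(nrow(comp)), comp$key),
                      function(i) integer(0))
  for (i in seq_len(n_rxn)) {
    if (rxn$product[i] %in% names(purch)) next
    for (r in unique(rxn_reactants[[i]])) {
      consumers[[r]] <- c(consumers[[r]], i)
    }
  }
  entries <- lapply(stats::setNames(seq_len(nrow(comp)), comp$key),
                    function(i) list())
  h <- heap_new()
  seq_no <- 0L

  push_candidates <- function(key, new_entry) {
    for (i in consumers[[key]]) {
      rs <- rxn_reactants[[i]]
      others <- rs[rs != key]
      combos <- if (length(others) == 0L) {
        if (length(rs) == 2L) {
          # the same compound twice: pair the new entry with every stored
          # entry plus itself
          lapply(entries[[key]], function(e) list(new_entry, e))
        } else {
          list(list(new_entry))
        }
      } else {
        lapply(entries[[others]], function(e) list(new_entry, e))
      }
      for (parts in combos) {
        # order parts to match (r1, r2)
        if (length(rs) == 2L && parts[[1]]$tree$compound != rs[1]) {
          parts <- rev(parts)
        }
        cost <- reaction_cost(vapply(parts, `[[`, numeric(1), "cost"),
                              yields[i], cm)
        seq_no <<- seq_no + 1L
        heap_push(h, cost, seq_no, list(cost = cost, rxn = i, parts = parts))
      }
    }
  }

  admit <- function(key, entry) {
    es <- entries[[key]]
    if (length(es) >= k) return(FALSE)
    for (e in es) if (identical(e$rset, entry$rset)) return(FALSE)
    entries[[key]] <<- c(es, list(entry))
    push_candidates(key, entry)
    TRUE
  }

  # seed: purchasable leaves, then (optionally) penalty leaves for open
  # dead-end compounds
  for (key in names(purch)) admit(key, leaf_entry(key, purch[[key]]))
  if (params$allow_partial) {
    producible <- unique(rxn$product)
    for (key in comp$key) {
      if (!(key %in% names(purch)) && !(key %in% producible)) {
        admit(key, leaf_entry(key, cm$partial_leaf_penalty))
      }
    }
  }

  while (length(entries[[target]]) < k) {
    cand <- heap_pop(h)
    if (is.null(cand)) break
    i <- cand$rxn
    p <- rxn$product[i]
    if (length(entries[[p]]) >= k) next
    # repetition check: the product must not occur inside any branch
    if (any(vapply(cand$parts, function(e) p %in% e$compounds, logical(1)))) next
    rset <- sort(unique(c(rxn$id[i],
                          unlist(lapply(cand$parts, `[[`, "rset"),
                                 use.names = FALSE))))
    dup <- FALSE
    for (e in entries[[p]]) if (identical(e$rset, rset)) { dup <- TRUE; break }
    if (dup) next
    entry <- list(
      cost = cand$cost, rset = rset,
      compounds = unique(c(p, unlist(lapply(cand$parts, `[[`, "compounds"),
                                     use.names = FALSE))),
      n_reactions = 1L + sum(vapply(cand$parts, `[[`, integer(1),
                                    "n_reactions")),
      tree = list(compound = p, reaction = rxn$id[i],
                  children = lapply(cand$parts, `[[`, "tree")))
    admit(p, entry)
  }

  routes <- Filter(function(e) e$n_reactions > 0L, entries[[target]])
  lapply(routes, function(e) finish_route(e, target, names(purch)))
}

finish_route <- function(entry, target, purch_keys) {
  leaves <- character(0)
  walk <- function(node) {
    if (is.null(node$reaction)) {
      leaves <<- c(leaves, node$compound)
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(entry$tree)
  structure(list(root = target, tree = entry$tree, cost = entry$cost,
                 n_reactions = entry$n_reactions,
                 reaction_ids = entry$rset, leaves = leaves,
                 is_partial = !all(leaves %in% purch_keys)),
            class = "synth_route")
}

#' @export
print.synth_route <- function(x, ...) {
  cat(sprintf("<route> to %s: cost %.4g, %d reaction(s)%s; leaves: %s\n",
              x$root, x$cost, x$n_reactions,
              if (x$is_partial) " [PARTIAL]" else "",
              paste(x$leaves, collapse = ", ")))
  invisible(x)
}

#' Exhaustive k-best oracle
#'
#' Enumerates every valid synthesis tree by depth-first recursion with an
#' ancestor ban-set (so root-to-leaf paths are repetition-free even on
#' cyclic graphs), costs them with the same recursion as the search,
#' deduplicates by reaction set, sorts, and truncates to `k`. Intended as an
#' independent test oracle for [k_best_routes()] on small subnetworks; it
#' refuses networks above the size guard.
#'
#' @inheritParams k_best_routes
#' @param k Number of routes.
#' @param max_compounds,max_reactions Size guard (defaults 15 and 20).
#' @export
brute_force_k_best <- function(subnet, k, cm = cost_model(),
                               target = subnet$target,
                               allow_partial = FALSE,
                               max_compounds = 15L, max_reactions = 20L) {
  stopifnot(inherits(subnet, "synth_subnetwork"))
  if (nrow(subnet$compounds) > max_compounds ||
      nrow(subnet$reactions) > max_reactions) {
    stop("subnetwork too large for the brute-force oracle", call. = FALSE)
  }
  comp <- subnet$compounds
  rxn <- subnet$reactions
  purch <- stats::setNames(comp$price, comp$key)[comp$purchasable]
  producible <- unique(rxn$product)
  yields <- if (nrow(rxn)) vapply(seq_len(nrow(rxn)), function(i)
    effective_yield(rxn[i, ], cm), numeric(1)) else numeric(0)

  enum <- function(key, banned) {
    if (key %in% names(purch)) return(list(leaf_entry(key, purch[[key]])))
    if (!(key %in% producible)) {
      if (allow_partial) return(list(leaf_entry(key, cm$partial_leaf_penalty)))
      return(list())
    }
    out <- list()
    for (i in which(rxn$product == key)) {
      rs <- as.character(stats::na.omit(c(rxn$r1[i], rxn$r2[i])))
      if (any(rs %in% c(banned, key))) next
      sub <- lapply(rs, enum, banned = c(banned, key))
      if (any(vapply(sub, length, integer(1)) == 0L)) next
      idx <- expand.grid(lapply(sub, seq_along))
      for (row in seq_len(nrow(idx))) {
        parts <- lapply(seq_along(rs), function(j) sub[[j]][[idx[row, j]]])
        cost <- reaction_cost(vapply(parts, `[[`, numeric(1), "cost"),
                              yields[i], cm)
        out[[length(out) + 1L]] <- list(
          cost = cost,
          rset = sort(unique(c(rxn$id[i],
                               unlist(lapply(parts, `[[`, "rset"),
                                      use.names = FALSE)))),
          compounds = unique(c(key, unlist(lapply(parts, `[[`, "compounds"),
                                           use.names = FALSE))),
          n_reactions = 1L + sum(vapply(parts, `[[`, integer(1),
                                        "n_reactions")),
          tree = list(compound = key, reaction = rxn$id[i],
                      children = lapply(parts, `[[`, "tree")))
      }
    }
    out
  }

  all_routes <- Filter(function(e) e$n_reactions > 0L,
                       enum(target, character(0)))
  if (!length(all_routes)) return(list())
  ord <- order(vapply(all_routes, `[[`, numeric(1), "cost"))
  all_routes <- all_routes[ord]
  seen <- list(); kept <- list()
  for (e in all_routes) {
    key <- paste(e$rset, collapse = "|")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    kept[[length(kept) + 1L]] <- e
    if (length(kept) >= k) break
  }
  lapply(kept, function(e) finish_route(e, target, names(purch)))
}

#' Group routes into strategies
#'
#' A strategy is the set of routes sharing the reaction that directly
#' produces the target. Strategies are ordered by their best member's cost;
#' routes within a strategy by cost ascending.
#'
#' @param routes List of `synth_route` objects (same target).
#' @return An object of class `route_strategies`: a list of
#'   `list(final_reaction, routes)`.
#' @export
group_strategies <- function(routes) {
  if (!length(routes)) return(structure(list(), class = "route_strategies"))
  finals <- vapply(routes, function(r) r$tree$reaction, character(1))
  costs <- vapply(routes, `[[`, numeric(1), "cost")
  groups <- split(seq_along(routes), finals)
  best <- vapply(groups, function(ix) min(costs[ix]), numeric(1))
  groups <- groups[order(best)]
  structure(lapply(groups, function(ix) {
    ix <- ix[order(costs[ix])]
    list(final_reaction = finals[ix[1]], routes = routes[ix])
  }), class = "route_strategies")
}

#' @export
print.route_strategies <- function(x, ...) {
  cat("<strategies> ", length(x), " strategies\n", sep = "")
  for (i in seq_along(x)) {
    cat(sprintf("  [%d] final reaction %s: %d route(s), best cost %.4g\n",
                i, x[[i]]$final_reaction, length(x[[i]]$routes),
                x[[i]]$routes[[1]]$cost))
  }
  invisible(x)
}

#' Route search with keep/avoid constraints
#'
#' Members of the avoid set (compound keys or reaction ids) are pruned from
#' the subnetwork before searching; every returned route contains all keep
#' members. Because keep filtering is applied to the pool of routes found,
#' the search internally requests `search_k` routes before filtering.
#'
#' @inheritParams k_best_routes
#' @param search_k Internal pool size before keep-filtering (default
#'   `max(8 * k, 32)`).
#' @return At most `params$k` routes satisfying the constraints.
#' @export
constrained_search <- function(subnet, params = search_params(),
                               cm = cost_model(), target = subnet$target,
                               search_k = max(8L * params$k, 32L)) {
  if (length(intersect(params$keep, params$avoid))) {
    stop("keep and avoid sets must be disjoint", call. = FALSE)
  }
  comp <- subnet$compounds
  rxn <- subnet$reactions
  if (length(params$avoid)) {
    if (target %in% params$avoid) stop("cannot avoid the target", call. = FALSE)
    comp <- comp[!(comp$key %in% params$avoid), , drop = FALSE]
    drop_rxn <- rxn$id %in% params$avoid |
      rxn$product %in% params$avoid | rxn$r1 %in% params$avoid |
      (!is.na(rxn$r2) & rxn$r2 %in% params$avoid)
    rxn <- rxn[!drop_rxn, , drop = FALSE]
  }
  pruned <- make_subnetwork(comp, rxn, target)
  pool_params <- search_params(k = search_k,
                               allow_partial = params$allow_partial)
  pool <- k_best_routes(pruned, pool_params, cm, target)
  if (length(params$keep)) {
    pool <- Filter(function(r) {
      ids <- c(r$reaction_ids, unique_route_compounds(r))
      all(params$keep %in% ids)
    }, pool)
  }
  if (length(pool) > params$k) pool <- pool[seq_len(params$k)]
  pool
}

unique_route_compounds <- function(route) {
  out <- character(0)
  walk <- function(node) {
    out <<- c(out, node$compound)
    for (ch in node$children) walk(ch)
  }
  walk(route$tree)
  unique(out)
}
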