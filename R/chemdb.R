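# Readers and writers for the two external databases (purchasable building
# blocks, fixed single-step reactions) and for route search results.

#' Read a building-block database
#'
#' Loads a vendor catalog CSV with columns `smiles,id,price,vendor,tier`.
#' Structures are canonicalized; rows whose tier is not in `tiers` are
#' dropped (tiers 1 and 2 correspond to fast-shipping stock); duplicate
#' structures keep the minimum price; unparsable SMILES are skipped with a
#' message.
#'
#' @param path CSV path.
#' @param tiers Integer allow-list of tiers (default `c(1, 2)`).
#' @return An object of class `building_block_db` (a data frame keyed by
#'   canonical SMILES with `price`, `vendor`, `tier`, `id`).
#' @export
read_building_blocks <- function(path, tiers = c(1L, 2L)) {
  if (!file.exists(path)) stop("building-block file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("smiles", "id", "price", "vendor", "tier")
  if (!all(need %in% names(df))) {
    stop("building-block CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[df$tier %in% tiers, , drop = FALSE]
  if (nrow(df)) {
    can <- chem_canon(df$smiles)
    n_bad <- sum(is.na(can))
    if (n_bad) message("read_building_blocks: skipped ", n_bad,
                       " unparsable SMILES row(s)")
    df$smiles <- can
    df <- df[!is.na(can) & !is.na(df$price) & df$price > 0, , drop = FALSE]
    df <- df[order(df$smiles, df$price), , drop = FALSE]
    df <- df[!duplicated(df$smiles), , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df[, need], class = c("building_block_db", "data.frame"))
}

#' Construct a building-block database in memory
#'
#' @param smiles,price,vendor,tier,id Parallel vectors describing one
#'   building block per element.
#' @param canonical Set to `TRUE` when `smiles` are already canonical keys
#'   (skips the backend round trip; used by the synthetic-network
#'   generators whose keys are abstract).
#' @export
building_block_db <- function(smiles, price, vendor = "synthetic",
                              tier = 1L, id = NULL, canonical = FALSE) {
  if (!canonical) smiles <- canonicalize(smiles)
  stopifnot(all(price > 0))
  df <- data.frame(smiles = smiles, id = if (is.null(id)) seq_along(smiles) else id,
                   price = as.numeric(price),
                   vendor = rep_len(vendor, length(smiles)),
                   tier = rep_len(as.integer(tier), length(smiles)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$smiles, df$price), , drop = FALSE]
  df <- df[!duplicated(df$smiles), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("building_block_db", "data.frame"))
}

bb_price <- function(db, smiles) {
  if (is.null(db) || nrow(db) == 0L) return(rep(NA_real_, length(smiles)))
  db$price[match(smiles, db$smiles)]
}

#' Read a fixed single-step reaction database
#'
#' Loads a TSV with columns `reaction_smiles` (the
#' `reactants>agents>product` dialect; agents are kept as metadata but play
#' no role in search), `yield` (fraction in (0,1] or empty), `name`,
#' `source`. Records with more than two reactants or not exactly one
#' single-fragment product are dropped, as are degenerate records whose
#' product equals a reactant; out-of-range yields are treated as unreported.
#'
#' @param path TSV path.
#' @return An object of class `fixed_reaction_db`: a data frame with columns
#'   `r1`, `r2` (NA when absent), `product`, `yield`, `agents`, `name`,
#'   `source`.
#' @export
read_reaction_db <- function(path) {
  if (!file.exists(path)) stop("reaction file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("reaction_smiles", "yield", "name", "source")
  if (!all(need %in% names(df))) {
    stop("reaction TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  recs <- list(); dropped <- 0L; bad_yield <- 0L
  for (i in seq_len(nrow(df))) {
    parts <- strsplit(df$reaction_smiles[i], ">", fixed = TRUE)[[1]]
    if (length(parts) == 2L) parts <- c(parts[1], "", parts[2])
    if (length(parts) != 3L) { dropped <- dropped + 1L; next }
    reactants <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
    products <- strsplit(parts[3], ".", fixed = TRUE)[[1]]
    if (length(reactants) < 1L || length(reactants) > 2L ||
        length(products) != 1L) { dropped <- dropped + 1L; next }
    can <- chem_canon(c(reactants, products))
    if (anyNA(can)) { dropped <- dropped + 1L; next }
    prod <- can[length(can)]
    rs <- can[-length(can)]
    if (prod %in% rs) { dropped <- dropped + 1L; next }
    y <- suppressWarnings(as.numeric(df$yield[i]))
    if (!is.na(y) && (y <= 0 || y > 1)) { bad_yield <- bad_yield + 1L; y <- NA_real_ }
    recs[[length(recs) + 1L]] <- data.frame(
      r1 = rs[1], r2 = if (length(rs) == 2L) rs[2] else NA_character_,
      product = prod, yield = y, agents = parts[2],
      name = df$name[i], source = df$source[i], stringsAsFactors = FALSE)
  }
  if (dropped) message("read_reaction_db: dropped ", dropped,
                       " malformed/out-of-shape record(s)")
  if (bad_yield) warning("read_reaction_db: ", bad_yield,
                         " yield value(s) outside (0,1] treated as unreported",
                         call. = FALSE)
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(r1 = character(0), r2 = character(0), product = character(0),
               yield = numeric(0), agents = character(0), name = character(0),
               source = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("fixed_reaction_db", "data.frame"))
}

#' Construct a fixed reaction database in memory
#'
#' @param r1,r2,product,yield,name,source Parallel vectors (use `NA` in `r2`
#'   for single-reactant records).
#' @export
fixed_reaction_db <- function(r1, r2 = NA_character_, product,
                              yield = NA_real_, name = "", source = "") {
  df <- data.frame(r1 = r1, r2 = rep_len(r2, length(r1)), product = product,
                   yield = rep_len(as.numeric(yield), length(r1)),
                   agents = "", name = rep_len(name, length(r1)),
                   source = rep_len(source, length(r1)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("fixed_reaction_db", "data.frame"))
}

# reactions of the fixed database producing `smiles`
fixed_producers <- function(db, smiles) {
  if (is.null(db) || nrow(db) == 0L) return(db)
  db[db$product == smiles, , drop = FALSE]
}

#' Write / read route search results
#'
#' Serializes a search result (routes or strategies plus their subnetwork
#' context) to a JSON document: target, parameters, and a `strategies` array
#' whose routes list reactions in dependency order with their origin,
#' template or source, effective yield and feasibility score, the priced
#' leaves, total cost and the partial flag.
#'
#' @param routes A list of `synth_route` objects (or a `route_strategies`
#'   object from [group_strategies()]).
#' @param subnet The `synth_subnetwork` the routes were extracted from.
#' @param path Output JSON path.
#' @param params Optional list of search parameters echoed in the document.
#' @param cm The [cost_model()] used (for effective yields).
#' @return `write_routes` returns `path` invisibly; `read_routes` the parsed
#'   document.
#' @export
write_routes <- function(routes, subnet, path, params = list(),
                         cm = cost_model()) {
  strategies <- if (inherits(routes, "route_strategies")) routes
                else group_strategies(routes)
  doc <- list(
    target = subnet$target,
    params = params,
    n_routes = sum(vapply(strategies, function(s) length(s$routes), integer(1))),
    strategies = lapply(strategies, function(s) {
      list(final_reaction = s$final_reaction,
           routes = lapply(s$routes, route_record, subnet = subnet, cm = cm))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_routes
#' @export
read_routes <- function(path) {
  jsonlite::read_json(path)
}

# flat JSON-able record of one route (reactions in dependency order:
# children before the reaction consuming them)
route_record <- function(route, subnet, cm = cost_model()) {
  rxn_idx <- stats::setNames(seq_len(nrow(subnet$reactions)),
                             subnet$reactions$id)
  steps <- list()
  leaves <- list()
  walk <- function(node) {
    if (is.null(node$reaction)) {
      price <- subnet$compounds$price[match(node$compound, subnet$compounds$key)]
      leaves[[length(leaves) + 1L]] <<- list(
        smiles = node$compound,
        price = if (is.na(price)) NULL else price,
        purchasable = !is.na(price))
      return(invisible(NULL))
    }
    for (ch in node$children) walk(ch)
    rx <- subnet$reactions[rxn_idx[[node$reaction]], ]
    steps[[length(steps) + 1L]] <<- list(
      id = rx$id,
      product = rx$product,
      reactants = as.list(stats::na.omit(c(rx$r1, rx$r2))),
      origin = rx$origin,
      label = rx$label,
      effective_yield = effective_yield(rx, cm),
      feasibility_score = if (rx$origin == "generated") rx$score else NULL)
    invisible(NULL)
  }
  walk(route$tree)
  list(cost = route$cost, n_reactions = route$n_reactions,
       is_partial = route$is_partial, reactions = steps, leaves = leaves)
}

#' Flat route table
#'
#' @param strategies A `route_strategies` object.
#' @return A data frame with one row per route: `route_id`, `rank`, `cost`,
#'   `n_reactions`, `is_partial`, `strategy_id`.
#' @export
route_table <- function(strategies) {
  rows <- list()
  rank <- 0L
  for (si in seq_along(strategies)) {
    for (r in strategies[[si]]$routes) {
      rank <- rank + 1L
      rows[[rank]] <- data.frame(route_id = rank, rank = rank, cost = r$cost,
                                 n_reactions = r$n_reactions,
                                 is_partial = r$is_partial, strategy_id = si)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(route_id = integer(0), rank = integer(0), cost = numeric(0),
               n_reactions = integer(0), is_partial = logical(0),
               strategy_id = integer(0))
  out <- out[order(out$cost), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
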