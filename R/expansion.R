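# Phase 1: grow a network of template-generated reactions from the target
# toward purchasable or known-synthesizable compounds under a budget on the
# number of kept generated reactions.

#' Expansion configuration
#'
#' @param algorithm One of `"breadth_first"`, `"depth_first"`,
#'   `"best_first_compound"`, `"best_first_reaction"`.
#' @param alpha Depth-discount exponent of the best-first priorities
#'   (default 1.1): a compound at depth `d` is scored
#'   `heavy_atoms * d^alpha`, so deeper compounds are selected later.
#' @param max_generated Budget on kept generated reactions.
#' @param max_depth Depth cutoff (default 10); depth-first never expands a
#'   compound at or beyond it.
#' @param score_threshold Feasibility score below which a generated reaction
#'   is rejected (default 0.2).
#' @param default_score Score for templates without a trained classifier
#'   (default 0.5).
#' @param seed Integer seed (the expansion itself is deterministic; the seed
#'   is recorded for provenance).
#' @export
expansion_config <- function(algorithm = c("best_first_reaction",
                                           "best_first_compound",
                                           "breadth_first", "depth_first"),
                             alpha = 1.1, max_generated = 100L,
                             max_depth = 10L, score_threshold = 0.2,
                             default_score = 0.5, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(alpha > 0, max_generated >= 0L, max_depth >= 1L,
            score_threshold >= 0, score_threshold <= 1)
  structure(list(algorithm = algorithm, alpha = alpha,
                 max_generated = as.integer(max_generated),
                 max_depth = as.integer(max_depth),
                 score_threshold = score_threshold,
                 default_score = default_score, seed = as.integer(seed)),
            class = "expansion_config")
}

#' Terminal status of a compound
#'
#' A compound is `purchasable` when present in the building-block database
#' (this takes precedence), `known_synthesizable` when it is the product of
#' at least one fixed reaction, and `open` otherwise. Terminal compounds are
#' never expanded by templates.
#'
#' @param compound SMILES key (canonical).
#' @param building_blocks A `building_block_db` or `NULL`.
#' @param fixed_db A `fixed_reaction_db` or `NULL`.
#' @return One of `"purchasable"`, `"known_synthesizable"`, `"open"`.
#' @export
terminal_status <- function(compound, building_blocks = NULL, fixed_db = NULL) {
  if (!is.null(building_blocks) && nrow(building_blocks) &&
      compound %in% building_blocks$smiles) {
    return("purchasable")
  }
  if (!is.null(fixed_db) && nrow(fixed_db) && compound %in% fixed_db$product) {
    return("known_synthesizable")
  }
  "open"
}

#' Expansion priority of a compound
#'
#' `heavy_atoms(compound) * depth^alpha`; lower values are selected first,
#' so small molecules close to the target are expanded before large or deep
#' ones.
#'
#' @param compound A molecule, a SMILES string, or a heavy-atom count.
#' @param depth Depth from the target (the target has depth 0; its direct
#'   precursors depth 1). Must be at least 1.
#' @param alpha Depth-discount exponent (default 1.1).
#' @export
compound_priority <- function(compound, depth, alpha = 1.1) {
  stopifnot(depth >= 1)
  h <- if (is.numeric(compound)) compound else heavy_atoms(mol_smiles(compound))
  h * depth^alpha
}

#' Expansion priority of a generated reaction
#'
#' The maximum heavy-atom count over the reaction's reactants multiplied by
#' `depth^alpha`, where `depth` is the reaction's depth. The factor is
#' applied once.
#'
#' @param reaction A list with elements `reactants` (SMILES) and `depth`, or
#'   heavy-atom counts directly via `heavy`.
#' @param alpha Depth-discount exponent (default 1.1).
#' @export
reaction_priority <- function(reaction, alpha = 1.1) {
  h <- if (!is.null(reaction$heavy)) max(reaction$heavy)
       else max(heavy_atoms(reaction$reactants))
  stopifnot(reaction$depth >= 1)
  h * reaction$depth^alpha
}

#' Retrosynthetic network expansion
#'
#' Iteratively selects a compound (or reaction) according to the configured
#' algorithm, one-step expands it with every applicable retro-template,
#' scores each candidate disconnection with the template's feasibility
#' classifier, keeps candidates scoring at least the threshold, and
#' registers their reactants. Terminal compounds (purchasable or
#' known-synthesizable) are never expanded; expansion stops when the budget
#' of kept generated reactions is exhausted or the frontier empties.
#'
#' Selection semantics: `breadth_first` pops open compounds FIFO;
#' `depth_first` LIFO with the `max_depth` cutoff; `best_first_compound`
#' pops the open compound with minimum [compound_priority()];
#' `best_first_reaction` pops the kept reaction with minimum
#' [reaction_priority()] and one-step expands all of its open reactants.
#' Ties are broken by insertion order.
#'
#' @param target Target SMILES (single molecule).
#' @param library A `retro_template_library`.
#' @param classifiers Named list of `template_classifier` objects (by
#'   template_id), or `NULL` to score every template with the default.
#' @param building_blocks A `building_block_db` or `NULL`.
#' @param fixed_db A `fixed_reaction_db` or `NULL`.
#' @param cfg An [expansion_config()].
#' @return An object of class `reaction_network`: list with `target`,
#'   `compounds` (data frame: `key`, `depth`, `status`), `reactions` (data
#'   frame of kept generated reactions: `id`, `product`, `r1`, `r2`,
#'   `template_id`, `label`, `score`, `depth`) and `counters` (generated,
#'   rejected, expanded).
#' @export
expand <- function(target, library, classifiers = NULL,
                   building_blocks = NULL, fixed_db = NULL,
                   cfg = expansion_config()) {
  target <- canonicalize(target)
  if (chem_nfrag(target) != 1L) {
    stop("target must be a single-fragment molecule: ", sQuote(target),
         call. = FALSE)
  }
  st <- new.env(parent = emptyenv())
  st$depth <- c(stats::setNames(0L, target))
  st$status <- c(stats::setNames(terminal_status(target, building_blocks,
                                                 fixed_db), target))
  st$ancestors <- list()
  st$ancestors[[target]] <- character(0)
  st$expanded <- character(0)
  st$rxn <- list()
  st$rxn_keys <- character(0)
  st$n_rejected <- 0L
  st$seq <- 0L

  # frontier of open compounds: parallel vectors (key, insertion seq)
  frontier_keys <- character(0)
  frontier_seq <- integer(0)
  push_compound <- function(key) {
    st$seq <- st$seq + 1L
    frontier_keys <<- c(frontier_keys, key)
    frontier_seq <<- c(frontier_seq, st$seq)
  }
  # best-first-reaction frontier: reactions not yet processed
  rxn_queue <- integer(0)

  pats <- vapply(library$smirks, product_pattern, character(1),
                 USE.NAMES = FALSE)

  budget_left <- function() length(st$rxn) < cfg$max_generated

  # one-step expansion of a single compound; returns FALSE when the budget
  # was exhausted mid-way
  expand_compound <- function(key) {
    if (key %in% st$expanded) return(TRUE)
    st$expanded <- c(st$expanded, key)
    if (nrow(library) == 0L) return(TRUE)
    d <- st$depth[[key]] + 1L
    hit <- which(chem_match_many(pats, key)[, 1])
    if (!length(hit)) return(TRUE)
    all_sets <- chem_retro_multi(library$smirks[hit], key)
    banned <- c(st$ancestors[[key]], key)
    for (j in seq_along(hit)) {
      ti <- hit[j]
      tid <- library$template_id[ti]
      sets <- Filter(function(rs) {
        length(rs) == library$n_reactants[ti] && !any(rs %in% banned)
      }, all_sets[[j]])
      if (!length(sets)) next
      # drop duplicates already in the network (same product/template/set)
      keys <- vapply(sets, function(rs) {
        paste(key, tid, paste(sort(rs), collapse = "|"), sep = "##")
      }, character(1))
      new <- !(keys %in% st$rxn_keys)
      sets <- sets[new]; keys <- keys[new]
      if (!length(sets)) next
      scores <- feasibility_scores(classifiers[[tid]], sets, key,
                                   default_score = cfg$default_score)
      for (s in seq_along(sets)) {
        if (scores[s] < cfg$score_threshold) {
          st$n_rejected <- st$n_rejected + 1L
          next
        }
        if (!budget_left()) return(FALSE)
        rs <- sets[[s]]
        rid <- sprintf("g%04d", length(st$rxn) + 1L)
        st$rxn[[length(st$rxn) + 1L]] <- list(
          id = rid, product = key, reactants = rs, template_id = tid,
          label = library$reaction_name[ti], score = scores[s], depth = d,
          heavy = chem_heavy(rs))
        st$rxn_keys <- c(st$rxn_keys, keys[s])
        if (cfg$algorithm == "best_first_reaction") {
          rxn_queue <<- c(rxn_queue, length(st$rxn))
        }
        for (r in rs) {
          if (!(r %in% names(st$depth))) {
            st$depth[[r]] <- d
            st$status[[r]] <- terminal_status(r, building_blocks, fixed_db)
            st$ancestors[[r]] <- banned
            if (st$status[[r]] == "open" &&
                cfg$algorithm != "best_first_reaction") {
              push_compound(r)
            }
          } else if (d < st$depth[[r]]) {
            st$depth[[r]] <- d  # keep the minimum observed depth
          }
        }
      }
    }
    TRUE
  }

  pop_compound <- function() {
    if (!length(frontier_keys)) return(NULL)
    i <- switch(cfg$algorithm,
      breadth_first = 1L,
      depth_first = length(frontier_keys),
      best_first_compound = {
        pr <- vapply(frontier_keys, function(k) {
          compound_priority(chem_heavy(k), max(st$depth[[k]], 1L), cfg$alpha)
        }, numeric(1), USE.NAMES = FALSE)
        order(pr, frontier_seq)[1]
      })
    key <- frontier_keys[i]
    frontier_keys <<- frontier_keys[-i]
    frontier_seq <<- frontier_seq[-i]
    key
  }

  if (cfg$max_generated > 0L && st$status[[target]] != "purchasable") {
    if (cfg$algorithm == "best_first_reaction") {
      expand_compound(target)
      while (length(rxn_queue) && budget_left()) {
        pr <- vapply(rxn_queue, function(i) {
          rx <- st$rxn[[i]]
          max(rx$heavy) * rx$depth^cfg$alpha
        }, numeric(1))
        i <- rxn_queue[order(pr, rxn_queue)[1]]
        rxn_queue <- setdiff(rxn_queue, i)
        rx <- st$rxn[[i]]
        ok <- TRUE
        for (r in rx$reactants) {
          if (st$status[[r]] == "open" && !(r %in% st$expanded)) {
            ok <- expand_compound(r)
            if (!ok) break
          }
        }
        if (!ok) break
      }
    } else {
      push_compound(target)
      while (budget_left()) {
        key <- pop_compound()
        if (is.null(key)) break
        if (cfg$algorithm == "depth_first" &&
            st$depth[[key]] >= cfg$max_depth) next
        if (!expand_compound(key)) break
      }
    }
  }

  rxn_df <- if (length(st$rxn)) {
    do.call(rbind, lapply(st$rxn, function(rx) {
      data.frame(id = rx$id, product = rx$product, r1 = rx$reactants[1],
                 r2 = if (length(rx$reactants) == 2L) rx$reactants[2] else NA_character_,
                 template_id = rx$template_id, label = rx$label,
                 score = rx$score, depth = rx$depth, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(id = character(0), product = character(0), r1 = character(0),
               r2 = character(0), template_id = character(0),
               label = character(0), score = numeric(0), depth = integer(0),
               stringsAsFactors = FALSE)
  }
  comp_df <- data.frame(key = names(st$depth),
                        depth = unname(unlist(st$depth)),
                        status = unname(unlist(st$status[names(st$depth)])),
                        stringsAsFactors = FALSE)
  structure(list(target = target, compounds = comp_df, reactions = rxn_df,
                 counters = list(generated = nrow(rxn_df),
                                 rejected = st$n_rejected,
                                 expanded = length(st$expanded)),
                 config = cfg),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction network> target ", x$target, "\n  ",
      nrow(x$compounds), " compounds, ", nrow(x$reactions),
      " kept generated reactions (", x$counters$rejected, " rejected, ",
      x$counters$expanded, " compounds expanded)\n", sep = "")
  invisible(x)
}
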