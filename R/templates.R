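# Named-reaction retro-templates. A template is stored in the retro
# direction: its SMIRKS left-hand side is the product pattern, the right-hand
# side lists the 1-2 reactant patterns. The same SMIRKS, reversed, is the
# forward (synthetic) transformation.

#' Load a retro-template library
#'
#' Reads a TSV file with columns `template_id`, `reaction_name`, `smirks`,
#' `n_reactants` and validates every row against the chemistry backend: the
#' SMIRKS must parse as a transformation with exactly one product pattern and
#' `n_reactants` (1 or 2) reactant patterns.
#'
#' @param path Path to the template TSV. Defaults to the library shipped with
#'   the package (27 general named-reaction transformations).
#' @return A data frame of class `retro_template_library` with one row per
#'   validated template. An empty file (header only) yields an empty library.
#' @export
load_templates <- function(path = default_template_file()) {
  if (!file.exists(path)) stop("template file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("template_id", "reaction_name", "smirks", "n_reactants")
  if (!all(need %in% names(df))) {
    stop("template file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(structure(df[, need], class = c("retro_template_library", "data.frame")))
  }
  if (anyDuplicated(df$template_id)) {
    stop("duplicate template_id in ", path, call. = FALSE)
  }
  df$n_reactants <- as.integer(df$n_reactants)
  checks <- chem_valid_smirks(df$smirks)
  for (i in seq_len(nrow(df))) {
    chk <- checks[[i]]
    id <- df$template_id[i]
    if (!isTRUE(chk$ok)) {
      stop("template ", id, ": SMIRKS does not parse (",
           if (!is.null(chk$reason)) chk$reason else "unknown reason", ")",
           call. = FALSE)
    }
    if (chk$n_lhs != 1L) {
      stop("template ", id, ": expected exactly one product pattern, found ",
           chk$n_lhs, call. = FALSE)
    }
    if (!df$n_reactants[i] %in% c(1L, 2L)) {
      stop("template ", id, ": n_reactants must be 1 or 2", call. = FALSE)
    }
    if (chk$n_rhs != df$n_reactants[i]) {
      stop("template ", id, ": declared n_reactants (", df$n_reactants[i],
           ") disagrees with the SMIRKS (", chk$n_rhs, " reactant patterns)",
           call. = FALSE)
    }
  }
  df <- df[, need]
  structure(df, class = c("retro_template_library", "data.frame"))
}

#' @rdname load_templates
#' @export
default_template_file <- function() {
  system.file("extdata", "templates.tsv", package = "retroplan", mustWork = TRUE)
}

#' @export
print.retro_template_library <- function(x, ...) {
  cat("<retro template library> ", nrow(x), " templates\n", sep = "")
  if (nrow(x)) print.data.frame(x[, c("template_id", "reaction_name", "n_reactants")])
  invisible(x)
}

# swap the two sides of a SMIRKS transformation
reverse_smirks <- function(smirks) {
  parts <- strsplit(smirks, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("not a two-sided SMIRKS: ", smirks, call. = FALSE)
  paste0(parts[2], ">>", parts[1])
}

# product-side SMARTS of a retro SMIRKS
product_pattern <- function(smirks) {
  strsplit(smirks, ">>", fixed = TRUE)[[1]][1]
}

get_template <- function(library, template_id) {
  i <- match(template_id, library$template_id)
  if (is.na(i)) stop("unknown template_id: ", template_id, call. = FALSE)
  as.list(library[i, ])
}

#' Templates applicable to a product molecule
#'
#' A template is applicable when its product pattern substructure-matches the
#' molecule. With a small curated library this direct SMARTS screen replaces
#' any learned template-selection model.
#'
#' @param library A `retro_template_library`.
#' @param product A molecule or SMILES string.
#' @return The matching rows of `library` (possibly zero rows).
#' @export
applicable_templates <- function(library, product) {
  stopifnot(inherits(library, "retro_template_library"))
  if (nrow(library) == 0L) return(library)
  smi <- mol_smiles(product)
  pats <- vapply(library$smirks, product_pattern, character(1), USE.NAMES = FALSE)
  hit <- chem_match_many(pats, smi)[, 1]
  structure(library[which(hit), , drop = FALSE],
            class = class(library))
}

#' Apply a template retrosynthetically
#'
#' Runs the retro transformation on a product, returning every distinct
#' reactant set. Each set is a character vector of canonical SMILES in the
#' template's reactant-pattern order. Duplicate sets (identical canonical
#' reactant multisets), unsanitizable structures, and degenerate outcomes in
#' which the product reappears among its own reactants are discarded.
#'
#' @param template A single-row template (a list or one row of a library).
#' @param product A molecule or SMILES string.
#' @return A list of character vectors; empty when the template does not
#'   apply.
#' @export
apply_retro <- function(template, product) {
  template <- as.list(template)
  smi <- mol_smiles(product)
  sets <- chem_retro(template$smirks, smi)[[1]]
  Filter(function(rs) length(rs) == template$n_reactants, sets)
}

#' Apply a template in the forward (synthetic) direction
#'
#' @param template A single-row template (a list or one row of a library).
#' @param reactants Character vector of reactant SMILES in the template's
#'   reactant-pattern order; its length must equal the template arity.
#' @return Character vector of distinct canonical product SMILES (possibly
#'   empty when the reactants do not match).
#' @export
apply_forward <- function(template, reactants) {
  template <- as.list(template)
  reactants <- vapply(reactants, mol_smiles, character(1), USE.NAMES = FALSE)
  if (length(reactants) != template$n_reactants) {
    stop("template ", template$template_id, " takes ", template$n_reactants,
         " reactant(s), got ", length(reactants), call. = FALSE)
  }
  chem_forward(reverse_smirks(template$smirks), list(reactants))[[1]]
}

# Forward application trying every reactant ordering (used when matching
# corpus records whose reactant order is arbitrary). Returns the union of
# products over orderings.
apply_forward_any_order <- function(template, reactants, batch = NULL) {
  template <- as.list(template)
  perms <- if (length(reactants) == 2L && template$n_reactants == 2L) {
    list(reactants, rev(reactants))
  } else if (length(reactants) == template$n_reactants) {
    list(reactants)
  } else {
    return(character(0))
  }
  out <- chem_forward(reverse_smirks(template$smirks), perms)
  unique(unlist(out, use.names = FALSE))
}
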