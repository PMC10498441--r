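#' Canonicalize SMILES strings
#'
#' Converts SMILES to the backend engine's canonical form so that every
#' spelling of a structure maps to a single string. Canonical SMILES are the
#' node keys of every reaction network in this package; stereochemistry
#' present in the input is retained.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#'   Canonicalization is idempotent: `canonicalize(canonicalize(s))` equals
#'   `canonicalize(s)`.
#' @examples
#' \dontrun{
#' canonicalize("C1=CC=CC=C1")  # "c1ccccc1"
#' }
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- chem_canon(smiles)
  if (anyNA(out)) {
    bad <- smiles[is.na(out)]
    stop("unparsable SMILES: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Heavy-atom count
#'
#' Number of non-hydrogen atoms of each molecule. This is the molecular
#' complexity proxy used by the best-first expansion priorities.
#'
#' @param x A `retro_molecule`, or a character vector of SMILES.
#' @return Integer vector of heavy-atom counts.
#' @export
heavy_atoms <- function(x) {
  if (inherits(x, "retro_molecule")) return(x$heavy_atom_count)
  stopifnot(is.character(x))
  out <- chem_heavy(x)
  if (anyNA(out)) {
    stop("unparsable SMILES: ", paste(sQuote(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Construct a molecule
#'
#' A molecule is keyed by its canonical SMILES and carries the heavy-atom
#' count plus purchasability information. Multi-fragment inputs (salts,
#' mixtures) are rejected: reaction products and network nodes are single
#' molecules.
#'
#' @param smiles A single SMILES string.
#' @param purchasable Logical; is the compound available from a vendor?
#' @param price Price in (unitless) currency units; required (and only
#'   allowed) when `purchasable` is `TRUE`, must be positive.
#' @return An object of class `retro_molecule`: a list with elements
#'   `smiles`, `heavy_atom_count`, `is_purchasable` and (if purchasable)
#'   `price`.
#' @export
molecule <- function(smiles, purchasable = FALSE, price = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- canonicalize(smiles)
  if (chem_nfrag(can) != 1L) {
    stop("multi-fragment SMILES not allowed for a molecule: ", sQuote(smiles),
         call. = FALSE)
  }
  if (isTRUE(purchasable)) {
    if (is.null(price) || !is.numeric(price) || length(price) != 1L || price <= 0) {
      stop("a purchasable molecule requires a single positive price",
           call. = FALSE)
    }
  } else if (!is.null(price)) {
    stop("price is only allowed for purchasable molecules", call. = FALSE)
  }
  out <- list(
    smiles = can,
    heavy_atom_count = chem_heavy(can),
    is_purchasable = isTRUE(purchasable)
  )
  if (isTRUE(purchasable)) out$price <- as.numeric(price)
  structure(out, class = "retro_molecule")
}

#' @export
print.retro_molecule <- function(x, ...) {
  cat("<molecule> ", x$smiles, "  (", x$heavy_atom_count, " heavy atoms",
      if (x$is_purchasable) sprintf(", purchasable @ %.2f", x$price),
      ")\n", sep = "")
  invisible(x)
}

# SMILES of a molecule-or-string argument
mol_smiles <- function(x) {
  if (inherits(x, "retro_molecule")) x$smiles else canonicalize(x)
}
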