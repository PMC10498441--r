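# Per-template feasibility classifiers: labeling rules for corpus records,
# reaction encoding as concatenated circular fingerprints, a one-hidden-layer
# MLP per template, and scoring of generated reactions.

#' Encoder configuration
#'
#' Reactions are encoded as the concatenation of three folded Morgan
#' fingerprint slots (first reactant, second reactant, product). ECFP4
#' corresponds to radius 2. A missing second reactant leaves its slot all
#' zero, so every encoding has length `3 * bits_per_molecule`.
#'
#' @param bits_per_molecule Bits per molecule slot (default 2048).
#' @param radius Circular fingerprint radius (default 2, i.e. ECFP4).
#' @export
encoder_config <- function(bits_per_molecule = 2048L, radius = 2L) {
  stopifnot(bits_per_molecule >= 8L, radius >= 1L)
  structure(list(bits_per_molecule = as.integer(bits_per_molecule),
                 radius = as.integer(radius)),
            class = "encoder_config")
}

#' Classifier training configuration
#'
#' @param hidden_size Hidden layer width of the multilayer perceptron
#'   (default 10).
#' @param min_positive_examples Minimum number of positive examples required
#'   to train a classifier (default 20); below it the template keeps the
#'   neutral default score.
#' @param split_fractions Train/test/evaluation fractions (default
#'   0.80/0.10/0.10); must sum to 1. Evaluation accuracy is computed on the
#'   last split.
#' @param max_iter Optimizer iteration cap (default 500).
#' @param default_score Score assigned to reactions of templates without a
#'   trained classifier (default 0.5, neutral and above the rejection
#'   threshold).
#' @param seed Integer seed; training is reproducible bit-for-bit.
#' @export
classifier_config <- function(hidden_size = 10L, min_positive_examples = 20L,
                              split_fractions = c(0.80, 0.10, 0.10),
                              max_iter = 500L, default_score = 0.5,
                              seed = 1L) {
  stopifnot(length(split_fractions) == 3L,
            abs(sum(split_fractions) - 1) < 1e-8,
            min_positive_examples >= 1L,
            default_score >= 0, default_score <= 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 min_positive_examples = as.integer(min_positive_examples),
                 split_fractions = split_fractions,
                 max_iter = as.integer(max_iter),
                 default_score = default_score,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# deterministic corpus slot ordering: descending heavy-atom count, ties by
# canonical SMILES in the C collation order
order_reactants_corpus <- function(reactants) {
  reactants <- reactants[!is.na(reactants)]
  if (length(reactants) < 2L) return(reactants)
  h <- chem_heavy(reactants)
  ord <- order(-h, rank_c_locale(reactants))
  reactants[ord]
}

rank_c_locale <- function(x) {
  match(x, sort(unique(x), method = "radix"))
}

#' Encode a reaction as a fingerprint vector
#'
#' @param reactants Character vector of 1 or 2 reactant SMILES.
#' @param product A single product SMILES.
#' @param cfg An [encoder_config()].
#' @param slot_order `"as_given"` keeps the reactant order (use for
#'   template-generated reactions, where the template's reactant-pattern
#'   order is meaningful); `"corpus"` applies the deterministic corpus rule
#'   (descending heavy-atom count, ties by canonical SMILES).
#' @return Integer 0/1 vector of length `3 * bits_per_molecule`.
#' @export
encode_reaction <- function(reactants, product, cfg = encoder_config(),
                            slot_order = c("as_given", "corpus")) {
  slot_order <- match.arg(slot_order)
  if (length(reactants) < 1L || length(reactants) > 2L) {
    stop("a reaction has 1 or 2 reactants, got ", length(reactants),
         call. = FALSE)
  }
  if (slot_order == "corpus") reactants <- order_reactants_corpus(reactants)
  encode_reactions(list(reactants), product, cfg)[1, ]
}

# vectorized encoder: one row per reaction, fingerprints fetched in a single
# backend round trip
encode_reactions <- function(reactant_sets, products, cfg = encoder_config()) {
  n <- length(reactant_sets)
  stopifnot(length(products) == n)
  bits <- cfg$bits_per_molecule
  all_smi <- unique(c(unlist(reactant_sets, use.names = FALSE), products))
  fps <- chem_morgan(all_smi, nbits = bits, radius = cfg$radius)
  names(fps) <- all_smi
  bad <- all_smi[vapply(fps, is.null, logical(1))]
  if (length(bad)) {
    stop("unparsable SMILES in reaction encoding: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  X <- matrix(0L, nrow = n, ncol = 3L * bits)
  for (i in seq_len(n)) {
    rs <- reactant_sets[[i]]
    X[i, fps[[rs[1]]] + 1L] <- 1L
    if (length(rs) >= 2L) X[i, bits + fps[[rs[2]]] + 1L] <- 1L
    X[i, 2L * bits + fps[[products[i]]] + 1L] <- 1L
  }
  X
}

#' Label corpus reactions as training examples for one template
#'
#' Applies the labeling rules used to build per-template training sets from a
#' single-step reaction corpus:
#' * positive: the record fully matches the template (its product matches the
#'   template's product pattern and forward application of the template to
#'   the record's reactants regenerates the record's product) and its yield
#'   is at least `yield_threshold` or is unreported;
#' * negative (`full-match-low-yield`): full match with yield below the
#'   threshold;
#' * negative (`product-mismatch`): the reactants match the template but the
#'   recorded product is not among the template's forward outcomes, whatever
#'   the yield;
#' * everything else is excluded.
#'
#' @param corpus A data frame with columns `r1`, `r2` (NA for single-reactant
#'   records), `product` (canonical SMILES) and `yield` (fraction in (0,1] or
#'   NA), e.g. a [read_reaction_db()] result.
#' @param template A single template (list or one row of a library).
#' @param yield_threshold Yield below which a full match becomes a negative
#'   (default 0.10).
#' @return A data frame with columns `r1`, `r2`, `product`, `yield`, `label`
#'   (`"positive"`/`"negative"`) and `provenance`; excluded records are
#'   dropped. Malformed records are skipped with a message.
#' @export
label_examples <- function(corpus, template, yield_threshold = 0.10) {
  template <- as.list(template)
  stopifnot(all(c("r1", "product") %in% names(corpus)))
  if (!"r2" %in% names(corpus)) corpus$r2 <- NA_character_
  if (!"yield" %in% names(corpus)) corpus$yield <- NA_real_
  n <- nrow(corpus)
  if (n == 0L) {
    return(data.frame(r1 = character(0), r2 = character(0),
                      product = character(0), yield = numeric(0),
                      label = character(0), provenance = character(0)))
  }
  malformed <- is.na(corpus$r1) | is.na(corpus$product)
  if (any(malformed)) {
    message("label_examples: skipping ", sum(malformed), " malformed record(s)")
  }
  # forward outcomes for each record, trying both reactant orderings
  perm_sets <- list(); perm_rec <- integer(0)
  for (i in seq_len(n)) {
    if (malformed[i]) next
    rs <- c(corpus$r1[i], corpus$r2[i])
    rs <- rs[!is.na(rs)]
    if (length(rs) != template$n_reactants) next
    perm_sets[[length(perm_sets) + 1L]] <- rs
    perm_rec <- c(perm_rec, i)
    if (length(rs) == 2L) {
      perm_sets[[length(perm_sets) + 1L]] <- rev(rs)
      perm_rec <- c(perm_rec, i)
    }
  }
  fwd <- chem_forward(reverse_smirks(template$smirks), perm_sets)
  outcomes <- vector("list", n)
  for (j in seq_along(perm_rec)) {
    i <- perm_rec[j]
    outcomes[[i]] <- unique(c(outcomes[[i]], fwd[[j]]))
  }
  prod_hit <- rep(FALSE, n)
  ok <- which(!malformed)
  prod_hit[ok] <- chem_match(product_pattern(template$smirks), corpus$product[ok])

  label <- rep(NA_character_, n)
  prov <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    outs <- outcomes[[i]]
    if (is.null(outs) || length(outs) == 0L) next  # reactants do not match
    full <- prod_hit[i] && corpus$product[i] %in% outs
    y <- corpus$yield[i]
    if (full) {
      if (is.na(y)) {
        label[i] <- "positive"; prov[i] <- "full-match-no-yield"
      } else if (y >= yield_threshold) {
        label[i] <- "positive"; prov[i] <- "full-match-high-yield"
      } else {
        label[i] <- "negative"; prov[i] <- "full-match-low-yield"
      }
    } else {
      label[i] <- "negative"; prov[i] <- "product-mismatch"
    }
  }
  keep <- !is.na(label)
  out <- data.frame(r1 = corpus$r1[keep], r2 = corpus$r2[keep],
                    product = corpus$product[keep], yield = corpus$yield[keep],
                    label = label[keep], provenance = prov[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Train the feasibility classifier of one template
#'
#' Fits a multilayer perceptron with a single hidden layer on labeled
#' examples encoded as concatenated fingerprints. Examples are split into
#' train/test/evaluation subsets (stratified by label, seeded); the reported
#' `evaluation_accuracy` comes from the held-out evaluation split. Templates
#' with fewer positives than `cfg$min_positive_examples` are not trainable
#' and keep the default score.
#'
#' @param examples A data frame as returned by [label_examples()] (columns
#'   `r1`, `r2`, `product`, `label`).
#' @param cfg A [classifier_config()].
#' @param encoder An [encoder_config()].
#' @param template_id Identifier stored with the model.
#' @return An object of class `template_classifier`. Check `$trained`; when
#'   `FALSE`, `$reason` explains why (too few positives).
#' @export
train_template_classifier <- function(examples, cfg = classifier_config(),
                                      encoder = encoder_config(),
                                      template_id = NA_character_) {
  stopifnot(all(c("r1", "product", "label") %in% names(examples)))
  n_pos <- sum(examples$label == "positive")
  n_neg <- sum(examples$label == "negative")
  if (n_pos < cfg$min_positive_examples) {
    return(structure(list(template_id = template_id, trained = FALSE,
                          reason = sprintf("only %d positive examples (minimum %d)",
                                           n_pos, cfg$min_positive_examples),
                          n_pos = n_pos, n_neg = n_neg,
                          default_score = cfg$default_score),
                     class = "template_classifier"))
  }
  if (n_neg < 1L) stop("cannot train a classifier without negative examples",
                       call. = FALSE)

  rsets <- lapply(seq_len(nrow(examples)), function(i) {
    rs <- c(examples$r1[i], examples$r2[i])
    order_reactants_corpus(rs[!is.na(rs)])
  })
  X <- encode_reactions(rsets, examples$product, encoder)
  y <- as.integer(examples$label == "positive")

  set.seed(cfg$seed)
  split <- integer(length(y))  # 1 = train, 2 = test, 3 = eval
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    m <- length(idx)
    n_tr <- round(cfg$split_fractions[1] * m)
    n_te <- round(cfg$split_fractions[2] * m)
    split[idx[seq_len(n_tr)]] <- 1L
    split[idx[n_tr + seq_len(min(n_te, m - n_tr))]] <- 2L
    split[idx[split[idx] == 0L]] <- 3L
  }
  tr <- split == 1L; ev <- split == 3L

  # constant columns carry no information for the fit; drop them (the kept
  # index travels with the model so scoring sees the same columns)
  keep <- which(apply(X[tr, , drop = FALSE], 2, function(col) any(col != col[1])))
  if (length(keep) == 0L) stop("degenerate training set: all encodings identical",
                               call. = FALSE)
  p <- length(keep)
  nwts <- (p + 1L) * cfg$hidden_size + (cfg$hidden_size + 1L)
  fit <- nnet::nnet(x = X[tr, keep, drop = FALSE], y = y[tr],
                    size = cfg$hidden_size, entropy = TRUE,
                    maxit = cfg$max_iter, MaxNWts = nwts + 1L,
                    trace = FALSE)
  clf <- structure(list(template_id = template_id, trained = TRUE,
                        n_input = ncol(X), keep = keep,
                        hidden_size = cfg$hidden_size, wts = fit$wts,
                        encoder = encoder, default_score = cfg$default_score,
                        n_pos = n_pos, n_neg = n_neg, seed = cfg$seed),
                   class = "template_classifier")
  pe <- mlp_forward(clf, X[ev, , drop = FALSE])
  clf$evaluation_accuracy <- mean((pe > 0.5) == (y[ev] == 1L))
  clf
}

# forward pass of the serialized MLP (logistic hidden and output units,
# matching the weight layout of nnet)
mlp_forward <- function(clf, X) {
  p <- length(clf$keep)
  h <- clf$hidden_size
  Xk <- X[, clf$keep, drop = FALSE]
  W1 <- matrix(0, nrow = h, ncol = p)
  b1 <- numeric(h)
  idx <- 1L
  for (j in seq_len(h)) {
    b1[j] <- clf$wts[idx]
    W1[j, ] <- clf$wts[idx + seq_len(p)]
    idx <- idx + p + 1L
  }
  b2 <- clf$wts[idx]
  v <- clf$wts[idx + seq_len(h)]
  Z <- stats::plogis(sweep(Xk %*% t(W1), 2, b1, "+"))
  as.numeric(stats::plogis(Z %*% v + b2))
}

#' @export
print.template_classifier <- function(x, ...) {
  if (isTRUE(x$trained)) {
    cat(sprintf("<template classifier> %s  eval accuracy %.3f (%d pos / %d neg)\n",
                x$template_id, x$evaluation_accuracy, x$n_pos, x$n_neg))
  } else {
    cat(sprintf("<template classifier> %s  not trained: %s\n",
                x$template_id, x$reason))
  }
  invisible(x)
}

#' Score the feasibility of a generated reaction
#'
#' Returns the classifier probability that the reaction would work, a value
#' in `[0, 1]`. Templates without a trained classifier get the configured
#' default score.
#'
#' @param clf A `template_classifier`, or `NULL` when the template has none.
#' @param reactants Character vector of reactant SMILES (template order).
#' @param product Product SMILES.
#' @param default_score Score for classifier-less templates (default 0.5).
#' @return A single numeric score in `[0, 1]`.
#' @export
feasibility_score <- function(clf, reactants, product, default_score = 0.5) {
  feasibility_scores(clf, list(reactants), product, default_score)
}

# vectorized scoring used by the expansion loop; the same slot-ordering rule
# as training, so train- and score-time encodings agree
feasibility_scores <- function(clf, reactant_sets, products,
                               default_score = 0.5) {
  n <- length(reactant_sets)
  if (length(products) == 1L) products <- rep(products, n)
  if (is.null(clf) || !isTRUE(clf$trained)) {
    ds <- if (!is.null(clf$default_score)) clf$default_score else default_score
    return(rep(ds, n))
  }
  reactant_sets <- lapply(reactant_sets, order_reactants_corpus)
  X <- encode_reactions(reactant_sets, products, clf$encoder)
  mlp_forward(clf, X)
}

#' Save / load trained classifiers
#'
#' Classifiers are serialized as plain JSON, one file per template, with a
#' `manifest.json` listing every template's training outcome and evaluation
#' accuracy.
#'
#' @param classifiers A named list of `template_classifier` objects.
#' @param dir Model directory (created if missing).
#' @return `save_classifiers` returns `dir` invisibly; `load_classifiers`
#'   returns a named list of `template_classifier` objects.
#' @export
save_classifiers <- function(classifiers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(classifiers, function(clf) {
    entry <- list(template_id = clf$template_id, trained = isTRUE(clf$trained),
                  n_pos = clf$n_pos, n_neg = clf$n_neg)
    if (isTRUE(clf$trained)) {
      entry$evaluation_accuracy <- clf$evaluation_accuracy
      entry$file <- paste0(clf$template_id, ".json")
      obj <- unclass(clf)
      obj$encoder <- unclass(obj$encoder)
      jsonlite::write_json(obj, file.path(dir, entry$file),
                           auto_unbox = TRUE, digits = NA)
    } else {
      entry$reason <- clf$reason
    }
    entry
  })
  jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_classifiers
#' @export
load_classifiers <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- list()
  for (entry in mf) {
    if (isTRUE(entry$trained)) {
      obj <- jsonlite::read_json(file.path(dir, entry$file),
                                 simplifyVector = TRUE)
      obj$encoder <- structure(as.list(obj$encoder), class = "encoder_config")
      clf <- structure(obj, class = "template_classifier")
    } else {
      clf <- structure(list(template_id = entry$template_id, trained = FALSE,
                            reason = entry$reason, n_pos = entry$n_pos,
                            n_neg = entry$n_neg),
                       class = "template_classifier")
    }
    out[[entry$template_id]] <- clf
  }
  out
}
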