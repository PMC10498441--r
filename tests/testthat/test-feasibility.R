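test_that("reaction encodings have the fixed three-slot layout", {
  cfg <- encoder_config(bits_per_molecule = 256L)
  v1 <- encode_reaction("CC(=O)O", "CC(=O)Nc1ccccc1", cfg)
  expect_length(v1, 3L * 256L)
  expect_gt(sum(v1[1:256]), 0)                 # reactant slot populated
  expect_identical(sum(v1[257:512]), 0L)       # missing second reactant
  expect_gt(sum(v1[513:768]), 0)               # product slot populated

  v2 <- encode_reaction(c("CC(=O)O", "Nc1ccccc1"), "CC(=O)Nc1ccccc1", cfg)
  expect_gt(sum(v2[257:512]), 0)
  expect_identical(v2, encode_reaction(c("CC(=O)O", "Nc1ccccc1"),
                                       "CC(=O)Nc1ccccc1", cfg))
  expect_error(encode_reaction(c("C", "C", "C"), "CC", cfg), "reactants")
})

test_that("the corpus slot rule makes encodings order-invariant", {
  cfg <- encoder_config(bits_per_molecule = 256L)
  pool <- pool_smiles()
  set.seed(11)
  for (i in 1:20) {
    rs <- sample(pool, 2L)
    p <- sample(pool, 1L)
    expect_identical(
      encode_reaction(rs, p, cfg, slot_order = "corpus"),
      encode_reaction(rev(rs), p, cfg, slot_order = "corpus"))
  }
})

test_that("labeling implements the yield and match rules", {
  t01 <- tpl("T01")
  corpus <- data.frame(
    r1 = c("CC(=O)O", "CC(=O)O", "CC(=O)O"),
    r2 = c("Nc1ccccc1", "Nc1ccccc1", "Nc1ccccc1"),
    product = c("CC(=O)Nc1ccccc1", "CC(=O)Nc1ccccc1", "CCO"),
    yield = c(NA, 0.05, 0.90),
    stringsAsFactors = FALSE)
  lab <- label_examples(corpus, t01)
  expect_identical(lab$label, c("positive", "negative", "negative"))
  expect_identical(lab$provenance,
                   c("full-match-no-yield", "full-match-low-yield",
                     "product-mismatch"))
})

test_that("labeling partitions the corpus: each record is positive, negative or excluded", {
  t01 <- tpl("T01")
  corpus <- data.frame(
    r1 = c("CC(=O)O", "CCO", "CC(=O)O", "c1ccccc1"),
    r2 = c("Nc1ccccc1", NA, "Nc1ccccc1", NA),
    product = c("CC(=O)Nc1ccccc1", "CC=O", "c1ccccc1", "C1CCCCC1"),
    yield = c(0.8, 0.9, 0.5, NA), stringsAsFactors = FALSE)
  lab <- label_examples(corpus, t01)
  # records 2 and 4 do not match the template's reactants at all: excluded
  expect_identical(nrow(lab), 2L)
  expect_true(all(lab$label %in% c("positive", "negative")))
})

test_that("training learns a separable set, reproducibly, at reduced size", {
  t01 <- tpl("T01")
  ts <- make_training_set(t01, n_pos = 60L, n_neg = 60L, seed = 3L)
  cfg <- classifier_config(seed = 5L, max_iter = 200L)
  enc <- encoder_config(bits_per_molecule = 256L)
  clf <- train_template_classifier(ts, cfg, enc, template_id = "T01")
  expect_true(clf$trained)
  expect_gte(clf$evaluation_accuracy, 0.8)
  clf2 <- train_template_classifier(ts, cfg, enc, template_id = "T01")
  expect_identical(clf$wts, clf2$wts)
  expect_identical(clf$evaluation_accuracy, clf2$evaluation_accuracy)
})

test_that("too few positives yields a not-trainable outcome; no negatives errors", {
  t01 <- tpl("T01")
  ts <- make_training_set(t01, n_pos = 19L, n_neg = 30L, seed = 2L)
  clf <- train_template_classifier(ts, classifier_config(),
                                   encoder_config(256L), "T01")
  expect_false(clf$trained)
  expect_match(clf$reason, "19 positive")
  # a skipped template still scores at the default
  expect_identical(feasibility_score(clf, "CCO", "CC=O"), 0.5)

  allpos <- ts[ts$label == "positive", ]
  allpos <- do.call(rbind, replicate(3, allpos, simplify = FALSE))
  expect_error(train_template_classifier(allpos, classifier_config(),
                                         encoder_config(256L), "T01"),
               "negative")
})

test_that("feasibility scores stay in [0,1] and default to 0.5 without a model", {
  expect_identical(feasibility_score(NULL, c("CC(=O)O", "CCO"), "CCOC(C)=O"),
                   0.5)
  expect_identical(feasibility_score(NULL, "CCO", "CC=O",
                                     default_score = 0.9), 0.9)
  t01 <- tpl("T01")
  ts <- make_training_set(t01, n_pos = 40L, n_neg = 40L, seed = 8L)
  clf <- train_template_classifier(ts, classifier_config(seed = 8L,
                                                         max_iter = 100L),
                                   encoder_config(128L), "T01")
  pool <- pool_smiles()
  set.seed(8)
  for (i in 1:25) {
    s <- feasibility_score(clf, sample(pool, 2L), sample(pool, 1L))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("serialized classifiers reproduce in-memory scores", {
  t01 <- tpl("T01")
  ts <- make_training_set(t01, n_pos = 40L, n_neg = 40L, seed = 9L)
  clf <- train_template_classifier(ts, classifier_config(seed = 9L,
                                                         max_iter = 100L),
                                   encoder_config(128L), "T01")
  d <- withr::local_tempdir()
  save_classifiers(list(T01 = clf,
                        T99 = structure(list(template_id = "T99",
                                             trained = FALSE,
                                             reason = "only 0 positive examples (minimum 20)",
                                             n_pos = 0L, n_neg = 5L),
                                        class = "template_classifier")), d)
  back <- load_classifiers(d)
  expect_named(back, c("T01", "T99"), ignore.order = TRUE)
  expect_false(back$T99$trained)
  rs <- c("CC(=O)O", "Nc1ccccc1"); p <- "CC(=O)Nc1ccccc1"
  expect_equal(feasibility_score(back$T01, rs, p),
               feasibility_score(clf, rs, p), tolerance = 1e-12)
})
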