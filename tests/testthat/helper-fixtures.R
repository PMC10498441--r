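# Shared fixtures, computed once per test run.

.fx <- new.env(parent = emptyenv())

tpl_lib <- function() {
  if (is.null(.fx$lib)) .fx$lib <- load_templates()
  .fx$lib
}

tpl <- function(id) as.list(tpl_lib()[tpl_lib()$template_id == id, ])

pool_smiles <- function() {
  if (is.null(.fx$pool)) .fx$pool <- fragment_pool()$smiles
  .fx$pool
}

# building-block DB over the whole fragment pool, flat price
pool_bb <- function(price = 5) {
  building_block_db(pool_smiles(), price = rep(price, length(pool_smiles())),
                    canonical = TRUE)
}

# fixture products for a template, derived by forward application on the
# fragment pool (independent of apply_retro)
fixture_products <- function(template, n = 5L) {
  rxns <- retroplan:::template_pool_reactions(template, limit = 4L * n)
  prods <- unique(unlist(lapply(rxns, `[[`, "products"), use.names = FALSE))
  head(prods, n)
}

# expansion fixture admitting a 2-step and a 4-step route:
# target CCN(CC)Cc1ccc(OCC)cc1 disconnects either at the benzylic amine
# (2 steps via the ethoxybenzyl alcohol building block) or at the aryl ethyl
# ether first (4 steps through the free phenol)
two_four_fixture <- function() {
  list(target = "CCN(CC)Cc1ccc(OCC)cc1",
       bb = building_block_db(
         c("CCNCC", "CCO", "OCc1ccc(OCC)cc1", "OCc1ccc(O)cc1"),
         price = c(3, 1, 8, 6)))
}

route_costs <- function(routes) vapply(routes, `[[`, numeric(1), "cost")
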