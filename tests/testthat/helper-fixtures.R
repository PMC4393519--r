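# Small fixture builders used across test files. Everything is generated
# in code; no data files.

toy_species <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_map <- c(a = "A", b = "B", c = "C")

# random binary rooted tree with clean labels
rand_tree <- function(n, prefix = "t") {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0(prefix, seq_len(n))
  tr
}

# random reconciliation instance: gene tree, species tree, many-to-one map
rand_instance <- function(max_leaves = 6) {
  mg <- sample(3:max_leaves, 1)
  ns <- sample(3:max_leaves, 1)
  g <- rand_tree(mg, "g")
  s <- rand_tree(ns, "S")
  map <- setNames(sample(s$tip.label, mg, replace = TRUE), g$tip.label)
  list(gene = g, species = s, map = map)
}

rand_costs <- function(p_inf = 0.2) {
  if (runif(1) < p_inf) {
    event_costs(duplication = Inf, transfer = runif(1, 0.5, 4),
                loss = runif(1, 0.2, 2))
  } else {
    event_costs(duplication = runif(1, 0.5, 4),
                transfer = runif(1, 0.5, 4), loss = runif(1, 0.2, 2))
  }
}

# one small simulated family for likelihood/search tests
small_family <- function(n_taxa = 10, length = 120, mutation_rate = 1,
                         rates = dtl_rates("low")) {
  simulate_family(n_taxa = n_taxa, rates = rates,
                  mutation_rate = mutation_rate, length = length)
}
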