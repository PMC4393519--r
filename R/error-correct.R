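#' Search configuration for gene tree error correction
#'
#' @param alpha Significance level of the SH test defining statistical
#'   equivalence to the input ML tree (default 0.05).
#' @param iterations Number of search iterations (default 1000).
#' @param costs DTL [event_costs()] (default 2, 3, 1).
#' @param p_nni Probability that a proposal is an NNI (otherwise SPR);
#'   default 0.5.
#' @param escape_prob Probability of accepting a statistically equivalent
#'   but non-improving proposal as the new search position, to escape
#'   local minima (default 0.05).
#' @param resamples SH bootstrap resamples (default 1000).
#' @param model Fixed [substitution_model()] used for all likelihoods.
#' @param optim_maxit Branch-length optimization sweeps per scored
#'   proposal (default 10; proposals start from the incumbent's lengths,
#'   so convergence is quick).
#' @param polish If `TRUE` (default), finish the stochastic search with
#'   deterministic steepest-descent sweeps over the full NNI
#'   neighbourhood of the best tree: neighbours are screened by
#'   reconciliation cost and strict improvements must still pass the SH
#'   test. This drains single-move gains that uniform random proposals
#'   may have missed.
#' @param seed Optional integer seed applied at the start of the run; with
#'   a fixed seed the whole search is reproducible.
#' @return Object of class `"search_config"`.
#' @export
search_config <- function(alpha = 0.05, iterations = 1000L,
                          costs = event_costs(), p_nni = 0.5,
                          escape_prob = 0.05, resamples = 1000L,
                          model = substitution_model(),
                          optim_maxit = 10L, polish = TRUE, seed = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, iterations >= 1, p_nni >= 0,
            p_nni <= 1, escape_prob >= 0, escape_prob <= 1)
  structure(list(alpha = alpha, iterations = as.integer(iterations),
                 costs = costs, p_nni = p_nni, escape_prob = escape_prob,
                 resamples = as.integer(resamples), model = model,
                 optim_maxit = as.integer(optim_maxit),
                 polish = isTRUE(polish), seed = seed),
            class = "search_config")
}

#' Species-tree-aware error correction of a gene tree
#'
#' Hill-climbing search for the gene tree of minimum DTL reconciliation
#' cost among topologies statistically equivalent to the input
#' maximum-likelihood tree. Each iteration proposes a random NNI or SPR
#' rearrangement of the current search position; the proposal's
#' reconciliation cost (minimized over all rootings) is computed first and
#' its branch lengths are re-optimized and SH-tested against the input
#' tree only when the cost is competitive (or on an escape draw). A
#' proposal becomes the new search position if it passes the SH test at
#' level `alpha` and either improves on the best cost so far, ties it with
#' a higher likelihood, or wins an escape draw. Among all visited trees
#' that pass the SH test and share the minimum cost, the one with the
#' highest likelihood is returned.
#'
#' @param ml_tree Input ML gene tree (`"phylo"`, branch lengths in
#'   substitutions/site; treated as unrooted).
#' @param alignment Amino-acid alignment covering the gene tree's leaves.
#' @param species Rooted binary species tree.
#' @param map Gene-to-species leaf map (see [leaf_map()]); `NULL` applies
#'   the `"_"`-prefix rule.
#' @param config A [search_config()].
#' @return Object of class `"gene_tree_correction"`: `tree` (corrected
#'   unrooted tree with optimized branch lengths), `cost`, `logLik`,
#'   `p_value` (SH p-value of the corrected tree against the input),
#'   `input_cost`, `input_logLik`, `trace` (per-iteration data frame),
#'   `feasible`, and the `config` used.
#' @export
correct_gene_tree <- function(ml_tree, alignment, species, map = NULL,
                              config = search_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  validate_tree(species)
  tree <- ape::unroot(ml_tree)
  validate_tree(tree)
  data <- as_phydat(alignment)
  model <- config$model
  costs <- config$costs
  alpha <- config$alpha

  # fixed species context reused across all cost evaluations
  sc <- .species_context(species)
  sigma <- leaf_map(tree$tip.label, map = map)
  unknown <- setdiff(unique(sigma), species$tip.label)
  if (length(unknown)) {
    stop("leaf map targets absent from species tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cost_of <- function(tr) {
    g <- if (ape::is.rooted(tr)) ape::unroot(tr) else tr
    tip_sp <- match(sigma[g$tip.label], species$tip.label) - 1L
    .dtl_dp_unrooted(g$edge - 1L, ape::Ntip(g), tip_sp, sc$arr$kids,
                     sc$arr$post, costs$duplication, costs$transfer,
                     costs$loss)$best_cost
  }

  fit0 <- optimize_branch_lengths(tree, data, model)
  ref_site <- fit0$site_loglik
  input_logLik <- fit0$logLik
  input_cost <- cost_of(fit0$tree)

  incumbent <- list(tree = fit0$tree, cost = input_cost,
                    logLik = input_logLik, p = 1)
  best <- incumbent
  cache <- new.env(parent = emptyenv())
  assign(topology_key(fit0$tree),
         list(cost = input_cost, scored = TRUE, logLik = input_logLik,
              p = 1, tree = fit0$tree),
         envir = cache)

  n_it <- config$iterations
  trace <- data.frame(iteration = seq_len(n_it),
                      move = character(n_it), cost = NA_real_,
                      p_value = NA_real_, logLik = NA_real_,
                      accepted = FALSE, escape = FALSE,
                      stringsAsFactors = FALSE)
  n_scored <- 0L
  better <- function(a, b) { # lexicographic (cost, -logLik)
    a$cost < b$cost || (a$cost == b$cost && a$logLik > b$logLik)
  }
  searchable <- ape::Ntip(tree) >= 4 # a 3-leaf unrooted tree is unique
  for (it in if (searchable) seq_len(n_it) else integer(0)) {
    move <- if (runif(1) < config$p_nni) "nni" else "spr"
    prop <- if (move == "nni") random_nni(incumbent$tree) else
      random_spr(incumbent$tree)
    key <- topology_key(prop)
    entry <- if (exists(key, envir = cache, inherits = FALSE))
      get(key, envir = cache) else NULL
    cost_p <- if (is.null(entry)) cost_of(prop) else entry$cost
    escape <- runif(1) < config$escape_prob
    # cheap screen: branch lengths are optimized and the SH test run only
    # for proposals that could improve on the best cost so far, tie it
    # (candidates for the likelihood tie-break), or win an escape draw
    candidate <- cost_p < best$cost ||
      (is.finite(cost_p) && cost_p == best$cost) || escape
    p_p <- NA_real_; logLik_p <- NA_real_
    if (candidate) {
      if (is.null(entry) || !isTRUE(entry$scored)) {
        opt <- optimize_branch_lengths(prop, data, model,
                                       maxit = config$optim_maxit)
        sh <- sh_test(ref_site, opt$site_loglik,
                      resamples = config$resamples)
        entry <- list(cost = cost_p, scored = TRUE, logLik = opt$logLik,
                      p = sh$p.value, tree = opt$tree)
        assign(key, entry, envir = cache)
        n_scored <- n_scored + 1L
      }
      p_p <- entry$p; logLik_p <- entry$logLik
      pass <- entry$p >= alpha
      cand <- list(tree = entry$tree, cost = cost_p, logLik = entry$logLik,
                   p = entry$p)
      if (pass) {
        improves_inc <- better(cand, incumbent)
        # ties on cost move the incumbent only with a likelihood gain
        # (the spec of better()); escape draws allow uphill moves
        if (improves_inc || escape) {
          incumbent <- cand
          trace$accepted[it] <- TRUE
          trace$escape[it] <- !improves_inc && escape
        }
        if (better(cand, best)) best <- cand
      }
    } else if (is.null(entry)) {
      assign(key, list(cost = cost_p, scored = FALSE), envir = cache)
    }
    trace$move[it] <- move
    trace$cost[it] <- cost_p
    trace$p_value[it] <- p_p
    trace$logLik[it] <- logLik_p
  }
  polish_steps <- 0L
  if (config$polish && searchable) {
    # deterministic NNI steepest descent from the best tree: screen the
    # full neighbourhood by cost, SH-test improvements cheapest-first
    repeat {
      nbrs <- phangorn::nni(best$tree)
      nb_cost <- vapply(nbrs, cost_of, numeric(1))
      ord <- order(nb_cost)
      moved <- FALSE
      for (j in ord) {
        if (!(nb_cost[j] < best$cost)) break
        key <- topology_key(nbrs[[j]])
        entry <- if (exists(key, envir = cache, inherits = FALSE))
          get(key, envir = cache) else NULL
        if (is.null(entry) || !isTRUE(entry$scored)) {
          tr_j <- nbrs[[j]]
          if (is.null(tr_j$edge.length)) {
            tr_j$edge.length <- rep(0.1, nrow(tr_j$edge))
          }
          opt <- optimize_branch_lengths(tr_j, data, model,
                                         maxit = config$optim_maxit)
          sh <- sh_test(ref_site, opt$site_loglik,
                        resamples = config$resamples)
          entry <- list(cost = nb_cost[j], scored = TRUE,
                        logLik = opt$logLik, p = sh$p.value,
                        tree = opt$tree)
          assign(key, entry, envir = cache)
          n_scored <- n_scored + 1L
        }
        if (entry$p >= alpha) {
          best <- list(tree = entry$tree, cost = nb_cost[j],
                       logLik = entry$logLik, p = entry$p)
          polish_steps <- polish_steps + 1L
          moved <- TRUE
          break
        }
      }
      if (!moved) break
    }
  }
  structure(list(tree = best$tree, cost = best$cost, logLik = best$logLik,
                 p_value = best$p, input_cost = input_cost,
                 input_logLik = input_logLik, trace = trace,
                 feasible = is.finite(best$cost),
                 evaluations = n_scored, polish_steps = polish_steps,
                 config = config),
            class = "gene_tree_correction")
}

#' Transfer-loss-only error correction
#'
#' [correct_gene_tree()] with the duplication cost set to infinity, for
#' single-copy gene families where all gene tree/species tree incongruence
#' is attributed to (additive) transfer and compensating loss. If no
#' finite-cost topology is encountered, the input tree is returned with
#' `feasible = FALSE`.
#'
#' @inheritParams correct_gene_tree
#' @export
correct_gene_tree_tl <- function(ml_tree, alignment, species, map = NULL,
                                 config = search_config()) {
  config$costs <- event_costs(transfer = config$costs$transfer,
                              loss = config$costs$loss, tl_only = TRUE)
  out <- correct_gene_tree(ml_tree, alignment, species, map = map,
                           config = config)
  if (!out$feasible) out$tree <- ape::unroot(ml_tree)
  out
}

#' @export
print.gene_tree_correction <- function(x, ...) {
  cat("species-tree-aware gene tree correction\n")
  cat(sprintf("  reconciliation cost: %s -> %s\n", format(x$input_cost),
              format(x$cost)))
  cat(sprintf("  log-likelihood: %.2f -> %.2f (SH p = %.3f)\n",
              x$input_logLik, x$logLik, x$p_value))
  cat(sprintf("  %d proposals scored with the SH test; %d acceptances\n",
              x$evaluations, sum(x$trace$accepted)))
  if (!x$feasible) cat("  NOTE: no finite-cost tree found (TL mode)\n")
  invisible(x)
}
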