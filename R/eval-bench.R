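#' Match inferred DTL events against a simulated true history
#'
#' Strict location-based matching, greedy one-to-one in simulation-time
#' order of the truth events: a duplication matches iff the gene clade
#' (surviving descendant leaf set) and species branch agree; a transfer
#' matches iff the moved subtree's gene clade and the (donor, recipient)
#' species branch pair agree; a loss matches iff the species branch where
#' the gene was lost and the surviving sibling lineage's gene clade agree.
#' Each truth event is consumed at most once.
#'
#' @param truth A `"dtl_history"` (or its `events` data frame).
#' @param inferred Event data frame from [enumerate_events()].
#' @return Class `"event_match_report"`: data frame with one row per event
#'   type (`true`, `inferred`, `matched`, `precision`, `sensitivity`).
#'   Conventions at empty margins: precision is 1 when nothing was
#'   inferred; sensitivity is 1 when nothing was there to find.
#' @export
match_events <- function(truth, inferred) {
  tev <- if (inherits(truth, "dtl_history")) truth$events else truth
  if (!is.null(tev$time)) tev <- tev[order(tev$time), , drop = FALSE]
  key <- function(df) {
    ifelse(df$type == "transfer",
           paste(df$type, df$gene_clade, df$donor, df$recipient, sep = "|"),
           paste(df$type, df$gene_clade, df$species, sep = "|"))
  }
  tkey <- key(tev)
  ikey <- key(inferred)
  used <- rep(FALSE, length(ikey))
  matched_t <- rep(FALSE, length(tkey))
  for (i in seq_along(tkey)) {
    j <- which(!used & ikey == tkey[i])
    if (length(j)) {
      used[j[1L]] <- TRUE
      matched_t[i] <- TRUE
    }
  }
  types <- c("duplication", "transfer", "loss")
  rep_df <- do.call(rbind, lapply(types, function(ty) {
    nt <- sum(tev$type == ty)
    ni <- sum(inferred$type == ty)
    nm <- sum(matched_t & tev$type == ty)
    data.frame(type = ty, true = nt, inferred = ni, matched = nm,
               precision = if (ni == 0L) 1 else nm / ni,
               sensitivity = if (nt == 0L) 1 else nm / nt,
               stringsAsFactors = FALSE)
  }))
  class(rep_df) <- c("event_match_report", "data.frame")
  rep_df
}

#' Aggregate event-match reports over replicates
#'
#' Pools counts (micro-average): precision = total matched / total
#' inferred, sensitivity = total matched / total true, per event type.
#'
#' @param reports List of `"event_match_report"` objects.
#' @export
pool_event_reports <- function(reports) {
  all <- do.call(rbind, lapply(reports, as.data.frame))
  agg <- do.call(rbind, lapply(split(all, all$type), function(d) {
    data.frame(type = d$type[1L], true = sum(d$true),
               inferred = sum(d$inferred), matched = sum(d$matched),
               precision = if (sum(d$inferred) == 0L) 1 else
                 sum(d$matched) / sum(d$inferred),
               sensitivity = if (sum(d$true) == 0L) 1 else
                 sum(d$matched) / sum(d$true),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  class(agg) <- c("event_match_report", "data.frame")
  agg
}

#' Collapse poorly supported branches
#'
#' Contracts internal edges whose support value (stored in
#' `tree$node.label`, scale 0-100) is below `threshold`, yielding a
#' multifurcating tree. With the symmetric NRFD definition, splits removed
#' by collapsing count as false negatives while the denominator 2(m-3) is
#' unchanged, so heavy collapsing drives the NRFD of a collapsed tree
#' against a binary reference towards 0.5.
#'
#' @param tree `"phylo"` with numeric internal-node support labels;
#'   missing/empty labels (e.g. at the root) are never collapsed.
#' @param threshold Support threshold; edges with support `< threshold`
#'   are contracted. 0 keeps the tree unchanged.
#' @return The collapsed (possibly multifurcating) tree, with attribute
#'   `"n_collapsed"`.
#' @export
collapse_low_support <- function(tree, threshold) {
  if (is.null(tree$node.label)) stop("tree has no support labels")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  m <- ape::Ntip(tree)
  keep_len <- tree$edge.length
  child <- tree$edge[, 2L]
  internal_child <- child > m
  sup_of_edge <- rep(NA_real_, nrow(tree$edge))
  sup_of_edge[internal_child] <- sup[child[internal_child] - m]
  contract <- internal_child & !is.na(sup_of_edge) & sup_of_edge < threshold
  work <- tree
  work$edge.length <- ifelse(contract, 0, 1)
  out <- ape::di2multi(work, tol = 0.5)
  out$edge.length <- NULL
  attr(out, "n_collapsed") <- sum(contract)
  out
}

#' Corrupt a species tree with random rooted NNI moves
#'
#' Applies `k` successive nearest-neighbour interchanges, each on a
#' uniformly chosen internal edge of the rooted tree (swapping a random
#' child of the edge's lower node with the node's sibling). Used to study
#' robustness of error correction to species-tree error.
#'
#' @param species Rooted binary `"phylo"`.
#' @param k Number of NNI moves (>= 0).
#' @return The corrupted tree; attribute `"moves"` records the edges used.
#' @export
corrupt_species_tree <- function(species, k) {
  stopifnot(k >= 0)
  tr <- species
  m <- ape::Ntip(tr)
  moves <- integer(0)
  root <- m + 1L
  for (i in seq_len(k)) {
    # exclude root-incident edges: swapping across the root only re-roots
    # the tree and leaves the unrooted topology unchanged
    internal_edges <- which(tr$edge[, 2L] > m & tr$edge[, 1L] != root)
    if (!length(internal_edges)) {
      internal_edges <- which(tr$edge[, 2L] > m)
    }
    e <- internal_edges[sample.int(length(internal_edges), 1L)]
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    v_children <- which(tr$edge[, 1L] == v)
    c_row <- v_children[sample.int(2L, 1L)]
    u_children <- which(tr$edge[, 1L] == u)
    b_row <- setdiff(u_children, e)
    # swap: child-of-v moves under u, sibling-of-v moves under v
    tr$edge[c_row, 1L] <- u
    tr$edge[b_row, 1L] <- v
    tr <- ape::reorder.phylo(tr, "cladewise")
    moves <- c(moves, e)
  }
  attr(tr, "moves") <- moves
  tr
}

#' Perturb a tree with random NNI moves
#'
#' Convenience used to build degraded "inferred" trees from true trees in
#' benchmarks: `k` successive [random_nni()] moves on the unrooted
#' topology.
#'
#' @param tree Binary `"phylo"` (>= 4 leaves).
#' @param k Number of moves.
#' @export
perturb_tree <- function(tree, k) {
  out <- ape::unroot(tree)
  for (i in seq_len(k)) out <- random_nni(out)
  out
}

#' Run a simulate-perturb-correct-score benchmark
#'
#' For each replicate: simulate a gene family, derive an error-laden input
#' tree (the true tree degraded by `perturb_nni` random NNI moves, branch
#' lengths re-optimized on the simulated alignment), apply `method`, and
#' score input and output against the true tree (NRFD, perfect-inference,
#' reconciliation cost, event precision/sensitivity).
#'
#' @param n_reps Number of replicates.
#' @param method Callable `(tree, alignment, species, map) -> phylo` (or an
#'   object with `$tree`); e.g. a wrapper around [correct_gene_tree()].
#'   `NULL` scores the input tree itself.
#' @param n_taxa,rates,mutation_rate,length Simulation-grid cell.
#' @param perturb_nni NNI moves applied to the true tree to form the input.
#' @param model Substitution model for sequence simulation and refitting.
#' @param max_fail_frac Abort if more than this fraction of replicates
#'   fails (default 0.1).
#' @return Class `"benchmark_summary"`: `replicates` data frame (per
#'   replicate NRFDs, costs), pooled `events` report, and `summary` list
#'   (mean NRFDs, perfect-inference percentage, mean cost).
#' @export
run_benchmark <- function(n_reps, method = NULL, n_taxa = 50L,
                          rates = dtl_rates("medium"), mutation_rate = 1,
                          length = 333L, perturb_nni = 2L,
                          model = substitution_model(),
                          max_fail_frac = 0.1) {
  rows <- list()
  ev_reports <- list()
  failures <- 0L
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      fam <- simulate_family(n_taxa = n_taxa, rates = rates,
                             mutation_rate = mutation_rate,
                             length = length, model = model,
                             min_leaves = if (perturb_nni > 0) 4L else 3L)
      input <- perturb_tree(fam$gene, perturb_nni)
      input <- optimize_branch_lengths(input, fam$alignment, model)$tree
      out_tree <- if (is.null(method)) input else {
        ans <- method(input, fam$alignment, fam$species, fam$map)
        if (is.list(ans) && !inherits(ans, "phylo")) ans$tree else ans
      }
      rec <- reconcile_unrooted(out_tree, fam$species, fam$map)
      report <- match_events(fam$history, enumerate_events(rec))
      ev_reports[[length(ev_reports) + 1L]] <- report
      data.frame(replicate = i,
                 nrfd_input = nrfd(input, fam$gene),
                 nrfd_output = nrfd(out_tree, fam$gene),
                 cost_output = rec$cost,
                 leaves = fam$history$counts[["leaves"]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (failures > max_fail_frac * n_reps) {
        stop("benchmark failed on >", 100 * max_fail_frac,
             "% of replicates; last error: ", conditionMessage(res))
      }
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  reps <- do.call(rbind, rows)
  out <- list(
    replicates = reps,
    events = pool_event_reports(ev_reports),
    failures = failures,
    summary = list(
      mean_nrfd_input = mean(reps$nrfd_input),
      mean_nrfd_output = mean(reps$nrfd_output),
      perfect_pct = 100 * mean(reps$nrfd_output == 0),
      mean_cost = mean(reps$cost_output[is.finite(reps$cost_output)])
    )
  )
  class(out) <- "benchmark_summary"
  out
}

#' @export
print.benchmark_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("benchmark over %d replicates (%d failures)\n",
                     "  mean NRFD: input %.4f -> output %.4f\n",
                     "  perfect inference: %.1f%%   mean cost: %.2f\n"),
              nrow(x$replicates), x$failures, s$mean_nrfd_input,
              s$mean_nrfd_output, s$perfect_pct, s$mean_cost))
  print(x$events)
  invisible(x)
}
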