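#' Exhaustive DTL reconciliation (test oracle)
#'
#' Enumerates every mapping of internal gene nodes to species nodes,
#' scoring each with the cheapest valid event labelling per node
#' (speciation with losses on both descent paths, duplication with losses
#' below the mapping node, or transfer with losses only on the kept side),
#' and returns the minimum total cost. This is exponential in the number of
#' internal gene nodes and is intended purely as an independent correctness
#' oracle for the dynamic programme; it shares no code with it.
#'
#' @inheritParams reconcile_rooted
#' @param max_leaves Refuse instances with more than this many gene or
#'   species leaves (default 7).
#' @return List with `cost` (possibly `Inf`), and for finite optima a
#'   `mapping` (0-based species node per gene node, leaves included) and
#'   per-node `events` labels.
#' @export
brute_force_reconcile <- function(gene, species, map = NULL,
                                  costs = event_costs(), max_leaves = 7L) {
  validate_tree(gene)
  validate_tree(species)
  stopifnot(ape::is.rooted(gene), ape::is.rooted(species))
  mg <- ape::Ntip(gene)
  ns <- ape::Ntip(species)
  if (mg > max_leaves || ns > max_leaves) {
    stop("instance too large for exhaustive search (limit ", max_leaves,
         " leaves)", call. = FALSE)
  }
  sc <- .species_context(species)
  N <- sc$arr$N
  cd <- costs$duplication; ct <- costs$transfer; cl <- costs$loss
  ANC <- sc$ANC
  depth <- sc$depth
  kids <- sc$arr$kids

  # local cost table L[s, s1, s2]: min event cost at a gene node mapped at
  # s whose children map exactly at s1 and s2 (with implied losses)
  L <- array(Inf, dim = c(N, N, N))
  lab <- array("", dim = c(N, N, N))
  for (s in seq_len(N)) {
    internal <- kids[s, 1L] >= 0L
    for (s1 in seq_len(N)) {
      for (s2 in seq_len(N)) {
        v <- Inf; e <- ""
        if (internal) {
          a <- kids[s, 1L] + 1L; b <- kids[s, 2L] + 1L
          if (ANC[a, s1] && ANC[b, s2]) {
            w <- cl * (depth[s1] - depth[a] + depth[s2] - depth[b])
            if (w < v) { v <- w; e <- "speciation" }
          }
          if (ANC[a, s2] && ANC[b, s1]) {
            w <- cl * (depth[s2] - depth[a] + depth[s1] - depth[b])
            if (w < v) { v <- w; e <- "speciation" }
          }
        }
        if (ANC[s, s1] && ANC[s, s2]) {
          w <- cd + cl * (depth[s1] + depth[s2] - 2L * depth[s])
          if (w < v) { v <- w; e <- "duplication" }
        }
        inc1 <- !(ANC[s, s1] || ANC[s1, s])
        inc2 <- !(ANC[s, s2] || ANC[s2, s])
        if (ANC[s, s1] && inc2) {
          w <- ct + cl * (depth[s1] - depth[s])
          if (w < v) { v <- w; e <- "transfer" }
        }
        if (ANC[s, s2] && inc1) {
          w <- ct + cl * (depth[s2] - depth[s])
          if (w < v) { v <- w; e <- "transfer" }
        }
        L[s, s1, s2] <- v
        lab[s, s1, s2] <- e
      }
    }
  }

  ga <- .tree_arrays(gene)
  img <- rep(NA_integer_, ga$N)
  img[seq_len(ga$m)] <- .gene_tip_images(gene, species, map) + 1L
  internal_nodes <- (ga$post + 1L)[ga$kids[ga$post + 1L, 1L] >= 0L]
  k <- length(internal_nodes)
  pos <- setNames(seq_len(k), internal_nodes) # assignment column per node

  child_spec <- lapply(internal_nodes, function(g) {
    ch <- ga$kids[g, ] + 1L
    lapply(ch, function(c1) {
      if (ga$kids[c1, 1L] < 0L) list(fixed = img[c1]) else
        list(col = pos[[as.character(c1)]])
    })
  })

  total <- N^k
  chunk <- 2^18
  best <- Inf
  best_assign <- NULL
  done <- 0
  while (done < total) {
    n_i <- min(chunk, total - done)
    t <- done + seq_len(n_i) - 1
    A <- matrix(0L, n_i, k)
    for (j in seq_len(k)) A[, j] <- as.integer((t %/% N^(j - 1)) %% N) + 1L
    cost <- numeric(n_i)
    for (i in seq_len(k)) {
      g <- internal_nodes[i]
      s <- A[, i]
      cs <- child_spec[[i]]
      s1 <- if (!is.null(cs[[1L]]$fixed)) rep(cs[[1L]]$fixed, n_i) else
        A[, cs[[1L]]$col]
      s2 <- if (!is.null(cs[[2L]]$fixed)) rep(cs[[2L]]$fixed, n_i) else
        A[, cs[[2L]]$col]
      cost <- cost + L[cbind(s, s1, s2)]
    }
    w <- which.min(cost)
    if (cost[w] < best) {
      best <- cost[w]
      best_assign <- A[w, ]
    }
    done <- done + n_i
  }

  out <- list(cost = best)
  if (is.finite(best)) {
    img[internal_nodes] <- best_assign
    events <- character(ga$N)
    for (i in seq_len(k)) {
      g <- internal_nodes[i]
      cs <- child_spec[[i]]
      s1 <- if (!is.null(cs[[1L]]$fixed)) cs[[1L]]$fixed else
        best_assign[cs[[1L]]$col]
      s2 <- if (!is.null(cs[[2L]]$fixed)) cs[[2L]]$fixed else
        best_assign[cs[[2L]]$col]
      events[g] <- lab[best_assign[i], s1, s2]
    }
    out$mapping <- img - 1L
    out$events <- events
  }
  out
}
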