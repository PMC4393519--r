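#' Event costs for DTL reconciliation
#'
#' The parsimony reconciliation charges `duplication` per duplication,
#' `transfer` per transfer and `loss` per implied loss; speciations are
#' free. The defaults (2, 3, 1) are the standard choice for microbial gene
#' families. `duplication = Inf` (or `tl_only = TRUE`) disables
#' duplications entirely ("TL mode"), appropriate for single-copy families
#' where all incongruence is attributed to transfer and loss.
#'
#' @param duplication,transfer,loss Non-negative costs; `duplication` may
#'   be `Inf`.
#' @param tl_only If `TRUE`, force `duplication = Inf`.
#' @return An object of class `"event_costs"`.
#' @export
event_costs <- function(duplication = 2, transfer = 3, loss = 1,
                        tl_only = FALSE) {
  if (tl_only) duplication <- Inf
  stopifnot(duplication >= 0, is.finite(transfer), transfer >= 0,
            is.finite(loss), loss >= 0)
  structure(list(duplication = duplication, transfer = transfer,
                 loss = loss), class = "event_costs")
}

#' @export
print.event_costs <- function(x, ...) {
  cat(sprintf("DTL event costs: duplication=%s transfer=%g loss=%g\n",
              format(x$duplication), x$transfer, x$loss))
  invisible(x)
}

#' Gene-leaf to species-leaf mapping
#'
#' Builds the total map from gene-tree leaf labels to species-tree leaf
#' labels. By default the species label is extracted from each gene label
#' by splitting on `sep` and keeping field `field` (e.g. `"S12_3"` maps to
#' `"S12"`); alternatively an explicit named vector or two-column
#' data frame / TSV file can be supplied.
#'
#' @param gene_labels Character vector of gene leaf labels.
#' @param map Optional explicit mapping: a named character vector
#'   (names = gene labels) or a two-column data frame (gene, species).
#' @param sep,field Pattern rule used when `map` is `NULL`.
#' @return Named character vector: `map[gene_label] == species_label`.
#' @export
leaf_map <- function(gene_labels, map = NULL, sep = "_", field = 1L) {
  if (is.null(map)) {
    sp <- vapply(strsplit(gene_labels, sep, fixed = TRUE),
                 function(x) x[[field]], character(1))
    return(setNames(sp, gene_labels))
  }
  if (is.data.frame(map)) map <- setNames(as.character(map[[2L]]),
                                          as.character(map[[1L]]))
  missing <- setdiff(gene_labels, names(map))
  if (length(missing)) {
    stop("no species mapping for gene leaves: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  map[gene_labels]
}

#' Read a two-column gene-to-species map file (TSV)
#' @param file Path to a tab-separated file `gene_label<TAB>species_label`.
#' @export
read_leaf_map <- function(file) {
  df <- read.table(file, sep = "\t", header = FALSE,
                   col.names = c("gene", "species"),
                   colClasses = "character")
  setNames(df$species, df$gene)
}

# Postorder array representation of a binary rooted phylo, 0-based for the
# C++ kernel. kids is -1 for leaves; post lists children before parents;
# rank is the postorder position (used for deterministic tie-breaking).
.tree_arrays <- function(phy) {
  m <- ape::Ntip(phy)
  N <- m + phy$Nnode
  kids <- matrix(-1L, N, 2L)
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    u <- po$edge[i, 1L]
    slot <- if (kids[u, 1L] < 0L) 1L else 2L
    kids[u, slot] <- po$edge[i, 2L] - 1L
  }
  root <- m + 1L
  post <- c(po$edge[, 2L], root) - 1L
  rank <- integer(N)
  rank[post + 1L] <- seq_len(N)
  list(m = m, N = N, kids = kids, post = post, root = root - 1L,
       rank = rank)
}

# Per-node species clade strings, ancestor relation and depths.
# ANC[a, b] is TRUE iff a is an ancestor of b or a == b (tip-set
# containment, exact for binary trees).
.species_context <- function(s) {
  arr <- .tree_arrays(s)
  N <- arr$N
  m <- arr$m
  tipsets <- vector("list", N)
  for (v in (arr$post + 1L)) {
    if (arr$kids[v, 1L] < 0L) {
      tipsets[[v]] <- s$tip.label[v]
    } else {
      tipsets[[v]] <- c(tipsets[[arr$kids[v, 1L] + 1L]],
                        tipsets[[arr$kids[v, 2L] + 1L]])
    }
  }
  clade <- vapply(tipsets, function(x) paste(sort(x), collapse = ","),
                  character(1))
  tip_id <- setNames(seq_len(m), s$tip.label)
  in_mat <- matrix(FALSE, N, m) # node x tip membership
  for (v in seq_len(N)) in_mat[v, tip_id[tipsets[[v]]]] <- TRUE
  sz <- lengths(tipsets)
  ANC <- (in_mat %*% t(in_mat)) == matrix(sz, N, N, byrow = TRUE)
  depth <- integer(N)
  parent <- integer(N)
  parent[arr$root + 1L] <- 0L
  for (v in rev(arr$post + 1L)) { # preorder
    if (arr$kids[v, 1L] >= 0L) {
      for (k in arr$kids[v, ] + 1L) {
        parent[k] <- v
        depth[k] <- depth[v] + 1L
      }
    }
  }
  list(arr = arr, clade = clade, ANC = ANC, depth = depth, parent = parent,
       tipsets = tipsets)
}

# Map gene tips to 0-based species node ids.
.gene_tip_images <- function(gene, species, map) {
  sigma <- leaf_map(gene$tip.label, map = map)
  unknown <- setdiff(unique(sigma), species$tip.label)
  if (length(unknown)) {
    stop("leaf map targets absent from species tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  match(sigma, species$tip.label) - 1L
}

#' Parsimony DTL reconciliation of a rooted gene tree
#'
#' Computes a minimum-cost reconciliation of a rooted binary gene tree with
#' a rooted binary (undated) species tree under the
#' duplication-transfer-loss model. Every internal gene node is labelled
#' speciation, duplication or transfer; losses are implied by the mapping.
#' Transfers may connect any two incomparable species lineages
#' (time-consistency is not checked). Ties are broken deterministically:
#' smallest species postorder index for mapping choices, and event
#' preference speciation > duplication > transfer at equal cost.
#'
#' @param gene Rooted binary `"phylo"` gene tree.
#' @param species Rooted binary `"phylo"` species tree.
#' @param map Gene-to-species leaf map (see [leaf_map()]); `NULL` applies
#'   the default `"_"`-prefix rule.
#' @param costs An [event_costs()] object.
#' @return Object of class `"dtl_reconciliation"`: total `cost`, `feasible`
#'   flag, `mapping` (species node id per gene node), `events` data frame
#'   (duplications, transfers, losses with gene clades and species
#'   locations), and event `counts`.
#' @export
reconcile_rooted <- function(gene, species, map = NULL,
                             costs = event_costs()) {
  validate_tree(gene)
  validate_tree(species)
  stopifnot(ape::is.rooted(species))
  if (!ape::is.rooted(gene)) {
    stop("gene tree is unrooted; use reconcile_unrooted()", call. = FALSE)
  }
  sc <- .species_context(species)
  ga <- .tree_arrays(gene)
  gleaf <- rep(-1L, ga$N)
  gleaf[seq_len(ga$m)] <- .gene_tip_images(gene, species, map)
  dp <- .dtl_dp_rooted(ga$kids, ga$post, gleaf, sc$arr$kids, sc$arr$post,
                       costs$duplication, costs$transfer, costs$loss, TRUE)
  res <- .backtrack(gene, species, ga, sc, dp, costs)
  res$gene <- gene
  res$species <- species
  res$costs <- costs
  class(res) <- "dtl_reconciliation"
  res
}

# Backtrack one optimal reconciliation from the DP tables. All tie-breaks
# deterministic: candidate species nodes are taken in postorder; at equal
# cost the event preference is speciation > duplication > transfer, and a
# lineage maps as high as its in() chain allows before charging losses.
.backtrack <- function(gene, species, ga, sc, dp, costs) {
  C <- dp$C; IN <- dp$IN; OUT <- dp$OUT
  cd <- costs$duplication; ct <- costs$transfer; cl <- costs$loss
  groot <- ga$root + 1L
  best <- dp$cost
  if (!is.finite(best)) {
    return(list(cost = Inf, feasible = FALSE, mapping = NULL,
                events = .empty_events(),
                counts = c(speciation = 0L, duplication = 0L,
                           transfer = 0L, loss = 0L)))
  }
  skids <- sc$arr$kids
  spost_nodes <- sc$arr$post + 1L # candidate order: species postorder
  pick_post <- function(vals, target) {
    for (v in spost_nodes) if (vals[v] == target) return(v)
    stop("backtrack failure: no candidate matches target cost")
  }
  gkids <- ga$kids
  m <- ga$m
  # gene clades
  gtips <- vector("list", ga$N)
  for (v in (ga$post + 1L)) {
    gtips[[v]] <- if (gkids[v, 1L] < 0L) gene$tip.label[v] else
      c(gtips[[gkids[v, 1L] + 1L]], gtips[[gkids[v, 2L] + 1L]])
  }
  gclade <- vapply(gtips, function(x) paste(sort(x), collapse = ","),
                   character(1))
  mapping <- integer(ga$N)
  evtype <- character(ga$N)
  ev <- list()
  add_event <- function(type, gnode, snode, donor = NA_integer_,
                        recipient = NA_integer_) {
    ev[[length(ev) + 1L]] <<- list(type = type, gene_node = gnode,
                                   species_node = snode, donor = donor,
                                   recipient = recipient)
  }
  descend <- function(g, s) {
    # g's lineage enters species node s; realize IN[g, s]
    repeat {
      if (IN[g, s] == C[g, s]) {
        assign_node(g, s)
        return(invisible())
      }
      s1 <- skids[s, 1L] + 1L; s2 <- skids[s, 2L] + 1L
      if (IN[g, s1] + cl == IN[g, s]) {
        add_event("loss", g, s2)
        s <- s1
      } else {
        add_event("loss", g, s1)
        s <- s2
      }
    }
  }
  assign_node <- function(g, s) {
    mapping[g] <<- s
    if (gkids[g, 1L] < 0L) {
      evtype[g] <<- "leaf"
      return(invisible())
    }
    a <- gkids[g, 1L] + 1L; b <- gkids[g, 2L] + 1L
    target <- C[g, s]
    internal_s <- skids[s, 1L] >= 0L
    if (internal_s) {
      s1 <- skids[s, 1L] + 1L; s2 <- skids[s, 2L] + 1L
      v1 <- IN[a, s1] + IN[b, s2]
      v2 <- IN[a, s2] + IN[b, s1]
      if (min(v1, v2) == target) {
        evtype[g] <<- "speciation"
        if (v1 <= v2) {
          descend(a, s1); descend(b, s2)
        } else {
          descend(a, s2); descend(b, s1)
        }
        return(invisible())
      }
    }
    if (IN[a, s] + IN[b, s] + cd == target) {
      evtype[g] <<- "duplication"
      add_event("duplication", g, s)
      descend(a, s); descend(b, s)
      return(invisible())
    }
    # transfer: keep one child in s's subtree, send the other to an
    # incomparable species node
    t1 <- IN[a, s] + OUT[b, s]
    t2 <- IN[b, s] + OUT[a, s]
    if (min(t1, t2) + ct != target) stop("backtrack failure at gene node ", g)
    evtype[g] <<- "transfer"
    if (t1 <= t2) { keep <- a; moved <- b } else { keep <- b; moved <- a }
    incomp <- !(sc$ANC[s, ] | sc$ANC[, s])
    cand <- C[moved, ]
    cand[!incomp] <- Inf
    rec <- pick_post(cand, OUT[moved, s])
    # identify the transfer by the moved subtree's clade: that is what a
    # true history records for the transferred lineage
    add_event("transfer", moved, s, donor = s, recipient = rec)
    descend(keep, s)
    assign_node(moved, rec)
    invisible()
  }
  s0 <- pick_post(C[groot, ], best)
  assign_node(groot, s0)
  events <- .events_frame(ev, gclade, sc)
  counts <- c(speciation = sum(evtype == "speciation"),
              duplication = sum(events$type == "duplication"),
              transfer = sum(events$type == "transfer"),
              loss = sum(events$type == "loss"))
  chg <- function(cost, n) if (n == 0L) 0 else cost * n # avoids Inf * 0
  total <- chg(cd, counts[["duplication"]]) +
    chg(ct, counts[["transfer"]]) + chg(cl, counts[["loss"]])
  if (abs(total - best) > 1e-6 * max(1, abs(best))) {
    stop("internal error: event decomposition does not match DP cost")
  }
  list(cost = best, feasible = TRUE, mapping = mapping, events = events,
       counts = counts, node_events = evtype)
}

.empty_events <- function() {
  data.frame(type = character(0), gene_clade = character(0),
             species = character(0), donor = character(0),
             recipient = character(0), stringsAsFactors = FALSE)
}

.events_frame <- function(ev, gclade, sc) {
  if (!length(ev)) return(.empty_events())
  data.frame(
    type = vapply(ev, `[[`, character(1), "type"),
    gene_clade = gclade[vapply(ev, `[[`, integer(1), "gene_node")],
    species = sc$clade[vapply(ev, function(e) e$species_node, integer(1))],
    donor = ifelse(is.na(vapply(ev, `[[`, integer(1), "donor")), NA,
                   sc$clade[vapply(ev, `[[`, integer(1), "donor")]),
    recipient = ifelse(is.na(vapply(ev, `[[`, integer(1), "recipient")), NA,
                       sc$clade[vapply(ev, `[[`, integer(1), "recipient")]),
    stringsAsFactors = FALSE
  )
}

#' Parsimony DTL reconciliation of an unrooted gene tree
#'
#' Evaluates all 2m-3 rootings of the unrooted gene tree and returns a
#' reconciliation of minimum cost over rootings, together with the chosen
#' rooted tree. Ties between rootings are broken by the smallest edge index
#' of the unrooted representation, so results are reproducible.
#'
#' @inheritParams reconcile_rooted
#' @param gene Gene tree `"phylo"`; rooted input is unrooted first.
#' @return A `"dtl_reconciliation"` with extra fields `rooted_gene` (the
#'   optimal rooting), `rooting_costs` (cost per candidate edge) and
#'   `root_edge`.
#' @export
reconcile_unrooted <- function(gene, species, map = NULL,
                               costs = event_costs()) {
  validate_tree(gene)
  validate_tree(species)
  g <- if (ape::is.rooted(gene)) ape::unroot(gene) else gene
  m <- ape::Ntip(g)
  stopifnot(m >= 3)
  tip_sp <- .gene_tip_images(g, species, map)
  sc <- .species_context(species)
  u <- .dtl_dp_unrooted(g$edge - 1L, m, tip_sp, sc$arr$kids, sc$arr$post,
                        costs$duplication, costs$transfer, costs$loss)
  if (!is.finite(u$best_cost)) {
    res <- list(cost = Inf, feasible = FALSE, mapping = NULL,
                events = .empty_events(),
                counts = c(speciation = 0L, duplication = 0L,
                           transfer = 0L, loss = 0L),
                rooting_costs = u$costs, root_edge = NA_integer_,
                rooted_gene = NULL, gene = g, species = species,
                costs = costs)
    class(res) <- "dtl_reconciliation"
    return(res)
  }
  rooted <- root_at_edge(g, u$best_edge)
  res <- reconcile_rooted(rooted, species, map = map, costs = costs)
  if (abs(res$cost - u$best_cost) > 1e-9 * max(1, abs(u$best_cost))) {
    stop("internal error: rooted DP disagrees with unrooted scan")
  }
  res$rooting_costs <- u$costs
  res$root_edge <- u$best_edge
  res$rooted_gene <- rooted
  res
}

#' Minimum DTL reconciliation cost of an unrooted gene tree
#'
#' Fast path used by the search: the optimal cost over all rootings,
#' without event backtracking.
#'
#' @inheritParams reconcile_unrooted
#' @export
dtl_cost <- function(gene, species, map = NULL, costs = event_costs()) {
  g <- if (ape::is.rooted(gene)) ape::unroot(gene) else gene
  tip_sp <- .gene_tip_images(g, species, map)
  sc <- .species_context(species)
  .dtl_dp_unrooted(g$edge - 1L, ape::Ntip(g), tip_sp, sc$arr$kids,
                   sc$arr$post, costs$duplication, costs$transfer,
                   costs$loss)$best_cost
}

#' Event records of a reconciliation
#'
#' One row per duplication, transfer and implied loss: the gene clade
#' (descendant leaf set of the gene node involved, comma-joined), the
#' species location (clade string identifying the species branch), and for
#' transfers the donor and recipient species branches.
#'
#' @param recon A `"dtl_reconciliation"`.
#' @return A data frame with columns `type`, `gene_clade`, `species`,
#'   `donor`, `recipient`.
#' @export
enumerate_events <- function(recon) {
  stopifnot(inherits(recon, "dtl_reconciliation"))
  if (!recon$feasible) stop("reconciliation is infeasible (infinite cost)")
  recon$events
}

#' @export
print.dtl_reconciliation <- function(x, ...) {
  cat("DTL reconciliation\n")
  if (!x$feasible) {
    cat("  infeasible under the given costs (cost = Inf)\n")
    return(invisible(x))
  }
  cat(sprintf("  cost: %g  (duplications: %d, transfers: %d, losses: %d)\n",
              x$cost, x$counts[["duplication"]], x$counts[["transfer"]],
              x$counts[["loss"]]))
  if (!is.null(x$root_edge)) {
    cat(sprintf("  optimal rooting: edge %d of the unrooted gene tree\n",
                x$root_edge))
  }
  invisible(x)
}
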