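#' Simulate a Yule (pure-birth) species tree
#'
#' Pure-birth tree grown until `n_taxa` extant lineages, rescaled to unit
#' root-to-tip height, with leaves labelled `S1..Sn`. Backed by
#' [phytools::pbtree()]; randomness flows from R's RNG.
#'
#' @param n_taxa Number of extant species (>= 3).
#' @return An ultrametric rooted binary `"phylo"` of height 1.
#' @export
simulate_species_tree <- function(n_taxa) {
  stopifnot(n_taxa >= 3)
  tr <- phytools::pbtree(n = n_taxa, scale = 1, quiet = TRUE)
  tr$tip.label <- paste0("S", seq_len(n_taxa))
  tr
}

#' DTL event rates for the gene-family simulator
#'
#' Rates are events per gene lineage per unit species-tree time (the
#' species tree has height 1). The named presets reproduce the published
#' mean observable event and leaf counts for 50-taxon unit-height Yule
#' species trees (mean leaves 52.3 / 70.4 / 91.3 / 109, duplications 1.2 /
#' 2.8 / 5.0 / 10.0, transfers 2.2 / 5.5 / 9.9 / 20.6, losses 2.1 / 2.3 /
#' 2.9 / 6.9 for low / medium / high / veryhigh); they were fitted with
#' [calibrate_rates()] against those targets and are fixed package
#' constants.
#'
#' @param preset One of `"low"`, `"medium"`, `"high"`, `"veryhigh"`, or
#'   `NULL` when giving explicit rates.
#' @param duplication,transfer,loss Explicit rates (ignored when `preset`
#'   is given).
#' @return Object of class `"dtl_rates"`.
#' @export
dtl_rates <- function(preset = NULL, duplication = 0, transfer = 0,
                      loss = 0) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(.rate_presets))
    r <- .rate_presets[[preset]]
    duplication <- r[[1]]; transfer <- r[[2]]; loss <- r[[3]]
  }
  stopifnot(duplication >= 0, transfer >= 0, loss >= 0,
            all(is.finite(c(duplication, transfer, loss))))
  structure(list(duplication = duplication, transfer = transfer,
                 loss = loss, preset = preset %||% "custom"),
            class = "dtl_rates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Calibrated against the published mean observable counts (see
# calibrate_rates and the methods vignette); values are rates per unit
# height of a 50-taxon Yule species tree.
.rate_presets <- list(
  low = c(0.08254, 0.14560, 0.15564),
  medium = c(0.15987, 0.30729, 0.15769),
  high = c(0.25065, 0.47865, 0.18503),
  veryhigh = c(0.41409, 0.82657, 0.40829)
)

#' @export
print.dtl_rates <- function(x, ...) {
  cat(sprintf("DTL rates (%s): duplication=%g transfer=%g loss=%g\n",
              x$preset, x$duplication, x$transfer, x$loss))
  invisible(x)
}

# internal: species timing context for the simulator
.sim_species_context <- function(species) {
  n <- ape::Ntip(species)
  N <- n + species$Nnode
  time <- ape::node.depth.edgelength(species)
  root <- n + 1L
  kids <- vector("list", N)
  parent <- integer(N)
  for (i in seq_len(nrow(species$edge))) {
    u <- species$edge[i, 1L]; v <- species$edge[i, 2L]
    kids[[u]] <- c(kids[[u]], v)
    parent[v] <- u
  }
  sc <- .species_context(species)
  list(n = n, N = N, time = time, root = root, kids = kids,
       parent = parent, clade = sc$clade, ANC = sc$ANC)
}

#' Simulate a gene tree along a species tree under a DTL birth-death model
#'
#' A single gene lineage enters at the species root and evolves down the
#' (ultrametric, unit-height) species tree. Within a species branch the
#' lineage duplicates in place at rate `duplication`, dies at rate `loss`,
#' and at rate `transfer` seeds a copy on a uniformly chosen contemporaneous
#' other species branch; at species-tree speciations it splits into both
#' descendant branches. Extinct lineages are pruned, unary nodes
#' suppressed, and all events recorded.
#'
#' The returned history lists the *observable* events: duplications and
#' transfers whose both child lineages left surviving descendants (these
#' correspond to binary nodes of the pruned gene tree), and losses, one per
#' maximal extinct subtree that branched off at a species-tree speciation
#' below the pruned gene root. Gene leaves are labelled
#' `<species>_<copy index>`.
#'
#' @param species Ultrametric rooted binary `"phylo"` species tree.
#' @param rates A [dtl_rates()] object.
#' @param min_leaves Resample families with fewer surviving leaves
#'   (default 3).
#' @param max_retries Retry cap before giving up.
#' @return List of class `"dtl_history"` with elements `gene` (pruned
#'   rooted gene tree, branch lengths in species-tree time units), `events`
#'   (data frame: `type`, `gene_clade`, `species`, `donor`, `recipient`,
#'   `time`), `counts` (leaves, duplication, transfer, loss), `retries`,
#'   and `species`.
#' @export
simulate_gene_tree <- function(species, rates, min_leaves = 3L,
                               max_retries = 100L) {
  stopifnot(inherits(rates, "dtl_rates"))
  ctx <- .sim_species_context(species)
  for (try in 0:max_retries) {
    sim <- .sim_once(ctx, rates)
    if (sim$n_leaves >= min_leaves) {
      sim$retries <- try
      sim$species <- species
      class(sim) <- "dtl_history"
      return(sim)
    }
  }
  stop("gene family went (nearly) extinct in ", max_retries + 1,
       " attempts; rates too loss-heavy?", call. = FALSE)
}

# One forward simulation plus pruning/bookkeeping.
.sim_once <- function(ctx, rates) {
  ld <- rates$duplication; lt <- rates$transfer; ll <- rates$loss
  tot <- ld + lt + ll
  time <- ctx$time; kids <- ctx$kids; parent <- ctx$parent
  n <- ctx$n; N <- ctx$N; root <- ctx$root

  alive_edges <- function(t) {
    w <- setdiff(seq_len(N), root)
    w[time[parent[w]] < t & t <= time[w]]
  }
  lca2 <- function(v, w) {
    while (v != w) if (time[v] >= time[w]) v <- parent[v] else w <- parent[w]
    v
  }
  # species position where a lineage first leaves an observable record:
  # pass-through nodes with an extinct side leave no trace; a surviving
  # speciation is observed at its species node, a duplication at the
  # junction (LCA) of its two copies' observable positions, and a
  # transfer at its donor-side continuation. This is the recipient
  # location recoverable for a transferred lineage.
  first_observable_sp <- function(node) {
    repeat {
      if (node$kind %in% c("leaf", "dead")) return(node$sp)
      s1 <- .has_survivor(node$children[[1L]])
      s2 <- .has_survivor(node$children[[2L]])
      if (s1 && s2) {
        if (node$kind == "spec") return(node$sp)
        if (node$kind == "dup") {
          return(lca2(first_observable_sp(node$children[[1L]]),
                      first_observable_sp(node$children[[2L]])))
        }
        node <- node$children[[1L]] # transfer: donor-side continuation
      } else {
        node <- node$children[[if (s1) 1L else 2L]]
      }
    }
  }

  raw <- c(duplication = 0L, transfer = 0L, loss = 0L)
  # recursive growth; nodes are nested lists
  grow <- function(v, t0) {
    repeat {
      dt <- if (tot > 0) rexp(1, tot) else Inf
      if (t0 + dt >= time[v]) {
        if (v <= n) return(list(kind = "leaf", sp = v, time = time[v]))
        return(list(kind = "spec", sp = v, time = time[v],
                    children = list(grow(kids[[v]][1L], time[v]),
                                    grow(kids[[v]][2L], time[v]))))
      }
      t0 <- t0 + dt
      u <- runif(1) * tot
      if (u < ll) {
        raw[["loss"]] <<- raw[["loss"]] + 1L
        return(list(kind = "dead", sp = v, time = t0))
      }
      if (u < ll + ld) {
        raw[["duplication"]] <<- raw[["duplication"]] + 1L
        return(list(kind = "dup", sp = v, time = t0,
                    children = list(grow(v, t0), grow(v, t0))))
      }
      cand <- setdiff(alive_edges(t0), v)
      if (!length(cand)) next # nowhere to transfer; redraw waiting time
      raw[["transfer"]] <<- raw[["transfer"]] + 1L
      r <- cand[sample.int(length(cand), 1L)]
      return(list(kind = "transfer", sp = v, time = t0, recipient = r,
                  children = list(grow(v, t0), grow(r, t0))))
    }
  }
  top <- list(kind = "spec", sp = root, time = 0,
              children = list(grow(kids[[root]][1L], 0),
                              grow(kids[[root]][2L], 0)))

  events <- list()
  leaf_count <- integer(n) # per-species copy counter
  newick_parts <- character(0)

  # prune recursively; returns NULL (extinct) or
  # list(nw = newick fragment, time, leaves). `entry` is the species node
  # where the current gene lineage segment started, i.e. the position
  # handed down by its nearest observable ancestor node (NA above the
  # pruned root and below a transfer landing, whose position is
  # unconstrained). Event locations are recorded at their observable
  # granularity: a transfer donor at the segment entry (the event is only
  # localizable to the segment between the last observable node and the
  # event itself; the raw branch is kept in the `species` column), the
  # recipient at the moved lineage's first observable node, and a loss
  # only when an anchored lineage is forced through the speciation where
  # the extinction happened.
  prune <- function(node, entry, penclose) {
    if (node$kind == "leaf") {
      leaf_count[node$sp] <<- leaf_count[node$sp] + 1L
      lab <- paste0(ctx$clade[node$sp], "_", leaf_count[node$sp])
      return(list(nw = lab, time = node$time, leaves = lab))
    }
    if (node$kind == "dead") return(NULL)
    k1 <- node$children[[1L]]
    k2 <- node$children[[2L]]
    s1 <- .has_survivor(k1); s2 <- .has_survivor(k2)
    if (!s1 && !s2) return(NULL)
    if (s1 && s2) {
      if (node$kind == "spec") {
        a <- prune(k1, kids[[node$sp]][1L], entry)
        b <- prune(k2, kids[[node$sp]][2L], entry)
      } else if (node$kind == "dup") {
        # a duplication is observed at the junction of its two copies;
        # extinctions between the raw branch and that junction leave no
        # trace, so the copies' lineages are anchored at the junction
        obs <- lca2(first_observable_sp(k1), first_observable_sp(k2))
        a <- prune(k1, obs, entry)
        b <- prune(k2, obs, entry)
        events[[length(events) + 1L]] <<- list(
          type = "duplication",
          gene_clade = .clade_str(c(a$leaves, b$leaves)),
          species = ctx$clade[node$sp], donor = NA_character_,
          recipient = NA_character_, time = node$time)
      } else { # transfer
        a <- prune(k1, node$sp, entry)
        b <- prune(k2, NA_integer_, NA_integer_)
        donor_sp <- if (is.na(entry)) node$sp else entry
        events[[length(events) + 1L]] <<- list(
          type = "transfer", gene_clade = .clade_str(b$leaves),
          species = ctx$clade[node$sp], donor = ctx$clade[donor_sp],
          recipient = ctx$clade[first_observable_sp(k2)],
          time = node$time)
      }
      lv <- c(a$leaves, b$leaves)
      nw <- paste0("(", a$nw, ":", sprintf("%.10f", a$time - node$time),
                   ",", b$nw, ":", sprintf("%.10f", b$time - node$time),
                   ")")
      return(list(nw = nw, time = node$time, leaves = lv))
    }
    # exactly one side survives: unary pass-through
    kept_died_transfer <- node$kind == "transfer" && s2
    res <- if (kept_died_transfer) {
      prune(k2, NA_integer_, NA_integer_)
    } else {
      prune(if (s1) k1 else k2, entry, penclose)
    }
    if (kept_died_transfer) {
      # donor lineage died out, but the jump of the surviving clade into
      # an incomparable species region is still observable; the jump is
      # detected at the enclosing binary gene node, whose own segment
      # entry is where the donor position is reported
      if (!is.na(penclose)) {
        events[[length(events) + 1L]] <<- list(
          type = "transfer", gene_clade = .clade_str(res$leaves),
          species = ctx$clade[node$sp], donor = ctx$clade[penclose],
          recipient = ctx$clade[first_observable_sp(k2)],
          time = node$time)
      }
      return(res)
    }
    if (node$kind == "spec" && !is.na(entry) &&
        ctx$ANC[entry, node$sp]) {
      dead_side <- kids[[node$sp]][if (s1) 2L else 1L]
      events[[length(events) + 1L]] <<- list(
        type = "loss", gene_clade = .clade_str(res$leaves),
        species = ctx$clade[dead_side], donor = NA_character_,
        recipient = NA_character_, time = node$time)
    }
    res
  }
  out <- prune(top, NA_integer_, NA_integer_)
  # out cannot be NULL here unless everything died
  if (is.null(out)) {
    return(list(n_leaves = 0L, gene = NULL, events = .empty_history(),
                counts = c(leaves = 0L, duplication = 0L, transfer = 0L,
                           loss = 0L)))
  }
  nleaf <- length(out$leaves)
  if (nleaf < 2L) {
    return(list(n_leaves = nleaf, gene = NULL, events = .empty_history(),
                counts = c(leaves = nleaf, duplication = 0L,
                           transfer = 0L, loss = 0L)))
  }
  gene <- ape::read.tree(text = paste0(out$nw, ";"))
  ev <- if (length(events)) {
    do.call(rbind, lapply(events, function(e)
      data.frame(e, stringsAsFactors = FALSE)))
  } else .empty_history()
  list(n_leaves = nleaf, gene = gene, events = ev,
       counts = c(leaves = nleaf,
                  duplication = sum(ev$type == "duplication"),
                  transfer = sum(ev$type == "transfer"),
                  loss = sum(ev$type == "loss")),
       counts_raw = raw)
}

.has_survivor <- function(node) {
  if (node$kind == "leaf") return(TRUE)
  if (node$kind == "dead") return(FALSE)
  .has_survivor(node$children[[1L]]) || .has_survivor(node$children[[2L]])
}

.clade_str <- function(x) paste(sort(x), collapse = ",")

.empty_history <- function() {
  data.frame(type = character(0), gene_clade = character(0),
             species = character(0), donor = character(0),
             recipient = character(0), time = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.dtl_history <- function(x, ...) {
  cat(sprintf(paste0("simulated gene family: %d leaves, %d duplications, ",
                     "%d transfers, %d losses\n"),
              x$counts[["leaves"]], x$counts[["duplication"]],
              x$counts[["transfer"]], x$counts[["loss"]]))
  invisible(x)
}

#' Rescale gene-tree branch lengths to a target mutation rate
#'
#' Uniformly rescales so that the mean root-to-leaf path length equals
#' `target` expected substitutions per site. Branch-length proportions are
#' preserved.
#'
#' @param gene Rooted `"phylo"` with positive total branch length.
#' @param target Mean root-to-leaf depth after scaling (substitutions per
#'   site).
#' @export
scale_to_mutation_rate <- function(gene, target) {
  stopifnot(target > 0, !is.null(gene$edge.length))
  depths <- ape::node.depth.edgelength(gene)[seq_len(ape::Ntip(gene))]
  mu <- mean(depths)
  if (mu <= 0) stop("tree has zero depth; cannot rescale", call. = FALSE)
  gene$edge.length <- gene$edge.length * (target / mu)
  gene
}

#' Simulate an amino-acid alignment down a gene tree
#'
#' Root sequence from the model's equilibrium frequencies; each site is
#' independently assigned one of the discrete-gamma rate categories (equal
#' prior weight) and evolved along the tree with the corresponding rate
#' multiplier. Sequence evolution itself is delegated to
#' [phangorn::simSeq()].
#'
#' @param gene Rooted `"phylo"`, branch lengths in substitutions/site.
#' @param length Alignment length (columns).
#' @param model A [substitution_model()]; default JTT, gamma shape 1, 4
#'   categories.
#' @return Character matrix (taxa x sites) of amino-acid states, class
#'   `"aa_alignment"`.
#' @export
simulate_alignment <- function(gene, length, model = substitution_model()) {
  k <- model$categories
  rates <- phangorn::discrete.gamma(model$shape, k)
  cat_of_site <- sample.int(k, length, replace = TRUE)
  out <- matrix(NA_character_, nrow = ape::Ntip(gene), ncol = length,
                dimnames = list(gene$tip.label, NULL))
  for (c_i in seq_len(k)) {
    idx <- which(cat_of_site == c_i)
    if (!length(idx)) next
    sim <- phangorn::simSeq(gene, l = length(idx), type = "AA",
                            model = model$exchange, rate = rates[c_i])
    m <- toupper(as.character(sim))
    out[rownames(m), idx] <- m
  }
  structure(out, class = c("aa_alignment", "matrix"))
}

#' Calibrate simulator rates against target mean counts
#'
#' Iterative multiplicative fitting: simulate `n_reps` gene families at the
#' current rates over the supplied species-tree ensemble, compare mean
#' observable counts with the targets, and update each rate by a damped
#' ratio. Used to produce the packaged presets; exposed for recalibration
#' against other regimes.
#'
#' @param targets Named list/vector with `duplications`, `transfers`,
#'   `losses` (mean counts per family; `leaves` may be present and is
#'   reported but not directly fitted).
#' @param species_trees List of ultrametric species trees to draw from.
#' @param n_reps Families simulated per evaluation (default 300).
#' @param rounds Update rounds (default 8).
#' @param start Optional starting [dtl_rates()].
#' @return A [dtl_rates()] with attribute `"achieved"` (mean counts at the
#'   returned rates).
#' @export
calibrate_rates <- function(targets, species_trees, n_reps = 300L,
                            rounds = 8L, start = NULL) {
  targets <- as.list(targets)
  need <- c("duplications", "transfers", "losses")
  stopifnot(all(need %in% names(targets)))
  Lbar <- mean(vapply(species_trees, function(s) sum(s$edge.length),
                      numeric(1)))
  r <- if (is.null(start)) {
    dtl_rates(duplication = max(targets$duplications, 1e-3) / Lbar,
              transfer = max(targets$transfers, 1e-3) / Lbar,
              loss = max(targets$losses, 1e-3) / Lbar)
  } else start
  achieved <- NULL
  measure <- function(rr) {
    cnt <- vapply(seq_len(n_reps), function(i) {
      s <- species_trees[[((i - 1L) %% length(species_trees)) + 1L]]
      simulate_gene_tree(s, rr)$counts
    }, numeric(4))
    rowMeans(cnt)
  }
  for (it in seq_len(rounds)) {
    achieved <- measure(r)
    upd <- function(rate, target, got) {
      if (target <= 0) return(0)
      f <- (target / max(got, 0.05))^0.7
      rate * min(max(f, 0.5), 2)
    }
    r <- dtl_rates(duplication = upd(r$duplication, targets$duplications,
                                     achieved[["duplication"]]),
                   transfer = upd(r$transfer, targets$transfers,
                                  achieved[["transfer"]]),
                   loss = upd(r$loss, targets$losses, achieved[["loss"]]))
  }
  attr(r, "achieved") <- measure(r)
  r
}

#' Simulate one complete gene family replicate
#'
#' Species tree (unless supplied), true gene tree with history, mutation
#' rate scaling and sequence alignment — one cell of the simulation grid.
#'
#' @param n_taxa Species-tree size (ignored when `species` given).
#' @param rates A [dtl_rates()].
#' @param mutation_rate Mean root-to-leaf substitutions/site (1, 3, 5 or
#'   10 in the study design).
#' @param length Alignment columns (173 or 333 in the study design).
#' @param species Optional pre-built species tree.
#' @param model A [substitution_model()].
#' @param min_leaves Minimum surviving gene leaves (families below are
#'   resampled; see [simulate_gene_tree()]).
#' @return List: `species`, `history` (with true gene tree in time units),
#'   `gene` (scaled true gene tree), `alignment`, `map` (leaf map).
#' @export
simulate_family <- function(n_taxa = 50L, rates = dtl_rates("medium"),
                            mutation_rate = 1, length = 333L,
                            species = NULL,
                            model = substitution_model(),
                            min_leaves = 3L) {
  if (is.null(species)) species <- simulate_species_tree(n_taxa)
  hist <- simulate_gene_tree(species, rates, min_leaves = min_leaves)
  scaled <- scale_to_mutation_rate(hist$gene, mutation_rate)
  aln <- simulate_alignment(scaled, length, model)
  list(species = species, history = hist, gene = scaled, alignment = aln,
       map = leaf_map(hist$gene$tip.label))
}
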