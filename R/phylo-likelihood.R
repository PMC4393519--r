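#' Amino-acid substitution model specification
#'
#' An empirical exchangeability model (default JTT) with discrete-gamma
#' rate heterogeneity. The model is held fixed across a whole error
#' correction run so that the likelihoods of alternative topologies remain
#' comparable.
#'
#' @param exchange Empirical amino-acid model name understood by phangorn
#'   (e.g. `"JTT"`, `"WAG"`, `"LG"`).
#' @param shape Gamma shape parameter (> 0).
#' @param categories Number of discrete gamma categories (>= 1).
#' @return Object of class `"substitution_model"`.
#' @export
substitution_model <- function(exchange = "JTT", shape = 1,
                               categories = 4L) {
  stopifnot(shape > 0, categories >= 1)
  structure(list(exchange = exchange, shape = shape,
                 categories = as.integer(categories)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("%s + gamma(shape=%g, %d categories)\n", x$exchange, x$shape,
              x$categories))
  invisible(x)
}

#' Coerce an alignment to phangorn's phyDat
#'
#' Accepts an `"aa_alignment"` character matrix or an existing `phyDat`.
#' Columns consisting entirely of gaps/ambiguities carry no information and
#' are dropped with a warning.
#'
#' @param alignment Character matrix (taxa x sites) or `phyDat`.
#' @export
as_phydat <- function(alignment) {
  if (inherits(alignment, "phyDat")) return(alignment)
  stopifnot(is.matrix(alignment))
  gapish <- alignment %in% c("-", "?", "X", "x", ".")
  dim(gapish) <- dim(alignment)
  allgap <- colSums(!gapish) == 0L
  if (any(allgap)) {
    warning(sum(allgap), " all-gap column(s) dropped")
    alignment <- alignment[, !allgap, drop = FALSE]
  }
  phangorn::phyDat(alignment, type = "AA")
}

#' Read an amino-acid alignment (FASTA or relaxed PHYLIP)
#' @param file Path.
#' @param format `"fasta"`, `"phylip"`, or `"auto"` (sniff the first
#'   character).
#' @return An `"aa_alignment"` character matrix.
#' @export
read_alignment <- function(file, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- substr(readLines(file, n = 1L), 1L, 1L)
    format <- if (first == ">") "fasta" else "phylip"
  }
  pd <- phangorn::read.phyDat(file, format = format, type = "AA")
  m <- toupper(as.character(pd))
  structure(m, class = c("aa_alignment", "matrix"))
}

#' Write an amino-acid alignment
#' @param alignment `"aa_alignment"` matrix or `phyDat`.
#' @param file Path.
#' @param format `"fasta"` or `"phylip"`.
#' @export
write_alignment <- function(alignment, file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  pd <- as_phydat(alignment)
  phangorn::write.phyDat(pd, file, format = format)
  invisible(file)
}

# Fit a pml object with the model fixed (no parameter re-estimation).
.pml_fit <- function(tree, data, model) {
  if (ape::is.rooted(tree) && ape::Ntip(tree) > 2) tree <- ape::unroot(tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  phangorn::pml(tree, data, model = model$exchange, k = model$categories,
                shape = model$shape)
}

#' Per-site log-likelihoods of a topology
#'
#' Felsenstein pruning likelihood of each alignment column under the fixed
#' substitution model, mixed over the discrete-gamma categories with equal
#' prior weight. Gaps and ambiguities are treated as missing data. The
#' result is invariant to root placement (the model is reversible).
#' Computation is delegated to [phangorn::pml()]; per-pattern values are
#' expanded back to per-column order.
#'
#' @param tree `"phylo"` with branch lengths (substitutions/site).
#' @param alignment Alignment (`"aa_alignment"` matrix or `phyDat`)
#'   covering all leaves of `tree`.
#' @param model A [substitution_model()].
#' @return Numeric vector of per-column log-likelihoods, with attribute
#'   `"logLik"` (their sum).
#' @export
site_log_likelihoods <- function(tree, alignment,
                                 model = substitution_model()) {
  data <- as_phydat(alignment)
  missing <- setdiff(tree$tip.label, names(data))
  if (length(missing)) {
    stop("alignment lacks sequences for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fit <- .pml_fit(tree, data, model)
  sl <- fit$siteLik[attr(data, "index")]
  if (any(!is.finite(sl))) {
    stop("non-finite site likelihood at column(s) ",
         paste(head(which(!is.finite(sl)), 5L), collapse = ", "),
         call. = FALSE)
  }
  structure(sl, logLik = fit$logLik)
}

#' Optimize branch lengths for a fixed topology
#'
#' Refits branch lengths by maximum likelihood with the substitution model
#' held fixed, as needed to make proposal topologies comparable in the SH
#' test. Iterates until the improvement falls below `epsilon` or `maxit`
#' sweeps.
#'
#' @inheritParams site_log_likelihoods
#' @param epsilon Convergence tolerance on the log-likelihood
#'   (default 1e-3).
#' @param maxit Maximum optimization sweeps (default 10).
#' @return List: `tree` (with optimized lengths, unrooted), `logLik`,
#'   `site_loglik` (per-column vector).
#' @export
optimize_branch_lengths <- function(tree, alignment,
                                    model = substitution_model(),
                                    epsilon = 1e-3, maxit = 10L) {
  data <- as_phydat(alignment)
  if (ape::Ntip(tree) == 2L) {
    # single free parameter: the path length between the two leaves
    score <- function(len) {
      tr <- tree
      tr$edge.length <- rep(len / 2, nrow(tr$edge))
      .pml_fit(tr, data, model)$logLik
    }
    opt <- optimize(score, c(1e-8, 50), maximum = TRUE, tol = 1e-6)
    tree$edge.length <- rep(opt$maximum / 2, nrow(tree$edge))
    fit <- .pml_fit(tree, data, model)
    sl <- fit$siteLik[attr(data, "index")]
    return(list(tree = fit$tree, logLik = fit$logLik,
                site_loglik = structure(sl, logLik = fit$logLik)))
  }
  fit <- .pml_fit(tree, data, model)
  opt <- suppressWarnings(
    phangorn::optim.pml(fit, optEdge = TRUE,
                        control = phangorn::pml.control(
                          epsilon = epsilon, maxit = maxit, trace = 0))
  )
  if (opt$logLik + 1e-9 < fit$logLik) opt <- fit # never degrade
  sl <- opt$siteLik[attr(data, "index")]
  list(tree = opt$tree, logLik = opt$logLik,
       site_loglik = structure(sl, logLik = opt$logLik))
}

#' Two-tree Shimodaira-Hasegawa test via RELL resampling
#'
#' Tests the null hypothesis that two topologies are equally supported by
#' the alignment. The statistic is the observed log-likelihood difference
#' delta = max(0, sum(best) - sum(alt)). The null distribution is built by
#' bootstrap resampling of alignment columns without re-optimization
#' (RELL): each tree's resampled log-likelihood sum is centred by that
#' tree's mean resampled sum, and the p-value is the fraction of resamples
#' whose centred difference is at least delta. One-sided; reproducible
#' under `set.seed()`.
#'
#' @param best,alt Per-site log-likelihood vectors (equal length), `best`
#'   conventionally the reference (input ML) tree.
#' @param resamples Bootstrap resamples (>= 100; default 1000).
#' @return Object of class `"sh_test"`: `delta`, `p.value`, `resamples`,
#'   and the two total log-likelihoods.
#' @export
sh_test <- function(best, alt, resamples = 1000L) {
  if (length(best) != length(alt)) {
    stop("site log-likelihood vectors differ in length", call. = FALSE)
  }
  stopifnot(resamples >= 100L)
  L <- length(best)
  delta <- max(0, sum(best) - sum(alt))
  w <- rmultinom(resamples, L, rep.int(1, L)) # L x B column weights
  sums <- crossprod(w, cbind(best, alt))      # B x 2
  centered <- sweep(sums, 2L, colMeans(sums))
  p <- mean(centered[, 1L] - centered[, 2L] >= delta)
  structure(list(delta = delta, p.value = p, resamples = resamples,
                 logLik = c(best = sum(best), alt = sum(alt))),
            class = "sh_test")
}

#' @export
print.sh_test <- function(x, ...) {
  cat(sprintf(paste0("SH test (RELL, %d resamples): delta = %.3f, ",
                     "p = %.4f\n"), x$resamples, x$delta, x$p.value))
  invisible(x)
}
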