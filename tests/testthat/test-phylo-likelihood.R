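# The pruning/likelihood machinery is delegated to phangorn; these tests
# check our wrapper contracts (per-column expansion, root invariance,
# missing-data handling) and the native SH/RELL test.

test_that("two-taxon site likelihoods match a matrix-exponential oracle", {
  tr <- ape::read.tree(text = "(A:0.3,B:0.5);")
  aln <- structure(matrix(c("M", "M", "K", "R"), nrow = 2,
                          dimnames = list(c("A", "B"), NULL)),
                   class = c("aa_alignment", "matrix"))
  model <- substitution_model(shape = 1, categories = 4)
  sl <- site_log_likelihoods(tr, aln, model)
  expect_length(sl, 2)
  # oracle: lik = sum_c (1/4) sum_x pi_x P_x,r1(r_c t1) P_x,r2(r_c t2),
  # using the generator phangorn assembled for the same model
  fit <- phangorn::pml(tr, as_phydat(aln), model = "JTT", k = 4, shape = 1)
  aa <- toupper(attr(as_phydat(aln), "levels"))
  Q <- matrix(0, 20, 20, dimnames = list(aa, aa))
  Q[lower.tri(Q)] <- fit$Q
  Q <- Q + t(Q)
  bf <- fit$bf
  Q <- Q * rep(bf, each = 20) # rate matrix with equilibrium frequencies
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * bf) # normalize to 1 substitution/unit length
  rates <- phangorn::discrete.gamma(1, 4)
  site_lik <- function(r1, r2) {
    tot <- 0
    for (rc in rates) {
      P1 <- ape::matexpo(Q * (rc * 0.3))
      P2 <- ape::matexpo(Q * (rc * 0.5))
      dimnames(P1) <- dimnames(P2) <- list(aa, aa)
      tot <- tot + 0.25 * sum(bf * P1[, r1] * P2[, r2])
    }
    log(tot)
  }
  expect_equal(sl[1], site_lik("M", "M"), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(sl[2], site_lik("K", "R"), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("site log-likelihoods are invariant to root placement", {
  set.seed(301)
  fam <- small_family(n_taxa = 8, length = 60)
  tr <- ape::unroot(fam$gene)
  base <- site_log_likelihoods(tr, fam$alignment)
  for (e in c(1, 4, 7)) {
    rooted <- root_at_edge(tr, e)
    sl <- site_log_likelihoods(rooted, fam$alignment)
    expect_equal(as.numeric(sl), as.numeric(base), tolerance = 1e-8)
  }
})

test_that("a no-substitution column at zero length reduces to log(pi)", {
  tr <- ape::read.tree(text = "(A:0,B:0,C:0);")
  aln <- structure(matrix("W", nrow = 3, ncol = 1,
                          dimnames = list(c("A", "B", "C"), NULL)),
                   class = c("aa_alignment", "matrix"))
  sl <- site_log_likelihoods(tr, aln)
  fit <- phangorn::pml(ape::unroot(ape::read.tree(text = "(A:1,B:1,C:1);")),
                       as_phydat(aln), model = "JTT")
  pi_w <- fit$bf[match("W", toupper(attr(as_phydat(aln), "levels")))]
  expect_equal(as.numeric(sl), log(pi_w), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("gaps are missing data and all-gap columns are dropped", {
  tr <- ape::read.tree(text = "(A:0.2,B:0.4);")
  aln <- structure(matrix(c("M", "M", "-", "-"), nrow = 2,
                          dimnames = list(c("A", "B"), NULL)),
                   class = c("aa_alignment", "matrix"))
  expect_warning(d <- as_phydat(aln), "all-gap")
  expect_equal(sum(attr(d, "weight")), 1)
  aln2 <- structure(matrix(c("M", "M", "-", "K"), nrow = 2,
                           dimnames = list(c("A", "B"), NULL)),
                    class = c("aa_alignment", "matrix"))
  sl <- site_log_likelihoods(tr, aln2)
  # a column with one gap has the likelihood of a single observed residue
  expect_lt(abs(exp(sl[2]) - sum(exp(sl[2]))), 1e-12)
  expect_true(all(is.finite(sl)))
  expect_error(site_log_likelihoods(ape::read.tree(text = "(A:1,Z:1);"),
                                    aln2), "lacks sequences")
})

test_that("branch-length optimization improves and then converges", {
  set.seed(302)
  fam <- small_family(n_taxa = 8, length = 100)
  start <- ape::unroot(fam$gene)
  start$edge.length <- rep(0.3, nrow(start$edge))
  l0 <- attr(site_log_likelihoods(start, fam$alignment), "logLik")
  opt1 <- optimize_branch_lengths(start, fam$alignment)
  expect_gte(opt1$logLik, l0)
  opt2 <- optimize_branch_lengths(opt1$tree, fam$alignment)
  expect_lt(abs(opt2$logLik - opt1$logLik), 1e-2) # converged
  # identical sequences force near-zero optimal lengths
  tr2 <- ape::read.tree(text = "(A:0.5,B:0.5);")
  same <- structure(matrix(rep(c("L", "L"), 50), nrow = 2, byrow = FALSE,
                           dimnames = list(c("A", "B"), NULL)),
                    class = c("aa_alignment", "matrix"))
  opt3 <- optimize_branch_lengths(tr2, same)
  expect_lt(sum(opt3$tree$edge.length), 1e-4)
})

test_that("sh_test contracts: identical input, monotonicity, errors", {
  set.seed(303)
  l1 <- rnorm(200, -10)
  r0 <- sh_test(l1, l1, resamples = 500)
  expect_identical(r0$delta, 0)
  expect_identical(r0$p.value, 1)
  # weaker alternative gets a smaller p than a near-equal one
  l2_weak <- l1 - rexp(200, 50)
  l2_bad <- l1 - rexp(200, 5)
  set.seed(1); p_weak <- sh_test(l1, l2_weak, resamples = 1000)$p.value
  set.seed(1); p_bad <- sh_test(l1, l2_bad, resamples = 1000)$p.value
  expect_lte(p_bad, p_weak)
  expect_error(sh_test(l1, l1[-1]), "length")
  expect_error(sh_test(l1, l1, resamples = 10), "resamples")
  # seeded reproducibility
  set.seed(5); a <- sh_test(l1, l2_weak)$p.value
  set.seed(5); b <- sh_test(l1, l2_weak)$p.value
  expect_identical(a, b)
})

test_that("sh_test broadly agrees with phangorn's SH implementation", {
  set.seed(304)
  fam <- small_family(n_taxa = 8, length = 300)
  t1 <- ape::unroot(fam$gene)
  t2 <- random_spr(random_spr(t1))
  d <- as_phydat(fam$alignment)
  f1 <- optimize_branch_lengths(t1, d)
  f2 <- optimize_branch_lengths(t2, d)
  ours <- sh_test(f1$site_loglik, f2$site_loglik, resamples = 2000)
  p1 <- phangorn::pml(f1$tree, d, model = "JTT", k = 4, shape = 1)
  p2 <- phangorn::pml(f2$tree, d, model = "JTT", k = 4, shape = 1)
  ref <- phangorn::SH.test(p1, p2, B = 2000)
  # same qualitative call at alpha = 0.05 and p-values in the same regime
  expect_equal(ours$p.value < 0.05, unname(ref[2, "p-value"] < 0.05))
  expect_lt(abs(ours$p.value - unname(ref[2, "p-value"])), 0.15)
})
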