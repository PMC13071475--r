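# GY94 engine: rate-matrix construction, F3x4, pruning against brute force,
# LRT arithmetic, fits and posteriors.

test_that("rate matrix has generator structure and detailed balance", {
  pi <- uniform_codon_freqs()
  for (pars in list(c(2, 0.5), c(5, 2), c(1, 1))) {
    rates <- build_rate_matrix(pars[1], pars[2], pi)
    expect_lt(max(abs(rowSums(rates$Q))), 1e-10)
    offdiag <- rates$Q - diag(diag(rates$Q))
    expect_true(all(offdiag >= 0))
    # reversibility: pi_i q_ij = pi_j q_ji
    flux <- sweep(rates$Q, 1L, pi, "*")
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    # mean rate scaled to 1
    expect_equal(-sum(pi * diag(rates$Q)), 1, tolerance = 1e-12)
  }
})

test_that("rate entries follow the kappa/omega construction rule", {
  tab <- codon_table()
  pi <- uniform_codon_freqs()
  rates <- build_rate_matrix(2, 0.5, pi)
  i <- tab$index[["TTT"]]
  # TTT->TTC: synonymous transition (Phe->Phe); TTT->TTA: nonsyn transversion
  r_ts_syn <- rates$Q[i, tab$index[["TTC"]]]
  r_tv_non <- rates$Q[i, tab$index[["TTA"]]]
  expect_equal(r_ts_syn / r_tv_non, 2 / 0.5, tolerance = 1e-12)
  # multi-nucleotide changes are forbidden
  expect_identical(rates$Q[i, tab$index[["GGG"]]], 0)
  # omega = kappa = 1, uniform pi: all allowed changes share one rate
  neutral <- build_rate_matrix(1, 1, pi)
  vals <- unique(round(neutral$Q[tab$single], 14))
  expect_length(vals, 1L)
  expect_error(build_rate_matrix(2, 0.5, c(rep(0, 1), rep(1 / 60, 60))),
               "degenerate")
})

test_that("F3x4 frequencies are a distribution reflecting the data", {
  aln <- random_codon_aln(letters[1:6], 3000, seed = 5)
  pi <- estimate_f3x4(aln)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  expect_length(pi, 61L)
  expect_true(all(pi > 0))
  # uniform codon usage => near-uniform F3x4
  expect_lt(max(abs(pi - 1 / 61)), 0.01)
  # single repeated codon concentrates mass on it
  atg <- codon_alignment(c(a = strrep("ATG", 10), b = strrep("ATG", 10)))
  pi_atg <- estimate_f3x4(atg)
  expect_equal(unname(which.max(pi_atg)),
               which(codon_table()$codons == "ATG"))
  expect_gt(pi_atg[["ATG"]], 0.99)
})

test_that("pruning equals brute-force enumeration over internal states", {
  pi <- uniform_codon_freqs()
  cases <- list(
    list(tree = fixture_tree3(), n = 2, kappa = 2, wbg = 0.5, wfg = 0.5),
    list(tree = fixture_tree3(), n = 3, kappa = 5, wbg = 2, wfg = 2),
    list(tree = tag_foreground(fixture_tree4(), c("a", "b")),
         n = 2, kappa = 2, wbg = 0.2, wfg = 3)
  )
  for (cs in cases) {
    aln <- random_codon_aln(cs$tree$tip.label, cs$n, seed = cs$n + 11)
    got <- codon_loglik(aln, cs$tree, cs$kappa, cs$wbg, cs$wfg, pi = pi)
    want <- oracle_brute_force_loglik(aln, cs$tree, cs$kappa, cs$wbg,
                                      cs$wfg, pi)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("single-sequence likelihood is the log product of frequencies", {
  aln <- codon_alignment(c(solo = "ATGGCTTGC"))
  pi <- uniform_codon_freqs()
  expect_equal(codon_loglik(aln, NULL, 2, 0.5, pi = pi),
               sum(log(pi[c("ATG", "GCT", "TGC")])))
})

test_that("site independence: duplicating all columns doubles the lnL", {
  tree <- fixture_tree4()
  aln <- random_codon_aln(tree$tip.label, 20, seed = 3)
  pi <- uniform_codon_freqs()
  ll1 <- codon_loglik(aln, tree, 2, 0.4, pi = pi)
  dup <- codon_alignment(vapply(aln$seqs, function(s) paste0(s, s),
                                character(1)))
  expect_equal(codon_loglik(dup, tree, 2, 0.4, pi = pi), 2 * ll1,
               tolerance = 1e-10)
})

test_that("likelihood is invariant to taxon order and rerooting", {
  tree <- fixture_tree4()
  aln <- random_codon_aln(tree$tip.label, 30, seed = 9)
  pi <- uniform_codon_freqs()
  ll <- codon_loglik(aln, tree, 2, 0.4, pi = pi)
  shuffled <- codon_alignment(aln$seqs[c("d", "b", "a", "c")])
  expect_equal(codon_loglik(shuffled, tree, 2, 0.4, pi = pi), ll,
               tolerance = 1e-10)
  # same unrooted topology, rooted on a different internal edge
  rerooted <- ape::read.tree(
    text = "((c:0.3,d:0.3):0.4,(a:0.3,b:0.3):0.0):0;")
  expect_equal(codon_loglik(aln, rerooted, 2, 0.4, pi = pi), ll,
               tolerance = 1e-8)
})

test_that("LRT arithmetic matches the chi-square upper tail", {
  eq <- lrt(-100, -100, df = 1)
  expect_equal(eq$stat, 0)
  expect_equal(eq$p, 1)
  # published branch-test pairs reproduce their printed p-values
  expect_lt(abs(lrt(-8052.433931, -8050.227062, df = 1)$p - 0.03565064),
            1e-8)
  expect_lt(abs(lrt(-4643.99952, -4638.188861, df = 1)$p - 0.000652002),
            1e-9)
  # clamped at zero when the alternative is (numerically) worse
  expect_equal(lrt(-99.9, -100, df = 1)$stat, 0)
  expect_error(lrt(NA, -1, 1))
})

test_that("M0 recovers the generating omega and kappa", {
  tree <- fixture_tree4()
  cfg <- simulation_config(tree, 2000, kappa = 2, omega_background = 0.2,
                           seed = 42)
  aln <- simulate_alignment(cfg)
  fit <- fit_codon_model(aln, tree, "M0", n_starts = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$omega - 0.2), 0.05)
  expect_lt(abs(fit$params$kappa - 2), 0.5)
  # fitted maximum at least as good as the true parameters
  expect_gte(fit$lnL,
             codon_loglik(aln, tree, 2, 0.2, pi = estimate_f3x4(aln)) - 1e-6)
})

test_that("nested models never lose likelihood and MA0 pins omega2", {
  tree <- tag_foreground(fixture_tree4(), c("a", "b"))
  cfg <- simulation_config(tree, 150, omega_background = 0.3,
                           omega_foreground = 1.5, seed = 17)
  aln <- simulate_alignment(cfg)
  m0 <- fit_codon_model(aln, tree, "M0", n_starts = 1)
  m2 <- fit_codon_model(aln, tree, "M2_branch", n_starts = 1)
  expect_gte(m2$lnL, m0$lnL - 1e-6)
  ma0 <- fit_codon_model(aln, tree, "MA0_null", n_starts = 1)
  ma <- fit_codon_model(aln, tree, "MA_branchsite", n_starts = 1)
  expect_gte(ma$lnL, ma0$lnL - 1e-6)
  expect_identical(ma0$params$omega2, 1)
  expect_gte(ma$params$omega2, 1)
  expect_true(all(c(ma$params$p0, ma$params$p1) >= 0))
  expect_lte(ma$params$p0 + ma$params$p1, 1)
})

test_that("site posteriors are probabilities and rank planted sites high", {
  tree <- fixture_study_tree()
  sel_pos <- seq(10, by = 9, length.out = 5)
  aln <- simulate_branchsite_gene(tree, 500, sel_pos, omega_bg = 0.3,
                                  omega_sel = 10, seed = 33)
  fit <- fit_codon_model(aln, tree, "MA_branchsite", n_starts = 1)
  post <- site_posteriors(fit, aln, tree)
  expect_equal(nrow(post), 500L)
  expect_true(all(post$posterior >= 0 & post$posterior <= 1))
  expect_identical(attr(post, "flavor"), "NEB")
  # the 5 high-omega foreground sites sit far above the background ranks:
  # the strongest lands in the top decile and the group as a whole is
  # rank-enriched (per-site evidence varies with the substitutions a site
  # happens to draw, so a one-site guarantee would overstate the method)
  rk <- rank(-post$posterior)[sel_pos]
  expect_lte(min(rk), 50)
  wil <- stats::wilcox.test(rk, rank(-post$posterior)[-sel_pos],
                            alternative = "less")
  expect_lt(wil$p.value, 0.05)
  # posteriors require a branch-site fit
  m0 <- fit_codon_model(aln, tree, "M0", n_starts = 1)
  expect_error(site_posteriors(m0, aln, tree), "branch-site")
})

test_that("invariant columns carry no positive-selection signal", {
  tree <- tag_foreground(fixture_tree4(), c("a", "b"))
  cfg <- simulation_config(tree, 120, omega_background = 0.5,
                           omega_foreground = 2, seed = 23)
  aln <- simulate_alignment(cfg)
  # append an invariant column
  aln2 <- codon_alignment(vapply(aln$seqs, function(s) paste0(s, "ATG"),
                                 character(1)))
  fit <- fit_codon_model(aln2, tree, "MA_branchsite", n_starts = 1)
  post <- site_posteriors(fit, aln2, tree)
  p <- fit$params
  prior2 <- 1 - p$p0 - p$p1
  expect_lte(post$posterior[121], prior2 + 1e-8)
})
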