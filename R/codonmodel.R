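# Goldman-Yang (GY94) codon substitution engine: rate matrix, F3x4
# frequencies, Felsenstein pruning over the 61 sense-codon states, ML fits of
# the one-ratio (M0), two-ratio branch (M2) and branch-site Model A / null
# models, the likelihood-ratio test, and empirical-Bayes site posteriors.

#' Build a GY94 codon rate matrix
#'
#' Off-diagonal rate \eqn{q_{ij}} is zero for multi-nucleotide changes and
#' otherwise proportional to \eqn{\pi_j}, multiplied by \eqn{\kappa} for
#' transitions and by \eqn{\omega} for nonsynonymous changes. The generator is
#' scaled so the mean rate at stationarity is 1, so branch lengths are in
#' expected substitutions per codon site.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0); > 1 positive selection, < 1 purifying,
#'   = 1 neutral.
#' @param pi Stationary distribution over the 61 sense codons.
#' @return Object of class \code{codon_rates}: list with \code{Q} (scaled
#'   generator), \code{kappa}, \code{omega}, \code{pi}.
#' @export
build_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega >= 0)
  tab <- codon_table()
  if (length(pi) != 61L) stop("pi must have 61 entries (sense codons)")
  if (any(pi <= 0)) stop("degenerate pi: zero or negative mass on codons ",
                         paste(tab$codons[pi <= 0], collapse = ", "))
  if (abs(sum(pi) - 1) > 1e-8) stop("pi does not sum to 1")
  pi <- pi / sum(pi)
  R <- matrix(0, 61L, 61L)
  R[tab$single] <- 1
  R[tab$ts] <- kappa
  R[tab$single & !tab$syn] <- R[tab$single & !tab$syn] * omega
  Q <- sweep(R, 2L, pi, "*")
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (zero mean rate)")
  Q <- Q / scale
  structure(list(Q = Q, kappa = kappa, omega = omega, pi = pi),
            class = "codon_rates")
}

# Symmetric eigendecomposition of a reversible generator; returns a closure
# P(t) built from A diag(exp(lambda t)) B.
rate_eigen <- function(rates) {
  sp <- sqrt(rates$pi)
  S <- sweep(sweep(rates$Q, 1L, sp, "*"), 2L, sp, "/")
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  A <- sweep(e$vectors, 1L, sp, "/")
  B <- t(sweep(e$vectors, 1L, sp, "*"))
  list(values = e$values, A = A, B = B)
}

transition_probs <- function(eig, t) {
  if (t < 0) stop("negative branch length: ", t)
  P <- eig$A %*% (exp(eig$values * t) * eig$B)
  P[P < 0] <- 0
  P
}

#' Estimate F3x4 codon frequencies from an alignment
#'
#' Codon frequencies proportional to the product of position-specific
#' nucleotide frequencies, renormalized over the 61 sense codons (stop codons
#' get zero mass before renormalization). Position frequencies are floored at
#' 1e-6 so the codon chain stays irreducible when a base is absent at one
#' position.
#'
#' @param aln A \code{codon_aln}.
#' @return Numeric vector of 61 codon frequencies summing to 1, named by
#'   codon.
#' @export
estimate_f3x4 <- function(aln) {
  m <- codon_matrix(aln)
  m <- m[m != "---" & !grepl("[^ACGT]", m)]
  if (length(m) == 0L) stop("alignment has no ungapped, unambiguous codons")
  bases <- c("A", "C", "G", "T")
  freq <- matrix(0, 3L, 4L, dimnames = list(NULL, bases))
  for (k in 1:3) {
    f <- table(factor(substr(m, k, k), levels = bases))
    f <- pmax(as.numeric(f) / sum(f), 1e-6)
    freq[k, ] <- f / sum(f)
  }
  tab <- codon_table()
  pi <- vapply(tab$codons, function(cd) {
    freq[1L, substr(cd, 1L, 1L)] * freq[2L, substr(cd, 2L, 2L)] *
      freq[3L, substr(cd, 3L, 3L)]
  }, numeric(1))
  pi / sum(pi)
}

#' Uniform codon frequencies
#' @return Vector of 61 equal frequencies, named by codon.
#' @export
uniform_codon_freqs <- function() {
  tab <- codon_table()
  stats::setNames(rep(1 / 61, 61L), tab$codons)
}

# Compress alignment columns into site patterns.
site_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(states = states[, u, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(u))),
       map = idx)
}

# Postorder-prepared tree with remapped foreground flags; computed once per
# fit so the optimizer's objective avoids repeated reordering.
prepare_tree <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  fg <- tree$foreground
  if (is.null(fg)) fg <- rep(FALSE, nrow(tree$edge))
  tr$foreground <- fg[match(paste(tr$edge[, 1L], tr$edge[, 2L]),
                            paste(tree$edge[, 1L], tree$edge[, 2L]))]
  tr
}

# Felsenstein pruning for one site-class. `Pedges` is a list of 61x61
# transition matrices indexed by edge row of the postorder tree. Returns
# per-pattern log-likelihoods. NA states are missing data (partial
# likelihood 1 over all states); per-node rescaling guards underflow.
prune_loglik <- function(states, ptree, Pedges, pi) {
  ntip <- length(ptree$tip.label)
  npat <- ncol(states)
  ord <- match(ptree$tip.label, rownames(states))
  if (anyNA(ord)) {
    stop("alignment taxa do not match tree tips: ",
         paste(setdiff(ptree$tip.label, rownames(states)), collapse = ", "))
  }
  partial <- vector("list", ntip + ptree$Nnode)
  edge <- ptree$edge
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2L]
    P <- Pedges[[e]]
    if (child <= ntip) {
      s <- states[ord[child], ]
      msg <- matrix(1, 61L, npat)
      ok <- !is.na(s)
      msg[, ok] <- P[, s[ok], drop = FALSE]
      msg_ls <- 0
    } else {
      msg <- P %*% partial[[child]]$mat
      msg_ls <- partial[[child]]$ls
    }
    parent <- edge[e, 1L]
    prev <- partial[[parent]]
    if (is.null(prev)) {
      partial[[parent]] <- list(mat = msg, ls = msg_ls)
    } else {
      m <- prev$mat * msg
      cs <- .colSums(m, 61L, npat)
      if (any(cs <= 0) || any(!is.finite(cs))) {
        stop("non-finite partial likelihood at pattern ",
             which(cs <= 0 | !is.finite(cs))[1L])
      }
      partial[[parent]] <- list(mat = m * rep(1 / cs, each = 61L),
                                ls = prev$ls + msg_ls + log(cs))
    }
  }
  root <- partial[[ntip + 1L]]
  lik <- .colSums(pi * root$mat, 61L, npat)
  if (any(!is.finite(lik)) || any(lik <= 0)) {
    stop("non-finite site likelihood at pattern ",
         which(!is.finite(lik) | lik <= 0)[1L])
  }
  log(lik) + root$ls
}

# Per-edge omega assignment for a (background, foreground) pair.
edge_omegas <- function(tree, omega_bg, omega_fg) {
  fg <- tree$foreground
  if (is.null(fg)) fg <- rep(FALSE, nrow(tree$edge))
  ifelse(fg, omega_fg, omega_bg)
}

# Per-pattern log-likelihood for one site class defined by (omega_bg,
# omega_fg) on a postorder-prepared tree; caches eigendecompositions (keyed
# by omega) and per-edge transition matrices (keyed by omega and length).
class_loglik <- function(states, ptree, kappa, omega_bg, omega_fg, pi,
                         cache) {
  om <- edge_omegas(ptree, omega_bg, omega_fg)
  Pedges <- vector("list", nrow(ptree$edge))
  for (e in seq_len(nrow(ptree$edge))) {
    pkey <- sprintf("%.12g|%.12g", om[e], ptree$edge.length[e])
    P <- cache$P[[pkey]]
    if (is.null(P)) {
      ekey <- sprintf("%.12g", om[e])
      if (is.null(cache$eig[[ekey]])) {
        cache$eig[[ekey]] <- rate_eigen(build_rate_matrix(kappa, om[e], pi))
      }
      P <- transition_probs(cache$eig[[ekey]], ptree$edge.length[e])
      cache$P[[pkey]] <- P
    }
    Pedges[[e]] <- P
  }
  prune_loglik(states, ptree, Pedges, pi)
}

new_eig_cache <- function() {
  cache <- new.env(parent = emptyenv())
  cache$eig <- list()
  cache$P <- list()
  cache
}

# Model A site-class structure (codeml model=2 NSsites=2): classes 0, 1, 2a,
# 2b with proportions p0, p1, p2*p0/(p0+p1), p2*p1/(p0+p1) and
# (background, foreground) omegas (w0,w0), (1,1), (w0,w2), (1,w2).
modelA_classes <- function(p0, p1, w0, w2) {
  p2 <- 1 - p0 - p1
  r <- p0 / (p0 + p1)
  list(
    props = c(p0, p1, p2 * r, p2 * (1 - r)),
    omega_bg = c(w0, 1, w0, 1),
    omega_fg = c(w0, 1, w2, w2)
  )
}

# Per-pattern class log-likelihood matrix for a set of site classes.
class_loglik_matrix <- function(states, ptree, kappa, classes, pi) {
  cache <- new_eig_cache()
  ll <- vapply(seq_along(classes$props), function(k) {
    class_loglik(states, ptree, kappa, classes$omega_bg[k],
                 classes$omega_fg[k], pi, cache)
  }, numeric(ncol(states)))
  if (ncol(states) == 1L) ll <- matrix(ll, nrow = 1L)
  ll
}

mixture_loglik <- function(ll_mat, props, weights) {
  m <- apply(ll_mat, 1L, max)
  lik <- log(drop(exp(ll_mat - m) %*% props)) + m
  sum(lik * weights)
}

#' Log-likelihood of a codon alignment under a GY94 model
#'
#' Felsenstein pruning over the 61 sense-codon states; gaps, stops and
#' ambiguous codons are missing data. For a single sequence (\code{tree =
#' NULL}) the likelihood is the product of stationary frequencies of the
#' observed codons.
#'
#' @param aln A \code{codon_aln}.
#' @param tree Rooted \code{phylo} with branch lengths in substitutions per
#'   codon site; needs a \code{foreground} flag vector (see
#'   \code{\link{tag_foreground}}) when \code{omega_fg} differs from
#'   \code{omega_bg}.
#' @param kappa Transition/transversion ratio.
#' @param omega_bg,omega_fg dN/dS on background / foreground branches (a
#'   single-class model; use \code{\link{fit_codon_model}} for the
#'   branch-site mixture).
#' @param pi Codon frequencies (default F3x4 from the alignment).
#' @return Total log-likelihood (numeric scalar).
#' @export
codon_loglik <- function(aln, tree, kappa, omega_bg, omega_fg = omega_bg,
                         pi = NULL) {
  if (is.null(pi)) pi <- estimate_f3x4(aln)
  states <- codon_states(aln)
  if (is.null(tree)) {
    if (nrow(states) != 1L) stop("tree required for more than one sequence")
    s <- states[1L, ]
    return(sum(log(pi[s[!is.na(s)]])))
  }
  pat <- site_patterns(states)
  ll <- class_loglik(pat$states, prepare_tree(tree), kappa, omega_bg,
                     omega_fg, pi, new_eig_cache())
  sum(ll * pat$weights)
}

#' Likelihood-ratio test between nested codon models
#'
#' The statistic is \eqn{2(\ell_{alt} - \ell_{null})}, clamped at zero, and
#' the p-value is the upper tail of a chi-square distribution with \code{df}
#' degrees of freedom.
#'
#' @param lnL_null,lnL_alt Log-likelihoods of the null and alternative fits.
#' @param df Degrees of freedom (>= 1).
#' @return Object of class \code{lrt_result}: list with \code{stat},
#'   \code{df}, \code{p}.
#' @export
lrt <- function(lnL_null, lnL_alt, df = 1L) {
  stopifnot(is.finite(lnL_null), is.finite(lnL_alt), df >= 1)
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  structure(list(stat = stat, df = df,
                 p = stats::pchisq(stat, df = df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*dlnL = %.6f, df = %d, p = %.6g\n", x$stat, x$df, x$p))
  invisible(x)
}

# parameter bounds (natural scale)
.kappa_bounds <- c(1e-3, 100)
.omega_bounds <- c(1e-6, 50)

#' Fit a codon substitution model by maximum likelihood
#'
#' Fits one of four GY94 models by bounded quasi-Newton (L-BFGS-B) search
#' with seeded random restarts, branch lengths fixed at the input tree's:
#' \describe{
#'   \item{M0}{one dN/dS ratio for all branches.}
#'   \item{M2_branch}{two-ratio branch model: \code{omega_bg} on background
#'     branches, \code{omega_fg} on foreground branches.}
#'   \item{MA_branchsite}{branch-site Model A: site classes 0 (purifying,
#'     \code{omega0 < 1} everywhere), 1 (neutral), 2a/2b (positive selection
#'     \code{omega2 >= 1} on foreground branches only), with free
#'     proportions.}
#'   \item{MA0_null}{Model A null with \code{omega2} fixed at 1.}
#' }
#'
#' @param aln A \code{codon_aln}.
#' @param tree Rooted \code{phylo} with branch lengths; must carry foreground
#'   flags (see \code{\link{tag_foreground}}) for the branch and branch-site
#'   models.
#' @param model One of \code{"M0"}, \code{"M2_branch"}, \code{"MA_branchsite"},
#'   \code{"MA0_null"} (aliases \code{"M2"}, \code{"MA"}, \code{"MA0"}).
#' @param freq Frequency model: \code{"F3x4"} (default), \code{"F61"}
#'   (observed codon frequencies), or \code{"uniform"}.
#' @param n_starts Number of optimizer starts (1 fixed + seeded random).
#' @param seed Seed for the random restarts.
#' @return Object of class \code{model_fit}: \code{model_name}, \code{lnL},
#'   \code{params} (named list), \code{converged}, \code{n_iter}, \code{pi}.
#' @export
fit_codon_model <- function(aln, tree, model = c("M0", "M2_branch",
                                                 "MA_branchsite", "MA0_null",
                                                 "M2", "MA", "MA0"),
                            freq = c("F3x4", "F61", "uniform"),
                            n_starts = 3L, seed = 1L) {
  model <- match.arg(model)
  model <- c(M2 = "M2_branch", MA = "MA_branchsite", MA0 = "MA0_null")[model] %|na|% model
  freq <- match.arg(freq)
  pi <- switch(freq,
    F3x4 = estimate_f3x4(aln),
    F61 = estimate_f61(aln),
    uniform = uniform_codon_freqs()
  )
  if (model != "M0" && is.null(tree$foreground)) {
    stop("tree has no foreground flags; run tag_foreground() first")
  }
  missing_taxa <- setdiff(tree$tip.label, aln$taxa)
  if (length(missing_taxa)) {
    stop("alignment taxa do not match tree tips: ",
         paste(missing_taxa, collapse = ", "))
  }
  states <- codon_states(aln)
  pat <- site_patterns(states)
  negll <- make_negll(pat, prepare_tree(tree), model, pi)

  starts <- model_starts(model, n_starts, seed)
  best <- NULL
  n_iter <- 0L
  for (st in starts) {
    opt <- try(stats::optim(st$par, negll, method = "L-BFGS-B",
                            lower = st$lower, upper = st$upper,
                            control = list(maxit = 500L, factr = 1e4)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    n_iter <- n_iter + opt$counts[["function"]]
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed for model ", model)
  params <- decode_params(model, best$par)
  structure(list(
    model_name = model,
    lnL = -best$value,
    params = params,
    converged = best$convergence == 0L,
    n_iter = n_iter,
    pi = pi,
    freq_model = freq
  ), class = "model_fit")
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.6f (%s)\n", x$model_name, x$lnL,
              if (x$converged) "converged" else "NOT converged"))
  cat("  ", paste(sprintf("%s = %.5g", names(unlist(x$params)),
                          unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}

estimate_f61 <- function(aln) {
  tab <- codon_table()
  m <- codon_matrix(aln)
  cnt <- table(factor(m[m %in% tab$codons], levels = tab$codons))
  pi <- pmax(as.numeric(cnt), 0.5)  # pseudo-count keeps pi positive
  stats::setNames(pi / sum(pi), tab$codons)
}

# Objective closures per model. Parameters are log-transformed rates;
# Model A proportions use a stick-breaking pair (s = p0 + p1, r = p0 / s).
make_negll <- function(pat, ptree, model, pi) {
  w <- pat$weights
  if (model %in% c("M0", "M2_branch")) {
    function(par) {
      kappa <- exp(par[1L])
      wbg <- exp(par[2L])
      wfg <- if (model == "M0") wbg else exp(par[3L])
      ll <- class_loglik(pat$states, ptree, kappa, wbg, wfg, pi,
                         new_eig_cache())
      -sum(ll * w)
    }
  } else {
    fixed_w2 <- model == "MA0_null"
    function(par) {
      kappa <- exp(par[1L])
      s <- par[2L]; r <- par[3L]
      w0 <- exp(par[4L])
      w2 <- if (fixed_w2) 1 else exp(par[5L])
      cl <- modelA_classes(s * r, s * (1 - r), w0, w2)
      ll_mat <- class_loglik_matrix(pat$states, ptree, kappa, cl, pi)
      -mixture_loglik(ll_mat, cl$props, w)
    }
  }
}

model_starts <- function(model, n_starts, seed) {
  lk <- log(.kappa_bounds); lw <- log(.omega_bounds)
  if (model == "M0") {
    base <- list(par = c(log(2), log(0.3)),
                 lower = c(lk[1L], lw[1L]), upper = c(lk[2L], lw[2L]))
    rand <- function() c(stats::runif(1, log(0.5), log(8)),
                         stats::runif(1, log(0.01), log(3)))
  } else if (model == "M2_branch") {
    base <- list(par = c(log(2), log(0.3), log(0.3)),
                 lower = c(lk[1L], lw[1L], lw[1L]),
                 upper = c(lk[2L], lw[2L], lw[2L]))
    rand <- function() c(stats::runif(1, log(0.5), log(8)),
                         stats::runif(2, log(0.01), log(3)))
  } else {
    # par: log kappa, s = p0+p1, r = p0/s, log w0, [log w2]
    has_w2 <- model == "MA_branchsite"
    base <- list(
      par = c(log(2), 0.9, 0.8, log(0.2), if (has_w2) log(2)),
      lower = c(lk[1L], 1e-4, 1e-4, lw[1L], if (has_w2) 0),
      upper = c(lk[2L], 1 - 1e-4, 1 - 1e-4, 0, if (has_w2) lw[2L])
    )
    rand <- function() c(stats::runif(1, log(0.5), log(8)),
                         stats::runif(1, 0.5, 0.99),
                         stats::runif(1, 0.3, 0.95),
                         stats::runif(1, log(0.01), log(0.9)),
                         if (has_w2) stats::runif(1, 0, log(10)))
  }
  starts <- list(base)
  if (n_starts > 1L) {
    set.seed(seed)
    for (i in seq_len(n_starts - 1L)) {
      p <- rand()
      starts[[i + 1L]] <- list(par = pmin(pmax(p, base$lower), base$upper),
                               lower = base$lower, upper = base$upper)
    }
  }
  starts
}

decode_params <- function(model, par) {
  if (model == "M0") {
    list(kappa = exp(par[1L]), omega = exp(par[2L]))
  } else if (model == "M2_branch") {
    list(kappa = exp(par[1L]), omega_bg = exp(par[2L]),
         omega_fg = exp(par[3L]))
  } else {
    s <- par[2L]; r <- par[3L]
    list(kappa = exp(par[1L]), p0 = s * r, p1 = s * (1 - r),
         omega0 = exp(par[4L]),
         omega2 = if (model == "MA0_null") 1 else exp(par[5L]))
  }
}

#' Empirical-Bayes site posteriors for the positive-selection class
#'
#' Per-codon-site posterior probability of membership in the
#' positive-selection classes (2a + 2b) of branch-site Model A, computed by
#' naive empirical Bayes at the maximum-likelihood estimates (flavor recorded
#' in the result as \code{"NEB"}).
#'
#' @param fit A \code{model_fit} with \code{model_name = "MA_branchsite"}.
#' @param aln,tree The alignment and foreground-tagged tree used for the fit.
#' @return Object of class \code{site_posteriors}: data frame with columns
#'   \code{site} (1-based codon position) and \code{posterior}, plus a
#'   \code{flavor} attribute.
#' @export
site_posteriors <- function(fit, aln, tree) {
  if (!inherits(fit, "model_fit") || fit$model_name != "MA_branchsite") {
    stop("site posteriors require a branch-site Model A fit")
  }
  p <- fit$params
  cl <- modelA_classes(p$p0, p$p1, p$omega0, p$omega2)
  states <- codon_states(aln)
  pat <- site_patterns(states)
  ll_mat <- class_loglik_matrix(pat$states, prepare_tree(tree), p$kappa, cl,
                                fit$pi)
  m <- apply(ll_mat, 1L, max)
  lik <- exp(ll_mat - m)
  num <- drop(lik[, 3:4, drop = FALSE] %*% cl$props[3:4])
  den <- drop(lik %*% cl$props)
  post <- (num / den)[pat$map]
  out <- data.frame(site = seq_along(post), posterior = post)
  attr(out, "flavor") <- "NEB"
  class(out) <- c("site_posteriors", "data.frame")
  out
}
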