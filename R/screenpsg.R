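# Decision rules on top of the codon-model fits: positively selected genes
# (branch-site test plus site filters) and rapidly evolving genes (branch
# test plus a faster-foreground requirement).

#' Construct a selection call
#'
#' @param gene_id Gene identifier.
#' @param test_type \code{"branch_site"} or \code{"branch"}.
#' @param lrt An \code{lrt_result}.
#' @param candidate_sites Data frame with columns \code{site},
#'   \code{posterior} (may have zero rows).
#' @param verdict \code{"PSG"}, \code{"REG"} or \code{"rejected"}.
#' @param reject_reasons Character vector of triggered rejection rules.
#' @return Object of class \code{selection_call}.
#' @export
selection_call <- function(gene_id, test_type, lrt, candidate_sites,
                           verdict, reject_reasons = character(0)) {
  structure(list(gene_id = gene_id, test_type = test_type, lrt = lrt,
                 candidate_sites = candidate_sites, verdict = verdict,
                 reject_reasons = reject_reasons),
            class = "selection_call")
}

#' @export
print.selection_call <- function(x, ...) {
  cat(sprintf("%s [%s]: %s (p = %.4g)", x$gene_id, x$test_type, x$verdict,
              x$lrt$p))
  if (length(x$reject_reasons)) {
    cat(" —", paste(x$reject_reasons, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Positively-selected-gene filter
#'
#' Applies the branch-site decision rules: a gene is called a PSG when the
#' branch-site LRT is significant and at least one site survives all site
#' filters. Candidate sites are codon positions with empirical-Bayes
#' posterior >= \code{posterior_threshold}. The gene is rejected when (a) the
#' LRT p-value is >= \code{alpha} (\code{p_ge_threshold}); (b) candidates
#' form a run of 3 or more consecutive codon positions
#' (\code{consecutive_run}); (c) any candidate falls on the first or last
#' codon (\code{terminal_site}); or (d) no site reaches the posterior
#' threshold (\code{low_posterior}). All triggered rules are reported.
#'
#' @param gene_id Gene identifier.
#' @param lrt An \code{lrt_result} for Model A vs its null.
#' @param posteriors A \code{site_posteriors} table (or numeric vector of
#'   per-codon posteriors).
#' @param alignment_length Number of codon sites; must equal the posterior
#'   table length.
#' @param alpha Significance threshold on the LRT p-value.
#' @param posterior_threshold Posterior cutoff defining candidate sites.
#' @return A \code{selection_call} with verdict \code{"PSG"} or
#'   \code{"rejected"}.
#' @export
filter_psg <- function(gene_id, lrt, posteriors, alignment_length,
                       alpha = 0.05, posterior_threshold = 0.95) {
  post <- if (is.data.frame(posteriors)) posteriors$posterior else posteriors
  if (length(post) == 0L) stop("empty posterior table for ", gene_id)
  if (length(post) != alignment_length) {
    stop("posterior table length ", length(post),
         " != alignment codon count ", alignment_length)
  }
  cand <- which(post >= posterior_threshold)
  reasons <- character(0)
  if (lrt$p >= alpha) reasons <- c(reasons, "p_ge_threshold")
  if (length(cand) >= 3L) {
    runs <- rle(diff(cand) == 1L)
    if (any(runs$lengths[runs$values] >= 2L)) {
      reasons <- c(reasons, "consecutive_run")
    }
  }
  if (any(cand == 1L | cand == alignment_length)) {
    reasons <- c(reasons, "terminal_site")
  }
  if (length(cand) == 0L) reasons <- c(reasons, "low_posterior")
  verdict <- if (length(reasons) == 0L) "PSG" else "rejected"
  selection_call(gene_id, "branch_site", lrt,
                 data.frame(site = cand, posterior = post[cand]),
                 verdict, reasons)
}

#' Rapidly-evolving-gene call
#'
#' A gene is a REG when the one-ratio vs two-ratio branch LRT (df = 1) is
#' significant at \code{alpha} and the foreground dN/dS exceeds the
#' background dN/dS; otherwise it is rejected with the triggered reasons
#' (\code{p_ge_threshold}, \code{foreground_not_faster}).
#'
#' @param gene_id Gene identifier.
#' @param fit_m0 M0 fit (or any list with \code{lnL}).
#' @param fit_m2 Two-ratio branch fit (list with \code{lnL} and
#'   \code{params$omega_bg}, \code{params$omega_fg}).
#' @param alpha Significance threshold.
#' @return A \code{selection_call} with verdict \code{"REG"} or
#'   \code{"rejected"}.
#' @export
call_reg <- function(gene_id, fit_m0, fit_m2, alpha = 0.05) {
  test <- lrt(fit_m0$lnL, fit_m2$lnL, df = 1L)
  reasons <- character(0)
  if (test$p >= alpha) reasons <- c(reasons, "p_ge_threshold")
  if (!(fit_m2$params$omega_fg > fit_m2$params$omega_bg)) {
    reasons <- c(reasons, "foreground_not_faster")
  }
  verdict <- if (length(reasons) == 0L) "REG" else "rejected"
  selection_call(gene_id, "branch", test,
                 data.frame(site = integer(0), posterior = numeric(0)),
                 verdict, reasons)
}

#' Intersect PSG and REG calls
#'
#' @param psgs,regs Character vectors of gene ids, or lists of
#'   \code{selection_call}s (only genes with verdict PSG / REG are kept).
#' @return Sorted character vector of gene ids present in both.
#' @export
intersect_calls <- function(psgs, regs) {
  ids <- function(x, v) {
    if (is.character(x)) return(x)
    vapply(Filter(function(cl) cl$verdict == v, x),
           function(cl) cl$gene_id, character(1))
  }
  sort(intersect(unique(ids(psgs, "PSG")), unique(ids(regs, "REG"))))
}
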