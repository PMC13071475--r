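# Synthetic data with the statistical structure the analysis assumes:
# codon alignments evolved on a fixed rooted tree under a Goldman-Yang model
# with branch-specific dN/dS on foreground lineages, optional planted
# identical amino-acid substitutions on all foreground tips, and annotation /
# domain fixtures for the enrichment stage.

#' Simulation configuration
#'
#' @param tree Rooted \code{phylo} with branch lengths (expected
#'   substitutions per codon site) and foreground flags (see
#'   \code{\link{tag_foreground}}); at least 3 tips, all lengths >= 0.
#' @param n_codons Number of codon sites (> 0).
#' @param kappa Transition/transversion ratio (> 0).
#' @param omega_background,omega_foreground dN/dS on background / foreground
#'   branches (> 0).
#' @param codon_freqs Distribution over the 61 sense codons (default
#'   uniform); must sum to 1 within 1e-12.
#' @param planted_sites Optional data frame with columns \code{pos} (1-based
#'   codon position) and \code{aa} (target residue) forced as identical
#'   substitutions on all foreground tips after simulation.
#' @param seed Integer RNG seed.
#' @return Object of class \code{sim_config}.
#' @export
simulation_config <- function(tree, n_codons, kappa = 2,
                              omega_background = 0.2,
                              omega_foreground = omega_background,
                              codon_freqs = uniform_codon_freqs(),
                              planted_sites = NULL, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L) stop("tree must have at least 3 tips")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    stop("negative branch length on edge to node ",
         tree$edge[neg[1L], 2L])
  }
  stopifnot(n_codons >= 1L, kappa > 0, omega_background > 0,
            omega_foreground > 0)
  if (length(codon_freqs) != 61L || abs(sum(codon_freqs) - 1) > 1e-12) {
    stop("codon_freqs must be 61 frequencies summing to 1 (within 1e-12)")
  }
  if (is.null(tree$foreground)) tree <- tag_foreground(tree, character(0))
  if (!is.null(planted_sites)) {
    stopifnot(is.data.frame(planted_sites),
              all(c("pos", "aa") %in% names(planted_sites)))
    if (any(planted_sites$pos < 1L | planted_sites$pos > n_codons)) {
      stop("planted positions must lie in [1, n_codons]")
    }
  }
  structure(list(tree = tree, n_codons = as.integer(n_codons), kappa = kappa,
                 omega_background = omega_background,
                 omega_foreground = omega_foreground,
                 codon_freqs = codon_freqs,
                 planted_sites = planted_sites, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-branch seed: one root stream split per branch keyed by
# the child node id, so subtree draws do not depend on traversal order.
branch_seed <- function(seed, child) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(child)) %%
               2147483647)
}

#' Simulate a codon alignment on a tree
#'
#' Samples a root codon per site from \code{codon_freqs} and evolves it along
#' each branch under the GY94 rate matrix with that branch's dN/dS
#' (foreground branches use \code{omega_foreground}). Sequences never contain
#' stop codons (61-state sense-codon space) and a fixed seed gives
#' bit-identical output. Planted substitutions, if any, are applied last via
#' \code{\link{plant_convergent_substitutions}}.
#'
#' @param config A \code{sim_config}.
#' @return A \code{codon_aln} with one sequence per tip.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tab <- codon_table()
  tree <- config$tree
  ntip <- length(tree$tip.label)
  n <- config$n_codons
  eig_bg <- rate_eigen(build_rate_matrix(config$kappa,
                                         config$omega_background,
                                         config$codon_freqs))
  eig_fg <- if (config$omega_foreground == config$omega_background) eig_bg
    else rate_eigen(build_rate_matrix(config$kappa, config$omega_foreground,
                                      config$codon_freqs))
  set.seed(config$seed)
  root_states <- sample.int(61L, n, replace = TRUE, prob = config$codon_freqs)
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- root_states
  tr <- stats::reorder(tree, "cladewise")  # parents before children
  fg <- tree$foreground[match(paste(tr$edge[, 1L], tr$edge[, 2L]),
                              paste(tree$edge[, 1L], tree$edge[, 2L]))]
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    P <- transition_probs(if (isTRUE(fg[e])) eig_fg else eig_bg,
                          tr$edge.length[e])
    ps <- states[[parent]]
    cs <- integer(n)
    set.seed(branch_seed(config$seed, child))
    for (s in unique(ps)) {
      idx <- which(ps == s)
      cs[idx] <- sample.int(61L, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[[child]] <- cs
  }
  seqs <- vapply(seq_len(ntip), function(i) {
    paste(tab$codons[states[[i]]], collapse = "")
  }, character(1))
  names(seqs) <- tree$tip.label
  aln <- codon_alignment(seqs)
  if (!is.null(config$planted_sites) && nrow(config$planted_sites)) {
    aln <- plant_convergent_substitutions(aln, foreground_taxa(tree),
                                          config$planted_sites)
  }
  aln
}

#' Foreground tip labels of a tagged tree
#' @param tree A \code{phylo} with foreground flags.
#' @return Character vector of tips whose terminal branch is foreground.
#' @export
foreground_taxa <- function(tree) {
  stopifnot(!is.null(tree$foreground))
  ntip <- length(tree$tip.label)
  term <- tree$edge[, 2L] <= ntip
  tree$tip.label[tree$edge[term & tree$foreground, 2L]]
}

#' Plant identical amino-acid substitutions on foreground tips
#'
#' Forces, at each planted codon position, every foreground taxon to carry a
#' codon encoding the target residue, leaving all other columns and all
#' background sequences untouched. Each planted position must be a
#' conservative site: all background taxa share a single residue there, and
#' the target must differ from it.
#'
#' @param aln A \code{codon_aln}.
#' @param foreground_taxa Character vector of foreground tip labels.
#' @param planted_sites Data frame with columns \code{pos} (1-based codon
#'   position) and \code{aa} (target residue).
#' @return The modified \code{codon_aln}.
#' @export
plant_convergent_substitutions <- function(aln, foreground_taxa,
                                           planted_sites) {
  if (is.null(planted_sites) || nrow(planted_sites) == 0L) return(aln)
  stopifnot(all(c("pos", "aa") %in% names(planted_sites)))
  dup <- planted_sites$pos[duplicated(planted_sites$pos)]
  for (p in unique(dup)) {
    if (length(unique(planted_sites$aa[planted_sites$pos == p])) > 1L) {
      stop("position ", p, " planted twice with conflicting residues")
    }
  }
  planted_sites <- planted_sites[!duplicated(planted_sites$pos), ,
                                 drop = FALSE]
  stopifnot(all(foreground_taxa %in% aln$taxa))
  bg_taxa <- setdiff(aln$taxa, foreground_taxa)
  tab <- codon_table()
  m <- codon_matrix(aln)
  for (i in seq_len(nrow(planted_sites))) {
    pos <- planted_sites$pos[i]
    target <- toupper(planted_sites$aa[i])
    if (pos < 1L || pos > aln$n_codons) {
      stop("planted position ", pos, " outside [1, ", aln$n_codons, "]")
    }
    bg_aa <- translate_codons(m[bg_taxa, pos])
    if (length(unique(bg_aa)) != 1L) {
      stop("planted position ", pos, " is not conservative in background; ",
           "offending taxa: ",
           paste(bg_taxa[bg_aa != names(which.max(table(bg_aa)))],
                 collapse = ", "))
    }
    if (unique(bg_aa) == target) {
      stop("target residue ", target, " at position ", pos,
           " equals the background residue")
    }
    codon <- tab$codons[tab$aa == target][1L]
    if (is.na(codon)) stop("no codon encodes residue ", target)
    m[foreground_taxa, pos] <- codon
  }
  seqs <- stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
  codon_alignment(seqs[aln$taxa])
}

#' Annotation and domain fixtures for the enrichment stage
#'
#' Deterministically (for a fixed seed) assigns every gene at least one
#' category, optionally planting an enriched gene set into one category, and
#' generates a 1-based closed-interval domain table within each protein's
#' length.
#'
#' @param genes Nonempty character vector of gene ids.
#' @param categories Nonempty character vector of category ids.
#' @param seed Integer seed.
#' @param enriched_category,enriched_genes Optionally force
#'   \code{enriched_genes} to carry \code{enriched_category} (and other genes
#'   to mostly avoid it), planting a detectable enrichment signal.
#' @param protein_lengths Optional named integer vector; defaults to lengths
#'   drawn in 200..500.
#' @return List with \code{annotation} (data frame \code{gene_id},
#'   \code{category_id}) and \code{domains} (data frame \code{protein_id},
#'   \code{domain_name}, \code{start}, \code{end}).
#' @export
make_annotation_fixture <- function(genes, categories, seed = 1L,
                                    enriched_category = NULL,
                                    enriched_genes = NULL,
                                    protein_lengths = NULL) {
  stopifnot(length(genes) > 0L, length(categories) > 0L)
  set.seed(seed)
  base_cats <- if (!is.null(enriched_category)) {
    setdiff(categories, enriched_category)
  } else categories
  if (length(base_cats) == 0L) base_cats <- categories
  ann <- do.call(rbind, lapply(genes, function(g) {
    if (!is.null(enriched_genes) && g %in% enriched_genes) {
      k <- min(length(base_cats), sample(0:1, 1L))
      cats <- unique(c(enriched_category, sample(base_cats, size = k)))
    } else {
      cats <- sample(base_cats, size = min(length(base_cats),
                                           sample(1:2, 1L)))
    }
    data.frame(gene_id = g, category_id = cats, stringsAsFactors = FALSE)
  }))
  if (is.null(protein_lengths)) {
    protein_lengths <- stats::setNames(
      sample(200:500, length(genes), replace = TRUE), genes)
  }
  dom <- do.call(rbind, lapply(genes, function(g) {
    len <- protein_lengths[[g]]
    k <- sample(0:2, 1L)
    if (k == 0L || len < 40L) return(NULL)
    starts <- sort(sample(seq_len(len - 30L), k))
    ends <- pmin(starts + sample(20:80, k, replace = TRUE), len)
    data.frame(protein_id = g,
               domain_name = paste0(g, "_dom", seq_len(k)),
               start = starts, end = ends, stringsAsFactors = FALSE)
  }))
  if (is.null(dom)) {
    dom <- data.frame(protein_id = character(0), domain_name = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(ann) <- NULL
  rownames(dom) <- NULL
  list(annotation = ann, domains = dom)
}
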