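# Fixtures and independent oracles, built in code.

# 4-taxon rooted tree with a 2-tip foreground clade
fixture_tree4 <- function(len = 0.3, stem = 0.2) {
  nw <- sprintf("((a:%1$s,b:%1$s):%2$s,(c:%1$s,d:%1$s):%2$s):0;", len, stem)
  ape::read.tree(text = nw)
}

# 3-taxon rooted tree
fixture_tree3 <- function() {
  ape::read.tree(text = "((a:0.2,b:0.3):0.1,c:0.4):0;")
}

# 12-taxon tree shaped like a multi-species phylogenomic study:
# 5 non-monophyletic foreground tips among 7 background tips.
fixture_study_tree <- function() {
  nw <- paste0(
    "(((fg1:0.35,fg2:0.35):0.15,((fg3:0.4,bg1:0.4):0.1,",
    "(fg4:0.35,fg5:0.35):0.15):0.05):0.1,((bg2:0.3,bg3:0.3):0.15,",
    "((bg4:0.35,bg5:0.35):0.1,(bg6:0.4,bg7:0.4):0.05):0.05):0.1):0;")
  codonsel::tag_foreground(ape::read.tree(text = nw), paste0("fg", 1:5))
}

study_foreground <- function() paste0("fg", 1:5)

# Independent GY94 rate matrix built by explicit looping over codon pairs
# (no sharing with the package's vectorized construction).
oracle_rate_matrix <- function(kappa, omega, pi) {
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)[gc_map != "*"]
  aa <- unname(gc_map[codons])
  n <- length(codons)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- strsplit(codons[i], "")[[1]]
      cj <- strsplit(codons[j], "")[[1]]
      diffpos <- which(ci != cj)
      if (length(diffpos) != 1) next
      a <- ci[diffpos]; b <- cj[diffpos]
      rate <- pi[j]
      if ((a %in% c("A", "G")) == (b %in% c("A", "G"))) rate <- rate * kappa
      if (aa[i] != aa[j]) rate <- rate * omega
      Q[i, j] <- rate
    }
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

# Matrix exponential by scaling-and-squaring on a truncated Taylor series
# (independent of the package's eigendecomposition route).
oracle_expm <- function(M) {
  k <- max(0, ceiling(log2(max(1, norm(M, "1")))) + 4)
  A <- M / 2^k
  P <- diag(nrow(M))
  term <- diag(nrow(M))
  for (i in 1:20) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}

# Brute-force codon-phylogeny log-likelihood: explicit sum over all
# internal-node codon state assignments. Gap-free alignments only.
oracle_brute_force_loglik <- function(aln, tree, kappa, omega_bg,
                                      omega_fg = omega_bg, pi) {
  states <- codonsel::codon_states(aln)
  stopifnot(!anyNA(states))
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  fg <- tree$foreground
  if (is.null(fg)) fg <- rep(FALSE, nrow(tree$edge))
  Pedge <- lapply(seq_len(nrow(tree$edge)), function(e) {
    om <- if (fg[e]) omega_fg else omega_bg
    oracle_expm(oracle_rate_matrix(kappa, om, pi) * tree$edge.length[e])
  })
  grid <- as.matrix(expand.grid(rep(list(1:61), nint)))
  root_col <- 1L  # internal node ntip+1 is the root in ape numbering
  total <- 0
  for (site in seq_len(ncol(states))) {
    f <- pi[grid[, root_col]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      ps <- grid[, p - ntip]
      cs <- if (ch <= ntip) {
        rep(states[match(tree$tip.label[ch], rownames(states)), site],
            nrow(grid))
      } else {
        grid[, ch - ntip]
      }
      f <- f * Pedge[[e]][cbind(ps, cs)]
    }
    total <- total + log(sum(f))
  }
  total
}

# Random gap-free codon alignment over given taxa (uniform sense codons).
random_codon_aln <- function(taxa, n_codons, seed) {
  set.seed(seed)
  tab <- codonsel::codon_table()
  seqs <- vapply(taxa, function(tx) {
    paste(tab$codons[sample.int(61, n_codons, replace = TRUE)],
          collapse = "")
  }, character(1))
  codonsel::codon_alignment(seqs)
}

# Simulate a branch-site-structured gene: `sel_pos` codon positions evolve
# with foreground omega `omega_sel`, the rest with background omega
# everywhere. Positions are interleaved so selected sites sit where planted.
simulate_branchsite_gene <- function(tree, n_codons, sel_pos, omega_bg = 0.2,
                                     omega_sel = 4, seed = 1) {
  ns <- length(sel_pos)
  stopifnot(all(sel_pos >= 1), all(sel_pos <= n_codons))
  c_bg <- codonsel::simulation_config(tree, n_codons - ns,
                                      omega_background = omega_bg,
                                      seed = seed)
  a_bg <- codonsel::simulate_alignment(c_bg)
  if (ns == 0) return(a_bg)
  c_sel <- codonsel::simulation_config(tree, ns, omega_background = omega_bg,
                                       omega_foreground = omega_sel,
                                       seed = seed + 7L)
  a_sel <- codonsel::simulate_alignment(c_sel)
  weave_codon_columns(a_bg, a_sel, sel_pos)
}

# Interleave codon columns of `a_sel` into `a_bg` at 1-based positions
# `sel_pos` of the combined alignment.
weave_codon_columns <- function(a_bg, a_sel, sel_pos) {
  n <- a_bg$n_codons + a_sel$n_codons
  taxa <- a_bg$taxa
  m_bg <- t(vapply(a_bg$seqs, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)),
    character(a_bg$n_codons)))
  m_sel <- t(vapply(a_sel$seqs, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)),
    character(a_sel$n_codons)))
  out <- matrix("", length(taxa), n)
  out[, sel_pos] <- m_sel
  out[, setdiff(seq_len(n), sel_pos)] <- m_bg
  codonsel::codon_alignment(
    stats::setNames(apply(out, 1, paste, collapse = ""), taxa))
}

# Protein alignment fixture builder: named residue vectors per column.
protein_aln_from_columns <- function(columns, taxa) {
  mat <- do.call(cbind, columns)
  stats::setNames(apply(mat, 1, paste, collapse = ""), taxa)
}
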