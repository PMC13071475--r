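# Sequence and tree IO: FASTA read/write, codon-alignment container,
# newick trees with foreground-branch labelling, and protein-guided
# back-translation of CDS to codon alignments.

#' Read a FASTA file
#'
#' Reads DNA or protein FASTA into a named character vector. Sequences are
#' upper-cased; identifiers must be unique and records non-empty.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty records in ", path, ": ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a codon alignment
#'
#' A codon alignment is the substrate of every downstream stage: equal-length
#' in-frame aligned coding sequences over the alphabet \code{A,C,G,T,N,-}.
#'
#' @param seqs Named character vector of aligned DNA sequences; all the same
#'   length, length divisible by 3.
#' @return An object of class \code{codon_aln}: list with \code{taxa},
#'   \code{seqs} (named character vector) and \code{n_codons}.
#' @export
codon_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences differ in length")
  if (len %% 3L != 0L) stop("alignment length ", len, " not divisible by 3")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("invalid characters in sequences: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  structure(
    list(taxa = names(seqs), seqs = seqs, n_codons = len %/% 3L),
    class = "codon_aln"
  )
}

#' @export
print.codon_aln <- function(x, ...) {
  cat("Codon alignment: ", length(x$taxa), " taxa, ", x$n_codons,
      " codons (", 3L * x$n_codons, " nt)\n", sep = "")
  invisible(x)
}

# Matrix of codon strings, taxa x sites.
codon_matrix <- function(aln) {
  m <- vapply(aln$seqs, split_codons, character(aln$n_codons))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)  # single-codon alignment
  m <- t(m)
  rownames(m) <- aln$taxa
  m
}

#' Codon state matrix
#'
#' Integer states 1..61 (sense codons of the standard code); gaps, ambiguous
#' codons and stop codons are \code{NA} and treated as missing data by the
#' likelihood engine.
#'
#' @param aln A \code{codon_aln}.
#' @return Integer matrix, taxa x codon sites.
#' @export
codon_states <- function(aln) {
  m <- codon_matrix(aln)
  s <- codon_state_indices(m)
  dim(s) <- dim(m)
  rownames(s) <- rownames(m)
  s
}

#' Translate a codon alignment to a protein alignment
#'
#' @param aln A \code{codon_aln}.
#' @return Named character vector of aligned amino-acid sequences.
#' @export
translate_alignment <- function(aln) {
  m <- codon_matrix(aln)
  am <- translate_codons(m)
  dim(am) <- dim(m)
  stats::setNames(apply(am, 1L, paste, collapse = ""), aln$taxa)
}

#' Concatenate codon alignments over the same taxa
#'
#' @param ... \code{codon_aln} objects sharing an identical taxon set.
#' @return A single \code{codon_aln}.
#' @export
concat_alignments <- function(...) {
  alns <- list(...)
  stopifnot(length(alns) >= 1L)
  taxa <- alns[[1L]]$taxa
  for (a in alns) stopifnot(identical(a$taxa, taxa))
  seqs <- vapply(taxa, function(tx) {
    paste(vapply(alns, function(a) a$seqs[[tx]], character(1)), collapse = "")
  }, character(1))
  codon_alignment(seqs)
}

#' Read a rooted newick tree
#'
#' @param path Path to a newick file with branch lengths.
#' @return An \pkg{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths: ", path)
  if (!ape::is.rooted(tree)) stop("tree must be rooted: ", path)
  tree
}

#' Label foreground branches of a species tree
#'
#' A branch is foreground iff the tip-descendant set of its child node is a
#' subset of \code{taxa}: that flags the terminal branches of the listed taxa
#' plus any internal branch whose descendants are all listed, mirroring the
#' foreground/background partition of branch and branch-site codon models on
#' a possibly non-monophyletic foreground.
#'
#' @param tree A rooted \code{phylo} with branch lengths.
#' @param taxa Character vector of foreground tip labels (may be empty).
#' @return The tree with a logical \code{foreground} element, one flag per
#'   row of \code{tree$edge}.
#' @export
tag_foreground <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) {
    stop("foreground taxa not in tree: ", paste(unknown, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  in_set <- tree$tip.label %in% taxa
  # for each edge, is every tip below the child node in the foreground set?
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  tr <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  flag <- vapply(seq_len(nrow(tree$edge)), function(e) {
    tips <- desc[[tree$edge[e, 2L]]]
    length(tips) > 0L && all(in_set[tips])
  }, logical(1))
  if (length(taxa) == 0L) flag[] <- FALSE
  tree$foreground <- flag
  tree
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each amino-acid column of a protein alignment to the source codon of
#' the corresponding (unaligned) CDS, so that translating the result
#' reproduces the protein alignment exactly. Protein gaps map to \code{"---"}.
#' A single trailing in-frame stop codon in a CDS is trimmed silently;
#' internal stops and translation mismatches are fatal.
#'
#' @param protein_aln Named character vector: aligned protein sequences.
#' @param cds_by_taxon Named character vector: unaligned in-frame CDS, one per
#'   taxon of the protein alignment.
#' @return A \code{codon_aln}.
#' @export
backtranslate <- function(protein_aln, cds_by_taxon) {
  stopifnot(!is.null(names(protein_aln)), !is.null(names(cds_by_taxon)))
  missing_cds <- setdiff(names(protein_aln), names(cds_by_taxon))
  if (length(missing_cds)) {
    stop("no CDS for taxa: ", paste(missing_cds, collapse = ", "))
  }
  out <- vapply(names(protein_aln), function(tx) {
    prot <- toupper(protein_aln[[tx]])
    cds <- toupper(cds_by_taxon[[tx]])
    if (nchar(cds) %% 3L != 0L) {
      stop("CDS length of ", tx, " (", nchar(cds), ") not divisible by 3")
    }
    codons <- split_codons(cds)
    aas <- translate_codons(codons)
    # trailing stop: trim; internal stop: fatal
    if (length(aas) && aas[length(aas)] == "*") {
      codons <- codons[-length(codons)]
      aas <- aas[-length(aas)]
    }
    if (any(aas == "*")) {
      stop("internal stop codon in CDS of ", tx, " at codon ",
           which(aas == "*")[1L])
    }
    cols <- strsplit(prot, "")[[1L]]
    ungapped <- cols[cols != "-"]
    if (length(ungapped) == 0L) {
      return(strrep("-", 3L * length(cols)))
    }
    if (length(ungapped) != length(codons)) {
      stop("CDS of ", tx, " encodes ", length(codons),
           " residues but its aligned protein has ", length(ungapped))
    }
    mism <- which(ungapped != aas & aas != "X" & ungapped != "X")
    if (length(mism)) {
      stop("translation mismatch for ", tx, " at protein position ", mism[1L],
           ": protein ", ungapped[mism[1L]], " vs CDS ", aas[mism[1L]])
    }
    res <- character(length(cols))
    res[cols == "-"] <- "---"
    res[cols != "-"] <- codons
    paste(res, collapse = "")
  }, character(1))
  codon_alignment(out)
}
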