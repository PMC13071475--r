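# Carnivore-specific convergent amino-acid substitution screen: detect
# alignment columns where all foreground (IN_list) taxa share a residue not
# seen in the background (ON_list), filter out genes with background sharing,
# restrict to conservative sites, annotate conserved-domain overlap and
# classify the biochemical property change.

#' Group specification for the substitution screen
#'
#' @param in_list Foreground taxa (e.g., carnivores); nonempty.
#' @param on_list Background taxa (e.g., herbivores); nonempty, disjoint from
#'   \code{in_list}.
#' @param outgroup Optional additional background taxa used only by the
#'   conservative-site filter.
#' @return Object of class \code{group_spec}.
#' @export
group_spec <- function(in_list, on_list, outgroup = character(0)) {
  stopifnot(length(in_list) > 0L, length(on_list) > 0L)
  if (length(intersect(in_list, on_list))) {
    stop("in_list and on_list overlap: ",
         paste(intersect(in_list, on_list), collapse = ", "))
  }
  structure(list(in_list = in_list, on_list = on_list, outgroup = outgroup),
            class = "group_spec")
}

# protein alignment (named character vector) -> character matrix taxa x cols
aa_matrix <- function(protein_aln) {
  lens <- unique(nchar(protein_aln))
  if (length(lens) != 1L) stop("protein sequences differ in length")
  m <- do.call(rbind, strsplit(toupper(protein_aln), ""))
  rownames(m) <- names(protein_aln)
  m
}

# ungapped position of `column` in the reference row (NA if ref is gapped)
ref_positions <- function(ref_row) {
  pos <- cumsum(ref_row != "-")
  pos[ref_row == "-"] <- NA_integer_
  pos
}

#' Detect shared foreground substitutions
#'
#' Scans a protein alignment for columns where every \code{in_list} taxon
#' carries one identical residue that differs from the background. Columns
#' with a gap or X in any \code{in_list} taxon are skipped; background gaps
#' are retained but flagged.
#'
#' @param protein_aln Named character vector of aligned protein sequences.
#' @param groups A \code{group_spec}; all group taxa must be present.
#' @param gene_id Gene identifier recorded in the output.
#' @param on_mode How the foreground residue must relate to the background:
#'   \code{"absent"} (default) requires that no \code{on_list} taxon carries
#'   it; \code{"majority"} requires only that it differs from the
#'   \code{on_list} majority residue.
#' @param ref_taxon Taxon whose ungapped coordinates are reported as
#'   \code{ref_position} (default: first \code{in_list} taxon).
#' @return Data frame of class \code{convergent_sites}: one row per called
#'   column with \code{gene_id}, \code{column}, \code{ref_position},
#'   \code{in_residue}, \code{on_residues} (collapsed string),
#'   \code{on_has_gap}.
#' @export
detect_shared_substitutions <- function(protein_aln, groups, gene_id = "gene",
                                        on_mode = c("absent", "majority"),
                                        ref_taxon = groups$in_list[1L]) {
  on_mode <- match.arg(on_mode)
  m <- aa_matrix(protein_aln)
  need <- c(groups$in_list, groups$on_list)
  miss <- setdiff(need, rownames(m))
  if (length(miss)) {
    stop("group taxa missing from alignment: ", paste(miss, collapse = ", "))
  }
  inm <- m[groups$in_list, , drop = FALSE]
  onm <- m[groups$on_list, , drop = FALSE]
  refpos <- ref_positions(m[ref_taxon, ])
  rows <- lapply(seq_len(ncol(m)), function(j) {
    inr <- inm[, j]
    if (any(inr %in% c("-", "X"))) return(NULL)
    if (length(unique(inr)) != 1L) return(NULL)
    r <- inr[1L]
    onr <- onm[, j]
    onr_res <- onr[!onr %in% c("-", "X")]
    hit <- if (on_mode == "absent") {
      length(onr_res) > 0L && !r %in% onr_res
    } else {
      maj <- names(which.max(table(onr_res)))
      length(onr_res) > 0L && !identical(r, maj)
    }
    if (!hit) return(NULL)
    data.frame(gene_id = gene_id, column = j, ref_position = refpos[j],
               in_residue = r,
               on_residues = paste(onr, collapse = ""),
               on_has_gap = any(onr %in% c("-", "X")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty_sites())))
  rownames(out) <- NULL
  class(out) <- c("convergent_sites", "data.frame")
  out
}

empty_sites <- function() {
  data.frame(gene_id = character(0), column = integer(0),
             ref_position = integer(0), in_residue = character(0),
             on_residues = character(0), on_has_gap = logical(0),
             stringsAsFactors = FALSE)
}

#' Remove genes whose substitutions are shared by background taxa
#'
#' A gene is dropped entirely (not just the offending site) when any
#' \code{on_list} taxon carries the foreground residue at any called column
#' of that gene — partial convergence in the background disqualifies the
#' gene as foreground-specific.
#'
#' @param sites A \code{convergent_sites} table (possibly over many genes).
#' @param alignments Named list of protein alignments, one per
#'   \code{gene_id} in \code{sites}.
#' @param groups A \code{group_spec}.
#' @return The filtered \code{convergent_sites} table.
#' @export
filter_background_shared <- function(sites, alignments, groups) {
  if (nrow(sites) == 0L) return(sites)
  shared_gene <- vapply(unique(sites$gene_id), function(g) {
    sub <- sites[sites$gene_id == g, , drop = FALSE]
    m <- aa_matrix(alignments[[g]])
    onm <- m[groups$on_list, , drop = FALSE]
    any(vapply(seq_len(nrow(sub)), function(i) {
      sub$in_residue[i] %in% onm[, sub$column[i]]
    }, logical(1)))
  }, logical(1))
  keep <- !sites$gene_id %in% names(shared_gene)[shared_gene]
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conservative-site (CCs) filter
#'
#' Convergence at Conservative Sites: a called site is retained only when
#' the background taxa (\code{on_list} plus \code{outgroup}, gaps excluded)
#' are conserved at that column. Two conservation modes: \code{"identity"}
#' requires a single residue at fraction >= \code{min_background_identity};
#' \code{"property"} requires a single biochemical property class (so a
#' lysine/arginine background — both basic — counts as conserved).
#'
#' @param sites A \code{convergent_sites} table.
#' @param alignments Named list of protein alignments by \code{gene_id}.
#' @param groups A \code{group_spec}.
#' @param min_background_identity Minimum fraction of background residues
#'   (or property classes) that must agree; default 1.0 (strict identity).
#' @param mode \code{"identity"} or \code{"property"}.
#' @param drop Drop non-conservative sites (default) or keep all rows
#'   annotated.
#' @return The table with added columns \code{conservative},
#'   \code{background_residues}, \code{ccs_mode}.
#' @export
conservative_site_filter <- function(sites, alignments, groups,
                                     min_background_identity = 1.0,
                                     mode = c("identity", "property"),
                                     drop = TRUE) {
  mode <- match.arg(mode)
  if (nrow(sites) == 0L) {
    sites$conservative <- logical(0)
    sites$background_residues <- character(0)
    sites$ccs_mode <- character(0)
    return(sites)
  }
  bg_taxa <- c(groups$on_list, groups$outgroup)
  ann <- lapply(seq_len(nrow(sites)), function(i) {
    m <- aa_matrix(alignments[[sites$gene_id[i]]])
    bg <- m[intersect(bg_taxa, rownames(m)), sites$column[i]]
    bg <- bg[!bg %in% c("-", "X")]
    vals <- if (mode == "property") aa_property_class(bg) else bg
    frac <- if (length(vals)) max(table(vals)) / length(vals) else 0
    list(conservative = length(vals) > 0L && frac >= min_background_identity,
         background = paste(bg, collapse = ""))
  })
  sites$conservative <- vapply(ann, `[[`, logical(1), "conservative")
  sites$background_residues <- vapply(ann, `[[`, character(1), "background")
  sites$ccs_mode <- mode
  out <- if (drop) sites[sites$conservative, , drop = FALSE] else sites
  rownames(out) <- NULL
  out
}

#' Annotate sites with conserved-domain overlap
#'
#' @param sites A \code{convergent_sites} table with \code{ref_position}
#'   coordinates (ungapped positions of the reference taxon).
#' @param domain_table Data frame with columns \code{protein_id} (matched
#'   against \code{gene_id}), \code{domain_name}, \code{start}, \code{end}
#'   (1-based closed intervals).
#' @param protein_lengths Optional named vector of protein lengths; intervals
#'   extending beyond a protein are clamped with a warning.
#' @return The table with added columns \code{in_domain}, \code{domain_name}.
#' @export
annotate_domains <- function(sites, domain_table, protein_lengths = NULL) {
  if (!is.null(domain_table) && nrow(domain_table) && !is.null(protein_lengths)) {
    len <- protein_lengths[domain_table$protein_id]
    over <- !is.na(len) & (domain_table$end > len | domain_table$start < 1L)
    if (any(over)) {
      warning("domain intervals out of protein bounds clamped: ",
              paste(domain_table$domain_name[over], collapse = ", "))
      domain_table$end[over] <- pmin(domain_table$end[over], len[over])
      domain_table$start[over] <- pmax(domain_table$start[over], 1L)
    }
  }
  hit <- function(g, pos) {
    if (is.null(domain_table) || nrow(domain_table) == 0L || is.na(pos)) {
      return(NA_character_)
    }
    d <- domain_table[domain_table$protein_id == g &
                        domain_table$start <= pos &
                        domain_table$end >= pos, , drop = FALSE]
    if (nrow(d) == 0L) NA_character_ else d$domain_name[1L]
  }
  dn <- vapply(seq_len(nrow(sites)),
               function(i) hit(sites$gene_id[i], sites$ref_position[i]),
               character(1))
  sites$in_domain <- !is.na(dn)
  sites$domain_name <- dn
  sites
}

# biochemical property classes of the 20 standard residues
.aa_classes <- c(
  G = "hydrophobic", A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
  I = "hydrophobic", P = "hydrophobic", F = "hydrophobic", M = "hydrophobic",
  W = "hydrophobic",
  S = "polar", T = "polar", C = "polar", Y = "polar", N = "polar", Q = "polar",
  K = "basic", R = "basic", H = "basic",
  D = "acidic", E = "acidic"
)

#' Biochemical property class of amino acids
#'
#' Four-class scheme: hydrophobic (G A V L I P F M W), polar
#' (uncharged-hydrophilic: S T C Y N Q), basic (K R H), acidic (D E).
#'
#' @param aa Character vector of single-letter residues.
#' @return Character vector of class labels.
#' @export
aa_property_class <- function(aa) {
  out <- .aa_classes[aa]
  if (anyNA(out)) {
    stop("unknown amino-acid letter: ",
         paste(unique(aa[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Classify the biochemical property change of a substitution
#'
#' Maps the ancestral residue(s) and the derived residue to property classes
#' (see \code{\link{aa_property_class}}). A multi-residue ancestral set is
#' admitted when all members share one class (e.g., lysine and arginine,
#' both basic).
#'
#' @param from_residues Character vector of background residue(s).
#' @param to_residue Single derived residue.
#' @return List with \code{from}, \code{to} (class labels; \code{from} is
#'   \code{"mixed"} when the ancestral residues span classes) and
#'   \code{no_change} (logical: same class on both sides).
#' @export
classify_property_change <- function(from_residues, to_residue) {
  from_cl <- unique(aa_property_class(unique(from_residues)))
  to_cl <- aa_property_class(to_residue)
  from <- if (length(from_cl) == 1L) from_cl else "mixed"
  list(from = from, to = to_cl, no_change = identical(from, to_cl))
}

#' Run the full convergent-substitution screen
#'
#' Chains detection, the background-sharing gene filter, the
#' conservative-site (CCs) filter, domain annotation and property-change
#' classification over a set of per-gene protein alignments, reporting
#' per-stage gene/site counts (the counts are non-increasing through the
#' pipeline; domain annotation never changes them).
#'
#' @param alignments Named list of protein alignments (named character
#'   vectors), one per gene.
#' @param groups A \code{group_spec}.
#' @param domain_table Optional domain interval table (see
#'   \code{\link{annotate_domains}}).
#' @param ccs_mode \code{"identity"} or \code{"property"}.
#' @param min_background_identity Conservation fraction for the CCs filter.
#' @param on_mode Passed to \code{\link{detect_shared_substitutions}}.
#' @return List with \code{sites} (annotated \code{convergent_sites} table
#'   including \code{property_from}, \code{property_to}) and
#'   \code{stage_counts} (named numeric: \code{detected},
#'   \code{after_background_filter}, \code{after_ccs}, \code{in_domain} —
#'   numbers of sites — and gene-count equivalents with suffix
#'   \code{_genes}).
#' @export
run_convergence_screen <- function(alignments, groups, domain_table = NULL,
                                   ccs_mode = c("identity", "property"),
                                   min_background_identity = 1.0,
                                   on_mode = "absent") {
  ccs_mode <- match.arg(ccs_mode)
  stopifnot(length(alignments) > 0L, !is.null(names(alignments)))
  detected <- do.call(rbind, lapply(names(alignments), function(g) {
    detect_shared_substitutions(alignments[[g]], groups, gene_id = g,
                                on_mode = on_mode)
  }))
  class(detected) <- c("convergent_sites", "data.frame")
  after_bg <- filter_background_shared(detected, alignments, groups)
  after_ccs <- conservative_site_filter(after_bg, alignments, groups,
                                        min_background_identity, ccs_mode)
  ann <- annotate_domains(after_ccs, domain_table)
  if (nrow(ann)) {
    prop <- lapply(seq_len(nrow(ann)), function(i) {
      bg <- strsplit(ann$background_residues[i], "")[[1L]]
      if (length(bg) == 0L) return(list(from = NA_character_,
                                        to = NA_character_))
      cls <- try(classify_property_change(bg, ann$in_residue[i]),
                 silent = TRUE)
      if (inherits(cls, "try-error")) list(from = NA_character_,
                                           to = NA_character_) else cls
    })
    ann$property_from <- vapply(prop, function(p) p$from, character(1))
    ann$property_to <- vapply(prop, function(p) p$to, character(1))
  } else {
    ann$property_from <- character(0)
    ann$property_to <- character(0)
  }
  counts <- c(
    detected = nrow(detected),
    after_background_filter = nrow(after_bg),
    after_ccs = nrow(after_ccs),
    in_domain = sum(ann$in_domain),
    detected_genes = length(unique(detected$gene_id)),
    after_background_filter_genes = length(unique(after_bg$gene_id)),
    after_ccs_genes = length(unique(after_ccs$gene_id)),
    in_domain_genes = length(unique(ann$gene_id[ann$in_domain]))
  )
  list(sites = ann, stage_counts = counts)
}
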