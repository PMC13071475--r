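# Convergent-substitution screen: detection, background-sharing filter,
# conservative-site modes, domain annotation, property classification, and
# planted-truth recovery through the full pipeline.

in5 <- paste0("carn", 1:4)
on5 <- paste0("herb", 1:5)
grp <- group_spec(in5, on5)

# columns: list of named residue vectors over c(in5, on5)
col <- function(in_res, on_res) {
  stats::setNames(c(rep_len(in_res, 4), rep_len(on_res, 5)), c(in5, on5))
}

test_that("detection requires foreground unanimity and background absence", {
  aln <- protein_aln_from_columns(
    list(col("S", "S"),      # conserved everywhere: no call
         col("G", "S"),      # unanimous IN, absent from ON: call
         col(c("G", "G", "G", "S"), "S"),  # IN not unanimous: no call
         col("A", c("A", "T", "T", "T", "T"))),  # IN residue in ON: no call
    c(in5, on5))
  sites <- detect_shared_substitutions(aln, grp, gene_id = "g1")
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$column, 2L)
  expect_identical(sites$in_residue, "G")
  expect_identical(sites$on_residues, "SSSSS")

  expect_error(detect_shared_substitutions(aln, group_spec(c(in5, "nope"),
                                                           on5)),
               "missing from alignment")
})

test_that("foreground gaps skip a column; background gaps only flag it", {
  aln <- protein_aln_from_columns(
    list(col(c("G", "G", "-", "G"), "S"),
         col("G", c("S", "S", "-", "S", "S"))),
    c(in5, on5))
  sites <- detect_shared_substitutions(aln, grp)
  expect_equal(sites$column, 2L)
  expect_true(sites$on_has_gap)
})

test_that("majority mode admits partial background sharing, and the
           background filter then removes the whole gene", {
  aln <- protein_aln_from_columns(
    list(col("G", c("S", "S", "S", "S", "G")),  # one ON taxon shares G
         col("A", "T")),
    c(in5, on5))
  strict <- detect_shared_substitutions(aln, grp, gene_id = "g1")
  expect_identical(strict$column, 2L)  # shared column not called

  loose <- detect_shared_substitutions(aln, grp, gene_id = "g1",
                                       on_mode = "majority")
  expect_setequal(loose$column, c(1L, 2L))
  # gene-level removal: one shared site disqualifies every site of the gene
  filtered <- filter_background_shared(loose, list(g1 = aln), grp)
  expect_equal(nrow(filtered), 0L)

  clean <- protein_aln_from_columns(list(col("A", "T")), c(in5, on5))
  sites2 <- detect_shared_substitutions(clean, grp, gene_id = "g2")
  kept <- filter_background_shared(sites2, list(g2 = clean), grp)
  expect_identical(kept, sites2)
  expect_equal(nrow(filter_background_shared(empty <- sites2[0, ],
                                             list(), grp)), 0L)
})

test_that("conservative-site filter applies identity fraction and
           property-class modes", {
  alnA <- protein_aln_from_columns(list(col("G", "S")), c(in5, on5))
  sA <- detect_shared_substitutions(alnA, grp, gene_id = "gA")
  consA <- conservative_site_filter(sA, list(gA = alnA), grp)
  expect_true(consA$conservative)

  # background S,S,S,S,T: fails at threshold 1.0, passes at 0.8
  alnB <- protein_aln_from_columns(
    list(col("G", c("S", "S", "S", "S", "T"))), c(in5, on5))
  sB <- detect_shared_substitutions(alnB, grp, gene_id = "gB")
  expect_equal(nrow(conservative_site_filter(sB, list(gB = alnB), grp,
                                             min_background_identity = 1)),
               0L)
  relaxed <- conservative_site_filter(sB, list(gB = alnB), grp,
                                      min_background_identity = 0.8)
  expect_true(relaxed$conservative)

  # K/R background: rejected under strict identity, admitted in property
  # mode because both residues are basic
  alnC <- protein_aln_from_columns(
    list(col("Q", c("K", "K", "R", "R", "R"))), c(in5, on5))
  sC <- detect_shared_substitutions(alnC, grp, gene_id = "gC")
  expect_equal(nrow(conservative_site_filter(sC, list(gC = alnC), grp)), 0L)
  prop <- conservative_site_filter(sC, list(gC = alnC), grp,
                                   mode = "property")
  expect_true(prop$conservative)
  expect_identical(prop$ccs_mode, "property")
})

test_that("domain annotation is 1-based closed-interval containment", {
  sites <- data.frame(gene_id = "phos", column = 71L, ref_position = 71L,
                      in_residue = "G", on_residues = "SSSSS",
                      on_has_gap = FALSE, stringsAsFactors = FALSE)
  dom <- data.frame(protein_id = "phos", domain_name = "phosphatase",
                    start = 50L, end = 120L, stringsAsFactors = FALSE)
  ann <- annotate_domains(sites, dom)
  expect_true(ann$in_domain)
  expect_identical(ann$domain_name, "phosphatase")

  dom2 <- transform(dom, start = 72L)
  expect_false(annotate_domains(sites, dom2)$in_domain)
  expect_false(annotate_domains(sites, dom[0, ])$in_domain)
  # interval beyond the protein end is clamped with a warning
  dom3 <- transform(dom, end = 500L)
  expect_warning(ann3 <- annotate_domains(sites, dom3,
                                          protein_lengths = c(phos = 300L)),
                 "clamped")
  expect_true(ann3$in_domain)
})

test_that("property classification follows the four-class scheme", {
  sg <- classify_property_change("S", "G")
  expect_identical(sg$from, "polar")        # serine: uncharged hydrophilic
  expect_identical(sg$to, "hydrophobic")    # glycine
  expect_false(sg$no_change)

  krq <- classify_property_change(c("K", "R"), "Q")
  expect_identical(krq$from, "basic")
  expect_identical(krq$to, "polar")         # glutamine: charge-neutral
  expect_false(krq$no_change)

  aa <- classify_property_change("A", "A")
  expect_identical(aa$from, "hydrophobic")
  expect_true(aa$no_change)

  mixed <- classify_property_change(c("K", "D"), "Q")
  expect_identical(mixed$from, "mixed")
  expect_error(classify_property_change("B", "Q"), "unknown")
})

test_that("screen output is invariant to taxon order and all-gap taxa", {
  aln <- protein_aln_from_columns(
    list(col("S", "S"), col("G", "S"), col("T", "A")), c(in5, on5))
  base <- run_convergence_screen(list(g = aln), grp)
  shuf <- run_convergence_screen(list(g = aln[sample(names(aln))]), grp)
  expect_identical(base$sites, shuf$sites)
  with_gap <- c(aln, stats::setNames(strrep("-", 3), "ghost"))
  gap <- run_convergence_screen(list(g = with_gap), grp)
  expect_identical(base$sites, gap$sites)
  expect_identical(base$stage_counts, gap$stage_counts)
})

test_that("stage counts narrow monotonically through the screen", {
  set.seed(41)
  tree <- fixture_study_tree()
  alns <- lapply(1:6, function(i) {
    translate_alignment(simulate_alignment(
      simulation_config(tree, 120, omega_background = 0.8,
                        seed = 300 + i)))
  })
  names(alns) <- sprintf("g%d", 1:6)
  res <- run_convergence_screen(alns, group_spec(study_foreground(),
                                                 paste0("bg", 1:7)))
  sc <- res$stage_counts
  expect_gte(sc[["detected"]], sc[["after_background_filter"]])
  expect_gte(sc[["after_background_filter"]], sc[["after_ccs"]])
  expect_gte(sc[["after_ccs"]], sc[["in_domain"]])
  expect_equal(nrow(res$sites), unname(sc[["after_ccs"]]))
})

test_that("the full screen recovers exactly the planted convergent sites", {
  tree <- tag_foreground(fixture_study_tree(), study_foreground())
  fg <- study_foreground()
  on_list <- paste0("bg", 1:7)
  plant_gene <- function(n_sites, seed) {
    # low omega keeps most columns conserved so planting targets exist
    aln <- simulate_alignment(
      simulation_config(tree, 100, omega_background = 0.05,
                        kappa = 2, seed = seed))
    prot <- translate_alignment(aln)
    bg_res <- do.call(rbind, strsplit(prot[on_list], ""))
    cons <- which(apply(bg_res, 2, function(cc)
      length(unique(cc)) == 1 && !any(cc %in% c("-", "X"))))
    # plant only where the foreground currently equals the background
    in_res <- do.call(rbind, strsplit(prot[fg], ""))
    same <- cons[vapply(cons, function(j)
      all(in_res[, j] == bg_res[1, j]), logical(1))]
    pos <- same[seq(2, by = 3, length.out = n_sites)]
    targets <- vapply(pos, function(j)
      setdiff(c("G", "W", "P", "H", "E"), bg_res[1, j])[1], character(1))
    if (n_sites == 0) return(list(aln = aln, pos = integer(0)))
    planted <- plant_convergent_substitutions(
      aln, fg, data.frame(pos = pos, aa = targets))
    list(aln = planted, pos = pos)
  }
  for (k in c(0L, 1L, 5L)) {
    g <- plant_gene(k, seed = 600 + k)
    prot <- translate_alignment(g$aln)
    res <- run_convergence_screen(list(gene = prot),
                                  group_spec(fg, on_list))
    expect_identical(sort(res$sites$column), sort(as.integer(g$pos)),
                     info = paste("k =", k))
    expect_equal(unname(res$stage_counts[["after_ccs"]]), k)
  }
})
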