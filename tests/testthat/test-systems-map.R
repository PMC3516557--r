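sig_row <- function(name, members, species = "fly", collection = "KEGG") {
  data.frame(set_name = name, collection = collection, k = length(members),
             K = length(members), n = 10, N = 100, p_value = 0.001,
             percent_mapped = 100, significant = TRUE,
             member_hits = paste(members, collapse = ";"),
             species = species, stringsAsFactors = FALSE)
}

test_that("pooling significant sets into classes unions their members", {
  cm <- data.frame(set_name = c("S1", "S2"), class_label = c("CL1", "CL1"))
  one <- pool_into_classes(sig_row("S1", c("a", "b", "c")),
                           data.frame(set_name = "S1", class_label = "CL1"))
  expect_identical(one$membership$gene_id, c("a", "b", "c"))

  # sizes 8 and 7 sharing 3 -> class membership 12
  two <- pool_into_classes(rbind(sig_row("S1", sprintf("g%d", 1:8)),
                                 sig_row("S2", sprintf("g%d", 6:12))), cm)
  expect_identical(nrow(two$membership), 12L)

  empty <- sig_row("S1", "a"); empty$significant <- FALSE
  expect_warning(none <- pool_into_classes(empty, cm), "no significant sets")
  expect_identical(nrow(none$membership), 0L)

  # unmapped sets are excluded and reported
  expect_warning(
    un <- pool_into_classes(rbind(sig_row("S1", "a"), sig_row("SX", "b")), cm),
    "missing from the class map")
  expect_identical(un$unassigned, "SX")
  expect_false("b" %in% un$membership$gene_id)
})

test_that("pooling is independent of input order and unifies species via orthologs", {
  cm <- data.frame(set_name = c("S1", "S2"), class_label = c("CL1", "CL2"))
  tab <- odf(c("CG1", "CG2"), c("H1", "H2"))
  r_fly <- sig_row("S1", c("CG1", "CG2"))
  r_hum <- sig_row("S2", c("H1", "H2"), species = "human")
  ab <- pool_into_classes(list(r_fly, r_hum), cm, ortholog_table = tab)
  ba <- pool_into_classes(list(r_hum, r_fly), cm, ortholog_table = tab)
  expect_identical(ab, ba)
  # human members collapse onto their fly anchors
  expect_identical(sort(unique(ab$membership$gene_id)), c("CG1", "CG2"))
})

test_that("map assembly is bipartite with total gene categorization", {
  memb <- data.frame(class_label = "CL1", gene_id = c("a", "b", "c"))
  cats <- data.frame(gene_id = c("a", "b", "c"),
                     category = c("pain", "pain", "binding_partner"))
  g <- suppressMessages(build_map(memb, cats))
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  el <- igraph::as_edgelist(g)
  kind <- stats::setNames(igraph::vertex_attr(g, "kind"), igraph::V(g)$name)
  expect_true(all(kind[el[, 1]] != kind[el[, 2]]))  # bipartite edges only

  expect_error(suppressMessages(
    build_map(memb, cats[1:2, ])), "integrity error")
})

test_that("a network-figure-scale map partitions its gene nodes by category", {
  fx <- fig1_scale_fixture(n_lethal = 12)
  g <- suppressMessages(build_map(fx$membership, fx$categories))
  kind <- igraph::vertex_attr(g, "kind")
  expect_identical(sum(kind == "class"), 20L)
  expect_identical(sum(kind == "gene"),
                   length(fx$pain) + length(fx$bp) + length(fx$lethal))
  # dropping the lethal list changes only lethal nodes and their edges
  fx0 <- fig1_scale_fixture(n_lethal = 0)
  g0 <- suppressMessages(build_map(fx0$membership, fx0$categories))
  gene_names <- function(gr) sort(igraph::V(gr)$name[
    igraph::vertex_attr(gr, "kind") == "gene"])
  expect_identical(setdiff(gene_names(g), gene_names(g0)), sort(fx$lethal))
})

test_that("class hit representation flags exactly the at-or-below-half classes", {
  fx <- fig1_scale_fixture()
  g <- suppressMessages(build_map(fx$membership, fx$categories))
  rep_tab <- class_hit_representation(g)
  expect_identical(sort(rep_tab$class_label[!rep_tab$above_half]),
                   fx$low_classes)
  expect_identical(attr(rep_tab, "n_at_or_below_half"),
                   length(fx$low_classes))
  all_pain <- suppressMessages(build_map(
    data.frame(class_label = "CL", gene_id = c("x", "y")),
    data.frame(gene_id = c("x", "y"), category = "pain")))
  expect_identical(class_hit_representation(all_pain)$frac_pain, 1)
  half <- suppressMessages(build_map(
    data.frame(class_label = "CL", gene_id = c("a", "b", "c", "d")),
    data.frame(gene_id = c("a", "b", "c", "d"),
               category = c("pain", "pain", "binding_partner", "binding_partner"))))
  expect_false(class_hit_representation(half)$above_half)  # 0.5 is NOT >50%
})

test_that("connectivity diagnostic detects partner-dependent classes", {
  fx <- fig1_scale_fixture()
  g <- suppressMessages(build_map(fx$membership, fx$categories))
  conn <- connectivity_without_partners(g)
  expect_true(conn$intact)       # every class keeps >= 1 pain gene
  expect_identical(conn$isolated_classes, character(0))

  # a map with no partners at all is untouched by the pruning
  only_pain <- suppressMessages(build_map(
    data.frame(class_label = "CL", gene_id = c("x", "y")),
    data.frame(gene_id = c("x", "y"), category = "pain")))
  cp <- connectivity_without_partners(only_pain)
  expect_identical(cp$components_full, cp$components_pruned)

  # a class whose only members are partners becomes isolated
  fxp <- fig1_scale_fixture(partner_only = "CLASS_07")
  gp <- suppressMessages(build_map(fxp$membership, fxp$categories))
  cpp <- connectivity_without_partners(gp)
  expect_false(cpp$intact)
  expect_identical(cpp$isolated_classes, "CLASS_07")
})

test_that("partner removal never isolates a class holding a pain gene", {
  for (seed in 1:5) {
    set.seed(seed)
    genes <- sprintf("g%02d", 1:40)
    cats <- data.frame(gene_id = genes,
                       category = sample(c("pain", "binding_partner"), 40,
                                         replace = TRUE))
    memb <- data.frame(class_label = sample(sprintf("CL%d", 1:6), 60, TRUE),
                       gene_id = sample(genes, 60, TRUE))
    memb <- unique(memb)
    g <- suppressMessages(build_map(memb, cats))
    conn <- connectivity_without_partners(g)
    with_pain <- unique(memb$class_label[
      cats$category[match(memb$gene_id, cats$gene_id)] == "pain"])
    expect_identical(intersect(conn$isolated_classes, with_pain), character(0))
  }
})

test_that("systems-map exports are readable text", {
  fx <- fig1_scale_fixture()
  g <- suppressMessages(build_map(fx$membership, fx$categories))
  prefix <- file.path(withr::local_tempdir(), "map")
  paths <- write_systems_map(g, prefix, header = c("# painmap test"))
  expect_true(all(file.exists(paths)))
  sif <- readLines(paste0(prefix, ".sif"))
  sif <- sif[!startsWith(sif, "#")]
  expect_equal(length(sif), igraph::ecount(g))
  memb <- read_tsv(paste0(prefix, ".membership.tsv"))
  expect_equal(nrow(memb), igraph::ecount(g))
})
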