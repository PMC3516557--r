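test_that("degenerate universe sizes and forced topologies behave", {
  u0 <- generate_universe(universe_spec(n_fly = 0, n_mouse = 0, n_human = 0))
  expect_identical(lengths(u0$genes), c(fly = 0L, mouse = 0L, human = 0L))
  expect_true(all(vapply(u0$tables, nrow, integer(1)) == 0L))

  un <- generate_universe(universe_spec(n_fly = 50, n_mouse = 50, n_human = 50,
                                        frac_one_to_one = 0, frac_many_to_many = 0,
                                        frac_unmapped = 1, seed = 4))
  expect_true(all(vapply(un$tables, nrow, integer(1)) == 0L))
  expect_length(un$genes$fly, 50)

  expect_error(universe_spec(frac_one_to_one = 0.7, frac_many_to_many = 0.2,
                             frac_unmapped = 0.3),
               "sum to at most 1")
})

test_that("universes are seed-reproducible and gene IDs unique per species", {
  spec <- universe_spec(n_fly = 300, n_mouse = 600, n_human = 650, seed = 11)
  u1 <- generate_universe(spec)
  u2 <- generate_universe(spec)
  expect_identical(u1, u2)
  for (sp in names(u1$genes)) expect_false(anyDuplicated(u1$genes[[sp]]) > 0)
  # at least two non-empty prediction sources whose union covers everything
  expect_gte(sum(vapply(u1$tables, nrow, integer(1)) > 0), 2)
})

test_that("ortholog-bearing gene counts match an independent walk of the emitted tables", {
  spec <- universe_spec(n_fly = 1000, n_mouse = 1600, n_human = 1700,
                        frac_one_to_one = 0.6, frac_many_to_many = 0.1,
                        frac_unmapped = 0.3, seed = 7)
  u <- generate_universe(spec)
  paths <- vapply(u$tables, write_tmp_tsv, character(1))
  merged <- merge_tables(u$tables)
  m <- map_genes(u$genes$fly, merged, "human", source_species = "fly")
  expect_identical(m$n_mapped,
                   walk_count_mapped(paths, u$genes$fly, "human"))
  # requested topology: ~70% of fly genes should map to human
  expect_equal(m$n_mapped / 1000, 0.7, tolerance = 0.02)
})

test_that("screen lists are disjoint, sized, unique and reproducible", {
  u <- generate_universe(universe_spec(n_fly = 14000, n_mouse = 17000,
                                       n_human = 19000, seed = 2))
  s1 <- generate_screen(u, n_hits = 580, n_lethal = 100, seed = 5)
  s2 <- generate_screen(u, n_hits = 580, n_lethal = 100, seed = 5)
  expect_identical(s1, s2)
  expect_length(s1$hits, 580)
  expect_false(anyDuplicated(s1$hits) > 0)
  expect_length(intersect(s1$hits, s1$lethals), 0)
  expect_identical(generate_screen(u, n_hits = 0, seed = 1)$hits, character(0))
  expect_error(generate_screen(u, n_hits = 14000, n_lethal = 1, seed = 1),
               "exceeds")
})

test_that("interaction generator follows the G(n, p) edge-count law and round-trips", {
  nodes <- sprintf("G%04d", 1:1000)
  expect_identical(nrow(generate_interactions(nodes, mean_degree = 0, seed = 1)), 0L)
  e <- generate_interactions(nodes, mean_degree = 4, seed = 1)
  # E[m] = n * d / 2 = 2000, binomial sd = sqrt(M p (1-p)), M = C(n,2)
  p <- 4 / 999
  sd_m <- sqrt(choose(1000, 2) * p * (1 - p))
  expect_lt(abs(nrow(e) - 2000), 3 * sd_m)
  expect_true(all(e$from < e$to))
  expect_false(anyDuplicated(e) > 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(e, path)
  expect_identical(load_interactions(path), e)
})

test_that("planted gene sets over-sample hits at the documented rate", {
  u <- generate_universe(universe_spec(n_fly = 14000, n_mouse = 17000,
                                       n_human = 19000, seed = 3))
  hits <- generate_screen(u, 580, 0, seed = 9)$hits
  eff <- planted_effects(n_sets = 1, set_size_range = c(50, 50),
                         n_planted = 1, enrichment_factor = 5)
  overlaps <- vapply(1:200, function(i) {
    gs <- generate_genesets(u$genes$fly, hits, eff, seed = 1000 + i)
    length(intersect(gs$sets[[1]], hits))
  }, numeric(1))
  expected <- 50 * 5 * 580 / 14000              # 10.357...
  p_hit <- 5 * 580 / 14000
  se <- sqrt(50 * p_hit * (1 - p_hit) / 200)
  expect_lt(abs(mean(overlaps) - expected), 3 * se)
})

test_that("factor-1 planted sets are indistinguishable from background sets", {
  u <- generate_universe(universe_spec(n_fly = 4000, n_mouse = 5000,
                                       n_human = 5000, seed = 5))
  hits <- generate_screen(u, 200, 0, seed = 2)$hits
  eff <- planted_effects(n_sets = 20, set_size_range = c(40, 60),
                         n_planted = 10, enrichment_factor = 1)
  frac <- function(members) length(intersect(members, hits)) / length(members)
  planted <- c(); plain <- c()
  for (i in 1:50) {
    gs <- generate_genesets(u$genes$fly, hits, eff, seed = 3000 + i)
    fr <- vapply(gs$sets, frac, numeric(1))
    planted <- c(planted, fr[gs$truth$planted])
    plain <- c(plain, fr[!gs$truth$planted])
  }
  ks <- suppressWarnings(stats::ks.test(planted, plain))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth table flags exactly the planted sets", {
  u <- list(genes = list(fly = sprintf("CG%04d", 1:500)))
  gs0 <- generate_genesets(u$genes$fly, u$genes$fly[1:20],
                           planted_effects(n_sets = 6, set_size_range = c(5, 10),
                                           n_planted = 0), seed = 1)
  expect_identical(sum(gs0$truth$planted), 0L)
  gs3 <- generate_genesets(u$genes$fly, u$genes$fly[1:20],
                           planted_effects(n_sets = 6, set_size_range = c(5, 10),
                                           n_planted = 3), seed = 1)
  expect_identical(sum(gs3$truth$planted), 3L)
  expect_error(
    generate_genesets(u$genes$fly[1:4], character(0),
                      planted_effects(n_sets = 1, set_size_range = c(5, 10),
                                      n_planted = 0), seed = 1),
    "exceeds background")
})

test_that("annotation generator hits its closed-form union expectation", {
  bg <- sprintf("CG%05d", 1:14000)
  mapg <- bg[1:166]
  eff0 <- planted_effects(annotation_base_rate = 0, annotation_hit_rate = 0)
  a0 <- generate_annotations(bg, mapg, eff0, seed = 1)
  expect_true(all(lengths(a0) == 0))
  eff1 <- planted_effects(annotation_base_rate = 0, annotation_hit_rate = 1)
  a1 <- generate_annotations(bg, mapg, eff1, seed = 1)
  expect_true(all(vapply(a1, function(x) all(mapg %in% x), logical(1))))

  eff <- planted_effects(annotation_base_rate = 0.03, annotation_hit_rate = 0.38)
  pct <- vapply(1:100, function(i) {
    ann <- generate_annotations(bg, mapg, eff, seed = 4000 + i)
    100 * sum(mapg %in% union(ann$OMIM, ann$microarray)) / length(mapg)
  }, numeric(1))
  p_union <- 1 - (1 - 0.38)^2                   # per-source independence
  se <- 100 * sqrt(p_union * (1 - p_union) / 166) / sqrt(100)
  expect_lt(abs(mean(pct) - 100 * p_union), 3 * se)
})

test_that("all generated files round-trip through their readers losslessly", {
  u <- generate_universe(universe_spec(n_fly = 120, n_mouse = 260,
                                       n_human = 280, seed = 6))
  s <- generate_screen(u, 20, 5, seed = 6)
  hdr <- c("# painmap test", "# seed=6")
  p1 <- withr::local_tempfile(); write_gene_list(s$hits, p1, hdr)
  expect_identical(read_gene_list(p1), s$hits)
  gs <- generate_genesets(u$genes$fly, s$hits,
                          planted_effects(n_sets = 5, set_size_range = c(5, 15),
                                          n_planted = 2), seed = 6)
  p2 <- withr::local_tempfile(fileext = ".gmt"); write_gmt(gs$sets, p2, header = hdr)
  back <- read_gmt(p2)
  expect_identical(lapply(back, identity), gs$sets[names(back)])
  ann <- generate_annotations(u$genes$fly, s$hits,
                              planted_effects(annotation_base_rate = 0.1,
                                              annotation_hit_rate = 0.5), seed = 6)
  p3 <- withr::local_tempfile(fileext = ".tsv"); write_annotations(ann, p3, hdr)
  expect_identical(read_annotations(p3), ann[order(names(ann))])
})
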