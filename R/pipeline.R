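# End-to-end orchestration: simulate (optional) -> ortholog projection ->
# partner expansion -> per-species enrichment -> systems-map assembly ->
# annotation-overlap validation. One run-level seed fans out to the
# stages via derive_seed(); the run directory receives the verbatim
# config, every table with a provenance header, and a JSON manifest with
# per-stage counts and file checksums, so identical configs reproduce
# byte-identical runs.

#' Pipeline run configuration
#'
#' @param seed Run-level integer seed; all stage seeds derive from it.
#' @param outdir Output directory (created if needed).
#' @param simulate Generate all inputs synthetically? (`FALSE` expects
#'   file paths in `inputs`.)
#' @param universe A [universe_spec()] describing the synthetic universe
#'   (its `seed` field is overridden by the derived stage seed).
#' @param n_hits,n_lethal Screen-list sizes for the synthetic screen.
#' @param mean_degree Mean degree of the synthetic interaction network.
#' @param effects A [planted_effects()] for gene-set and annotation
#'   generation.
#' @param target_species Mammalian species to project into.
#' @param go_query Query mode for GO collections: `"hits"` (orthologs of
#'   direct hits only, the default) or `"hits+partners"`.
#' @param policy A [significance_policy()].
#' @param n_random_lists Number of random lists for the overlap null.
#' @param n_classes Number of functional classes for the synthetic class
#'   map.
#' @param expand Include first-degree binding partners? Turning this off
#'   reproduces the "primary hits only" map variant.
#' @param validate Run the annotation-overlap validation stage?
#' @param inputs Named list of input file paths for `simulate = FALSE`
#'   runs: `hits`, `lethals`, `tables` (character vector of ortholog
#'   TSVs), `interactions`, `collections` (list of lists with fields
#'   `species`, `label`, `gmt`, optional `ontology`), `class_map`,
#'   `annotations`, `background`.
#' @return Object of class `painmap_config`.
#' @export
painmap_config <- function(seed = 1L, outdir = tempfile("painmap_run_"),
                           simulate = TRUE,
                           universe = universe_spec(),
                           n_hits = 580, n_lethal = 100, mean_degree = 1,
                           effects = planted_effects(),
                           target_species = c("mouse", "human"),
                           go_query = c("hits", "hits+partners"),
                           policy = significance_policy(),
                           n_random_lists = 100, n_classes = 8,
                           expand = TRUE, validate = TRUE,
                           inputs = NULL) {
  go_query <- match.arg(go_query)
  if (!is_count(seed)) stop_param("'seed' must be a single non-negative integer")
  structure(
    list(seed = as.integer(seed), outdir = outdir, simulate = simulate,
         universe = universe, n_hits = n_hits, n_lethal = n_lethal,
         mean_degree = mean_degree, effects = effects,
         target_species = target_species, go_query = go_query,
         policy = policy, n_random_lists = n_random_lists,
         n_classes = n_classes, expand = expand, validate = validate,
         inputs = inputs),
    class = "painmap_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [painmap_config()];
#' `universe`, `effects` and `policy` are nested maps passed to their
#' constructors.
#'
#' @param path YAML file path.
#' @param overrides Named list of values that win over the file.
#' @return Object of class `painmap_config`.
#' @export
painmap_config_from_yaml <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  args <- raw
  if (!is.null(raw$universe)) args$universe <- do.call(universe_spec, raw$universe)
  if (!is.null(raw$effects)) args$effects <- do.call(planted_effects, raw$effects)
  if (!is.null(raw$policy)) args$policy <- do.call(significance_policy, raw$policy)
  do.call(painmap_config, args[names(args) %in% names(formals(painmap_config))])
}

config_as_list <- function(config) {
  list(seed = config$seed, simulate = config$simulate,
       universe = unclass(config$universe),
       n_hits = config$n_hits, n_lethal = config$n_lethal,
       mean_degree = config$mean_degree,
       effects = unclass(config$effects),
       target_species = config$target_species, go_query = config$go_query,
       policy = unclass(config$policy),
       n_random_lists = config$n_random_lists,
       n_classes = config$n_classes, expand = config$expand,
       validate = config$validate, inputs = config$inputs)
}

stage_record <- function(name, status = "complete", counts = list(),
                         outputs = character(0)) {
  list(name = name, status = status, counts = counts, outputs = as.list(outputs))
}

#' Run the full cross-species systems-mapping pipeline
#'
#' Executes simulate (optional), ortholog projection, binding-partner
#' expansion, enrichment across collections and species, systems-map
#' assembly and annotation-overlap validation. Any stage failure halts
#' the run with a stage-tagged error. Re-running with an identical
#' configuration reproduces byte-identical outputs.
#'
#' @param config A [painmap_config()].
#' @return Invisibly, a list with the run `manifest` and the in-memory
#'   stage results (`universe`, `screen`, `queries`, `enrichment`, `map`,
#'   `diagnostics`, `report`, `nulls`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "painmap_config")) {
    stop_param("'config' must be a painmap_config")
  }
  if (!config$simulate && is.null(config$inputs)) {
    stop_param("[config] simulate = FALSE requires 'inputs'")
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config_as_list(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  hdr <- provenance_header(seed = config$seed, config_hash = cfg_hash)
  seeds <- derive_seed(config$seed,
                       c("universe", "screen", "interactions", "genesets",
                         "annotations", "ontology", "class_map", "null"))
  names(seeds) <- c("universe", "screen", "interactions", "genesets",
                    "annotations", "ontology", "class_map", "null")
  stages <- list()
  out_files <- character(0)
  emit <- function(fn) { out_files <<- c(out_files, file.path(outdir, fn)); file.path(outdir, fn) }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  ## -- stage 1: simulate / load inputs ------------------------------------
  sim <- run_stage("simulate", {
    if (config$simulate) {
      uspec <- config$universe
      uspec$seed <- seeds[["universe"]]
      universe <- generate_universe(uspec)
      screen <- generate_screen(universe, config$n_hits, config$n_lethal,
                                seed = seeds[["screen"]])
      edges <- generate_interactions(universe, config$mean_degree,
                                     seed = seeds[["interactions"]])
      write_gene_list(screen$hits, emit("hits.txt"), hdr)
      write_gene_list(screen$lethals, emit("lethals.txt"), hdr)
      write_interactions(edges, emit("interactions.tsv"), hdr)
      for (src in names(universe$tables)) {
        write_tsv(universe$tables[[src]],
                  emit(sprintf("orthologs.%s.tsv", src)), hdr)
      }
      list(universe = universe, hits = screen$hits, lethals = screen$lethals,
           edges = edges, tables = universe$tables)
    } else {
      inp <- config$inputs
      tables <- lapply(inp$tables, load_ortholog_table)
      list(universe = NULL, hits = read_gene_list(inp$hits),
           lethals = if (!is.null(inp$lethals)) read_gene_list(inp$lethals) else character(0),
           edges = load_interactions(inp$interactions), tables = tables)
    }
  })
  stages$simulate <- stage_record("simulate",
    status = if (config$simulate) "complete" else "skipped (inputs supplied)",
    counts = list(n_hits = length(sim$hits), n_lethals = length(sim$lethals),
                  n_interactions = nrow(sim$edges)))

  ## -- stage 2: ortholog projection of the hit list -----------------------
  ortho <- run_stage("map-orthologs", {
    merged <- merge_tables(sim$tables)
    maps <- lapply(config$target_species, function(sp) {
      m <- map_genes(sim$hits, merged, sp, source_species = "fly")
      write_mapping_report(m, emit(sprintf("hits.%s.mapping.tsv", sp)), hdr)
      m
    })
    names(maps) <- config$target_species
    list(merged = merged, hit_maps = maps)
  })
  stages$orthology <- stage_record("map-orthologs",
    counts = c(list(n_mappings = nrow(ortho$merged)),
               stats::setNames(lapply(ortho$hit_maps, function(m) m$n_mapped),
                               paste0("hits_mapped_", names(ortho$hit_maps)))))

  ## -- stage 3: first-degree binding-partner expansion ---------------------
  exp_res <- run_stage("expand", {
    partners <- if (config$expand) {
      first_degree_partners(sim$hits, sim$edges)
    } else character(0)
    categories_fly <- categorize_nodes(sim$hits, partners, sim$lethals)
    write_node_categories(categories_fly, emit("node_categories.tsv"),
                          species = "fly", header = hdr)
    list(partners = partners, categories = categories_fly)
  })
  stages$expand <- stage_record("expand",
    status = if (config$expand) "complete" else "skipped (expand = FALSE)",
    counts = list(n_hits_in = length(sim$hits),
                  n_partners = length(exp_res$partners)))

  ## -- stage 4: enrichment per species and collection ----------------------
  enr <- run_stage("enrich", {
    query_fly <- sort_unique(c(sim$hits, exp_res$partners))
    queries <- list(fly = query_fly)
    for (sp in config$target_species) {
      queries[[sp]] <- map_genes(query_fly, ortho$merged, sp,
                                 source_species = "fly")$targets
    }
    plan <- list(list(species = "fly", label = "KEGG"))
    for (sp in config$target_species) {
      plan <- c(plan, list(list(species = sp, label = "KEGG"),
                           list(species = sp, label = "C2"),
                           list(species = sp, label = "GO")))
    }
    results <- list()
    collections <- list()
    for (i in seq_along(plan)) {
      sp <- plan[[i]]$species; lab <- plan[[i]]$label
      if (config$simulate) {
        query <- queries[[sp]]
        if (lab == "GO" && config$go_query == "hits") {
          query <- if (sp == "fly") sim$hits else {
            map_genes(sim$hits, ortho$merged, sp, source_species = "fly")$targets
          }
        }
        gs <- generate_genesets(sim$universe$genes[[sp]], query,
                                config$effects,
                                seed = seeds[["genesets"]] + i,
                                prefix = sprintf("%s_%s_", toupper(lab),
                                                 toupper(substr(sp, 1, 2))))
        sets <- gs$sets
        write_gmt(sets, emit(sprintf("genesets.%s.%s.gmt", sp, lab)), header = hdr)
        write_tsv(gs$truth, emit(sprintf("genesets.%s.%s.truth.tsv", sp, lab)), hdr)
        bg <- sort_unique(c(unlist(sets, use.names = FALSE), queries[[sp]]))
        ontology <- if (lab == "GO") {
          generate_ontology(names(sets), seed = seeds[["ontology"]] + i)
        } else NULL
      } else {
        coll <- Filter(function(x) x$species == sp && x$label == lab,
                       config$inputs$collections)
        if (!length(coll)) next
        sets <- read_gmt(coll[[1]]$gmt)
        query <- queries[[sp]]
        bg <- if (!is.null(config$inputs$background)) {
          read_gene_list(config$inputs$background)
        } else sort_unique(c(unlist(sets, use.names = FALSE), queries[[sp]]))
        ontology <- if (!is.null(coll[[1]]$ontology)) {
          read_parent_child(coll[[1]]$ontology)
        } else NULL
      }
      res <- enrich_collection(query, sets, bg, config$policy,
                               collection_label = lab)
      if (lab == "GO" && !is.null(ontology)) {
        res <- prune_go_results(res, ontology, config$policy)$results
      }
      res$species <- rep(sp, nrow(res))
      write_enrichment(res, emit(sprintf("enrichment.%s.%s.tsv", sp, lab)), hdr)
      key <- sprintf("%s.%s", sp, lab)
      results[[key]] <- res
      collections[[key]] <- sets
    }
    list(results = results, collections = collections, queries = queries)
  })
  stages$enrich <- stage_record("enrich",
    counts = c(list(n_query_fly = length(enr$queries$fly)),
               stats::setNames(lapply(enr$results, function(r) sum(r$significant)),
                               paste0("significant_", names(enr$results)))))

  ## -- stage 5: systems-map assembly ---------------------------------------
  map_res <- run_stage("build-map", {
    all_sig <- unlist(lapply(enr$results, function(r) r$set_name[r$significant]),
                      use.names = FALSE)
    class_map <- if (config$simulate) {
      cm <- generate_class_map(sort_unique(all_sig), config$n_classes,
                               seed = seeds[["class_map"]])
      write_tsv(cm, emit("class_map.tsv"), hdr)
      cm
    } else {
      read_class_map(config$inputs$class_map)
    }
    anchor_univ <- sort_unique(c(sim$hits, exp_res$partners, sim$lethals))
    pooled <- pool_into_classes(enr$results, class_map,
                                ortholog_table = ortho$merged,
                                anchor_species = "fly",
                                anchor_universe = anchor_univ)
    # lethal genes are never query seeds but are displayed when they sit in
    # a significant set that contributes to a class
    if (length(sim$lethals) && nrow(pooled$membership)) {
      extra <- lapply(seq_len(nrow(pooled$provenance)), function(i) {
        key <- sprintf("%s.%s", pooled$provenance$species[i],
                       pooled$provenance$collection[i])
        members <- enr$collections[[key]][[pooled$provenance$set_name[i]]]
        if (is.null(members)) return(NULL)
        anchored <- anchor_genes(members, pooled$provenance$species[i],
                                 ortho$merged, "fly",
                                 restrict = anchor_univ)
        found <- intersect(anchored, sim$lethals)
        if (!length(found)) return(NULL)
        data.frame(class_label = pooled$provenance$class_label[i],
                   gene_id = found, stringsAsFactors = FALSE)
      })
      extra <- do.call(rbind, c(extra, list(make.row.names = FALSE)))
      if (!is.null(extra) && nrow(extra)) {
        memb <- unique(rbind(pooled$membership, extra))
        pooled$membership <- memb[order(memb$class_label, memb$gene_id,
                                        method = "radix"), , drop = FALSE]
        rownames(pooled$membership) <- NULL
      }
    }
    map_genes_all <- sort_unique(pooled$membership$gene_id)
    categories <- categorize_nodes(sim$hits, exp_res$partners, sim$lethals,
                                   nodes = map_genes_all)
    map <- build_map(pooled, categories)
    write_systems_map(map, file.path(outdir, "systems_map"), hdr)
    out_files <<- c(out_files, file.path(outdir, c("systems_map.graphml",
                                                   "systems_map.sif",
                                                   "systems_map.membership.tsv")))
    rep_tab <- class_hit_representation(map)
    conn <- connectivity_without_partners(map)
    write_tsv(rep_tab, emit("class_hit_representation.tsv"), hdr)
    list(pooled = pooled, categories = categories, map = map,
         representation = rep_tab, connectivity = conn)
  })
  cat_counts <- attr(map_res$categories, "counts")
  stages$map <- stage_record("build-map",
    counts = list(n_classes = sum(igraph::vertex_attr(map_res$map, "kind") == "class"),
                  n_genes = sum(igraph::vertex_attr(map_res$map, "kind") == "gene"),
                  n_pain = unname(cat_counts[["pain"]]),
                  n_binding_partner = unname(cat_counts[["binding_partner"]]),
                  n_lethal = unname(cat_counts[["lethal"]]),
                  connectivity_intact = map_res$connectivity$intact,
                  n_classes_at_or_below_half = attr(map_res$representation,
                                                    "n_at_or_below_half")))

  ## -- stage 6: annotation-overlap validation -------------------------------
  val <- if (config$validate) run_stage("validate", {
    cats <- map_res$categories
    if (config$simulate) {
      bg <- sim$universe$genes$fly
      map_pain_bp <- cats$gene_id[cats$category %in% c("pain", "binding_partner")]
      ann <- generate_annotations(bg, map_pain_bp, config$effects,
                                  seed = seeds[["annotations"]])
      write_annotations(ann, emit("annotations.tsv"), hdr)
    } else {
      ann <- read_annotations(config$inputs$annotations)
      bg <- if (!is.null(config$inputs$background)) {
        read_gene_list(config$inputs$background)
      } else sort_unique(c(unlist(ann, use.names = FALSE), cats$gene_id))
    }
    a <- ann[[1]]; b <- if (length(ann) > 1) ann[[2]] else character(0)
    report <- overlap_report(cats, a, b)
    nulls <- list()
    for (i in seq_len(nrow(report))) {
      if (report$total[i] == 0) next
      nulls[[report$category[i]]] <- random_list_null(
        bg, report$total[i], a, b, R = config$n_random_lists,
        seed = seeds[["null"]] + i, observed = report$union_pct[i]
      )
    }
    write_overlap_report(report, nulls, file.path(outdir, "validation"), hdr)
    out_files <<- c(out_files, file.path(outdir, c("validation.overlap.tsv",
                                                   "validation.overlap.json",
                                                   "validation.null.tsv")))
    list(report = report, nulls = nulls)
  }) else NULL
  stages$validate <- if (config$validate) {
    stage_record("validate",
      counts = list(
        union_pct = stats::setNames(as.list(val$report$union_pct),
                                    val$report$category),
        null_max = lapply(val$nulls, function(x) x$max),
        null_min = lapply(val$nulls, function(x) x$min),
        p_empirical = lapply(val$nulls, function(x) x$p_empirical)))
  } else stage_record("validate", status = "skipped (validate = FALSE)")

  ## -- manifest -------------------------------------------------------------
  out_files <- unique(out_files)
  manifest <- list(
    tool = "painmap",
    version = as.character(utils::packageVersion("painmap")),
    seed = config$seed,
    config_file = basename(cfg_path),
    config_hash = cfg_hash,
    stages = unname(stages),
    files = stats::setNames(as.list(unname(tools::md5sum(out_files))),
                            basename(out_files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, universe = sim$universe,
                 screen = list(hits = sim$hits, lethals = sim$lethals),
                 edges = sim$edges, merged_table = ortho$merged,
                 hit_maps = ortho$hit_maps, partners = exp_res$partners,
                 queries = enr$queries, enrichment = enr$results,
                 map = map_res$map, membership = map_res$pooled,
                 categories = map_res$categories,
                 representation = map_res$representation,
                 connectivity = map_res$connectivity,
                 report = if (!is.null(val)) val$report else NULL,
                 nulls = if (!is.null(val)) val$nulls else NULL))
}
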