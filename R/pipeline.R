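#' Assemble a pipeline run configuration
#'
#' @param synth A `synth_config` describing the synthetic dataset, or
#'   `NULL` when `dataset_path` supplies an external long-format CSV.
#' @param dataset_path Optional path to a dataset CSV
#'   (see [read_dataset_csv()]); overrides `synth`.
#' @param atlas_path Atlas CSV path; `NULL` uses the packaged 52-area atlas.
#' @param arima_order,trim,max_cv,method Prewhitening settings
#'   (see [prewhiten_dataset()]).
#' @param leaf_policy Leaf-order policy (see [leaf_order()]).
#' @param rectify_lr Rectify LR for the bilateral compactness analysis.
#' @param n_perms,n_subsets,subset_sizes Permutation-test settings.
#' @param seed Root seed recorded in every output and used for all
#'   permutation streams.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(), dataset_path = NULL,
                       atlas_path = NULL, arima_order = c(15, 1, 1),
                       trim = 3, max_cv = 0.05, method = "CSS",
                       leaf_policy = "olo", rectify_lr = TRUE,
                       n_perms = 1000, n_subsets = 1000,
                       subset_sizes = NULL, seed = 1L) {
  structure(list(synth = synth, dataset_path = dataset_path,
                 atlas_path = atlas_path,
                 arima_order = as.numeric(arima_order), trim = trim,
                 max_cv = max_cv, method = method,
                 leaf_policy = leaf_policy, rectify_lr = rectify_lr,
                 n_perms = n_perms, n_subsets = n_subsets,
                 subset_sizes = subset_sizes, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `synth` key
#' holds the arguments of [synth_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  synth <- if (!is.null(y$synth)) do.call(synth_config, y$synth)
           else if (is.null(y$dataset_path)) synth_config() else NULL
  y$synth <- NULL
  args <- c(list(synth = synth), y)
  do.call(run_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full layout pipeline
#'
#' Executes, in order: dataset generation (or loading), ARIMA prewhitening,
#' proximity-matrix construction, UPGMA clustering with leaf ordering,
#' the order-on-coordinates regression, and the compactness permutation
#' tests (bilateral and per hemisphere, with size-law and metamodule
#' analyses when `subset_sizes` is set). Six stage artifacts plus a
#' manifest are written to `out_dir`; artifacts are written with a
#' `.partial` suffix and renamed on stage success, so a failed stage leaves
#' its partial output behind. Per-hemisphere trees are re-clustered from
#' the hemisphere submatrix of the proximity matrix.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if absent).
#' @return A `layout_run` report: manifest, artifact paths, and the key
#'   in-memory results (proximity, tree, order, regression, compactness).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  artifact <- function(name) file.path(out_dir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  finalize <- function(partial) {
    final <- sub("\\.partial$", "", partial)
    file.rename(partial, final)
    final
  }

  atlas <- stage("atlas", {
    load_reference_atlas(config$atlas_path)
  })

  dataset <- stage("dataset", {
    if (!is.null(config$dataset_path)) {
      if (!file.exists(config$dataset_path)) {
        stop("dataset file not found: ", config$dataset_path)
      }
      read_dataset_csv(config$dataset_path, atlas = atlas)
    } else {
      simulate_dataset(atlas, config$synth)
    }
  })

  innov <- stage("prewhiten", {
    prewhiten_dataset(dataset, order = config$arima_order,
                      trim = config$trim, max_cv = config$max_cv,
                      method = config$method)
  })
  p_diag <- artifact("innovations_diagnostics.csv.partial")
  utils::write.csv(innov$diagnostics, p_diag, row.names = FALSE)
  f_diag <- finalize(p_diag)

  prox <- stage("proximity", build_proximity(innov, atlas))
  p_prox <- artifact("proximity.csv.partial")
  write_proximity_csv(prox, p_prox)
  f_prox <- finalize(p_prox)

  tree_order <- stage("clustering", {
    tree <- upgma(profile_distance_matrix(prox))
    ord <- orient_anterior(leaf_order(tree, policy = config$leaf_policy),
                           atlas)
    list(tree = tree, order = ord)
  })
  p_tree <- artifact("tree.nwk.partial")
  write_newick(tree_order$tree, p_tree)
  f_tree <- finalize(p_tree)
  p_ord <- artifact("leaf_order.csv.partial")
  write_leaf_order_csv(tree_order$order, p_ord, atlas = atlas)
  f_ord <- finalize(p_ord)

  reg <- stage("regression", {
    fit_order_on_coordinates(tree_order$order, atlas)
  })
  p_reg <- artifact("regression.json.partial")
  jsonlite::write_json(list(
    coefficients = as.list(reg$coefficients),
    t_stats = as.list(reg$t_stats), p_values = as.list(reg$p_values),
    f_statistic = reg$f_statistic,
    df = as.list(reg$df), r_squared = reg$r_squared,
    observed_vs_predicted = predicted_order(reg),
    serial_order_convention = "rank 1 = top of dendrogram",
    seed = config$seed),
    p_reg, auto_unbox = TRUE, digits = NA)
  f_reg <- finalize(p_reg)

  comp <- stage("compactness", {
    seq_bi <- layout_sequence(tree_order$order, atlas,
                              rectify_lr = config$rectify_lr)
    out <- list(bilateral = adjacency_test(seq_bi, config$n_perms,
                                           seed = config$seed))
    for (h in c("left", "right")) {
      sel <- atlas$hemisphere == h
      if (sum(sel) >= 2) {
        sub_atlas <- atlas[sel, , drop = FALSE]
        class(sub_atlas) <- c("area_atlas", "data.frame")
        sub_p <- unclass(prox)[sel, sel, drop = FALSE]
        h_tree <- upgma(profile_distance_matrix(sub_p))
        h_ord <- orient_anterior(
          leaf_order(h_tree, policy = config$leaf_policy), sub_atlas)
        h_seq <- layout_sequence(h_ord, sub_atlas, rectify_lr = FALSE)
        out[[h]] <- adjacency_test(h_seq, config$n_perms,
                                   seed = config$seed)
      }
    }
    if (!is.null(config$subset_sizes)) {
      out$size_law <- size_law_curve(seq_bi, config$subset_sizes,
                                     n_subsets = config$n_subsets,
                                     n_perms = config$n_perms,
                                     seed = config$seed)
      out$metamodule <- metamodule_test(seq_bi, config$subset_sizes,
                                        n_subsets = config$n_subsets,
                                        n_perms = config$n_perms,
                                        seed = config$seed)
    }
    out
  })
  p_comp <- artifact("compactness.json.partial")
  comp_json <- lapply(comp, function(x) {
    if (inherits(x, "compactness_result")) x[setdiff(names(x), "perm_means")]
    else x
  })
  comp_json$seed <- config$seed
  jsonlite::write_json(comp_json, p_comp, auto_unbox = TRUE, digits = NA)
  f_comp <- finalize(p_comp)

  artifacts <- c(f_diag, f_prox, f_tree, f_ord, f_reg, f_comp)
  manifest <- list(
    package = "cortexlayout",
    version = as.character(utils::packageVersion("cortexlayout")),
    seed = config$seed,
    config_hash = config_hash(config),
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(f) unname(tools::md5sum(f))))
  p_man <- artifact("manifest.json.partial")
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA)
  f_man <- finalize(p_man)

  structure(list(manifest = manifest, manifest_path = f_man,
                 artifacts = artifacts, atlas = atlas,
                 proximity = prox, tree = tree_order$tree,
                 order = tree_order$order, regression = reg,
                 compactness = comp, diagnostics = innov$diagnostics),
            class = "layout_run")
}

#' @export
print.layout_run <- function(x, ...) {
  cat("layout_run:", length(x$artifacts), "artifacts\n")
  cat("  R^2 =", signif(x$regression$r_squared, 3),
      "| bilateral c =", signif(x$compactness$bilateral$c_index, 3),
      "| violations =", x$compactness$bilateral$violations, "/",
      x$compactness$bilateral$n_perms, "\n")
  invisible(x)
}
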