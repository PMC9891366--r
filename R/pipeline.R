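#' Default run configuration
#'
#' Builds the configuration list consumed by the pipeline commands
#' ([run_featurize()], [run_train()], [run_attribute()], [run_map()]).
#' All settings are plain values, so the resolved configuration is fully
#' serializable; every command writes it, with the descriptor
#' configuration hash, into `manifest.json` inside the run directory.
#'
#' @param data_dir Directory holding `crystals.xyz`, `molecules.xyz`,
#'   `energies.csv` (the layout [write_synthetic_dataset()] produces).
#' @param run_dir Output directory for all artifacts.
#' @param descriptor Named list of [soap_config()] arguments.
#' @param filter Named list of [filter_config()] arguments.
#' @param model List: `feature_spaces` (subset of s/g/concat/remnant),
#'   `folds`, `train_fraction`, `split` (`"fps"` or `"random"`).
#' @param motifs List: `table` (optional TSV path), `min_count`.
#' @param pcovr List: `alpha`, `k`, `per_class` (fit per-motif-class maps),
#'   `query` (optional motif-instance ids for similarity search).
#' @param seed Integer seed for any stochastic step (random split).
#' @return A named list (class `run_config`).
#' @export
run_config <- function(data_dir, run_dir,
                       descriptor = list(),
                       filter = list(),
                       model = list(),
                       motifs = list(),
                       pcovr = list(),
                       seed = 1L) {
  cfg <- list(
    data_dir = data_dir, run_dir = run_dir,
    descriptor = utils::modifyList(
      list(
        r_cut = 4.0, n_max = 3L, l_max = 3L, sigma_atom = 0.35,
        species = c("C", "H", "N", "O"), normalize = TRUE, n_quad = 60L
      ),
      descriptor
    ),
    filter = utils::modifyList(
      list(varsigma = 0.5, neighbor_cutoff = 2.0), filter
    ),
    model = utils::modifyList(
      list(
        feature_spaces = c("s", "g", "concat", "remnant"),
        folds = 5L, train_fraction = 0.75, split = "fps"
      ),
      model
    ),
    motifs = utils::modifyList(list(table = NULL, min_count = 200L), motifs),
    pcovr = utils::modifyList(
      list(alpha = 0.5, k = 4L, per_class = FALSE, query = NULL), pcovr
    ),
    seed = as.integer(seed)
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

soap_config_from <- function(cfg) do.call(soap_config, cfg$descriptor)

# drop S3 classes recursively so configs serialize to JSON cleanly
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}

update_manifest <- function(cfg, step, extra = list()) {
  dir.create(cfg$run_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cfg$run_dir, "manifest.json")
  man <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    list(
      package_version = as.character(utils::packageVersion("latticemotifs")),
      config = strip_classes(cfg), steps = list(), warnings = list()
    )
  }
  man$steps[[step]] <- c(
    list(completed = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(man)
}

load_dataset_records <- function(cfg) {
  crystals <- read_extxyz(file.path(cfg$data_dir, "crystals.xyz"))
  mols <- read_extxyz(file.path(cfg$data_dir, "molecules.xyz"))
  en <- read_energy_table(file.path(cfg$data_dir, "energies.csv"))
  mol_ids <- vapply(mols, function(m) m$id, "")
  ecr <- en[en$kind == "crystal", ]
  lapply(crystals, function(cr) {
    my <- en[en$kind == "molecule" & en$parent_id == cr$id, ]
    if (nrow(my) == 0) {
      stop("no molecules listed for crystal ", cr$id, call. = FALSE)
    }
    gm <- mols[match(my$id, mol_ids)]
    Ec <- ecr$E_kJ_per_mol[match(cr$id, ecr$id)]
    assemble_crystal_record(cr, gm, Ec, my$E_kJ_per_mol)
  })
}

#' Compute and store descriptors for a dataset (both phases + remnant)
#'
#' Reads the exchange layout in `cfg$data_dir`, pairs every crystal with
#' its gas-phase molecules, computes solid, gas and remnant descriptors,
#' and writes the collection matrices (`collections_<space>.csv`) plus
#' per-crystal per-atom remnant rows (`remnant_atoms/<id>.csv`) under the
#' run directory.  If the step already completed with the same descriptor
#' configuration hash, the stored outputs are reused.
#'
#' @param cfg A [run_config()].
#' @return The run directory, invisibly.
#' @export
run_featurize <- function(cfg) {
  scfg <- soap_config_from(cfg)
  man_path <- file.path(cfg$run_dir, "manifest.json")
  if (file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    done <- man$steps$featurize$config_hash
    if (identical(done, scfg$config_hash)) {
      message("featurize: outputs up to date (hash ", substr(done, 1, 8), ")")
      return(invisible(cfg$run_dir))
    }
  }
  records <- load_dataset_records(cfg)
  dir.create(file.path(cfg$run_dir, "remnant_atoms"),
    showWarnings = FALSE, recursive = TRUE
  )
  rows <- list()
  for (r in records) {
    ds_s <- compute_descriptors(r$crystal, scfg)
    ds_g <- lapply(r$molecules, function(m) compute_descriptors(m$gas_structure, scfg))
    rem <- remnant_descriptor(r, ds_s, ds_g)
    x_s <- average_descriptor(ds_s)
    gas_rows <- do.call(rbind, lapply(seq_along(ds_g), function(k) ds_g[[k]]$X))
    x_g <- colMeans(gas_rows) # n_m-weighted molecular average
    rows[[r$crystal$id]] <- list(
      s = x_s$x, g = x_g, remnant = rem$collection$x,
      concat = c(x_s$x, x_g),
      gas_per_molecule = lapply(ds_g, function(d) colMeans(d$X))
    )
    utils::write.table(
      rem$per_atom,
      file.path(cfg$run_dir, "remnant_atoms", paste0(r$crystal$id, ".csv")),
      sep = ",", row.names = FALSE, col.names = FALSE
    )
  }
  ids <- names(rows)
  for (space in c("s", "g", "remnant", "concat")) {
    M <- do.call(rbind, lapply(rows, `[[`, space))
    utils::write.table(
      data.frame(id = ids, M, check.names = FALSE),
      file.path(cfg$run_dir, paste0("collections_", space, ".csv")),
      sep = ",", row.names = FALSE
    )
  }
  # per-molecule gas averages (for the molecular-energy model)
  gm <- purrr::map_dfr(names(rows), function(id) {
    g <- rows[[id]]$gas_per_molecule
    tibble::tibble(
      crystal_id = id, molecule = seq_along(g),
      as.data.frame(do.call(rbind, g))
    )
  })
  readr::write_csv(gm, file.path(cfg$run_dir, "collections_g_molecules.csv"))
  readr::write_csv(
    dplyr::select(energy_view(records), -"n_m", -"e_m"),
    file.path(cfg$run_dir, "energies_view.csv")
  )
  update_manifest(cfg, "featurize", list(
    config_hash = scfg$config_hash, n_crystals = length(records)
  ))
  invisible(cfg$run_dir)
}

read_collection_matrix <- function(cfg, space) {
  tab <- utils::read.csv(
    file.path(cfg$run_dir, paste0("collections_", space, ".csv")),
    check.names = FALSE
  )
  X <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(X) <- NULL
  list(ids = tab[[1]], X = X)
}

#' Fit the lattice-energy model family and report errors
#'
#' Fits, on a farthest-point-sampled (or random) training split: the
#' composition-baselined per-atom crystal-energy model (solid features),
#' the molecular-energy model (gas features, per molecule), their
#' combination, and the direct lattice-energy models on each requested
#' feature space.  Writes `metrics.csv` (RMSE/MAE in kJ per mol of atoms
#' with the test-set target SD alongside) and the remnant model as
#' `model_remnant.json`.
#'
#' @param cfg A [run_config()].
#' @return The metrics tibble, invisibly.
#' @export
run_train <- function(cfg) {
  records <- load_dataset_records(cfg)
  ev <- energy_view(records)
  scfg <- soap_config_from(cfg)
  spaces <- cfg$model$feature_spaces
  coll <- lapply(
    stats::setNames(
      c("s", "g", "remnant", "concat"),
      c("s", "g", "remnant", "concat")
    ),
    function(sp) read_collection_matrix(cfg, sp)
  )
  ids <- coll$s$ids
  stopifnot(identical(ids, ev$id))
  n <- length(ids)
  n_train <- max(2L, round(cfg$model$train_fraction * n))
  if (cfg$model$split == "fps") {
    train <- fps_select(coll$remnant$X, n_train, start = 1L)
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(cfg$seed)
    train <- sample(n, n_train)
  }
  test <- setdiff(seq_len(n), train)

  crystals <- lapply(records, function(r) r$crystal)
  elements_seen <- sort(unique(unlist(lapply(crystals, species))))
  base_c <- fit_baseline(crystals[train], ev$e_c[train],
    elements = elements_seen, allow_rank_deficient = TRUE
  )
  ec_base <- ev$e_c - predict(base_c, crystals)
  metrics <- list()
  models <- list()

  # crystal-energy model on solid features
  m_ec <- fit_energy_model(coll$s$X[train, ], ec_base[train], "s",
    folds = cfg$model$folds
  )
  metrics$e_c <- evaluate_model(
    predict(m_ec, coll$s$X[test, ]), ec_base[test]
  ) |> dplyr::mutate(target = "e_c", feature_space = "s")

  # molecular-energy model on per-molecule gas features
  gm <- readr::read_csv(
    file.path(cfg$run_dir, "collections_g_molecules.csv"),
    show_col_types = FALSE
  )
  mol_feats <- as.matrix(gm[, -(1:2)])
  mol_struct <- unlist(lapply(records, function(r) {
    lapply(r$molecules, function(m) m$gas_structure)
  }), recursive = FALSE)
  mol_e <- unlist(lapply(records, function(r) {
    vapply(r$molecules, function(m) m$E / n_atoms(m$gas_structure), numeric(1))
  }))
  mol_parent <- match(gm$crystal_id, ids)
  mol_train <- which(mol_parent %in% train)
  mol_test <- which(mol_parent %in% test)
  base_m <- fit_baseline(mol_struct[mol_train], mol_e[mol_train],
    elements = elements_seen, allow_rank_deficient = TRUE
  )
  em_base <- mol_e - predict(base_m, mol_struct)
  m_em <- fit_energy_model(mol_feats[mol_train, ], em_base[mol_train], "g",
    folds = cfg$model$folds
  )
  metrics$e_m <- evaluate_model(
    predict(m_em, mol_feats[mol_test, ]), em_base[mol_test]
  ) |> dplyr::mutate(target = "e_m", feature_space = "g")

  # combined two-model lattice-energy estimate; the molecular model is
  # evaluated on the atom-count-weighted molecular average (= the gas
  # collection descriptor).  Both models predict baselined targets; since
  # crystal and molecules share one composition, a SHARED baseline would
  # cancel exactly -- with independently fitted baselines the residual
  # difference of the two baseline predictions is added back.
  delta_hat <- predict(m_ec, coll$s$X[test, ]) - predict(m_em, coll$g$X[test, ]) +
    (predict(base_c, crystals[test]) - predict(base_m, crystals[test]))
  metrics$combined <- evaluate_model(
    delta_hat, ev$delta_c[test]
  ) |> dplyr::mutate(target = "delta_c", feature_space = "combined")

  # direct lattice-energy models
  for (sp in spaces) {
    m <- fit_energy_model(coll[[sp]]$X[train, ], ev$delta_c[train], sp,
      folds = cfg$model$folds
    )
    models[[sp]] <- m
    metrics[[paste0("delta_", sp)]] <- evaluate_model(
      predict(m, coll[[sp]]$X[test, ]), ev$delta_c[test]
    ) |> dplyr::mutate(target = "delta_c", feature_space = sp)
  }
  tab <- dplyr::bind_rows(metrics) |>
    dplyr::select("target", "feature_space", "rmse", "mae", "sd_truth", "n")
  readr::write_csv(tab, file.path(cfg$run_dir, "metrics.csv"))
  if (!is.null(models$remnant)) {
    write_lattice_model(
      models$remnant, file.path(cfg$run_dir, "model_remnant.json"),
      baseline = base_c, config_hash = scfg$config_hash
    )
  }
  split_tab <- tibble::tibble(
    id = ids, role = ifelse(seq_len(n) %in% train, "train", "test")
  )
  readr::write_csv(split_tab, file.path(cfg$run_dir, "split.csv"))
  update_manifest(cfg, "train", list(
    config_hash = scfg$config_hash,
    split = cfg$model$split, n_train = n_train
  ))
  invisible(tab)
}

#' Per-atom and per-motif contribution tables
#'
#' Loads the stored remnant per-atom descriptors and the remnant model,
#' computes raw and Gaussian-filtered atomic contributions (asserting the
#' conservation contract per structure), matches the motif table on every
#' extracted molecule, evaluates motif contributions and their
#' distribution summaries, and detects hydrogen bonds.  Writes
#' `atom_contributions.csv`, `motif_instances.csv`,
#' `motif_contributions.csv`, `motif_summary.csv` and `hbonds.csv`.
#'
#' @param cfg A [run_config()].
#' @return Tibble of motif contributions, invisibly.
#' @export
run_attribute <- function(cfg) {
  records <- load_dataset_records(cfg)
  stored <- read_lattice_model(file.path(cfg$run_dir, "model_remnant.json"))
  scfg <- soap_config_from(cfg)
  if (!is.null(stored$config_hash) &&
    !identical(stored$config_hash, scfg$config_hash)) {
    stop("model/descriptor configuration hash mismatch", call. = FALSE)
  }
  fcfg <- do.call(filter_config, cfg$filter)
  patterns <- motif_patterns(cfg$motifs$table, min_count = cfg$motifs$min_count)

  atts <- list()
  inst_rows <- list()
  hb_rows <- list()
  for (r in records) {
    Xr <- as.matrix(utils::read.table(
      file.path(cfg$run_dir, "remnant_atoms", paste0(r$crystal$id, ".csv")),
      sep = ","
    ))
    dimnames(Xr) <- NULL
    att <- atomic_contributions(Xr, stored$model, r$crystal) |>
      gaussian_filter(r$crystal, fcfg)
    stopifnot(abs(sum(att$atoms$delta_filtered) - sum(att$atoms$delta)) <=
      1e-10 * max(1, abs(sum(att$atoms$delta))))
    atts[[r$crystal$id]] <- att
    graphs <- lapply(seq_along(r$molecules), function(k) {
      m <- r$molecules[[k]]$gas_structure
      m$id <- sprintf("%s_mol%d", r$crystal$id, k)
      perceive_molecular_graph(m)
    })
    inst <- match_motifs(graphs, patterns)
    if (nrow(inst) > 0) {
      mol_k <- as.integer(sub(".*_mol", "", inst$molecule_id))
      inst$structure_id <- r$crystal$id
      inst$crystal_atoms <- purrr::map2(
        inst$atoms, mol_k,
        function(a, k) r$molecules[[k]]$index_map[a]
      )
      inst$epsilon_motif <- vapply(
        inst$crystal_atoms,
        function(a) motif_contribution(att, a), numeric(1)
      )
      inst_rows[[r$crystal$id]] <- inst
    }
    hb <- detect_hbonds(r$crystal)
    if (nrow(hb) > 0) {
      hb$structure_id <- r$crystal$id
      hb_rows[[r$crystal$id]] <- hb
    }
  }
  write_attribution(atts, file.path(cfg$run_dir, "atom_contributions.csv"))
  inst <- dplyr::bind_rows(inst_rows)
  if (nrow(inst) > 0) {
    flat <- inst |>
      dplyr::mutate(
        instance_id = paste0(
          .data$structure_id, ":", .data$molecule_id, ":",
          .data$pattern, ":",
          vapply(.data$atoms, function(a) paste(a, collapse = "-"), "")
        ),
        atoms = vapply(.data$atoms, function(a) paste(a, collapse = " "), ""),
        crystal_atoms = vapply(
          .data$crystal_atoms,
          function(a) paste(a, collapse = " "), ""
        )
      )
    readr::write_csv(flat, file.path(cfg$run_dir, "motif_instances.csv"))
    readr::write_csv(
      flat[, c("instance_id", "pattern", "epsilon_motif")],
      file.path(cfg$run_dir, "motif_contributions.csv")
    )
    summ <- flat |>
      dplyr::group_by(.data$pattern) |>
      dplyr::summarise(
        count = dplyr::n(),
        mean = mean(.data$epsilon_motif),
        sd = stats::sd(.data$epsilon_motif),
        min = min(.data$epsilon_motif),
        max = max(.data$epsilon_motif),
        .groups = "drop"
      ) |>
      dplyr::left_join(
        patterns[, c("name", "min_count")],
        by = c(pattern = "name")
      ) |>
      dplyr::mutate(low_sample = .data$count < .data$min_count)
    readr::write_csv(summ, file.path(cfg$run_dir, "motif_summary.csv"))
  }
  hb <- dplyr::bind_rows(hb_rows)
  readr::write_csv(hb, file.path(cfg$run_dir, "hbonds.csv"))
  update_manifest(cfg, "attribute", list(
    n_motif_instances = nrow(inst), n_hbonds = nrow(hb)
  ))
  invisible(inst)
}

#' PCovR maps of motif environments and similarity queries
#'
#' Builds the motif-averaged remnant feature matrix (mean remnant row over
#' each motif instance's atoms), fits the global PCovR map against the
#' motif contributions, optionally re-fits a dedicated map per motif
#' class, and answers latent-space similarity queries using all retained
#' covariates.  Writes `map_global_map.csv` / `map_global_model.json`
#' (and `map_<class>_*` when `per_class`), plus `similar_motifs.csv` for
#' any queries.
#'
#' @param cfg A [run_config()].
#' @return The global `pcovr_map`, invisibly.
#' @export
run_map <- function(cfg) {
  inst <- readr::read_csv(
    file.path(cfg$run_dir, "motif_instances.csv"),
    show_col_types = FALSE
  )
  if (nrow(inst) < 3) stop("too few motif instances to map", call. = FALSE)
  feats <- t(vapply(seq_len(nrow(inst)), function(r) {
    Xr <- as.matrix(utils::read.table(
      file.path(
        cfg$run_dir, "remnant_atoms",
        paste0(inst$structure_id[r], ".csv")
      ),
      sep = ","
    ))
    idx <- as.integer(strsplit(inst$crystal_atoms[r], " ")[[1]])
    colMeans(Xr[idx, , drop = FALSE])
  }, numeric(ncol(read_collection_matrix(cfg, "remnant")$X))))
  y <- inst$epsilon_motif
  k <- min(cfg$pcovr$k, nrow(feats) - 1)
  model <- fit_pcovr(feats, y, alpha = cfg$pcovr$alpha, k = k)
  pts <- pcovr_map_points(model, feats,
    ids = inst$instance_id, color = y, in_sample = TRUE
  )
  pts$class <- inst$pattern
  write_pcovr(model, pts, file.path(cfg$run_dir, "map_global"))
  if (isTRUE(cfg$pcovr$per_class)) {
    for (cl in unique(inst$pattern)) {
      sel <- inst$pattern == cl
      if (sum(sel) < 3) next
      kc <- min(k, sum(sel) - 1)
      mc <- tryCatch(
        fit_pcovr(feats[sel, , drop = FALSE], y[sel],
          alpha = cfg$pcovr$alpha, k = kc
        ),
        error = function(e) NULL
      )
      if (is.null(mc)) next
      pc <- pcovr_map_points(mc, feats[sel, , drop = FALSE],
        ids = inst$instance_id[sel], color = y[sel]
      )
      pc$class <- cl
      write_pcovr(mc, pc, file.path(cfg$run_dir, paste0("map_", cl)))
    }
  }
  if (!is.null(cfg$pcovr$query)) {
    if (!all(cfg$pcovr$query %in% pts$id)) {
      stop("unknown query id(s) in pcovr$query", call. = FALSE)
    }
    sim <- similar_motifs(pts, cfg$pcovr$query,
      k = min(5L, nrow(pts) - length(cfg$pcovr$query))
    )
    readr::write_csv(sim, file.path(cfg$run_dir, "similar_motifs.csv"))
  }
  update_manifest(cfg, "map", list(alpha = cfg$pcovr$alpha, k = k))
  invisible(pts)
}

#' Generate a synthetic dataset from a config and write it out
#' @param cfg A [run_config()]; `cfg$synth` may hold [synthetic_spec()]
#'   arguments.
#' @return The dataset directory, invisibly.
#' @export
run_synth <- function(cfg) {
  args <- cfg$synth %||% list()
  args$seed <- args$seed %||% cfg$seed
  spec <- do.call(synthetic_spec, args)
  ds <- generate_synthetic(spec)
  write_synthetic_dataset(ds, cfg$data_dir)
  invisible(cfg$data_dir)
}

#' Read a run configuration from YAML
#' @param path YAML file with any subset of the [run_config()] fields.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config(
    data_dir = y$data_dir %||% stop("config needs data_dir"),
    run_dir = y$run_dir %||% stop("config needs run_dir"),
    descriptor = y$descriptor %||% list(),
    filter = y$filter %||% list(),
    model = y$model %||% list(),
    motifs = y$motifs %||% list(),
    pcovr = y$pcovr %||% list(),
    seed = y$seed %||% 1L
  )
  cfg$synth <- y$synth
  cfg
}
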