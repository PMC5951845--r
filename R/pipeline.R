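#' Configuration of a full analysis run
#'
#' Bundles all inputs of [run_full_analysis()]: where the trees and
#' character matrices live, which characters and dataset variant to analyse,
#' the taxon subsets, the MCMC profile and replicate counts, the seed, and
#' the output directory.
#'
#' @param trees Path to a (multi-)Newick tree file, or a `multiPhylo`.
#' @param matrix_files Named list with paths `all` and/or `effective` to
#'   character-matrix CSVs (or `character_matrix` objects).
#' @param characters Characters to analyse (default all three).
#' @param variant `"all"` or `"effective"` — which matrix feeds the analysis.
#' @param subsets Taxon subsets to run the signal tests on: any of
#'   `"all"`, `"passerines"`.
#' @param mcmc An [mcmc_config()] (its seed is overridden by `seed`).
#' @param n_perm Permutation count for the conventional Mantel tests.
#' @param n_sim Simulation count for the EM-Mantel tests.
#' @param seed Integer seed driving every stage.
#' @param out_dir Output directory (created if needed).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(trees, matrix_files, characters = nest_characters(),
                            variant = c("effective", "all"),
                            subsets = c("all", "passerines"),
                            mcmc = mcmc_config(), n_perm = 999L, n_sim = 999L,
                            seed = 1L, out_dir = tempfile("nestevo_run_")) {
  variant <- match.arg(variant)
  subsets <- match.arg(subsets, several.ok = TRUE)
  characters <- vapply(characters, check_character_name, character(1))
  stopifnot(inherits(mcmc, "mcmc_config"))
  structure(list(trees = trees, matrix_files = matrix_files,
                 characters = unname(characters), variant = variant,
                 subsets = subsets, mcmc = mcmc, n_perm = as.integer(n_perm),
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "analysis_config")
}

load_tree_set <- function(trees) {
  if (inherits(trees, "phylo")) return(as_tree_set(trees))
  if (is.character(trees)) {
    ts <- ape::read.tree(trees)
    if (inherits(ts, "phylo")) ts <- list(ts)
    return(as_tree_set(ts))
  }
  as_tree_set(trees)
}

load_matrix <- function(matrix_files, variant) {
  m <- matrix_files[[variant]]
  if (is.null(m))
    stop_nestevo(sprintf("no '%s' matrix in the configuration", variant),
                 "nestevo_input_error")
  if (inherits(m, "character_matrix")) return(m)
  read_character_matrix(m, variant)
}

#' Run the full nest-character analysis
#'
#' Orchestrates, under one seed: the majority-rule consensus tree;
#' Bayesian Mk ancestral-state reconstruction per character (with ESS and
#' split R-hat diagnostics); the three preset correlated-evolution tests
#' (dependent vs independent models, harmonic-mean Bayes factors,
#' transition-rate directionality); and conventional + EM-Mantel
#' phylogenetic-signal tests per character and taxon subset. All reports are
#' written as JSON/TSV under `config$out_dir` and are byte-identical across
#' reruns with the same configuration and seed (timings go to a separate
#' `run_timings.tsv`).
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  warn_log <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(errorCondition(sprintf("[stage %s] %s", name, conditionMessage(e)),
                            class = c(paste0("nestevo_stage_", name),
                                      "nestevo_stage_error", "nestevo_error")))
      }),
      warning = function(w) {
        warn_log <<- c(warn_log, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  paths <- character(0)
  write_report <- function(x, file) {
    p <- file.path(config$out_dir, file)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <<- c(paths, p)
    p
  }

  inputs <- stage("load", {
    list(trees = load_tree_set(config$trees),
         matrix = load_matrix(config$matrix_files, config$variant))
  })
  trees <- inputs$trees
  cmat <- inputs$matrix

  cons <- stage("consensus", consensus_tree(trees))
  cons_path <- file.path(config$out_dir, "consensus_tree.nwk")
  ape::write.tree(cons, cons_path)
  paths <- c(paths, cons_path)

  passerine_tips <- cmat$records$family[cmat$records$passerine]

  asr_results <- list()
  fitted <- list()
  for (ci in seq_along(config$characters)) {
    ch <- config$characters[ci]
    res <- stage(paste0("asr_", ch), {
      sets <- state_sets(cmat, ch)
      model <- mk_model(nest_state_vocabulary()[[ch]], "ER")
      cfg <- config$mcmc
      cfg$seed <- derive_seed(config$seed, 10L + ci)
      trace <- mcmc_sample(trees, sets, model, cfg)
      diag <- list(
        ess = tryCatch(effective_sample_size(trace), error = function(e) NA_real_),
        rhat = tryCatch(unname(convergence_diagnostic(trace)["rate"]),
                        error = function(e) NA_real_),
        acceptance = trace$acceptance)
      clades <- NULL
      if (length(passerine_tips) >= 2L) {
        cons_ntip <- length(cons$tip.label)
        clades <- lapply(cons_ntip + seq_len(cons$Nnode),
                         function(nd) clade_tips(cons, nd))
        names(clades) <- ifelse(cons_ntip + seq_len(cons$Nnode) == cons_ntip + 1L,
                                "root", paste0("node_", cons_ntip + seq_len(cons$Nnode)))
        clades$passerines <- passerine_tips
      }
      asr <- reconstruct_ancestral_states(trace, trees, sets, clades = clades)
      list(trace = trace, asr = asr, diagnostics = diag,
           post_mean_rate = mean(trace$samples$rate),
           map_root = map_root_state(asr))
    })
    asr_results[[ch]] <- res
    fitted[[ch]] <- res
    p <- file.path(config$out_dir, sprintf("asr_%s.tsv", ch))
    write_asr_tsv(res$asr, p)
    paths <- c(paths, p)
  }

  coevo <- list()
  presets <- nest_recode_presets()
  for (pi in seq_along(presets)) {
    pr <- presets[[pi]]
    res <- stage(paste0("coevolve_", pr$name), {
      a <- do.call(binary_recode, c(list(matrix = cmat), pr$a))
      b <- do.call(binary_recode, c(list(matrix = cmat), pr$b))
      pair <- binary_pair(a, b, pr$a$derived_label, pr$b$derived_label)
      cfg <- config$mcmc
      cfg$seed <- derive_seed(config$seed, 20L + pi)
      dep <- fit_pagel_model(trees, pair, "dependent", cfg)
      cfg$seed <- derive_seed(config$seed, 30L + pi)
      ind <- fit_pagel_model(trees, pair, "independent", cfg)
      bf <- bayes_factor(dep, ind)
      asym <- transition_asymmetry(dep)
      list(preset = pr$name,
           bf = bf$bf, support_call = bf$support_call,
           lnml_dependent = bf$lnml_dep, lnml_independent = bf$lnml_indep,
           dependent_rates = as.list(colMeans(dep$samples[dep$rate_names])),
           independent_rates = as.list(colMeans(ind$samples[ind$rate_names])),
           orderings = as.list(asym$orderings),
           acceptance_dependent = dep$acceptance,
           acceptance_independent = ind$acceptance)
    })
    coevo[[pr$name]] <- res
    write_report(res, sprintf("coevolution_%s.json", pr$name))
  }

  mantel_results <- list()
  for (ch in config$characters) {
    for (ss in config$subsets) {
      key <- paste(ch, ss, sep = ".")
      res <- stage(paste0("signal_", ch, "_", ss), {
        sets <- state_sets(cmat, ch, drop_missing = TRUE)
        keep <- names(sets)
        if (ss == "passerines") keep <- intersect(keep, passerine_tips)
        if (length(keep) < 4L) {
          warning(sprintf("subset '%s' has fewer than 4 taxa with data; skipped", ss))
          NULL
        } else {
        tr <- ape::keep.tip(cons, keep)
        D_phylo <- patristic_distances(tr)
        D_trait <- bray_curtis_matrix(sets[keep])[rownames(D_phylo), rownames(D_phylo)]
        conv <- conventional_mantel(D_phylo, D_trait, config$n_perm,
                                    seed = derive_seed(config$seed, 40L + length(mantel_results)))
        fm <- mk_model(nest_state_vocabulary()[[ch]], "ER",
                       rates = fitted[[ch]]$post_mean_rate)
        em <- em_mantel(tr, sets[keep], fm, fitted[[ch]]$map_root, config$n_sim,
                        seed = derive_seed(config$seed, 50L + length(mantel_results)))
        list(conventional = conv, em = em)
        }
      })
      if (is.null(res)) next
      mantel_results[[key]] <- res
      write_report(list(character = ch, subset = ss,
                        r = res$conventional$empirical_r,
                        p_perm = res$conventional$p_two,
                        p_em = res$em$p_two,
                        null_mean_perm = mean(res$conventional$null_r),
                        null_mean_em = mean(res$em$null_r),
                        n_perm = res$conventional$n_replicates,
                        n_sim = res$em$n_replicates,
                        n_dropped_em = res$em$n_dropped),
                   sprintf("mantel_%s_%s.json", ch, gsub("/", "-", ss)))
    }
  }

  report <- signal_report(mantel_results)
  log <- list(
    seed = config$seed,
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    variant = config$variant,
    characters = config$characters,
    subsets = config$subsets,
    n_trees = length(trees),
    n_families = nrow(cmat$records),
    asr_diagnostics = lapply(asr_results, function(r)
      c(r$diagnostics, list(post_mean_rate = r$post_mean_rate,
                            map_root = r$map_root))),
    warnings = warn_log)
  write_report(log, "run_log.json")
  tp <- file.path(config$out_dir, "run_timings.tsv")
  write.table(data.frame(stage = names(timings),
                         seconds = round(unlist(timings), 3)),
              tp, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(consensus = cons, asr = asr_results, coevolution = coevo,
                 mantel = mantel_results, signal_table = report,
                 log = log, paths = c(paths, tp), out_dir = config$out_dir))
}

#' Generate a synthetic demonstration dataset
#'
#' Emulates the shape of the real analysis inputs: a 242-family tree set
#' with topological and branch-length uncertainty, and character matrices
#' (`all` and `effective` variants) whose state-frequency profile mimics the
#' reported avian one. Structure and site are simulated on the base tree under
#' equal-rates Mk models rooted at scrape/ground, with the rate solved from
#' the closed-form transition probability so the root state is retained by
#' roughly one fifth of the families; attachment is allocated by exact
#' counts (80% of characterizable families exclusively basal, 10% basal plus
#' another approach, 10% non-basal only), with non-basal states placed inside
#' the passerine clade. A few families are flagged missing (brood parasites,
#' a mound builder, no data). A species-level table (10,978 species across
#' the 242 families) accompanies the matrix for the effective-state rule.
#'
#' @param out_dir Writable output directory.
#' @param seed Integer seed.
#' @param n_tips Number of families (default 242).
#' @param n_trees Size of the emulated tree set (default 25).
#' @return Invisibly, a list with the generated objects and file paths
#'   (`trees`, `matrix_files`, `species_table`, `config`).
#' @export
make_demo_dataset <- function(out_dir, seed = 1L, n_tips = 242L, n_trees = 25L) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_nestevo(sprintf("cannot create output directory '%s'", out_dir),
                 "nestevo_io_error")
  labels <- sprintf("Fam%03d", seq_len(n_tips))
  base <- simulate_yule_tree(n_tips, 1, seed = derive_seed(seed, 1),
                             tip_labels = labels)
  trees <- perturb_tree_set(base, n_trees, perturb_strength = 2L,
                            bl_jitter = 0.1, seed = derive_seed(seed, 2))
  height <- max(ape::node.depth.edgelength(base))
  vocab <- nest_state_vocabulary()

  # passerine flag = the clade whose size is closest to 45% of families
  ntip <- length(base$tip.label)
  nodes <- ntip + seq_len(base$Nnode)
  sizes <- vapply(nodes, function(nd) length(clade_tips(base, nd)), numeric(1))
  pnode <- nodes[which.min(abs(sizes - 0.45 * ntip))]
  passerines <- clade_tips(base, pnode)

  # ER rate such that P(tip state = root state) hits `target` at the tree
  # height: solve 1/k + (k-1)/k exp(-k q h) = target
  rate_for_retention <- function(k, target, h)
    -log((target - 1 / k) * k / (k - 1)) / (k * h)

  q_structure <- rate_for_retention(7, 0.20, height)
  q_site <- rate_for_retention(7, 0.20, height)
  m_structure <- mk_model(vocab$structure, "ER", q_structure)
  m_site <- mk_model(vocab$site, "ER", q_site)
  structure_tips <- simulate_discrete_trait(base, m_structure, "scrape",
                                            seed = derive_seed(seed, 3))
  site_tips <- simulate_discrete_trait(base, m_site, "ground",
                                       seed = derive_seed(seed, 4))
  structure_sets <- simulate_polymorphic_tipset(structure_tips, m_structure,
                                                poly_prob = 0.15,
                                                seed = derive_seed(seed, 5))
  site_sets <- simulate_polymorphic_tipset(site_tips, m_site, poly_prob = 0.15,
                                           seed = derive_seed(seed, 6))

  # families whose nests cannot be characterized
  missing_fams <- with_seed(derive_seed(seed, 7),
                            sample(labels, 6L))
  missing_reason <- setNames(rep("none", n_tips), labels)
  missing_reason[missing_fams] <- c("brood_parasite", "brood_parasite",
                                    "brood_parasite", "mound_builder",
                                    "no_data", "no_data")

  # attachment: exact-count allocation over characterizable families
  attach_sets <- with_seed(derive_seed(seed, 8), {
    eff_fams <- setdiff(labels, missing_fams)
    n_eff <- length(eff_fams)
    n_excl <- round(0.80 * n_eff)
    n_mixed <- round(0.10 * n_eff)
    n_nonbasal <- n_eff - n_excl - n_mixed
    other <- setdiff(vocab$attachment, "basal")
    pass_eff <- intersect(passerines, eff_fams)
    nonpass_eff <- setdiff(eff_fams, pass_eff)
    # non-basal and mixed records live (mostly) inside the passerine clade
    pool <- c(sample(pass_eff), sample(nonpass_eff))
    nonbasal_fams <- pool[seq_len(n_nonbasal)]
    mixed_fams <- pool[n_nonbasal + seq_len(n_mixed)]
    sets <- setNames(rep(list("basal"), n_eff), eff_fams)
    for (f in nonbasal_fams) sets[[f]] <- other[sample.int(3L, 1L)]
    for (f in mixed_fams) sets[[f]] <- c("basal", other[sample.int(3L, 1L)])
    sets
  })

  blank_missing <- function(sets) {
    out <- setNames(vector("list", n_tips), labels)
    for (f in labels)
      out[[f]] <- if (f %in% missing_fams) character(0)
                  else unname(sets[[f]]) %||% character(0)
    out
  }
  eff_cols <- list(structure = blank_missing(structure_sets),
                   site = blank_missing(site_sets),
                   attachment = blank_missing(attach_sets))

  # the "all" variant adds a rare extra state to ~12% of characterizable
  # families per character (a state mentioned for few species, below the
  # effective threshold)
  all_cols <- with_seed(derive_seed(seed, 9), {
    lapply(nest_characters(), function(ch) {
      col <- eff_cols[[ch]]
      for (f in setdiff(labels, missing_fams)) {
        if (runif(1) < 0.12) {
          extra <- setdiff(vocab[[ch]], col[[f]])
          if (length(extra)) col[[f]] <- c(col[[f]], extra[sample.int(length(extra), 1L)])
        }
      }
      col
    }) |> setNames(nest_characters())
  })

  build_matrix <- function(cols, variant) {
    rec <- data.frame(family = labels,
                      passerine = labels %in% passerines,
                      missing_reason = unname(missing_reason),
                      stringsAsFactors = FALSE)
    rec$structure <- cols$structure
    rec$site <- cols$site
    rec$attachment <- cols$attachment
    character_matrix(rec, variant)
  }
  m_eff <- build_matrix(eff_cols, "effective")
  m_all <- build_matrix(all_cols, "all")

  species_table <- make_demo_species_table(m_all, seed = derive_seed(seed, 10))

  tree_path <- file.path(out_dir, "trees.nwk")
  base_path <- file.path(out_dir, "base_tree.nwk")
  eff_path <- file.path(out_dir, "matrix_effective.csv")
  all_path <- file.path(out_dir, "matrix_all.csv")
  sp_path <- file.path(out_dir, "species_table.csv")
  ape::write.tree(trees, tree_path)
  ape::write.tree(base, base_path)
  write_character_matrix(m_eff, eff_path)
  write_character_matrix(m_all, all_path)
  sp_out <- species_table
  sp_out$states <- vapply(sp_out$states, paste, character(1), collapse = "|")
  write.csv(sp_out, sp_path, row.names = FALSE)
  cfg <- analysis_config(trees = tree_path,
                         matrix_files = list(all = all_path, effective = eff_path),
                         seed = seed, out_dir = file.path(out_dir, "results"))
  invisible(list(base_tree = base, trees = trees,
                 matrix_effective = m_eff, matrix_all = m_all,
                 species_table = species_table, passerines = passerines,
                 simulated = list(structure = structure_tips, site = site_tips,
                                  rates = c(structure = q_structure,
                                            site = q_site),
                                  roots = c(structure = "scrape",
                                            site = "ground")),
                 paths = list(trees = tree_path, base_tree = base_path,
                              matrix_files = list(all = all_path,
                                                  effective = eff_path),
                              species_table = sp_path),
                 config = cfg))
}

#' Synthetic species-level table for the effective-state rule
#'
#' Allocates a fixed total number of species (default 10,978, so the mean
#' per family is 45) across the families of a character matrix with skewed
#' (gamma-weighted, largest-remainder) family sizes, assigns each species to
#' a genus, and draws each species' structure states so that the family's
#' recorded states dominate.
#'
#' @param matrix A `character_matrix` providing the family list and state
#'   sets.
#' @param total_species Total species count to allocate.
#' @param seed Optional integer seed.
#' @return Data frame with columns `family`, `genus`, `species`, `states`
#'   (list-column).
#' @export
make_demo_species_table <- function(matrix, total_species = 10978L, seed = NULL) {
  stopifnot(inherits(matrix, "character_matrix"))
  rec <- matrix$records
  nf <- nrow(rec)
  with_seed(seed, {
    w <- rgamma(nf, shape = 0.6)
    raw <- total_species * w / sum(w)
    sizes <- pmax(1L, floor(raw))
    rem <- total_species - sum(sizes)
    if (rem > 0) {
      extra <- order(raw - floor(raw), decreasing = TRUE)
      sizes[extra[seq_len(rem)]] <- sizes[extra[seq_len(rem)]] + 1L
    } else if (rem < 0) {
      shrink <- order(sizes, decreasing = TRUE)
      i <- 1L
      while (rem < 0) {
        if (sizes[shrink[i]] > 1L) { sizes[shrink[i]] <- sizes[shrink[i]] - 1L
                                     rem <- rem + 1L }
        i <- if (i == nf) 1L else i + 1L
      }
    }
    rows <- lapply(seq_len(nf), function(i) {
      n <- sizes[i]
      fam <- rec$family[i]
      n_gen <- max(1L, round(n / 8))
      genus <- sprintf("%s_g%02d", fam, sample.int(n_gen, n, replace = TRUE))
      fam_states <- rec$structure[[i]]
      states <- if (!length(fam_states)) replicate(n, character(0), simplify = FALSE)
                else lapply(seq_len(n), function(j)
                  fam_states[sample.int(length(fam_states), 1L)])
      data.frame(family = fam, genus = genus,
                 species = sprintf("%s_sp%04d", fam, seq_len(n)),
                 stringsAsFactors = FALSE) |>
        (\(df) { df$states <- states; df })()
    })
    do.call(rbind, rows)
  })
}
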