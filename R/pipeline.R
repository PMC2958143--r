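## End-to-end orchestration: synthesize (or load) data, mine markers,
## build and describe the supermatrix, run MP / ML / Bayesian inference
## with their support diagnostics, reconstruct ancestral states, and
## bundle the artifacts with a reproducibility manifest.

## FNV-1a 32-bit hash (pure R, split multiply to stay in double range)
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b)) +
      (if (h >= 2^31) 2^31 else 0)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536) * 65536 + (h0 * 16777619) %% 2^32
    h <- h %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## derive a stage seed from the global seed and the stage name
stage_seed <- function(seed, stage) {
  (seed + strtoi(substr(fnv1a(stage), 1, 7), 16L)) %% 2147483647L
}

default_config <- function() {
  list(
    seed = 1L,
    outdir = tempfile("phylopipe_run_"),
    synthetic = list(n_genes = 20, length_scale = 0.25,
                     missing_fraction = 0.1, n_traits = 4,
                     trait_rate = 2, proteome = list(n_single = 12,
                                                     n_pairs = 4)),
    stages = list(mine = TRUE, describe = TRUE, mp = TRUE, ml = TRUE,
                  bayes = TRUE, asr = TRUE),
    mp = list(bootstrap_reps = 30, vlb_sizes = NULL, bremer = FALSE,
              n_addition_replicates = 3),
    ml = list(family = "HKY", aic = FALSE, clock = TRUE,
              calibration_age = 1.81),
    bayes = list(n_gens = 3000, sample_every = 25, burn_in_frac = 0.25,
                 scheme = "exon_intron", compare_schemes = FALSE),
    asr = list(mode = "pruning")
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]]))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages run in dependency order: synthetic-data generation (or input
#' loading), marker mining on the fixture proteome, supermatrix
#' assembly and description, maximum parsimony with bootstrap (and
#' optionally variable-length bootstrap and Bremer support), maximum
#' likelihood with clock test and dating, Bayesian MCMC with consensus
#' and (optionally) partition-strategy Bayes factors, and
#' ancestral-state reconstruction. A stage failure aborts with prior
#' artifacts preserved on disk.
#'
#' @param config named list (see `phylopipe:::default_config()` for the
#'   shape) or path to a YAML file; missing entries take defaults. One
#'   global seed fans out deterministically to per-stage seeds.
#' @return invisible `report_bundle` list: per-stage results plus
#'   `manifest` (config, stage seeds, config hash, package version).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(names(config), names(default_config()))
  if (length(bad)) stop("invalid config keys: ", paste(bad, collapse = ", "))
  cfg <- merge_config(default_config(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- vapply(c("synth", "mine", "mp", "ml", "bayes", "asr"),
                  function(s) stage_seed(cfg$seed, s), 0)
  bundle <- list()
  logf <- file.path(cfg$outdir, "run.log")
  note <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ..., "\n",
                            file = logf, append = TRUE)

  ## -- synthesize ---------------------------------------------------------
  note("stage synth")
  sc <- cfg$synthetic
  config_obj <- preset_config(n_genes = sc$n_genes,
                              length_scale = sc$length_scale,
                              seed = seeds[["synth"]],
                              missing_fraction = sc$missing_fraction)
  genes <- simulate_alignments(config_obj)
  truth <- attr(genes, "truth")
  ape::write.tree(truth$tree, file.path(cfg$outdir, "true_tree.nwk"))
  tree_rooted <- ape::root(truth$tree, "outgroup", resolve.root = TRUE)
  ## traits evolve on the tree rescaled to unit root-to-tip depth, so the
  ## trait rate reads as expected changes per root-to-tip path
  tree_traits <- tree_rooted
  tree_traits$edge.length <- tree_traits$edge.length /
    max(ape::node.depth.edgelength(tree_traits))
  traits <- simulate_traits(tree_traits, n_chars = sc$n_traits,
                            state_counts = c(2, 2, 3, 3),
                            rate = sc$trait_rate,
                            seed = seeds[["synth"]] + 1)
  proteome <- simulate_genome(sc$proteome$n_single, sc$proteome$n_pairs,
                              similarity_targets = 75,
                              seed = seeds[["synth"]] + 2)
  bundle$truth <- truth
  bundle$traits <- traits

  ## -- mine ---------------------------------------------------------------
  if (isTRUE(cfg$stages$mine)) {
    note("stage mine")
    hits <- all_vs_all_search(proteome)
    filt <- filter_single_copy(hits)
    write_tsv(as.data.frame(hits), file.path(cfg$outdir, "hit_table.tsv"))
    writeLines(filt$retained, file.path(cfg$outdir, "single_copy.txt"))
    bundle$mining <- list(hits = hits, filter = filt,
                          truth = proteome$truth)
  }

  ## -- supermatrix + description -----------------------------------------
  note("stage describe")
  sm <- concatenate(genes)
  write_supermatrix_nexus(sm, file.path(cfg$outdir, "supermatrix.nex"))
  bundle$supermatrix <- sm
  if (isTRUE(cfg$stages$describe)) {
    sc_cls <- site_classes(sm)
    report <- per_gene_report(genes)
    dm <- distance_matrix(sm)
    write_tsv(report, file.path(cfg$outdir, "per_gene_report.tsv"))
    write_tsv(as.data.frame(dm$matrix), file.path(cfg$outdir, "k2p.tsv"))
    bundle$describe <- list(
      site_classes = sc_cls$counts, percent = sc_cls$percent,
      base_composition = base_composition(sm),
      chi_square = chi_square_homogeneity(sm, scheme = "exon_intron"),
      titv = ti_tv_ratio(sm), k2p = dm, per_gene = report)
  }

  ## -- maximum parsimony --------------------------------------------------
  mp_res <- NULL
  if (isTRUE(cfg$stages$mp)) {
    note("stage mp")
    mp_res <- mp_search(sm$matrix, seed = seeds[["mp"]],
                        n_addition_replicates = cfg$mp$n_addition_replicates)
    boot <- bootstrap_support(sm$matrix, n_reps = cfg$mp$bootstrap_reps,
                              seed = seeds[["mp"]] + 1,
                              reference = mp_res$trees[[1]])
    ape::write.tree(mp_res$trees[[1]], file.path(cfg$outdir, "mp_tree.nwk"))
    write_tsv(boot$table, file.path(cfg$outdir, "mp_bootstrap.tsv"))
    bundle$mp <- list(search = mp_res, bootstrap = boot)
    if (!is.null(cfg$mp$vlb_sizes)) {
      vlb <- variable_length_bootstrap(sm$matrix, sizes = cfg$mp$vlb_sizes,
                                       n_reps = cfg$mp$bootstrap_reps,
                                       seed = seeds[["mp"]] + 2,
                                       reference = mp_res$trees[[1]])
      write_tsv(vlb, file.path(cfg$outdir, "vlb_curve.tsv"))
      bundle$mp$vlb <- vlb
    }
    if (isTRUE(cfg$mp$bremer)) {
      part <- rep(sm$genes$id, sm$genes$end - sm$genes$start + 1)
      pbs <- bremer_support(sm$matrix, mp_res$trees[[1]], part = part,
                            seed = seeds[["mp"]] + 3)
      write_tsv(pbs, file.path(cfg$outdir, "bremer_pbs.tsv"))
      bundle$mp$bremer <- pbs
    }
  }

  ## -- maximum likelihood -------------------------------------------------
  if (isTRUE(cfg$stages$ml)) {
    note("stage ml")
    model <- subst_model(cfg$ml$family)
    if (isTRUE(cfg$ml$aic)) {
      aic <- model_select_aic(sm$matrix,
                              if (!is.null(mp_res)) mp_res$trees[[1]]
                              else ape::unroot(truth$tree))
      write_tsv(aic, file.path(cfg$outdir, "model_selection.tsv"))
      bundle$ml$aic <- aic
      best <- aic$model[1]
      fam <- sub("\\+.*$", "", best)
      model <- subst_model(fam,
                           p_inv = if (grepl("\\+I", best)) 0.1 else 0,
                           gamma_shape = if (grepl("\\+G", best)) 0.5 else NULL)
    }
    ml <- ml_tree_search(sm$matrix, model, seed = seeds[["ml"]])
    ape::write.tree(ml$tree, file.path(cfg$outdir, "ml_tree.nwk"))
    bundle$ml$search <- ml
    if (isTRUE(cfg$ml$clock)) {
      out_tax <- "outgroup" %in% rownames(sm$matrix)
      lrt <- clock_lrt(sm$matrix, ml$tree, model,
                       outgroup = if (out_tax) "outgroup" else
                         rownames(sm$matrix)[1])
      bundle$ml$clock <- lrt
      ingroup <- setdiff(rownames(sm$matrix),
                         if (out_tax) "outgroup" else rownames(sm$matrix)[1])
      dated <- date_nodes(lrt$clock_tree, ingroup[1:2],
                          min_age = cfg$ml$calibration_age)
      ape::write.tree(dated$tree, file.path(cfg$outdir, "dated_tree.nwk"))
      bundle$ml$dated <- dated
    }
  }

  ## -- Bayesian -----------------------------------------------------------
  if (isTRUE(cfg$stages$bayes)) {
    note("stage bayes")
    tr <- mcmc_run(sm, scheme = cfg$bayes$scheme,
                   model = subst_model("JC"),
                   n_gens = cfg$bayes$n_gens,
                   sample_every = cfg$bayes$sample_every,
                   seed = seeds[["bayes"]],
                   start_tree = if (!is.null(mp_res)) mp_res$trees[[1]])
    nb <- floor(cfg$bayes$burn_in_frac * length(tr$trees))
    cons <- consensus_with_pp(tr, burn_in = nb)
    ape::write.tree(cons$tree, file.path(cfg$outdir, "bi_consensus.nwk"))
    write_tsv(tr$samples, file.path(cfg$outdir, "mcmc_trace.tsv"))
    bundle$bayes <- list(trace = tr, consensus = cons,
                         harmonic_mean = harmonic_mean_lnL(tr, burn_in = nb))
    if (isTRUE(cfg$bayes$compare_schemes)) {
      cmp <- compare_partition_strategies(
        sm, strategies = c("exon_intron", "single"),
        n_gens = cfg$bayes$n_gens, sample_every = cfg$bayes$sample_every,
        seed = seeds[["bayes"]] + 1,
        start_tree = if (!is.null(mp_res)) mp_res$trees[[1]])
      write_tsv(cmp, file.path(cfg$outdir, "partition_bayes_factors.tsv"))
      bundle$bayes$comparison <- cmp
    }
  }

  ## -- ancestral states ---------------------------------------------------
  if (isTRUE(cfg$stages$asr)) {
    note("stage asr")
    asr <- ancestral_states(tree_traits, traits, mode = cfg$asr$mode,
                            seed = seeds[["asr"]])
    bundle$asr <- asr
  }

  ## -- agreement + manifest ----------------------------------------------
  have <- !vapply(list(bundle$mp, bundle$ml, bundle$bayes), is.null, TRUE)
  if (all(have)) {
    agree <- topology_agreement(
      mp = bundle$mp$search$trees[[1]],
      ml = bundle$ml$search$tree,
      bi = bundle$bayes$consensus$tree,
      mp_bootstrap = bundle$mp$bootstrap$freqs,
      pp = bundle$bayes$consensus$pp)
    write_tsv(agree, file.path(cfg$outdir, "topology_agreement.tsv"))
    bundle$agreement <- agree
  }
  manifest <- list(config = cfg, stage_seeds = as.list(seeds),
                   package_version = as.character(utils::packageVersion("phylopipe")),
                   config_hash = fnv1a(jsonlite::toJSON(
                     cfg[setdiff(names(cfg), "outdir")], auto_unbox = TRUE)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle$manifest <- manifest
  invisible(structure(bundle, class = "report_bundle"))
}

#' Per-split agreement table across MP, ML and Bayesian trees
#'
#' One row per split in the union of the three trees' splits:
#' presence flags plus support values. Bootstrap support below
#' `threshold` is rendered `"-"` (a display convention only, never a
#' filter).
#'
#' @param mp,ml,bi trees (`phylo`) on the same leaf set.
#' @param mp_bootstrap,ml_bootstrap named split->percent vectors.
#' @param pp named split->posterior probability vector.
#' @param threshold display threshold for bootstrap columns.
#' @return data.frame.
#' @export
topology_agreement <- function(mp, ml, bi, mp_bootstrap = NULL,
                               ml_bootstrap = NULL, pp = NULL,
                               threshold = 70) {
  if (!setequal(mp$tip.label, ml$tip.label) ||
      !setequal(mp$tip.label, bi$tip.label)) stop("leaf sets differ")
  s_mp <- tree_splits(mp); s_ml <- tree_splits(ml); s_bi <- tree_splits(bi)
  splits <- union(union(s_mp, s_ml), s_bi)
  fmt <- function(v, key) {
    if (is.null(v) || !key %in% names(v)) return(NA_character_)
    x <- v[[key]]
    if (x < threshold) "-" else sprintf("%.0f", x)
  }
  data.frame(
    split = splits,
    in_mp = splits %in% s_mp, in_ml = splits %in% s_ml,
    in_bi = splits %in% s_bi,
    mp_bootstrap = unname(vapply(splits, fmt, "", v = mp_bootstrap)),
    ml_bootstrap = unname(vapply(splits, fmt, "", v = ml_bootstrap)),
    pp = unname(vapply(splits, function(k)
      if (!is.null(pp) && k %in% names(pp)) sprintf("%.2f", pp[[k]])
      else NA_character_, "")),
    stringsAsFactors = FALSE, row.names = NULL)
}
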