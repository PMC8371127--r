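# End-to-end orchestration: simulate -> rates -> slow-fast (-> dollo ->
# profiles), with a flat key=value config, deterministic outputs and a
# JSON manifest recording config, seed, input checksums and package
# version.

#' Build a pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param stages character subset of
#'   `c("simulate", "rates", "slowfast", "dollo", "profiles")`.
#' @param seed integer seed governing every stochastic stage.
#' @param aln_path,tree_path,traits_path input files; when the
#'   `simulate` stage is active they are generated instead.
#' @param sim a [sim_config()] for the simulate stage.
#' @param step slow-fast step fraction.
#' @param n_bootstrap bootstrap replicates per slow-fast step.
#' @param alpha gamma shape (fitted when `NULL`).
#' @param K rate categories.
#' @param hypotheses list of [hypothesis()] objects for the slow-fast
#'   stage; defaults to the true-tree split containing half the taxa.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, stages = c("simulate", "rates", "slowfast"),
                       seed = 1L, aln_path = NULL, tree_path = NULL,
                       traits_path = NULL, sim = sim_config(seed = seed),
                       step = 0.05, n_bootstrap = 100L, alpha = NULL,
                       K = 4L, hypotheses = NULL) {
  known <- c("simulate", "rates", "slowfast", "dollo", "profiles")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 aln_path = aln_path, tree_path = tree_path,
                 traits_path = traits_path, sim = sim, step = step,
                 n_bootstrap = as.integer(n_bootstrap), alpha = alpha,
                 K = as.integer(K), hypotheses = hypotheses),
            class = "run_config")
}

#' Read a flat key=value pipeline config file
#'
#' Recognised keys: `out_dir`, `stages` (comma-separated), `seed`,
#' `aln_path`, `tree_path`, `traits_path`, `step`, `n_bootstrap`,
#' `alpha`, `K`, and the `sim.*` fields of [sim_config()]
#' (`sim.n_taxa`, `sim.n_sites`, `sim.alpha`, `sim.loss_prob`,
#' `sim.n_traits`, `sim.tree_height`, `sim.birth_rate`).
#'
#' @param path config file; lines `key = value`, `#` comments allowed.
#' @param overrides named list overriding file values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(vapply(kv, `[`, character(1L), 2L),
                   vapply(kv, `[`, character(1L), 1L))
  vals[names(overrides)] <- unlist(overrides)
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  chr <- function(k, d) if (k %in% names(vals)) vals[[k]] else d
  seed <- as.integer(num("seed", 1))
  sim <- sim_config(n_taxa = num("sim.n_taxa", 16), seed = seed,
                    birth_rate = num("sim.birth_rate", 1),
                    tree_height = num("sim.tree_height", 1),
                    alpha = num("sim.alpha", 0.5),
                    n_sites = num("sim.n_sites", 1000),
                    loss_prob = num("sim.loss_prob", 0.1),
                    n_traits = num("sim.n_traits", 200))
  run_config(out_dir = chr("out_dir", "."),
             stages = strsplit(chr("stages", "simulate,rates,slowfast"),
                               ",")[[1L]],
             seed = seed,
             aln_path = chr("aln_path", NULL),
             tree_path = chr("tree_path", NULL),
             traits_path = chr("traits_path", NULL),
             sim = sim, step = num("step", 0.05),
             n_bootstrap = as.integer(num("n_bootstrap", 100)),
             alpha = if ("alpha" %in% names(vals)) num("alpha", NA) else NULL,
             K = as.integer(num("K", 4)))
}

#' Run the pipeline
#'
#' Executes the configured stages in dependency order, writing TSV /
#' Newick / FASTA artifacts plus `manifest.json` into `out_dir`.
#' Reruns with an identical config and seed reproduce byte-identical
#' outputs. A failing stage aborts with an error naming it.
#'
#' @param config a [run_config()].
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inputs <- c(config$aln_path, config$tree_path, config$traits_path)
  missing <- inputs[!vapply(inputs, file.exists, logical(1L))]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  aln <- NULL; tree <- NULL; traits <- NULL; truth <- NULL
  if ("simulate" %in% config$stages) {
    stage("simulate", {
      tree <- simulate_tree(config$sim)
      sim_aln <- simulate_alignment(tree, config$sim)
      aln <- sim_aln$alignment
      sim_tr <- simulate_traits(tree, config$sim)
      traits <- sim_tr$traits
      outputs$tree <- write_tree(tree, file.path(config$out_dir, "true_tree.nwk"))
      outputs$alignment <- write_alignment(
        aln, file.path(config$out_dir, "alignment.fasta"), "fasta")
      outputs$traits <- write_trait_matrix(
        traits, file.path(config$out_dir, "traits.tsv"))
      truth <- data.frame(site = seq_along(sim_aln$site_rates),
                          true_rate = sim_aln$site_rates)
      outputs$true_rates <- file.path(config$out_dir, "true_site_rates.tsv")
      write.table(truth, outputs$true_rates, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  } else {
    if (!is.null(config$tree_path)) tree <- read_tree(config$tree_path)
    if (!is.null(config$aln_path)) aln <- read_alignment(config$aln_path)
    if (!is.null(config$traits_path))
      traits <- read_trait_matrix(config$traits_path)
  }

  profile <- NULL
  if ("rates" %in% config$stages) {
    stage("rates", {
      if (is.null(aln) || is.null(tree))
        stop("alignment and tree required")
      profile <- posterior_mean_rates(tree, aln, alpha = config$alpha,
                                      K = config$K)
      outputs$rates <- write_site_rates(
        profile, file.path(config$out_dir, "site_rates.tsv"))
    })
  }

  if ("slowfast" %in% config$stages) {
    stage("slowfast", {
      if (is.null(aln) || is.null(tree))
        stop("alignment and tree required")
      hyps <- config$hypotheses
      if (is.null(hyps)) {
        splits <- unrooted_splits(tree)
        sizes <- lengths(splits)
        pick <- which.min(abs(sizes - length(tree$tip.label) / 2))
        hyps <- list(hypothesis("true_split", splits[[pick]]))
      }
      curve <- support_curve(aln, tree, hyps, step = config$step,
                             n_bootstrap = config$n_bootstrap,
                             seed = config$seed, alpha = config$alpha,
                             K = config$K)
      outputs$curve <- write_support_curve(
        curve, file.path(config$out_dir, "curve.tsv"))
    })
  }

  if ("dollo" %in% config$stages) {
    stage("dollo", {
      if (is.null(traits) || is.null(tree))
        stop("trait matrix and rooted tree required")
      map <- dollo_reconstruct(tree, traits)
      outputs$states <- file.path(config$out_dir, "states.tsv")
      write.table(node_percentages(map), outputs$states, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      outputs$events <- file.path(config$out_dir, "events.tsv")
      write.table(gain_loss_table(map), outputs$events, sep = "\t",
                  quote = FALSE, row.names = FALSE)
    })
  }

  if ("profiles" %in% config$stages) {
    stage("profiles", {
      if (is.null(traits)) stop("trait matrix required")
      d <- profile_distance(traits)
      outputs$distances <- file.path(config$out_dir, "distances.tsv")
      write.table(data.frame(species = rownames(d), unclass(d),
                             check.names = FALSE),
                  outputs$distances, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      ord <- pcoa(d, n_axes = 2L)
      outputs$pcoa <- file.path(config$out_dir, "pcoa.tsv")
      write.table(data.frame(species = rownames(ord$coordinates),
                             ord$coordinates, check.names = FALSE),
                  outputs$pcoa, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  manifest <- list(
    package = "phylosf",
    version = as.character(utils::packageVersion("phylosf")),
    seed = config$seed,
    stages = config$stages,
    step = config$step,
    n_bootstrap = config$n_bootstrap,
    K = config$K,
    sim = config$sim[c("n_taxa", "tree_height", "alpha", "n_sites",
                       "loss_prob", "n_traits")],
    input_checksums = as.list(tools::md5sum(
      unlist(outputs[c("alignment", "tree", "traits")], use.names = FALSE))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  outputs$manifest <- manifest_path
  invisible(outputs)
}
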