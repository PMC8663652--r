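## End-to-end orchestration: search, indices, consensus, bootstrap and
## change mapping in one call, with all outputs written to a run directory.

#' Configure an analysis run
#'
#' @param input path to a character matrix file, or `"builtin:table1"` for
#'   the bundled study matrix.
#' @param dialect input dialect (ignored for the builtin matrix).
#' @param outgroup outgroup taxon; defaults to the builtin's outgroup, or
#'   the first taxon of a file input.
#' @param search `"exact"` (exhaustive), `"branch_and_bound"` or
#'   `"ratchet"`.
#' @param replications bootstrap replicates (0 skips the bootstrap).
#' @param iterations,trees_to_hold,characters_to_sample,random_constraint_level
#'   ratchet settings (used when `search = "ratchet"`).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for all stochastic stages.
#' @return a `run_config` list.
#' @export
run_config <- function(input = "builtin:table1",
                       dialect = c("plain", "nexus", "tnt"),
                       outgroup = NULL,
                       search = c("exact", "branch_and_bound", "ratchet"),
                       replications = 500,
                       iterations = 1000, trees_to_hold = 5,
                       characters_to_sample = 10,
                       random_constraint_level = 10,
                       out_dir = tempfile("morphpars_run_"),
                       seed = 0) {
  structure(list(input = input, dialect = match.arg(dialect),
                 outgroup = outgroup, search = match.arg(search),
                 replications = replications, iterations = iterations,
                 trees_to_hold = trees_to_hold,
                 characters_to_sample = characters_to_sample,
                 random_constraint_level = random_constraint_level,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run a complete cladistic analysis
#'
#' Performs tree search, computes homoplasy indices on the first most
#' parsimonious tree, takes the strict consensus, runs the bootstrap, maps
#' unambiguous changes per tree and across trees, and writes everything to
#' the configured output directory: `mpts.nwk`, `consensus.nwk`,
#' `support.tsv`, `changes.tsv`, `indices.tsv`, `summary.json` and
#' `run.log`.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory results (`search`,
#'   `indices`, `consensus`, `support`, `changes`, `shared_changes`,
#'   `summary`) and the output directory `out_dir`.
#' @export
run_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  say <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ..., "\n",
                           sep = "", file = logf, append = TRUE)
  say("morphpars ", as.character(utils::packageVersion("morphpars")),
      " seed=", config$seed)
  say("config: ", paste(names(config), unlist(lapply(config, paste,
      collapse = "/")), sep = "=", collapse = " "))

  if (identical(config$input, "builtin:table1")) {
    b <- bundled_study_matrix()
    m <- b$matrix; spec <- b$spec
    outgroup <- if (is.null(config$outgroup)) b$outgroup else config$outgroup
  } else {
    if (!file.exists(config$input)) {
      say("ERROR: input file not found: ", config$input)
      stop("input file not found: ", config$input)
    }
    m <- read_matrix(config$input, config$dialect)
    spec <- char_type_spec(m$n_chars)
    outgroup <- if (is.null(config$outgroup)) m$taxa[1] else config$outgroup
  }
  say("matrix: ", m$n_taxa, " taxa x ", m$n_chars, " characters; outgroup ",
      outgroup)

  res <- switch(config$search,
    exact = exhaustive_search(m, spec, outgroup = outgroup),
    branch_and_bound = branch_and_bound_search(m, spec, outgroup = outgroup),
    ratchet = ratchet_search(m, spec,
                             iterations = config$iterations,
                             trees_to_hold = config$trees_to_hold,
                             characters_to_sample = config$characters_to_sample,
                             random_constraint_level =
                               config$random_constraint_level,
                             seed = config$seed, outgroup = outgroup))
  say("search (", res$method, "): length ", res$best_length, ", ",
      length(res$trees), " MPT(s)")

  ind <- homoplasy_indices(res$trees[[1]], m, spec)
  cons <- strict_consensus(res$trees)
  rooted_mpts <- lapply(res$trees, root_on_outgroup, outgroup = outgroup)
  changes <- lapply(rooted_mpts, unambiguous_changes, m = m, spec = spec)
  shared <- shared_changes_across_mpts(res$trees, m, spec,
                                       outgroup = outgroup)
  supp <- NULL
  if (config$replications > 0) {
    supp <- bootstrap_support(m, spec, outgroup,
                              replications = config$replications,
                              seed = config$seed)
    say("bootstrap: ", config$replications, " replicates")
  }

  write_newick(rooted_mpts, file.path(config$out_dir, "mpts.nwk"))
  cons_out <- if (is.null(supp)) root_on_outgroup(cons, outgroup)
              else annotate_support(cons, supp)
  write_newick(cons_out, file.path(config$out_dir, "consensus.nwk"))
  write_indices_tsv(ind, file.path(config$out_dir, "indices.tsv"))
  all_changes <- do.call(rbind, c(lapply(seq_along(changes), function(i)
    cbind(tree = i, as.data.frame(changes[[i]]))),
    list(cbind(tree = "all", as.data.frame(shared)))))
  utils::write.table(all_changes, file.path(config$out_dir, "changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(supp))
    utils::write.table(as.data.frame(supp),
                       file.path(config$out_dir, "support.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    version = as.character(utils::packageVersion("morphpars")),
    seed = config$seed,
    settings = unclass(config)[setdiff(names(config), "out_dir")],
    n_taxa = m$n_taxa, n_chars = m$n_chars, outgroup = outgroup,
    method = res$method,
    length = res$best_length,
    n_mpts = length(res$trees),
    ci = ind$ci_2dp, ri = ind$ri_2dp,
    ci_full = ind$ci, ri_full = ind$ri,
    supports = if (is.null(supp)) NULL else
      stats::setNames(as.list(supp$support), supp$clade),
    synapomorphies = stats::setNames(
      lapply(split(shared, shared$clade), function(d)
        as.list(d[c("character", "from", "to", "classification")])),
      NULL)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done")
  invisible(list(search = res, indices = ind, consensus = cons,
                 support = supp, changes = changes, shared_changes = shared,
                 summary = summary, out_dir = config$out_dir))
}
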