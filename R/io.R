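#' Load a simulation configuration from YAML or JSON
#'
#' Reads a config file whose keys mirror the [sim_config()] arguments
#' (`N`, `L`, `mu` or `muL`, `s0`, `s_mode`, `E`, `E_mode`, `f0`,
#' `outcross_prob`, `crossover_mean`, `n_generations`, `record_times`,
#' `seed`), fills in the defaults for anything omitted, and validates the
#' result.  Unknown keys are an error (typo protection), as is any invariant
#' violation.  An empty file yields the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [sim_config()].
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  # keep YAML-1.1 boolean-like scalars (notably the key "N") as strings
  keep <- function(x) x
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path, handlers =
      list("bool#yes" = keep, "bool#no" = keep)),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)"))
  if (is.null(raw)) raw <- list()
  known <- setdiff(names(formals(sim_config)), "topology")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  }
  if (!is.null(raw[["mu"]]) && !is.null(raw[["muL"]])) {
    stop("config sets both mu and muL; give one")
  }
  if (!is.null(raw[["mu"]])) raw[["muL"]] <- NULL
  do.call(sim_config, raw)
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization, used to stamp output files so
#' that tables can be traced back to the exact run parameters.
#'
#' @param cfg A [sim_config()].
#' @return A 32-character hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- unclass(cfg)
  if (!is.null(plain$topology)) plain$topology <- unclass(plain$topology)
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

header_lines <- function(cfg) {
  c(paste0("# epiwindow ", as.character(utils::packageVersion("epiwindow"))),
    paste0("# config_hash: ", config_hash(cfg)),
    paste0("# seed: ", cfg$seed))
}

write_stamped_tsv <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) writeLines(header_lines(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an LD panel table as TSV
#'
#' The on-disk schema is the [compute_panel()] data frame (1-based site
#' indices, one row per pair); optional header comment lines carry the
#' package version, config hash, and seed.
#'
#' @param panel A panel data frame.
#' @param path Output path.
#' @param cfg Optional [sim_config()] for the provenance header.
#' @return `write_panel_tsv`: the path, invisibly.  `read_panel_tsv`: the
#'   panel data frame.
#' @export
write_panel_tsv <- function(panel, path, cfg = NULL) {
  write_stamped_tsv(panel, path, cfg)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read per-pair haplotype count tables as TSV
#'
#' Long format with columns `time`, `site_i`, `site_j`, `n00`, `n01`,
#' `n10`, `n11` — the interchange format through which externally supplied
#' haplotype counts enter the panel and detection stages.
#'
#' @param record A `"simulation_record"` (all recorded times are written),
#'   or a single count matrix from [all_pair_counts()] (then give `time`).
#' @param path Output path.
#' @param time Generation stamp when `record` is a bare count matrix.
#' @param cfg Optional config for the provenance header.
#' @return `write_haplotype_counts_tsv`: the path, invisibly.
#'   `read_haplotype_counts_tsv`: a data frame in the schema above.
#' @export
write_haplotype_counts_tsv <- function(record, path, time = NA_integer_,
                                       cfg = NULL) {
  to_df <- function(counts, t) {
    data.frame(time = t,
               site_i = attr(counts, "site_i"),
               site_j = attr(counts, "site_j"),
               n00 = counts[, "n00"], n01 = counts[, "n01"],
               n10 = counts[, "n10"], n11 = counts[, "n11"])
  }
  df <- if (inherits(record, "simulation_record")) {
    if (is.null(cfg)) cfg <- record$config
    do.call(rbind, Map(to_df, record$counts, record$times))
  } else {
    to_df(record, time)
  }
  write_stamped_tsv(df, path, cfg)
}

#' @rdname write_haplotype_counts_tsv
#' @export
read_haplotype_counts_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a population snapshot as two-symbol FASTA
#'
#' Allele 0 maps to 'A' and allele 1 (the deleterious allele) to 'G'; one
#' record per genome with ids `g<generation>_<index>`.  This is the
#' interchange format for binary alignments entering the LD stage from
#' outside the simulator.
#'
#' @param pop Population matrix.
#' @param path Output path.
#' @return `write_population_fasta`: the path, invisibly.
#'   `read_population_fasta`: a 0/1 population matrix with the generation
#'   attribute recovered from the ids when present.
#' @export
write_population_fasta <- function(pop, path) {
  g <- population_generation(pop)
  if (is.na(g)) g <- 0L
  chars <- matrix(c("A", "G")[pop + 1L], nrow = nrow(pop))
  seqs <- apply(chars, 1L, paste, collapse = "")
  names(seqs) <- sprintf("g%d_%d", g, seq_len(nrow(pop)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = max(80L, ncol(pop)))
  invisible(path)
}

#' @rdname write_population_fasta
#' @export
read_population_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  mat <- as.matrix(ss)
  if (!all(mat %in% c("A", "G"))) {
    stop("expected a two-symbol alignment over {A, G}")
  }
  pop <- matrix(as.integer(mat == "G"), nrow = nrow(mat))
  ids <- names(ss)
  g <- suppressWarnings(as.integer(sub("^g(\\d+)_.*$", "\\1", ids[1L])))
  attr(pop, "generation") <- if (is.na(g)) NA_integer_ else g
  pop
}

#' Write a clustering tree as Newick
#'
#' @param tree A [sample_and_tree()] result, an `ape::phylo`, or an
#'   `hclust` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  phy <- if (inherits(tree, "phylo")) tree
         else if (inherits(tree, "hclust")) ape::as.phylo(tree)
         else if (is.list(tree) && !is.null(tree$phylo)) tree$phylo
         else stop("cannot interpret 'tree' as a tree")
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Run manifest
#'
#' Records everything needed to reproduce a pipeline run bit-exactly: the
#' resolved configuration, master and derived child seeds, the package
#' version, the output files written, and a wall-clock stamp.
#'
#' @param cfg A [sim_config()].
#' @param files Named character vector / list of output paths per stage.
#' @param child_seeds Integer child seeds actually used (if any).
#' @return A list of class `"run_manifest"`.
#' @export
run_manifest <- function(cfg, files = character(), child_seeds = integer()) {
  structure(list(config = unclass(cfg),
                 topology = if (!is.null(cfg$topology))
                   unclass(cfg$topology) else NULL,
                 config_hash = config_hash(cfg),
                 master_seed = cfg$seed,
                 child_seeds = as.integer(child_seeds),
                 version = as.character(utils::packageVersion("epiwindow")),
                 files = as.list(files),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `"run_manifest"`.
#' @param path Output path (JSON).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
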