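#' Read a protein FASTA file
#'
#' Wrapped or unwrapped lines are accepted; sequences are upper-cased and a
#' trailing `*` stop character is stripped with a warning. Duplicate ids and
#' empty sequences are errors.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences; names are the full header
#'   lines' first tokens, with descriptions in the `"description"` attribute.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(ss))
  if (any(endsWith(seqs, "*"))) {
    warning("stripped '*' stop characters")
    seqs <- sub("\\*+$", "", seqs)
  }
  if (any(!nzchar(seqs))) stop("empty sequence for id: ", ids[!nzchar(seqs)][1])
  names(seqs) <- ids
  attr(seqs, "description") <- setNames(desc, ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs))) stop("sequences must be named")
  con <- file(path, "w"); on.exit(close(con))
  desc <- attr(seqs, "description")
  for (id in names(seqs)) {
    hdr <- if (!is.null(desc) && nzchar(desc[[id]])) paste(id, desc[[id]]) else id
    writeLines(paste0(">", hdr), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a tree as newick
#'
#' Bootstrap supports (node labels) are preserved as internal-node labels;
#' branch lengths are written with 6 significant digits. Tip names containing
#' spaces or newick metacharacters are quoted.
#'
#' @param tree an `ape::phylo` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree) || !inherits(tree, "phylo") || ape::Ntip(tree) == 0)
    stop("empty tree")
  tr <- tree
  bad <- grepl("[ ():,;]", tr$tip.label)
  tr$tip.label[bad] <- paste0("'", tr$tip.label[bad], "'")
  ape::write.tree(tr, file = path, digits = 6)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path newick file.
#' @return An `ape::phylo` tree (internal-node labels hold supports).
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write / read a spectroscopy matrix as CSV
#'
#' Layout: first column `wavelength` (nm, integers where on-grid), remaining
#' column headers are the time (ms) or pH values; `.` decimal separator.
#'
#' @param wavelength wavelength grid.
#' @param cols time or pH values (column headers).
#' @param mat wavelength-by-column matrix.
#' @param path CSV path.
#' @return `path` invisibly, or for the reader a list with `wavelength`,
#'   `cols`, `mat`.
#' @export
write_spectro_csv <- function(wavelength, cols, mat, path) {
  df <- data.frame(wavelength = wavelength, mat, check.names = FALSE)
  names(df) <- c("wavelength", format(cols, trim = TRUE, digits = 10))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectro_csv
#' @export
read_spectro_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  list(wavelength = df[[1]],
       cols = as.numeric(names(df)[-1]),
       mat = as.matrix(df[, -1, drop = FALSE]))
}

#' Run configuration
#'
#' One structured object carrying the master seed and the tunables of every
#' stage; round-trips losslessly through YAML. Unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param master_seed integer master seed; all stage seeds derive from it via
#'   [substream_seed()].
#' @param out_dir run output directory.
#' @param n_genomes,genes_per_genome,decoys_per_genome generator sizes.
#' @param min_identity,min_coverage screening thresholds.
#' @param bootstrap_n bootstrap replicate count (default 100).
#' @param flash_noise_sigma,titration_noise_sigma simulation noise levels.
#' @return A list of class `run_config`.
#' @export
run_config <- function(master_seed = 1L, out_dir = "cyrho_run",
                       n_genomes = 10L, genes_per_genome = 1L,
                       decoys_per_genome = 5L, min_identity = 25,
                       min_coverage = 0.6, bootstrap_n = 100L,
                       flash_noise_sigma = 0.001,
                       titration_noise_sigma = 0.002) {
  structure(list(master_seed = as.integer(master_seed), out_dir = out_dir,
                 n_genomes = as.integer(n_genomes),
                 genes_per_genome = as.integer(genes_per_genome),
                 decoys_per_genome = as.integer(decoys_per_genome),
                 min_identity = min_identity, min_coverage = min_coverage,
                 bootstrap_n = as.integer(bootstrap_n),
                 flash_noise_sigma = flash_noise_sigma,
                 titration_noise_sigma = titration_noise_sigma),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for [write_config()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}
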