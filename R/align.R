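#' Alignment parameters
#'
#' @param matrix_name substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open positive gap-opening penalty (default 11).
#' @param gap_extend positive gap-extension penalty (default 1).
#' @param mode `"global"` for global alignment with free end gaps (overlap),
#'   or `"local"`.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(matrix_name = "BLOSUM62", gap_open = 11,
                             gap_extend = 1, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  structure(list(matrix_name = matrix_name, gap_open = gap_open,
                 gap_extend = gap_extend, mode = mode),
            class = "alignment_params")
}

.subst_cache <- new.env(parent = emptyenv())

subst_matrix <- function(name) {
  if (!exists(name, envir = .subst_cache)) {
    e <- new.env()
    data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .subst_cache)
  }
  get(name, envir = .subst_cache)
}

check_aa <- function(x, what = "sequence") {
  if (!nzchar(x)) stop(what, " must be non-empty")
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x))
    stop(what, " contains non-amino-acid characters")
  invisible(x)
}

#' Optimal pairwise protein alignment
#'
#' Affine-gap alignment under a BLOSUM-type scoring scheme. In `"global"`
#' mode end gaps are free (overlap alignment), which is the behaviour wanted
#' when mapping full-length homologs of slightly different length onto a
#' reference numbering.
#'
#' @param query,reference amino-acid sequences (single strings).
#' @param params an [alignment_params()].
#' @return A list of class `pairwise_alignment`: `query_aln` / `ref_aln`
#'   (gapped strings of equal length), `score`, `percent_identity` (over
#'   aligned columns, gaps counted in the denominator), `aligned_length`,
#'   `query_start` / `ref_start` (1-based position of the first aligned
#'   residue in each unaligned sequence), and `ref_coverage` (fraction of the
#'   reference inside the aligned region).
#' @export
align_pair <- function(query, reference, params = alignment_params()) {
  check_aa(query, "query"); check_aa(reference, "reference")
  type <- if (params$mode == "global") "overlap" else "local"
  pa <- Biostrings::pairwiseAlignment(
    query, reference, type = type,
    substitutionMatrix = subst_matrix(params$matrix_name),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  qa <- as.character(Biostrings::alignedPattern(pa))
  ra <- as.character(Biostrings::alignedSubject(pa))
  structure(list(
    query_aln = qa, ref_aln = ra,
    score = Biostrings::score(pa),
    percent_identity = Biostrings::pid(pa, type = "PID1"),
    aligned_length = nchar(qa),
    query_start = Biostrings::start(Biostrings::pattern(pa)),
    ref_start = Biostrings::start(Biostrings::subject(pa)),
    ref_coverage = Biostrings::width(Biostrings::subject(pa)) / nchar(reference)
  ), class = "pairwise_alignment")
}

#' Screen a proteome for rhodopsin homologs
#'
#' Aligns every protein against every labelled reference and keeps, per
#' protein, the best-scoring reference if it clears the identity and coverage
#' thresholds. The defaults (25% identity, 0.6 reference coverage) separate
#' diverged homologs from unrelated decoys with margin. The same machinery
#' screens against any reference family, e.g. a retinal-biosynthesis (diox1)
#' panel to produce presence flags.
#'
#' @param proteome named character vector of protein sequences (may be empty).
#' @param references named character vector of reference sequences.
#' @param ref_clades optional named character vector mapping reference id to
#'   clade label (carried onto hits).
#' @param params an [alignment_params()].
#' @param min_identity minimum percent identity over aligned columns.
#' @param min_coverage minimum fraction of the reference covered.
#' @param genome_id optional genome label stamped onto every hit.
#' @return A data.frame of hits: `protein_id`, `genome_id`,
#'   `best_reference_id`, `ref_clade`, `score`, `percent_identity`,
#'   `aligned_length`, `ref_coverage`. Zero rows when nothing passes.
#' @export
screen_proteome <- function(proteome, references, ref_clades = NULL,
                            params = alignment_params(),
                            min_identity = 25, min_coverage = 0.6,
                            genome_id = NA_character_) {
  if (length(references) == 0L) stop("references must be non-empty")
  if (is.null(names(references))) stop("references must be named")
  empty <- data.frame(protein_id = character(0), genome_id = character(0),
                      best_reference_id = character(0), ref_clade = character(0),
                      score = numeric(0), percent_identity = numeric(0),
                      aligned_length = integer(0), ref_coverage = numeric(0))
  if (length(proteome) == 0L) return(empty)
  if (is.null(names(proteome))) stop("proteome sequences must be named")
  for (s in proteome) check_aa(s, "proteome sequence")
  type <- if (params$mode == "global") "overlap" else "local"
  sm <- subst_matrix(params$matrix_name)
  qset <- Biostrings::AAStringSet(proteome)
  np <- length(proteome); nr <- length(references)
  scores <- pids <- covs <- alens <- matrix(NA_real_, np, nr)
  # one vectorised call per reference: every protein against that reference
  for (j in seq_len(nr)) {
    pa <- Biostrings::pairwiseAlignment(
      qset, references[[j]], type = type, substitutionMatrix = sm,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    scores[, j] <- Biostrings::score(pa)
    pids[, j] <- Biostrings::pid(pa, type = "PID1")
    covs[, j] <- Biostrings::width(Biostrings::subject(pa)) / nchar(references[[j]])
    alens[, j] <- Biostrings::nchar(pa)
  }
  rows <- list()
  for (i in seq_len(np)) {
    j <- which.max(scores[i, ])
    if (pids[i, j] >= min_identity && covs[i, j] >= min_coverage) {
      rid <- names(references)[j]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = names(proteome)[i], genome_id = genome_id,
        best_reference_id = rid,
        ref_clade = if (is.null(ref_clades)) NA_character_ else unname(ref_clades[rid]),
        score = scores[i, j], percent_identity = pids[i, j],
        aligned_length = as.integer(alens[i, j]), ref_coverage = covs[i, j])
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Screen a set of genomes
#'
#' Convenience wrapper running [screen_proteome()] over every proteome in a
#' [gen_genome_set()]-shaped object (or any named list of proteomes).
#'
#' @param proteomes named list of named sequence vectors, one per genome.
#' @inheritParams screen_proteome
#' @return One hits data.frame over all genomes.
#' @export
screen_genomes <- function(proteomes, references, ref_clades = NULL,
                           params = alignment_params(),
                           min_identity = 25, min_coverage = 0.6) {
  out <- lapply(names(proteomes), function(gid)
    screen_proteome(proteomes[[gid]], references, ref_clades, params,
                    min_identity, min_coverage, genome_id = gid))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
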